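wx <- generate_worked_example()

test_that("state vectors count states in alphabet order", {
  Q5 <- build_state_vector(wx$alignment, wx$partition$query, 5)
  R5 <- build_state_vector(wx$alignment, wx$partition$reference, 5)
  expect_equal(unname(unclass(Q5)), c(0L, 0L, 3L, 0L, 0L, 0L))
  expect_equal(unname(unclass(R5)), c(2L, 0L, 0L, 2L, 0L, 0L))
  expect_equal(names(Q5), c("A", "C", "G", "T", "-", "N"))
  expect_error(build_state_vector(wx$alignment, wx$partition$query, 25),
               "out of range")
  expect_error(build_state_vector(wx$alignment, character(0), 1), "empty")
})

test_that("L1 norm equals group size at every position (conservation)", {
  for (p in seq_len(alignment_length(wx$alignment))) {
    expect_equal(sum(build_state_vector(wx$alignment, wx$partition$query, p)), 3L)
    expect_equal(sum(build_state_vector(wx$alignment, wx$partition$reference, p)), 4L)
  }
})

test_that("discriminative power matches hand-computed values", {
  expect_identical(discriminative_power(sv(c(0, 0, 3, 0, 0, 0)),
                                        sv(c(2, 0, 0, 2, 0, 0))), 1)
  expect_identical(discriminative_power(sv(c(3, 0, 0, 0, 0, 0)),
                                        sv(c(3, 0, 0, 0, 0, 0))), 0)
  # |3-1| + |0-2| + |0-1| = 5 over 3 + 4 = 7
  expect_equal(discriminative_power(sv(c(3, 0, 0, 0, 0, 0)),
                                    sv(c(1, 2, 1, 0, 0, 0))), 5 / 7)
  expect_error(discriminative_power(sv(rep(0, 6)), sv(c(1, 0, 0, 0, 0, 0))),
               "all-zero")
  expect_error(
    discriminative_power(sv(c(1, 0, 0, 0, 0, 0)), sv(rep(1, 36), sig_pair_states())),
    "different state lists")
})

test_that("d-power is in [0,1], symmetric, and 1 iff supports disjoint", {
  set.seed(7)
  for (i in 1:200) {
    q <- sv(rpois(6, 1))
    r <- sv(rpois(6, 1))
    if (sum(q) == 0 || sum(r) == 0) next
    d <- discriminative_power(q, r)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_identical(d, discriminative_power(r, q))
    expect_identical(d == 1, !any(unclass(q) > 0 & unclass(r) > 0))
  }
})

test_that("vector_rank counts non-zero dimensions", {
  expect_equal(vector_rank(sv(c(0, 0, 3, 0, 0, 0))), 1L)
  expect_equal(vector_rank(sv(c(2, 0, 0, 2, 0, 0))), 2L)
  expect_equal(vector_rank(sv(rep(0, 6))), 0L)
  set.seed(8)
  for (i in 1:50) {
    v <- sv(rpois(6, 2))
    expect_lte(vector_rank(v), 6L)
    if (sum(v) > 0) expect_gte(vector_rank(v), 1L)
  }
})

test_that("consensus state is the maximal state, ties to earliest in alphabet", {
  cs <- consensus_state(sv(c(0, 0, 3, 0, 0, 0)))
  expect_equal(cs$state, "G")
  expect_true(cs$is_uniform)

  cs <- consensus_state(sv(c(2, 0, 0, 2, 0, 0)))  # A/T tie -> A
  expect_equal(cs$state, "A")
  expect_false(cs$is_uniform)

  cs <- consensus_state(sv(c(0, 5, 0, 0, 0, 0)))
  expect_equal(cs$state, "C")
  expect_true(cs$is_uniform)

  expect_error(consensus_state(sv(rep(0, 6))), "all-zero")
})
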