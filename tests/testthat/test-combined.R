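wx <- generate_worked_example()
ranked <- rank_positions(position_metrics(wx$alignment, wx$partition))

test_that("pair enumeration respects the k-window", {
  p <- c(8L, 19L, 20L, 23L)
  got <- enumerate_pairs(p, k = 5)
  expect_equal(got, rbind(c(19L, 20L), c(19L, 23L), c(20L, 23L)),
               ignore_attr = TRUE)

  expect_equal(nrow(enumerate_pairs(p, k = 1)), 0L)
  expect_equal(nrow(enumerate_pairs(integer(0), k = 5)), 0L)
  expect_equal(enumerate_pairs(c(1L, 2L, 3L), k = 3),
               rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)), ignore_attr = TRUE)
  expect_error(enumerate_pairs(p, k = 0), "k must be")
  expect_error(enumerate_pairs(c(3L, 1L), k = 2), "strictly increasing")
})

test_that("enumerated pair set is non-decreasing in k and matches brute force", {
  p <- c(2L, 5L, 6L, 11L, 14L)
  all_pairs <- t(utils::combn(p, 2L))
  prev <- 0L
  for (k in 1:15) {
    got <- enumerate_pairs(p, k)
    # oracle: brute-force filter of all pairs
    want <- all_pairs[all_pairs[, 2] - all_pairs[, 1] < k, , drop = FALSE]
    expect_equal(unname(got), unname(want[order(want[, 1], want[, 2]), ,
                                          drop = FALSE]))
    expect_gte(nrow(got), prev)
    prev <- nrow(got)
  }
})

test_that("pair state vectors count ordered state pairs", {
  Q2 <- build_pair_vector(wx$alignment, wx$partition$query, 19, 20)
  R2 <- build_pair_vector(wx$alignment, wx$partition$reference, 19, 20)
  expect_equal(sum(Q2), 3L)
  expect_equal(sum(R2), 4L)
  expect_equal(unclass(Q2)[["CA"]], 3L)
  expect_equal(vector_rank(Q2), 1L)
  nz <- names(R2)[unclass(R2) > 0]
  expect_setequal(nz, c("GA", "CT"))
  expect_equal(unclass(R2)[["GA"]], 2L)
  expect_equal(unclass(R2)[["CT"]], 2L)
})

test_that("combined characters of the worked example classify as expected", {
  cc <- find_combined_characters(wx$alignment, wx$partition, ranked, k = 5)
  expect_equal(nrow(cc), 3L)
  expect_equal(cc$i[1], 19L)
  expect_equal(cc$j[1], 20L)
  expect_equal(cc$d_power[1], 1)
  expect_equal(cc$q_rank[1], 1L)
  expect_equal(cc$r_rank[1], 2L)
  expect_equal(cc$char_class[1], "asymmetric")
  expect_equal(cc$query_pair[1], "CA")
  rest <- cc[cc$char_class != "asymmetric", ]
  expect_setequal(paste(rest$i, rest$j), c("19 23", "20 23"))
  expect_true(all(rest$char_class == "noisy"))
  expect_equal(sum(cc$is_signature), 1L)
})

test_that("k=1 yields nothing; a wide window reaches position 8", {
  expect_equal(nrow(find_combined_characters(wx$alignment, wx$partition,
                                             ranked, k = 1)), 0L)
  cc <- find_combined_characters(wx$alignment, wx$partition, ranked, k = 20)
  expect_setequal(paste(cc$i, cc$j),
                  c("8 19", "8 20", "8 23", "19 20", "19 23", "20 23"))
  # window >= alignment length == unwindowed all-pairs enumeration
  cc_all <- find_combined_characters(wx$alignment, wx$partition, ranked,
                                     k = alignment_length(wx$alignment))
  expect_equal(nrow(cc_all), choose(4, 2))
  expect_identical(cc, cc_all)
})

test_that("identical pair vectors classify as conserved with d = 0", {
  Q2 <- build_pair_vector(wx$alignment, wx$partition$query, 19, 20)
  got <- classify_pair(Q2, Q2)
  expect_equal(got$d_power, 0)
  expect_equal(got$char_class, "conserved")
  expect_error(classify_pair(sv(c(1, rep(0, 5))), sv(c(1, rep(0, 5)))),
               "36")
})

test_that("pairs of candidate positions always have pair q-rank 1", {
  set.seed(19)
  for (rep in 1:10) {
    n_pos <- 12L
    plan <- stats::setNames(rep("noisy", 4), sample(n_pos, 4))
    fx <- generate_random_fixture(3, 4, n_pos, plan, seed = 100 + rep)
    noisy <- sort(as.integer(names(plan)))
    for (r in seq_len(nrow(enumerate_pairs(noisy, k = n_pos)))) {
      pr <- enumerate_pairs(noisy, k = n_pos)[r, ]
      Q2 <- build_pair_vector(fx$alignment, fx$partition$query, pr[1], pr[2])
      expect_equal(vector_rank(Q2), 1L)
      R2 <- build_pair_vector(fx$alignment, fx$partition$reference, pr[1], pr[2])
      d <- discriminative_power(Q2, R2)
      expect_identical(d == 1, !any(unclass(Q2) > 0 & unclass(R2) > 0))
    }
  }
})
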