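wx <- generate_worked_example()

test_that("candidacy requires a uniform, N-free query", {
  expect_true(is_candidate(sv(c(0, 0, 3, 0, 0, 0))))
  expect_false(is_candidate(sv(c(2, 1, 0, 0, 0, 0))))  # q-rank 2
  expect_false(is_candidate(sv(c(0, 0, 0, 0, 0, 3))))  # N present
  expect_true(is_candidate(sv(c(0, 0, 0, 0, 3, 0))))   # uniform gap qualifies
})

test_that("classification follows the metric table exactly", {
  Q1 <- build_state_vector(wx$alignment, wx$partition$query, 1)
  R1 <- build_state_vector(wx$alignment, wx$partition$reference, 1)
  expect_equal(classify(Q1, R1), "binary")
  expect_equal(classify(sv(c(0, 0, 3, 0, 0, 0)), sv(c(2, 0, 0, 2, 0, 0))),
               "asymmetric")
  # shared T => d < 1; reference rank 3 => noisy
  expect_equal(classify(sv(c(0, 0, 0, 3, 0, 0)), sv(c(1, 0, 0, 2, 1, 0))),
               "noisy")
  # same single state, unequal sizes: d = 1/7 < 1, q = r = 1 => conserved
  expect_equal(classify(sv(c(3, 0, 0, 0, 0, 0)), sv(c(4, 0, 0, 0, 0, 0))),
               "conserved")
  expect_equal(classify(sv(c(2, 1, 0, 0, 0, 0)), sv(c(3, 0, 0, 0, 0, 0))),
               "non_candidate")
})

test_that("worked-example positions carry the expected metrics", {
  m5 <- compute_position_metrics(wx$alignment, wx$partition, 5)
  expect_equal(m5$d_power, 1)
  expect_equal(m5$q_rank, 1L)
  expect_equal(m5$r_rank, 2L)
  expect_equal(m5$char_class, "asymmetric")
  expect_true(m5$is_signature)
  expect_equal(m5$query_state, "G")
  expect_true(m5$query_uniform)

  expect_equal(compute_position_metrics(wx$alignment, wx$partition, 16)$char_class,
               "conserved")
  expect_equal(compute_position_metrics(wx$alignment, wx$partition, 20)$char_class,
               "noisy")
})

test_that("signature characters are exactly the binary and asymmetric rows", {
  metrics <- position_metrics(wx$alignment, wx$partition)
  expect_true(is_signature(metrics[metrics$position == 5, ]))
  expect_false(is_signature(metrics[metrics$position == 8, ]))   # noisy
  expect_false(is_signature(metrics[metrics$position == 15, ]))  # conserved
  expect_identical(is_signature(metrics),
                   metrics$char_class %in% c("binary", "asymmetric"))
  # equivalent formulation: candidate with d-power 1
  expect_identical(
    is_signature(metrics),
    metrics$char_class != "non_candidate" & metrics$d_power == 1)
})

test_that("reference N states are counted and flagged", {
  ca <- column_alignment(c("A", "A"), c("C", "N", "N"))
  m <- compute_position_metrics(ca$alignment, ca$partition, 1)
  expect_true(m$ref_has_missing)
  expect_equal(m$r_rank, 2L)             # C and N both count
  expect_equal(m$char_class, "asymmetric")  # N can never match a candidate
  ca2 <- column_alignment(c("A", "A"), c("C", "C"))
  expect_false(compute_position_metrics(ca2$alignment, ca2$partition, 1)$ref_has_missing)
})

test_that("ranking is lexicographic with position as final tie-break", {
  rows <- data.frame(
    position = 1:3,
    d_power = c(1, 1, 0.5), q_rank = c(1L, 1L, 1L), r_rank = c(2L, 1L, 2L),
    query_state = "A", query_uniform = TRUE, reference_state = "C",
    reference_uniform = TRUE, char_class = "noisy", is_signature = FALSE,
    ref_has_missing = FALSE, stringsAsFactors = FALSE)
  ranked <- rank_positions(rows)
  expect_equal(ranked$position, c(2L, 1L, 3L))  # (1,1,1) < (1,1,2) < (.5,1,2)
  expect_equal(ranked$rank, 1:3)

  # all metrics tied: position ascending
  rows$d_power <- 1; rows$r_rank <- 2L
  expect_equal(rank_positions(rows)$position, 1:3)

  expect_equal(rank_positions(rows[2, , drop = FALSE])$position, 2L)
  rows$position <- c(1L, 1L, 3L)
  expect_error(rank_positions(rows), "duplicate position")
})

test_that("ranked table covers each position once and orders signatures first", {
  ranked <- rank_positions(position_metrics(wx$alignment, wx$partition))
  expect_setequal(ranked$position, 1:24)
  idx <- function(cls) which(ranked$char_class == cls)
  expect_true(max(idx("binary")) < min(idx("asymmetric")))
  expect_true(all(ranked$d_power[ranked$is_signature] == 1))
  # every d=1 row precedes every d<1 row
  expect_true(max(which(ranked$d_power == 1)) < min(which(ranked$d_power < 1)))
})

test_that("vector classification agrees with the set-based oracle", {
  set.seed(31)
  states <- sig_states()
  for (i in 1:500) {
    q <- sample(states, sample(1:6, 1), replace = TRUE)
    r <- sample(states, sample(1:6, 1), replace = TRUE)
    ca <- column_alignment(q, r)
    got <- compute_position_metrics(ca$alignment, ca$partition, 1)$char_class
    expect_identical(got, oracle_classify(q, r))
  }
})
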