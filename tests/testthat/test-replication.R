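test_that("run extraction matches the definition and the exhaustive oracle", {
  rl <- run_lengths(c("S1", "S1", "S0", "S1"))
  expect_equal(rl$state, c("S1", "S0", "S1"))
  expect_equal(rl$length, c(2L, 1L, 1L))
  # every binary sequence of length <= 12 against the brute-force oracle
  mismatches <- 0L
  for (len in 1:12) {
    for (code in 0:(2^len - 1)) {
      x <- as.integer(intToBits(code))[1:len]
      got <- run_lengths(x)
      want <- oracle_runs(as.character(x))
      if (!identical(got$state, want$state) ||
          !identical(as.integer(got$length), want$length)) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("run-length totals conserve the state counts in every file", {
  ft <- with_cache("straight_table",
                   generate_feature_table(synthetic_params(), seed = 8,
                                          table_cv = 0.02))
  d <- file_run_lengths(ft$annotations, ft$calls)
  tot <- d$histogram |>
    dplyr::group_by(state) |>
    dplyr::summarise(n = sum(length * count))
  lab_truth <- table(ft$calls$pattern != "S0")
  expect_equal(tot$n[tot$state == "S0"], unname(lab_truth["FALSE"]))
  expect_equal(tot$n[tot$state == "labelled"], unname(lab_truth["TRUE"]))
})

test_that("i.i.d. labelling yields geometric run lengths", {
  set.seed(31)
  n <- 10000
  p <- 0.3
  ann <- tibble::tibble(id = seq_len(n), layer = "epidermis", file = 1,
                        z_root = seq_len(n))
  calls <- tibble::tibble(id = seq_len(n),
                          pattern = ifelse(runif(n) < p, "S1", "S0"))
  d <- file_run_lengths(ann, calls)
  h <- d$histogram[d$histogram$state == "labelled", ]
  R <- sum(h$count)
  for (k in 1:6) {
    q <- p^(k - 1) * (1 - p)
    expected <- R * q
    se <- sqrt(R * q * (1 - q))
    observed <- if (k %in% h$length) h$count[h$length == k] else 0
    expect_lte(abs(observed - expected), 3 * se)
  }
})

test_that("Markov patch labelling lengthens runs beyond the i.i.d. law", {
  p_iid <- small_root_params(edu_cluster_rho = 0)
  p_blk <- small_root_params(edu_cluster_rho = 0.5)
  m_iid <- generate_feature_table(p_iid, seed = 6)
  m_blk <- generate_feature_table(p_blk, seed = 6)
  r_iid <- file_run_lengths(m_iid$annotations, m_iid$calls)
  r_blk <- file_run_lengths(m_blk$annotations, m_blk$calls)
  mean_of <- function(d) {
    d$mean_length$mean_length[d$mean_length$state == "labelled"]
  }
  expect_gt(mean_of(r_blk), mean_of(r_iid))
})

test_that("EdU patterns are classified from the stack with ground-truth accuracy", {
  gr <- small_root()
  calls <- classify_edu_pattern(gr$stack, gr$labels, run_config())
  m <- dplyr::inner_join(calls, gr$truth[, c("id", "pattern", "n_spots")],
                         by = "id")
  expect_gte(mean(m$pattern.x == m$pattern.y), 0.95)
  s2 <- m[m$pattern.y == "S2", ]
  expect_true(all(abs(s2$n_spots.x - s2$n_spots.y) <= 1))
  # uniform rescaling of the EdU channel leaves every call unchanged
  scaled <- gr$stack
  scaled$channels$edu <- scaled$channels$edu * 12.5
  scaled$bit_depth <- scaled$bit_depth * 12.5
  calls2 <- classify_edu_pattern(scaled, gr$labels, run_config())
  expect_equal(calls2$pattern, calls$pattern)
  # no EdU signal anywhere: everything is S0
  dark <- gr$stack
  dark$channels$edu[] <- 0
  expect_true(all(classify_edu_pattern(dark, gr$labels)$pattern == "S0"))
})

test_that("timecourse homogeneity statistics match hand computation", {
  calls <- tibble::tibble(
    pattern = c(rep(c("S1", "S0"), c(20, 80)), rep(c("S1", "S0"), c(60, 40))),
    time = rep(c(45, 300), each = 100)
  )
  tc <- pattern_timecourse(calls)
  expect_equal(tc$statistic, 100 / 3, tolerance = 1e-10) # sum (O-E)^2/E
  expect_lt(tc$p_value, 1e-6)
  expect_true(tc$monotone)
  same <- tibble::tibble(pattern = rep(rep(c("S0", "S1", "S2"), c(5, 3, 2)),
                                       2),
                         time = rep(c(45, 300), each = 10))
  tc0 <- pattern_timecourse(same)
  expect_equal(tc0$statistic, 0)
  expect_equal(tc0$p_value, 1)
  expect_error(pattern_timecourse(same[same$time == 45, ]), "2 time points")
})

test_that("late-replicating (spotted) nuclei colocalize with heterochromatin", {
  gr <- small_root()
  calls <- classify_edu_pattern(gr$stack, gr$labels, run_config())
  mo <- mark_overlap_by_pattern(calls, gr$stack, gr$labels)
  s <- mo$summary
  het_s2 <- s$mean_overlap[s$pattern == "S2" & s$mark == "h3k9me2"]
  het_s1 <- s$mean_overlap[s$pattern == "S1" & s$mark == "h3k9me2"]
  expect_gt(het_s2, het_s1)
  # identical and disjoint masks give overlap 1 and 0
  dims <- c(10, 10, 6)
  lab <- array(0L, dims); lab[3:8, 3:8, 2:5] <- 1L
  edu <- array(0, dims); mk <- array(0, dims)
  edu[lab == 1L] <- 50
  mk[lab == 1L] <- 50
  stk1 <- voxel_stack(list(edu = edu, m = mk), c(1, 1, 1))
  c1 <- tibble::tibble(id = 1L, pattern = "S1")
  o1 <- mark_overlap_by_pattern(c1, stk1, lab, marks = "m")
  expect_equal(o1$per_nucleus$overlap, 1)
  mk2 <- array(0, dims)
  mk2[lab == 0L] <- 50
  o0 <- mark_overlap_by_pattern(c1, voxel_stack(list(edu = edu, m = mk2),
                                                c(1, 1, 1)), lab,
                                marks = "m")
  expect_equal(o0$per_nucleus$overlap, 0)
})

test_that("cluster-distribution comparison is calibrated and discriminates", {
  ann <- tibble::tibble(id = 1:100, layer = "a", file = 1, z_root = 1:100)
  mk <- function(pat) tibble::tibble(id = 1:100, pattern = pat)
  set.seed(41)
  d1 <- file_run_lengths(ann, mk(sample(c("S0", "S1"), 100, TRUE)))
  same <- compare_cluster_distributions(d1, d1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # all-singletons vs all-runs-of-five: maximal heterogeneity
  h1 <- structure(list(histogram = tibble::tibble(state = "labelled",
                                                  length = 1L, count = 100L)),
                  class = "cluster_distribution")
  h5 <- structure(list(histogram = tibble::tibble(state = "labelled",
                                                  length = 5L, count = 100L)),
                  class = "cluster_distribution")
  far <- compare_cluster_distributions(h1, h5)
  expect_equal(far$statistic, 200)
  expect_lt(far$p_value, 1e-6)
})

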