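test_that("hue mapping places red, overlay and green in their ranges", {
  # pure red -> 0; balanced overlay -> yellow (~42); pure green -> ~85
  expect_equal(hue_from_rg(10, 0), 0)
  expect_equal(hue_from_rg(10, 10), 42)
  expect_equal(hue_from_rg(0, 10), 85)
  expect_true(is.na(hue_from_rg(0, 0)))
  # a hue of 10 falls in the exclusive-red range 0-15
  g_for_hue10 <- 10 / 256 * 360 / 60 # g/r ratio giving 14 degrees
  fr <- hue_overlap_fractions(red = 1, green = g_for_hue10 * 0.99)
  expect_equal(fr$red_exclusive, 1)
})

test_that("overlap fractions sum to one and respect degenerate cases", {
  set.seed(5)
  r <- runif(500); g <- runif(500)
  fr <- hue_overlap_fractions(r, g)
  expect_equal(fr$red_exclusive + fr$overlap + fr$green_exclusive, 1)
  # uniform rescaling changes nothing
  expect_equal(hue_overlap_fractions(7.3 * r, 7.3 * g), fr)
  # identical channels are pure overlay; disjoint channels never overlap
  expect_equal(hue_overlap_fractions(r, r)$overlap, 1)
  mask <- c(rep(TRUE, 250), rep(FALSE, 250))
  disj <- hue_overlap_fractions(r * mask, g * !mask)
  expect_equal(disj$overlap, 0)
  expect_equal(disj$red_exclusive + disj$green_exclusive, 1)
  expect_error(hue_overlap_fractions(r, g, mask = rep(FALSE, 500)),
               "empty mask")
})

make_ball_stack <- function(dims = c(24, 24, 16), vx = c(0.5, 0.5, 0.5),
                            spot_angle = NULL) {
  ctr <- dims * vx / 2
  labels <- array(0L, dims)
  vol <- array(0, dims)
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    p <- (c(i, j, k) - 0.5) * vx
    if (sum((p - ctr)^2) <= 4^2) {
      labels[i, j, k] <- 1L
      vol[i, j, k] <- 10
      if (!is.null(spot_angle)) {
        sp <- ctr + 3.2 * c(cos(spot_angle), sin(spot_angle), 0)
        vol[i, j, k] <- vol[i, j, k] +
          100 * max(0, exp(-sum((p - sp)^2) / (2 * 0.4^2)) - exp(-4.5))
      }
    }
  }
  list(stack = voxel_stack(list(dna = vol), vx), labels = labels)
}

test_that("peripheral profiles are flat for uniform nuclei and peak at speckles", {
  flat <- make_ball_stack()
  pf <- peripheral_profile(flat$stack, flat$labels, 1, "dna")
  expect_lt(diff(range(pf$intensity, na.rm = TRUE)), 1e-6)
  spot <- make_ball_stack(spot_angle = pi / 3)
  ps <- peripheral_profile(spot$stack, spot$labels, 1, "dna")
  peak <- ps$angle[which.max(ps$intensity)]
  step <- 2 * pi / nrow(ps)
  expect_lt(min(abs(peak - pi / 3), 2 * pi - abs(peak - pi / 3)), 2 * step)
})

test_that("peripheral profiles are rotation-equivariant", {
  a1 <- make_ball_stack(spot_angle = 0)
  a2 <- make_ball_stack(spot_angle = pi / 2)
  p1 <- peripheral_profile(a1$stack, a1$labels, 1, "dna")
  p2 <- peripheral_profile(a2$stack, a2$labels, 1, "dna")
  n <- nrow(p1)
  xc <- vapply(seq_len(n) - 1, function(s) {
    stats::cor(p1$intensity, p2$intensity[(seq_len(n) - 1 + s) %% n + 1])
  }, numeric(1))
  # the cross-correlation peak sits at the applied quarter turn
  expect_equal(which.max(xc) - 1, n / 4, tolerance = 1)
})

test_that("shared chromocenters give correlated DNA/heterochromatin profiles", {
  # unpolarised marks, strong speckles: the two channels share their peaks
  probs <- setNames(1, "uniform_uniform")
  p <- small_root_params(chromocenter_boost = 8, config_probs = probs)
  gr <- generate_root(p, seed = 19)
  ids <- gr$truth$id[1:12]
  cors <- vapply(ids, function(id) {
    profile_correlation(
      peripheral_profile(gr$stack, gr$labels, id, "dna", radius_frac = 0.8),
      peripheral_profile(gr$stack, gr$labels, id, "h3k9me2",
                         radius_frac = 0.8))
  }, numeric(1))
  expect_gte(median(cors), 0.8)
})

test_that("orientation codes follow their hemisphere definition", {
  expect_equal(configuration_code(0.9, 0.5), "1")
  expect_equal(configuration_code(0.1, 0.5), "2")
  expect_equal(configuration_code(0.5, 0.95), "3")
  expect_equal(configuration_code(0.5, 0.05), "4")
  expect_equal(configuration_code(0.5, 0.5), "uniform")
  # mirror antisymmetry through the division plane: 1_2 <-> 2_1
  f_eu <- 1; f_het <- 0
  joint <- paste(configuration_code(f_eu, 0.5),
                 configuration_code(f_het, 0.5), sep = "_")
  mirrored <- paste(configuration_code(1 - f_eu, 0.5),
                    configuration_code(1 - f_het, 0.5), sep = "_")
  expect_equal(joint, "1_2")
  expect_equal(mirrored, "2_1")
  expect_error(configuration_code(0.9, 0.5, threshold = 0.4))
})

test_that("assigned configuration codes are recovered from the raster", {
  sr <- small_root_features()
  gr <- sr$root
  cfg <- classify_configuration(gr$stack, gr$labels, sr$records, sr$frame,
                                enrichment_threshold = 0.55)
  m <- dplyr::inner_join(cfg, gr$truth[, c("id", "config")], by = "id")
  expect_gte(mean(m$config.x == m$config.y), 0.90)
  # reversing the root's orientation (QC at the far end) swaps the axial
  # polarity convention, hence codes 1 and 2, leaving 3/4/uniform unchanged
  far_qc <- c(dim(gr$labels)[1] * gr$stack$voxel_size[1] - gr$qc[1],
              gr$qc[2], gr$qc[3])
  rev_frame <- fit_axis(sr$records, qc_position = far_qc)
  rev_cfg <- classify_configuration(gr$stack, gr$labels, sr$records,
                                    rev_frame, enrichment_threshold = 0.55)
  swap <- c("1" = "2", "2" = "1")
  axial <- cfg$config_eu %in% c("1", "2") & cfg$config_het %in% c("1", "2")
  expect_gte(mean(rev_cfg$config_eu[axial] == swap[cfg$config_eu[axial]]),
             0.98)
  expect_gte(mean(rev_cfg$config_het[axial] == swap[cfg$config_het[axial]]),
             0.98)
})

test_that("configuration frequency tests match hand-computed statistics", {
  calls <- tibble::tibble(config = rep(c("1_2", "2_1", "1_1", "2_2"),
                                       each = 25))
  eq <- configuration_frequencies(calls)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  skew <- tibble::tibble(config = rep(c("1_2", "2_1", "1_1", "2_2"),
                                      c(70, 10, 10, 10)))
  sk <- configuration_frequencies(skew)
  expect_equal(sk$statistic, 108) # sum((O - 25)^2 / 25)
  expect_lt(sk$p_value, 1e-6)
  expect_equal(sum(tidy(sk)$count), 100)
  expect_error(configuration_frequencies(calls[1:10, ]), "fewer than")
})

test_that("the uniform-null test keeps its nominal size", {
  codes <- as.vector(outer(1:4, 1:4, paste, sep = "_"))
  set.seed(123)
  rejections <- vapply(seq_len(1000), function(i) {
    cfg <- tibble::tibble(config = sample(codes, 160, replace = TRUE))
    configuration_frequencies(cfg, code_space = codes)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("anaphase binning reduces to masked means and sees polarity", {
  dims <- c(20, 10, 10)
  vx <- c(0.5, 0.5, 0.5)
  vol <- array(0, dims)
  mask <- array(FALSE, dims)
  # two daughter blobs on either side of the plane at x = 5
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    p <- (c(i, j, k) - 0.5) * vx
    if (sum((p - c(3, 2.5, 2.5))^2) <= 1.5^2 ||
        sum((p - c(7, 2.5, 2.5))^2) <= 1.5^2) {
      mask[i, j, k] <- TRUE
      # heterochromatin-like: intensity grows away from the plane
      vol[i, j, k] <- abs(p[1] - 5)
    }
  }
  stk <- voxel_stack(list(h3k9me2 = vol), vx)
  prof <- anaphase_region_intensity(stk, mask, "h3k9me2",
                                    plane_point = c(5, 2.5, 2.5),
                                    plane_normal = c(1, 0, 0), nbins = 3)
  # distal bins exceed proximal bins on both sides
  for (s in unique(prof$side)) {
    m <- prof$mean_intensity[prof$side == s]
    expect_true(all(diff(m) > 0))
  }
  # nbins = 1 equals the brute-force masked mean per side
  one <- anaphase_region_intensity(stk, mask, "h3k9me2",
                                   plane_point = c(5, 2.5, 2.5),
                                   plane_normal = c(1, 0, 0), nbins = 1)
  idx <- which(mask)
  px <- (arrayInd(idx, dims)[, 1] - 0.5) * vx[1]
  expect_equal(one$mean_intensity[one$side == "negative"],
               mean(vol[idx][px < 5]))
  expect_equal(one$mean_intensity[one$side == "positive"],
               mean(vol[idx][px >= 5]))
  # uniform intensity: all bins equal
  vol2 <- array(0, dims); vol2[mask] <- 3
  stk2 <- voxel_stack(list(h3k9me2 = vol2), vx)
  u <- anaphase_region_intensity(stk2, mask, "h3k9me2",
                                 plane_point = c(5, 2.5, 2.5),
                                 plane_normal = c(1, 0, 0), nbins = 3)
  expect_true(all(abs(u$mean_intensity - 3) < 1e-12, na.rm = TRUE))
})
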