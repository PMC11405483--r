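test_that("noise-free synthetic nuclei are recovered exactly in count", {
  gr <- small_root()
  labs <- segment_nuclei(gr$stack, run_config())
  expect_equal(max(labs), nrow(gr$truth))
  rec <- extract_features(labs, gr$stack)
  # match recovered nuclei to truth by nearest centroid
  tr <- gr$truth
  nn <- vapply(seq_len(nrow(rec)), function(i) {
    which.min((tr$x - rec$x[i])^2 + (tr$y - rec$y[i])^2 +
                (tr$z - rec$z[i])^2)
  }, integer(1))
  expect_equal(sort(nn), seq_len(nrow(tr)))
  verr <- abs(rec$volume_um3 - tr$volume_um3[nn]) / tr$volume_um3[nn]
  expect_lt(median(verr), 0.10)
})

test_that("touching nuclei with distinct cores are split by the watershed", {
  # two ellipsoids overlapping slightly along x
  dims <- c(40, 20, 20)
  vx <- c(0.5, 0.5, 0.5)
  dna <- array(0, dims)
  centres <- rbind(c(8, 5, 5), c(13.5, 5, 5)) # µm; 5.5 apart, radii 3
  for (ci in 1:2) {
    for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
      p <- (c(i, j, k) - 0.5) * vx
      if (sum(((p - centres[ci, ]) / 3)^2) <= 1) dna[i, j, k] <- 100
    }
  }
  stk <- voxel_stack(list(dna = dna), vx, bit_depth = 255)
  merged <- segment_nuclei(stk, run_config(split_touching = FALSE))
  expect_equal(max(merged), 1)
  split <- segment_nuclei(stk, run_config(min_seed_sep_um = 3))
  expect_equal(max(split), 2)
  # each recovered object holds one centre
  rec <- extract_features(split, stk)
  expect_equal(sort(rec$x), centres[order(centres[, 1]), 1], tolerance = 0.2)
})

test_that("flat and empty volumes yield no objects, with a warning", {
  stk <- voxel_stack(list(dna = array(0, c(8, 8, 4))), c(1, 1, 1))
  expect_warning(labs <- segment_nuclei(stk), "flat")
  expect_equal(max(labs), 0)
})

test_that("extract_features matches the brute-force per-voxel oracle", {
  set.seed(21)
  dims <- c(14, 12, 10)
  vx <- c(0.5, 0.4, 0.9)
  labels <- array(0L, dims)
  labels[2:6, 2:6, 2:5] <- 1L
  labels[9:13, 4:10, 3:8] <- 2L
  labels[2:4, 8:11, 6:9] <- 3L
  stk <- voxel_stack(list(dna = array(runif(prod(dims), 1, 10), dims),
                          edu = array(runif(prod(dims)), dims)),
                     vx, bit_depth = 16)
  rec <- extract_features(labels, stk)
  orc <- oracle_features(labels, stk)
  for (i in seq_len(nrow(rec))) {
    o <- orc[[as.character(rec$id[i])]]
    expect_equal(rec$volume_um3[i], o$volume)
    expect_equal(rec$surface_um2[i], o$surface)
    expect_equal(c(rec$x[i], rec$y[i], rec$z[i]), c(o$x, o$y, o$z))
    expect_equal(c(rec$w_um[i], rec$h_um[i], rec$d_um[i]),
                 c(o$w, o$h, o$d))
    expect_equal(rec$dna_total[i], unname(o$totals["dna"]))
    expect_equal(rec$edu_total[i], unname(o$totals["edu"]))
    expect_equal(c(rec$dna_com_x[i], rec$dna_com_y[i], rec$dna_com_z[i]),
                 unname(o$com[, "dna"]))
  }
  # total foreground volume conservation
  expect_equal(sum(rec$volume_um3), sum(labels > 0) * prod(vx))
})

test_that("uniform cubes give symmetric features and shifted mass moves the center", {
  dims <- c(12, 12, 12)
  labels <- array(0L, dims)
  labels[2:11, 2:11, 2:11] <- 1L
  dna <- array(0, dims)
  dna[labels == 1L] <- 5
  stk <- voxel_stack(list(dna = dna), c(1, 1, 1), bit_depth = 16)
  rec <- extract_features(labels, stk)
  expect_equal(rec$volume_um3, 1000)
  expect_equal(c(rec$w_um, rec$h_um, rec$d_um), c(10, 10, 10))
  expect_equal(rec$asym_norm, 0)
  # double the intensity in the upper x half
  dna2 <- dna
  dna2[7:11, 2:11, 2:11] <- 10
  rec2 <- extract_features(labels, voxel_stack(list(dna = dna2), c(1, 1, 1),
                                               bit_depth = 16))
  # closed-form weighted mean: centres 1.5..10.5, weight 1 on 1.5..5.5 (x5),
  # 2 on 6.5..10.5 (x5) per unit row
  expected_com <- (sum(seq(1.5, 5.5)) + 2 * sum(seq(6.5, 10.5))) / 15
  expect_equal(rec2$dna_com_x, expected_com)
  expect_gt(rec2$asym_norm, 0)
  expect_equal(rec2$x, 6) # geometric centroid unchanged
})

test_that("curation drops out-of-window volumes and reports them", {
  rec <- tibble::tibble(id = 1:3, volume_um3 = c(5, 50, 500))
  kept <- curate(rec, 10, 300)
  expect_equal(kept$id, 2L)
  expect_equal(attr(kept, "removed")$id, c(1L, 3L))
  all_in <- curate(rec, 1, 1000)
  expect_equal(all_in$id, rec$id)
  expect_error(curate(rec, 10, 5))
})

test_that("speckle-noise objects are removed by the volume window", {
  gr <- small_root()
  labs <- segment_nuclei(gr$stack, run_config())
  rec <- extract_features(labs, gr$stack)
  # inject fake speckle records to emulate residual background detections
  fake <- rec[1:5, ]
  fake$id <- max(rec$id) + 1:5
  fake$volume_um3 <- runif(5, 0.1, 2)
  rec2 <- dplyr::bind_rows(rec, fake)
  kept <- curate(rec2, vmin = 5, vmax = 500)
  expect_equal(nrow(kept), nrow(gr$truth))
})

test_that("nucleolar cavities are measured and open cavities rejected", {
  dims <- c(16, 16, 12)
  labels <- array(0L, dims)
  labels[3:14, 3:14, 2:11] <- 1L
  stk <- voxel_stack(list(dna = array(1, dims)), c(1, 1, 1), bit_depth = 2)
  # solid: no cavity
  expect_equal(detect_nucleolus(labels, stk)$nucleolus_um3, 0)
  # enclosed cavity of 3x3x3 voxels
  lab2 <- labels
  lab2[7:9, 7:9, 5:7] <- 0L
  expect_equal(detect_nucleolus(lab2, stk)$nucleolus_um3, 27)
  # cavity reaching the nucleus surface is not enclosed
  lab3 <- labels
  lab3[7:9, 7:9, 9:11] <- 0L
  expect_equal(detect_nucleolus(lab3, stk)$nucleolus_um3, 0)
})

test_that("generator nucleoli are recovered within tolerance", {
  gr <- small_root()
  ids <- gr$truth$id[1:25]
  nuc <- detect_nucleolus(gr$labels, gr$stack, ids = ids)
  truth <- gr$truth$nucleolus_vox[match(ids, gr$truth$id)] *
    voxel_volume(gr$stack)
  expect_true(all(abs(nuc$nucleolus_um3 - truth) / truth <= 0.15))
})
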