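axis_rms_error <- function(frame, bend_amplitude, root_length) {
  # distance of fitted axis points to the true generator axis
  zg <- seq(5, root_length - 5, by = 2)
  fitted <- from_cylindrical(frame, tibble::tibble(z_root = zg, r = 0,
                                                   phi = 0))
  ug <- seq(0, root_length, length.out = 4000)
  true_axis <- cbind(ug, bend_amplitude * (ug / root_length)^2, 0)
  d <- vapply(seq_len(nrow(fitted)), function(i) {
    min(sqrt((true_axis[, 1] - fitted$x[i])^2 +
               (true_axis[, 2] - fitted$y[i])^2 +
               (true_axis[, 3] - fitted$z[i])^2))
  }, numeric(1))
  sqrt(mean(d^2))
}

test_that("the fitted axis tracks straight and bent generator axes", {
  p0 <- synthetic_params()
  f0 <- generate_feature_table(p0, seed = 8, table_cv = 0.02)
  fr0 <- fit_axis(f0$records, qc_position = f0$qc)
  expect_lt(axis_rms_error(fr0, 0, p0$root_length), 1)

  fb <- bent_table()
  frb <- fit_axis(fb$records, qc_position = fb$qc)
  expect_lt(axis_rms_error(frb, 12, 120), 3)
})

test_that("too few or degenerate centroids are rejected", {
  few <- tibble::tibble(id = 1:5, x = 1:5, y = 0, z = 0)
  expect_error(fit_axis(few, c(0, 0, 0)), "at least 20")
})

test_that("cylindrical coordinates are exact on a straight axis", {
  fr <- straight_frame(100)
  on_axis <- to_cylindrical(fr, from_cylindrical(
    fr, tibble::tibble(z_root = 50, r = 0, phi = 0)))
  expect_lt(on_axis$r, 1e-8)
  expect_equal(on_axis$z_root, 50, tolerance = 1e-6)
  # a point offset 10 um laterally at z = 50
  p <- from_cylindrical(fr, tibble::tibble(z_root = 50, r = 0, phi = 0))
  # closed-form up to the residual wiggle of the fitted axis
  fa <- to_cylindrical(fr, tibble::tibble(x = p$x, y = p$y + 10, z = p$z))
  expect_equal(fa$z_root, 50, tolerance = 0.01)
  expect_equal(fa$r, 10, tolerance = 0.01)
})

test_that("forward/inverse mapping round-trips random interior points", {
  for (bend in c(0, 12)) {
    p <- synthetic_params(bend_amplitude = bend)
    ft <- generate_feature_table(p, seed = 3, table_cv = 0.02)
    fr <- fit_axis(ft$records, qc_position = ft$qc)
    set.seed(99)
    pts <- tibble::tibble(x = runif(2000, 10, 110),
                          y = runif(2000, -15, 15 + bend),
                          z = runif(2000, -15, 15))
    cyl <- to_cylindrical(fr, pts)
    back <- from_cylindrical(fr, cyl)
    err <- sqrt((back$x - pts$x)^2 + (back$y - pts$y)^2 +
                  (back$z - pts$z)^2)
    expect_lt(max(err[!cyl$extrapolated]), 1e-6)
  }
})

test_that("points beyond the curve ends are flagged as extrapolated", {
  fr <- straight_frame(100)
  far <- to_cylindrical(fr, tibble::tibble(x = 1e3, y = 0, z = 0))
  expect_true(far$extrapolated)
})

test_that("radial bins assign layers inner-inclusively", {
  radii <- c(vascular = 8, pericycle = 13, endodermis = 18)
  ann <- tibble::tibble(id = 1:5, z_root = c(10, 10, 10, 10, -5),
                        r = c(0, 8, 15, 30, 10))
  out <- assign_layer(ann, radii, lrc_zmax = 60, columella_radius = 15)
  expect_equal(out$layer,
               c("vascular", "vascular", "endodermis", "LRC", "columella"))
  # beyond the cap's longitudinal extent the call is unassigned
  deep <- assign_layer(tibble::tibble(id = 1, z_root = 90, r = 30), radii,
                       lrc_zmax = 60)
  expect_true(is.na(deep$layer))
})

test_that("layer assignment survives a rigid rotation of the stack", {
  ft <- bent_table()
  fr <- fit_axis(ft$records, qc_position = ft$qc)
  ann <- assign_layer(annotate_coordinates(ft$records, fr),
                      ft$params$layer_radii, lrc_zmax = ft$params$lrc_zmax)
  # rotate the whole cloud 90 degrees about the x axis: (y, z) -> (-z, y)
  rot <- ft$records
  rot$y <- -ft$records$z
  rot$z <- ft$records$y
  frr <- fit_axis(rot, qc_position = c(ft$qc[1], -ft$qc[3], ft$qc[2]))
  annr <- assign_layer(annotate_coordinates(rot, frr),
                       ft$params$layer_radii, lrc_zmax = ft$params$lrc_zmax)
  expect_gt(mean(ann$layer == annr$layer, na.rm = TRUE), 0.99)
})

test_that("azimuthal clustering recovers cell files", {
  ft <- bent_table()
  fr <- fit_axis(ft$records, qc_position = ft$qc)
  ann <- assign_layer(annotate_coordinates(ft$records, fr),
                      ft$params$layer_radii, lrc_zmax = ft$params$lrc_zmax)
  ann <- assign_files(ann)
  tr <- ft$truth
  for (ly in c("epidermis", "cortex")) {
    sel <- ann$layer == ly & tr$layer == ly
    tab <- table(ann$file[sel], tr$file[sel])
    # clusters may over-split but must not mix true files
    expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
  }
  # degenerate case: all nuclei at one azimuth form one file
  one <- tibble::tibble(id = 1:20, layer = "epidermis",
                        phi = rep(1, 20) + rnorm(20, 0, 0.001))
  expect_equal(unique(assign_files(one)$file), 1L)
  # two files opposite each other are separated deterministically
  two <- tibble::tibble(id = 1:20, layer = "epidermis",
                        phi = rep(c(0.5, 0.5 + pi), 10))
  expect_equal(sort(unique(assign_files(two)$file)), c(1L, 2L))
})

test_that("zone boundaries are located by the spacing increase", {
  ft <- bent_table()
  fr <- fit_axis(ft$records, qc_position = ft$qc)
  ann <- assign_files(assign_layer(annotate_coordinates(ft$records, fr),
                                   ft$params$layer_radii,
                                   lrc_zmax = ft$params$lrc_zmax))
  ann <- assign_zone(ann, k_td = 1.5, k_ez = 3)
  b <- attr(ann, "boundaries")
  # PD/TD within one PD cell spacing of the generated step at z = 60
  expect_lt(abs(b["pd_td"] - 60), ft$params$spacing)
  expect_true(all(c("PD", "TD", "EZ") %in% ann$zone))
  # monotone: every PD nucleus sits below every EZ nucleus
  expect_lt(max(ann$z_root[ann$zone == "PD"]),
            min(ann$z_root[ann$zone == "EZ"]))
  # constant spacing: no boundary, whole root PD
  const <- tibble::tibble(id = 1:30, layer = "cortex", file = 1,
                          z_root = seq(2, 60, by = 2))
  expect_warning(cz <- assign_zone(const), "whole root")
  expect_true(all(cz$zone == "PD"))
  expect_error(assign_zone(ann, k_td = 1), "k_td > 1")
})

test_that("trichoblast files are recognised by their tighter spacing", {
  ft <- bent_table()
  fr <- fit_axis(ft$records, qc_position = ft$qc)
  ann <- assign_zone(assign_files(assign_layer(
    annotate_coordinates(ft$records, fr), ft$params$layer_radii,
    lrc_zmax = ft$params$lrc_zmax)))
  ann <- classify_epidermis(ann)
  tr <- ft$truth
  sel <- !is.na(ann$subtype) & !is.na(tr$subtype)
  expect_gte(mean(ann$subtype[sel] == tr$subtype[sel]), 0.95)
  # indistinguishable spacings stay unassigned
  flat <- tibble::tibble(id = 1:40, layer = "epidermis",
                         file = rep(1:4, each = 10),
                         phi = rep(c(0.5, 1.5, 2.5, 3.5), each = 10),
                         z_root = rep(seq(2, 20, by = 2), 4),
                         zone = "PD")
  expect_warning(out <- classify_epidermis(flat), "indistinguishable")
  expect_true(all(is.na(out$subtype)))
})

test_that("L1/L2 measure the radial position of the nucleus in its cell", {
  sr <- small_root_features()
  gr <- sr$root
  # pericycle nuclei sit midway between the walls at r = 8 and r = 13
  peri <- sr$records[gr$truth$layer[match(sr$records$id, gr$truth$id)] ==
                       "pericycle", ][1:10, ]
  lp <- nucleus_position_in_cell(peri, gr$stack, gr$labels, sr$frame)
  expect_true(all(lp$measured))
  # both gaps are (13 - 8)/2 - a_r = 0.5 um up to jitter and voxelisation
  expect_true(all(abs(lp$L1 - 0.5) < 1.2))
  expect_true(all(abs(lp$L2 - 0.5) < 1.2))
  nowall <- voxel_stack(list(dna = gr$stack$channels$dna),
                        gr$stack$voxel_size)
  expect_error(nucleus_position_in_cell(peri, nowall, gr$labels, sr$frame),
               "wall")
})
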