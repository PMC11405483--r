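#' Nuclear shape factor in the root frame
#'
#' Re-expresses the stack-axis bounding extents (W/H/D) of each nucleus as
#' an axial and a radial extent in the root frame and returns their ratio.
#' The extent of a nucleus along a unit direction `e` is taken as
#' `sqrt(sum((ext_k * e_k)^2))`, exact for an ellipsoid whose axes align
#' with the stack; spheres give a ratio of 1 in any frame.
#'
#' @param records Feature tibble with `id`, `x`, `y`, `z`, `w_um`, `h_um`,
#'   `d_um`.
#' @param frame A [fit_axis()] result.
#' @return Tibble with `id`, `ext_axial`, `ext_radial`, `shape_factor`
#'   (axial / radial).
#' @export
shape_factor <- function(records, frame) {
  P <- as.matrix(records[, c("x", "y", "z")])
  fp <- foot_point(frame, P)
  fr <- frame_at(frame, fp$t)
  C0 <- curve_at(frame, fp$t)
  if (is.null(dim(C0))) C0 <- matrix(C0, ncol = 3)
  res <- P - C0
  res <- res - rowSums(res * fr$T) * fr$T
  nr <- sqrt(rowSums(res^2))
  if (any(nr < 1e-9)) {
    stop("nucleus on the axis: radial direction undefined", call. = FALSE)
  }
  Rhat <- res / nr
  ext <- as.matrix(records[, c("w_um", "h_um", "d_um")])
  ext_axial <- sqrt(rowSums((ext * fr$T)^2))
  ext_radial <- sqrt(rowSums((ext * Rhat)^2))
  if (any(ext_radial <= 0)) stop("zero radial extent", call. = FALSE)
  tibble::tibble(id = records$id, ext_axial = ext_axial,
                 ext_radial = ext_radial,
                 shape_factor = ext_axial / ext_radial)
}

#' Estimate relative ploidy against a 2C reference at the QC
#'
#' The median integrated DNA intensity of nuclei within
#' `|z| <= calibration_window` of the quiescent center (excluding columella
#' and lateral root cap) is assigned 2C; every nucleus then gets
#' `C = 2 * intensity / reference`. The estimate is scale-invariant:
#' rescaling all intensities leaves every C unchanged. C is reported
#' continuously; [ploidy_class()] bins to the nearest power-of-two class.
#'
#' @param records Feature tibble with `id` and the intensity column.
#' @param annotations Annotation tibble with `id`, `z_root`, `layer`.
#' @param calibration_window Half-width of the calibration window (µm).
#' @param intensity_col Name of the integrated DNA intensity column.
#' @return Tibble with `id`, `intensity`, `C`; calibration details in
#'   attributes `reference` and `n_calibration`.
#' @export
estimate_ploidy <- function(records, annotations, calibration_window = 15,
                            intensity_col = "dna_total") {
  joined <- dplyr::inner_join(
    records[, c("id", intensity_col)], annotations[, c("id", "z_root", "layer")],
    by = "id")
  cal <- joined |>
    dplyr::filter(abs(.data$z_root) <= calibration_window,
                  !(.data$layer %in% c("columella", "LRC")),
                  !is.na(.data$layer))
  if (nrow(cal) < 5) {
    stop("fewer than 5 nuclei in the 2C calibration window", call. = FALSE)
  }
  ref <- stats::median(cal[[intensity_col]])
  if (ref <= 0) stop("non-positive calibration reference", call. = FALSE)
  out <- tibble::tibble(id = joined$id,
                        intensity = joined[[intensity_col]],
                        C = 2 * joined[[intensity_col]] / ref)
  attr(out, "reference") <- ref
  attr(out, "n_calibration") <- nrow(cal)
  out
}

#' Nearest power-of-two ploidy class
#' @param C Continuous C values from [estimate_ploidy()].
#' @return Numeric class values (2, 4, 8, ...).
#' @export
ploidy_class <- function(C) 2^pmax(1, round(log2(C)))

#' In situ ploidy map in root coordinates
#'
#' Joins ploidy estimates with cylindrical positions into the long-format
#' table used for map rendering and axial trend summaries.
#'
#' @param estimates Output of [estimate_ploidy()].
#' @param annotations Annotation tibble with `id`, `z_root`, `r`, `phi`,
#'   `layer`.
#' @return Tibble `(id, z_root, r, phi, layer, C)`; ids present in only one
#'   input are dropped with a message.
#' @export
ploidy_map <- function(estimates, annotations) {
  n_in <- nrow(estimates)
  out <- dplyr::inner_join(estimates,
                           annotations[, c("id", "z_root", "r", "phi", "layer")],
                           by = "id") |>
    dplyr::select("id", "z_root", "r", "phi", "layer", "C")
  if (nrow(out) < n_in) {
    message(n_in - nrow(out), " estimate(s) had no matching annotation; dropped")
  }
  class(out) <- c("ploidy_map", class(out))
  out
}

#' Axial ploidy trend per layer
#'
#' Least-squares slope of C against arclength per layer, with confidence
#' intervals.
#'
#' @param map A [ploidy_map()] tibble.
#' @param conf_level Confidence level.
#' @return Tibble with one row per layer: `slope`, `conf_low`, `conf_high`,
#'   `n`.
#' @export
ploidy_trend <- function(map, conf_level = 0.95) {
  map |>
    dplyr::group_by(.data$layer) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || length(unique(d$z_root)) < 2) {
        return(tibble::tibble(slope = NA_real_, conf_low = NA_real_,
                              conf_high = NA_real_, n = nrow(d)))
      }
      fit <- lm(C ~ z_root, data = d)
      ci <- confint(fit, "z_root", level = conf_level)
      tibble::tibble(slope = coef(fit)[["z_root"]],
                     conf_low = ci[1], conf_high = ci[2], n = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Axial change point of ploidy in one layer
#'
#' Two-segment piecewise-constant fit of C against arclength: the split
#' minimising the residual sum of squares is the estimated transition.
#'
#' @param map A [ploidy_map()] tibble.
#' @param layer Layer to analyse.
#' @return List with `z_star`, `mean_left`, `mean_right`.
#' @export
ploidy_changepoint <- function(map, layer) {
  d <- map[map$layer == layer & map$z_root >= 0, ]
  d <- d[order(d$z_root), ]
  n <- nrow(d)
  if (n < 6) stop("need at least 6 nuclei in layer '", layer, "'",
                  call. = FALSE)
  best <- list(sse = Inf)
  cs <- cumsum(d$C); cs2 <- cumsum(d$C^2)
  for (k in 3:(n - 3)) {
    sl <- cs[k]; sl2 <- cs2[k]
    sr <- cs[n] - sl; sr2 <- cs2[n] - sl2
    sse <- (sl2 - sl^2 / k) + (sr2 - sr^2 / (n - k))
    if (sse < best$sse) {
      best <- list(sse = sse, k = k,
                   z_star = unname((d$z_root[k] + d$z_root[k + 1]) / 2),
                   mean_left = unname(sl / k),
                   mean_right = unname(sr / (n - k)))
    }
  }
  best[c("z_star", "mean_left", "mean_right")]
}

#' Axial DNA-volume trend by layer
#'
#' Per-layer least-squares regression of nuclear volume on arclength, plus a
#' shared interaction model testing slope differences between layers.
#'
#' @param records Feature tibble with `id`, `volume_um3`.
#' @param annotations Annotation tibble with `id`, `z_root`, `layer`.
#' @param layers Layers to include (default: all with enough nuclei).
#' @param min_n Minimum nuclei per layer.
#' @return Object of class `dna_trend`; see [tidy()] and [glance()] methods.
#' @export
dna_volume_trend <- function(records, annotations, layers = NULL, min_n = 10) {
  d <- dplyr::inner_join(records[, c("id", "volume_um3")],
                         annotations[, c("id", "z_root", "layer")],
                         by = "id") |>
    dplyr::filter(!is.na(.data$layer), .data$z_root >= 0)
  if (!is.null(layers)) d <- d[d$layer %in% layers, ]
  counts <- table(d$layer)
  keep <- names(counts)[counts >= min_n]
  if (length(keep) == 0) stop("no layer has >= ", min_n, " nuclei",
                              call. = FALSE)
  d <- d[d$layer %in% keep, ]
  per_layer <- d |>
    dplyr::group_by(.data$layer) |>
    dplyr::group_modify(function(dd, key) {
      fit <- lm(volume_um3 ~ z_root, data = dd)
      ci <- confint(fit, "z_root")
      tibble::tibble(slope = coef(fit)[["z_root"]],
                     conf_low = ci[1], conf_high = ci[2],
                     p_value = summary(fit)$coefficients["z_root", 4],
                     n = nrow(dd))
    }) |>
    dplyr::ungroup()
  inter <- NULL
  if (length(keep) > 1) {
    d$layer <- factor(d$layer)
    full <- lm(volume_um3 ~ z_root * layer, data = d)
    reduced <- lm(volume_um3 ~ z_root + layer, data = d)
    inter <- stats::anova(reduced, full)
  }
  structure(list(per_layer = per_layer, interaction = inter, data = d),
            class = "dna_trend")
}

#' @export
print.dna_trend <- function(x, ...) {
  cat("<dna_trend> per-layer DNA-volume slopes (um^3 per um):\n")
  print(x$per_layer)
  if (!is.null(x$interaction)) {
    cat("slope-homogeneity test p =",
        signif(x$interaction$`Pr(>F)`[2], 3), "\n")
  }
  invisible(x)
}

#' @export
tidy.dna_trend <- function(x, ...) x$per_layer

#' @export
glance.dna_trend <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$data),
    n_layers = nrow(x$per_layer),
    p_slope_difference = if (is.null(x$interaction)) NA_real_
                         else x$interaction$`Pr(>F)`[2]
  )
}
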