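#' Map a red/green channel pair to the 0-255 hue scale
#'
#' Standard RGB-to-hue conversion with a zero blue channel, scaled so the
#' full hue circle spans 256 units: pure red maps to 0, the balanced
#' red/green overlay (yellow) to ~42, pure green to ~85. Zero pixels in both
#' channels return `NA` (no signal).
#'
#' @param red,green Non-negative intensity vectors/arrays of equal shape.
#' @return Hue values in `[0, 255]`, `NA` where both channels are 0.
#' @export
hue_from_rg <- function(red, green) {
  r <- as.numeric(red); g <- as.numeric(green)
  stopifnot(length(r) == length(g))
  mx <- pmax(r, g)
  h_deg <- ifelse(r >= g, 60 * g / r, 60 * (2 - r / g))
  h_deg[mx <= 0] <- NA_real_
  pmin(255, floor(h_deg / 360 * 256))
}

#' Colocalization fractions by hue thresholding
#'
#' Quantifies overlap between a heterochromatin (red) and a euchromatin
#' (green) channel inside a nucleus mask by classing each signal pixel's hue
#' into exclusive-red, overlay and exclusive-green ranges on the 0-255 hue
#' scale. Default ranges: red 0-15, overlay 16-58, green 59-255. Fractions
#' are normalised by the total signal pixel count and sum to 1; the measure
#' is invariant to uniform intensity rescaling.
#'
#' @param red,green Channel intensities (vectors or arrays of equal shape).
#' @param mask Optional logical mask restricting the analysis.
#' @param ranges List with `red`, `overlap`, `green` inclusive hue bounds.
#' @return One-row tibble: `red_exclusive`, `overlap`, `green_exclusive`,
#'   `n_signal`.
#' @export
hue_overlap_fractions <- function(red, green, mask = NULL,
                                  ranges = list(red = c(0, 15),
                                                overlap = c(16, 58),
                                                green = c(59, 255))) {
  r <- as.numeric(red); g <- as.numeric(green)
  if (!is.null(mask)) {
    m <- as.logical(mask)
    if (!any(m)) stop("empty mask", call. = FALSE)
    r <- r[m]; g <- g[m]
  }
  h <- hue_from_rg(r, g)
  h <- h[!is.na(h)]
  if (!length(h)) stop("no signal pixels in mask", call. = FALSE)
  in_rng <- function(rg) h >= rg[1] & h <= rg[2]
  tibble::tibble(
    red_exclusive = mean(in_rng(ranges$red)),
    overlap = mean(in_rng(ranges$overlap)),
    green_exclusive = mean(in_rng(ranges$green)),
    n_signal = length(h)
  )
}

#' Peripheral intensity profile of a nucleus
#'
#' On the equatorial plane of the nucleus (the z-slice with the largest mask
#' area), the channel is maximum-projected over `band` neighbouring slices and
#' sampled at uniform azimuthal steps along a reference line just inside the
#' mask boundary (`radius_frac` of the local boundary radius). The same arc
#' parametrisation is reused across channels of one nucleus, so profiles of
#' different channels are directly comparable point by point.
#'
#' @param stack A [voxel_stack()].
#' @param labels Label array.
#' @param id Nucleus label.
#' @param channel Channel name.
#' @param n_arc Number of azimuthal samples.
#' @param radius_frac Sampling radius relative to the boundary radius.
#' @param band Half-width (slices) of the equatorial projection.
#' @return Tibble with `angle` (rad) and `intensity`.
#' @export
peripheral_profile <- function(stack, labels, id, channel, n_arc = 72,
                               radius_frac = 0.9, band = 1) {
  vol <- get_channel(stack, channel)
  dims <- dim(vol)
  vx <- stack$voxel_size
  idx <- which(labels == id)
  if (!length(idx)) stop("label ", id, " not present", call. = FALSE)
  coord <- arrayInd(idx, dims)
  zs <- sort(unique(coord[, 3]))
  if (length(zs) < 3) {
    stop("nucleus mask spans fewer than 3 slices", call. = FALSE)
  }
  area <- table(coord[, 3])
  z_eq <- as.integer(names(area)[which.max(area)])
  z_win <- max(1, z_eq - band):min(dims[3], z_eq + band)
  proj <- apply(vol[, , z_win, drop = FALSE], c(1, 2), max)
  mask2d <- matrix(FALSE, dims[1], dims[2])
  in_win <- coord[, 3] %in% z_win
  mask2d[coord[in_win, 1:2, drop = FALSE]] <- TRUE
  ctr <- colMeans(coord[in_win, 1:2, drop = FALSE] - 0.5) * vx[1:2]
  step <- min(vx[1:2]) / 2
  rmax <- max(dims[1] * vx[1], dims[2] * vx[2])
  angles <- 2 * pi * (seq_len(n_arc) - 1) / n_arc
  out <- purrr::map_dfr(angles, function(th) {
    dir <- c(cos(th), sin(th))
    ss <- seq(0, rmax, by = step)
    px <- ceiling((ctr[1] + ss * dir[1]) / vx[1])
    py <- ceiling((ctr[2] + ss * dir[2]) / vx[2])
    ok <- px >= 1 & px <= dims[1] & py >= 1 & py <= dims[2]
    inm <- ok & mask2d[cbind(pmax(1, pmin(dims[1], px)),
                             pmax(1, pmin(dims[2], py)))]
    if (!any(inm)) {
      return(tibble::tibble(angle = th, intensity = NA_real_))
    }
    rb <- max(ss[inm])
    # sample the in-mask ray point nearest the reference radius, so the
    # reference line never mixes with background pixels
    s_in <- ss[inm]
    sp <- s_in[which.min(abs(s_in - radius_frac * rb))]
    px_s <- ceiling((ctr[1] + sp * dir[1]) / vx[1])
    py_s <- ceiling((ctr[2] + sp * dir[2]) / vx[2])
    val <- proj[pmax(1, pmin(dims[1], px_s)), pmax(1, pmin(dims[2], py_s))]
    tibble::tibble(angle = th, intensity = val)
  })
  if (sum(!is.na(out$intensity)) < 8) {
    stop("degenerate boundary: fewer than 8 profile samples", call. = FALSE)
  }
  out
}

#' Correlation between two peripheral profiles
#' @param p1,p2 Profiles from [peripheral_profile()] sharing the arc grid.
#' @return Pearson correlation of the paired intensities.
#' @export
profile_correlation <- function(p1, p2) {
  ok <- !is.na(p1$intensity) & !is.na(p2$intensity)
  a <- p1$intensity[ok]; b <- p2$intensity[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    stop("profile has zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Orientation code from hemisphere signal fractions
#'
#' Codes: `1` rootward-enriched, `2` shootward-enriched (axial pair),
#' `3`/`4` the two lateral hemispheres, `uniform` when no hemisphere holds
#' at least `threshold` of the integrated signal. Axial polarisation takes
#' precedence over lateral.
#'
#' @param f_rootward Fraction of integrated signal in the rootward (toward
#'   the QC) axial hemisphere.
#' @param f_lateral Fraction in the positive lateral hemisphere.
#' @param threshold Enrichment threshold in (0.5, 1].
#' @return Character vector of codes.
#' @export
configuration_code <- function(f_rootward, f_lateral, threshold = 0.55) {
  stopifnot(threshold > 0.5, threshold <= 1)
  dplyr::case_when(
    f_rootward >= threshold ~ "1",
    1 - f_rootward >= threshold ~ "2",
    f_lateral >= threshold ~ "3",
    1 - f_lateral >= threshold ~ "4",
    TRUE ~ "uniform"
  )
}

#' Classify per-nucleus chromatin-configuration codes from a stack
#'
#' Splits each nucleus into hemisphere pairs along the local root axis
#' (rootward/shootward) and along the lateral direction orthogonal to both
#' the axis and the radial direction, computes the fraction of each mark's
#' integrated signal per hemisphere, and assigns orientation codes via
#' [configuration_code()]. The joint code is euchromatin-first, e.g.
#' `"1_2"` for euchromatin rootward and heterochromatin shootward.
#'
#' @param stack A [voxel_stack()].
#' @param labels Label array.
#' @param records Feature tibble with `id`, `x`, `y`, `z` centroids.
#' @param frame A [fit_axis()] result.
#' @param marks Named pair `c(eu = ..., het = ...)` of channel names.
#' @param enrichment_threshold Passed to [configuration_code()].
#' @return Tibble with per-mark codes, hemisphere fractions and the joint
#'   `config` string.
#' @export
classify_configuration <- function(stack, labels, records, frame,
                                   marks = c(eu = "h3k4me1",
                                             het = "h3k9me2"),
                                   enrichment_threshold = 0.55) {
  dims <- dim(stack)
  eu <- get_channel(stack, marks[["eu"]])
  het <- get_channel(stack, marks[["het"]])
  vx <- stack$voxel_size
  P <- as.matrix(records[, c("x", "y", "z")])
  fp <- foot_point(frame, P)
  fr <- frame_at(frame, fp$t)
  C0 <- curve_at(frame, fp$t)
  if (is.null(dim(C0))) C0 <- matrix(C0, ncol = 3)
  res <- P - C0
  res <- res - rowSums(res * fr$T) * fr$T
  Rhat <- res / sqrt(rowSums(res^2))
  Lhat <- cbind(fr$T[, 2] * Rhat[, 3] - fr$T[, 3] * Rhat[, 2],
                fr$T[, 3] * Rhat[, 1] - fr$T[, 1] * Rhat[, 3],
                fr$T[, 1] * Rhat[, 2] - fr$T[, 2] * Rhat[, 1])
  idx_all <- which(labels > 0L)
  lab_all <- labels[idx_all]
  coord_all <- arrayInd(idx_all, dims)
  pos_all <- sweep(coord_all - 0.5, 2, vx, "*")
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    sel <- lab_all == records$id[i]
    if (!any(sel)) {
      stop("label ", records$id[i], " not present in the volume",
           call. = FALSE)
    }
    U <- sweep(pos_all[sel, , drop = FALSE], 2, P[i, ])
    ax <- drop(U %*% fr$T[i, ])
    lat <- drop(U %*% Lhat[i, ])
    frac <- function(w) {
      tot <- sum(w)
      if (tot <= 0) stop("zero mark signal in nucleus ", records$id[i],
                         call. = FALSE)
      c(rootward = sum(w[ax < 0]) / tot, lateral = sum(w[lat >= 0]) / tot)
    }
    vi <- idx_all[sel]
    feu <- frac(eu[vi]); fhet <- frac(het[vi])
    eu_code <- configuration_code(feu[1], feu[2], enrichment_threshold)
    het_code <- configuration_code(fhet[1], fhet[2], enrichment_threshold)
    tibble::tibble(
      id = records$id[i],
      config_eu = eu_code, config_het = het_code,
      config = paste(eu_code, het_code, sep = "_"),
      eu_frac_rootward = feu[1], eu_frac_lateral = feu[2],
      het_frac_rootward = fhet[1], het_frac_lateral = fhet[2]
    )
  })
}

#' Test configuration-code frequencies against the uniform null
#'
#' If chromatin were rearranged at random after mitosis, every orientation
#' configuration would be equally likely. This computes the joint-code
#' frequency table, a chi-squared goodness-of-fit test against equal
#' probabilities over the code space, and per-code binomial enrichment
#' tests with Benjamini-Hochberg adjustment. When any expected count drops
#' below 1 the chi-squared p-value is replaced by a Monte Carlo multinomial
#' p-value and flagged.
#'
#' @param calls Tibble with a `config` column (e.g. from
#'   [classify_configuration()]).
#' @param code_space Codes defining the null space; default: codes observed.
#' @param drop_uniform Drop joint codes involving an unpolarised mark
#'   before testing.
#' @param min_n Minimum classified nuclei required.
#' @return Object of class `configuration_freq`; see [tidy()]/[glance()].
#' @export
configuration_frequencies <- function(calls, code_space = NULL,
                                      drop_uniform = TRUE, min_n = 30) {
  codes <- calls$config
  if (drop_uniform) codes <- codes[!grepl("uniform", codes)]
  if (!is.null(code_space)) codes <- codes[codes %in% code_space]
  if (length(codes) < min_n) {
    stop("fewer than ", min_n, " classified nuclei", call. = FALSE)
  }
  space <- if (is.null(code_space)) sort(unique(codes)) else code_space
  counts <- table(factor(codes, levels = space))
  n <- sum(counts)
  k <- length(space)
  expected <- n / k
  exact <- expected < 1
  ct <- suppressWarnings(
    chisq.test(counts, p = rep(1 / k, k), simulate.p.value = exact,
               B = if (exact) 5000 else 2000)
  )
  per_code <- tibble::tibble(
    config = space,
    count = as.integer(counts),
    proportion = as.integer(counts) / n,
    p_binomial = vapply(as.integer(counts), function(x) {
      binom.test(x, n, p = 1 / k)$p.value
    }, numeric(1))
  )
  per_code$p_adjusted <- p.adjust(per_code$p_binomial, method = "BH")
  structure(
    list(per_code = per_code, statistic = unname(ct$statistic),
         df = if (exact) NA_real_ else unname(ct$parameter),
         p_value = ct$p.value, n = n, k = k,
         method = if (exact) "Monte Carlo multinomial" else "chi-squared"),
    class = "configuration_freq"
  )
}

#' @export
print.configuration_freq <- function(x, ...) {
  cat("<configuration_freq> ", x$n, " nuclei over ", x$k, " codes; ",
      x$method, " X2 = ", signif(x$statistic, 4), ", p = ",
      signif(x$p_value, 3), "\n", sep = "")
  print(x$per_code)
  invisible(x)
}

#' @export
tidy.configuration_freq <- function(x, ...) x$per_code

#' @export
glance.configuration_freq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = x$n, n_codes = x$k, method = x$method)
}

#' Mark intensity by distance from the division plane
#'
#' Bins chromatin voxels by signed distance from a division plane (point
#' plus normal) into equal-width bins per daughter side and returns the mean
#' channel intensity per bin; used to profile mark distribution along the
#' spindle axis during anaphase.
#'
#' @param stack A [voxel_stack()].
#' @param mask Logical array selecting the chromatin voxels.
#' @param channel Channel name.
#' @param plane_point,plane_normal Plane specification (µm, Cartesian).
#' @param nbins Bins per side.
#' @return Tibble with `side` (`proximal` negative, `distal` positive),
#'   `bin`, `d_lo`, `d_hi`, `mean_intensity`, `n_vox`; one-sided inputs are
#'   flagged via `attr(, "one_sided")`.
#' @export
anaphase_region_intensity <- function(stack, mask, channel, plane_point,
                                      plane_normal, nbins = 4) {
  vol <- get_channel(stack, channel)
  dims <- dim(vol)
  stopifnot(all(dim(mask) == dims), nbins >= 1)
  if (!any(mask)) stop("empty chromatin mask", call. = FALSE)
  nrm <- normalize(plane_normal)
  idx <- which(mask)
  pos <- sweep(arrayInd(idx, dims) - 0.5, 2, stack$voxel_size, "*")
  d <- drop(sweep(pos, 2, plane_point) %*% nrm)
  one_sided <- all(d >= 0) || all(d <= 0)
  out <- purrr::map_dfr(c(-1, 1), function(sgn) {
    ds <- d[sign(d) == sgn | (sgn == 1 & d == 0)]
    vs <- vol[idx][sign(d) == sgn | (sgn == 1 & d == 0)]
    if (!length(ds)) return(NULL)
    amax <- max(abs(ds))
    edges <- seq(0, amax, length.out = nbins + 1)
    vox_bin <- pmin(nbins, pmax(1, findInterval(abs(ds), edges,
                                                rightmost.closed = TRUE)))
    bin_mean <- vapply(seq_len(nbins), function(b) {
      if (any(vox_bin == b)) mean(vs[vox_bin == b]) else NA_real_
    }, numeric(1))
    bin_n <- vapply(seq_len(nbins), function(b) sum(vox_bin == b),
                    integer(1))
    tibble::tibble(
      side = if (sgn < 0) "negative" else "positive",
      bin = seq_len(nbins),
      d_lo = edges[-(nbins + 1)], d_hi = edges[-1],
      mean_intensity = bin_mean,
      n_vox = bin_n
    )
  })
  attr(out, "one_sided") <- one_sided
  out
}
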