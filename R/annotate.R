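#' Assign tissue layer from radial position
#'
#' Radial bins are half-open and inner-inclusive: a nucleus exactly on a bin
#' boundary belongs to the inner layer. Nuclei beyond the outermost bound
#' are called `LRC` while within the cap's longitudinal extent, otherwise
#' flagged unassigned; nuclei below the QC (`z_root < 0`) are split into
#' `columella` (inner) and `LRC` (outer) by `columella_radius`.
#'
#' @param annotations Tibble with `z_root`, `r` (from
#'   [annotate_coordinates()]).
#' @param layer_radii Named strictly increasing outer bounds (µm),
#'   innermost first.
#' @param lrc_zmax Longitudinal extent of the lateral root cap (µm).
#' @param columella_radius Columella/LRC radial split below the QC (µm).
#' @return `annotations` with a `layer` column (`NA` = unassigned).
#' @export
assign_layer <- function(annotations, layer_radii,
                         lrc_zmax = 80, columella_radius = 15) {
  stopifnot(!is.unsorted(layer_radii, strictly = TRUE))
  nms <- names(layer_radii)
  idx <- rowSums(outer(annotations$r, unname(layer_radii), ">")) + 1L
  layer <- c(nms, "outer")[idx]
  layer[layer == "outer"] <-
    ifelse(annotations$z_root[layer == "outer"] <= lrc_zmax, "LRC",
           NA_character_)
  below <- annotations$z_root < 0
  layer[below] <- ifelse(annotations$r[below] <= columella_radius,
                         "columella", "LRC")
  annotations$layer <- layer
  annotations
}

# circular single-linkage clustering of azimuths: split the sorted circle at
# gaps larger than max(3 * median gap, min_gap)
circular_clusters <- function(phi, min_gap = 0.05) {
  n <- length(phi)
  if (n == 1) return(1L)
  ord <- order(phi)
  gaps <- diff(c(phi[ord], phi[ord[1]] + 2 * pi))
  thr <- max(3 * stats::median(gaps), min_gap)
  cut <- gaps > thr
  if (!any(cut)) return(rep(1L, n))
  # start numbering right after the largest gap so indices are deterministic
  start <- which.max(gaps)
  cl <- integer(n)
  cur <- 0L
  for (k in seq_len(n)) {
    pos <- (start + k - 1L) %% n + 1L
    prev <- (start + k - 2L) %% n + 1L
    if (k == 1L || cut[prev]) cur <- cur + 1L
    cl[ord[pos]] <- cur
  }
  cl
}

#' Cluster nuclei of each layer into longitudinal cell files
#'
#' Within each layer, nuclei are clustered by azimuth (circular
#' single-linkage with a data-driven gap threshold); file indices are stable
#' along `z` but arbitrary up to rotation, numbered from the largest
#' azimuthal gap. With fewer than `min_per_file` nuclei in a layer a single
#' file is assumed.
#'
#' @param annotations Tibble with `layer`, `phi`.
#' @param min_gap Minimum azimuthal gap (rad) accepted as a file boundary.
#' @param min_per_file Below this layer population, fall back to one file.
#' @return `annotations` with a `file` column (integer, per layer).
#' @export
assign_files <- function(annotations, min_gap = 0.05, min_per_file = 4) {
  stopifnot("layer" %in% names(annotations))
  annotations |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(file = if (dplyr::n() < min_per_file) {
      if (dplyr::n() < min_per_file && dplyr::n() > 1) {
        warning("layer '", .data$layer[1],
                "' has too few nuclei for file clustering; single file",
                call. = FALSE)
      }
      1L
    } else {
      circular_clusters(.data$phi, min_gap)
    }) |>
    dplyr::ungroup()
}

#' Classify epidermal files as trichoblast (T) or atrichoblast (AT)
#'
#' Uses the signature that T files in the proliferation domain are markedly
#' thinner (shorter cells, hence smaller inter-nucleus spacing) than AT
#' files. Per-file mean axial spacing is computed (within the PD when a
#' `zone` column exists), split into two classes by k-means, and the
#' smaller-spacing class is called T. If the two class means differ by less
#' than `min_contrast`, all files are left `NA` with a warning; borderline
#' files are resolved by alternation with their azimuthal neighbours.
#'
#' @param annotations Tibble with `layer`, `file`, `z_root`, `phi` (and
#'   optionally `zone`).
#' @param min_contrast Minimum AT/T spacing ratio accepted as real contrast.
#' @return `annotations` with a `subtype` column (`"T"`, `"AT"`, or `NA`).
#' @export
classify_epidermis <- function(annotations, min_contrast = 1.3) {
  annotations$subtype <- NA_character_
  epi <- annotations |> dplyr::filter(.data$layer == "epidermis")
  if (nrow(epi) == 0) return(annotations)
  scope <- if ("zone" %in% names(epi)) dplyr::filter(epi, .data$zone == "PD")
           else epi
  spacing <- scope |>
    dplyr::group_by(.data$file) |>
    dplyr::arrange(.data$z_root, .by_group = TRUE) |>
    dplyr::summarise(spacing = if (dplyr::n() >= 3) mean(diff(.data$z_root))
                     else NA_real_,
                     phi_mean = atan2(mean(sin(.data$phi)),
                                      mean(cos(.data$phi))),
                     .groups = "drop") |>
    dplyr::filter(!is.na(.data$spacing))
  if (nrow(spacing) < 2) {
    warning("not enough epidermal files with >= 3 PD nuclei; T/AT left NA",
            call. = FALSE)
    return(annotations)
  }
  if (diff(range(spacing$spacing)) < 1e-8) {
    warning("T/AT spacing distributions indistinguishable; subtype left NA",
            call. = FALSE)
    return(annotations)
  }
  km <- kmeans(spacing$spacing, centers = range(spacing$spacing))
  lo <- which.min(km$centers)
  if (max(km$centers) / min(km$centers) < min_contrast) {
    warning("T/AT spacing distributions indistinguishable; subtype left NA",
            call. = FALSE)
    return(annotations)
  }
  spacing$subtype <- ifelse(km$cluster == lo, "T", "AT")
  # alternation tie-break for files near the class midpoint
  mid <- mean(range(km$centers))
  spacing <- spacing[order(spacing$phi_mean), ]
  nf <- nrow(spacing)
  if (nf >= 3) {
    for (i in seq_len(nf)) {
      if (abs(spacing$spacing[i] - mid) < 0.1 * mid) {
        nb <- c(spacing$subtype[(i - 2) %% nf + 1],
                spacing$subtype[i %% nf + 1])
        flip <- setdiff(c("T", "AT"), nb)
        if (length(flip) == 1) spacing$subtype[i] <- flip
      }
    }
  }
  map <- setNames(spacing$subtype, spacing$file)
  sel <- annotations$layer == "epidermis" &
    as.character(annotations$file) %in% names(map)
  annotations$subtype[sel] <- map[as.character(annotations$file[sel])]
  annotations
}

#' Locate the PD/TD and TD/EZ zone boundaries from cell-size increase
#'
#' Per file, the PD/TD boundary is the tip-side end of the first
#' inter-nucleus spacing interval exceeding `k_td` times the median spacing
#' of the file's tip-most quarter, and the TD/EZ boundary where spacing
#' exceeds `k_ez` times that reference. Per-file boundaries are pooled
#' across files by the median, which provides the robustness to jitter. If
#' no file shows a spacing increase the whole root is called PD with a
#' warning.
#'
#' @param annotations Tibble with `layer`, `file`, `z_root`.
#' @param k_td Spacing-increase factor defining the PD/TD boundary (> 1).
#' @param k_ez Factor defining the TD/EZ boundary (> `k_td`).
#' @param min_file_n Files with fewer nuclei are skipped.
#' @return `annotations` with a `zone` column; pooled boundaries are
#'   attached as `attr(, "boundaries")`.
#' @export
assign_zone <- function(annotations, k_td = 1.5, k_ez = 3, min_file_n = 5) {
  stopifnot(k_td > 1, k_ez > k_td)
  per_file <- annotations |>
    dplyr::filter(.data$z_root >= 0) |>
    dplyr::group_by(.data$layer, .data$file) |>
    dplyr::arrange(.data$z_root, .by_group = TRUE) |>
    dplyr::summarise(bounds = list({
      zs <- .data$z_root
      if (length(zs) < min_file_n) c(NA_real_, NA_real_) else {
        sp <- diff(zs)
        zlo <- zs[-length(zs)] # tip-side end of each spacing interval
        ref <- stats::median(sp[seq_len(max(3, ceiling(length(sp) / 4)))])
        # raw spacings: robustness comes from pooling boundaries across
        # files, and smoothing would suppress a step at a file's end
        b1 <- zlo[which(sp > k_td * ref)[1]]
        b2 <- zlo[which(sp > k_ez * ref)[1]]
        c(if (is.na(b1)) NA_real_ else b1, if (is.na(b2)) NA_real_ else b2)
      }
    }), .groups = "drop")
  B <- do.call(rbind, per_file$bounds)
  z_td <- stats::median(B[, 1], na.rm = TRUE)
  z_ez <- stats::median(B[, 2], na.rm = TRUE)
  if (is.na(z_td)) {
    warning("no spacing increase found; whole root assigned PD",
            call. = FALSE)
    annotations$zone <- "PD"
    attr(annotations, "boundaries") <- c(pd_td = NA_real_, td_ez = NA_real_)
    return(annotations)
  }
  if (!is.na(z_ez) && z_ez < z_td) z_ez <- z_td
  annotations$zone <- ifelse(annotations$z_root < z_td, "PD",
                             ifelse(is.na(z_ez) | annotations$z_root < z_ez,
                                    "TD", "EZ"))
  attr(annotations, "boundaries") <- c(pd_td = z_td, td_ez = z_ez)
  annotations
}

#' Radial position of the nucleus within its cell (L1/L2)
#'
#' Walks the radial ray through each nucleus centroid: L1 is the distance
#' from the outer edge of the nucleus to the first cell-wall intensity peak
#' outward, L2 the inward analogue. Both in µm; `NA` with a flag when no
#' wall signal is found on the ray.
#'
#' @param records Feature tibble with `id`, `x`, `y`, `z`.
#' @param stack [voxel_stack()] with a `wall` channel.
#' @param labels Label array matching `stack`.
#' @param frame A [fit_axis()] result (defines the radial direction).
#' @param max_reach Maximum ray length searched on each side (µm).
#' @param wall_min Minimum wall intensity accepted as a wall peak, as a
#'   fraction of the channel's maximum.
#' @return Tibble with `id`, `L1`, `L2`, `measured`.
#' @export
nucleus_position_in_cell <- function(records, stack, labels, frame,
                                     max_reach = 12, wall_min = 0.25) {
  wall <- get_channel(stack, "wall")
  dims <- dim(wall)
  vx <- stack$voxel_size
  step <- min(vx) / 2
  thr <- wall_min * max(wall)
  cyl <- to_cylindrical(frame, records[, c("x", "y", "z")])
  fp <- foot_point(frame, as.matrix(records[, c("x", "y", "z")]))
  C0 <- curve_at(frame, fp$t)
  if (is.null(dim(C0))) C0 <- matrix(C0, ncol = 3)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    p0 <- as.numeric(records[i, c("x", "y", "z")])
    dir <- p0 - C0[i, ]
    nr <- sqrt(sum(dir^2))
    if (nr < 1e-9) {
      return(tibble::tibble(id = records$id[i], L1 = NA_real_,
                            L2 = NA_real_, measured = FALSE))
    }
    dir <- dir / nr
    sample_ray <- function(sign) {
      ss <- seq(0, max_reach, by = step)
      pts <- sweep(outer(sign * ss, dir), 2, p0, "+")
      iv <- round(sweep(pts, 2, vx, "/") + 0.5)
      ok <- iv[, 1] >= 1 & iv[, 1] <= dims[1] & iv[, 2] >= 1 &
        iv[, 2] <= dims[2] & iv[, 3] >= 1 & iv[, 3] <= dims[3]
      flat <- (iv[, 3] - 1) * dims[1] * dims[2] + (iv[, 2] - 1) * dims[1] +
        iv[, 1]
      list(s = ss[ok], wall = wall[flat[ok]], lab = labels[flat[ok]])
    }
    measure <- function(ray) {
      inside <- ray$lab == records$id[i]
      if (!any(inside)) return(NA_real_)
      edge_s <- max(ray$s[inside]) # last ray sample still in the nucleus
      beyond <- ray$s > edge_s
      w <- ray$wall
      w[!beyond] <- -Inf
      peaks <- which(w >= thr &
                       w >= c(-Inf, w[-length(w)]) &
                       w >= c(w[-1], -Inf))
      if (!length(peaks)) return(NA_real_)
      ray$s[peaks[1]] - edge_s
    }
    L1 <- measure(sample_ray(+1)) # outward
    L2 <- measure(sample_ray(-1)) # inward
    tibble::tibble(id = records$id[i], L1 = L1, L2 = L2,
                   measured = !is.na(L1) && !is.na(L2))
  })
}
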