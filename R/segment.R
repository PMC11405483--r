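#' Otsu threshold of an intensity volume
#'
#' Standard between-class-variance maximisation on a fixed-bin histogram;
#' the reproducible stand-in for an interactive threshold choice.
#'
#' @param x Numeric vector or array of intensities.
#' @param levels Number of histogram bins.
#' @return Threshold value on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(levels, 1L + floor((x - r[1]) / diff(r) * levels)),
                nbins = levels)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(levels) - 0.5) / levels * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# fill background cavities not connected to the volume boundary (6-conn
# complement, the dual of 26-conn foreground)
fill_holes_3d <- function(mask, dims) {
  bg <- !mask
  comp <- .cc_label_3d(as.logical(bg), as.integer(dims), 6L)
  comp <- array(comp, dims)
  edge_ids <- unique(c(comp[1, , ], comp[dims[1], , ],
                       comp[, 1, ], comp[, dims[2], ],
                       comp[, , 1], comp[, , dims[3]]))
  edge_ids <- setdiff(edge_ids, 0L)
  mask | (comp > 0L & !(comp %in% edge_ids))
}

#' Detect nuclei in the DNA channel
#'
#' Thresholds the DNA channel (Otsu by default), labels 26-connected
#' components, and optionally splits touching nuclei by a distance-transform
#' watershed: internal cavities (nucleoli) are filled, seeds are placed on
#' local maxima of the anisotropic distance transform (keeping, per
#' component, maxima at least half the component's peak depth and at least
#' `min_seed_sep_um` apart, strongest first), and seed labels are grown by
#' priority flood. Final labels are intersected with the unfilled mask, so
#' DNA-void nucleolar cavities stay unlabelled.
#'
#' @param stack A [voxel_stack()] with a `dna` channel.
#' @param config A [run_config()]; uses `threshold`, `connectivity`,
#'   `split_touching`, `min_seed_sep_um`.
#' @return Integer label array (0 = background), with the threshold used in
#'   attribute `threshold`.
#' @export
segment_nuclei <- function(stack, config = run_config()) {
  dna <- get_channel(stack, "dna")
  dims <- dim(dna)
  if (diff(range(dna)) == 0) {
    warning("DNA channel is flat; no objects detected")
    return(structure(array(0L, dims), threshold = NA_real_))
  }
  thr <- if (is.null(config$threshold)) otsu_threshold(dna) else config$threshold
  mask <- dna > thr
  if (!any(mask)) {
    warning("no voxels above threshold; no objects detected")
    return(structure(array(0L, dims), threshold = thr))
  }
  labels <- .cc_label_3d(as.logical(mask), as.integer(dims),
                         as.integer(config$connectivity))
  if (isTRUE(config$split_touching)) {
    filled <- fill_holes_3d(mask, dims)
    dist <- .chamfer_dist_3d(as.logical(filled), as.integer(dims),
                             stack$voxel_size)
    maxima <- .local_maxima_3d(dist, as.logical(filled), as.integer(dims), 0)
    plateau <- .cc_label_3d(maxima, as.integer(dims), 26L)
    cand <- which(plateau > 0L)
    if (length(cand)) {
      comp_of <- .cc_label_3d(as.logical(filled), as.integer(dims),
                              as.integer(config$connectivity))
      pl <- plateau[cand]
      first <- !duplicated(pl)
      seed_vox <- cand[first]
      seed_val <- dist[seed_vox]
      seed_comp <- comp_of[seed_vox]
      pos <- sweep(arrayInd(seed_vox, dims) - 0.5, 2, stack$voxel_size, "*")
      keep <- logical(length(seed_vox))
      for (cmp in unique(seed_comp)) {
        in_c <- which(seed_comp == cmp)
        in_c <- in_c[seed_val[in_c] >= 0.5 * max(seed_val[in_c])]
        in_c <- in_c[order(-seed_val[in_c])]
        kept <- integer(0)
        for (s in in_c) {
          if (!length(kept) ||
              min(sqrt(rowSums((pos[kept, , drop = FALSE] -
                                matrix(pos[s, ], length(kept), 3,
                                       byrow = TRUE))^2))) >=
                config$min_seed_sep_um) {
            kept <- c(kept, s)
          }
        }
        keep[kept] <- TRUE
      }
      seeds <- array(0L, dims)
      seeds[seed_vox[keep]] <- seq_len(sum(keep))
      ws <- .watershed_seeded_3d(dist, as.integer(seeds), as.logical(filled),
                                 as.integer(dims),
                                 as.integer(config$connectivity))
      labels <- ws
      labels[!mask] <- 0L
    }
  }
  # relabel sequentially
  uid <- sort(unique(labels[labels > 0L]))
  out <- array(0L, dims)
  nz <- labels > 0L
  out[nz] <- match(labels[nz], uid)
  structure(out, threshold = thr)
}

#' Extract per-nucleus morphometric features
#'
#' One record per label: centroid, volume (voxel count times voxel volume),
#' surface area by boundary-face counting (faces weighted by their physical
#' area), bounding extents W/H/D along the stack axes, per-channel integrated
#' intensity and intensity-weighted center of mass, and the asymmetry vector
#' (centroid minus DNA center of mass) with its Euclidean norm. All outputs
#' are in µm-based units.
#'
#' @param labels Integer label array from [segment_nuclei()].
#' @param stack The [voxel_stack()] the labels were derived from.
#' @return A tibble with one row per nucleus.
#' @export
extract_features <- function(labels, stack) {
  dims <- dim(stack)
  stopifnot(all(dim(labels) == dims))
  vx <- stack$voxel_size
  idx <- which(labels > 0L)
  empty <- tibble::tibble(
    id = integer(), x = double(), y = double(), z = double(),
    volume_um3 = double(), surface_um2 = double(),
    w_um = double(), h_um = double(), d_um = double()
  )
  if (!length(idx)) return(empty)
  lab <- labels[idx]
  uid <- sort(unique(lab))
  li <- match(lab, uid)
  counts <- tabulate(li, nbins = length(uid))
  coord <- arrayInd(idx, dims)
  pos <- sweep(coord - 0.5, 2, vx, "*")
  centroid <- rowsum(pos, li) / counts
  dimnames(centroid) <- NULL
  ext <- vapply(1:3, function(d) {
    rng <- vapply(split(coord[, d], li), range, numeric(2))
    unname((rng[2, ] + 1 - rng[1, ]) * vx[d])
  }, numeric(length(uid)))
  if (is.null(dim(ext))) ext <- matrix(ext, nrow = 1)

  # surface area: count label boundary faces per axis, weighted by face area
  surf <- numeric(length(uid))
  for (d in 1:3) {
    area <- prod(vx[-d])
    n_d <- dims[d]
    take <- function(i) switch(d,
                               labels[i, , , drop = FALSE],
                               labels[, i, , drop = FALSE],
                               labels[, , i, drop = FALSE])
    a <- take(seq_len(n_d - 1)); b <- take(2:n_d)
    mism <- a != b
    expose <- c(a[mism & a > 0L], b[mism & b > 0L],
                take(1)[take(1) > 0L], take(n_d)[take(n_d) > 0L])
    if (length(expose)) {
      cnt <- tabulate(match(expose, uid), nbins = length(uid))
      surf <- surf + cnt * area
    }
  }

  rec <- tibble::tibble(
    id = uid,
    x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
    volume_um3 = counts * prod(vx),
    surface_um2 = surf,
    w_um = ext[, 1], h_um = ext[, 2], d_um = ext[, 3]
  )
  for (ch in names(stack$channels)) {
    w <- stack$channels[[ch]][idx]
    tot <- unname(rowsum(w, li)[, 1])
    com <- rowsum(pos * w, li) / ifelse(tot > 0, tot, NA_real_)
    dimnames(com) <- NULL
    rec[[paste0(ch, "_total")]] <- tot
    rec[[paste0(ch, "_com_x")]] <- com[, 1]
    rec[[paste0(ch, "_com_y")]] <- com[, 2]
    rec[[paste0(ch, "_com_z")]] <- com[, 3]
  }
  if ("dna_total" %in% names(rec)) {
    rec$asym_x <- rec$x - rec$dna_com_x
    rec$asym_y <- rec$y - rec$dna_com_y
    rec$asym_z <- rec$z - rec$dna_com_z
    rec$asym_norm <- sqrt(rec$asym_x^2 + rec$asym_y^2 + rec$asym_z^2)
  }
  rec
}

#' Remove records outside a plausible volume window
#'
#' Rule-based replacement for manual curation: drops putative fused nuclei
#' (too large) and background speckles (too small).
#'
#' @param records Feature tibble from [extract_features()].
#' @param vmin,vmax Volume window in µm³.
#' @return The retained records; the removed rows are attached as
#'   `attr(, "removed")`.
#' @export
curate <- function(records, vmin, vmax) {
  stopifnot(vmin < vmax)
  drop <- records$volume_um3 < vmin | records$volume_um3 > vmax
  out <- records[!drop, , drop = FALSE]
  attr(out, "removed") <- records[drop, , drop = FALSE]
  out
}

#' Measure the DNA-void nucleolar cavity of each nucleus
#'
#' A nucleolus is detected as the largest connected low-intensity cavity
#' fully enclosed by the nucleus label mask (6-connected complement within a
#' one-voxel-padded bounding box); cavities that touch the outside of the
#' nucleus are not counted. Volume 0 means no enclosed cavity.
#'
#' @param labels Integer label array.
#' @param stack The matching [voxel_stack()] (used for voxel spacing).
#' @param ids Labels to measure (default: all).
#' @return Tibble with `id` and `nucleolus_um3`.
#' @export
detect_nucleolus <- function(labels, stack, ids = NULL) {
  dims <- dim(labels)
  vx <- stack$voxel_size
  if (is.null(ids)) ids <- sort(unique(labels[labels > 0L]))
  idx_all <- which(labels > 0L)
  coord_all <- arrayInd(idx_all, dims)
  lab_all <- labels[idx_all]
  out <- purrr::map_dfr(ids, function(id) {
    sel <- lab_all == id
    if (!any(sel)) return(tibble::tibble(id = id, nucleolus_um3 = NA_real_))
    cc <- coord_all[sel, , drop = FALSE]
    i0 <- pmax(apply(cc, 2, min) - 1L, 1L)
    i1 <- pmin(apply(cc, 2, max) + 1L, dims)
    crop <- labels[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
    cd <- dim(crop)
    bg <- crop != id
    comp <- array(.cc_label_3d(as.logical(bg), as.integer(cd), 6L), cd)
    edge <- unique(c(comp[1, , ], comp[cd[1], , ], comp[, 1, ],
                     comp[, cd[2], ], comp[, , 1], comp[, , cd[3]]))
    cavity_ids <- setdiff(unique(comp[comp > 0L]), edge)
    vol <- if (length(cavity_ids)) {
      max(tabulate(match(comp[comp %in% cavity_ids], cavity_ids))) * prod(vx)
    } else 0
    tibble::tibble(id = id, nucleolus_um3 = vol)
  })
  out
}
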