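#' Maximal same-state runs of a sequence
#'
#' Thin wrapper over [rle()] returning one row per maximal run, the
#' primitive behind the cell-file clustering statistics.
#'
#' @param x Atomic vector of states, already in positional order.
#' @return Tibble with `state` and `length`, in sequence order.
#' @export
run_lengths <- function(x) {
  if (!length(x)) return(tibble::tibble(state = character(), length = integer()))
  r <- rle(as.character(x))
  tibble::tibble(state = r$values, length = r$lengths)
}

#' Classify per-nucleus EdU incorporation patterns (S0/S1/S2)
#'
#' Background statistics are taken from the EdU channel outside all labels;
#' a voxel is EdU-positive above `mean + noise_k * SD` and a nucleus is S0
#' when its integrated EdU signal is within `noise_k` SD of the expected
#' background sum. Labelled nuclei are S1 (homogeneous) when the positive
#' fraction of the mask reaches `coverage_threshold`, otherwise S2 (spotted)
#' via local-maximum focus detection (`min_spots` foci at least
#' `min_spot_sep_um` apart). A labelled nucleus matching neither archetype
#' is resolved to S2 when it has any focus, else S1, and flagged ambiguous.
#' All thresholds are relative to background statistics, so calls are
#' invariant to uniform intensity rescaling.
#'
#' @param stack A [voxel_stack()] with an `edu` channel.
#' @param labels Label array.
#' @param config A [run_config()]; uses `noise_k`, `coverage_threshold`,
#'   `min_spots`, `min_spot_sep_um`.
#' @return Tibble with `id`, `pattern`, `edu_total`, `coverage`, `n_spots`,
#'   `ambiguous`, and a nested `spots` tibble (centroids and integrated
#'   intensity per focus).
#' @export
classify_edu_pattern <- function(stack, labels, config = run_config()) {
  edu <- get_channel(stack, "edu")
  dims <- dim(edu)
  vx <- stack$voxel_size
  bg <- edu[labels == 0L]
  bg_mean <- mean(bg); bg_sd <- sd(bg)
  if (is.na(bg_sd)) bg_sd <- 0
  pos_thr <- bg_mean + config$noise_k * bg_sd
  idx_all <- which(labels > 0L)
  lab_all <- labels[idx_all]
  ids <- sort(unique(lab_all))
  purrr::map_dfr(ids, function(id) {
    vi <- idx_all[lab_all == id]
    v <- edu[vi]
    n <- length(v)
    total <- sum(v)
    floor_n <- n * bg_mean + config$noise_k * bg_sd * sqrt(n)
    coverage <- mean(v > pos_thr)
    spots <- tibble::tibble(x = double(), y = double(), z = double(),
                            intensity = double())
    pattern <- "S0"; ambiguous <- FALSE
    if (total > floor_n && coverage > 0) {
      # focus detection on the nucleus crop
      coord <- arrayInd(vi, dims)
      i0 <- pmax(apply(coord, 2, min) - 1L, 1L)
      i1 <- pmin(apply(coord, 2, max) + 1L, dims)
      cd <- i1 - i0 + 1L
      crop <- array(0, cd); cmask <- array(FALSE, cd)
      rel <- sweep(coord, 2, i0 - 1L)
      flat <- (rel[, 3] - 1) * cd[1] * cd[2] + (rel[, 2] - 1) * cd[1] + rel[, 1]
      crop[flat] <- v
      cmask[flat] <- TRUE
      mx <- .local_maxima_3d(crop, as.logical(cmask), as.integer(cd), pos_thr)
      plateau <- .cc_label_3d(mx, as.integer(cd), 26L)
      cand <- which(plateau > 0L)
      if (length(cand)) {
        first <- !duplicated(plateau[cand])
        sv <- cand[first]
        val <- crop[sv]
        posn <- sweep(arrayInd(sv, cd) + (matrix(i0 - 1L, length(sv), 3,
                                                 byrow = TRUE)) - 0.5,
                      2, vx, "*")
        ord <- order(-val)
        kept <- integer(0)
        for (s in ord) {
          if (!length(kept) ||
              min(sqrt(rowSums((posn[kept, , drop = FALSE] -
                                matrix(posn[s, ], length(kept), 3,
                                       byrow = TRUE))^2))) >=
                config$min_spot_sep_um) {
            kept <- c(kept, s)
          }
        }
        if (length(kept)) {
          # integrate each focus over the positive voxels nearest to it
          pvi <- vi[v > pos_thr]
          ppos <- sweep(arrayInd(pvi, dims) - 0.5, 2, vx, "*")
          d2 <- vapply(kept, function(s) {
            rowSums(sweep(ppos, 2, posn[s, ])^2)
          }, numeric(nrow(ppos)))
          if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
          assign_to <- max.col(-d2)
          spots <- tibble::tibble(
            x = posn[kept, 1], y = posn[kept, 2], z = posn[kept, 3],
            intensity = vapply(seq_along(kept), function(k) {
              sum(edu[pvi[assign_to == k]])
            }, numeric(1))
          )
        }
      }
      n_spots <- nrow(spots)
      if (coverage >= config$coverage_threshold) {
        pattern <- "S1"
      } else if (n_spots >= config$min_spots) {
        pattern <- "S2"
      } else {
        pattern <- if (n_spots >= 1) "S2" else "S1"
        ambiguous <- TRUE
      }
    }
    tibble::tibble(id = id, pattern = pattern, edu_total = total,
                   coverage = coverage, n_spots = nrow(spots),
                   ambiguous = ambiguous, spots = list(spots))
  })
}

#' Pattern proportions across incubation times
#'
#' Tabulates S0/S1/S2 proportions per incubation time (and optionally per
#' cell type), tests homogeneity of the pattern composition across times
#' with a chi-squared test (no continuity correction), and summarises the
#' monotonicity of the labelled fraction over time.
#'
#' @param calls Tibble with `pattern` and `time` columns (and optionally
#'   `cell_type`).
#' @return Object of class `pattern_timecourse`; see [tidy()]/[glance()].
#' @export
pattern_timecourse <- function(calls) {
  stopifnot(all(c("pattern", "time") %in% names(calls)))
  if (length(unique(calls$time)) < 2) {
    stop("need at least 2 time points", call. = FALSE)
  }
  has_type <- "cell_type" %in% names(calls)
  grp <- if (has_type) c("time", "cell_type") else "time"
  props <- calls |>
    dplyr::count(dplyr::across(dplyr::all_of(c(grp, "pattern")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  tab <- table(calls$time, calls$pattern)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  lab_frac <- calls |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(labelled = mean(.data$pattern != "S0"),
                     .groups = "drop") |>
    dplyr::arrange(.data$time)
  monotone <- all(diff(lab_frac$labelled) >= 0) ||
    all(diff(lab_frac$labelled) <= 0)
  structure(
    list(proportions = props, statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value,
         labelled_fraction = lab_frac, monotone = monotone),
    class = "pattern_timecourse"
  )
}

#' @export
print.pattern_timecourse <- function(x, ...) {
  cat("<pattern_timecourse> X2 = ", signif(x$statistic, 4), " (df ", x$df,
      "), p = ", signif(x$p_value, 3),
      if (x$monotone) "; labelled fraction monotone in time" else "",
      "\n", sep = "")
  print(x$labelled_fraction)
  invisible(x)
}

#' @export
tidy.pattern_timecourse <- function(x, ...) x$proportions

#' @export
glance.pattern_timecourse <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 monotone_labelled_fraction = x$monotone)
}

#' Mark colocalization of EdU-positive chromatin by pattern
#'
#' For each S1/S2 nucleus, the fraction of EdU-positive voxels that are also
#' positive for each chromatin mark (both thresholded at background mean
#' plus `noise_k` SD of the respective channel outside all labels), with
#' group means and normal-theory confidence intervals by pattern.
#'
#' @param calls Output of [classify_edu_pattern()].
#' @param stack A [voxel_stack()].
#' @param labels Label array.
#' @param marks Channel names to test (default both histone marks).
#' @param config A [run_config()].
#' @return List of class `mark_overlap` with `per_nucleus` and `summary`
#'   tibbles.
#' @export
mark_overlap_by_pattern <- function(calls, stack, labels,
                                    marks = c("h3k4me1", "h3k9me2"),
                                    config = run_config()) {
  edu <- get_channel(stack, "edu")
  thr_of <- function(ch) {
    v <- get_channel(stack, ch)[labels == 0L]
    mean(v) + config$noise_k * sd(v)
  }
  edu_thr <- thr_of("edu")
  mark_thr <- vapply(marks, thr_of, numeric(1))
  idx_all <- which(labels > 0L)
  lab_all <- labels[idx_all]
  lab_calls <- calls[calls$pattern %in% c("S1", "S2"), ]
  per <- purrr::map_dfr(seq_len(nrow(lab_calls)), function(i) {
    id <- lab_calls$id[i]
    vi <- idx_all[lab_all == id]
    pos <- edu[vi] > edu_thr
    if (!any(pos)) {
      stop("S1/S2 nucleus ", id, " has no EdU-positive voxels: ",
           "inconsistent call", call. = FALSE)
    }
    ov <- vapply(seq_along(marks), function(m) {
      mean(get_channel(stack, marks[m])[vi][pos] > mark_thr[m])
    }, numeric(1))
    tibble::tibble(id = id, pattern = lab_calls$pattern[i],
                   mark = marks, overlap = ov)
  })
  summ <- per |>
    dplyr::group_by(.data$pattern, .data$mark) |>
    dplyr::summarise(
      mean_overlap = mean(.data$overlap),
      conf_low = mean(.data$overlap) -
        1.96 * sd(.data$overlap) / sqrt(dplyr::n()),
      conf_high = mean(.data$overlap) +
        1.96 * sd(.data$overlap) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
  structure(list(per_nucleus = per, summary = summ), class = "mark_overlap")
}

#' @export
print.mark_overlap <- function(x, ...) {
  cat("<mark_overlap> mean mark/EdU overlap by pattern:\n")
  print(x$summary)
  invisible(x)
}

#' Run-length clustering of nuclei states along cell files
#'
#' Orders the nuclei of each cell file by arclength (ties broken by id),
#' maps EdU patterns to state groups (default: labelled = S1 or S2 versus
#' S0), extracts maximal same-state runs per file and pools them into a
#' run-length histogram per state.
#'
#' @param annotations Tibble with `id`, `layer`, `file`, `z_root` (and
#'   `zone` if `zones` is used).
#' @param calls Tibble with `id`, `pattern`.
#' @param states Named list mapping state-group name to the patterns it
#'   contains.
#' @param layers Optional layer restriction.
#' @param zones Optional zone restriction (applied before run extraction).
#' @return Object of class `cluster_distribution` with elements
#'   `histogram` (state, length, count), `mean_length`, `n_runs`, `n_nuclei`.
#' @export
file_run_lengths <- function(annotations, calls,
                             states = list(labelled = c("S1", "S2"),
                                           S0 = "S0"),
                             layers = NULL, zones = NULL) {
  d <- dplyr::inner_join(annotations, calls[, c("id", "pattern")], by = "id")
  if (!is.null(layers)) d <- d[d$layer %in% layers, ]
  if (!is.null(zones)) d <- d[d$zone %in% zones, ]
  smap <- unlist(lapply(names(states), function(s) {
    setNames(rep(s, length(states[[s]])), states[[s]])
  }))
  d$state <- smap[d$pattern]
  d <- d[!is.na(d$state), ]
  if (anyDuplicated(d[, c("layer", "file", "z_root")])) {
    warning("ties in z within a file; ordered by id", call. = FALSE)
  }
  runs <- d |>
    dplyr::group_by(.data$layer, .data$file) |>
    dplyr::arrange(.data$z_root, .data$id, .by_group = TRUE) |>
    dplyr::group_modify(function(dd, key) run_lengths(dd$state)) |>
    dplyr::ungroup()
  hist <- runs |>
    dplyr::count(.data$state, .data$length, name = "count") |>
    dplyr::arrange(.data$state, .data$length)
  means <- runs |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mean_length = mean(.data$length),
                     n_runs = dplyr::n(), .groups = "drop")
  structure(
    list(histogram = hist, mean_length = means,
         n_runs = nrow(runs),
         n_nuclei = tibble::as_tibble(table(state = d$state))),
    class = "cluster_distribution"
  )
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat("<cluster_distribution> ", x$n_runs, " runs\n", sep = "")
  print(x$mean_length)
  invisible(x)
}

#' Compare two run-length distributions
#'
#' Chi-squared homogeneity test on the binned run-length histograms of one
#' state, with tail bins pooled so every expected count is at least 5.
#'
#' @param d1,d2 [file_run_lengths()] results.
#' @param state State-group to compare.
#' @return Object of class `cluster_comparison` with `statistic`, `df`,
#'   `p_value`, and the pooled table.
#' @export
compare_cluster_distributions <- function(d1, d2, state = "labelled") {
  h1 <- d1$histogram[d1$histogram$state == state, ]
  h2 <- d2$histogram[d2$histogram$state == state, ]
  if (nrow(h1) == 0 || nrow(h2) == 0) {
    stop("state '", state, "' absent from a histogram", call. = FALSE)
  }
  lens <- sort(unique(c(h1$length, h2$length)))
  c1 <- setNames(rep(0, length(lens)), lens)
  c2 <- c1
  c1[as.character(h1$length)] <- h1$count
  c2[as.character(h2$length)] <- h2$count
  if (length(lens) == 1) {
    out <- list(statistic = 0, df = 0, p_value = 1,
                table = rbind(c1, c2), pooled_from = length(lens))
    class(out) <- "cluster_comparison"
    return(out)
  }
  # pool from the longest run downward until all expected counts reach 5
  repeat {
    tab <- rbind(c1, c2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (ncol(tab) <= 2 || min(expected) >= 5) break
    k <- ncol(tab)
    c1 <- c(c1[1:(k - 2)], sum(c1[(k - 1):k]))
    c2 <- c(c2[1:(k - 2)], sum(c2[(k - 1):k]))
  }
  if (ncol(tab) < 2 ||
      any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    out <- list(statistic = 0, df = 0, p_value = 1, table = tab,
                pooled_from = length(lens))
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out <- list(statistic = unname(ct$statistic),
                df = unname(ct$parameter), p_value = ct$p.value,
                table = tab, pooled_from = length(lens))
  }
  class(out) <- "cluster_comparison"
  out
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat("<cluster_comparison> X2 = ", signif(x$statistic, 4), " (df ", x$df,
      "), p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' @export
glance.cluster_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}
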