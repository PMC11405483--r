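#' Fit the root axis through a cloud of nucleus centroids
#'
#' Orders centroids along their first principal axis, fits one smoothing
#' spline per Cartesian coordinate against that ordering, reparametrises the
#' fitted curve, and anchors arclength `z = 0` at the projection of the
#' supplied quiescent-center position. The azimuthal reference is a
#' parallel-transported normal frame, so file indices derived from it are
#' stable along the root but arbitrary up to a global rotation.
#'
#' @param records Feature tibble with centroid columns `x`, `y`, `z` (µm).
#' @param qc_position Numeric length-3, Cartesian QC position (µm).
#' @param df Effective degrees of freedom of the axis spline; 4 accommodates
#'   a smooth bend while resisting the radial (layer) structure of the
#'   cloud.
#' @param n_grid Resolution of the internal arclength grid.
#' @return An object of class `root_frame`.
#' @export
fit_axis <- function(records, qc_position, df = 4, n_grid = 512) {
  P <- as.matrix(records[, c("x", "y", "z")])
  if (nrow(P) < 20) {
    stop("need at least 20 nuclei to fit the root axis", call. = FALSE)
  }
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  if (sv$d[2] / sv$d[1] > 0.9 && sv$d[1] < 1e-8) {
    stop("degenerate point cloud: no principal axis", call. = FALSE)
  }
  u1 <- sv$v[, 1]
  # orient the axis away from the QC so arclength increases shootward
  if (sum((as.numeric(qc_position) - ctr) * u1) > 0) u1 <- -u1
  t_raw <- drop(sweep(P, 2, ctr) %*% u1)
  # average the tube cloud in axial bins, then spline through the bin means:
  # fitting raw centroids would chase the radial (layer) structure
  n_bins <- max(8L, min(40L, floor(nrow(P) / 15)))
  bin <- cut(t_raw, breaks = n_bins, labels = FALSE)
  bt <- tapply(t_raw, bin, mean)
  bw <- tapply(t_raw, bin, length)
  fits <- lapply(1:3, function(k) {
    bm <- tapply(P[, k], bin, mean)
    stats::smooth.spline(bt, bm, w = bw, df = min(df, length(bt) - 2))
  })
  t_rng <- range(t_raw)
  # pad slightly so the QC projection cannot fall off the curve end
  t_rng <- t_rng + c(-0.03, 0.03) * diff(t_rng)
  tg <- seq(t_rng[1], t_rng[2], length.out = n_grid)
  C <- vapply(fits, function(f) predict(f, tg)$y, numeric(n_grid))
  D <- vapply(fits, function(f) predict(f, tg, deriv = 1)$y, numeric(n_grid))
  speed <- sqrt(rowSums(D^2))
  s_grid <- c(0, cumsum((speed[-1] + speed[-n_grid]) / 2 * diff(tg)))
  # parallel-transported normal along the grid
  Tm <- D / speed
  Nm <- matrix(0, n_grid, 3)
  ref <- c(0, 1, 0)
  if (abs(sum(ref * Tm[1, ])) > 0.9) ref <- c(0, 0, 1)
  Nm[1, ] <- normalize(ref - sum(ref * Tm[1, ]) * Tm[1, ])
  for (i in 2:n_grid) {
    v <- Nm[i - 1, ] - sum(Nm[i - 1, ] * Tm[i, ]) * Tm[i, ]
    Nm[i, ] <- normalize(v)
  }
  frame <- structure(
    list(fits = fits, t_grid = tg, s_grid = s_grid, C_grid = C,
         T_grid = Tm, N_grid = Nm, s_qc = 0, length = max(s_grid)),
    class = "root_frame"
  )
  qc <- foot_point(frame, matrix(qc_position, 1))
  frame$s_qc <- qc$s_raw
  cyl <- to_cylindrical(frame, records[, c("x", "y", "z")])
  frame$residual_r_rms <- sqrt(mean(cyl$r^2)) # spread of centroids about axis
  frame
}

normalize <- function(v) v / sqrt(sum(v^2))

#' @export
print.root_frame <- function(x, ...) {
  cat("<root_frame> length ", round(x$length, 1), " um; QC at arclength ",
      round(x$s_qc, 1), " um from curve start\n", sep = "")
  if (!is.null(x$residual_r_rms)) {
    cat("  RMS radial spread of fitted nuclei: ",
        round(x$residual_r_rms, 2), " um\n", sep = "")
  }
  invisible(x)
}

# curve evaluation in the internal spline parameter t
curve_at <- function(frame, t, deriv = 0) {
  vapply(frame$fits, function(f) predict(f, t, deriv = deriv)$y,
         numeric(length(t)))
}

# orthonormal (T, N, B) at parameter t; N interpolated from the transported
# grid and re-orthogonalised, so forward and inverse mappings agree exactly
frame_at <- function(frame, t) {
  t <- pmin(max(frame$t_grid), pmax(min(frame$t_grid), t))
  D <- curve_at(frame, t, deriv = 1)
  if (is.null(dim(D))) D <- matrix(D, ncol = 3)
  Tm <- D / sqrt(rowSums(D^2))
  Ni <- vapply(1:3, function(k) {
    stats::approx(frame$t_grid, frame$N_grid[, k], t, rule = 2)$y
  }, numeric(length(t)))
  if (is.null(dim(Ni))) Ni <- matrix(Ni, ncol = 3)
  Ni <- Ni - rowSums(Ni * Tm) * Tm
  Ni <- Ni / sqrt(rowSums(Ni^2))
  Bm <- cbind(Tm[, 2] * Ni[, 3] - Tm[, 3] * Ni[, 2],
              Tm[, 3] * Ni[, 1] - Tm[, 1] * Ni[, 3],
              Tm[, 1] * Ni[, 2] - Tm[, 2] * Ni[, 1])
  list(T = Tm, N = Ni, B = Bm)
}

arclength_at <- function(frame, t) {
  stats::approx(frame$t_grid, frame$s_grid, t, rule = 2)$y
}

t_of_arclength <- function(frame, s) {
  stats::approx(frame$s_grid, frame$t_grid, s, rule = 2)$y
}

# nearest curve point: coarse grid argmin + vectorised Newton refinement of
# g(t) = (p - c(t)) . c'(t) = 0 across all points at once
foot_point <- function(frame, P) {
  n <- nrow(P)
  tg <- frame$t_grid
  # coarse init, chunked to bound memory
  t <- numeric(n)
  step_size <- 2000L
  for (lo in seq(1, n, by = step_size)) {
    hi <- min(n, lo + step_size - 1L)
    G2 <- rowSums(frame$C_grid^2)
    D2 <- outer(rowSums(P[lo:hi, , drop = FALSE]^2), G2, "+") -
      2 * P[lo:hi, , drop = FALSE] %*% t(frame$C_grid)
    t[lo:hi] <- tg[max.col(-D2, ties.method = "first")]
  }
  active <- rep(TRUE, n)
  for (iter in 1:50) {
    ia <- which(active)
    if (!length(ia)) break
    ta <- t[ia]
    c0 <- curve_at(frame, ta)
    d1 <- curve_at(frame, ta, deriv = 1)
    d2v <- curve_at(frame, ta, deriv = 2)
    if (is.null(dim(c0))) {
      c0 <- matrix(c0, ncol = 3); d1 <- matrix(d1, ncol = 3)
      d2v <- matrix(d2v, ncol = 3)
    }
    res <- P[ia, , drop = FALSE] - c0
    g <- rowSums(res * d1)
    gp <- -rowSums(d1^2) + rowSums(res * d2v)
    gp[abs(gp) < 1e-12] <- -1e-12
    t_new <- pmin(max(tg), pmax(min(tg), ta - g / gp))
    moved <- abs(t_new - ta) > 1e-12
    t[ia] <- t_new
    active[ia] <- moved
  }
  ext <- t <= min(tg) + 1e-9 | t >= max(tg) - 1e-9
  list(t = t, s_raw = arclength_at(frame, t), extrapolated = ext)
}

#' Convert Cartesian points to cylindrical root coordinates
#'
#' For each point: `z` is the arclength of the nearest axis point (0 at the
#' QC, positive shootward), `r` the distance to the axis, and `phi` the
#' azimuth in the parallel-transported normal frame, in `[0, 2*pi)`.
#' Points whose nearest axis point is a curve end are flagged as
#' extrapolated.
#'
#' @param frame A [fit_axis()] result.
#' @param points Data frame or matrix with columns/entries `x`, `y`, `z` (µm).
#' @return Tibble with `z_root`, `r`, `phi`, `extrapolated`.
#' @export
to_cylindrical <- function(frame, points) {
  P <- as.matrix(points)
  colnames(P) <- NULL
  fp <- foot_point(frame, P)
  C0 <- curve_at(frame, fp$t)
  if (is.null(dim(C0))) C0 <- matrix(C0, ncol = 3)
  fr <- frame_at(frame, fp$t)
  res <- P - C0
  # drop any residual tangential component (Newton tolerance)
  res <- res - rowSums(res * fr$T) * fr$T
  r <- sqrt(rowSums(res^2))
  phi <- atan2(rowSums(res * fr$B), rowSums(res * fr$N)) %% (2 * pi)
  tibble::tibble(z_root = fp$s_raw - frame$s_qc, r = r, phi = phi,
                 extrapolated = fp$extrapolated)
}

#' Map cylindrical root coordinates back to Cartesian space
#'
#' Inverse of [to_cylindrical()]: reconstructs `c(z) + r cos(phi) N +
#' r sin(phi) B` using the same frame evaluation, so the round trip is the
#' identity to numerical tolerance for interior points.
#'
#' @param frame A [fit_axis()] result.
#' @param cyl Data frame with `z_root`, `r`, `phi`.
#' @return Tibble with Cartesian `x`, `y`, `z` (µm).
#' @export
from_cylindrical <- function(frame, cyl) {
  s <- cyl$z_root + frame$s_qc
  # exact inverse of the piecewise-linear arclength interpolant
  sg <- frame$s_grid; tg <- frame$t_grid
  s_cl <- pmin(max(sg), pmax(min(sg), s))
  j <- pmin(length(sg) - 1L, findInterval(s_cl, sg))
  t <- tg[j] + (s_cl - sg[j]) * (tg[j + 1] - tg[j]) / (sg[j + 1] - sg[j])
  C0 <- curve_at(frame, t)
  if (is.null(dim(C0))) C0 <- matrix(C0, ncol = 3)
  fr <- frame_at(frame, t)
  P <- C0 + cyl$r * cos(cyl$phi) * fr$N + cyl$r * sin(cyl$phi) * fr$B
  tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3])
}

#' Annotate nuclei with cylindrical coordinates
#'
#' Convenience wrapper producing the annotation table the fate-assignment
#' steps consume.
#'
#' @param records Feature tibble with `id`, `x`, `y`, `z`.
#' @param frame A [fit_axis()] result.
#' @return Tibble with `id`, `z_root`, `r`, `phi`, `extrapolated`.
#' @export
annotate_coordinates <- function(records, frame) {
  cyl <- to_cylindrical(frame, records[, c("x", "y", "z")])
  dplyr::bind_cols(tibble::tibble(id = records$id), cyl)
}
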