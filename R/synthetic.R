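#' Parameters of the synthetic root generator
#'
#' Defines the geometry and statistical structure of a simulated root tip:
#' concentric tissue layers around a (optionally bent) axis, longitudinal
#' cell files of ellipsoidal nuclei with peripheral chromocenter speckles and
#' a central DNA-void nucleolus, a ploidy profile along the axis, per-zone
#' EdU pattern probabilities, and per-nucleus axial chromatin-configuration
#' codes. Lengths are µm; the quiescent center sits at arclength `z = 0`.
#'
#' Trichoblast (T) files alternate with atrichoblast (AT) files in the
#' epidermis; T files use an inter-nucleus spacing `t_spacing_ratio` (default
#' 1/1.8) of the AT spacing and axially flattened nuclei (`t_aspect`), the
#' geometry reported for the root epidermis.
#'
#' @param root_length Usable axis length above the QC (µm).
#' @param layer_radii Named increasing outer radial bounds of the inner
#'   layers (µm), innermost first.
#' @param lrc_outer Outer radial bound of the lateral root cap (µm).
#' @param lrc_zmax LRC files stop at this arclength (µm).
#' @param cell_width Tangential spacing between neighbouring files (µm).
#' @param spacing Axial inter-nucleus spacing in the proliferation domain
#'   for AT/generic files (µm).
#' @param t_spacing_ratio T-file spacing relative to AT files.
#' @param zone_breaks `c(pd = ..., td = ...)`: arclength where the
#'   proliferation domain ends and where the transition domain ends (µm).
#' @param zone_spacing_factor Spacing multiplier per zone (`pd`, `td`, `ez`),
#'   emulating cell-size increase along the axis.
#' @param nucleus_radius Radial semi-axis of the nuclear ellipsoid (µm).
#' @param nucleus_aspect Axial-to-radial semi-axis ratio of AT/generic nuclei.
#' @param t_aspect Axial-to-radial ratio of T nuclei (flattened).
#' @param nucleolus_fraction Nucleolus radius as a fraction of the nucleus
#'   semi-axes (volume fraction is its cube).
#' @param n_chromocenters Chromocenter speckles per nucleus.
#' @param chromocenter_sigma Gaussian radius of a speckle (µm).
#' @param chromocenter_boost Speckle amplitude relative to the diffuse DNA
#'   signal.
#' @param chromocenter_radius_frac Radial position of speckles relative to
#'   the nuclear envelope (1 = at the envelope).
#' @param dna_per_c Integrated DNA-channel intensity per C unit (a.u.).
#' @param ploidy_profile `function(layer, z)` returning the C value; the
#'   default keeps inner layers and the LRC at 2C and steps the epidermis and
#'   cortex through 2C/4C/8C across the PD/TD/EZ zones (endoreduplication of
#'   the outer layers).
#' @param edu_probs 3-column matrix (`S0`, `S1`, `S2`) of per-zone pattern
#'   probabilities with rows `pd`, `td`, `ez`.
#' @param edu_cluster_rho Markov stay-boost in `[0, 1)` producing patches of
#'   like-labelled nuclei along files; 0 gives i.i.d. labelling.
#' @param s1_coverage Nominal EdU coverage of S1 nuclei (table generator).
#' @param s2_spots EdU focus count of S2 nuclei.
#' @param edu_intensity,eu_intensity,het_intensity Per-nucleus integrated
#'   intensity scales of the EdU, euchromatin and heterochromatin channels.
#' @param config_probs Named probability vector over joint configuration
#'   codes (`"1_2"`, `"uniform_uniform"`, ...). The default favours the
#'   opposed `1_2` arrangement, sets the fully colocalised lateral codes
#'   `3_3`/`4_4` to zero, and spreads the rest evenly.
#' @param config_enrichment Fraction of a mark's integrated signal placed in
#'   its coded hemisphere.
#' @param wall_intensity,wall_thickness Cell-wall channel shell amplitude
#'   and half-thickness (µm).
#' @param bend_amplitude Lateral offset of the axis at the far end (µm);
#'   the axis is a quadratic bend in the x-y plane (0 = straight).
#' @param jitter_axial,jitter_phi,jitter_radial Placement jitter SDs
#'   (µm, rad, µm).
#' @param noise_sd Additive Gaussian noise SD on every channel (a.u.).
#' @param background Constant background level added to every channel.
#' @param voxel_size Voxel spacing `(dx, dy, dz)` µm for rasterisation.
#' @param bit_depth Intensity ceiling of the rasterised stack.
#' @param max_retries Jitter resampling attempts before a placement error.
#'
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(root_length = 120,
                             layer_radii = c(vascular = 8, pericycle = 13,
                                             endodermis = 18, cortex = 24,
                                             epidermis = 30),
                             lrc_outer = 34,
                             lrc_zmax = 80,
                             cell_width = 7,
                             spacing = 7,
                             t_spacing_ratio = 1 / 1.8,
                             zone_breaks = c(pd = 60, td = 95),
                             zone_spacing_factor = c(pd = 1, td = 2, ez = 3.5),
                             nucleus_radius = 2.0,
                             nucleus_aspect = 0.9,
                             t_aspect = 0.5,
                             nucleolus_fraction = 0.3,
                             n_chromocenters = 8,
                             chromocenter_sigma = 0.35,
                             chromocenter_boost = 3,
                             chromocenter_radius_frac = 0.8,
                             dna_per_c = 1000,
                             ploidy_profile = NULL,
                             edu_probs = rbind(pd = c(0.5, 0.3, 0.2),
                                               td = c(0.5, 0.25, 0.25),
                                               ez = c(0.85, 0.1, 0.05)),
                             edu_cluster_rho = 0,
                             s1_coverage = 0.9,
                             s2_spots = 5,
                             edu_intensity = 600,
                             eu_intensity = 800,
                             het_intensity = 500,
                             config_probs = NULL,
                             config_enrichment = 0.8,
                             wall_intensity = 200,
                             wall_thickness = 0.5,
                             bend_amplitude = 0,
                             jitter_axial = 0.4,
                             jitter_phi = 0.015,
                             jitter_radial = 0.3,
                             noise_sd = 0,
                             background = 0,
                             voxel_size = c(0.4, 0.4, 0.8),
                             bit_depth = 65535,
                             max_retries = 20) {
  if (is.unsorted(layer_radii, strictly = TRUE) || any(layer_radii <= 0)) {
    stop("`layer_radii` must be strictly increasing and positive",
         call. = FALSE)
  }
  stopifnot(lrc_outer > max(layer_radii),
            noise_sd >= 0,
            t_spacing_ratio > 0, t_spacing_ratio <= 1,
            nucleolus_fraction >= 0, nucleolus_fraction < 1,
            config_enrichment > 0.5, config_enrichment <= 1,
            edu_cluster_rho >= 0, edu_cluster_rho < 1,
            zone_breaks["pd"] < zone_breaks["td"],
            zone_breaks["td"] <= root_length)
  colnames(edu_probs) <- c("S0", "S1", "S2")
  if (any(abs(rowSums(edu_probs) - 1) > 1e-8) || any(edu_probs < 0)) {
    stop("rows of `edu_probs` must be probabilities summing to 1",
         call. = FALSE)
  }
  if (is.null(config_probs)) config_probs <- default_config_probs()
  if (abs(sum(config_probs) - 1) > 1e-8 || any(config_probs < 0)) {
    stop("`config_probs` must be probabilities summing to 1", call. = FALSE)
  }
  if (is.null(ploidy_profile)) {
    zb <- zone_breaks
    ploidy_profile <- function(layer, z) {
      ifelse(layer %in% c("epidermis", "cortex"),
             ifelse(z < zb["pd"], 2, ifelse(z < zb["td"], 4, 8)),
             2)
    }
  }
  structure(
    list(root_length = root_length, layer_radii = layer_radii,
         lrc_outer = lrc_outer, lrc_zmax = lrc_zmax, cell_width = cell_width,
         spacing = spacing, t_spacing_ratio = t_spacing_ratio,
         zone_breaks = zone_breaks, zone_spacing_factor = zone_spacing_factor,
         nucleus_radius = nucleus_radius, nucleus_aspect = nucleus_aspect,
         t_aspect = t_aspect, nucleolus_fraction = nucleolus_fraction,
         n_chromocenters = n_chromocenters,
         chromocenter_sigma = chromocenter_sigma,
         chromocenter_boost = chromocenter_boost,
         chromocenter_radius_frac = chromocenter_radius_frac,
         dna_per_c = dna_per_c, ploidy_profile = ploidy_profile,
         edu_probs = edu_probs, edu_cluster_rho = edu_cluster_rho,
         s1_coverage = s1_coverage, s2_spots = s2_spots,
         edu_intensity = edu_intensity, eu_intensity = eu_intensity,
         het_intensity = het_intensity, config_probs = config_probs,
         config_enrichment = config_enrichment,
         wall_intensity = wall_intensity, wall_thickness = wall_thickness,
         bend_amplitude = bend_amplitude, jitter_axial = jitter_axial,
         jitter_phi = jitter_phi, jitter_radial = jitter_radial,
         noise_sd = noise_sd, background = background,
         voxel_size = as.numeric(voxel_size), bit_depth = bit_depth,
         max_retries = max_retries),
    class = "synthetic_params"
  )
}

#' Default joint configuration-code distribution
#'
#' Joint codes combine an euchromatin and a heterochromatin orientation from
#' `{1, 2, 3, 4, uniform}` (axial rootward/shootward, lateral +/-, or no
#' polarisation). The default puts extra mass on the opposed `1_2`
#' arrangement, none on the fully colocalised lateral codes `3_3`/`4_4`, and
#' spreads the remainder evenly.
#'
#' @return Named probability vector over the 25 joint codes.
#' @export
default_config_probs <- function() {
  codes <- c("1", "2", "3", "4", "uniform")
  joint <- as.vector(outer(codes, codes, function(a, b) paste(a, b, sep = "_")))
  p <- setNames(rep(0, length(joint)), joint)
  p["1_2"] <- 0.28
  p["uniform_uniform"] <- 0.20
  rest <- setdiff(joint, c("1_2", "uniform_uniform", "3_3", "4_4"))
  p[rest] <- (1 - 0.48) / length(rest)
  p
}

# axis representation: point(s), frame(s) = list(T, N, B) as row-matrices,
# for a quadratic bend of amplitude A in the x-y plane, parametrised by
# arclength s in [0, root_length]
gen_axis <- function(params) {
  L <- params$root_length
  A <- params$bend_amplitude
  ugrid <- seq(0, L, length.out = 1024)
  dy <- 2 * A * ugrid / L^2
  ds <- sqrt(1 + dy^2)
  sgrid <- c(0, cumsum((ds[-1] + ds[-length(ds)]) / 2 * diff(ugrid)))
  u_of_s <- stats::approxfun(sgrid, ugrid, rule = 2)
  point <- function(s) {
    u <- u_of_s(s)
    cbind(x = u, y = A * (u / L)^2, z = 0)
  }
  frame <- function(s) {
    u <- u_of_s(s)
    tx <- rep(1, length(u)); ty <- 2 * A * u / L^2
    nrm <- sqrt(tx^2 + ty^2)
    Tm <- cbind(tx / nrm, ty / nrm, 0)
    Nm <- cbind(-Tm[, 2], Tm[, 1], 0)
    Bm <- cbind(0, 0, rep(1, length(u)))
    list(T = Tm, N = Nm, B = Bm)
  }
  list(point = point, frame = frame, s_max = max(sgrid))
}

zone_of <- function(z, zone_breaks) {
  ifelse(z < zone_breaks["pd"], "PD",
         ifelse(z < zone_breaks["td"], "TD", "EZ"))
}

# sample the S0/S1/S2 sequence along one file: two-state Markov chain on
# labelled/unlabelled with stay-boost rho (stationary labelled prob follows
# the per-zone probabilities), then S1/S2 split within labelled
sample_edu_file <- function(zones, params) {
  probs <- params$edu_probs
  rho <- params$edu_cluster_rho
  n <- length(zones)
  p_lab <- 1 - probs[tolower(zones), "S0"]
  lab <- logical(n)
  lab[1] <- runif(1) < p_lab[1]
  if (n > 1) {
    for (i in 2:n) {
      p <- if (lab[i - 1]) p_lab[i] + rho * (1 - p_lab[i])
           else p_lab[i] * (1 - rho)
      lab[i] <- runif(1) < p
    }
  }
  pattern <- rep("S0", n)
  for (i in which(lab)) {
    w <- probs[tolower(zones[i]), c("S1", "S2")]
    pattern[i] <- sample(c("S1", "S2"), 1, prob = w / sum(w))
  }
  pattern
}

# ground-truth placement shared by both generators; caller controls the RNG
place_nuclei <- function(params) {
  axis <- gen_axis(params)
  bounds <- c(0, params$layer_radii, lrc = params$lrc_outer)
  layer_names <- c(names(params$layer_radii), "LRC")
  rows <- list()
  for (li in seq_along(layer_names)) {
    layer <- layer_names[li]
    r_mid <- (bounds[li] + bounds[li + 1]) / 2
    n_files <- max(1L, round(2 * pi * r_mid / params$cell_width))
    if (layer == "epidermis" && n_files %% 2 == 1) n_files <- n_files + 1L
    zmax <- if (layer == "LRC") min(params$lrc_zmax, params$root_length)
            else params$root_length
    for (fi in seq_len(n_files)) {
      phi0 <- 2 * pi * (fi - 0.5) / n_files
      subtype <- if (layer == "epidermis") c("AT", "T")[fi %% 2 + 1] else NA
      sp_base <- params$spacing *
        if (identical(subtype, "T")) params$t_spacing_ratio else 1
      z <- sp_base / 2
      zs <- numeric(0)
      while (z <= zmax) {
        zs <- c(zs, z)
        zn <- zone_of(z, params$zone_breaks)
        z <- z + sp_base * unname(params$zone_spacing_factor[tolower(zn)])
      }
      if (length(zs) == 0) next
      zones <- zone_of(zs, params$zone_breaks)
      pattern <- sample_edu_file(zones, params)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = layer, file = fi, subtype = subtype,
        z_root = zs, zone = zones, phi = phi0, r = r_mid,
        pattern = pattern
      )
    }
  }
  truth <- dplyr::bind_rows(rows)
  n <- nrow(truth)
  truth$id <- seq_len(n)
  # C value from the design positions; endoreduplicated nuclei are enlarged
  # (linear dimension ~ (C/2)^(1/6), i.e. volume ~ sqrt(C))
  truth$C <- params$ploidy_profile(truth$layer, truth$z_root)
  size_scale <- (truth$C / 2)^(1 / 6)
  a_r <- rep(params$nucleus_radius, n) * size_scale
  a_ax <- a_r * ifelse(!is.na(truth$subtype) & truth$subtype == "T",
                       params$t_aspect, params$nucleus_aspect)
  jitter_and_project <- function(idx, tr) {
    tr$z_root[idx] <- tr$z_root[idx] + rnorm(length(idx), 0, params$jitter_axial)
    tr$z_root[idx] <- pmax(tr$z_root[idx], 0.1)
    tr$phi[idx] <- tr$phi[idx] + rnorm(length(idx), 0, params$jitter_phi)
    tr$r[idx] <- tr$r[idx] + rnorm(length(idx), 0, params$jitter_radial)
    tr
  }
  truth0 <- truth
  truth <- jitter_and_project(seq_len(n), truth)
  to_cart <- function(tr) {
    pt <- axis$point(tr$z_root)
    fr <- axis$frame(tr$z_root)
    dir <- cos(tr$phi) * fr$N + sin(tr$phi) * fr$B
    pt + tr$r * dir
  }
  min_gap <- 0.2 # µm clearance between ellipsoid support radii
  for (try in seq_len(params$max_retries)) {
    P <- to_cart(truth)
    Tv <- axis$frame(truth$z_root)$T
    nn <- nearest_clash(P, a_ax, a_r, Tv, min_gap)
    if (length(nn) == 0) break
    if (try == params$max_retries) {
      stop("nuclei overlap persists after ", params$max_retries,
           " placement retries", call. = FALSE)
    }
    truth$z_root[nn] <- truth0$z_root[nn]
    truth$phi[nn] <- truth0$phi[nn]
    truth$r[nn] <- truth0$r[nn]
    truth <- jitter_and_project(nn, truth)
  }
  P <- to_cart(truth)
  fr <- axis$frame(truth$z_root)
  cfg <- sample(names(params$config_probs), n, replace = TRUE,
                prob = params$config_probs)
  parts <- strsplit(cfg, "_")
  truth$config_eu <- vapply(parts, `[`, "", 1)
  truth$config_het <- vapply(parts, `[`, "", 2)
  truth$config <- cfg
  truth$n_spots <- ifelse(truth$pattern == "S2", params$s2_spots, 0L)
  truth$a_ax <- a_ax
  truth$a_r <- a_r
  truth$x <- P[, 1]; truth$y <- P[, 2]; truth$z <- P[, 3]
  attr(truth, "axis") <- axis
  attr(truth, "frames") <- fr
  truth
}

# indices of nuclei whose ellipsoids (approximated by their support radius
# along the centre-connecting direction) clash; one index per clashing pair,
# swept along x with a vectorised window
nearest_clash <- function(P, a_ax, a_r, Tv, min_gap) {
  n <- nrow(P)
  ord <- order(P[, 1])
  xo <- P[ord, 1]
  maxr <- max(pmax(a_ax, a_r))
  win <- 2 * maxr + min_gap
  bad <- logical(n)
  hi <- 1L
  for (i in seq_len(n - 1)) {
    if (hi < i + 1L) hi <- i + 1L
    while (hi <= n && xo[hi] - xo[i] < win) hi <- hi + 1L
    if (hi == i + 1L) next
    a <- ord[i]
    js <- ord[(i + 1L):(hi - 1L)]
    dvec <- P[js, , drop = FALSE] -
      matrix(P[a, ], length(js), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dvec^2))
    d <- dvec / pmax(dist, 1e-9)
    ct_a <- drop(d %*% Tv[a, ])
    sup_a <- sqrt((a_ax[a] * ct_a)^2 + a_r[a]^2 * pmax(0, 1 - ct_a^2))
    ct_b <- rowSums(d * Tv[js, , drop = FALSE])
    sup_b <- sqrt((a_ax[js] * ct_b)^2 + a_r[js]^2 * pmax(0, 1 - ct_b^2))
    clash <- dist < sup_a + sup_b + min_gap
    bad[js[clash]] <- TRUE
  }
  which(bad)
}

ellipsoid_volume <- function(a_ax, a_r) 4 / 3 * pi * a_ax * a_r^2

ellipsoid_surface <- function(a, b, cc) {
  p <- 1.6075
  4 * pi * ((a^p * b^p + a^p * cc^p + b^p * cc^p) / 3)^(1 / p)
}

# hemisphere fractions implied by a configuration code at enrichment e
code_fractions <- function(code, e) {
  f_ax <- ifelse(code == "1", e, ifelse(code == "2", 1 - e, 0.5))
  f_lat <- ifelse(code == "3", e, ifelse(code == "4", 1 - e, 0.5))
  cbind(axial_rootward = f_ax, lateral_pos = f_lat)
}

#' Generate a ground-truth feature table without rasterisation
#'
#' Draws per-nucleus records from the same generative model as
#' [generate_root()] but computes features analytically (ellipsoid volume and
#' surface, bounding extents projected onto the stack axes, integrated
#' intensities proportional to the assigned C value) instead of rasterising
#' and re-extracting them. Fast path for testing the tabular stages.
#'
#' @param params A [synthetic_params()].
#' @param seed Integer seed; the generator is deterministic given it.
#' @param table_cv Multiplicative coefficient of variation applied to
#'   volumes and integrated intensities (0 = noiseless).
#'
#' @return A list with `records` (per-nucleus features), `annotations`
#'   (true positional fate), `calls` (true EdU calls with coverage and spot
#'   counts plus true hemisphere signal fractions), and `truth` (everything,
#'   one row per nucleus).
#' @export
generate_feature_table <- function(params, seed = 1L, table_cv = 0.05) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(seed)
  truth <- place_nuclei(params)
  fr <- attr(truth, "frames")
  n <- nrow(truth)
  noisy <- function(x) x * (1 + rnorm(n, 0, table_cv))
  f <- params$nucleolus_fraction
  vol <- noisy(ellipsoid_volume(truth$a_ax, truth$a_r) * (1 - f^3))
  surf <- noisy(ellipsoid_surface(truth$a_ax, truth$a_r, truth$a_r))
  # bounding extent along stack axis e: 2 * sqrt(sum_i (a_i * u_i.e)^2)
  Rhat <- cos(truth$phi) * fr$N + sin(truth$phi) * fr$B
  Lhat <- cbind(
    fr$T[, 2] * Rhat[, 3] - fr$T[, 3] * Rhat[, 2],
    fr$T[, 3] * Rhat[, 1] - fr$T[, 1] * Rhat[, 3],
    fr$T[, 1] * Rhat[, 2] - fr$T[, 2] * Rhat[, 1]
  )
  ext_along <- function(k) {
    2 * sqrt((truth$a_ax * fr$T[, k])^2 + (truth$a_r * Rhat[, k])^2 +
               (truth$a_r * Lhat[, k])^2)
  }
  dna_total <- noisy(truth$C * params$dna_per_c)
  eu_total <- noisy(rep(params$eu_intensity, n))
  het_total <- noisy(rep(params$het_intensity, n))
  coverage <- dplyr::case_when(
    truth$pattern == "S0" ~ 0,
    truth$pattern == "S1" ~ pmin(1, pmax(0, rnorm(n, params$s1_coverage, 0.03))),
    TRUE ~ pmin(1, pmax(0, rnorm(n, 0.15, 0.03)))
  )
  edu_total <- ifelse(truth$pattern == "S0", 0,
                      noisy(rep(params$edu_intensity, n)))
  asym <- matrix(rnorm(3 * n, 0, 0.05), ncol = 3)
  e <- params$config_enrichment
  feu <- code_fractions(truth$config_eu, e) +
    matrix(rnorm(2 * n, 0, 0.02), ncol = 2)
  fhet <- code_fractions(truth$config_het, e) +
    matrix(rnorm(2 * n, 0, 0.02), ncol = 2)
  clamp01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
  feu <- clamp01(feu); fhet <- clamp01(fhet)
  records <- tibble::tibble(
    id = truth$id,
    x = truth$x, y = truth$y, z = truth$z,
    volume_um3 = vol, surface_um2 = surf,
    w_um = ext_along(1), h_um = ext_along(2), d_um = ext_along(3),
    dna_total = dna_total, h3k4me1_total = eu_total,
    h3k9me2_total = het_total, edu_total = edu_total,
    asym_x = asym[, 1], asym_y = asym[, 2], asym_z = asym[, 3],
    asym_norm = sqrt(rowSums(asym^2)),
    nucleolus_um3 = ellipsoid_volume(truth$a_ax, truth$a_r) * f^3
  )
  annotations <- tibble::tibble(
    id = truth$id, z_root = truth$z_root, r = truth$r, phi = truth$phi %% (2 * pi),
    layer = truth$layer, file = truth$file, subtype = truth$subtype,
    zone = truth$zone
  )
  calls <- tibble::tibble(
    id = truth$id, pattern = truth$pattern, edu_total = edu_total,
    coverage = coverage, n_spots = truth$n_spots,
    config_eu = truth$config_eu, config_het = truth$config_het,
    config = truth$config,
    eu_frac_rootward = feu[, 1], eu_frac_lateral = feu[, 2],
    het_frac_rootward = fhet[, 1], het_frac_lateral = fhet[, 2]
  )
  list(records = records, annotations = annotations, calls = calls,
       truth = truth, qc = c(0, 0, 0), params = params)
}

#' Generate a rasterised multi-channel synthetic root stack
#'
#' Rasterises the placement model of [synthetic_params()] into a
#' [voxel_stack()] with channels `dna`, `h3k4me1`, `h3k9me2`, `edu` and
#' `wall`, a matching integer label volume, and the full ground truth.
#'
#' Per nucleus: the DNA channel is a diffuse ellipsoid with peripheral
#' chromocenter speckles and a central void (nucleolus), normalised so the
#' integrated intensity is exactly `C * dna_per_c` before noise; the
#' heterochromatin channel consists of the same speckles; the euchromatin
#' channel fills the nucleus minus nucleolus; the EdU channel follows the
#' assigned S0/S1/S2 pattern (nothing, homogeneous fill, or foci placed on
#' chromocenters); both marks are reweighted voxelwise so the coded
#' hemisphere holds exactly `config_enrichment` of the integrated signal.
#' The wall channel draws shells at the layer boundary radii.
#'
#' @inheritParams generate_feature_table
#' @return A list with `stack` ([voxel_stack()]), `labels` (integer array,
#'   0 = background), `truth` (tibble, one row per nucleus, in stack
#'   coordinates, including rasterised voxel counts), and `qc` (Cartesian
#'   position of the quiescent center in stack coordinates).
#' @export
generate_root <- function(params, seed = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(seed)
  truth <- place_nuclei(params)
  fr <- attr(truth, "frames")
  vx <- params$voxel_size
  pad <- 3
  outer_r <- params$lrc_outer
  nx <- ceiling((params$root_length + 2 * pad) / vx[1])
  ny <- ceiling((2 * (outer_r + pad) + max(0, params$bend_amplitude)) / vx[2])
  nz <- ceiling(2 * (outer_r + pad) / vx[3])
  dims <- c(nx, ny, nz)
  origin <- c(pad, outer_r + pad, outer_r + pad) # cartesian offset of axis
  dna_arr <- array(0, dims); eu_arr <- array(0, dims)
  het_arr <- array(0, dims); edu_arr <- array(0, dims)
  wall_arr <- array(0, dims)
  labels <- array(0L, dims)

  n <- nrow(truth)
  truth$volume_vox <- 0L
  truth$nucleolus_vox <- 0L
  e <- params$config_enrichment
  f <- params$nucleolus_fraction

  for (i in seq_len(n)) {
    ctr <- c(truth$x[i], truth$y[i], truth$z[i]) + origin
    Tv <- fr$T[i, ]
    Rhat <- cos(truth$phi[i]) * fr$N[i, ] + sin(truth$phi[i]) * fr$B[i, ]
    Lhat <- c(Tv[2] * Rhat[3] - Tv[3] * Rhat[2],
              Tv[3] * Rhat[1] - Tv[1] * Rhat[3],
              Tv[1] * Rhat[2] - Tv[2] * Rhat[1])
    a_ax <- truth$a_ax[i]; a_r <- truth$a_r[i]
    rmax <- max(a_ax, a_r) + 2 * params$chromocenter_sigma
    i0 <- pmax(1, floor((ctr - rmax) / vx) + 1)
    i1 <- pmin(dims, ceiling((ctr + rmax) / vx))
    if (any(i0 > i1)) next
    gx <- (i0[1]:i1[1] - 0.5) * vx[1] - ctr[1]
    gy <- (i0[2]:i1[2] - 0.5) * vx[2] - ctr[2]
    gz <- (i0[3]:i1[3] - 0.5) * vx[3] - ctr[3]
    G <- expand.grid(x = gx, y = gy, z = gz)
    U <- as.matrix(G)
    q_ax <- U %*% Tv / a_ax
    q_r <- U %*% Rhat / a_r
    q_l <- U %*% Lhat / a_r
    rho2 <- q_ax^2 + q_r^2 + q_l^2
    inside <- rho2 <= 1
    nucleolus <- rho2 <= f^2
    keep <- inside & !nucleolus
    if (!any(keep)) next
    # voxel indices of the crop, flattened for the full arrays
    ix <- rep(i0[1]:i1[1], times = length(gy) * length(gz))
    iy <- rep(rep(i0[2]:i1[2], each = length(gx)), times = length(gz))
    iz <- rep(i0[3]:i1[3], each = length(gx) * length(gy))
    flat <- (iz - 1) * nx * ny + (iy - 1) * nx + ix
    vox <- flat[keep]
    labels[vox] <- truth$id[i]
    truth$volume_vox[i] <- length(vox)
    truth$nucleolus_vox[i] <- sum(nucleolus)

    # chromocenters: quasi-uniform peripheral speckle centres (golden-spiral
    # points under a random rotation), mutually separated by construction so
    # foci stay resolvable and every hemisphere carries raw signal
    K <- params$n_chromocenters
    gold <- pi * (3 - sqrt(5))
    kk <- seq_len(K)
    zs_f <- 1 - (2 * kk - 1) / K
    rs_f <- sqrt(pmax(0, 1 - zs_f^2))
    fib <- cbind(rs_f * cos(gold * kk), rs_f * sin(gold * kk), zs_f)
    for (attempt in 1:20) {
      Q <- qr.Q(qr(matrix(rnorm(9), 3)))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      V <- fib %*% Q
      cc_pos <- params$chromocenter_radius_frac *
        (outer(a_ax * V[, 1], Tv) + outer(a_r * V[, 2], Rhat) +
           outer(a_r * V[, 3], Lhat))
      ax_sign <- cc_pos %*% Tv
      lat_sign <- cc_pos %*% Lhat
      if (any(ax_sign < 0) && any(ax_sign > 0) &&
          any(lat_sign < 0) && any(lat_sign >= 0)) break
    }
    Uk <- U[keep, , drop = FALSE]
    # speckles are truncated Gaussians (zero beyond 3 sigma) so channels
    # have a true zero background
    gauss_blob <- function(centres) {
      s2 <- 2 * params$chromocenter_sigma^2
      out <- rep(0, nrow(Uk))
      for (k in seq_len(nrow(centres))) {
        d2 <- rowSums((Uk - matrix(centres[k, ], nrow(Uk), 3,
                                   byrow = TRUE))^2)
        out <- out + pmax(0, exp(-d2 / s2) - exp(-4.5))
      }
      out
    }
    blob <- gauss_blob(cc_pos)
    dna_pat <- 1 + params$chromocenter_boost * blob
    dna_pat <- dna_pat * (truth$C[i] * params$dna_per_c / sum(dna_pat))
    dna_arr[vox] <- dna_pat

    ax_coord <- Uk %*% Tv
    lat_coord <- Uk %*% Lhat
    reweight <- function(w, code) {
      # iterative proportional fitting: the coded hemisphere holds exactly
      # the enrichment fraction of the signal while the orthogonal axis is
      # balanced at 0.5, so codes are well-defined even for lumpy patterns
      t_ax <- switch(code, "1" = e, "2" = 1 - e, 0.5)
      t_lat <- switch(code, "3" = e, "4" = 1 - e, 0.5)
      ax_h <- ax_coord < 0
      lat_h <- lat_coord >= 0
      for (it in 1:20) {
        s <- sum(w[ax_h]) / sum(w)
        if (s > 0 && s < 1) {
          w[ax_h] <- w[ax_h] * (t_ax / s)
          w[!ax_h] <- w[!ax_h] * ((1 - t_ax) / (1 - s))
        }
        s2 <- sum(w[lat_h]) / sum(w)
        if (s2 > 0 && s2 < 1) {
          w[lat_h] <- w[lat_h] * (t_lat / s2)
          w[!lat_h] <- w[!lat_h] * ((1 - t_lat) / (1 - s2))
        }
        if (abs(s - t_ax) < 1e-9 && abs(s2 - t_lat) < 1e-9) break
      }
      w
    }
    eu_pat <- reweight(rep(1, nrow(Uk)), truth$config_eu[i])
    eu_pat <- eu_pat * (params$eu_intensity / sum(eu_pat))
    eu_arr[vox] <- eu_pat
    het_pat <- reweight(blob, truth$config_het[i])
    het_pat <- het_pat * (params$het_intensity / sum(het_pat))
    het_arr[vox] <- het_pat

    if (truth$pattern[i] == "S1") {
      edu_arr[vox] <- params$edu_intensity / length(vox)
    } else if (truth$pattern[i] == "S2") {
      ns <- min(truth$n_spots[i], K)
      pick <- unique(round(seq(1, K, length.out = ns)))
      spot <- gauss_blob(cc_pos[pick, , drop = FALSE])
      edu_arr[vox] <- spot * (params$edu_intensity / sum(spot))
    }
  }

  # wall shells at layer boundaries, per x-slab around the local axis centre
  axis <- attr(truth, "axis")
  bounds <- c(params$layer_radii, params$lrc_outer)
  ygrid <- (seq_len(ny) - 0.5) * vx[2] - origin[2]
  zgrid <- (seq_len(nz) - 0.5) * vx[3] - origin[3]
  L <- params$root_length; A <- params$bend_amplitude
  for (xi in seq_len(nx)) {
    xc <- (xi - 0.5) * vx[1] - origin[1]
    if (xc < 0 || xc > L) next
    yc <- A * (xc / L)^2
    rho <- sqrt(outer((ygrid - yc)^2, zgrid^2, "+"))
    wall <- matrix(0, ny, nz)
    for (b in bounds) {
      wall <- wall + params$wall_intensity *
        (abs(rho - b) <= params$wall_thickness)
    }
    wall_arr[xi, , ] <- wall
  }

  vols <- list(dna = dna_arr, h3k4me1 = eu_arr, h3k9me2 = het_arr,
               edu = edu_arr, wall = wall_arr)
  if (params$noise_sd > 0 || params$background > 0) {
    for (nm in names(vols)) {
      vols[[nm]] <- vols[[nm]] + params$background +
        rnorm(length(vols[[nm]]), 0, params$noise_sd)
      vols[[nm]][vols[[nm]] < 0] <- 0
    }
  }
  truth$volume_um3 <- truth$volume_vox * prod(vx)
  # report ground truth in stack coordinates; the QC sits at the axis origin
  truth$x <- truth$x + origin[1]
  truth$y <- truth$y + origin[2]
  truth$z <- truth$z + origin[3]
  stack <- voxel_stack(vols, voxel_size = vx,
                       bit_depth = max(params$bit_depth,
                                       max(vapply(vols, max, 1))))
  list(stack = stack, labels = labels, truth = truth, qc = origin,
       params = params)
}
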