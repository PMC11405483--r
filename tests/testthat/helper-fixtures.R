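# Shared fixtures, memoised so expensive rasters are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# compact two-layer root used by most raster tests (~190 nuclei)
small_root_params <- function(...) {
  defaults <- list(
    root_length = 80,
    layer_radii = c(vascular = 8, pericycle = 13),
    lrc_outer = 18, lrc_zmax = 60,
    zone_breaks = c(pd = 50, td = 70),
    ploidy_profile = function(layer, z) ifelse(z < 50, 2, 4)
  )
  do.call(synthetic_params, utils::modifyList(defaults, list(...)))
}

small_root <- function() {
  with_cache("small_root", generate_root(small_root_params(), seed = 7))
}

small_root_features <- function() {
  with_cache("small_root_features", {
    gr <- small_root()
    rec <- extract_features(gr$labels, gr$stack)
    frame <- fit_axis(rec, qc_position = gr$qc)
    list(root = gr, records = rec, frame = frame)
  })
}

# full bent root feature table for fate-assignment tests
bent_table <- function() {
  with_cache("bent_table", {
    p <- synthetic_params(bend_amplitude = 12)
    generate_feature_table(p, seed = 5, table_cv = 0.02)
  })
}

# brute-force per-voxel feature oracle: independent re-implementation by
# direct summation over every voxel (loops, no vectorised shortcuts)
oracle_features <- function(labels, stack) {
  dims <- dim(labels)
  vx <- unname(stack$voxel_size)
  ids <- sort(unique(labels[labels > 0]))
  out <- list()
  for (id in ids) {
    n <- 0; sx <- sy <- sz <- 0
    xr <- c(Inf, -Inf); yr <- c(Inf, -Inf); zr <- c(Inf, -Inf)
    tot <- setNames(numeric(length(stack$channels)), names(stack$channels))
    wx <- wy <- wz <- tot
    faces <- 0
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
      for (i in seq_len(dims[1])) {
        if (labels[i, j, k] != id) next
        n <- n + 1
        px <- (i - 0.5) * vx[1]; py <- (j - 0.5) * vx[2]
        pz <- (k - 0.5) * vx[3]
        sx <- sx + px; sy <- sy + py; sz <- sz + pz
        xr <- c(min(xr[1], i), max(xr[2], i))
        yr <- c(min(yr[1], j), max(yr[2], j))
        zr <- c(min(zr[1], k), max(zr[2], k))
        for (ch in names(stack$channels)) {
          v <- stack$channels[[ch]][i, j, k]
          tot[ch] <- tot[ch] + v
          wx[ch] <- wx[ch] + v * px
          wy[ch] <- wy[ch] + v * py
          wz[ch] <- wz[ch] + v * pz
        }
        nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                   c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
        areas <- c(vx[2] * vx[3], vx[2] * vx[3], vx[1] * vx[3],
                   vx[1] * vx[3], vx[1] * vx[2], vx[1] * vx[2])
        for (q in 1:6) {
          co <- nb[[q]]
          outside <- any(co < 1) || co[1] > dims[1] || co[2] > dims[2] ||
            co[3] > dims[3]
          if (outside || labels[co[1], co[2], co[3]] != id) {
            faces <- faces + areas[q]
          }
        }
      }
    rec <- list(id = id, volume = n * prod(vx), surface = faces,
                x = sx / n, y = sy / n, z = sz / n,
                w = (xr[2] - xr[1] + 1) * vx[1],
                h = (yr[2] - yr[1] + 1) * vx[2],
                d = (zr[2] - zr[1] + 1) * vx[3],
                totals = tot,
                com = rbind(wx / tot, wy / tot, wz / tot))
    out[[as.character(id)]] <- rec
  }
  out
}

# brute-force run extraction: walk the sequence and count maximal runs
oracle_runs <- function(x) {
  if (!length(x)) return(data.frame(state = character(), length = integer()))
  states <- character(0); lens <- integer(0)
  cur <- x[1]; len <- 1L
  for (i in seq_along(x)[-1]) {
    if (x[i] == cur) len <- len + 1L
    else {
      states <- c(states, cur); lens <- c(lens, len)
      cur <- x[i]; len <- 1L
    }
  }
  data.frame(state = c(states, cur), length = c(lens, len))
}

# minimal straight-axis frame for tests that need root coordinates without
# a full generator run: a synthetic straight cloud along x
straight_frame <- function(length_um = 100) {
  set.seed(42)
  n <- 300
  cloud <- tibble::tibble(
    id = seq_len(n),
    x = runif(n, 0, length_um),
    y = rnorm(n, 0, 5),
    z = rnorm(n, 0, 5)
  )
  fit_axis(cloud, qc_position = c(0, 0, 0))
}
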