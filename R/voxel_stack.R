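#' Multi-channel 3D intensity volume
#'
#' A `voxel_stack` bundles one or more named 3D intensity arrays sharing a
#' common shape, the physical voxel spacing, and the intensity ceiling.
#' Arrays are indexed `[x, y, z]`; physical positions are voxel-centre
#' coordinates in micrometres, `x = (i - 0.5) * dx` and so on, so that a
#' single unit system (µm) is used everywhere downstream.
#'
#' @param channels Named list of 3D numeric arrays, all with identical `dim`.
#' @param voxel_size Numeric length-3, voxel spacing `(dx, dy, dz)` in µm.
#' @param bit_depth Intensity ceiling (e.g. 65535 for 16-bit data).
#'
#' @return An object of class `voxel_stack`.
#' @export
#' @examples
#' vol <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
#' stk <- voxel_stack(list(dna = vol), voxel_size = c(0.5, 0.5, 1))
#' dim(stk)
voxel_stack <- function(channels, voxel_size, bit_depth = 65535) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of 3D arrays",
         call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("all channels must be 3D arrays", call. = FALSE)
  }
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channel volumes must share one shape", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive numbers (dx, dy, dz) in um",
         call. = FALSE)
  }
  names(voxel_size) <- c("dx", "dy", "dz")
  rng <- range(vapply(channels, function(v) range(v), numeric(2)))
  if (rng[1] < 0 || rng[2] > bit_depth) {
    stop("channel intensities must lie in [0, bit_depth]", call. = FALSE)
  }
  structure(
    list(channels = channels, voxel_size = voxel_size, bit_depth = bit_depth),
    class = "voxel_stack"
  )
}

#' @export
dim.voxel_stack <- function(x) dim(x$channels[[1]])

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x)
  cat("<voxel_stack> ", paste(d, collapse = " x "), " voxels, ",
      length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  cat("  voxel size (um): ", paste(signif(x$voxel_size, 4), collapse = " x "),
      "; bit depth ", x$bit_depth, "\n", sep = "")
  invisible(x)
}

#' Volume of one voxel in cubic micrometres
#' @param stack A [voxel_stack()].
#' @return Scalar voxel volume (µm³).
#' @export
voxel_volume <- function(stack) prod(stack$voxel_size)

#' Fetch a channel, with a named-channel error
#' @param stack A [voxel_stack()].
#' @param name Channel name.
#' @return The 3D intensity array.
#' @export
get_channel <- function(stack, name) {
  if (!name %in% names(stack$channels)) {
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(stack$channels), collapse = ", ")),
         call. = FALSE)
  }
  stack$channels[[name]]
}

is_h5_path <- function(path) grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)

#' Read a multi-channel stack from HDF5 or multi-page TIFF
#'
#' HDF5 containers use one dataset per channel under the group `channels/`,
#' with voxel spacing in a `voxel_size` dataset and the intensity ceiling in
#' `bit_depth` (the layout [write_stack()] produces). Multi-page TIFF files
#' are interpreted as contiguous per-channel blocks of z-slices; because TIFF
#' carries no voxel-size metadata, `config$voxel_size` must be supplied.
#'
#' @param path Path to a `.h5`/`.hdf5` or `.tif`/`.tiff` file.
#' @param config A [run_config()]; `channel_map` renames (HDF5) or names
#'   (TIFF) channels by position, `voxel_size` overrides file metadata.
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, config = run_config()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is_h5_path(path)) {
    stored <- rhdf5::h5ls(path)
    ch_names <- stored$name[stored$group == "/channels"]
    if (length(ch_names) == 0) {
      stop("no datasets under /channels in ", path, call. = FALSE)
    }
    channels <- lapply(ch_names, function(nm) {
      rhdf5::h5read(path, paste0("channels/", nm))
    })
    names(channels) <- ch_names
    voxel_size <- tryCatch(as.numeric(rhdf5::h5read(path, "voxel_size")),
                           error = function(e) NULL)
    bit_depth <- tryCatch(as.numeric(rhdf5::h5read(path, "bit_depth")),
                          error = function(e) 65535)
    rhdf5::h5closeAll()
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    n_ch <- if (is.null(config$channel_map)) 1L else length(config$channel_map)
    if (length(pages) %% n_ch != 0) {
      stop("page count ", length(pages),
           " is not a multiple of the mapped channel count ", n_ch,
           call. = FALSE)
    }
    nz <- length(pages) %/% n_ch
    channels <- lapply(seq_len(n_ch), function(c) {
      block <- pages[((c - 1) * nz + 1):(c * nz)]
      # readTIFF pages are (row = y, col = x); stored as [x, y, z]
      arr <- array(0, dim = c(ncol(block[[1]]), nrow(block[[1]]), nz))
      for (k in seq_len(nz)) arr[, , k] <- t(block[[k]])
      arr
    })
    names(channels) <- paste0("ch", seq_len(n_ch))
    voxel_size <- NULL
    bit_depth <- 65535
  }
  if (!is.null(config$channel_map)) {
    cm <- config$channel_map
    idx <- as.integer(cm)
    if (any(idx < 1) || any(idx > length(channels))) {
      stop(sprintf("channel map requests index %d but only %d channel(s) present",
                   max(idx), length(channels)), call. = FALSE)
    }
    channels <- setNames(channels[idx], names(cm))
  }
  if (!is.null(config$voxel_size)) voxel_size <- config$voxel_size
  if (is.null(voxel_size)) {
    stop("no voxel size in file metadata and no `config$voxel_size` override",
         call. = FALSE)
  }
  if (!is.null(config$bit_depth)) bit_depth <- config$bit_depth
  voxel_stack(channels, voxel_size, bit_depth = max(bit_depth,
              max(vapply(channels, max, 1))))
}

#' Write a stack to HDF5 (lossless) or 16-bit multi-page TIFF
#'
#' The HDF5 layout mirrors what [read_stack()] expects: `channels/<name>`
#' datasets plus `voxel_size` and `bit_depth`. TIFF output quantises
#' intensities to 16-bit relative to `bit_depth` and stacks the z-slices of
#' each channel as a contiguous page block.
#'
#' @param stack A [voxel_stack()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  if (is_h5_path(path)) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "channels")
    for (nm in names(stack$channels)) {
      rhdf5::h5write(stack$channels[[nm]], path, paste0("channels/", nm))
    }
    rhdf5::h5write(unname(stack$voxel_size), path, "voxel_size")
    rhdf5::h5write(stack$bit_depth, path, "bit_depth")
    rhdf5::h5closeAll()
  } else {
    pages <- list()
    for (nm in names(stack$channels)) {
      vol <- stack$channels[[nm]] / stack$bit_depth
      for (k in seq_len(dim(vol)[3])) {
        pages[[length(pages) + 1L]] <- t(vol[, , k])
      }
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  invisible(path)
}

#' Write a label volume as multi-page TIFF
#'
#' Integer labels are stored losslessly as 16-bit pages (one per z-slice).
#'
#' @param labels Integer 3D array (0 = background).
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(length(dim(labels)) == 3, max(labels) < 65536)
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(k) t(labels[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#' @param path Path to the label TIFF.
#' @return Integer 3D array.
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(t(pages[[k]]))
  arr
}
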