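#' Simulate a fully sampled multi-coil cine volume
#'
#' Generates `n_frames` phantom images (each frame re-drawn from a
#' deterministically derived per-frame seed, mimicking cardiac phases),
#' expands them to `n_coils` receiver coils through Biot-Savart sensitivity
#' maps, and stores the fully sampled coil k-space. The result is the unit
#' every training/testing pipeline consumes.
#'
#' @param shape Integer `(nx, ny)`, even, >= 32.
#' @param n_coils Number of simulated receiver coils.
#' @param n_frames Number of frames (cardiac phases) in the volume.
#' @param seed Integer seed; the volume is a pure function of its arguments.
#' @param kind Phantom kind, see [make_phantom()].
#' @param geometry Optional [coil_geometry()]; defaults to `n_coils` loops on
#'   the standard ring for this grid size.
#' @param pixel_spacing_mm Nominal pixel spacing recorded as metadata.
#' @return An object of class `multicoil_volume`: `kspace` (`nx` x `ny` x
#'   `n_coils` x `n_frames` complex array), `maps`, `seed`, `kind`,
#'   `pixel_spacing_mm`.
#' @export
simulate_volume <- function(shape, n_coils = 8L, n_frames = 1L, seed = 0L,
                            kind = "cardiac", geometry = NULL,
                            pixel_spacing_mm = 1.3) {
  shape <- as.integer(shape)
  if (is.null(geometry)) geometry <- coil_geometry(n_coils, nx = shape[1])
  maps <- biot_savart_maps(geometry, shape)
  frame_seeds <- withr::with_seed(as.integer(seed), {
    sample.int(.Machine$integer.max - 1L, n_frames)
  })
  kspace <- array(0i, dim = c(shape, n_coils, n_frames))
  for (f in seq_len(n_frames)) {
    ph <- make_phantom(shape, seed = frame_seeds[f], kind = kind)
    mc <- expand_to_coils(ph$image, maps)
    kspace[, , , f] <- mc$coil_kspace
  }
  structure(list(kspace = kspace, maps = maps, seed = as.integer(seed),
                 kind = kind, n_coils = as.integer(n_coils),
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "multicoil_volume")
}

#' @export
print.multicoil_volume <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf("<multicoil_volume> %dx%d, %d coils, %d frames, kind=%s, seed=%d\n",
              d[1], d[2], d[3], d[4], x$kind, x$seed))
  invisible(x)
}

#' Extract one frame of a volume as fully sampled multi-coil data
#'
#' @param volume A `multicoil_volume`.
#' @param frame Frame index.
#' @return A `multicoil_data` object (with coil images recomputed by
#'   [ifft2c()]).
#' @export
volume_frame <- function(volume, frame = 1L) {
  stopifnot(inherits(volume, "multicoil_volume"))
  d <- dim(volume$kspace)
  stopifnot(frame >= 1L, frame <= d[4])
  kspace <- volume$kspace[, , , frame, drop = FALSE]
  dim(kspace) <- d[1:3]
  coil_images <- array(0i, dim = d[1:3])
  for (ci in seq_len(d[3])) coil_images[, , ci] <- ifft2c(kspace[, , ci])
  structure(list(coil_images = coil_images, coil_kspace = kspace,
                 maps = volume$maps, geometry = volume$maps$geometry),
            class = "multicoil_data")
}

#' Write / read multi-coil volumes as HDF5
#'
#' The container holds one group per volume: `/volumes/<v>/kspace` with float
#' datasets `real` and `imag` of shape `[n_coils, nx, ny, n_frames]`,
#' `/volumes/<v>/maps` with `real`/`imag` of shape `[n_coils, nx, ny]`, and
#' group attributes `seed`, `kind`, `n_coils`, `pixel_spacing_mm`. (HDF5 has
#' no native complex type, hence the real/imaginary dataset pair.) The round
#' trip is lossless.
#'
#' @param volumes A list of `multicoil_volume` objects (or a single one).
#' @param path Output `.h5` file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a list of `multicoil_volume` objects.
#' @export
write_dataset <- function(volumes, path) {
  if (inherits(volumes, "multicoil_volume")) volumes <- list(volumes)
  stopifnot(all(vapply(volumes, inherits, TRUE, "multicoil_volume")))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "volumes")
  for (v in seq_along(volumes)) {
    vol <- volumes[[v]]
    g <- sprintf("volumes/%d", v - 1L)
    rhdf5::h5createGroup(path, g)
    k <- aperm(vol$kspace, c(3, 1, 2, 4))         # -> [n_coils, nx, ny, nf]
    m <- aperm(vol$maps$maps, c(3, 1, 2))         # -> [n_coils, nx, ny]
    rhdf5::h5createGroup(path, paste0(g, "/kspace"))
    rhdf5::h5write(Re(k), path, paste0(g, "/kspace/real"))
    rhdf5::h5write(Im(k), path, paste0(g, "/kspace/imag"))
    rhdf5::h5createGroup(path, paste0(g, "/maps"))
    rhdf5::h5write(Re(m), path, paste0(g, "/maps/real"))
    rhdf5::h5write(Im(m), path, paste0(g, "/maps/imag"))
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(vol$seed, gid, "seed")
    rhdf5::h5writeAttribute(vol$kind, gid, "kind")
    rhdf5::h5writeAttribute(vol$n_coils, gid, "n_coils")
    rhdf5::h5writeAttribute(vol$pixel_spacing_mm, gid, "pixel_spacing_mm")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    stop("dataset file not found: ", path, call. = FALSE)
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- rhdf5::h5ls(path, recursive = FALSE)
  if (!"volumes" %in% top$name) {
    stop("not a mricascade dataset (missing group 'volumes'): ", path,
         call. = FALSE)
  }
  listing <- rhdf5::h5ls(path)
  vnames <- listing$name[listing$group == "/volumes"]
  vnames <- vnames[order(as.integer(vnames))]
  out <- vector("list", length(vnames))
  for (i in seq_along(vnames)) {
    g <- paste0("/volumes/", vnames[i])
    sub <- listing$name[listing$group == g]
    for (req in c("kspace", "maps")) {
      if (!req %in% sub) {
        stop("malformed dataset: volume ", vnames[i], " is missing group '",
             req, "'", call. = FALSE)
      }
    }
    kr <- rhdf5::h5read(path, paste0(g, "/kspace/real"))
    ki <- rhdf5::h5read(path, paste0(g, "/kspace/imag"))
    mr <- rhdf5::h5read(path, paste0(g, "/maps/real"))
    mi <- rhdf5::h5read(path, paste0(g, "/maps/imag"))
    attrs <- rhdf5::h5readAttributes(path, g)
    kspace <- aperm(complex(real = kr, imaginary = ki) |>
                      array(dim = dim(kr)), c(2, 3, 1, 4))
    maps <- aperm(complex(real = mr, imaginary = mi) |>
                    array(dim = dim(mr)), c(2, 3, 1))
    out[[i]] <- structure(
      list(kspace = kspace,
           maps = structure(list(maps = maps, geometry = NULL),
                            class = "sensitivity_maps"),
           seed = as.integer(attrs$seed), kind = as.character(attrs$kind),
           n_coils = as.integer(attrs$n_coils),
           pixel_spacing_mm = as.numeric(attrs$pixel_spacing_mm)),
      class = "multicoil_volume")
  }
  out
}

#' Count the 2-D examples available in a list of volumes
#'
#' Each (frame) of each volume is one independent 2-D training example.
#'
#' @param volumes List of `multicoil_volume`.
#' @return Integer example count.
#' @export
n_examples <- function(volumes) {
  if (inherits(volumes, "multicoil_volume")) volumes <- list(volumes)
  sum(vapply(volumes, function(v) dim(v$kspace)[4], integer(1)))
}

#' Export a magnitude image as PNG for visual inspection
#'
#' @param image Complex or numeric matrix.
#' @param path Output PNG path.
#' @param max_value Normalization ceiling; defaults to the image maximum.
#' @return `path`, invisibly.
#' @export
export_png <- function(image, path, max_value = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for export_png()", call. = FALSE)
  }
  m <- Mod(image)
  if (is.null(max_value)) max_value <- max(m)
  if (max_value <= 0) max_value <- 1
  png::writePNG(pmin(m / max_value, 1), path)
  invisible(path)
}
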