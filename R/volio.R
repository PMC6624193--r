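#' Two-channel volumetric movie
#'
#' Container for a dual-color volumetric time series as produced by
#' single-objective light-sheet imaging: a 5-D intensity array in
#' `(time, channel, z, y, x)` order with physical voxel spacing and the
#' volumetric sampling rate. Channel 1 is the dynamic (calcium-sensitive)
#' green channel, channel 2 the static red reference channel.
#'
#' Coordinate convention used throughout the package: `y` is the
#' anterior-posterior axis (anterior at larger y), `x` is left-right,
#' `z` is depth. Voxel indices are 0-based in physical terms: the center of
#' voxel `i` (1-based R index) sits at `(i - 1) * spacing` micrometers.
#'
#' @param data numeric 5-D array, dimensions `(time, channel, z, y, x)`,
#'   finite and non-negative, with exactly 2 channels.
#' @param spacing_um numeric length-3, voxel spacing in micrometers in
#'   `(z, y, x)` order; strictly positive.
#' @param volume_rate volumes per second; strictly positive.
#' @param channel_names character length-2, defaults to `c("green", "red")`.
#' @return An object of class `two_channel_movie`.
#' @export
two_channel_movie <- function(data, spacing_um, volume_rate,
                              channel_names = c("green", "red")) {
  if (!is.array(data) || length(dim(data)) != 5L)
    stop("`data` must be a 5-D array (time, channel, z, y, x)")
  if (is.integer(data)) storage.mode(data) <- "double"
  if (dim(data)[2] != 2L)
    stop("channel axis (axis 2) must have exactly 2 channels, found ",
         dim(data)[2])
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be >= 0")
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L || any(spacing_um <= 0))
    stop("`spacing_um` must be 3 positive numbers (z, y, x)")
  if (!is.numeric(volume_rate) || length(volume_rate) != 1L || volume_rate <= 0)
    stop("`volume_rate` must be a positive scalar")
  if (length(channel_names) != 2L)
    stop("`channel_names` must have length 2")
  structure(
    list(data = data,
         spacing_um = spacing_um,
         volume_rate = as.numeric(volume_rate),
         channel_names = as.character(channel_names)),
    class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$data)
  cat("two_channel_movie:", d[1], "volumes x", d[2], "channels,",
      paste(d[3:5], collapse = " x "), "(z y x) voxels\n")
  cat("  spacing (z,y,x):", paste(x$spacing_um, collapse = ", "),
      "um; rate:", x$volume_rate, "volumes/s\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Times (s) of the volumes of a movie
#' @param movie a `two_channel_movie`.
#' @return numeric vector, `(0:(T-1)) / volume_rate`.
#' @export
movie_times <- function(movie) {
  (seq_len(dim(movie$data)[1]) - 1) / movie$volume_rate
}

channel_index <- function(movie, channel = c("green", "red")) {
  channel <- match.arg(channel)
  i <- match(channel, movie$channel_names)
  if (is.na(i)) stop("channel not present: ", channel)
  i
}

#' Raw oblique-plane stack
#'
#' Raw output of an oblique light-sheet scan before geometric correction:
#' successive y-z' planes collected while the sheet sweeps along x. The
#' sheet is inclined by `sheet_angle_deg` from vertical, so each z' layer is
#' displaced along x proportionally to its depth; [deskew()] undoes this.
#'
#' @param planes numeric 4-D array `(x_scan_step, channel, zprime, y)` with
#'   exactly 2 channels.
#' @param sheet_angle_deg sheet inclination from vertical, in `(0, 90)`.
#' @param x_step_um scan step along x, micrometers.
#' @param z_step_um sample spacing along z', micrometers.
#' @param y_step_um pixel pitch along y, micrometers.
#' @return An object of class `oblique_stack`.
#' @export
oblique_stack <- function(planes, sheet_angle_deg, x_step_um, z_step_um,
                          y_step_um) {
  if (!is.array(planes) || length(dim(planes)) != 4L)
    stop("`planes` must be a 4-D array (x_scan_step, channel, zprime, y)")
  if (dim(planes)[2] != 2L)
    stop("channel axis (axis 2) must have exactly 2 channels")
  if (any(dim(planes) == 0L)) stop("empty stack")
  if (!is.numeric(sheet_angle_deg) || length(sheet_angle_deg) != 1L ||
      sheet_angle_deg <= 0 || sheet_angle_deg >= 90)
    stop("`sheet_angle_deg` must lie strictly between 0 and 90 degrees")
  steps <- c(x_step_um, z_step_um, y_step_um)
  if (any(!is.finite(steps)) || any(steps <= 0))
    stop("all step sizes must be positive")
  structure(
    list(planes = planes, sheet_angle_deg = sheet_angle_deg,
         x_step_um = x_step_um, z_step_um = z_step_um, y_step_um = y_step_um),
    class = "oblique_stack")
}

#' Deskew an oblique stack into a Cartesian volume
#'
#' Applies the only reconstruction step used on such data: a shear along x
#' that compensates the sheet's oblique angle. The z' layer at depth index
#' `k` (0-based) is shifted along x by `k * z_step_um * tan(angle)`
#' micrometers, with linear interpolation onto the Cartesian x grid. The
#' output x axis is extended so that sheared content is never lost; voxels
#' with no source data are filled with 0 and flagged in the result's
#' `oob_filled` attribute. No scaling or other resampling is applied.
#'
#' @param stack an [oblique_stack()].
#' @param volume_rate volumes per second recorded in the output movie
#'   metadata (a single deskewed stack is one volume; default 1).
#' @return A `two_channel_movie` with one timepoint and spacing
#'   `(z_step_um, y_step_um, x_step_um)`.
#' @export
deskew <- function(stack, volume_rate = 1) {
  stopifnot(inherits(stack, "oblique_stack"))
  d <- dim(stack$planes)
  nx <- d[1]; nc <- d[2]; nz <- d[3]; ny <- d[4]
  shift_vox <- (seq_len(nz) - 1) * stack$z_step_um *
    tan(stack$sheet_angle_deg * pi / 180) / stack$x_step_um
  nx_out <- nx + ceiling(max(shift_vox))
  out <- array(0, dim = c(1L, nc, nz, ny, nx_out))
  xin <- seq_len(nx) - 1
  xout <- seq_len(nx_out) - 1
  for (ci in seq_len(nc)) {
    for (k in seq_len(nz)) {
      s <- shift_vox[k]
      for (yi in seq_len(ny)) {
        row <- stack$planes[, ci, k, yi]
        out[1, ci, k, yi, ] <- stats::approx(xin, row, xout = xout - s,
                                             method = "linear",
                                             yleft = 0, yright = 0)$y
      }
    }
  }
  out[out < 0] <- 0
  movie <- two_channel_movie(
    out, spacing_um = c(stack$z_step_um, stack$y_step_um, stack$x_step_um),
    volume_rate = volume_rate)
  attr(movie, "oob_filled") <- max(shift_vox) > 0
  attr(movie, "sheet_angle_deg") <- stack$sheet_angle_deg
  movie
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a movie to disk
#'
#' Two on-disk layouts are supported. TIFF: a multi-page file in TCZYX page
#' order (time slowest) storing 32-bit float pages, with all metadata
#' (dimensions, spacing, rate, channel names, intensity scale) in a JSON
#' sidecar `<path>.json`; intensities are divided by a power-of-two scale so
#' integer-valued data round-trips bit-identically. HDF5: dataset `movie`
#' holding the full 5-D array with attributes `spacing_um`, `volume_rate`
#' and `channel_names`. Readers never rescale intensities.
#'
#' @param movie a `two_channel_movie`.
#' @param path output file; format chosen by extension (`.tif`/`.tiff` or
#'   `.h5`/`.hdf5`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "two_channel_movie"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    d <- dim(movie$data)
    mx <- max(movie$data)
    # pages are stored as 32-bit samples quantized over [0, scale]; with
    # scale = max the step is scale / 2^32, and integer-valued data (flagged
    # in the sidecar) is re-rounded on read, making the round trip exact
    scale <- max(mx, 1)
    data_integer <- all(movie$data == round(movie$data))
    pages <- vector("list", d[1] * d[2] * d[3])
    i <- 0L
    for (t in seq_len(d[1])) for (ci in seq_len(d[2])) for (k in seq_len(d[3])) {
      i <- i + 1L
      pages[[i]] <- movie$data[t, ci, k, , ] / scale
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    meta <- list(dims = d, dim_order = "TCZYX",
                 spacing_um = movie$spacing_um,
                 volume_rate = movie$volume_rate,
                 channel_names = movie$channel_names,
                 intensity_scale = scale,
                 data_integer = data_integer)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext %in% c("h5", "hdf5")) {
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(movie$data, path, "movie")
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, "movie")
    rhdf5::h5writeAttribute(movie$spacing_um, did, "spacing_um")
    rhdf5::h5writeAttribute(movie$volume_rate, did, "volume_rate")
    rhdf5::h5writeAttribute(movie$channel_names, did, "channel_names")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  } else {
    stop("unsupported format: .", ext, " (use .tif/.tiff or .h5/.hdf5)")
  }
  invisible(path)
}

#' Read a movie from disk
#'
#' Counterpart of [write_movie()]. Fails hard if spacing metadata is absent
#' (no silent default) or if the stored channel axis does not have exactly
#' two channels.
#'
#' @param path file written by [write_movie()].
#' @return A `two_channel_movie`.
#' @export
read_movie <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    sp <- sidecar_path(path)
    if (!file.exists(sp))
      stop("missing spacing metadata: sidecar not found at ", sp)
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    for (f in c("dims", "spacing_um", "volume_rate", "channel_names",
                "intensity_scale"))
      if (is.null(meta[[f]])) stop("metadata field missing: ", f)
    d <- as.integer(meta$dims)
    if (d[2] != 2L)
      stop("channel axis (axis 2 of TCZYX) must have 2 channels, found ", d[2])
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != d[1] * d[2] * d[3])
      stop("page count does not match metadata dims")
    data <- array(0, dim = d)
    i <- 0L
    for (t in seq_len(d[1])) for (ci in seq_len(d[2])) for (k in seq_len(d[3])) {
      i <- i + 1L
      page <- pages[[i]] * meta$intensity_scale
      if (isTRUE(meta$data_integer)) page <- round(page)
      data[t, ci, k, , ] <- page
    }
    two_channel_movie(data, meta$spacing_um, meta$volume_rate,
                      meta$channel_names)
  } else if (ext %in% c("h5", "hdf5")) {
    x <- rhdf5::h5read(path, "movie", read.attributes = TRUE)
    spacing <- attr(x, "spacing_um")
    rate <- attr(x, "volume_rate")
    ch <- attr(x, "channel_names")
    if (is.null(spacing)) stop("missing spacing metadata: no `spacing_um` attribute")
    if (is.null(rate)) stop("missing `volume_rate` attribute")
    if (is.null(ch)) ch <- c("green", "red")
    data <- array(as.numeric(x), dim = dim(x))
    if (dim(data)[2] != 2L)
      stop("channel axis (axis 2) must have 2 channels, found ", dim(data)[2])
    two_channel_movie(data, as.numeric(spacing), as.numeric(rate),
                      as.character(ch))
  } else {
    stop("unsupported format: .", ext)
  }
}
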