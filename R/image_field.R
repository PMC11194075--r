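#' Multi-channel 3D image field
#'
#' An `ImageField` is the unit of acquisition: a multi-channel z-stack stored
#' as a 4-dimensional array indexed `(channel, z, y, x)`, together with the
#' physical voxel geometry and the biological role of each channel. The
#' default z geometry matches a 5 um stack acquired at 0.2 um spacing
#' (26 slices, inclusive endpoints). All pixel coordinates in the package are
#' 1-based `(y, x)` indices with the origin at the top-left of the first
#' slice; distances are in pixels unless the name carries a `_um` suffix.
#'
#' @param voxels numeric array with `dim = c(channels, z, y, x)`; intensities
#'   must be integer-valued and lie in `[0, 2^bit_depth - 1]`.
#' @param channel_roles character vector, one role per channel, each one of
#'   `"dapi"`, `"telomere"`, `"pml"`, `"edu"`, `"custom"`.
#' @param z_spacing_um z-step in micrometres (default 0.2).
#' @param xy_pixel_um lateral pixel size in micrometres (default 0.1).
#' @param bit_depth camera bit depth, 8 or 16.
#' @param field_id identifier string for the field of view.
#' @param check validate the intensity range (skipped for freshly rendered
#'   fields whose range is guaranteed by construction).
#' @return an object of class `ImageField`.
#' @export
image_field <- function(voxels, channel_roles, z_spacing_um = 0.2,
                        xy_pixel_um = 0.1, bit_depth = 16,
                        field_id = "field", check = TRUE) {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    stop("`voxels` must be a 4-d array (channel, z, y, x)")
  if (length(channel_roles) != dim(voxels)[1])
    stop("`channel_roles` must name every channel")
  bad <- setdiff(channel_roles, c("dapi", "telomere", "pml", "edu", "custom"))
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (z_spacing_um <= 0 || xy_pixel_um <= 0)
    stop("voxel spacings must be positive")
  if (check) {
    rng <- range(voxels)
    if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
      stop("intensities must lie in [0, 2^bit_depth - 1]")
  }
  structure(list(
    voxels = voxels,
    channel_roles = as.character(channel_roles),
    z_spacing_um = z_spacing_um,
    xy_pixel_um = xy_pixel_um,
    bit_depth = as.integer(bit_depth),
    field_id = as.character(field_id)
  ), class = "ImageField")
}

#' @export
print.ImageField <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageField '%s': %d channel(s) [%s], %d z-slices, %d x %d px\n",
              x$field_id, d[1], paste(x$channel_roles, collapse = ", "),
              d[2], d[3], d[4]))
  cat(sprintf("  z spacing %.3g um, pixel %.3g um, %d-bit\n",
              x$z_spacing_um, x$xy_pixel_um, x$bit_depth))
  invisible(x)
}

#' @export
dim.ImageField <- function(x) dim(x$voxels)

channel_index <- function(field, channel_role) {
  i <- which(field$channel_roles == channel_role)
  if (!length(i))
    stop("channel role '", channel_role, "' not present in field '",
         field$field_id, "'")
  i[1]
}

#' 2D projection of one channel
#'
#' Wraps a `(y, x)` intensity matrix with its provenance. Most detection
#' functions also accept a plain matrix.
#'
#' @param pixels numeric matrix indexed `(y, x)`.
#' @param channel_role role of the source channel.
#' @param source_field_id id of the originating [image_field()].
#' @return an object of class `Projection2D` (a matrix with attributes).
#' @export
projection2d <- function(pixels, channel_role = "custom",
                         source_field_id = "") {
  stopifnot(is.matrix(pixels))
  structure(pixels, channel_role = channel_role,
            source_field_id = source_field_id,
            class = c("Projection2D", "matrix", "array"))
}

as_pixel_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "channel_role") <- NULL
  attr(m, "source_field_id") <- NULL
  m
}

#' Write an image field as a multi-page TIFF with a YAML sidecar
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...)
#' as plain 8- or 16-bit grayscale TIFF. Geometry, channel roles and the
#' interleave are declared in `<path>.yml` so that [read_field()] can restore
#' the field exactly.
#'
#' @param field an [image_field()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "ImageField"))
  d <- dim(field$voxels)
  scale <- 2^field$bit_depth - 1
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[k]] <- field$voxels[ch, z, , ] / scale
      k <- k + 1L
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = field$bit_depth)
  meta <- list(
    field_id = field$field_id,
    n_channels = d[1],
    n_z = d[2],
    channel_roles = as.list(field$channel_roles),
    z_spacing_um = field$z_spacing_um,
    xy_pixel_um = field$xy_pixel_um,
    bit_depth = field$bit_depth,
    page_order = "channel_major"
  )
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a multi-page TIFF into an image field
#'
#' If `<path>.yml` (written by [write_field()]) exists it supplies the
#' channel layout and geometry; otherwise `channel_role_map` must be given
#' and the page count must be divisible by its length (channel-major
#' interleave is assumed).
#'
#' @param path TIFF file path.
#' @param channel_role_map named list/vector mapping channel index (1-based,
#'   as character or integer order) to role; ignored when a sidecar exists.
#' @param z_spacing_um,xy_pixel_um geometry used when no sidecar exists.
#' @param bit_depth bit depth used when no sidecar exists.
#' @return an [image_field()].
#' @export
read_field <- function(path, channel_role_map = NULL, z_spacing_um = 0.2,
                       xy_pixel_um = 0.1, bit_depth = 16) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".yml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else NULL
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("inconsistent page shapes in ", path)
  if (!is.null(meta)) {
    roles <- unlist(meta$channel_roles)
    n_ch <- meta$n_channels
    n_z <- meta$n_z
    z_spacing_um <- meta$z_spacing_um
    xy_pixel_um <- meta$xy_pixel_um
    bit_depth <- meta$bit_depth
    field_id <- meta$field_id
  } else {
    if (is.null(channel_role_map))
      stop("no sidecar metadata; `channel_role_map` is required")
    roles <- unlist(channel_role_map)
    n_ch <- length(roles)
    if (length(pages) %% n_ch != 0)
      stop("page count ", length(pages),
           " not divisible by declared channel count ", n_ch)
    n_z <- length(pages) %/% n_ch
    field_id <- tools::file_path_sans_ext(basename(path))
  }
  if (length(pages) != n_ch * n_z)
    stop("expected ", n_ch * n_z, " pages, found ", length(pages))
  vox <- array(0, dim = c(n_ch, n_z, shp[1], shp[2]))
  k <- 1L
  for (ch in seq_len(n_ch)) {
    for (z in seq_len(n_z)) {
      vox[ch, z, , ] <- pages[[k]]
      k <- k + 1L
    }
  }
  image_field(vox, roles, z_spacing_um = z_spacing_um,
              xy_pixel_um = xy_pixel_um, bit_depth = bit_depth,
              field_id = field_id)
}
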