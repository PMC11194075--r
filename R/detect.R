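#' Detection parameters
#'
#' Parameters of the focus-detection chain. `prominence = NULL` selects the
#' automatic threshold `k * noise`, where the noise scale is the robust
#' standard deviation `1.4826 * MAD` of the tophat-filtered image (the
#' package's reading of ImageJ's "noise tolerance").
#'
#' @param tophat_radius_px disk radius of the white-tophat structuring
#'   element (about twice the expected focus radius).
#' @param prominence absolute prominence threshold, or `NULL` for automatic.
#' @param k auto-threshold factor when `prominence` is `NULL` (the default
#'   7 keeps the expected number of spurious noise maxima per field near
#'   zero on sparse channels while costing no recall at typical focus
#'   signal-to-noise).
#' @param peak_fraction segmentation cut as a fraction of each peak height
#'   (0.5 = full width at half maximum).
#' @param min_focus_area_px objects smaller than this are discarded.
#' @return a `DetectionParams` list.
#' @export
detection_params <- function(tophat_radius_px = 5, prominence = NULL,
                             k = 7, peak_fraction = 0.5,
                             min_focus_area_px = 2) {
  if (tophat_radius_px < 1) stop("tophat_radius_px must be >= 1")
  if (!is.null(prominence) && prominence <= 0)
    stop("prominence must be positive")
  if (peak_fraction <= 0 || peak_fraction > 1)
    stop("peak_fraction must lie in (0, 1]")
  if (min_focus_area_px < 0) stop("min_focus_area_px must be >= 0")
  structure(list(tophat_radius_px = as.integer(tophat_radius_px),
                 prominence = prominence, k = k,
                 peak_fraction = peak_fraction,
                 min_focus_area_px = as.integer(min_focus_area_px)),
            class = "DetectionParams")
}

#' Maximum-intensity projection of one channel
#'
#' Collapses the z-stack of the requested channel to a 2D image whose every
#' pixel is the maximum over z at that position.
#'
#' @param field an [image_field()].
#' @param channel_role channel to project.
#' @return a [projection2d()].
#' @export
max_project <- function(field, channel_role) {
  stopifnot(inherits(field, "ImageField"))
  ci <- channel_index(field, channel_role)
  d <- dim(field$voxels)
  m <- mip_cpp(as.numeric(field$voxels[ci, , , ]), d[2], d[3], d[4])
  projection2d(m, channel_role = channel_role,
               source_field_id = field$field_id)
}

disc_mask <- function(radius_px) {
  r <- as.integer(radius_px)
  outer(-r:r, -r:r, function(a, b) as.numeric(a^2 + b^2 <= r^2))
}

#' White-tophat background subtraction
#'
#' Subtracts the grayscale opening (erosion then dilation) by a disk of the
#' given radius from the image, removing background structure larger than
#' the disk while retaining small bright foci. The result is nonnegative.
#'
#' @param image matrix or [projection2d()].
#' @param radius_px disk radius in pixels (>= 1).
#' @return filtered image of the same class/shape.
#' @export
tophat_subtract <- function(image, radius_px) {
  if (radius_px < 1) stop("radius_px must be >= 1")
  m <- as_pixel_matrix(image)
  kern <- disc_mask(radius_px)
  # grayscale morphology commutes with positive scaling; EBImage expects
  # intensities in [0, 1]
  lo <- min(m); hi <- max(m)
  if (hi > lo) {
    m01 <- (m - lo) / (hi - lo)
    opened <- EBImage::dilate(EBImage::erode(m01, kern), kern)
    opened <- lo + opened * (hi - lo)
  } else {
    opened <- m
  }
  out <- pmax(m - opened, 0)
  if (inherits(image, "Projection2D"))
    projection2d(out, attr(image, "channel_role"),
                 attr(image, "source_field_id"))
  else out
}

robust_noise_sd <- function(image) {
  stats::mad(as.numeric(as_pixel_matrix(image)))  # 1.4826 * MAD
}

#' Find local intensity maxima by topographic prominence
#'
#' Returns the 8-connected local maxima whose prominence (height above the
#' lowest level at which the peak's region would merge into a higher region,
#' or above the image minimum for the global maximum) is at least
#' `prominence`. A connected plateau of equal maxima is reported once, at
#' the plateau pixel nearest its centroid (ties toward smaller `(y, x)`).
#' When two equal-height regions merge, the peak with the smaller `(y, x)`
#' survives.
#'
#' @param image matrix or [projection2d()].
#' @param prominence positive prominence threshold.
#' @return integer matrix with columns `y`, `x`, sorted by `(y, x)`.
#' @export
find_maxima <- function(image, prominence) {
  if (!is.numeric(prominence) || prominence <= 0)
    stop("prominence must be positive")
  m <- as_pixel_matrix(image)
  storage.mode(m) <- "double"
  pk <- find_maxima_cpp(m, prominence)
  if (nrow(pk) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  coll <- t(apply(pk, 1, function(p) plateau_centroid_cpp(m, p[1], p[2])))
  coll <- unique(coll)
  coll <- coll[order(coll[, 1], coll[, 2]), , drop = FALSE]
  colnames(coll) <- c("y", "x")
  coll
}

#' Set of segmented focus objects on one projection
#'
#' @param channel_role channel of origin.
#' @param objects data.frame with columns `label, y, x, area_px,
#'   peak_intensity, peak_y, peak_x` (`y`, `x` are mask centroids).
#' @param labels integer label image (0 = background) of the same shape as
#'   the source projection; object masks are its positive levels.
#' @param source_field_id provenance.
#' @return a `FociSet`.
#' @export
foci_set <- function(channel_role, objects, labels, source_field_id = "") {
  structure(list(channel_role = channel_role, objects = objects,
                 labels = labels, source_field_id = source_field_id),
            class = "FociSet")
}

#' @export
print.FociSet <- function(x, ...) {
  cat(sprintf("FociSet (%s): %d object(s), total area %d px\n",
              x$channel_role, nrow(x$objects), sum(x$objects$area_px)))
  invisible(x)
}

empty_objects_df <- function() {
  data.frame(label = integer(), y = numeric(), x = numeric(),
             area_px = integer(), peak_intensity = numeric(),
             peak_y = integer(), peak_x = integer())
}

#' Segment focus objects around detected peaks
#'
#' Each peak's object is the 8-connected region of pixels with intensity at
#' least `peak_fraction` times the peak height, grown from the peak; pixels
#' claimed by several peaks are split by a marker-based watershed (descending
#' priority flood from the peaks). Objects smaller than `min_focus_area_px`
#' are discarded together with their peaks.
#'
#' @param image matrix or [projection2d()] the peaks were found on.
#' @param peaks integer matrix of `(y, x)` peak coordinates from
#'   [find_maxima()].
#' @param params a [detection_params()].
#' @return a [foci_set()].
#' @export
segment_foci <- function(image, peaks, params = detection_params()) {
  m <- as_pixel_matrix(image)
  storage.mode(m) <- "double"
  role <- attr(image, "channel_role")
  src <- attr(image, "source_field_id")
  if (is.null(role)) role <- "custom"
  if (is.null(src)) src <- ""
  if (is.null(dim(peaks))) peaks <- matrix(peaks, ncol = 2)
  n <- nrow(peaks)
  lab_final <- matrix(0L, nrow(m), ncol(m))
  if (n == 0)
    return(foci_set(role, empty_objects_df(), lab_final, src))
  ny <- nrow(m); nx <- ncol(m)
  for (i in seq_len(n)) {
    y <- peaks[i, 1]; x <- peaks[i, 2]
    nb <- m[max(1, y - 1):min(ny, y + 1), max(1, x - 1):min(nx, x + 1)]
    if (m[y, x] < max(nb))
      stop("peak at (", y, ",", x, ") is not a local maximum of the image")
  }
  markers <- matrix(0L, ny, nx)
  markers[cbind(peaks[, 1], peaks[, 2])] <- seq_len(n)
  h <- m[cbind(peaks[, 1], peaks[, 2])]
  # pixels below the lowest possible segmentation cut can never join an
  # object; restricting the flood there leaves object territories unchanged
  flood_mask <- m >= params$peak_fraction * min(h)
  territory <- marker_watershed_cpp(m, markers, flood_mask)
  objs <- list()
  next_label <- 1L
  ord <- order(peaks[, 1], peaks[, 2])
  for (i in ord) {
    # grow the component inside an expanding local window; exact because a
    # component fully interior to the window cannot extend beyond it
    w <- 24L
    repeat {
      y0 <- max(1L, peaks[i, 1] - w); y1 <- min(ny, peaks[i, 1] + w)
      x0 <- max(1L, peaks[i, 2] - w); x1 <- min(nx, peaks[i, 2] + w)
      sub <- territory[y0:y1, x0:x1, drop = FALSE] == i &
        m[y0:y1, x0:x1, drop = FALSE] >= params$peak_fraction * h[i]
      cc <- label8_cpp(sub)
      comp <- cc[peaks[i, 1] - y0 + 1, peaks[i, 2] - x0 + 1]
      full <- y0 == 1L && x0 == 1L && y1 == ny && x1 == nx
      if (comp == 0 || full) break
      on_edge <- any(cc[1, ] == comp) || any(cc[nrow(cc), ] == comp) ||
        any(cc[, 1] == comp) || any(cc[, ncol(cc)] == comp)
      edge_real <- (y0 > 1L && any(cc[1, ] == comp)) ||
        (y1 < ny && any(cc[nrow(cc), ] == comp)) ||
        (x0 > 1L && any(cc[, 1] == comp)) ||
        (x1 < nx && any(cc[, ncol(cc)] == comp))
      if (!on_edge || !edge_real) break
      w <- w * 2L
    }
    if (comp == 0) next   # peak itself below cut (cannot happen for frac<=1)
    mask_idx <- which(cc == comp, arr.ind = TRUE)
    area <- nrow(mask_idx)
    if (area < params$min_focus_area_px) next
    yy <- mask_idx[, 1] + y0 - 1; xx <- mask_idx[, 2] + x0 - 1
    lab_final[cbind(yy, xx)] <- next_label
    objs[[next_label]] <- data.frame(
      label = next_label, y = mean(yy), x = mean(xx), area_px = area,
      peak_intensity = h[i], peak_y = peaks[i, 1], peak_x = peaks[i, 2])
    next_label <- next_label + 1L
  }
  objects <- if (length(objs)) do.call(rbind, objs) else empty_objects_df()
  foci_set(role, objects, lab_final, src)
}

#' Detect foci on one channel of a field
#'
#' Convenience chain: maximum-intensity projection, white tophat, automatic
#' (or fixed) prominence threshold, maxima finding, segmentation.
#'
#' @param field an [image_field()].
#' @param channel_role channel to analyze.
#' @param params a [detection_params()].
#' @return a [foci_set()]; the prominence used is stored as attribute
#'   `"prominence"`.
#' @export
detect_foci <- function(field, channel_role, params = detection_params()) {
  proj <- max_project(field, channel_role)
  th <- tophat_subtract(proj, params$tophat_radius_px)
  prom <- params$prominence
  if (is.null(prom)) {
    prom <- params$k * robust_noise_sd(th)
    if (prom <= 0) prom <- params$k   # degenerate all-flat image
  }
  peaks <- find_maxima(th, prom)
  fs <- segment_foci(th, peaks, params)
  attr(fs, "prominence") <- prom
  fs
}

#' Map of segmented nuclei
#'
#' @param labels integer label image (0 = background, k = nucleus k;
#'   labels are consecutive).
#' @param table data.frame with `label, area_px, y0, x0, y1, x1`.
#' @param excluded_border_count nuclei dropped for touching the border.
#' @return a `NucleusMap`.
#' @export
nucleus_map <- function(labels, table, excluded_border_count = 0L) {
  structure(list(labels = labels, table = table,
                 excluded_border_count = as.integer(excluded_border_count)),
            class = "NucleusMap")
}

#' @export
print.NucleusMap <- function(x, ...) {
  cat(sprintf("NucleusMap: %d nucleus(ei), %d excluded at border\n",
              nrow(x$table), x$excluded_border_count))
  invisible(x)
}

#' Segment nuclei from a DAPI projection
#'
#' Gaussian blur, Otsu threshold, hole filling, 8-connected labelling;
#' components smaller than `min_area_px` are removed and components touching
#' any image border are excluded (their number is recorded).
#'
#' @param dapi DAPI [projection2d()] or matrix.
#' @param min_area_px minimum nucleus area.
#' @param blur_sigma_px Gaussian presmoothing sigma.
#' @return a [nucleus_map()].
#' @export
segment_nuclei <- function(dapi, min_area_px = 500, blur_sigma_px = 2) {
  m <- as_pixel_matrix(dapi)
  ny <- nrow(m); nx <- ncol(m)
  if (max(m) <= 0)
    return(nucleus_map(matrix(0L, ny, nx),
                       data.frame(label = integer(), area_px = integer(),
                                  cy = numeric(), cx = numeric(),
                                  y0 = integer(), x0 = integer(),
                                  y1 = integer(), x1 = integer())))
  sm <- as_pixel_matrix(EBImage::gblur(m / max(m), sigma = blur_sigma_px))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- sm > thr
  bin <- EBImage::fillHull(bin)
  lab <- label8_cpp(matrix(as.logical(bin), ny, nx))
  n0 <- max(lab)
  if (n0 == 0)
    return(nucleus_map(matrix(0L, ny, nx),
                       data.frame(label = integer(), area_px = integer(),
                                  cy = numeric(), cx = numeric(),
                                  y0 = integer(), x0 = integer(),
                                  y1 = integer(), x1 = integer())))
  areas <- tabulate(lab[lab > 0], nbins = n0)
  border_labels <- unique(c(lab[1, ], lab[ny, ], lab[, 1], lab[, nx]))
  border_labels <- border_labels[border_labels > 0]
  keep <- which(areas >= min_area_px & !(seq_len(n0) %in% border_labels))
  excluded_border <- sum(areas[border_labels] >= min_area_px)
  relab <- integer(n0)
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, ny, nx)
  pos <- lab > 0
  out[pos] <- relab[lab[pos]]
  tab <- do.call(rbind, lapply(seq_along(keep), function(i) {
    idx <- which(out == i, arr.ind = TRUE)
    data.frame(label = i, area_px = nrow(idx),
               cy = mean(idx[, 1]), cx = mean(idx[, 2]),
               y0 = min(idx[, 1]), x0 = min(idx[, 2]),
               y1 = max(idx[, 1]), x1 = max(idx[, 2]))
  }))
  if (is.null(tab))
    tab <- data.frame(label = integer(), area_px = integer(),
                      cy = numeric(), cx = numeric(),
                      y0 = integer(), x0 = integer(), y1 = integer(),
                      x1 = integer())
  nucleus_map(out, tab, excluded_border)
}

#' Assign foci to nuclei by centroid containment
#'
#' A focus belongs to the nucleus whose mask contains its (rounded) centroid
#' pixel; foci whose centroid falls in background are dropped and counted.
#'
#' @param foci a [foci_set()].
#' @param nuclei a [nucleus_map()] over the same image geometry.
#' @return list with `assignment` (integer nucleus id per object, 0 =
#'   dropped) and `dropped` (count of background foci).
#' @export
assign_foci <- function(foci, nuclei) {
  if (!identical(dim(foci$labels), dim(nuclei$labels)))
    stop("foci and nuclei come from different image geometries")
  if (!nrow(foci$objects))
    return(list(assignment = integer(0), dropped = 0L))
  py <- pmin(pmax(floor(foci$objects$y + 0.5), 1), nrow(nuclei$labels))
  px <- pmin(pmax(floor(foci$objects$x + 0.5), 1), ncol(nuclei$labels))
  a <- nuclei$labels[cbind(py, px)]
  list(assignment = as.integer(a), dropped = sum(a == 0L))
}

#' Restrict a foci set to a subset of its objects
#'
#' @param foci a [foci_set()].
#' @param labels_keep object labels to retain.
#' @return a [foci_set()] containing only those objects (labels preserved).
#' @export
subset_foci <- function(foci, labels_keep) {
  obj <- foci$objects[foci$objects$label %in% labels_keep, , drop = FALSE]
  lab <- foci$labels
  lab[!(lab %in% labels_keep)] <- 0L
  foci_set(foci$channel_role, obj, lab, foci$source_field_id)
}
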