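#' Configuration for the synthetic microscopy generator
#'
#' Parameterizes fields of interphase nuclei carrying telomere FISH foci,
#' PML bodies (a configurable fraction colocalized with telomeres, i.e.
#' APBs), and EdU foci placed at APBs, rendered as 3D stacks with Gaussian
#' PSF blur, Poisson shot noise and Gaussian read noise. Defaults give the
#' package's reference imaging conditions: 0.1 um pixels, 26 z-slices at
#' 0.2 um (a 5 um stack), 16-bit, diffraction-limited PSF of 1 px sigma,
#' and foci resolvable at a 4 px minimum separation.
#'
#' @param n_cells nuclei per field.
#' @param image_shape_px `(ny, nx)` field size in pixels.
#' @param nucleus_radii_px nominal `(major, minor)` semi-axes; each axis is
#'   jittered uniformly by +/-15\% and the ellipse randomly rotated.
#' @param telomere_count_mean Poisson mean of telomere foci per nucleus.
#' @param merge_prob clustering parameter in `[0,1]`: probability a telomere
#'   focus is merged into its nearest neighbour (fewer, larger foci).
#' @param apb_prob probability a telomere focus carries a colocalized PML
#'   body (an APB).
#' @param free_pml_mean Poisson mean of non-telomeric PML bodies per nucleus.
#' @param edu_at_apb_prob probability an APB carries an EdU focus
#'   (telomeric DNA synthesis).
#' @param focus_radius_px pre-blur Gaussian scale of a focus.
#' @param min_separation_px minimum center separation between foci of the
#'   same channel within a nucleus.
#' @param psf_sigma_px lateral PSF sigma.
#' @param z_sigma_slices axial extent (sigma, in slices) of a focus.
#' @param photons_per_peak expected peak signal above background, in counts.
#' @param read_noise_sd Gaussian read noise sigma, in counts.
#' @param background_level uniform background, in counts.
#' @param dapi_level DAPI fill level inside nuclei, in counts.
#' @param jitter_sd_px sd of the displacement of PML/EdU partners from their
#'   telomere center (0 = exactly concentric).
#' @param channels channel roles to render, subset of
#'   `c("dapi","telomere","pml","edu")`.
#' @param n_z,z_spacing_um,xy_pixel_um,bit_depth stack geometry.
#' @param seed default RNG seed used by [simulate_field()] when none is
#'   passed explicitly.
#' @return a validated `SimulationConfig` (list).
#' @export
simulation_config <- function(n_cells = 16,
                              image_shape_px = c(416, 416),
                              nucleus_radii_px = c(38, 30),
                              telomere_count_mean = 45,
                              merge_prob = 0,
                              apb_prob = 0.05,
                              free_pml_mean = 10,
                              edu_at_apb_prob = 0.7,
                              focus_radius_px = 1.5,
                              min_separation_px = 4.5,
                              psf_sigma_px = 1.0,
                              z_sigma_slices = 1.5,
                              photons_per_peak = 800,
                              read_noise_sd = 10,
                              background_level = 50,
                              dapi_level = 200,
                              jitter_sd_px = 0,
                              channels = c("dapi", "telomere", "pml", "edu"),
                              n_z = 26, z_spacing_um = 0.2,
                              xy_pixel_um = 0.1, bit_depth = 16,
                              seed = NULL) {
  cfg <- as.list(environment())
  probs <- c(merge_prob = merge_prob, apb_prob = apb_prob,
             edu_at_apb_prob = edu_at_apb_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (telomere_count_mean < 0 || free_pml_mean < 0)
    stop("focus count means must be nonnegative")
  if (focus_radius_px <= 0 || psf_sigma_px <= 0)
    stop("focus_radius_px and psf_sigma_px must be positive")
  if (read_noise_sd < 0 || background_level < 0)
    stop("noise and background must be nonnegative")
  if (!all(channels %in% c("dapi", "telomere", "pml", "edu")))
    stop("unknown channel in `channels`")
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(paste0("SimulationConfig: %d cells/field, E[telomeres]=%.3g, ",
                     "merge %.2g, APB %.2g, EdU@APB %.2g\n"),
              x$n_cells, x$telomere_count_mean, x$merge_prob, x$apb_prob,
              x$edu_at_apb_prob))
  invisible(x)
}

# n uniform points in the inner (scaled) rotated ellipse of a nucleus row
sample_in_ellipse <- function(nuc, n = 1, shrink = 0.85) {
  r <- sqrt(runif(n)); phi <- runif(n, 0, 2 * pi)
  ey <- shrink * nuc$radius_y * r * cos(phi)
  ex <- shrink * nuc$radius_x * r * sin(phi)
  th <- nuc$theta
  cbind(y = nuc$center_y + ey * cos(th) - ex * sin(th),
        x = nuc$center_x + ey * sin(th) + ex * cos(th))
}

# Stratified placement: nuclei sit on a jittered grid, which packs fields
# densely while guaranteeing non-overlap (circumscribing-circle criterion).
place_nuclei <- function(cfg) {
  ny <- cfg$image_shape_px[1]; nx <- cfg$image_shape_px[2]
  rmaj <- max(cfg$nucleus_radii_px) * 1.15
  margin <- rmaj + 6
  min_dist <- 2 * rmaj + 8
  if (2 * margin >= min(ny, nx))
    stop("capacity error: nucleus_radii_px too large for image_shape_px")
  gr <- max(1L, ceiling(sqrt(cfg$n_cells * ny / nx)))
  gc <- ceiling(cfg$n_cells / gr)
  sy <- if (gr > 1) (ny - 2 * margin) / (gr - 1) else Inf
  sx <- if (gc > 1) (nx - 2 * margin) / (gc - 1) else Inf
  if (min(sy, sx) < min_dist)
    stop("capacity error: cannot place ", cfg$n_cells,
         " non-overlapping nuclei; reduce n_cells or nucleus_radii_px ",
         "or enlarge image_shape_px")
  jy <- min(6, (sy - min_dist) / 2); jx <- min(6, (sx - min_dist) / 2)
  slots <- sample(gr * gc, cfg$n_cells)
  gy <- (slots - 1) %% gr; gx <- (slots - 1) %/% gr
  cy0 <- if (gr > 1) margin + gy * sy else rep(ny / 2, cfg$n_cells)
  cx0 <- if (gc > 1) margin + gx * sx else rep(nx / 2, cfg$n_cells)
  data.frame(cell_id = seq_len(cfg$n_cells),
             center_y = cy0 + runif(cfg$n_cells, -jy, jy),
             center_x = cx0 + runif(cfg$n_cells, -jx, jx),
             radius_y = cfg$nucleus_radii_px[1] *
               runif(cfg$n_cells, 0.85, 1.15),
             radius_x = cfg$nucleus_radii_px[2] *
               runif(cfg$n_cells, 0.85, 1.15),
             theta = runif(cfg$n_cells, 0, pi))
}

# Random sequential placement with a minimum-separation (and optional
# exclusion-zone) constraint, batched for speed. In a crowded nucleus the
# attainable count saturates (excluded volume); placement then stops early
# and the truth tables record what was actually placed.
place_foci_in_nucleus <- function(nuc, n, min_sep, avoid = NULL,
                                  avoid_dist = 0, max_tries_per = 2048L) {
  pts <- matrix(numeric(0), 0, 2)
  batch <- 64L
  for (i in seq_len(n)) {
    placed <- FALSE
    tries <- 0L
    while (tries < max_tries_per) {
      cand <- sample_in_ellipse(nuc, batch)
      tries <- tries + batch
      ok <- rep(TRUE, batch)
      if (nrow(pts)) {
        d2 <- outer(cand[, 1], pts[, 1], "-")^2 +
          outer(cand[, 2], pts[, 2], "-")^2
        ok <- ok & apply(d2 >= min_sep^2, 1, all)
      }
      if (!is.null(avoid) && nrow(avoid)) {
        d2a <- outer(cand[, 1], avoid[, 1], "-")^2 +
          outer(cand[, 2], avoid[, 2], "-")^2
        ok <- ok & apply(d2a >= avoid_dist^2, 1, all)
      }
      hit <- which(ok)
      if (length(hit)) {
        pts <- rbind(pts, cand[hit[1], , drop = FALSE])
        placed <- TRUE
        break
      }
    }
    if (!placed) return(pts)
  }
  pts
}

#' Simulate the ground truth of one field (no rendering)
#'
#' Runs the generative model through focus placement, clustering, APB/EdU
#' partner assignment and per-cell count bookkeeping, without rendering any
#' voxels. [simulate_field()] calls this internally; it is also the fast
#' path for statistical power studies that only need true per-cell counts.
#'
#' @param config a [simulation_config()].
#' @param field_id field identifier recorded in the tables.
#' @param seed optional RNG seed (defaults to `config$seed`; `NULL` leaves
#'   the RNG state untouched).
#' @return a [ground_truth_table()].
#' @export
simulate_truth <- function(config, field_id = "sim", seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  nuc <- place_nuclei(cfg)
  foci <- empty_foci_df()
  next_id <- 1L
  for (i in seq_len(nrow(nuc))) {
    n_tel <- rpois(1, cfg$telomere_count_mean)
    if (n_tel > 0) {
      pts <- place_foci_in_nucleus(nuc[i, ], n_tel, cfg$min_separation_px)
      n_tel <- nrow(pts)
    }
    if (n_tel > 0) {
      foci <- rbind(foci, data.frame(
        field_id = field_id, cell_id = nuc$cell_id[i],
        channel_role = "telomere",
        focus_id = seq.int(next_id, length.out = n_tel),
        y = pts[, 1], x = pts[, 2],
        true_radius_px = cfg$focus_radius_px,
        linked_focus_ids = "", stringsAsFactors = FALSE))
      next_id <- next_id + n_tel
    }
  }
  cells <- nuc
  cells$field_id <- field_id
  cells <- cells[, c("field_id", "cell_id", "center_y", "center_x",
                     "radius_y", "radius_x")]
  cells$theta <- nuc$theta
  truth <- structure(list(foci = foci, cells = cells),
                     class = "GroundTruthTable")
  truth <- apply_clustering(truth, cfg$merge_prob, seed = NULL,
                            recount = FALSE)
  foci <- truth$foci

  # APB partners: PML body concentric with (or jittered about) the telomere
  add_partner <- function(anchor_row, role, id) {
    jit <- if (cfg$jitter_sd_px > 0) rnorm(2, 0, cfg$jitter_sd_px) else c(0, 0)
    data.frame(field_id = field_id, cell_id = anchor_row$cell_id,
               channel_role = role, focus_id = id,
               y = anchor_row$y + jit[1], x = anchor_row$x + jit[2],
               true_radius_px = cfg$focus_radius_px,
               linked_focus_ids = format_links(anchor_row$focus_id),
               stringsAsFactors = FALSE)
  }
  tel_idx <- which(foci$channel_role == "telomere")
  is_apb <- if (length(tel_idx))
    rbinom(length(tel_idx), 1, cfg$apb_prob) == 1 else logical(0)
  new_rows <- list()
  for (k in seq_along(tel_idx)) {
    if (!is_apb[k]) next
    i <- tel_idx[k]
    pml_id <- next_id; next_id <- next_id + 1L
    new_rows[[length(new_rows) + 1L]] <- add_partner(foci[i, ], "pml", pml_id)
    links <- c(parse_links(foci$linked_focus_ids[i]), pml_id)
    if (rbinom(1, 1, cfg$edu_at_apb_prob) == 1) {
      edu_id <- next_id; next_id <- next_id + 1L
      new_rows[[length(new_rows) + 1L]] <-
        add_partner(foci[i, ], "edu", edu_id)
      links <- c(links, edu_id)
    }
    foci$linked_focus_ids[i] <- format_links(links)
  }
  if (length(new_rows)) foci <- rbind(foci, do.call(rbind, new_rows))

  # free PML bodies, kept clear of every telomere center
  for (i in seq_len(nrow(nuc))) {
    n_free <- rpois(1, cfg$free_pml_mean)
    if (n_free == 0) next
    tel_pts <- as.matrix(foci[foci$cell_id == nuc$cell_id[i] &
                                foci$channel_role == "telomere",
                              c("y", "x"), drop = FALSE])
    pts <- place_foci_in_nucleus(nuc[i, ], n_free, cfg$min_separation_px,
                                 avoid = tel_pts,
                                 avoid_dist = 4 * cfg$focus_radius_px)
    n_free <- nrow(pts)
    if (n_free == 0) next
    foci <- rbind(foci, data.frame(
      field_id = field_id, cell_id = nuc$cell_id[i], channel_role = "pml",
      focus_id = seq.int(next_id, length.out = n_free),
      y = pts[, 1], x = pts[, 2], true_radius_px = cfg$focus_radius_px,
      linked_focus_ids = "", stringsAsFactors = FALSE))
    next_id <- next_id + n_free
  }

  cells_out <- cells[, c("field_id", "cell_id", "center_y", "center_x",
                         "radius_y", "radius_x")]
  truth <- structure(list(foci = foci, cells = cells_out),
                     class = "GroundTruthTable")
  rc <- truth_recount(truth)
  truth$cells <- merge(truth$cells, rc, by = c("field_id", "cell_id"))
  truth$cells <- truth$cells[order(truth$cells$cell_id), ]
  rownames(truth$cells) <- NULL
  attr(truth, "nucleus_theta") <- nuc$theta
  validate_truth(truth)
  truth
}

#' Merge telomere foci pairwise into nearest neighbours
#'
#' Models telomere clustering: each telomere focus is, independently with
#' probability `merge_prob`, merged into its nearest surviving neighbour in
#' the same cell. The survivor keeps its position and grows so that focus
#' area is conserved (`r^2` additive); links of the merged focus transfer to
#' the survivor. With `n` foci the expected surviving count is approximately
#' `n * (1 - merge_prob * (1 - 1/n))`.
#'
#' @param truth a [ground_truth_table()] containing telomere rows.
#' @param merge_prob merge probability in `[0,1]`.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param recount update the per-cell counts in `truth$cells` (set `FALSE`
#'   only when counts are rebuilt later).
#' @return the modified `GroundTruthTable`.
#' @export
apply_clustering <- function(truth, merge_prob, seed = NULL,
                             recount = TRUE) {
  if (merge_prob < 0 || merge_prob > 1)
    stop("merge_prob must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  if (merge_prob == 0) return(truth)
  foci <- truth$foci
  for (key in unique(paste(foci$field_id, foci$cell_id))) {
    sel <- which(paste(foci$field_id, foci$cell_id) == key &
                   foci$channel_role == "telomere")
    if (length(sel) < 2) next
    flagged <- sel[rbinom(length(sel), 1, merge_prob) == 1]
    alive <- rep(TRUE, nrow(foci))
    for (i in flagged) {
      surv <- sel[alive[sel] & sel != i]
      if (!length(surv) || !alive[i]) next
      d2 <- (foci$y[surv] - foci$y[i])^2 + (foci$x[surv] - foci$x[i])^2
      j <- surv[which.min(d2)]
      foci$true_radius_px[j] <-
        sqrt(foci$true_radius_px[j]^2 + foci$true_radius_px[i]^2)
      merged_links <- union(parse_links(foci$linked_focus_ids[j]),
                            parse_links(foci$linked_focus_ids[i]))
      foci$linked_focus_ids[j] <- format_links(merged_links)
      # repoint partners of the merged focus at the survivor
      for (id in parse_links(foci$linked_focus_ids[i])) {
        k <- which(foci$field_id == foci$field_id[i] & foci$focus_id == id)
        lk <- parse_links(foci$linked_focus_ids[k])
        lk[lk == foci$focus_id[i]] <- foci$focus_id[j]
        foci$linked_focus_ids[k] <- format_links(unique(lk))
      }
      alive[i] <- FALSE
    }
    drop <- sel[!alive[sel]]
    if (length(drop)) foci <- foci[-drop, , drop = FALSE]
  }
  rownames(foci) <- NULL
  truth$foci <- foci
  if (recount) {
    rc <- truth_recount(truth)
    keep <- setdiff(names(truth$cells),
                    c("true_telomere_count", "true_apb_count",
                      "true_edu_telomere_count"))
    truth$cells <- merge(truth$cells[, keep, drop = FALSE], rc,
                         by = c("field_id", "cell_id"))
    truth$cells <- truth$cells[order(truth$cells$cell_id), ]
    rownames(truth$cells) <- NULL
  }
  truth
}

#' Render a synthetic multi-channel field with exact ground truth
#'
#' Draws nuclei and foci per [simulate_truth()], then renders each channel
#' as a 3D stack: foci become Gaussian spots whose lateral scale is the
#' pre-blur focus radius convolved with the PSF
#' (`sigma = sqrt(radius^2 + psf_sigma^2)`), confined to an axial band;
#' DAPI fills the nucleus ellipse. Poisson shot noise is applied to
#' signal + background, followed by additive Gaussian read noise, clipping
#' and quantization to the configured bit depth. Identical `config` and
#' `seed` give bit-identical output.
#'
#' @inheritParams simulate_truth
#' @return `list(field = ImageField, truth = GroundTruthTable)`.
#' @export
simulate_field <- function(config, field_id = "sim", seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  truth <- simulate_truth(cfg, field_id = field_id, seed = NULL)
  ny <- cfg$image_shape_px[1]; nx <- cfg$image_shape_px[2]
  nz <- cfg$n_z
  chans <- cfg$channels
  sigma_xy <- function(r) sqrt(r^2 + cfg$psf_sigma_px^2)

  # z placement: anchors draw a slice in the central band, partners inherit
  foci <- truth$foci
  zc <- numeric(nrow(foci))
  band <- c(1 + 2 * cfg$z_sigma_slices, nz - 2 * cfg$z_sigma_slices)
  anchor <- foci$channel_role == "telomere" | foci$linked_focus_ids == ""
  zc[anchor] <- runif(sum(anchor), band[1], band[2])
  for (i in which(!anchor)) {
    a <- parse_links(foci$linked_focus_ids[i])[1]
    j <- which(foci$focus_id == a)
    zc[i] <- if (length(j)) zc[j[1]] else runif(1, band[1], band[2])
  }

  vox <- array(0, dim = c(length(chans), nz, ny, nx))
  top <- 2^cfg$bit_depth - 1
  for (ci in seq_along(chans)) {
    role <- chans[ci]
    if (role == "dapi") {  # nucleus fill with soft edge and axial taper
      plane <- matrix(0, ny, nx)
      yy <- matrix(seq_len(ny), ny, nx)
      xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
      th_all <- attr(truth, "nucleus_theta")
      for (i in seq_len(nrow(truth$cells))) {
        nc <- truth$cells[i, ]
        th <- if (!is.null(th_all)) th_all[i] else 0
        dy <- yy - nc$center_y; dx <- xx - nc$center_x
        u <- dy * cos(th) + dx * sin(th)
        v <- -dy * sin(th) + dx * cos(th)
        inside <- (u / nc$radius_y)^2 + (v / nc$radius_x)^2 <= 1
        plane[inside] <- cfg$dapi_level
      }
      plane <- as_pixel_matrix(EBImage::gblur(plane, sigma = 1.5))
      zprof <- exp(-((seq_len(nz) - (nz + 1) / 2)^2) / (2 * (nz / 4)^2))
      sig <- dapi_signal_cpp(plane, zprof, cfg$background_level)
    } else {
      rows <- which(foci$channel_role == role)
      spots <- cbind(foci$y[rows], foci$x[rows], zc[rows],
                     sigma_xy(foci$true_radius_px[rows]),
                     rep(cfg$photons_per_peak, length(rows)))
      sig <- render_spots_cpp(nz, ny, nx, cfg$background_level, spots,
                              cfg$z_sigma_slices)
    }
    set_channel_cpp(vox, ci, length(chans),
                    apply_camera_cpp(sig, cfg$read_noise_sd, top))
  }
  field <- image_field(vox, chans, z_spacing_um = cfg$z_spacing_um,
                       xy_pixel_um = cfg$xy_pixel_um,
                       bit_depth = cfg$bit_depth, field_id = field_id,
                       check = FALSE)
  list(field = field, truth = truth)
}

#' Simulate a two-condition experiment, optionally split into units
#'
#' Emits paired condition arms (e.g. control vs treated), each made of
#' `n_units` grouping units ("tumors") of `fields_per_unit` fields. With
#' `unit_logit_sd > 0` every unit draws a logit-normal perturbation of its
#' arm's `apb_prob`, modelling between-unit biological variability. Per-field
#' seeds are derived deterministically from `seed`.
#'
#' @param control,treated [simulation_config()]s for the two arms.
#' @param n_units grouping units per arm (1 = flat cell-level design); a
#'   length-2 vector gives the two arms different unit counts, e.g.
#'   `c(7, 8)` for a 7-vs-8-tumor design.
#' @param fields_per_unit fields simulated per unit.
#' @param out_dir directory to write TIFF fields, truth CSVs and a
#'   `manifest.csv`; `NULL` keeps everything in memory.
#' @param seed base seed.
#' @param unit_logit_sd sd of the per-unit logit-scale APB-rate effect.
#' @param render render voxel data (`FALSE` = ground truth only, fast).
#' @return list with `manifest` (data.frame: condition, unit, field_id,
#'   seed, and file paths when written), `truths` (named list of
#'   `GroundTruthTable`s) and, when `render` and `out_dir` is `NULL`,
#'   `fields` (named list of `ImageField`s).
#' @export
simulate_experiment <- function(control, treated, n_units = 1,
                                fields_per_unit = 2, out_dir = NULL,
                                seed = 1, unit_logit_sd = 0,
                                render = TRUE) {
  if (any(n_units < 1)) stop("n_units must be >= 1")
  n_units <- rep_len(n_units, 2L)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  arms <- list(control = control, treated = treated)
  manifest <- NULL
  truths <- list()
  fields <- list()
  for (ai in seq_along(arms)) {
    arm <- names(arms)[ai]
    cfg0 <- arms[[ai]]
    for (u in seq_len(n_units[ai])) {
      cfg <- cfg0
      if (unit_logit_sd > 0 && cfg0$apb_prob > 0 && cfg0$apb_prob < 1) {
        set.seed(seed + 7919L * (2L * u + ai))
        cfg$apb_prob <- plogis(qlogis(cfg0$apb_prob) +
                                 rnorm(1, 0, unit_logit_sd))
      }
      for (f in seq_len(fields_per_unit)) {
        fid <- sprintf("%s_u%02d_f%02d", arm, u, f)
        fseed <- seed + 104729L * ai + 1009L * u + 131L * f
        if (render) {
          sim <- simulate_field(cfg, field_id = fid, seed = fseed)
          truths[[fid]] <- sim$truth
          tiff_path <- truth_prefix <- NA_character_
          if (!is.null(out_dir)) {
            adir <- file.path(out_dir, arm)
            dir.create(adir, showWarnings = FALSE)
            tiff_path <- file.path(adir, paste0(fid, ".tif"))
            write_field(sim$field, tiff_path)
            truth_prefix <- file.path(adir, fid)
            write_truth(sim$truth, truth_prefix)
          } else {
            fields[[fid]] <- sim$field
          }
        } else {
          truths[[fid]] <- simulate_truth(cfg, field_id = fid, seed = fseed)
          tiff_path <- truth_prefix <- NA_character_
        }
        manifest <- rbind(manifest, data.frame(
          condition = arm, unit = u, field_id = fid, seed = fseed,
          apb_prob = cfg$apb_prob, tiff = tiff_path,
          truth_prefix = truth_prefix, stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  out <- list(manifest = manifest, truths = truths)
  if (length(fields)) out$fields <- fields
  out
}

#' Draw per-cell true counts from the generative count model
#'
#' The count marginal of [simulate_truth()]: telomere count ~ Poisson,
#' clustering removes one focus per merge draw while at least two remain,
#' APBs are Binomial over surviving telomeres, EdU foci Binomial over APBs.
#' Geometry does not enter any of these distributions, so this is the fast
#' path for statistical power studies over many replicates.
#'
#' @param config a [simulation_config()].
#' @param n_cells number of cells to draw (defaults to `config$n_cells`).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return data.frame `true_telomere_count, true_apb_count,
#'   true_edu_telomere_count`, one row per cell.
#' @export
simulate_cell_counts <- function(config, n_cells = config$n_cells,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n0 <- rpois(n_cells, config$telomere_count_mean)
  merged <- pmin(rbinom(n_cells, n0, config$merge_prob), pmax(n0 - 1L, 0L))
  n_tel <- n0 - merged
  n_apb <- rbinom(n_cells, n_tel, config$apb_prob)
  n_edu <- rbinom(n_cells, n_apb, config$edu_at_apb_prob)
  data.frame(true_telomere_count = n_tel, true_apb_count = n_apb,
             true_edu_telomere_count = n_edu)
}

#' Power of the two-level (xenograft) design by simulation
#'
#' Repeats the two-arm, unit-structured design at the true-count level:
#' every unit draws its APB rate (logit-normal around its arm's rate),
#' cells' true APB counts are drawn from the count model, unit means are
#' compared by the unpaired t-test, and the fraction of repetitions with
#' two-sided p below `alpha` is reported.
#'
#' @param control,treated [simulation_config()]s for the two arms.
#' @param n_units_control,n_units_treated units per arm.
#' @param cells_per_unit cells per unit.
#' @param unit_logit_sd between-unit APB-rate variability (logit scale).
#' @param n_reps repetitions.
#' @param alpha significance level.
#' @param seed base seed.
#' @param metric per-cell count column compared.
#' @return list `power`, `p_values`.
#' @export
xenograft_power <- function(control, treated, n_units_control = 7,
                            n_units_treated = 8, cells_per_unit = 200,
                            unit_logit_sd = 0.2, n_reps = 100,
                            alpha = 0.05, seed = 1,
                            metric = "true_apb_count") {
  set.seed(seed)
  pvals <- numeric(n_reps)
  unit_means <- function(cfg, n_units) {
    vapply(seq_len(n_units), function(u) {
      c2 <- cfg
      if (unit_logit_sd > 0 && cfg$apb_prob > 0 && cfg$apb_prob < 1)
        c2$apb_prob <- plogis(qlogis(cfg$apb_prob) +
                                rnorm(1, 0, unit_logit_sd))
      mean(simulate_cell_counts(c2, cells_per_unit)[[metric]])
    }, numeric(1))
  }
  for (r in seq_len(n_reps)) {
    a <- unit_means(control, n_units_control)
    b <- unit_means(treated, n_units_treated)
    pvals[r] <- unpaired_t(a, b)$p_two_sided
  }
  list(power = mean(pvals < alpha), p_values = pvals)
}
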