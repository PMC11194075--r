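#' Phenotype / colocalization parameters
#'
#' @param apb_positive_threshold a cell is APB-positive when its APB count
#'   strictly exceeds this (default 5, i.e. "more than five" events).
#' @param coloc_criterion `"mask_overlap"` (objects sharing at least one
#'   pixel; the primary definition) or `"centroid_distance"`.
#' @param max_centroid_distance_px distance cut used only under
#'   `"centroid_distance"`.
#' @param apb_count_mode `"telomere_anchored"` counts distinct telomere
#'   objects with at least one PML overlap (so APB count can never exceed
#'   the telomere count); `"pairs"` counts every overlapping pair.
#' @return a `PhenotypeParams` list.
#' @export
phenotype_params <- function(apb_positive_threshold = 5,
                             coloc_criterion = c("mask_overlap",
                                                 "centroid_distance"),
                             max_centroid_distance_px = 2,
                             apb_count_mode = c("telomere_anchored",
                                                "pairs")) {
  if (apb_positive_threshold < 0) stop("threshold must be >= 0")
  structure(list(apb_positive_threshold = as.integer(apb_positive_threshold),
                 coloc_criterion = match.arg(coloc_criterion),
                 max_centroid_distance_px = max_centroid_distance_px,
                 apb_count_mode = match.arg(apb_count_mode)),
            class = "PhenotypeParams")
}

#' Object-based colocalization between two channels
#'
#' Under `mask_overlap`, emits one pair per combination of an object in `a`
#' and an object in `b` whose segmented masks share at least one pixel —
#' the operational definition of an APB when `a` is the telomere channel and
#' `b` the PML channel. Under `centroid_distance`, pairs are objects whose
#' centroids lie within `max_centroid_distance_px`.
#'
#' @param a,b [foci_set()]s over the same projection geometry.
#' @param params a [phenotype_params()].
#' @return data.frame `channel_a_label, channel_b_label, overlap_area_px,
#'   centroid_distance_px`, sorted by `(a, b)` label. Under
#'   `centroid_distance`, `overlap_area_px` is reported as 0 when masks do
#'   not intersect.
#' @export
colocalize <- function(a, b, params = phenotype_params()) {
  if (!identical(dim(a$labels), dim(b$labels)))
    stop("foci sets come from different projection geometries")
  empty <- data.frame(channel_a_label = integer(),
                      channel_b_label = integer(),
                      overlap_area_px = integer(),
                      centroid_distance_px = numeric())
  if (!nrow(a$objects) || !nrow(b$objects)) return(empty)
  cda <- function(la, lb) {
    oa <- a$objects[match(la, a$objects$label), ]
    ob <- b$objects[match(lb, b$objects$label), ]
    sqrt((oa$y - ob$y)^2 + (oa$x - ob$x)^2)
  }
  if (params$coloc_criterion == "mask_overlap") {
    both <- a$labels > 0L & b$labels > 0L
    if (!any(both)) return(empty)
    la <- a$labels[both]; lb <- b$labels[both]
    key <- paste(la, lb)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
    out <- data.frame(channel_a_label = as.integer(parts[, 1]),
                      channel_b_label = as.integer(parts[, 2]),
                      overlap_area_px = as.integer(tab))
    out$centroid_distance_px <- cda(out$channel_a_label,
                                    out$channel_b_label)
  } else {
    grid <- expand.grid(channel_a_label = a$objects$label,
                        channel_b_label = b$objects$label)
    grid$centroid_distance_px <- cda(grid$channel_a_label,
                                     grid$channel_b_label)
    grid <- grid[grid$centroid_distance_px <=
                   params$max_centroid_distance_px, , drop = FALSE]
    if (!nrow(grid)) return(empty)
    ov <- mapply(function(la, lb)
      sum(a$labels == la & b$labels == lb),
      grid$channel_a_label, grid$channel_b_label)
    out <- data.frame(channel_a_label = grid$channel_a_label,
                      channel_b_label = grid$channel_b_label,
                      overlap_area_px = as.integer(ov),
                      centroid_distance_px = grid$centroid_distance_px)
  }
  out <- out[order(out$channel_a_label, out$channel_b_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count APBs in one cell
#'
#' An APB event is a distinct telomere object overlapping at least one PML
#' object; a telomere overlapped by two PML bodies counts once (under the
#' default telomere-anchored mode).
#'
#' @param telomere,pml per-cell [foci_set()]s.
#' @param params a [phenotype_params()].
#' @return integer APB count.
#' @export
count_apb <- function(telomere, pml, params = phenotype_params()) {
  pairs <- colocalize(telomere, pml, params)
  if (params$apb_count_mode == "pairs") nrow(pairs)
  else length(unique(pairs$channel_a_label))
}

#' Count telomeres undergoing DNA synthesis (EdU at telomeres)
#'
#' @param telomere,edu per-cell [foci_set()]s.
#' @param params a [phenotype_params()].
#' @return number of distinct telomere objects overlapping an EdU focus.
#' @export
count_edu_telomere <- function(telomere, edu, params = phenotype_params()) {
  pairs <- colocalize(telomere, edu, params)
  length(unique(pairs$channel_a_label))
}

#' Count triple telomere + PML + EdU colocalization events
#'
#' @param telomere,pml,edu per-cell [foci_set()]s.
#' @param params a [phenotype_params()].
#' @return number of distinct telomere objects overlapping at least one PML
#'   object and at least one EdU object.
#' @export
count_triple <- function(telomere, pml, edu, params = phenotype_params()) {
  tp <- unique(colocalize(telomere, pml, params)$channel_a_label)
  te <- unique(colocalize(telomere, edu, params)$channel_a_label)
  length(intersect(tp, te))
}

#' Number of foci in a set
#'
#' Per-cell focus counting for any single channel (telomere numbers, PML
#' body numbers, or native-FISH ssTeloC foci alike).
#'
#' @param foci a [foci_set()].
#' @return integer object count.
#' @export
count_channel_foci <- function(foci) nrow(foci$objects)

#' APB-positive classification of a cell
#'
#' A cell is APB-positive when strictly more than `threshold` telomere +
#' PML colocalization events are observed in it.
#'
#' @param apb_count nonnegative integer.
#' @param threshold classification threshold (default 5).
#' @return logical.
#' @export
classify_apb_positive <- function(apb_count, threshold = 5) {
  if (any(apb_count < 0)) stop("apb_count must be nonnegative")
  apb_count > threshold
}

#' Per-cell phenotypes for one field
#'
#' Assigns each channel's foci to nuclei and computes, for every retained
#' nucleus (cells with zero foci included), the per-cell metrics: telomere
#' count, mean telomere area, PML body count, APB count and APB-positive
#' flag, EdU-at-telomere count and triple-colocalization count. Metrics
#' whose channel is absent are `NA`.
#'
#' @param foci_by_role named list of [foci_set()]s (names are roles;
#'   `telomere` is required for telomere-based metrics).
#' @param nuclei a [nucleus_map()].
#' @param params a [phenotype_params()].
#' @param field_id recorded in the output.
#' @return data.frame, one row per nucleus: `field_id, cell_id,
#'   telomere_count, mean_telomere_area_px, pml_body_count, apb_count,
#'   apb_positive, edu_telomere_count, triple_count`, plus attribute
#'   `"dropped_foci"` (background-focus counts per channel).
#' @export
build_phenotypes <- function(foci_by_role, nuclei,
                             params = phenotype_params(),
                             field_id = "") {
  roles <- names(foci_by_role)
  assigns <- lapply(foci_by_role, assign_foci, nuclei = nuclei)
  dropped <- vapply(assigns, function(a) a$dropped, integer(1))
  cell_sub <- function(role, k) {
    fs <- foci_by_role[[role]]
    keep <- fs$objects$label[assigns[[role]]$assignment == k]
    subset_foci(fs, keep)
  }
  n_cells <- nrow(nuclei$table)
  rows <- vector("list", n_cells)
  for (k in seq_len(n_cells)) {
    tel <- if ("telomere" %in% roles) cell_sub("telomere", k) else NULL
    pml <- if ("pml" %in% roles) cell_sub("pml", k) else NULL
    edu <- if ("edu" %in% roles) cell_sub("edu", k) else NULL
    tel_n <- if (!is.null(tel)) count_channel_foci(tel) else NA_integer_
    tel_area <- if (!is.null(tel) && tel_n > 0)
      mean(tel$objects$area_px) else NA_real_
    pml_n <- if (!is.null(pml)) count_channel_foci(pml) else NA_integer_
    apb <- if (!is.null(tel) && !is.null(pml))
      count_apb(tel, pml, params) else NA_integer_
    edu_n <- if (!is.null(tel) && !is.null(edu))
      count_edu_telomere(tel, edu, params) else NA_integer_
    trip <- if (!is.null(tel) && !is.null(pml) && !is.null(edu))
      count_triple(tel, pml, edu, params) else NA_integer_
    rows[[k]] <- data.frame(
      field_id = field_id, cell_id = k,
      telomere_count = tel_n, mean_telomere_area_px = tel_area,
      pml_body_count = pml_n, apb_count = apb,
      apb_positive = if (is.na(apb)) NA else
        classify_apb_positive(apb, params$apb_positive_threshold),
      edu_telomere_count = edu_n, triple_count = trip,
      stringsAsFactors = FALSE)
  }
  out <- if (n_cells) do.call(rbind, rows) else
    data.frame(field_id = character(), cell_id = integer(),
               telomere_count = integer(),
               mean_telomere_area_px = numeric(),
               pml_body_count = integer(), apb_count = integer(),
               apb_positive = logical(), edu_telomere_count = integer(),
               triple_count = integer())
  attr(out, "dropped_foci") <- dropped
  out
}

# connected components of the bipartite within-radius graph, then an
# optimal assignment (Hungarian) inside each component
match_points <- function(det, tru, radius) {
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(0L)
  d2 <- outer(det[, 1], tru[, 1], "-")^2 + outer(det[, 2], tru[, 2], "-")^2
  adj <- d2 <= radius^2
  parent <- seq_len(nd + nt)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nd)) for (j in which(adj[i, ])) {
    ri <- find(i); rj <- find(nd + j)
    if (ri != rj) parent[rj] <- ri
  }
  roots_d <- vapply(seq_len(nd), find, integer(1))
  roots_t <- vapply(seq_len(nt), function(j) find(nd + j), integer(1))
  matched <- 0L
  for (r in unique(roots_d)) {
    di <- which(roots_d == r); tj <- which(roots_t == r)
    if (!length(tj)) next
    cost <- sqrt(d2[di, tj, drop = FALSE])
    cost[cost > radius] <- 1e6
    if (nrow(cost) > ncol(cost)) cost <- t(cost)
    asg <- hungarian_cpp(cost)
    matched <- matched + sum(cost[cbind(seq_along(asg), asg)] <= radius)
  }
  matched
}

#' Detection precision and recall against ground truth
#'
#' Matches detected centroids to true focus positions one-to-one by optimal
#' assignment (minimum total distance), pairs farther apart than
#' `match_radius_px` remaining unmatched. Precision = matched/detected,
#' recall = matched/true; an undefined ratio (zero denominator) is reported
#' as 0 with `undefined = TRUE`.
#'
#' @param detected a [foci_set()].
#' @param truth a [ground_truth_table()] for the same field.
#' @param match_radius_px matching radius (default 2).
#' @param channel_role truth channel compared against (defaults to the
#'   detected set's role).
#' @return list `precision, recall, f1, n_matched, n_detected, n_true,
#'   undefined`.
#' @export
detection_metrics <- function(detected, truth, match_radius_px = 2,
                              channel_role = detected$channel_role) {
  tru <- truth$foci[truth$foci$channel_role == channel_role, , drop = FALSE]
  det <- as.matrix(detected$objects[, c("y", "x"), drop = FALSE])
  tpts <- as.matrix(tru[, c("y", "x"), drop = FALSE])
  m <- match_points(det, tpts, match_radius_px)
  nd <- nrow(det); nt <- nrow(tpts)
  undefined <- nd == 0 || nt == 0
  precision <- if (nd > 0) m / nd else 0
  recall <- if (nt > 0) m / nt else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = as.integer(m), n_detected = nd, n_true = nt,
       undefined = undefined)
}
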