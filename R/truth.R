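#' Ground-truth table for simulated fields
#'
#' The simulator's record of what is really in a field: one row per rendered
#' focus (`foci`) and one row per nucleus (`cells`). Focus rows carry the
#' sub-pixel true center `(y, x)`, the pre-blur radius, and the ids of
#' cross-channel partner foci (a telomere focus links to the PML body and/or
#' EdU focus placed on it, and vice versa). Cell rows carry the nucleus
#' ellipse geometry and the true per-cell counts, which must always equal the
#' counts recomputable from the focus rows.
#'
#' @param foci data.frame with columns `field_id, cell_id, channel_role,
#'   focus_id, y, x, true_radius_px, linked_focus_ids` (semicolon-separated
#'   ids, `""` if none). `focus_id` is unique within a field across channels.
#' @param cells data.frame with columns `field_id, cell_id, center_y,
#'   center_x, radius_y, radius_x, true_telomere_count, true_apb_count,
#'   true_edu_telomere_count`.
#' @param validate check link integrity and count consistency.
#' @return object of class `GroundTruthTable` (list of the two data frames).
#' @export
ground_truth_table <- function(foci = empty_foci_df(),
                               cells = empty_cells_df(), validate = TRUE) {
  foci <- as.data.frame(foci)
  cells <- as.data.frame(cells)
  obj <- structure(list(foci = foci, cells = cells),
                   class = "GroundTruthTable")
  if (validate) validate_truth(obj)
  obj
}

empty_foci_df <- function() {
  data.frame(field_id = character(), cell_id = integer(),
             channel_role = character(), focus_id = integer(),
             y = numeric(), x = numeric(), true_radius_px = numeric(),
             linked_focus_ids = character(), stringsAsFactors = FALSE)
}

empty_cells_df <- function() {
  data.frame(field_id = character(), cell_id = integer(),
             center_y = numeric(), center_x = numeric(),
             radius_y = numeric(), radius_x = numeric(),
             true_telomere_count = integer(), true_apb_count = integer(),
             true_edu_telomere_count = integer(), stringsAsFactors = FALSE)
}

parse_links <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
}

format_links <- function(ids) {
  if (!length(ids)) "" else paste(ids, collapse = ";")
}

#' Recompute per-cell true counts from focus rows
#'
#' @param truth a [ground_truth_table()].
#' @return data.frame keyed by `(field_id, cell_id)` with
#'   `true_telomere_count`, `true_apb_count`, `true_edu_telomere_count`.
#' @export
truth_recount <- function(truth) {
  foci <- truth$foci
  cells <- truth$cells
  out <- cells[, c("field_id", "cell_id"), drop = FALSE]
  out$true_telomere_count <- rep(0L, nrow(out))
  out$true_apb_count <- rep(0L, nrow(out))
  out$true_edu_telomere_count <- rep(0L, nrow(out))
  if (!nrow(foci)) return(out)
  role_of <- split(foci$channel_role, paste(foci$field_id, foci$focus_id))
  for (i in seq_len(nrow(out))) {
    sel <- foci$field_id == out$field_id[i] & foci$cell_id == out$cell_id[i] &
      foci$channel_role == "telomere"
    tel <- foci[sel, , drop = FALSE]
    out$true_telomere_count[i] <- nrow(tel)
    if (!nrow(tel)) next
    link_roles <- lapply(tel$linked_focus_ids, function(s) {
      ids <- parse_links(s)
      unlist(role_of[paste(out$field_id[i], ids)], use.names = FALSE)
    })
    out$true_apb_count[i] <-
      sum(vapply(link_roles, function(r) "pml" %in% r, logical(1)))
    out$true_edu_telomere_count[i] <-
      sum(vapply(link_roles, function(r) "edu" %in% r, logical(1)))
  }
  out
}

validate_truth <- function(truth) {
  foci <- truth$foci
  cells <- truth$cells
  need_f <- names(empty_foci_df())
  need_c <- names(empty_cells_df())
  if (!all(need_f %in% names(foci))) stop("foci table missing columns")
  if (!all(need_c %in% names(cells))) stop("cells table missing columns")
  if (nrow(foci)) {
    key <- paste(foci$field_id, foci$focus_id)
    if (anyDuplicated(key)) stop("duplicate focus_id within a field")
    idx <- setNames(seq_len(nrow(foci)), key)
    for (i in seq_len(nrow(foci))) {
      for (id in parse_links(foci$linked_focus_ids[i])) {
        j <- idx[paste(foci$field_id[i], id)]
        if (is.na(j))
          stop("dangling linked focus id ", id, " in field ",
               foci$field_id[i])
        if (foci$channel_role[j] == foci$channel_role[i])
          stop("focus link within a single channel (focus ", id, ")")
        if (foci$cell_id[j] != foci$cell_id[i])
          stop("focus link crosses cells (focus ", id, ")")
      }
    }
  }
  rc <- truth_recount(truth)
  m <- merge(cells, rc, by = c("field_id", "cell_id"),
             suffixes = c("", ".rc"))
  for (col in c("true_telomere_count", "true_apb_count",
                "true_edu_telomere_count")) {
    if (any(m[[col]] != m[[paste0(col, ".rc")]]))
      stop("per-cell ", col, " inconsistent with focus rows")
  }
  invisible(truth)
}

#' @export
print.GroundTruthTable <- function(x, ...) {
  cat(sprintf("GroundTruthTable: %d foci in %d cell(s), %d field(s)\n",
              nrow(x$foci), nrow(x$cells),
              length(unique(x$cells$field_id))))
  invisible(x)
}

#' Write / read a ground-truth table as paired CSV files
#'
#' `write_truth()` writes `<prefix>_foci.csv` and `<prefix>_cells.csv`
#' (RFC-4180, header row, UTF-8); `read_truth()` restores the table and
#' re-validates it.
#'
#' @param truth a [ground_truth_table()].
#' @param prefix path prefix for the two CSV files.
#' @return `prefix` (write) or a `GroundTruthTable` (read).
#' @export
write_truth <- function(truth, prefix) {
  validate_truth(truth)
  write.csv(truth$foci, paste0(prefix, "_foci.csv"), row.names = FALSE)
  write.csv(truth$cells, paste0(prefix, "_cells.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  foci <- read.csv(paste0(prefix, "_foci.csv"),
                   colClasses = c(linked_focus_ids = "character",
                                  field_id = "character"))
  cells <- read.csv(paste0(prefix, "_cells.csv"),
                    colClasses = c(field_id = "character"))
  if (!nrow(foci)) foci <- empty_foci_df()
  if (!nrow(cells)) cells <- empty_cells_df()
  foci$linked_focus_ids[is.na(foci$linked_focus_ids)] <- ""
  ground_truth_table(foci, cells)
}
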