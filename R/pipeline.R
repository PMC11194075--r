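#' Run configuration
#'
#' Bundles everything a reproducible simulation-backed run needs: the two
#' arm configurations, the design (units, fields per unit, between-unit
#' variability), detection and phenotype parameters, and the comparison
#' plan. Identical configurations and seeds reproduce every CSV bit for bit.
#'
#' @param control,treated [simulation_config()]s for the two arms.
#' @param n_units grouping units ("tumors") per arm; 1 = flat cell-level
#'   design.
#' @param fields_per_unit fields imaged per unit.
#' @param unit_logit_sd between-unit APB-rate variability (logit scale).
#' @param detection a [detection_params()] applied to every focus channel.
#' @param phenotype a [phenotype_params()].
#' @param comparisons list of `list(metric =, test =, by =)` entries; the
#'   special metric `apb_positive_fraction` is compared at unit level as
#'   the per-unit fraction of APB-positive cells.
#' @param out_dir run directory (created).
#' @param seed base seed for all randomness.
#' @param write_images also write every simulated field as TIFF (slower,
#'   larger runs).
#' @return a `RunConfig` list.
#' @export
run_config <- function(control = simulation_config(),
                       treated = simulation_config(apb_prob = 0.3),
                       n_units = 1, fields_per_unit = 2,
                       unit_logit_sd = 0,
                       detection = detection_params(),
                       phenotype = phenotype_params(),
                       comparisons = list(
                         list(metric = "apb_count", test = "mwu",
                              by = "cell"),
                         list(metric = "telomere_count", test = "mwu",
                              by = "cell")),
                       out_dir = tempfile("apbquant_run_"),
                       seed = 1, write_images = FALSE) {
  structure(as.list(environment()), class = "RunConfig")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Run the full simulate - detect - phenotype - compare pipeline
#'
#' The package's counterpart of an automated quantification macro: simulates
#' every field of the configured two-arm design, runs the detection chain on
#' each focus channel, segments nuclei, builds per-cell phenotypes, scores
#' detection against the ground truth, runs the requested group comparisons,
#' and writes a self-contained run directory (resolved config snapshot,
#' per-field foci CSVs, phenotype CSV, detection CSV, comparisons CSV,
#' scatter plots with the group summary line, and a parameter log).
#'
#' @param config a [run_config()].
#' @param verbose print progress.
#' @return (invisibly) list with `out_dir`, `manifest`, `phenotypes`,
#'   `detection`, `comparisons` (data.frame), `comparison_objects`,
#'   `truth_cells`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "foci"), showWarnings = FALSE)
  yaml::write_yaml(strip_classes(config[setdiff(names(config),
                                                c("out_dir"))]),
                   file.path(out_dir, "config.yml"))
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("apbquant run, seed = %d", config$seed)
  logf("detection: tophat_radius_px = %d, prominence = %s, k = %.3g, %s",
       config$detection$tophat_radius_px,
       if (is.null(config$detection$prominence)) "auto (k * robust noise)"
       else format(config$detection$prominence), config$detection$k,
       sprintf("peak_fraction = %.3g, min_focus_area_px = %d",
               config$detection$peak_fraction,
               config$detection$min_focus_area_px))
  logf("phenotype: APB+ rule apb_count > %d, criterion = %s, mode = %s",
       config$phenotype$apb_positive_threshold,
       config$phenotype$coloc_criterion, config$phenotype$apb_count_mode)

  plan <- simulate_experiment(config$control, config$treated,
                              n_units = config$n_units,
                              fields_per_unit = config$fields_per_unit,
                              out_dir = NULL, seed = config$seed,
                              unit_logit_sd = config$unit_logit_sd,
                              render = FALSE)
  manifest <- plan$manifest
  arms <- list(control = config$control, treated = config$treated)

  phen_all <- list()
  det_all <- list()
  truth_cells <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    cfg <- arms[[row$condition]]
    if ("apb_prob" %in% names(manifest)) cfg$apb_prob <- row$apb_prob
    sim <- simulate_field(cfg, field_id = row$field_id, seed = row$seed)
    if (config$write_images) {
      adir <- file.path(out_dir, "fields", row$condition)
      dir.create(adir, recursive = TRUE, showWarnings = FALSE)
      write_field(sim$field, file.path(adir, paste0(row$field_id, ".tif")))
      write_truth(sim$truth, file.path(adir, row$field_id))
    }
    focus_roles <- intersect(cfg$channels, c("telomere", "pml", "edu"))
    foci <- list()
    for (role in focus_roles) {
      fs <- detect_foci(sim$field, role, config$detection)
      foci[[role]] <- fs
      dm <- detection_metrics(fs, sim$truth, match_radius_px = 2)
      det_all[[length(det_all) + 1L]] <- data.frame(
        field_id = row$field_id, condition = row$condition,
        unit = row$unit, channel = role,
        prominence = attr(fs, "prominence"),
        precision = dm$precision, recall = dm$recall, f1 = dm$f1,
        n_detected = dm$n_detected, n_true = dm$n_true,
        stringsAsFactors = FALSE)
      logf("field %s / %s: prominence %.4g, %d foci, F1 %.4f",
           row$field_id, role, attr(fs, "prominence"), dm$n_detected,
           dm$f1)
    }
    nuclei <- segment_nuclei(max_project(sim$field, "dapi"))
    phen <- build_phenotypes(foci, nuclei, config$phenotype,
                             field_id = row$field_id)
    phen$condition <- row$condition
    phen$unit <- row$unit
    phen_all[[i]] <- phen
    tc <- sim$truth$cells
    tc$condition <- row$condition
    tc$unit <- row$unit
    truth_cells[[i]] <- tc
    obj_out <- do.call(rbind, lapply(foci, function(fs) {
      o <- fs$objects
      if (nrow(o)) o$channel <- fs$channel_role else o$channel <- character(0)
      o
    }))
    write.csv(obj_out, file.path(out_dir, "foci",
                                 paste0(row$field_id, "_foci.csv")),
              row.names = FALSE)
    if (verbose)
      message(sprintf("[%d/%d] %s: %d cells", i, nrow(manifest),
                      row$field_id, nrow(phen)))
  }
  phenotypes <- do.call(rbind, phen_all)
  detection <- do.call(rbind, det_all)
  truth_cells <- do.call(rbind, truth_cells)
  write.csv(phenotypes, file.path(out_dir, "phenotypes.csv"),
            row.names = FALSE)
  write.csv(detection, file.path(out_dir, "detection.csv"),
            row.names = FALSE)
  write.csv(truth_cells, file.path(out_dir, "truth_cells.csv"),
            row.names = FALSE)

  comp_rows <- list()
  comp_objs <- list()
  for (cm in config$comparisons) {
    metric <- cm$metric
    by <- if (is.null(cm$by)) "cell" else cm$by
    test <- if (is.null(cm$test)) "mwu" else cm$test
    gc <- tryCatch({
      if (metric == "apb_positive_fraction") {
        ph <- phenotypes
        ph$apb_positive_num <- as.numeric(ph$apb_positive)
        compare_groups(ph, "apb_positive_num", test = test, by = "unit")
      } else compare_groups(phenotypes, metric, test = test, by = by)
    }, error = function(e) e)
    if (inherits(gc, "error")) {
      logf("comparison %s (%s, by %s) failed: %s", metric, test, by,
           conditionMessage(gc))
      next
    }
    logf("comparison %s (%s, by %s): p = %.4g [%s], branch: %s",
         metric, test, by, gc$p_two_sided, gc$label, gc$branch)
    comp_objs[[metric]] <- gc
    comp_rows[[length(comp_rows) + 1L]] <- data.frame(
      metric = metric, test = gc$test, by = by, statistic = gc$statistic,
      p_two_sided = gc$p_two_sided, label = gc$label,
      n_a = gc$n_a, n_b = gc$n_b, summary_a = gc$summary_a,
      summary_b = gc$summary_b, stringsAsFactors = FALSE)
    if (metric %in% names(phenotypes)) {
      plot_path <- file.path(out_dir, paste0("scatter_", metric, ".png"))
      grDevices::png(plot_path, width = 480, height = 480)
      plot_phenotype_scatter(phenotypes, metric,
                             summary = if (gc$test == "mann_whitney")
                               "median" else "mean",
                             label = gc$label)
      grDevices::dev.off()
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame()
  logf("%d pairwise test(s) performed, no multiple-testing correction",
       length(comp_rows))
  write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)
  invisible(list(out_dir = out_dir, manifest = manifest,
                 phenotypes = phenotypes, detection = detection,
                 comparisons = comparisons,
                 comparison_objects = comp_objs,
                 truth_cells = truth_cells))
}

#' Per-cell scatter plot with group summary lines
#'
#' One jittered dot per cell, grouped by condition, with a red line at the
#' group median (rank-based comparisons) or mean (t-based comparisons).
#'
#' @param phenotypes per-cell phenotype data.frame with a `condition`
#'   column.
#' @param metric column to plot.
#' @param summary `"median"` or `"mean"`.
#' @param label optional significance label drawn above the groups.
#' @return invisibly, the group summary values.
#' @export
plot_phenotype_scatter <- function(phenotypes, metric,
                                   summary = c("median", "mean"),
                                   label = NULL) {
  summary <- match.arg(summary)
  conds <- unique(phenotypes$condition)
  v <- phenotypes[[metric]]
  g <- match(phenotypes$condition, conds)
  keep <- !is.na(v)
  v <- v[keep]; g <- g[keep]
  set.seed(0)  # cosmetic jitter only
  graphics::plot(g + runif(length(g), -0.15, 0.15), v,
                 xlim = c(0.5, length(conds) + 0.5),
                 xaxt = "n", xlab = "", ylab = metric,
                 pch = 16, cex = 0.5, col = "grey30")
  graphics::axis(1, at = seq_along(conds), labels = conds)
  sm <- vapply(seq_along(conds), function(i)
    if (summary == "median") median(v[g == i]) else mean(v[g == i]),
    numeric(1))
  for (i in seq_along(conds))
    graphics::segments(i - 0.25, sm[i], i + 0.25, sm[i],
                       col = "red", lwd = 2)
  if (!is.null(label))
    graphics::mtext(label, side = 3, line = 0.2)
  invisible(sm)
}

#' Validate a simulation-backed run against its ground truth
#'
#' Summarizes detection accuracy per channel and the recovery of the
#' APB-positive cell fraction, and checks both against tolerances.
#'
#' @param run result of [run_pipeline()], or a run directory containing
#'   `detection.csv`, `phenotypes.csv` and `truth_cells.csv`.
#' @param f1_min minimum acceptable mean F1 per channel.
#' @param apb_fraction_tol_pp maximum acceptable absolute difference, in
#'   percentage points, between the pipeline and truth APB-positive
#'   fractions per condition.
#' @param apb_positive_threshold the ">" rule used on true APB counts.
#' @return list with `detection` (per-channel mean precision/recall/F1),
#'   `apb_recovery` (per-condition estimated vs true APB+ fractions, in
#'   percent), and `pass` (logical).
#' @export
validate_run <- function(run, f1_min = 0.95, apb_fraction_tol_pp = 5,
                         apb_positive_threshold = 5) {
  if (is.character(run)) {
    run <- list(
      detection = read.csv(file.path(run, "detection.csv")),
      phenotypes = read.csv(file.path(run, "phenotypes.csv")),
      truth_cells = read.csv(file.path(run, "truth_cells.csv")))
  }
  if (is.null(run$truth_cells)) stop("ground truth missing from run")
  det <- aggregate(cbind(precision, recall, f1) ~ channel,
                   data = run$detection, FUN = mean)
  apb <- NULL
  for (cond in unique(run$phenotypes$condition)) {
    ph <- run$phenotypes[run$phenotypes$condition == cond, ]
    tc <- run$truth_cells[run$truth_cells$condition == cond, ]
    est <- 100 * mean(ph$apb_positive, na.rm = TRUE)
    tru <- 100 * mean(tc$true_apb_count > apb_positive_threshold)
    apb <- rbind(apb, data.frame(condition = cond,
                                 estimated_pct = est, true_pct = tru,
                                 error_pp = est - tru))
  }
  pass <- all(det$f1 >= f1_min) &&
    all(abs(apb$error_pp) <= apb_fraction_tol_pp)
  list(detection = det, apb_recovery = apb, pass = pass)
}
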