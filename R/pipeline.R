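# run-configuration handling and the batch entry points behind the
# command-line wrapper (inst/cli/fragindex.R)

default_run_config <- function() {
  list(
    locus = list(name = "HTT_CAG", repeat_unit = "CAG", flank_bp = 100,
                 window_min_repeat = 70, window_max_repeat = 150),
    threshold_frac = 0.05,
    peaks = list(smooth_window_bp = 0.3, min_height = 20,
                 min_prominence = 10, baseline_window_bp = 20,
                 residual_tol_bp = 1.0),
    stats = list(control = "NTC", alpha = 0.05, seed = 1L, n_mc = 2e5),
    msi = list(min_shift = 1L),
    simulation = NULL
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) && nm != "simulation") {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline run configuration
#'
#' The configuration is a single human-readable YAML file holding the locus
#' definition, the signal-to-noise threshold, peak-calling parameters,
#' statistics options (control label, alpha, seed) and, optionally, a
#' simulation design. Values omitted from the file take package defaults;
#' function arguments of the `run_*` entry points override both
#' (precedence: call > file > defaults).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_input("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop_input("config file must contain a YAML mapping")
    cfg <- merge_config(cfg, user)
  }
  if (!is_number(cfg$threshold_frac) || cfg$threshold_frac < 0 ||
      cfg$threshold_frac >= 1)
    stop_input("config: threshold_frac must lie in [0, 1)")
  if (!is_number(cfg$stats$alpha) || cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1)
    stop_input("config: stats.alpha must lie in (0, 1)")
  # constructing the locus validates its fields
  cfg$locus_obj <- repeat_locus(cfg$locus$name, cfg$locus$repeat_unit,
                                cfg$locus$flank_bp %||% NA_real_,
                                cfg$locus$window_min_repeat,
                                cfg$locus$window_max_repeat)
  class(cfg) <- "run_config"
  cfg
}

config_design <- function(config, seed = NULL) {
  sim <- config$simulation
  if (is.null(sim) || is.null(sim$groups))
    stop_input("config has no simulation design")
  groups <- lapply(sim$groups, function(g) {
    cohort_group(
      label = g$label, n_animals = g$n_animals %||% 6L,
      true_gain = g$true_gain %||% 0, months = g$months %||% 2,
      inherited_repeat = g$inherited_repeat %||% 110L,
      animal_sd = g$animal_sd %||% 1.0,
      expanding_frac = g$expanding_frac %||% 0.6,
      contraction_rate = g$contraction_rate %||% 0,
      n_cells = g$n_cells %||% 1e5,
      stutter = do.call(stutter_params, g$stutter %||% list()),
      render = do.call(render_params, g$render %||% list())
    )
  })
  cohort_design(groups, config$locus_obj,
                seed = seed %||% sim$seed %||% 1L,
                output = sim$output %||% "peaks")
}

#' Simulate a cohort to files
#'
#' Generates the configured synthetic cohort and writes one generic-dialect
#' peak table (or trace file) per animal, a `truth.csv` ground-truth table
#' (`group,animal,true_gain`), and a `manifest.csv` listing every output file
#' with its sample id and group label.
#'
#' @param config A [read_run_config()] result (must contain a simulation
#'   design).
#' @param out_dir Output directory; refused if it already exists unless
#'   `force = TRUE`.
#' @param seed Overrides the design seed.
#' @param force Overwrite an existing `out_dir`.
#' @return Invisibly, the manifest data frame.
#' @export
run_simulate <- function(config, out_dir, seed = NULL, force = FALSE) {
  if (!inherits(config, "run_config")) stop_input("expected a `run_config`")
  if (dir.exists(out_dir) && !force)
    stop_input("output directory exists (use force = TRUE): ", out_dir)
  design <- config_design(config, seed)
  sim <- simulate_cohort(design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(names(sim$samples), function(sid) {
    obj <- sim$samples[[sid]]
    if (inherits(obj, "repeat_peakset")) {
      file <- file.path(out_dir, paste0(sid, ".csv"))
      write_peak_table(peak_table(locus_size_bp(obj$locus, obj$repeats),
                                  obj$heights, sample_id = sid),
                       file, dialect = "generic")
    } else {
      file <- file.path(out_dir, paste0(sid, "_trace.csv"))
      write_trace(obj, file)
    }
    data.frame(file = basename(file), sample_id = sid,
               group = attr(obj, "group"))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth[, c("group", "animal", "true_gain")],
                   file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

read_manifest_groups <- function(paths, manifest_path) {
  if (!is.null(manifest_path) && file.exists(manifest_path)) {
    man <- utils::read.csv(manifest_path, colClasses = "character")
    grp <- man$group[match(basename(paths), man$file)]
    if (!all(is.na(grp))) return(grp)
  }
  # fall back to "<group>_<animal>" file naming
  sub("_[0-9]+$", "", sub("\\.[^.]*$", "", basename(paths)))
}

#' Batch instability indexing of peak-table files
#'
#' Reads each peak table, bins it against the configured locus, and computes
#' per-sample instability indices. Unreadable or unbinnable samples are
#' logged and skipped; the batch aborts only if no sample can be read.
#'
#' @param inputs Paths to peak-table files (generic dialect).
#' @param config A [read_run_config()] result; its locus must have a flank.
#' @param out Optional CSV path for the results table.
#' @param threshold_frac Overrides the configured threshold.
#' @param mode Index variant; see [instability_index()].
#' @param manifest Optional `manifest.csv` path supplying group labels
#'   (defaults to `manifest.csv` next to the first input, else labels are
#'   parsed from `<group>_<animal>` file names).
#' @return The results data frame (one row per indexed sample).
#' @export
run_index <- function(inputs, config, out = NULL, threshold_frac = NULL,
                      mode = "all", manifest = NULL) {
  if (!inherits(config, "run_config")) stop_input("expected a `run_config`")
  if (!length(inputs)) stop_input("no input files given")
  thr <- threshold_frac %||% config$threshold_frac
  locus <- config$locus_obj
  manifest <- manifest %||% file.path(dirname(inputs[1L]), "manifest.csv")
  groups <- read_manifest_groups(inputs, manifest)
  sets <- list()
  grp_kept <- character(0)
  for (i in seq_along(inputs)) {
    rps <- tryCatch({
      tab <- read_peak_table(inputs[i], dialect = "generic")
      bin_to_repeats(tab, locus,
                     residual_tol_bp = config$peaks$residual_tol_bp)
    }, error = function(e) e)
    if (inherits(rps, "error")) {
      warning("skipping ", inputs[i], ": ", conditionMessage(rps),
              call. = FALSE)
      next
    }
    sets[[length(sets) + 1L]] <- rps
    grp_kept <- c(grp_kept, groups[i])
  }
  if (!length(sets)) stop_input("no readable samples among the inputs")
  res <- index_cohort(sets, threshold_frac = thr, mode = mode,
                      groups = grp_kept)
  if (!is.null(out))
    utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Batch microsatellite-instability comparison against a reference
#'
#' @param inputs Paths to sample peak-table files.
#' @param reference Path to the reference sample's peak table.
#' @param config A [read_run_config()] result.
#' @param out Optional CSV path.
#' @param min_shift Overrides the configured minimum unstable shift.
#' @return Data frame of per-sample [msi_compare()] results.
#' @export
run_msi <- function(inputs, reference, config, out = NULL, min_shift = NULL) {
  if (!inherits(config, "run_config")) stop_input("expected a `run_config`")
  if (is.null(reference) || !file.exists(reference))
    stop_input("reference sample not found: ", reference %||% "<missing>")
  if (!length(inputs)) stop_input("no input files given")
  locus <- config$locus_obj
  tol <- config$peaks$residual_tol_bp
  ms <- min_shift %||% config$msi$min_shift
  ref <- bin_to_repeats(read_peak_table(reference, dialect = "generic"),
                        locus, residual_tol_bp = tol)
  rows <- lapply(inputs, function(path) {
    res <- tryCatch({
      rps <- bin_to_repeats(read_peak_table(path, dialect = "generic"),
                            locus, residual_tol_bp = tol)
      msi_compare(rps, ref, threshold_frac = config$threshold_frac,
                  min_shift = ms)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", path, ": ", conditionMessage(res), call. = FALSE)
      return(NULL)
    }
    data.frame(locus = res$locus, sample_id = res$sample_id,
               reference_id = res$reference_id,
               main_allele_shift = res$main_allele_shift,
               index_difference = res$index_difference,
               unstable = res$unstable)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop_input("no readable samples among the inputs")
  res <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Group statistics on an instability results table
#'
#' Runs one-way ANOVA with Dunnett's many-to-one comparisons versus the
#' configured control group on the per-sample indices produced by
#' [run_index()].
#'
#' @param results A results data frame from [run_index()], or a path to its
#'   CSV.
#' @param config A [read_run_config()] result.
#' @param out Optional CSV path for the comparison report.
#' @param control,alpha,seed Override the configured statistics options.
#' @param value_col Which results column to analyse (default the
#'   mode-selected `index`).
#' @return A [dunnett()] `group_comparison`.
#' @export
run_stats <- function(results, config, out = NULL, control = NULL,
                      alpha = NULL, seed = NULL, value_col = "index") {
  if (!inherits(config, "run_config")) stop_input("expected a `run_config`")
  if (is.character(results)) {
    if (!file.exists(results)) stop_input("no such results table: ", results)
    results <- utils::read.csv(results)
  }
  if (!all(c("group", value_col) %in% names(results)))
    stop_input("results table needs 'group' and '", value_col, "' columns")
  results <- results[!is.na(results[[value_col]]) & !is.na(results$group), ]
  groups <- split(results[[value_col]], results$group)
  if (length(groups) < 2L) stop_input("need at least 2 groups for statistics")
  ctrl <- control %||% config$stats$control
  if (!ctrl %in% names(groups))
    stop_input("control group '", ctrl, "' not present in results")
  cmp <- dunnett(groups, control_label = ctrl,
                 alpha = alpha %||% config$stats$alpha,
                 n_mc = config$stats$n_mc,
                 seed = seed %||% config$stats$seed)
  if (!is.null(out)) {
    report <- merge(cmp$summary, cmp$comparisons, by = "group", all.x = TRUE)
    report$control <- ctrl
    report$anova_F <- cmp$anova$F
    report$anova_p <- cmp$anova$p
    utils::write.csv(report, out, row.names = FALSE, quote = FALSE)
  }
  cmp
}
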