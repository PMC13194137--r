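# Batch orchestration: configuration, per-image measurement, cohort
# simulation, and report generation.

.config_defaults <- function() list(
  pixels_per_cm = NULL,       # manual calibration override
  page_width_cm = 21.0,       # A4 portrait page-fit fallback
  strict_calibration = FALSE, # refuse page-fit when TRUE
  min_speck_px = 25,          # speck floor, referenced to 300 dpi
  margin_frac = 0.08,         # annotation-exclusion band per edge
  closing_radius_px = 3,      # pen-gap bridging radius
  alpha = 0.45,               # crown-collapse fraction
  beta = 1.6,                 # root-flare multiple of trunk median
  run_rows = NULL,            # boundary run length; NULL = 1% of height
  smooth_window_rows = NULL,  # profile smoothing; NULL = 2% of height
  seed = 1,
  group_pairs = list(c("depressed-adult", "control"),
                     c("depressed-adolescent", "depressed-adult")),
  metric_vars = c("crown_area_cm2", "trunk_area_cm2", "total_area_cm2"),
  scale_var = "hdrs")

#' Build a pipeline run configuration
#'
#' All thresholds of the measurement pipeline plus the group pairs and
#' variables used by the report stage. Unknown keys are rejected; values
#' are range-checked.
#'
#' @param ... named overrides of the defaults (see Details in the package
#'   vignette for each parameter's meaning and units).
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop_treedraw("config overrides must be named",
                    "treedraw_config_error")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop_treedraw(paste("unknown config keys:",
                          paste(unknown, collapse = ", ")),
                    "treedraw_config_error")
    cfg[names(over)] <- over
  }
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  chk <- function(ok, what)
    if (!ok) stop_treedraw(paste("invalid config:", what),
                           "treedraw_config_error")
  if (!is.null(cfg$pixels_per_cm))
    chk(is_scalar_number(cfg$pixels_per_cm) && cfg$pixels_per_cm > 0,
        "pixels_per_cm must be > 0")
  chk(is_scalar_number(cfg$page_width_cm) && cfg$page_width_cm > 0,
      "page_width_cm must be > 0")
  chk(is_scalar_number(cfg$min_speck_px) && cfg$min_speck_px >= 0,
      "min_speck_px must be >= 0")
  chk(is_scalar_number(cfg$margin_frac) && cfg$margin_frac >= 0 &&
        cfg$margin_frac < 0.5, "margin_frac must be in [0, 0.5)")
  chk(is_scalar_number(cfg$closing_radius_px) && cfg$closing_radius_px >= 0,
      "closing_radius_px must be >= 0")
  chk(is_scalar_number(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is_scalar_number(cfg$beta) && cfg$beta > 1, "beta must exceed 1")
  if (!is.null(cfg$run_rows))
    chk(is_scalar_number(cfg$run_rows) && cfg$run_rows >= 1,
        "run_rows must be >= 1")
  if (!is.null(cfg$smooth_window_rows))
    chk(is_scalar_number(cfg$smooth_window_rows) &&
          cfg$smooth_window_rows >= 1, "smooth_window_rows must be >= 1")
  invisible(cfg)
}

as_run_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (is.list(x)) return(do.call(run_config, x))
  stop_treedraw("config must be a run_config or named list",
                "treedraw_config_error")
}

#' Read a configuration file
#'
#' YAML or JSON file whose keys mirror [run_config()] arguments.
#'
#' @param path config file path (`.yaml`, `.yml` or `.json`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_treedraw(sprintf("config file '%s' not found", path),
                  "treedraw_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_treedraw("config must be YAML or JSON", "treedraw_config_error"))
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

# Provenance record written next to every batch/report output.
.provenance <- function(config, extra = list()) {
  cfg <- unclass(config)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null")
  tf <- tempfile(); writeLines(json, tf)
  c(list(package = "treedraw",
         version = as.character(packageVersion("treedraw")),
         r_version = as.character(getRversion()),
         config = cfg,
         config_md5 = unname(tools::md5sum(tf))),
    extra)
}

#' Measure a single drawing (CLI-style)
#'
#' Thin wrapper over [measure_file()] that returns the metrics as a one-row
#' data frame (2-decimal interface scale) and optionally writes a review
#' overlay and a JSON audit record.
#'
#' @param image_path input image.
#' @param config a [run_config()] or named list.
#' @param overlay_path optional PNG path for the tinted segmentation
#'   overlay.
#' @param audit_path optional JSON path for the stage-parameter audit
#'   record.
#' @return one-row data frame: `id` (file stem), metric columns, `flags`.
#' @export
cmd_measure <- function(image_path, config = run_config(),
                        overlay_path = NULL, audit_path = NULL) {
  config <- as_run_config(config)
  res <- measure_file(image_path, config)
  if (!is.null(overlay_path)) {
    img <- load_image(image_path)
    write_overlay(img, res$segmentation, overlay_path)
  }
  if (!is.null(audit_path)) {
    jsonlite::write_json(res$audit, audit_path, auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  row <- metrics_as_row(res$metrics, digits = 2)
  cbind(data.frame(id = tools::file_path_sans_ext(basename(image_path)),
                   stringsAsFactors = FALSE), row)
}

#' Measure a directory of drawings against a roster
#'
#' Each roster id must map to an image file `<id>.<ext>` in `image_dir`.
#' Per-image failures are logged and the run continues; processing order is
#' deterministic (sorted by id).
#'
#' @param image_dir directory of scans.
#' @param roster_csv roster CSV with at least an `id` column.
#' @param config a [run_config()] or named list.
#' @param out_csv optional path for the joined metrics CSV; a provenance
#'   JSON is written alongside as `<out_csv>.provenance.json`.
#' @return list with `table` (roster joined to metrics, sorted by id),
#'   `failures` (data frame id/message), `n_ok`, `n_failed`.
#' @export
cmd_batch <- function(image_dir, roster_csv, config = run_config(),
                      out_csv = NULL) {
  config <- as_run_config(config)
  if (!dir.exists(image_dir))
    stop_treedraw(sprintf("image directory '%s' not found", image_dir),
                  "treedraw_io_error")
  roster <- read.csv(roster_csv, stringsAsFactors = FALSE)
  if (!"id" %in% names(roster))
    stop_treedraw("roster must have an 'id' column",
                  "treedraw_schema_error")
  files <- list.files(image_dir, full.names = TRUE)
  stems <- tools::file_path_sans_ext(basename(files))
  roster <- roster[order(roster$id), , drop = FALSE]
  match_i <- match(roster$id, stems)
  orphans <- roster$id[is.na(match_i)]
  for (o in orphans)
    warning(sprintf("no image found for roster id '%s'", o), call. = FALSE)
  if (all(is.na(match_i)))
    stop_treedraw("no roster id matches any image file",
                  "treedraw_io_error")
  rows <- list(); fails <- list()
  for (k in which(!is.na(match_i))) {
    id <- roster$id[k]
    path <- files[match_i[k]]
    r <- tryCatch(cmd_measure(path, config),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) {
      fails[[id]] <- data.frame(id = id, message = r,
                                stringsAsFactors = FALSE)
      message(sprintf("[treedraw] %s failed: %s", id, r))
    } else {
      rows[[id]] <- r
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(id = character(0), message = character(0))
  table <- if (is.null(metrics)) roster[0, , drop = FALSE] else
    merge(roster, metrics, by = "id", sort = TRUE)
  rownames(table) <- NULL
  if (!is.null(out_csv)) {
    write.csv(table, out_csv, row.names = FALSE)
    prov <- .provenance(config, list(
      inputs = list(image_dir = image_dir, roster = roster_csv),
      n_ok = nrow(table), n_failed = nrow(failures)))
    jsonlite::write_json(prov, paste0(out_csv, ".provenance.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  list(table = table, failures = failures,
       n_ok = if (is.null(metrics)) 0L else nrow(metrics),
       n_failed = nrow(failures))
}

#' Simulate a cohort from a spec file
#'
#' Reads a YAML/JSON cohort description (keys mirror [cohort_spec()]
#' arguments; group entries under `groups`) and delegates to
#' [generate_cohort()].
#'
#' @param cohort_spec_file YAML/JSON file, or a [cohort_spec()] object.
#' @param out_dir output directory.
#' @param render_images write page images (default `TRUE`).
#' @return invisibly, the [generate_cohort()] result.
#' @export
cmd_simulate <- function(cohort_spec_file, out_dir, render_images = TRUE) {
  spec <- if (inherits(cohort_spec_file, "cohort_spec")) cohort_spec_file
  else {
    ext <- tolower(tools::file_ext(cohort_spec_file))
    raw <- switch(ext,
      yaml = , yml = yaml::read_yaml(cohort_spec_file),
      json = jsonlite::read_json(cohort_spec_file, simplifyVector = TRUE),
      stop_treedraw("cohort spec must be YAML or JSON",
                    "treedraw_config_error"))
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
    raw$groups <- lapply(raw$groups, function(g) {
      names(g)[names(g) %in% c("FALSE", "no")] <- "n"
      g
    })
    do.call(cohort_spec, raw)
  }
  generate_cohort(spec, output_dir = out_dir,
                  render_images = render_images)
}

#' Statistical report from a measured roster
#'
#' Produces the report battery from a metrics CSV (a roster joined to
#' metric columns, as written by [cmd_batch()]): a demographic table,
#' group comparisons for each configured group pair, metric-severity
#' correlations, and a power-analysis appendix. Comparisons are skipped
#' with a notice when a configured group is absent; correlations are
#' skipped when the scale column is missing. No multiple-testing
#' correction is applied (stated in the report header).
#'
#' @param metrics_csv input CSV (or a data frame).
#' @param config a [run_config()] or named list (supplies `group_pairs`,
#'   `metric_vars`, `scale_var`).
#' @param out_dir optional directory; writes `demographics.csv`,
#'   `comparison_<a>_vs_<b>.csv`, `correlations.csv`, `report.txt` and a
#'   provenance JSON.
#' @return list with `demographics`, `comparisons` (named list),
#'   `correlations`, `power`, `notices`.
#' @export
cmd_stats <- function(metrics_csv, config = run_config(), out_dir = NULL) {
  config <- as_run_config(config)
  roster <- if (is.data.frame(metrics_csv)) metrics_csv else
    read.csv(metrics_csv, stringsAsFactors = FALSE)
  if (!"group" %in% names(roster))
    stop_treedraw("metrics table must have a 'group' column",
                  "treedraw_schema_error")
  notices <- character(0)
  demo <- demographics_table(roster)
  metric_vars <- intersect(config$metric_vars, names(roster))
  comparisons <- list()
  for (pair in config$group_pairs) {
    key <- paste(pair, collapse = "_vs_")
    if (!all(pair %in% roster$group)) {
      notices <- c(notices, sprintf(
        "comparison %s skipped: group(s) absent", key))
      next
    }
    vars <- metric_vars
    for (extra in c(config$scale_var, "hama")) {
      if (!extra %in% names(roster)) next
      per_group_n <- vapply(pair, function(g)
        sum(!is.na(roster[[extra]][roster$group == g])), numeric(1))
      if (all(per_group_n >= 2)) vars <- c(vars, extra)
    }
    comparisons[[key]] <- compare_groups(roster, vars, pair[1], pair[2])
  }
  correlations <- NULL
  if (config$scale_var %in% names(roster) && length(metric_vars)) {
    patients <- roster[!is.na(roster[[config$scale_var]]), , drop = FALSE]
    if (nrow(patients) >= 3)
      correlations <- correlate_with_scale(patients, metric_vars,
                                           config$scale_var)
  } else {
    notices <- c(notices,
                 sprintf("correlations skipped: no '%s' column",
                         config$scale_var))
  }
  power <- data.frame(effect_size = 0.5, alpha = 0.05, power = 0.80,
                      n_per_group = required_sample_size(0.5, 0.05, 0.80))
  res <- list(demographics = demo, comparisons = comparisons,
              correlations = correlations, power = power,
              notices = notices)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(demo$counts, file.path(out_dir, "demographics.csv"),
              row.names = FALSE)
    for (key in names(comparisons))
      write.csv(comparisons[[key]],
                file.path(out_dir, paste0("comparison_", key, ".csv")),
                row.names = FALSE)
    if (!is.null(correlations))
      write.csv(correlations, file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
    writeLines(.render_report_text(res), file.path(out_dir, "report.txt"))
    prov <- .provenance(config, list(input = if (is.character(metrics_csv))
      metrics_csv else "<data.frame>"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  res
}

# Human-readable report mirroring the published table layout.
.render_report_text <- function(res) {
  out <- c("Tree drawing morphometry report",
           "(no multiple-testing correction applied)", "")
  out <- c(out, sprintf("Participants: %d", res$demographics$total_n), "")
  fmt_ms <- function(m, s) sprintf("%.2f ± %.2f", round_half_up(m, 2),
                                   round_half_up(s, 2))
  for (key in names(res$comparisons)) {
    cmp <- res$comparisons[[key]]
    out <- c(out, sprintf("Comparison: %s", gsub("_vs_", " vs ", key)))
    for (i in seq_len(nrow(cmp))) {
      r <- cmp[i, ]
      stat_lbl <- if (r$test == "mann-whitney") "U" else "t"
      out <- c(out, sprintf(
        "  %-18s %s vs %s  %s = %.3f  p = %.4g%s  d = %.2f",
        r$variable, fmt_ms(r$mean_1, r$sd_1), fmt_ms(r$mean_2, r$sd_2),
        stat_lbl, r$statistic, r$p, r$stars, r$cohens_d))
    }
    out <- c(out, "")
  }
  if (!is.null(res$correlations)) {
    out <- c(out, "Correlation with severity scale (Spearman):")
    for (i in seq_len(nrow(res$correlations))) {
      r <- res$correlations[i, ]
      out <- c(out, sprintf("  %-18s rho = %.3f  p = %.4g%s  (n = %d)",
                            r$variable, r$rho, r$p, r$stars, r$n))
    }
    out <- c(out, "")
  }
  out <- c(out, sprintf(
    "Power appendix: d = %.1f, alpha = %.2f, power = %.2f -> n = %d/group",
    res$power$effect_size, res$power$alpha, res$power$power,
    res$power$n_per_group))
  if (length(res$notices)) out <- c(out, "", paste("NOTE:", res$notices))
  out <- c(out, "", "Stars: ** p < 0.01, *** p < 0.001")
  out
}
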