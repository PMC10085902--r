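# CSV schemas, pipeline configuration and fixture generation. All files are
# UTF-8 CSV with a header row and "." as decimal separator.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

# report offending rows by data line number (header = line 1)
bad_rows <- function(cond) which(cond) + 1L

#' Read per-field diatom counts
#'
#' Expects columns `field_index` and `count`; rows must be complete, counts
#' non-negative integers. Malformed rows are reported with their line
#' numbers.
#'
#' @param path CSV file path.
#' @return Data frame with `field_index` and integer `count`, ordered by
#'   field index.
#' @export
read_counts_csv <- function(path) {
  df <- read_csv_checked(path, c("field_index", "count"))
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(cnt) | cnt < 0 | cnt != floor(cnt)
  if (any(bad)) {
    stop(sprintf("%s: invalid count on line(s) %s (must be non-negative integers)",
                 path, paste(bad_rows(bad), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(field_index = as.integer(df$field_index), count = as.integer(cnt))
  out[order(out$field_index), , drop = FALSE]
}

#' Read case measurements
#'
#' One row per sample: `case_id`, `sample_kind` (one of `lung`, `liver`,
#' `kidney`, `medium`), `size` (grams for tissues, ml for media), `count`,
#' and optional `flags`. Sizes must be positive numbers and counts
#' non-negative integers; offending rows are reported by line number.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_case_csv <- function(path) {
  df <- read_csv_checked(path, c("case_id", "sample_kind", "size", "count"))
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  kinds <- c("lung", "liver", "kidney", "medium")
  bad_kind <- !df$sample_kind %in% kinds
  if (any(bad_kind)) {
    stop(sprintf("%s: invalid sample_kind on line(s) %s (must be one of %s)",
                 path, paste(bad_rows(bad_kind), collapse = ", "),
                 paste(kinds, collapse = "/")), call. = FALSE)
  }
  size <- suppressWarnings(as.numeric(df$size))
  bad_size <- is.na(size) | size <= 0
  if (any(bad_size)) {
    stop(sprintf("%s: invalid size on line(s) %s (must be positive numbers)",
                 path, paste(bad_rows(bad_size), collapse = ", ")), call. = FALSE)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad_cnt <- is.na(cnt) | cnt < 0 | cnt != floor(cnt)
  if (any(bad_cnt)) {
    stop(sprintf("%s: invalid count on line(s) %s (must be non-negative integers)",
                 path, paste(bad_rows(bad_cnt), collapse = ", ")), call. = FALSE)
  }
  df$size <- size
  df$count <- as.integer(cnt)
  df
}

#' Write an acquisition plan to CSV
#'
#' @param plan An `acquisition_plan`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plan_csv <- function(plan, path) {
  if (!inherits(plan, "acquisition_plan")) stop("`plan` must be an acquisition_plan", call. = FALSE)
  utils::write.csv(plan$fields, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analyse every case in a case table
#'
#' Groups a validated case table (see [read_case_csv()]) by `case_id`,
#' requires exactly one lung and one medium sample per case, treats liver
#' and kidney rows as peripheral screens, and runs [analyze_case()] on each.
#'
#' @param cases Data frame as returned by [read_case_csv()].
#' @return Data frame of case records (one row per case) with peripheral
#'   categories in `liver` / `kidney` columns where present.
#' @export
analyze_case_table <- function(cases) {
  out <- lapply(split(cases, cases$case_id), function(cc) {
    lung <- cc[cc$sample_kind == "lung", , drop = FALSE]
    medium <- cc[cc$sample_kind == "medium", , drop = FALSE]
    if (nrow(lung) != 1L || nrow(medium) != 1L) {
      stop(sprintf("L/D stage: case %s needs exactly one lung and one medium sample",
                   cc$case_id[1L]), call. = FALSE)
    }
    periph <- cc[cc$sample_kind %in% c("liver", "kidney"), , drop = FALSE]
    pc <- if (nrow(periph)) stats::setNames(periph$count, periph$sample_kind) else NULL
    flags <- unique(cc$flags[nzchar(cc$flags)])
    rec <- analyze_case(cc$case_id[1L],
                        lung_count = lung$count, lung_mass_g = lung$size,
                        medium_count = medium$count, medium_volume_ml = medium$size,
                        peripheral_counts = pc, flags = flags)
    row <- as.data.frame(rec)
    for (tis in c("liver", "kidney")) {
      row[[tis]] <- if (!is.null(rec$peripheral) && tis %in% names(rec$peripheral)) {
        as.character(rec$peripheral[[tis]])
      } else NA_character_
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

default_pipeline_config <- function() {
  list(
    membrane = list(diameter_mm = 10, fields_per_diameter = 40),
    process = list(kind = "clustered", intensity = 20,
                   cluster_rate = 0.15, cluster_size_mean = 60, cluster_sd_mm = 0.3),
    experiment = list(n_replicates = 200, seed = 20230304),
    target_pct = 95,
    cases = NULL  # path to a case CSV, or a data frame; NULL -> bundled series
  )
}

#' Run the full diagnostic pipeline
#'
#' Executes the simulation experiment (strategy ladder under the configured
#' deposition process), fits the logarithmic accuracy curve per strategy,
#' solves for the minimum image counts at the target accuracy, and analyses
#' the configured case table. Deterministic under the configured seed; all
#' stage outputs plus a run log (package version, seed, config hash) are
#' written under `out_dir`.
#'
#' @param config Configuration list, or the path to a YAML file holding one;
#'   see `Details`. Omitted entries fall back to defaults: the standard
#'   10 mm / 40-field membrane, a clustered deposition process, 200
#'   replicates, a 95% target, and the bundled reference case series.
#' @param out_dir Output directory (created if needed).
#' @details The configuration mirrors the stage parameters:
#' `membrane` (`diameter_mm`, `fields_per_diameter`), `process` (`kind`,
#' `intensity`, `cluster_rate`, `cluster_size_mean`, `cluster_sd_mm`),
#' `experiment` (`n_replicates`, `seed`), `target_pct`, and `cases` (CSV
#' path or data frame in the [read_case_csv()] schema).
#' @return Invisibly, a list with `experiment` (data frame), `curves`
#'   (per-strategy `accuracy_curve`s), `thresholds` (images needed per
#'   strategy), `case_records` (data frame) and `files` (paths written).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("diatomLD_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$experiment$seed)) stop("config must provide experiment$seed", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  spec <- membrane_spec(cfg$membrane$diameter_mm, cfg$membrane$fields_per_diameter)

  exp_tab <- run_strategy_experiment(
    spec,
    process = cfg$process$kind,
    intensity = cfg$process$intensity,
    cluster_rate = cfg$process$cluster_rate,
    cluster_size_mean = cfg$process$cluster_size_mean,
    cluster_sd_mm = cfg$process$cluster_sd_mm,
    n_replicates = cfg$experiment$n_replicates,
    seed = cfg$experiment$seed
  )

  curves <- lapply(split(exp_tab, exp_tab$strategy), function(d) {
    fit_log_curve(data.frame(n_images = d$n_images,
                             accuracy_pct = d$mean_accuracy_pct),
                  strategy = d$strategy[1L])
  })
  thresholds <- vapply(curves, images_needed, integer(1), target_pct = cfg$target_pct)

  cases <- cfg$cases
  if (is.null(cases)) {
    ref <- reference_cases()
    # concentrations are already per unit size: feed them as unit samples
    cases <- rbind(
      data.frame(case_id = ref$case_id, sample_kind = "lung",
                 size = 1, count = ref$lung_per_gram, flags = ref$flags),
      data.frame(case_id = ref$case_id, sample_kind = "medium",
                 size = 1, count = ref$medium_per_ml, flags = "")
    )
  } else if (is.character(cases)) {
    cases <- read_case_csv(cases)
  }
  case_records <- analyze_case_table(cases)

  files <- c(
    experiment = file.path(out_dir, "experiment.csv"),
    curves = file.path(out_dir, "accuracy_curves.csv"),
    cases = file.path(out_dir, "case_records.csv"),
    log = file.path(out_dir, "run_log.txt")
  )
  utils::write.csv(exp_tab, files[["experiment"]], row.names = FALSE)
  curve_tab <- data.frame(
    strategy = names(curves),
    a = vapply(curves, `[[`, 0, "a"),
    b = vapply(curves, `[[`, 0, "b"),
    images_needed = thresholds,
    target_pct = cfg$target_pct
  )
  utils::write.csv(curve_tab, files[["curves"]], row.names = FALSE)
  utils::write.csv(case_records, files[["cases"]], row.names = FALSE)

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "cases")], cfg_file)
  writeLines(c(
    sprintf("diatomLD %s", as.character(utils::packageVersion("diatomLD"))),
    sprintf("seed: %s", cfg$experiment$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_file))),
    sprintf("stages: experiment (%d replicates), curve fit, thresholds, %d cases",
            cfg$experiment$n_replicates, nrow(case_records))
  ), files[["log"]])

  invisible(list(experiment = exp_tab, curves = curves, thresholds = thresholds,
                 case_records = case_records, files = c(files, config = cfg_file)))
}

#' Generate checked-in style fixtures
#'
#' Writes a small, fully seeded set of inputs exercising every reader: a
#' simulated point pattern, a plan with its per-field counts, a case table
#' that includes the bundled reference series (as unit-size samples) plus
#' one synthetic case, and the control weight/count series. Regeneration
#' with the same seed is byte-identical.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of file paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- membrane_spec()
  pat <- simulate_membrane(spec, "homogeneous", intensity = 2, seed = seed)
  plan <- make_scatter_plan(spec, "eighth")
  fc <- count_fields(pat, plan)

  paths <- c(
    pattern = file.path(dir, "point_pattern.csv"),
    plan = file.path(dir, "plan_scatter_eighth.csv"),
    counts = file.path(dir, "field_counts.csv"),
    cases = file.path(dir, "cases.csv"),
    controls = file.path(dir, "control_counts.csv")
  )
  utils::write.csv(as.data.frame(pat), paths[["pattern"]], row.names = FALSE)
  write_plan_csv(plan, paths[["plan"]])
  utils::write.csv(data.frame(field_index = seq_along(fc$counts), count = fc$counts),
                   paths[["counts"]], row.names = FALSE)

  ref <- reference_cases()
  sc <- simulate_case(400, 100, tissue_masses = 1.0, medium_volumes = 10, seed = seed + 1L)
  cases <- rbind(
    data.frame(case_id = ref$case_id, sample_kind = "lung",
               size = 1, count = ref$lung_per_gram, flags = ref$flags),
    data.frame(case_id = ref$case_id, sample_kind = "medium",
               size = 1, count = ref$medium_per_ml, flags = ""),
    data.frame(case_id = "synthetic_1", sample_kind = "lung",
               size = sc$tissue_samples$mass_g,
               count = sc$tissue_samples$observed_count, flags = "synthetic"),
    data.frame(case_id = "synthetic_1", sample_kind = "medium",
               size = sc$medium_samples$volume_ml,
               count = sc$medium_samples$observed_count, flags = "synthetic")
  )
  utils::write.csv(cases, paths[["cases"]], row.names = FALSE)
  utils::write.csv(control_case_counts(), paths[["controls"]], row.names = FALSE)
  invisible(paths)
}
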