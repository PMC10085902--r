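# L/D diagnostics: per-gram / per-ml concentrations, the L/D ratio and its
# diagnostic classification, replicability statistics, peripheral-tissue
# categories and acid-digestion volume recommendations.

#' Diatom concentration per gram of tissue
#'
#' @param count Diatom count (>= 0).
#' @param mass_g Tissue mass in grams (> 0).
#' @return Diatoms per gram.
#' @examples
#' per_gram(57, 0.5)  # 114
#' @export
per_gram <- function(count, mass_g) {
  if (any(mass_g <= 0)) stop("`mass_g` must be positive", call. = FALSE)
  if (any(count < 0)) stop("`count` must be non-negative", call. = FALSE)
  count / mass_g
}

#' Diatom concentration per ml of drowning medium
#'
#' @param count Diatom count (>= 0).
#' @param volume_ml Medium volume in ml (> 0).
#' @return Diatoms per ml.
#' @export
per_ml <- function(count, volume_ml) {
  if (any(volume_ml <= 0)) stop("`volume_ml` must be positive", call. = FALSE)
  if (any(count < 0)) stop("`count` must be non-negative", call. = FALSE)
  count / volume_ml
}

#' The L/D diagnostic ratio
#'
#' Ratio of the diatom concentration in one gram of lung tissue to the
#' concentration in one ml of the putative drowning medium. Active
#' aspiration during drowning concentrates diatoms in the lung beyond the
#' medium's level (L/D > 1), whereas passive post-mortal infiltration can at
#' most reach equality (L/D <= 1). Reports conventionally round to one
#' decimal; classification always uses the unrounded value.
#'
#' @param lung_per_gram Diatoms per gram of lung tissue (>= 0).
#' @param medium_per_ml Diatoms per ml of drowning medium (> 0; a medium
#'   without measurable diatom content cannot serve as reference).
#' @return The unrounded L/D ratio.
#' @examples
#' round(ld_ratio(3426, 315), 1)  # 10.9
#' @export
ld_ratio <- function(lung_per_gram, medium_per_ml) {
  if (any(medium_per_ml <= 0)) {
    stop("`medium_per_ml` must be positive: the drowning medium is the reference concentration",
         call. = FALSE)
  }
  if (any(lung_per_gram < 0)) stop("`lung_per_gram` must be non-negative", call. = FALSE)
  lung_per_gram / medium_per_ml
}

#' Diagnostic classification of an L/D ratio
#'
#' Classifies the unrounded ratio against the published probability
#' thresholds: ratios above 2 correspond to drowning probabilities of 100%
#' in prior series (`strong_drowning`), ratios above 1 to 96%
#' (`drowning_supportive`), while ratios at or below 1 are compatible with
#' post-mortal immersion and remain inconclusive (`immersion_compatible`).
#' Exactly 1 falls in the immersion-compatible class, since passive
#' infiltration can reach, but not exceed, the medium concentration.
#'
#' @param ld Non-negative L/D ratio(s).
#' @return Factor with ordered levels `immersion_compatible` <
#'   `drowning_supportive` < `strong_drowning`.
#' @examples
#' classify_ld(c(10.9, 1.5, 0.1))
#' @export
classify_ld <- function(ld) {
  if (any(is.na(ld)) || any(ld < 0)) stop("`ld` must be non-negative", call. = FALSE)
  cls <- ifelse(ld > 2, "strong_drowning",
         ifelse(ld > 1, "drowning_supportive", "immersion_compatible"))
  factor(cls, levels = c("immersion_compatible", "drowning_supportive", "strong_drowning"),
         ordered = TRUE)
}

#' Semi-quantitative category for peripheral-tissue diatom counts
#'
#' Liver and kidney samples are screened qualitatively; their counts are
#' reported on the conventional four-step scale: `-` (0 diatoms), `+` (1-4),
#' `++` (5-9), `+++` (10 or more).
#'
#' @param count Non-negative integer count(s).
#' @return Factor with ordered levels `-` < `+` < `++` < `+++`.
#' @examples
#' categorize_peripheral(c(0, 3, 9, 10))
#' @export
categorize_peripheral <- function(count) {
  if (any(is.na(count)) || any(count < 0) || any(count != floor(count))) {
    stop("`count` must consist of non-negative integers", call. = FALSE)
  }
  cls <- cut(count, breaks = c(-0.5, 0.5, 4.5, 9.5, Inf),
             labels = c("-", "+", "++", "+++"), ordered_result = TRUE)
  names(cls) <- names(count)
  cls
}

#' Replicability of per-gram concentrations across tissue masses
#'
#' Checks that diatoms-per-gram values are stable across replicate samples
#' of different weight from the same lung: the spread of the per-gram
#' values (range over mean, as a percentage), the Spearman rank correlation
#' between sample mass and diatom count, and optionally a Kruskal-Wallis
#' test across per-image count groups when the underlying per-field counts
#' are available.
#'
#' @param samples Data frame with columns `mass_g` (> 0) and `diatom_count`
#'   (>= 0); at least two rows.
#' @param per_field_counts Optional list of integer vectors, one per sample,
#'   holding the raw per-image counts behind each total; enables the
#'   Kruskal-Wallis comparison of count distributions across samples.
#' @return A `replicability_report`: `per_gram_values`,
#'   `max_rel_deviation_pct` (100 * (max - min) / mean), `spearman_r`,
#'   `spearman_p`, and `kruskal_p` (`NA` without per-field counts).
#' @examples
#' replicability(data.frame(mass_g = c(0.5, 1.1, 1.5),
#'                          diatom_count = c(57, 108, 155)))
#' @export
replicability <- function(samples, per_field_counts = NULL) {
  if (!is.data.frame(samples) || !all(c("mass_g", "diatom_count") %in% names(samples))) {
    stop("`samples` must be a data frame with columns mass_g and diatom_count", call. = FALSE)
  }
  if (nrow(samples) < 2L) stop("need at least two samples", call. = FALSE)
  pg <- per_gram(samples$diatom_count, samples$mass_g)
  sp <- suppressWarnings(
    stats::cor.test(samples$mass_g, samples$diatom_count, method = "spearman")
  )
  kw_p <- NA_real_
  if (!is.null(per_field_counts)) {
    if (length(per_field_counts) != nrow(samples)) {
      stop("`per_field_counts` must have one element per sample", call. = FALSE)
    }
    grp <- rep(seq_along(per_field_counts), lengths(per_field_counts))
    kw_p <- stats::kruskal.test(unlist(per_field_counts), factor(grp))$p.value
  }
  structure(
    list(
      per_gram_values = pg,
      max_rel_deviation_pct = 100 * (max(pg) - min(pg)) / mean(pg),
      spearman_r = unname(sp$estimate),
      spearman_p = sp$p.value,
      kruskal_p = kw_p
    ),
    class = "replicability_report"
  )
}

#' @export
print.replicability_report <- function(x, ...) {
  cat(sprintf("Per-gram values: %s (max relative deviation %.1f%%)\n",
              paste(sprintf("%.1f", x$per_gram_values), collapse = ", "),
              x$max_rel_deviation_pct))
  cat(sprintf("Spearman mass~count: r = %.3f, p = %.3g; Kruskal-Wallis p = %s\n",
              x$spearman_r, x$spearman_p,
              if (is.na(x$kruskal_p)) "n/a" else format(x$kruskal_p, digits = 3)))
  invisible(x)
}

#' Digestion reagent volume for a tissue sample
#'
#' Recommends the nitric acid / hydrogen peroxide batch (always mixed 4:1)
#' validated for complete tissue dissolution without frustule damage:
#' 5 ml (4 + 1) for samples up to 0.5 g, 10 ml (8 + 2) up to 1.0 g, and
#' 15 ml (12 + 3) above. Oversized reagent volumes on small samples promote
#' diatom disintegration, so a warning is attached when 10 ml or more meets
#' a sample of at most 0.5 g, or 15 ml meets at most 1.0 g. Masses outside
#' the validated range (0, 2] g are rejected with a request to adjust the
#' tissue mass.
#'
#' @param tissue_mass_g Tissue mass in grams, in (0, 2].
#' @param total_volume_ml Optional override of the recommended total volume
#'   (must be 5, 10 or 15); warnings are evaluated on the actual volume.
#' @return A `digestion_recommendation`: `tissue_mass_g`, `total_volume_ml`,
#'   `hno3_ml`, `h2o2_ml`, `warnings` (character vector).
#' @examples
#' recommend_digestion(1.0)  # 10 ml: 8 ml HNO3 + 2 ml H2O2
#' @export
recommend_digestion <- function(tissue_mass_g, total_volume_ml = NULL) {
  if (!is.numeric(tissue_mass_g) || length(tissue_mass_g) != 1L ||
      is.na(tissue_mass_g) || tissue_mass_g <= 0 || tissue_mass_g > 2) {
    stop("tissue mass outside the validated range (0, 2] g: adjust the tissue mass",
         call. = FALSE)
  }
  if (is.null(total_volume_ml)) {
    total_volume_ml <- if (tissue_mass_g <= 0.5) 5 else if (tissue_mass_g <= 1.0) 10 else 15
  } else if (!total_volume_ml %in% c(5, 10, 15)) {
    stop("`total_volume_ml` must be one of the validated batches: 5, 10 or 15 ml", call. = FALSE)
  }
  warnings <- character()
  if (total_volume_ml >= 10 && tissue_mass_g <= 0.5) {
    warnings <- c(warnings, sprintf(
      "%g ml of reagent on a %g g sample risks diatom disintegration",
      total_volume_ml, tissue_mass_g))
  } else if (total_volume_ml == 15 && tissue_mass_g <= 1.0) {
    warnings <- c(warnings, sprintf(
      "15 ml of reagent on a %g g sample risks diatom disintegration", tissue_mass_g))
  }
  structure(
    list(
      tissue_mass_g = tissue_mass_g,
      total_volume_ml = total_volume_ml,
      hno3_ml = total_volume_ml * 4 / 5,
      h2o2_ml = total_volume_ml / 5,
      warnings = warnings
    ),
    class = "digestion_recommendation"
  )
}

#' @export
print.digestion_recommendation <- function(x, ...) {
  cat(sprintf("Digestion for %g g tissue: %g ml total (%g ml HNO3 + %g ml H2O2)\n",
              x$tissue_mass_g, x$total_volume_ml, x$hno3_ml, x$h2o2_ml))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Full diagnostic work-up of one case
#'
#' Composes the quantitative stages into a single case record: per-gram lung
#' concentration, per-ml medium concentration, the L/D ratio, its diagnostic
#' class, semi-quantitative categories for any peripheral tissues, and
#' free-text flags (e.g. a debris-laden drowning medium, which inflates the
#' reference concentration and undermines the ratio's interpretability).
#'
#' @param case_id Case label.
#' @param lung_count,lung_mass_g Diatom count and mass of the lung sample.
#' @param medium_count,medium_volume_ml Diatom count and volume of the
#'   drowning-medium sample.
#' @param peripheral_counts Optional named integer vector (e.g.
#'   `c(liver = 2, kidney = 7)`) of peripheral-tissue counts.
#' @param flags Optional character vector of caveats attached verbatim.
#' @return A `case_record` with `lung_per_gram`, `medium_per_ml`,
#'   `ld_ratio` (unrounded), `ld_ratio_reported` (one decimal),
#'   `diagnostic_class`, `peripheral` and `flags`.
#' @examples
#' analyze_case("case_4", lung_count = 4521, lung_mass_g = 1,
#'              medium_count = 6750, medium_volume_ml = 10)
#' @export
analyze_case <- function(case_id, lung_count, lung_mass_g,
                         medium_count, medium_volume_ml,
                         peripheral_counts = NULL, flags = character()) {
  lpg <- per_gram(lung_count, lung_mass_g)
  mpm <- per_ml(medium_count, medium_volume_ml)
  ld <- ld_ratio(lpg, mpm)
  peripheral <- if (!is.null(peripheral_counts)) categorize_peripheral(peripheral_counts) else NULL
  structure(
    list(
      case_id = as.character(case_id),
      lung_per_gram = lpg,
      medium_per_ml = mpm,
      ld_ratio = ld,
      ld_ratio_reported = round(ld, 1),
      diagnostic_class = classify_ld(ld),
      peripheral = peripheral,
      flags = flags
    ),
    class = "case_record"
  )
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("Case %s: %.0f diatoms/g lung, %.0f diatoms/ml medium, L/D %.1f -> %s\n",
              x$case_id, x$lung_per_gram, x$medium_per_ml,
              x$ld_ratio_reported, as.character(x$diagnostic_class)))
  if (!is.null(x$peripheral)) {
    cat("  peripheral:",
        paste(names(x$peripheral), as.character(x$peripheral), sep = " = ", collapse = ", "), "\n")
  }
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}

#' @export
as.data.frame.case_record <- function(x, ...) {
  data.frame(
    case_id = x$case_id,
    lung_per_gram = x$lung_per_gram,
    medium_per_ml = x$medium_per_ml,
    ld_ratio = x$ld_ratio_reported,
    diagnostic_class = as.character(x$diagnostic_class),
    flags = paste(x$flags, collapse = "; ")
  )
}

#' Bundled reference case series
#'
#' Published per-gram / per-ml concentration pairs for five immersion
#' deaths analysed with this workflow: four cases with classical drowning
#' signs (or, in one, advanced decomposition masking them) and one case
#' whose drowning medium was laden with plant debris, inflating the
#' reference concentration. Useful as a worked example and as the fixture
#' behind the diagnostic-classification checks.
#'
#' @return Data frame with `case_id`, `lung_per_gram`, `medium_per_ml`,
#'   `ld_ratio` (the reported one-decimal value) and `flags`.
#' @export
reference_cases <- function() {
  data.frame(
    case_id = paste0("case_", 1:5),
    lung_per_gram = c(3426, 410, 11928, 4521, 2567),
    medium_per_ml = c(315, 175, 3336, 675, 24148),
    ld_ratio = c(10.9, 2.3, 3.6, 6.7, 0.1),
    flags = c("", "", "", "advanced decomposition",
              "drowning medium contained plenty of debris"),
    stringsAsFactors = FALSE
  )
}

#' Bundled control-case weight/count series
#'
#' Lung tissue samples of three confirmed drownings, each digested at three
#' different masses, with their total diatom counts: the data behind the
#' per-gram replicability check.
#'
#' @return Data frame with `control_case`, `mass_g`, `diatom_count`.
#' @export
control_case_counts <- function() {
  data.frame(
    control_case = rep(c("A", "B", "C"), each = 3L),
    mass_g = c(0.5, 1.1, 1.5, 1.0, 2.0, 3.0, 0.4, 0.9, 1.4),
    diatom_count = c(57L, 108L, 155L, 207L, 444L, 640L, 55L, 108L, 181L)
  )
}
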