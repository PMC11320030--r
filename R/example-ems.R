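#' Worked example: prioritising point-of-care test use cases in ambulance care
#'
#' A complete worked example of the MCDA pipeline, drawn from a stakeholder
#' exercise prioritising candidate use cases for in-vitro point-of-care (POC)
#' testing in UK emergency medical services ahead of a platform trial.
#' Twelve candidate use cases were identified; seven were excluded by the
#' stakeholder panel as meeting deal-breaker (satisfice) levels, and the
#' remainder were scored by a ~14-person panel against four weighted
#' criteria, with weights taken as mean 0-10 importance scores from a
#' 15-respondent expert survey.
#'
#' `ems_poc_usecases()` returns the twelve candidate use cases;
#' `ems_poc_excluded()` the seven panel-named exclusions;
#' `ems_poc_criteria()` the scoring configuration for the five scored use
#' cases (four criteria with survey-derived weights, rating scales and
#' satisfice rules); `ems_poc_printed_matrix()` the published per-cell mean
#' ratings and final scores with option totals, for verification against the
#' engine's own arithmetic; and `ems_poc_device_criteria()` the companion
#' criteria set for prioritising individual POC devices (all with
#' lowest-level satisfice rules; its precision criterion's rule was left
#' undefined by the panel and is stored as no-rule).
#'
#' The scored option set reflects the panel's workshop as conducted: it
#' includes natriuretic-peptide testing in acute heart failure and omits
#' SARS-CoV-2 testing, which differs from a mechanical application of the
#' exclusion list to the candidate list. The scored set is therefore supplied
#' as explicit configuration, not recomputed.
#'
#' @return See each function's description; configurations are
#'   [decision_config()] objects, tables are tibbles.
#' @examples
#' cfg <- ems_poc_criteria()
#' printed <- ems_poc_printed_matrix()
#' m <- score_from_means(cfg, printed$cells[, c("option", "criterion", "mean")])
#' m$ranking
#' @name ems_poc_example
NULL

#' @rdname ems_poc_example
#' @export
ems_poc_usecases <- function() {
  tibble::tibble(
    id = c("lactate_trauma", "sars_cov2_rti", "lactate_sepsis", "troponin_ami",
           "coag_trauma", "bloodgas_copd", "ketones_dka", "ntprobnp_hf",
           "ntprobnp_sepsis", "crp_sepsis", "bhcg_pregnancy", "tbi_biomarkers"),
    label = c(
      "Lactate testing in trauma",
      "SARS-CoV-2 testing in suspected respiratory tract infection",
      "Lactate testing in sepsis",
      "Troponin for acute myocardial infarction",
      "Coagulation testing in trauma",
      "Blood gas testing in COPD",
      "Blood ketone testing to diagnose diabetic ketoacidosis",
      "NT-proBNP to identify heart failure",
      "NT-proBNP to identify sepsis",
      "C-reactive protein (CRP) testing in sepsis",
      "Beta-HCG testing to identify pregnancy",
      "Biomarkers of traumatic brain injury"
    ),
    pre_excluded = FALSE
  )
}

#' @rdname ems_poc_example
#' @export
ems_poc_excluded <- function() {
  c("coag_trauma", "bloodgas_copd", "ntprobnp_hf", "ntprobnp_sepsis",
    "crp_sepsis", "bhcg_pregnancy", "tbi_biomarkers")
}

usecase_rating_scales <- function() {
  list(
    care_pathway = rating_scale(
      0:3, c("No/Very low potential", "Low potential", "Moderate potential",
             "High potential")),
    diagnostic_accuracy = rating_scale(
      0:4, c("Absent", "Very low", "Low", "Moderate", "High")),
    clinical_effectiveness = rating_scale(
      0:4, c("Absent", "Very low", "Low", "Moderate", "High")),
    # published call-volume scale: no level 2; boundaries stored verbatim
    population_size = rating_scale(
      c(0L, 1L, 3L, 4L), c("<1%", "2.9%", "4.9%", ">=5%"))
  )
}

#' @rdname ems_poc_example
#' @export
ems_poc_criteria <- function() {
  sc <- usecase_rating_scales()
  criteria <- list(
    criterion("care_pathway", "Potential to improve the care pathway",
              sc$care_pathway, weight = 7.2,
              weight_summary = importance_summary(7.2, 7, 3, 10, 15)),
    criterion("diagnostic_accuracy",
              "Certainty of evidence for diagnostic accuracy",
              sc$diagnostic_accuracy, weight = 8.8,
              satisfice = satisfice_rule(0:2),
              weight_summary = importance_summary(8.8, 9, 6, 10, 15)),
    criterion("clinical_effectiveness",
              "Certainty of evidence for clinical effectiveness",
              sc$clinical_effectiveness, weight = 7.0,
              satisfice = satisfice_rule(4L),
              weight_summary = importance_summary(7.0, 8, 2, 10, 15)),
    criterion("population_size", "Size of the population affected",
              sc$population_size, weight = 5.9,
              weight_summary = importance_summary(5.9, 6, 2, 9, 15))
  )
  options <- tibble::tibble(
    id = c("troponin_ami", "ntprobnp_ahf", "lactate_sepsis", "lactate_trauma",
           "ketones_dka"),
    label = c("Troponin AMI", "Natriuretic peptides AHF", "Lactate sepsis",
              "Lactate trauma", "Ketones for DKA"),
    pre_excluded = FALSE
  )
  decision_config(criteria, options, rounding_dp = 2L, top_k = 3L)
}

#' @rdname ems_poc_example
#' @export
ems_poc_printed_matrix <- function() {
  opts <- c("troponin_ami", "ntprobnp_ahf", "lactate_sepsis", "lactate_trauma",
            "ketones_dka")
  cells <- tibble::tibble(
    option = rep(opts, times = 4),
    criterion = rep(c("care_pathway", "diagnostic_accuracy",
                      "clinical_effectiveness", "population_size"), each = 5),
    mean = c(2.85, 2.42, 2.54, 2.15, 2.54,
             3.33, 2.15, 3.08, 2.62, 1.69,
             3.17, 0.42, 2.15, 1.62, 1.77,
             0, 0, 1, 1, 0),
    final = c(27.32, 23.19, 24.36, 20.67, 24.36,
              29.33, 18.95, 27.08, 23.02, 14.89,
              22.17, 2.92, 15.08, 11.31, 12.38,
              0.00, 0.00, 5.90, 5.90, 0.00)
  )
  totals <- c(troponin_ami = 78.82, ntprobnp_ahf = 45.06,
              lactate_sepsis = 72.42, lactate_trauma = 60.89,
              ketones_dka = 51.64)
  list(cells = cells, totals = totals)
}

#' @rdname ems_poc_example
#' @export
ems_poc_device_criteria <- function() {
  # generic 0-3 suitability scale; the exercise's device rating systems were
  # agreed only at the level of their deal-breaker (level 0) rules
  suit <- rating_scale(0:3, c("Unsuitable", "Low suitability",
                              "Moderate suitability", "High suitability"))
  zero <- satisfice_rule(0L)
  mk <- function(id, desc, w, med, lo, hi, sat = zero) {
    criterion(id, desc, suit, weight = w, satisfice = sat,
              weight_summary = importance_summary(w, med, lo, hi, 15))
  }
  criteria <- list(
    mk("power_supply", "Suitability of the power supply for prehospital use",
       8, 8, 5, 10),
    mk("device_size", "Suitability of the size of the device for prehospital use",
       7, 8, 5, 10),
    mk("device_weight", "Suitability of the weight of the device for prehospital use",
       6, 7, 0, 8),
    mk("turnaround_time", "Suitability of the turnaround time for prehospital use",
       8, 8, 5, 9),
    mk("risk", "Risk of the POC test", 8, 8, 5, 9),
    mk("sustainability", "Sustainability of the manufacturing process",
       5, 5, 1, 8),
    mk("integration", "Integration with ambulance systems", 7, 6, 1, 10),
    mk("precision", "Precision (reproducibility and reliability) of the test method",
       9, 9, 7, 10, sat = satisfice_rule())  # rule left undefined by the panel
  )
  decision_config(criteria, options = tibble::tibble(id = character(0),
                                                     label = character(0),
                                                     pre_excluded = logical(0)),
                  rounding_dp = 2L, top_k = 3L)
}
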