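#' Ordinal rating scale
#'
#' A rating scale is an ordered set of integer codes with text labels, e.g.
#' 0 = "Absent", 1 = "Very low", ..., 4 = "High". Codes must be strictly
#' increasing but need not be consecutive: published scales sometimes skip a
#' level (a call-volume scale with codes 0, 1, 3, 4, say), and the scale is
#' stored verbatim rather than reinterpreted.
#'
#' @param codes integer vector of category codes, strictly increasing,
#'   length >= 2.
#' @param labels character vector of category labels, same length as `codes`.
#' @return An object of class `rating_scale` with elements `codes`, `labels`,
#'   `min_code`, `max_code`.
#' @examples
#' rating_scale(0:3, c("No/Very low potential", "Low potential",
#'                     "Moderate potential", "High potential"))
#' @export
rating_scale <- function(codes, labels = as.character(codes)) {
  codes <- as.integer(codes)
  if (length(codes) < 2L) {
    stop_pocmcda("a rating scale needs at least 2 levels")
  }
  if (anyNA(codes) || any(diff(codes) <= 0L)) {
    stop_pocmcda("rating scale codes must be strictly increasing integers")
  }
  if (length(labels) != length(codes)) {
    stop_pocmcda("labels must match codes in length")
  }
  structure(
    list(codes = codes, labels = as.character(labels),
         min_code = codes[[1L]], max_code = codes[[length(codes)]]),
    class = "rating_scale"
  )
}

#' @export
print.rating_scale <- function(x, ...) {
  cat("<rating_scale> ", paste0(x$codes, " = ", x$labels, collapse = "; "),
      "\n", sep = "")
  invisible(x)
}

#' Satisfice ("deal-breaker") rule
#'
#' A satisfice rule names the rating levels whose attainment disqualifies an
#' option from further consideration. The excluded codes are interpreted as a
#' contiguous tail of the scale (its worst or best end) and reduced to a
#' threshold on the panel's mean rating; see [classify_satisfice()].
#'
#' @param excluded_codes integer vector of scale codes that trigger exclusion;
#'   empty (the default) means the criterion has no deal-breaker level.
#' @return An object of class `satisfice_rule`.
#' @examples
#' satisfice_rule(c(0, 1, 2)) # low tail: mean <= 2 disqualifies
#' satisfice_rule(4)          # high tail: mean >= 4 disqualifies
#' satisfice_rule()           # no rule
#' @export
satisfice_rule <- function(excluded_codes = integer()) {
  excluded_codes <- sort(unique(as.integer(excluded_codes)))
  if (anyNA(excluded_codes)) stop_pocmcda("satisfice codes must be integers")
  structure(list(excluded_codes = excluded_codes), class = "satisfice_rule")
}

#' @export
print.satisfice_rule <- function(x, ...) {
  if (length(x$excluded_codes) == 0L) {
    cat("<satisfice_rule> none\n")
  } else {
    cat("<satisfice_rule> excluded codes:",
        paste(x$excluded_codes, collapse = ","), "\n")
  }
  invisible(x)
}

#' Classify a satisfice rule as a tail of the scale
#'
#' Reduces a set of excluded codes to a tail direction and a threshold:
#' a set containing the scale minimum but not the maximum is a *low* tail with
#' threshold `max(set)` (mean ratings at or below it disqualify); a set
#' containing the maximum but not the minimum is a *high* tail with threshold
#' `min(set)`; an empty set is no rule. Any other set — non-contiguous within
#' the scale, touching both ends, or an interior block — has no tail reading
#' and is rejected so the configuration can be rewritten explicitly.
#'
#' @param rule a [satisfice_rule()].
#' @param scale the criterion's [rating_scale()].
#' @return A list with `tail` (`"low"`, `"high"` or `"none"`) and `threshold`
#'   (integer code, `NA` when `tail = "none"`).
#' @examples
#' sc <- rating_scale(0:4)
#' classify_satisfice(satisfice_rule(0:2), sc) # low tail, threshold 2
#' classify_satisfice(satisfice_rule(4), sc)   # high tail, threshold 4
#' @export
classify_satisfice <- function(rule, scale) {
  stopifnot(inherits(rule, "satisfice_rule"), inherits(scale, "rating_scale"))
  set <- rule$excluded_codes
  if (length(set) == 0L) {
    return(list(tail = "none", threshold = NA_integer_))
  }
  if (!all(set %in% scale$codes)) {
    stop_pocmcda("satisfice codes ", paste(setdiff(set, scale$codes), collapse = ","),
                 " are not levels of the rating scale")
  }
  idx <- match(set, scale$codes)
  contiguous <- all(diff(sort(idx)) == 1L)
  has_min <- scale$min_code %in% set
  has_max <- scale$max_code %in% set
  if (!contiguous || (has_min && has_max) || (!has_min && !has_max)) {
    stop_pocmcda("ambiguous satisfice tail: codes {",
                 paste(set, collapse = ","),
                 "} do not form a single tail of the scale")
  }
  if (has_min) {
    list(tail = "low", threshold = max(set))
  } else {
    list(tail = "high", threshold = min(set))
  }
}

#' Importance-score summary for a criterion
#'
#' Summary statistics of stakeholders' 0-10 importance scores for one
#' criterion, as elicited by an importance survey. The mean becomes the
#' criterion weight; median, minimum and maximum are reported for transparency.
#'
#' @param mean,median numeric summary statistics.
#' @param minimum,maximum integer extremes of the observed scores.
#' @param n_respondents number of stakeholders who scored the criterion.
#' @return An object of class `importance_summary`.
#' @export
importance_summary <- function(mean, median, minimum, maximum, n_respondents) {
  if (!is_count(n_respondents) || n_respondents < 1) {
    stop_pocmcda("n_respondents must be a positive integer")
  }
  if (minimum > maximum || mean < minimum || mean > maximum ||
      median < minimum || median > maximum) {
    stop_pocmcda("importance summary must satisfy min <= mean, median <= max")
  }
  structure(
    list(mean = as.numeric(mean), median = as.numeric(median),
         minimum = as.integer(minimum), maximum = as.integer(maximum),
         n_respondents = as.integer(n_respondents)),
    class = "importance_summary"
  )
}

#' Scoring criterion
#'
#' A criterion couples a rating scale with an importance weight and an
#' optional satisfice rule. Weights are used exactly as elicited (typically
#' mean 0-10 importance scores) and are deliberately *not* normalised to sum
#' to one: the weighted-sum totals are on the elicitation scale.
#'
#' @param id short unique identifier.
#' @param description human-readable description.
#' @param scale a [rating_scale()].
#' @param weight non-negative finite weight; `NA` until assigned from an
#'   importance survey via [assign_weights()].
#' @param satisfice a [satisfice_rule()]; default no rule.
#' @param weight_summary optional [importance_summary()] backing the weight.
#' @return An object of class `criterion`.
#' @export
criterion <- function(id, description = id, scale, weight = NA_real_,
                      satisfice = satisfice_rule(), weight_summary = NULL) {
  stopifnot(is_string(id), inherits(scale, "rating_scale"),
            inherits(satisfice, "satisfice_rule"))
  structure(
    list(id = id, description = description, scale = scale,
         weight = as.numeric(weight), satisfice = satisfice,
         weight_summary = weight_summary),
    class = "criterion"
  )
}

#' Decision configuration
#'
#' Bundles the criteria, the candidate options, and display/selection settings
#' for one MCDA exercise. Two independent criteria sets (for instance one for
#' clinical use cases and one for the devices serving them) are simply two
#' configurations of the same type.
#'
#' @param criteria list of [criterion()] objects (order is the report order).
#' @param options data frame with columns `id`, `label` and optionally
#'   `pre_excluded` (logical; options removed before scoring by an explicit
#'   panel decision). A character vector of ids is also accepted.
#' @param rounding_dp display precision in decimal places (default 2).
#' @param top_k how many top-ranked options to select (default 3).
#' @return An object of class `decision_config`.
#' @seealso [validate_config()], [read_decision_config()]
#' @export
decision_config <- function(criteria, options, rounding_dp = 2L, top_k = 3L) {
  if (inherits(criteria, "criterion")) criteria <- list(criteria)
  if (is.character(options)) options <- tibble::tibble(id = options)
  options <- tibble::as_tibble(options)
  if (!"label" %in% names(options)) options$label <- options$id
  if (!"pre_excluded" %in% names(options)) options$pre_excluded <- FALSE
  structure(
    list(criteria = criteria,
         options = options[, c("id", "label", "pre_excluded")],
         rounding_dp = as.integer(rounding_dp), top_k = as.integer(top_k)),
    class = "decision_config"
  )
}

#' @export
print.decision_config <- function(x, ...) {
  cat("<decision_config> ", length(x$criteria), " criteria x ",
      nrow(x$options), " options (top_k = ", x$top_k, ")\n", sep = "")
  for (cr in x$criteria) {
    sat <- if (length(cr$satisfice$excluded_codes)) {
      paste0(" [satisfice ", paste(cr$satisfice$excluded_codes, collapse = ","), "]")
    } else ""
    cat("  ", format(cr$id, width = 20), " weight ",
        formatC(cr$weight, format = "fg"), sat, "\n", sep = "")
  }
  invisible(x)
}

criterion_ids <- function(cfg) vapply(cfg$criteria, `[[`, character(1), "id")

get_criterion <- function(cfg, id) {
  i <- match(id, criterion_ids(cfg))
  if (is.na(i)) stop_pocmcda("unknown criterion '", id, "'")
  cfg$criteria[[i]]
}

#' Validate a decision configuration
#'
#' Checks every structural invariant of a [decision_config()] and returns one
#' diagnostic message per violation, naming the offending field. An empty
#' character vector means the configuration is valid. Diagnostics, not errors:
#' a configuration assembled from a file is checked in one pass so all
#' problems surface together.
#'
#' @param cfg a [decision_config()].
#' @return Character vector of diagnostics (length 0 if valid).
#' @export
validate_config <- function(cfg) {
  diags <- character()
  note <- function(msg) diags <<- c(diags, msg)
  if (!inherits(cfg, "decision_config")) {
    return("not a decision_config object")
  }
  if (length(cfg$criteria) < 1L) note("criteria: at least one criterion required")
  if (nrow(cfg$options) < 1L) note("options: at least one option required")
  ids <- criterion_ids(cfg)
  if (anyDuplicated(ids)) {
    note(paste0("criteria: duplicate ids: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(cfg$options$id)) {
    note(paste0("options: duplicate ids: ",
                paste(unique(cfg$options$id[duplicated(cfg$options$id)]),
                      collapse = ", ")))
  }
  for (cr in cfg$criteria) {
    if (!is.na(cr$weight) && (!is.finite(cr$weight) || cr$weight < 0)) {
      note(paste0("criterion '", cr$id, "': weight must be finite and >= 0"))
    }
    bad <- setdiff(cr$satisfice$excluded_codes, cr$scale$codes)
    if (length(bad)) {
      note(paste0("criterion '", cr$id, "': satisfice codes ",
                  paste(bad, collapse = ","), " outside the rating scale"))
    } else if (length(cr$satisfice$excluded_codes)) {
      ok <- tryCatch({classify_satisfice(cr$satisfice, cr$scale); TRUE},
                     error = function(e) FALSE)
      if (!ok) note(paste0("criterion '", cr$id,
                           "': satisfice codes are not a single tail of the scale"))
    }
    ws <- cr$weight_summary
    if (!is.null(ws) && !inherits(ws, "importance_summary")) {
      note(paste0("criterion '", cr$id, "': weight_summary is not an importance_summary"))
    }
  }
  if (cfg$rounding_dp < 0) note("rounding_dp: must be >= 0")
  if (cfg$top_k < 1) note("top_k: must be >= 1")
  diags
}
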