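#' Read an importance-survey table
#'
#' Reads long-format importance responses: one row per (stakeholder,
#' criterion) with an integer score on the importance scale (0-10 by
#' default). Duplicate (stakeholder, criterion) rows and out-of-range scores
#' are rejected with their row numbers.
#'
#' @param path CSV file (UTF-8, header) with columns `stakeholder`,
#'   `criterion`, `score`.
#' @param scale_min,scale_max inclusive bounds of the importance scale
#'   (default the 11-point 0-10 scale).
#' @return A tibble with columns `stakeholder`, `criterion`, `score`.
#' @export
read_importance <- function(path, scale_min = 0L, scale_max = 10L) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if ("score" %in% names(tab)) tab$score <- as.numeric(tab$score)
  validate_importance(tab, scale_min = scale_min, scale_max = scale_max)
}

#' Validate importance responses
#'
#' @param responses data frame with columns `stakeholder`, `criterion`,
#'   `score`.
#' @inheritParams read_importance
#' @return The validated responses as a tibble.
#' @export
validate_importance <- function(responses, scale_min = 0L, scale_max = 10L) {
  tab <- tibble::as_tibble(responses)
  need <- c("stakeholder", "criterion", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_pocmcda("importance table: missing column(s) ",
                 paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(tab$score) | tab$score < scale_min |
                 tab$score > scale_max | tab$score != floor(tab$score))
  if (length(bad)) {
    stop_pocmcda("importance table: score outside ", scale_min, "-", scale_max,
                 " integer scale at row(s) ", paste(bad, collapse = ", "))
  }
  dup <- which(duplicated(tab[, c("stakeholder", "criterion")]))
  if (length(dup)) {
    stop_pocmcda("importance table: duplicate (stakeholder, criterion) at row(s) ",
                 paste(dup, collapse = ", "))
  }
  tab
}

#' Summarise importance scores for one criterion
#'
#' Mean, median, minimum, maximum and respondent count over the responses
#' present for the criterion. Respondents who skipped the criterion are simply
#' absent; the mean is over those who answered. The median uses the midpoint
#' convention for even n.
#'
#' @param responses importance responses (see [read_importance()]).
#' @param criterion criterion id.
#' @return An [importance_summary()].
#' @examples
#' resp <- tibble::tibble(stakeholder = paste0("s", 1:4),
#'                        criterion = "acc", score = c(6, 9, 10, 10))
#' summarize_importance(resp, "acc") # mean 8.75, median 9.5
#' @export
summarize_importance <- function(responses, criterion) {
  scores <- responses$score[responses$criterion == criterion]
  if (length(scores) == 0L) {
    stop_pocmcda("no responses for criterion '", criterion, "'")
  }
  importance_summary(
    mean = mean(scores),
    median = stats::median(scores),
    minimum = min(scores),
    maximum = max(scores),
    n_respondents = length(scores)
  )
}

#' Assign survey-derived weights to the criteria of a configuration
#'
#' Sets each criterion's weight to the arithmetic mean of its importance
#' scores, kept at full precision (rounding is display-only). The full
#' summary (mean, median, min, max, n) is attached as the criterion's
#' `weight_summary`.
#'
#' @param cfg a [decision_config()].
#' @param responses importance responses covering every criterion in `cfg`,
#'   or a named list of [importance_summary()] objects keyed by criterion id.
#' @return `cfg` with weights and weight summaries filled in.
#' @export
assign_weights <- function(cfg, responses) {
  ids <- criterion_ids(cfg)
  summaries <- if (is.data.frame(responses)) {
    stats::setNames(lapply(ids, function(id) {
      if (!any(responses$criterion == id)) {
        stop_pocmcda("no importance responses for criterion '", id, "'")
      }
      summarize_importance(responses, id)
    }), ids)
  } else {
    responses
  }
  miss <- setdiff(ids, names(summaries))
  if (length(miss)) {
    stop_pocmcda("missing importance summary for criterion '",
                 paste(miss, collapse = "', '"), "'")
  }
  cfg$criteria <- lapply(cfg$criteria, function(cr) {
    s <- summaries[[cr$id]]
    cr$weight <- s$mean
    cr$weight_summary <- s
    cr
  })
  cfg
}

#' Tabulate criterion weights and their survey summaries
#'
#' @param cfg a [decision_config()] whose criteria carry weights (and
#'   optionally weight summaries).
#' @return A tibble with one row per criterion: `criterion`, `weight`,
#'   `mean`, `median`, `minimum`, `maximum`, `n_respondents`, `satisfice`.
#' @export
weight_table <- function(cfg) {
  purrr::map_dfr(cfg$criteria, function(cr) {
    ws <- cr$weight_summary
    tibble::tibble(
      criterion = cr$id,
      weight = cr$weight,
      mean = if (is.null(ws)) NA_real_ else ws$mean,
      median = if (is.null(ws)) NA_real_ else ws$median,
      minimum = if (is.null(ws)) NA_integer_ else ws$minimum,
      maximum = if (is.null(ws)) NA_integer_ else ws$maximum,
      n_respondents = if (is.null(ws)) NA_integer_ else ws$n_respondents,
      satisfice = paste(cr$satisfice$excluded_codes, collapse = ",")
    )
  })
}
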