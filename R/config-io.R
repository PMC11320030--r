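#' Read a decision configuration from a YAML file
#'
#' The configuration format is a UTF-8 YAML document:
#'
#' ```yaml
#' rounding_dp: 2
#' top_k: 3
#' criteria:
#'   - id: diagnostic_accuracy
#'     description: Certainty of evidence for diagnostic accuracy
#'     weight: 8.8
#'     scale:
#'       - {code: 0, label: Absent}
#'       - {code: 1, label: Very low}
#'       - {code: 2, label: Low}
#'       - {code: 3, label: Moderate}
#'       - {code: 4, label: High}
#'     satisfice: [0, 1, 2]
#' options:
#'   - {id: troponin_ami, label: Troponin for acute myocardial infarction}
#'   - {id: coag_trauma, label: Coagulation testing in trauma, pre_excluded: true}
#' exclude: [coag_trauma]
#' ```
#'
#' `weight`, `satisfice`, `pre_excluded` and `exclude` are optional. An
#' optional `weight_summary` mapping (`mean`, `median`, `minimum`, `maximum`,
#' `n_respondents`) records the survey statistics behind a weight.
#'
#' @param path path to the YAML file.
#' @return A validated [decision_config()]; the optional top-level `exclude`
#'   list is attached as attribute `"exclude"`.
#' @seealso [write_decision_config()] for the inverse; the two round-trip.
#' @export
read_decision_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$criteria)) stop_pocmcda("config: missing 'criteria'")
  if (is.null(raw$options)) stop_pocmcda("config: missing 'options'")
  criteria <- lapply(raw$criteria, function(cr) {
    if (is.null(cr$id)) stop_pocmcda("config: criterion without an 'id'")
    if (is.null(cr$scale)) {
      stop_pocmcda("config: criterion '", cr$id, "' has no 'scale'")
    }
    codes <- vapply(cr$scale, function(l) as.integer(l$code), integer(1))
    labels <- vapply(cr$scale, function(l) as.character(l$label %||% l$code),
                     character(1))
    ws <- cr$weight_summary
    if (!is.null(ws)) {
      ws <- importance_summary(ws$mean, ws$median, ws$minimum, ws$maximum,
                               ws$n_respondents)
    }
    criterion(
      id = cr$id,
      description = cr$description %||% cr$id,
      scale = rating_scale(codes, labels),
      weight = as.numeric(cr$weight %||% NA_real_),
      satisfice = satisfice_rule(unlist(cr$satisfice) %||% integer()),
      weight_summary = ws
    )
  })
  options <- tibble::tibble(
    id = vapply(raw$options, function(o) as.character(o$id), character(1)),
    label = vapply(raw$options, function(o) as.character(o$label %||% o$id),
                   character(1)),
    pre_excluded = vapply(raw$options, function(o)
      isTRUE(o$pre_excluded), logical(1))
  )
  cfg <- decision_config(criteria, options,
                         rounding_dp = raw$rounding_dp %||% 2L,
                         top_k = raw$top_k %||% 3L)
  diags <- validate_config(cfg)
  if (length(diags)) {
    stop_pocmcda("invalid configuration:\n  ", paste(diags, collapse = "\n  "))
  }
  attr(cfg, "exclude") <- as.character(unlist(raw$exclude) %||% character())
  cfg
}

#' Write a decision configuration to a YAML file
#'
#' @param cfg a [decision_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_decision_config <- function(cfg, path) {
  as_plain <- function(cr) {
    out <- list(
      id = cr$id, description = cr$description,
      scale = unname(Map(function(code, label) list(code = code, label = label),
                         cr$scale$codes, cr$scale$labels))
    )
    if (!is.na(cr$weight)) out$weight <- cr$weight
    if (length(cr$satisfice$excluded_codes)) {
      out$satisfice <- as.list(cr$satisfice$excluded_codes)
    }
    if (!is.null(cr$weight_summary)) {
      out$weight_summary <- unclass(cr$weight_summary)
    }
    out
  }
  doc <- list(
    rounding_dp = cfg$rounding_dp,
    top_k = cfg$top_k,
    criteria = lapply(cfg$criteria, as_plain),
    options = lapply(seq_len(nrow(cfg$options)), function(i) {
      o <- list(id = cfg$options$id[i], label = cfg$options$label[i])
      if (isTRUE(cfg$options$pre_excluded[i])) o$pre_excluded <- TRUE
      o
    })
  )
  exclude <- attr(cfg, "exclude")
  if (length(exclude)) doc$exclude <- as.list(exclude)
  yaml::write_yaml(doc, path)
  invisible(path)
}
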