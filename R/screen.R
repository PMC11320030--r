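#' Apply named pre-scoring exclusions
#'
#' Removes options that a stakeholder panel has excluded by explicit decision
#' (typically because a deal-breaker level was judged met) before any votes
#' are cast. Survivors keep their original order; every exclusion is recorded.
#'
#' @param options options tibble from a [decision_config()] (columns `id`,
#'   `label`, optionally `pre_excluded`), or a character vector of ids.
#' @param excluded_ids character vector of option ids to exclude; must all
#'   exist among `options`.
#' @param reason exclusion reason recorded on each record, by default
#'   `"named_decision"`.
#' @param detail free-text detail recorded on each record.
#' @return A list with `surviving` (options tibble, original order) and
#'   `records` (tibble: `option`, `reason`, `criterion`, `detail`).
#' @examples
#' opts <- tibble::tibble(id = c("a", "b", "c"), label = c("A", "B", "C"))
#' apply_exclusions(opts, "b")$surviving$id # "a" "c"
#' @export
apply_exclusions <- function(options, excluded_ids,
                             reason = "named_decision", detail = "") {
  if (is.character(options)) options <- tibble::tibble(id = options)
  options <- tibble::as_tibble(options)
  excluded_ids <- unique(as.character(excluded_ids))
  unknown <- setdiff(excluded_ids, options$id)
  if (length(unknown)) {
    stop_pocmcda("unknown option id(s) in exclusion list: ",
                 paste(unknown, collapse = ", "))
  }
  records <- tibble::tibble(
    option = excluded_ids,
    reason = reason,
    criterion = NA_character_,
    detail = detail
  )
  list(surviving = options[!options$id %in% excluded_ids, , drop = FALSE],
       records = records)
}

#' Read a one-column exclusion list
#'
#' @param path text file with one option id per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of option ids.
#' @export
read_exclusions <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Is a satisfice rule met by a mean rating?
#'
#' The deal-breaker test is a threshold comparison on the *unrounded* panel
#' mean: a low-tail rule is met when the mean is at or below its threshold, a
#' high-tail rule when at or above, and a criterion without a rule is never
#' met. Comparing the mean (rather than its rounded category) is what makes a
#' mean of 1.69 trip a "levels 0-2" rule while 2.15 does not.
#'
#' @param mean_rating unrounded mean rating for one option on one criterion.
#' @param rule a [satisfice_rule()].
#' @param scale the criterion's [rating_scale()].
#' @return `TRUE` if the rule is met (option disqualified on this criterion).
#' @examples
#' sc <- rating_scale(0:4)
#' satisfice_met(1.69, satisfice_rule(0:2), sc) # TRUE
#' satisfice_met(2.15, satisfice_rule(0:2), sc) # FALSE
#' @export
satisfice_met <- function(mean_rating, rule, scale) {
  if (!is.finite(mean_rating) || mean_rating < scale$min_code ||
      mean_rating > scale$max_code) {
    stop_pocmcda("mean rating ", mean_rating, " outside scale bounds [",
                 scale$min_code, ", ", scale$max_code, "]")
  }
  cls <- classify_satisfice(rule, scale)
  switch(cls$tail,
         none = FALSE,
         low = mean_rating <= cls$threshold,
         high = mean_rating >= cls$threshold)
}
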