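#' Render a scoring matrix as a plain-text report
#'
#' Mirrors the conventional published layout: one block per criterion with a
#' weighting row, a mean-rating row, a satisfice Yes/No row and a final-score
#' row, options as columns, and a closing total row. Every number is the
#' full-precision matrix value rounded half-up to the configuration's display
#' precision — the report never carries more (or different) precision than
#' the matrix.
#'
#' @param matrix a `scoring_matrix` from [build_matrix()] or
#'   [score_from_means()].
#' @return Character vector of report lines.
#' @export
render_matrix_report <- function(matrix) {
  cfg <- matrix$config
  dp <- cfg$rounding_dp
  fmt <- function(x) formatC(round_half_up(x, dp), format = "f", digits = dp)
  opts <- matrix$options$option
  wl <- max(nchar(c("Total", "Satisfice met?", "Mean rating",
                    "Weighting", criterion_ids(cfg)))) + 2L
  cw <- pmax(nchar(opts), dp + 6L)
  pad <- function(label, cells) {
    paste0(formatC(label, width = wl, flag = "-"),
           paste(mapply(formatC, cells, width = cw + 2L), collapse = ""))
  }
  lines <- c(pad("", opts))
  for (cr in cfg$criteria) {
    cc <- matrix$cells[matrix$cells$criterion == cr$id, ]
    cc <- cc[match(opts, cc$option), ]
    lines <- c(
      lines,
      pad(cr$id, rep("", length(opts))),
      pad("  Weighting", rep(fmt(cr$weight), length(opts))),
      pad("  Mean rating", fmt(cc$mean)),
      pad("  Satisfice met?", ifelse(cc$satisfice_met, "Yes", "No")),
      pad("  Final score", fmt(cc$weighted))
    )
  }
  ranked <- matrix$options[match(opts, matrix$options$option), ]
  lines <- c(
    lines,
    pad("Total", fmt(ranked$total)),
    pad("Rank", as.character(ranked$rank)),
    pad("Selected", ifelse(ranked$top_k, "*", ""))
  )
  lines
}

#' Write a scoring matrix to delimited files
#'
#' Writes `cells.csv` (long format, one row per option x criterion) and
#' `options.csv` (totals, ranks, flags) into a directory, plus the rendered
#' plain-text report as `matrix.txt`.
#'
#' @param matrix a `scoring_matrix`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scoring_matrix <- function(matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             options = file.path(dir, "options.csv"),
             report = file.path(dir, "matrix.txt"))
  readr::write_csv(matrix$cells, paths[["cells"]])
  readr::write_csv(matrix$options, paths[["options"]])
  writeLines(render_matrix_report(matrix), paths[["report"]])
  invisible(paths)
}

#' Verify a published (printed) scoring matrix against its own weights
#'
#' Published scoring matrices print rounded means and rounded final scores.
#' This check asks, cell by cell, whether the printed final score is
#' *reconcilable* with printed weight x printed mean once display rounding is
#' accounted for: the printed mean stands for any value within half a display
#' unit of it, so the final score must fall inside the induced interval
#' (widened by half a unit for its own rounding). Cells outside that interval
#' cannot be explained by rounding and indicate a transcription or
#' computation inconsistency in the source. The per-criterion implied
#' multiplier (final / mean, averaged over nonzero-mean cells) is reported to
#' help diagnose what weight was actually applied.
#'
#' @param cfg a [decision_config()] carrying the printed weights.
#' @param printed data frame with columns `option`, `criterion`, `mean`,
#'   `final` — the printed cell values.
#' @param totals optional named numeric vector of printed option totals;
#'   checked against sums of printed finals with rounding slack.
#' @return A list with `cells` (per-cell tibble adding `expected`, `lo`,
#'   `hi`, `consistent`), `criteria` (per-criterion `weight`,
#'   `implied_weight`, `n_inconsistent`, `consistent`) and, when `totals` is
#'   given, `totals` (per-option `printed`, `sum_printed_finals`,
#'   `consistent`).
#' @export
verify_printed_matrix <- function(cfg, printed, totals = NULL) {
  printed <- tibble::as_tibble(printed)
  dp <- cfg$rounding_dp
  h <- 0.5 * 10^(-dp)
  weights <- stats::setNames(vapply(cfg$criteria, `[[`, numeric(1), "weight"),
                             criterion_ids(cfg))
  w <- weights[printed$criterion]
  lo <- w * (printed$mean - h) - h
  hi <- w * (printed$mean + h) + h
  cells <- tibble::tibble(
    option = printed$option, criterion = printed$criterion,
    mean = printed$mean, final = printed$final,
    expected = w * printed$mean, lo = lo, hi = hi,
    consistent = printed$final >= lo & printed$final <= hi
  )
  criteria <- purrr::map_dfr(cfg$criteria, function(cr) {
    cc <- cells[cells$criterion == cr$id, ]
    nz <- cc$mean > 0
    tibble::tibble(
      criterion = cr$id,
      weight = cr$weight,
      implied_weight = if (any(nz)) mean(cc$final[nz] / cc$mean[nz]) else NA_real_,
      n_inconsistent = sum(!cc$consistent),
      consistent = all(cc$consistent)
    )
  })
  out <- list(cells = cells, criteria = criteria)
  if (!is.null(totals)) {
    slack <- h * length(cfg$criteria) + h
    out$totals <- purrr::map_dfr(names(totals), function(o) {
      s <- sum(printed$final[printed$option == o])
      tibble::tibble(option = o, printed = unname(totals[[o]]),
                     sum_printed_finals = s,
                     consistent = abs(totals[[o]] - s) <= slack)
    })
  }
  out
}
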