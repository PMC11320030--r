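#' Validate a vote table against a configuration
#'
#' A vote table is long-format ordinal data: one row per (stakeholder,
#' option, criterion) with an integer score that must be a code of that
#' criterion's rating scale. Participation may vary by cell, so missing rows
#' are allowed; duplicates are not.
#'
#' @param votes data frame with columns `stakeholder`, `option`, `criterion`,
#'   `score`.
#' @param cfg a [decision_config()].
#' @return The validated votes as a tibble.
#' @export
validate_votes <- function(votes, cfg) {
  tab <- tibble::as_tibble(votes)
  need <- c("stakeholder", "option", "criterion", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_pocmcda("vote table: missing column(s) ", paste(miss, collapse = ", "))
  }
  bad_opt <- which(!tab$option %in% cfg$options$id)
  if (length(bad_opt)) {
    stop_pocmcda("vote table: unknown option '", tab$option[bad_opt[1L]],
                 "' at row ", bad_opt[1L])
  }
  ids <- criterion_ids(cfg)
  bad_cr <- which(!tab$criterion %in% ids)
  if (length(bad_cr)) {
    stop_pocmcda("vote table: unknown criterion '", tab$criterion[bad_cr[1L]],
                 "' at row ", bad_cr[1L])
  }
  for (cr in cfg$criteria) {
    rows <- which(tab$criterion == cr$id & !tab$score %in% cr$scale$codes)
    if (length(rows)) {
      stop_pocmcda("vote table: score ", tab$score[rows[1L]],
                   " is not a level of criterion '", cr$id, "' at row ", rows[1L])
    }
  }
  dup <- which(duplicated(tab[, c("stakeholder", "option", "criterion")]))
  if (length(dup)) {
    stop_pocmcda("vote table: duplicate (stakeholder, option, criterion) at row(s) ",
                 paste(dup, collapse = ", "))
  }
  tab
}

#' Mean rating for one option on one criterion
#'
#' Arithmetic mean over the votes present for the cell; stakeholders who did
#' not vote on the cell contribute nothing. Cells may therefore have
#' different numbers of votes.
#'
#' @param votes a vote table (see [validate_votes()]).
#' @param option,criterion ids selecting the cell.
#' @return The unrounded mean rating.
#' @export
mean_rating <- function(votes, option, criterion) {
  s <- votes$score[votes$option == option & votes$criterion == criterion]
  if (length(s) == 0L) {
    stop_pocmcda("no votes for option '", option, "' x criterion '",
                 criterion, "'")
  }
  mean(s)
}

#' Weighted score for one cell
#'
#' The criterion weight multiplied by the panel's mean rating, at full
#' precision. Rounding happens only when a report is rendered.
#'
#' @param weight non-negative criterion weight.
#' @param mean unrounded mean rating.
#' @return `weight * mean`.
#' @export
weighted_score <- function(weight, mean) {
  stopifnot(is.finite(weight), weight >= 0)
  weight * mean
}

#' Total score for an option
#'
#' @param weighted numeric vector of per-criterion weighted scores, one per
#'   criterion.
#' @param n_criteria expected number of criteria; when given, a length
#'   mismatch is an error.
#' @return Sum at full precision.
#' @export
total_score <- function(weighted, n_criteria = NULL) {
  if (!is.null(n_criteria) && length(weighted) != n_criteria) {
    stop_pocmcda("expected ", n_criteria, " weighted scores, got ",
                 length(weighted))
  }
  sum(weighted)
}

#' Rank options by total score
#'
#' Descending by total; equal totals keep their input order and are annotated
#' as tied. The first `k` ranked options are flagged as selected.
#'
#' @param totals named numeric vector of option totals, or a data frame with
#'   columns `option` and `total`.
#' @param k number of top options to select (default 3).
#' @return A tibble in rank order: `option`, `total`, `rank`, `top_k`, `tied`.
#' @export
rank_options <- function(totals, k = 3L) {
  if (is.data.frame(totals)) {
    tab <- tibble::as_tibble(totals)[, c("option", "total")]
  } else {
    tab <- tibble::tibble(option = names(totals), total = unname(totals))
  }
  if (k > nrow(tab)) {
    stop_pocmcda("top_k = ", k, " exceeds the number of options (", nrow(tab), ")")
  }
  ord <- order(-tab$total)  # stable: ties keep input order
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$top_k <- tab$rank <= k
  tab$tied <- duplicated(tab$total) | duplicated(tab$total, fromLast = TRUE)
  tab
}

cells_from_votes <- function(cfg, votes) {
  grid <- expand.grid(option = cfg$options$id, criterion = criterion_ids(cfg),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_votes <- paste(votes$option, votes$criterion, sep = "\r")
  key_grid <- paste(grid$option, grid$criterion, sep = "\r")
  n <- vapply(key_grid, function(k) sum(key_votes == k), integer(1),
              USE.NAMES = FALSE)
  empty <- which(n == 0L)
  if (length(empty)) {
    stop_pocmcda("no votes for option '", grid$option[empty[1L]],
                 "' x criterion '", grid$criterion[empty[1L]], "'")
  }
  mean <- vapply(key_grid, function(k) mean(votes$score[key_votes == k]),
                 numeric(1), USE.NAMES = FALSE)
  tibble::tibble(option = grid$option, criterion = grid$criterion,
                 n = n, mean = mean)
}

assemble_matrix <- function(cfg, cells, k) {
  crit_ids <- criterion_ids(cfg)
  weights <- stats::setNames(vapply(cfg$criteria, `[[`, numeric(1), "weight"),
                             crit_ids)
  if (anyNA(weights)) {
    stop_pocmcda("criterion '", crit_ids[which(is.na(weights))[1L]],
                 "' has no weight; run assign_weights() or set one in the config")
  }
  met <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cr <- get_criterion(cfg, cells$criterion[i])
    met[i] <- satisfice_met(cells$mean[i], cr$satisfice, cr$scale)
  }
  cells$satisfice_met <- met
  cells$weighted <- unname(weights[cells$criterion]) * cells$mean

  totals <- vapply(cfg$options$id, function(o) {
    total_score(cells$weighted[cells$option == o], length(crit_ids))
  }, numeric(1))
  ranking <- rank_options(totals, k = k)
  opts <- tibble::tibble(
    option = cfg$options$id,
    label = cfg$options$label,
    total = unname(totals),
    eligible = vapply(cfg$options$id, function(o)
      !any(cells$satisfice_met[cells$option == o]), logical(1))
  )
  opts <- dplyr::left_join(opts,
                           ranking[, c("option", "rank", "top_k", "tied")],
                           by = "option")
  structure(list(cells = cells, options = opts, ranking = ranking,
                 config = cfg),
            class = "scoring_matrix")
}

#' Build the weighted scoring matrix from a vote table
#'
#' The core aggregation step: per (option, criterion) cell the mean rating
#' and vote count, the satisfice flag (tested on the unrounded mean), and the
#' weighted score (weight x mean); per option the total (sum of weighted
#' scores across criteria), the rank, a top-k selection flag, and an
#' eligibility flag. Options meeting a satisfice rule are flagged ineligible
#' but still scored and ranked — the flag informs the panel, it does not
#' silently drop rows.
#'
#' @param cfg a valid [decision_config()] whose criteria carry weights.
#' @param votes a vote table; validated against `cfg` first.
#' @param k top-k selection size; defaults to `cfg$top_k`.
#' @return An object of class `scoring_matrix`: list with tibbles `cells`
#'   (`option`, `criterion`, `n`, `mean`, `satisfice_met`, `weighted`),
#'   `options` (`option`, `label`, `total`, `eligible`, `rank`, `top_k`,
#'   `tied`), `ranking` (rank order), and the `config`.
#' @export
build_matrix <- function(cfg, votes, k = cfg$top_k) {
  diags <- validate_config(cfg)
  if (length(diags)) {
    stop_pocmcda("invalid configuration:\n  ", paste(diags, collapse = "\n  "))
  }
  votes <- validate_votes(votes, cfg)
  assemble_matrix(cfg, cells_from_votes(cfg, votes), k = k)
}

#' Build a scoring matrix from pre-computed cell means
#'
#' Used when only per-cell mean ratings are available — for instance when
#' checking a published scoring matrix, where the underlying individual votes
#' were never released. Behaves exactly like [build_matrix()] downstream of
#' the mean-rating step.
#'
#' @param cfg a valid [decision_config()] whose criteria carry weights.
#' @param means data frame with columns `option`, `criterion`, `mean` and
#'   optionally `n` (vote count, `NA` if unknown); one row per cell, covering
#'   every option x criterion pair.
#' @param k top-k selection size; defaults to `cfg$top_k`.
#' @return A `scoring_matrix` (see [build_matrix()]).
#' @export
score_from_means <- function(cfg, means, k = cfg$top_k) {
  means <- tibble::as_tibble(means)
  need <- c("option", "criterion", "mean")
  miss <- setdiff(need, names(means))
  if (length(miss)) {
    stop_pocmcda("means table: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (!"n" %in% names(means)) means$n <- NA_integer_
  grid_key <- paste(rep(cfg$options$id, times = length(cfg$criteria)),
                    rep(criterion_ids(cfg), each = nrow(cfg$options)), sep = "\r")
  have_key <- paste(means$option, means$criterion, sep = "\r")
  missing_cell <- setdiff(grid_key, have_key)
  if (length(missing_cell)) {
    parts <- strsplit(missing_cell[1L], "\r", fixed = TRUE)[[1L]]
    stop_pocmcda("no mean for option '", parts[1L], "' x criterion '",
                 parts[2L], "'")
  }
  means <- means[match(grid_key, have_key), c("option", "criterion", "n", "mean")]
  assemble_matrix(cfg, means, k = k)
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(render_matrix_report(x), sep = "\n")
  invisible(x)
}
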