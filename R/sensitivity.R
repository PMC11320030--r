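#' Leave-one-out jackknife over stakeholders
#'
#' Re-scores the full matrix once per stakeholder, with that stakeholder's
#' votes removed, and reports every rank change relative to the full panel.
#' A replicate in which some removal empties a cell entirely is flagged
#' incomplete (and its ranks are not computed) rather than silently dropped.
#'
#' @param cfg a valid [decision_config()] with weights.
#' @param votes a vote table (see [validate_votes()]).
#' @param k top-k selection size; defaults to `cfg$top_k`.
#' @return An object of class `jackknife_report`: list with `baseline` (the
#'   full-panel ranking), `replicates` (tibble: `stakeholder`, `option`,
#'   `total`, `rank`, `top_k`), `changes` (tibble of options whose rank moved
#'   under some removal: `stakeholder`, `option`, `rank_full`, `rank_loo`),
#'   and `incomplete` (stakeholders whose removal emptied a cell).
#' @export
jackknife_ranks <- function(cfg, votes, k = cfg$top_k) {
  votes <- validate_votes(votes, cfg)
  full <- build_matrix(cfg, votes, k = k)
  base_rank <- stats::setNames(full$options$rank, full$options$option)
  stakeholders <- unique(votes$stakeholder)
  reps <- list(); changes <- list(); incomplete <- character()
  for (s in stakeholders) {
    loo <- votes[votes$stakeholder != s, , drop = FALSE]
    m <- tryCatch(build_matrix(cfg, loo, k = k), error = function(e) NULL)
    if (is.null(m)) {
      incomplete <- c(incomplete, s)
      next
    }
    reps[[s]] <- tibble::tibble(
      stakeholder = s,
      option = m$ranking$option, total = m$ranking$total,
      rank = m$ranking$rank, top_k = m$ranking$top_k
    )
    moved <- m$ranking$option[m$ranking$rank != base_rank[m$ranking$option]]
    if (length(moved)) {
      changes[[s]] <- tibble::tibble(
        stakeholder = s, option = moved,
        rank_full = unname(base_rank[moved]),
        rank_loo = m$ranking$rank[match(moved, m$ranking$option)]
      )
    }
  }
  empty_changes <- tibble::tibble(stakeholder = character(),
                                  option = character(),
                                  rank_full = integer(), rank_loo = integer())
  structure(
    list(baseline = full$ranking,
         replicates = dplyr::bind_rows(reps),
         changes = if (length(changes)) dplyr::bind_rows(changes) else empty_changes,
         incomplete = incomplete),
    class = "jackknife_report"
  )
}

#' @export
print.jackknife_report <- function(x, ...) {
  n <- length(unique(x$replicates$stakeholder)) + length(x$incomplete)
  cat("<jackknife_report> ", n, " leave-one-out replicates; ",
      nrow(x$changes), " rank change(s)",
      if (length(x$incomplete)) paste0("; incomplete: ",
                                       paste(x$incomplete, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo weight perturbation of the ranking
#'
#' Resamples the criterion weights `n_reps` times, multiplying each baseline
#' weight by an independent log-normal factor with unit median and log-scale
#' `noise_scale`, recomputes the ranking for every replicate, and reports how
#' often each option holds each rank, how often each option stays in the
#' top-k, and how often the baseline top-k set is retained in full.
#' Multiplicative noise keeps weights positive and perturbs *relative*
#' importance, which is the quantity elicitation uncertainty acts on.
#'
#' @param cfg a valid [decision_config()] with weights.
#' @param votes a vote table; alternatively supply `means`.
#' @param means optional pre-computed cell means (`option`, `criterion`,
#'   `mean`), used instead of `votes`.
#' @param n_reps number of replicates (default 10000).
#' @param noise_scale standard deviation of the log perturbation factor
#'   (default 0.1; 0 reproduces the baseline exactly in every replicate).
#' @param seed integer seed; required, so every report is reproducible.
#' @param k top-k selection size; defaults to `cfg$top_k`.
#' @return An object of class `sensitivity_report`: list with `baseline`
#'   ranking, `rank_freq` (tibble: `option`, `rank`, `freq`),
#'   `topk_retention` (tibble: `option`, `baseline_top_k`, `freq`),
#'   `set_retention` (share of replicates whose top-k set equals the
#'   baseline's), `first_place` (tibble: `option`, `freq`), and the
#'   `n_reps`, `noise_scale`, `seed` used.
#' @export
perturb_weights <- function(cfg, votes = NULL, means = NULL, n_reps = 10000L,
                            noise_scale = 0.1, seed, k = cfg$top_k) {
  stopifnot(n_reps >= 1L, noise_scale >= 0)
  if (missing(seed)) stop_pocmcda("perturb_weights() requires a seed")
  if (is.null(means)) {
    if (is.null(votes)) stop_pocmcda("supply either votes or means")
    base <- build_matrix(cfg, votes, k = k)
  } else {
    base <- score_from_means(cfg, means, k = k)
  }
  crit_ids <- criterion_ids(cfg)
  opt_ids <- cfg$options$id
  w0 <- vapply(cfg$criteria, `[[`, numeric(1), "weight")
  # options x criteria mean matrix, in config order
  S <- Matrix_from_cells(base$cells, opt_ids, crit_ids)

  set.seed(as.integer(seed))
  factors <- matrix(exp(stats::rnorm(n_reps * length(crit_ids),
                                     mean = 0, sd = noise_scale)),
                    nrow = length(crit_ids), ncol = n_reps)
  W <- w0 * factors                       # criteria x reps
  totals <- S %*% W                       # options x reps

  n_opt <- length(opt_ids)
  ranks <- apply(totals, 2L, function(t) {
    r <- integer(n_opt)
    r[order(-t)] <- seq_len(n_opt)        # stable: ties keep config order
    r
  })
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = n_opt)

  rank_freq <- tidyr::crossing(option = opt_ids, rank = seq_len(n_opt))
  rank_freq$freq <- unname(mapply(function(o, r) {
    mean(ranks[match(o, opt_ids), ] == r)
  }, rank_freq$option, rank_freq$rank))

  in_topk <- ranks <= k
  base_topk <- base$ranking$option[base$ranking$top_k]
  base_mask <- opt_ids %in% base_topk
  topk_retention <- tibble::tibble(
    option = opt_ids,
    baseline_top_k = base_mask,
    freq = rowMeans(in_topk)
  )
  set_retention <- mean(apply(in_topk, 2L, function(col) all(col == base_mask)))
  first_place <- tibble::tibble(option = opt_ids,
                                freq = rowMeans(ranks == 1L))
  structure(
    list(baseline = base$ranking, rank_freq = rank_freq,
         topk_retention = topk_retention, set_retention = set_retention,
         first_place = first_place,
         n_reps = as.integer(n_reps), noise_scale = noise_scale,
         seed = as.integer(seed)),
    class = "sensitivity_report"
  )
}

Matrix_from_cells <- function(cells, opt_ids, crit_ids) {
  S <- matrix(NA_real_, nrow = length(opt_ids), ncol = length(crit_ids),
              dimnames = list(opt_ids, crit_ids))
  S[cbind(match(cells$option, opt_ids), match(cells$criterion, crit_ids))] <-
    cells$mean
  S
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report> ", x$n_reps, " replicates, noise_scale ",
      x$noise_scale, ", seed ", x$seed, "\n", sep = "")
  cat("  baseline top-k retained in full: ",
      formatC(100 * x$set_retention, format = "f", digits = 1), "%\n", sep = "")
  for (i in seq_len(nrow(x$topk_retention))) {
    cat("  ", format(x$topk_retention$option[i], width = 20), " in top-k ",
        formatC(100 * x$topk_retention$freq[i], format = "f", digits = 1),
        "% of replicates\n", sep = "")
  }
  invisible(x)
}

#' Write a sensitivity report to delimited files
#'
#' @param report a `sensitivity_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sensitivity_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(rank_freq = file.path(dir, "rank_freq.csv"),
             topk = file.path(dir, "topk_retention.csv"))
  readr::write_csv(report$rank_freq, paths[["rank_freq"]])
  readr::write_csv(report$topk_retention, paths[["topk"]])
  invisible(paths)
}
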