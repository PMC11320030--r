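#' Synthetic stakeholder-panel model
#'
#' Defines a panel with known latent structure: every (option, criterion)
#' cell has a latent consensus `mu` on the criterion's scale interval and a
#' dispersion `sigma`; every criterion has a latent importance `mu_w` on the
#' 0-10 importance scale with its own dispersion; stakeholders answer each
#' question independently with probability `participation`. Responses are
#' drawn as normal(mu, sigma), clamped to the scale interval, then rounded to
#' the nearest scale code — the simplest generative model with a
#' consensus-plus-dispersion reading. Clamping and rounding deliberately bias
#' cell means near scale edges; [recovery_experiment()] measures (rather than
#' hides) that bias.
#'
#' @param cfg a [decision_config()] providing the options, criteria and
#'   scales the panel votes on.
#' @param n_stakeholders panel size (default 14, a typical workshop panel).
#' @param participation probability in `[0, 1]` that a stakeholder answers
#'   any given question (default 1).
#' @param consensus data frame with columns `option`, `criterion`, `mu` and
#'   optionally `sigma`, covering every cell; `mu` must lie within the
#'   criterion's scale interval.
#' @param sigma default dispersion for cells without their own `sigma`
#'   (default 0.75, moderate disagreement on a 5-level scale).
#' @param importance data frame with columns `criterion`, `mu_w` and
#'   optionally `sigma_w`, one row per criterion; `mu_w` in `[0, 10]`.
#'   Optional — omit if only votes are to be generated.
#' @param importance_sigma default dispersion for importance scores
#'   (default 1.5).
#' @param seed integer seed; mandatory, there is no hidden global state.
#' @return An object of class `panel_model`.
#' @export
panel_model <- function(cfg, n_stakeholders = 14L, participation = 1,
                        consensus, sigma = 0.75,
                        importance = NULL, importance_sigma = 1.5, seed) {
  if (missing(seed)) stop_pocmcda("panel_model() requires a seed")
  stopifnot(is_count(n_stakeholders), n_stakeholders >= 1,
            participation >= 0, participation <= 1, sigma >= 0)
  consensus <- tibble::as_tibble(consensus)
  if (!"sigma" %in% names(consensus)) consensus$sigma <- sigma
  consensus$sigma[is.na(consensus$sigma)] <- sigma
  for (i in seq_len(nrow(consensus))) {
    cr <- get_criterion(cfg, consensus$criterion[i])
    if (consensus$mu[i] < cr$scale$min_code || consensus$mu[i] > cr$scale$max_code) {
      stop_pocmcda("consensus mu ", consensus$mu[i], " outside scale of criterion '",
                   cr$id, "'")
    }
    if (consensus$sigma[i] < 0) stop_pocmcda("sigma must be >= 0")
  }
  grid <- paste(rep(cfg$options$id, times = length(cfg$criteria)),
                rep(criterion_ids(cfg), each = nrow(cfg$options)))
  have <- paste(consensus$option, consensus$criterion)
  if (length(setdiff(grid, have))) {
    stop_pocmcda("consensus table must cover every option x criterion cell")
  }
  if (!is.null(importance)) {
    importance <- tibble::as_tibble(importance)
    if (!"sigma_w" %in% names(importance)) importance$sigma_w <- importance_sigma
    importance$sigma_w[is.na(importance$sigma_w)] <- importance_sigma
    if (any(importance$mu_w < 0 | importance$mu_w > 10)) {
      stop_pocmcda("importance mu_w must lie in [0, 10]")
    }
  }
  structure(
    list(cfg = cfg, n_stakeholders = as.integer(n_stakeholders),
         participation = participation, consensus = consensus,
         importance = importance, seed = as.integer(seed)),
    class = "panel_model"
  )
}

# snap real values to the nearest code of a (possibly gappy) scale,
# halves rounding toward the higher code
snap_to_codes <- function(x, codes) {
  if (length(codes) == 1L) return(rep(codes, length(x)))
  mids <- (codes[-length(codes)] + codes[-1L]) / 2
  codes[findInterval(x, mids) + 1L]
}

draw_ordinal <- function(n, mu, sigma, codes) {
  x <- stats::rnorm(n, mean = mu, sd = sigma)
  x <- pmin(pmax(x, codes[1L]), codes[length(codes)])
  snap_to_codes(x, codes)
}

#' Generate a synthetic vote table
#'
#' Draws one clamped-and-rounded normal response per participating
#' (stakeholder, option, criterion) triple. Output always passes
#' [validate_votes()] against the model's configuration and is bit-identical
#' under a fixed seed.
#'
#' @param model a [panel_model()].
#' @param seed integer seed; defaults to the model's seed.
#' @return A long-format vote tibble (`stakeholder`, `option`, `criterion`,
#'   `score`).
#' @export
generate_votes <- function(model, seed = model$seed) {
  set.seed(as.integer(seed))
  cfg <- model$cfg
  n <- model$n_stakeholders
  stakeholders <- sprintf("s%03d", seq_len(n))
  out <- vector("list", nrow(model$consensus))
  for (i in seq_len(nrow(model$consensus))) {
    row <- model$consensus[i, ]
    present <- stats::runif(n) < model$participation
    m <- sum(present)
    if (m == 0L) next
    codes <- get_criterion(cfg, row$criterion)$scale$codes
    out[[i]] <- tibble::tibble(
      stakeholder = stakeholders[present],
      option = row$option, criterion = row$criterion,
      score = draw_ordinal(m, row$mu, row$sigma, codes)
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(stakeholder = character(), option = character(),
                          criterion = character(), score = integer())
  }
  res
}

#' Generate synthetic importance-survey responses
#'
#' As [generate_votes()], but on the 11-point 0-10 importance scale, one
#' question per criterion. Uses its own seed (by default the model seed plus
#' one) so votes and importance responses are independent streams.
#'
#' @param model a [panel_model()] with an `importance` table.
#' @param seed integer seed; defaults to `model$seed + 1`.
#' @return A long-format importance tibble (`stakeholder`, `criterion`,
#'   `score`).
#' @export
generate_importance <- function(model, seed = model$seed + 1L) {
  if (is.null(model$importance)) {
    stop_pocmcda("panel model has no importance table")
  }
  set.seed(as.integer(seed))
  n <- model$n_stakeholders
  stakeholders <- sprintf("s%03d", seq_len(n))
  codes <- 0:10
  out <- vector("list", nrow(model$importance))
  for (i in seq_len(nrow(model$importance))) {
    row <- model$importance[i, ]
    present <- stats::runif(n) < model$participation
    m <- sum(present)
    if (m == 0L) next
    out[[i]] <- tibble::tibble(
      stakeholder = stakeholders[present],
      criterion = row$criterion,
      score = draw_ordinal(m, row$mu_w, row$sigma_w, codes)
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(stakeholder = character(), criterion = character(),
                          score = integer())
  }
  res
}

#' Parameter-recovery experiment for the synthetic panel
#'
#' Generates `n_reps` independent panels from the model, recomputes cell
#' means and weighted totals from each, and reports bias and RMSE against the
#' latent truth: cell truth is the consensus `mu`; option-total truth is the
#' dot product of the latent importances `mu_w` with the cell `mu` vector.
#' Totals on each replicate use the same latent weights, isolating vote
#' noise. Bias near scale edges (from clamping and rounding) shows up here as
#' nonzero bias even for large panels — by design, so the generator's
#' distortions are visible rather than hidden.
#'
#' @param model a [panel_model()] with an `importance` table (for weights).
#' @param n_reps number of replicate panels (default 50).
#' @return A list with `cells` (tibble: `option`, `criterion`, `mu`,
#'   `mean_est`, `bias`, `rmse`), `options` (tibble: `option`, `truth_total`,
#'   `total_est`, `bias`, `rmse`), `n_reps` and the model `seed`.
#' @export
recovery_experiment <- function(model, n_reps = 50L) {
  stopifnot(n_reps >= 1L)
  if (is.null(model$importance)) {
    stop_pocmcda("recovery_experiment() needs latent importances for totals")
  }
  cfg <- model$cfg
  crit_ids <- criterion_ids(cfg)
  opt_ids <- cfg$options$id
  w <- model$importance$mu_w[match(crit_ids, model$importance$criterion)]
  truth_S <- Matrix_from_cells(
    tibble::tibble(option = model$consensus$option,
                   criterion = model$consensus$criterion,
                   mean = model$consensus$mu),
    opt_ids, crit_ids)
  truth_T <- drop(truth_S %*% w)

  est_means <- array(NA_real_, c(length(opt_ids), length(crit_ids), n_reps))
  est_T <- matrix(NA_real_, length(opt_ids), n_reps)
  for (r in seq_len(n_reps)) {
    votes <- generate_votes(model, seed = model$seed + r - 1L)
    cells <- cells_from_votes(cfg, votes)
    S <- Matrix_from_cells(cells, opt_ids, crit_ids)
    est_means[, , r] <- S
    est_T[, r] <- drop(S %*% w)
  }
  cell_idx <- cbind(match(model$consensus$option, opt_ids),
                    match(model$consensus$criterion, crit_ids))
  cells_out <- tibble::tibble(
    option = model$consensus$option,
    criterion = model$consensus$criterion,
    mu = model$consensus$mu,
    mean_est = apply(est_means, c(1, 2), mean)[cell_idx],
    bias = apply(est_means, c(1, 2), mean)[cell_idx] - model$consensus$mu,
    rmse = sqrt(apply((est_means - array(truth_S,
                                         dim = dim(est_means)))^2,
                      c(1, 2), mean))[cell_idx]
  )
  options_out <- tibble::tibble(
    option = opt_ids,
    truth_total = truth_T,
    total_est = rowMeans(est_T),
    bias = rowMeans(est_T) - truth_T,
    rmse = sqrt(rowMeans((est_T - truth_T)^2))
  )
  list(cells = cells_out, options = options_out,
       n_reps = as.integer(n_reps), seed = model$seed)
}
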