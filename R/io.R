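#' Read a long-format vote table
#'
#' @param path CSV file (UTF-8, header) with columns `stakeholder`, `option`,
#'   `criterion`, `score`.
#' @param cfg optional [decision_config()]; when supplied the table is
#'   validated against it (unknown ids, out-of-scale scores, duplicates all
#'   rejected with row numbers).
#' @return A vote tibble.
#' @export
read_votes <- function(path, cfg = NULL) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("stakeholder", "option", "criterion", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_pocmcda("vote table: missing column(s) ", paste(miss, collapse = ", "))
  }
  tab$score <- as.numeric(tab$score)
  dup <- which(duplicated(tab[, c("stakeholder", "option", "criterion")]))
  if (length(dup)) {
    stop_pocmcda("vote table: duplicate (stakeholder, option, criterion) at row(s) ",
                 paste(dup, collapse = ", "))
  }
  if (!is.null(cfg)) tab <- validate_votes(tab, cfg)
  tab
}

#' Write a vote table
#'
#' @param votes vote tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_votes <- function(votes, path) {
  readr::write_csv(votes, path)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_pocmcda("stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' Run the full prioritisation pipeline
#'
#' Executes the stages in order — weight assignment (if an importance table
#' is given), pre-scoring exclusions, vote aggregation into the weighted
#' scoring matrix, ranking with top-k selection, and (optionally) weight
#' perturbation and jackknife sensitivity — and writes every result plus a
#' machine-readable run manifest to `out_dir`. Any stage error aborts with
#' the stage name and cause. Re-running with identical inputs and seed
#' reproduces byte-identical tabular outputs.
#'
#' @param config a [decision_config()] or path to a YAML configuration.
#' @param votes vote tibble or path to a vote CSV.
#' @param importance optional importance tibble or path to an importance CSV;
#'   when given, criterion weights are (re)assigned from it.
#' @param exclude optional character vector of option ids, or path to a
#'   one-id-per-line file; merged with the config's inline `exclude` list and
#'   any `pre_excluded` options.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the sensitivity stage (required when
#'   `reps > 0`).
#' @param top_k top-k selection size; defaults to the config's.
#' @param reps weight-perturbation replicates; 0 (default) skips the
#'   sensitivity stage.
#' @param noise_scale log-scale of the weight perturbation (default 0.1).
#' @param jackknife also run the leave-one-out jackknife when `reps > 0`
#'   (default `TRUE`).
#' @return Invisibly, a list with the `matrix` (`scoring_matrix`),
#'   `exclusions`, `sensitivity`, `jackknife` and `manifest` (paths +
#'   digests).
#' @export
run_pipeline <- function(config, votes, importance = NULL, exclude = NULL,
                         out_dir, seed = NULL, top_k = NULL, reps = 0L,
                         noise_scale = 0.1, jackknife = TRUE) {
  input_paths <- character()
  note_input <- function(x, label) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      input_paths[[label]] <<- x
    }
  }
  note_input(config, "config"); note_input(votes, "votes")
  note_input(importance, "importance"); note_input(exclude, "exclude")

  cfg <- run_stage("config", {
    if (is.character(config)) read_decision_config(config) else config
  })
  if (!is.null(top_k)) cfg$top_k <- as.integer(top_k)

  if (!is.null(importance)) {
    cfg <- run_stage("weights", {
      resp <- if (is.character(importance)) read_importance(importance) else
        validate_importance(importance)
      assign_weights(cfg, resp)
    })
  }

  screened <- run_stage("screen", {
    ids <- character()
    if (!is.null(exclude)) {
      ids <- if (is.character(exclude) && length(exclude) == 1L &&
                 file.exists(exclude)) read_exclusions(exclude) else exclude
    }
    ids <- unique(c(ids, attr(cfg, "exclude") %||% character(),
                    cfg$options$id[cfg$options$pre_excluded]))
    apply_exclusions(cfg$options, ids)
  })
  cfg_scored <- cfg
  cfg_scored$options <- screened$surviving
  cfg_scored$options$pre_excluded <- FALSE

  matrix <- run_stage("score", {
    v <- if (is.character(votes)) read_votes(votes) else tibble::as_tibble(votes)
    build_matrix(cfg_scored, v, k = cfg_scored$top_k)
  })

  sens <- NULL; jack <- NULL
  if (reps > 0L) {
    if (is.null(seed)) stop_pocmcda("stage 'sensitivity' failed: seed required")
    v <- if (is.character(votes)) read_votes(votes) else tibble::as_tibble(votes)
    sens <- run_stage("sensitivity", {
      perturb_weights(cfg_scored, votes = v, n_reps = reps,
                      noise_scale = noise_scale, seed = seed,
                      k = cfg_scored$top_k)
    })
    if (jackknife) {
      jack <- run_stage("jackknife", {
        jackknife_ranks(cfg_scored, v, k = cfg_scored$top_k)
      })
    }
  }

  run_stage("write", {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(weight_table(cfg_scored), file.path(out_dir, "weights.csv"))
    readr::write_csv(screened$records, file.path(out_dir, "exclusions.csv"))
    write_scoring_matrix(matrix, out_dir)
    readr::write_csv(matrix$ranking, file.path(out_dir, "ranking.csv"))
    if (!is.null(sens)) write_sensitivity_report(sens, out_dir)
    if (!is.null(jack)) {
      readr::write_csv(jack$changes, file.path(out_dir, "jackknife_changes.csv"))
    }
  })

  manifest <- list(
    inputs = lapply(input_paths, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    seed = seed,
    top_k = cfg_scored$top_k,
    reps = as.integer(reps),
    noise_scale = noise_scale,
    n_options_scored = nrow(cfg_scored$options),
    n_excluded = nrow(screened$records),
    outputs = local({
      outs <- list.files(out_dir, pattern = "\\.(csv|txt)$", full.names = TRUE)
      lapply(stats::setNames(outs, basename(outs)), function(p)
        list(md5 = unname(tools::md5sum(p))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(matrix = matrix, exclusions = screened$records,
                 sensitivity = sens, jackknife = jack,
                 manifest = file.path(out_dir, "manifest.json")))
}
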