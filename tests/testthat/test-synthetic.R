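synth_cfg <- function() {
  decision_config(
    list(criterion("c1", scale = rating_scale(0:3), weight = 7.2),
         criterion("c2", scale = rating_scale(0:4), weight = 8.8)),
    options = c("a", "b"), top_k = 1
  )
}

synth_consensus <- function(mu = c(2, 3, 1, 2), sigma = NA) {
  tibble::tibble(option = rep(c("a", "b"), each = 2),
                 criterion = rep(c("c1", "c2"), 2), mu = mu, sigma = sigma)
}

test_that("zero dispersion reproduces the consensus exactly", {
  model <- panel_model(synth_cfg(), n_stakeholders = 5, participation = 1,
                       consensus = synth_consensus(), sigma = 0, seed = 1)
  votes <- generate_votes(model)
  expect_equal(nrow(votes), 5 * 4)
  for (i in 1:4) {
    cons <- synth_consensus()
    cell <- votes[votes$option == cons$option[i] &
                    votes$criterion == cons$criterion[i], ]
    expect_true(all(cell$score == cons$mu[i]))
  }
  m <- build_matrix(synth_cfg(), votes)
  expect_equal(sort(m$cells$mean), sort(synth_consensus()$mu))
})

test_that("zero participation yields an empty, still-valid table", {
  model <- panel_model(synth_cfg(), n_stakeholders = 5, participation = 0,
                       consensus = synth_consensus(), sigma = 0.5, seed = 2)
  votes <- generate_votes(model)
  expect_equal(nrow(votes), 0)
  expect_named(votes, c("stakeholder", "option", "criterion", "score"))
})

test_that("large panels recover interior consensus within Monte-Carlo error", {
  cfg <- decision_config(
    criterion("c1", scale = rating_scale(0:3), weight = 1), "a", top_k = 1)
  model <- panel_model(cfg, n_stakeholders = 2000, participation = 1,
                       consensus = tibble::tibble(option = "a", criterion = "c1",
                                                  mu = 2.0, sigma = 0.5),
                       seed = 3)
  votes <- generate_votes(model)
  se <- stats::sd(votes$score) / sqrt(nrow(votes))
  expect_lt(abs(mean(votes$score) - 2.0), 3 * se + 1e-9)
})

test_that("generated tables always validate and are seed-reproducible", {
  set.seed(61)
  for (i in 1:20) {
    cfg <- random_config(sample(2:3, 1), sample(2:3, 1))
    cons <- expand.grid(option = cfg$options$id,
                        criterion = vapply(cfg$criteria, `[[`, "", "id"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cons$mu <- vapply(cons$criterion, function(cid) {
      sc <- NULL
      for (cr in cfg$criteria) if (cr$id == cid) sc <- cr$scale
      stats::runif(1, sc$min_code, sc$max_code)
    }, numeric(1))
    model <- panel_model(cfg, n_stakeholders = sample(5:15, 1),
                         participation = stats::runif(1, 0.5, 1),
                         consensus = cons, sigma = stats::runif(1, 0, 1.5),
                         importance = tibble::tibble(
                           criterion = vapply(cfg$criteria, `[[`, "", "id"),
                           mu_w = stats::runif(length(cfg$criteria), 0, 10)),
                         seed = i)
    v1 <- generate_votes(model)
    expect_silent(validate_votes(v1, cfg))
    expect_identical(v1, generate_votes(model))
    imp1 <- generate_importance(model)
    expect_silent(validate_importance(imp1))
    expect_identical(imp1, generate_importance(model))
  }
})

test_that("synthetic importance surveys recover the latent weights", {
  cfg <- decision_config(
    lapply(1:4, function(i) criterion(paste0("c", i),
                                      scale = rating_scale(0:4), weight = NA)),
    options = "a", top_k = 1
  )
  mu_w <- c(7.2, 8.8, 7.0, 5.9)
  model <- panel_model(
    cfg, n_stakeholders = 2000, participation = 1,
    consensus = tibble::tibble(option = "a", criterion = paste0("c", 1:4),
                               mu = 2, sigma = 0.5),
    importance = tibble::tibble(criterion = paste0("c", 1:4), mu_w = mu_w,
                                sigma_w = 1.5),
    seed = 4
  )
  imp <- generate_importance(model)
  fitted <- assign_weights(cfg, imp)
  for (i in 1:4) {
    scores <- imp$score[imp$criterion == paste0("c", i)]
    se <- stats::sd(scores) / sqrt(length(scores))
    # the estimator converges to the ordinal model's analytic mean, which for
    # interior mu_w coincides with mu_w and near the scale top sits below it
    target <- expected_ordinal_mean(mu_w[i], 1.5, 0:10)
    expect_lt(abs(fitted$criteria[[i]]$weight - target), 3 * se + 1e-9)
    if (mu_w[i] <= 7.2) expect_lt(abs(target - mu_w[i]), 0.05)
  }
  # clamping at the 10 end biases the highest latent importance downwards
  expect_lt(expected_ordinal_mean(8.8, 1.5, 0:10), 8.8)
})

test_that("partial participation thins the panel at the expected rate", {
  cfg <- decision_config(
    criterion("c1", scale = rating_scale(0:4), weight = 1), "a", top_k = 1)
  model <- panel_model(cfg, n_stakeholders = 28, participation = 0.54,
                       consensus = tibble::tibble(option = "a",
                                                  criterion = "c1",
                                                  mu = 2, sigma = 1),
                       importance = tibble::tibble(criterion = "c1", mu_w = 8),
                       seed = 5)
  # expected respondents per question = 28 x 0.54 ~ 15; average over replicates
  counts <- vapply(1:200, function(r) {
    nrow(generate_importance(model, seed = 1000 + r))
  }, numeric(1))
  expect_equal(mean(counts), 28 * 0.54, tolerance = 0.05)
})

test_that("recovery experiment reports zero error at sigma 0 and edge bias at the cap", {
  cfg <- synth_cfg()
  model0 <- panel_model(cfg, n_stakeholders = 8, participation = 1,
                        consensus = synth_consensus(), sigma = 0,
                        importance = tibble::tibble(criterion = c("c1", "c2"),
                                                    mu_w = c(7, 9)),
                        seed = 6)
  rec0 <- recovery_experiment(model0, n_reps = 3)
  expect_equal(rec0$cells$bias, rep(0, 4))
  expect_equal(rec0$cells$rmse, rep(0, 4))
  expect_equal(rec0$options$rmse, rep(0, 2))

  # consensus at the scale maximum: clamping + rounding can only pull down
  cap <- panel_model(cfg, n_stakeholders = 200, participation = 1,
                     consensus = synth_consensus(mu = c(3, 4, 3, 4)),
                     sigma = 0.8,
                     importance = tibble::tibble(criterion = c("c1", "c2"),
                                                 mu_w = c(7, 9)),
                     seed = 7)
  rec_cap <- recovery_experiment(cap, n_reps = 10)
  expect_true(all(rec_cap$cells$bias < 0))

  # interior consensus: |bias| shrinks with panel size
  small <- panel_model(cfg, n_stakeholders = 10, participation = 1,
                       consensus = synth_consensus(mu = c(1.5, 2, 1.5, 2)),
                       sigma = 0.5,
                       importance = tibble::tibble(criterion = c("c1", "c2"),
                                                   mu_w = c(7, 9)),
                       seed = 8)
  big <- panel_model(cfg, n_stakeholders = 1000, participation = 1,
                     consensus = synth_consensus(mu = c(1.5, 2, 1.5, 2)),
                     sigma = 0.5,
                     importance = tibble::tibble(criterion = c("c1", "c2"),
                                                 mu_w = c(7, 9)),
                     seed = 8)
  rec_small <- recovery_experiment(small, n_reps = 30)
  rec_big <- recovery_experiment(big, n_reps = 30)
  expect_lt(mean(abs(rec_big$cells$bias)), mean(abs(rec_small$cells$bias)))
})
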