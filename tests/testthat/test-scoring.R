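test_that("cell means, weighted scores and totals match direct arithmetic", {
  votes <- tibble::tibble(
    stakeholder = paste0("s", 1:4), option = "o1", criterion = "c1",
    score = c(3, 3, 3, 4)
  )
  expect_equal(mean_rating(votes, "o1", "c1"), 3.25)
  votes$score <- c(0, 0, 1, 1)
  expect_equal(mean_rating(votes, "o1", "c1"), 0.5)
  const <- tibble::tibble(stakeholder = paste0("s", 1:13), option = "o1",
                          criterion = "c1", score = 3)
  expect_equal(mean_rating(const, "o1", "c1"), 3.0)
  expect_error(mean_rating(votes, "o1", "c2"), "no votes")

  expect_equal(weighted_score(5.90, 1.0), 5.90)
  expect_equal(weighted_score(5.90, 0), 0)
  expect_equal(weighted_score(2.5, 2), 5.0)

  expect_equal(total_score(c(27.32, 29.33, 22.17, 0.00)), 78.82)
  expect_equal(total_score(c(24.36, 27.08, 15.08, 5.90)), 72.42)
  expect_equal(total_score(c(0, 0, 0, 0)), 0)
  expect_error(total_score(c(1, 2), n_criteria = 4), "expected 4")
})

test_that("ranking is descending, stable under ties, and flags the top k", {
  totals <- c(troponin_ami = 78.82, ntprobnp_ahf = 45.06,
              lactate_sepsis = 72.42, lactate_trauma = 60.89,
              ketones_dka = 51.64)
  r <- rank_options(totals, k = 3)
  expect_equal(r$option, c("troponin_ami", "lactate_sepsis", "lactate_trauma",
                           "ketones_dka", "ntprobnp_ahf"))
  expect_equal(r$option[r$top_k],
               c("troponin_ami", "lactate_sepsis", "lactate_trauma"))
  expect_false(any(r$tied))

  single <- rank_options(c(only = 5), k = 1)
  expect_equal(single$rank, 1L)
  expect_true(single$top_k)

  tied <- rank_options(c(a = 3, b = 3, c = 1), k = 1)
  expect_equal(tied$option, c("a", "b", "c"))  # first-listed ranked ahead
  expect_equal(tied$tied, c(TRUE, TRUE, FALSE))
  expect_error(rank_options(c(a = 1), k = 2), "exceeds")
})

test_that("degenerate matrices behave as identities", {
  cfg1 <- decision_config(
    criterion("c1", scale = rating_scale(0:4), weight = 1), "o1", top_k = 1)
  votes <- tibble::tibble(stakeholder = c("s1", "s2"), option = "o1",
                          criterion = "c1", score = c(1, 4))
  m <- build_matrix(cfg1, votes)
  expect_equal(m$options$total, 2.5)  # total = mean vote when weight is 1

  cfg2 <- random_config(3, 2, with_satisfice = FALSE)
  floor_votes <- expand.grid(stakeholder = c("s1", "s2"),
                             option = cfg2$options$id,
                             criterion = vapply(cfg2$criteria, `[[`, "", "id"),
                             stringsAsFactors = FALSE)
  floor_votes$score <- 0
  m2 <- build_matrix(cfg2, floor_votes)
  expect_equal(m2$options$total, rep(0, 3))
})

test_that("totals conserve the weight-by-mean dot product at full precision", {
  set.seed(21)
  for (i in 1:50) {
    cfg <- random_config(sample(2:5, 1), sample(2:4, 1))
    votes <- random_votes(cfg, sample(3:8, 1), participation = 0.8)
    m <- build_matrix(cfg, votes)
    w <- vapply(cfg$criteria, `[[`, numeric(1), "weight")
    for (o in cfg$options$id) {
      cc <- m$cells[m$cells$option == o, ]
      cc <- cc[match(vapply(cfg$criteria, `[[`, "", "id"), cc$criterion), ]
      expect_equal(m$options$total[m$options$option == o],
                   sum(w * cc$mean), tolerance = 1e-14)
    }
  }
})

test_that("raising a single vote never hurts that option's standing", {
  set.seed(31)
  for (i in 1:60) {
    cfg <- random_config(sample(2:4, 1), sample(2:3, 1),
                         with_satisfice = FALSE)
    votes <- tibble::as_tibble(random_votes(cfg, sample(2:5, 1)))
    m0 <- build_matrix(cfg, votes)
    r <- sample(nrow(votes), 1)
    cr <- NULL
    for (c0 in cfg$criteria) if (c0$id == votes$criterion[r]) cr <- c0
    higher <- cr$scale$codes[cr$scale$codes > votes$score[r]]
    if (length(higher) == 0) next
    votes2 <- votes
    votes2$score[r] <- higher[length(higher)]
    m1 <- build_matrix(cfg, votes2)
    o <- votes$option[r]
    expect_gte(m1$options$total[m1$options$option == o],
               m0$options$total[m0$options$option == o])
    # no other option overtakes it
    others <- setdiff(cfg$options$id, o)
    before <- m0$options$rank[m0$options$option == o]
    after <- m1$options$rank[m1$options$option == o]
    expect_lte(after, before)
  }
})

test_that("the matrix is invariant to vote-record order", {
  set.seed(41)
  for (i in 1:30) {
    cfg <- random_config(sample(2:4, 1), sample(2:3, 1))
    votes <- tibble::as_tibble(random_votes(cfg, 5, participation = 0.7))
    m1 <- build_matrix(cfg, votes)
    m2 <- build_matrix(cfg, votes[sample(nrow(votes)), ])
    expect_equal(m1$cells, m2$cells)
    expect_equal(m1$options, m2$options)
  }
})

test_that("build_matrix agrees with the brute-force oracle on small panels", {
  set.seed(51)
  for (n_s in 1:4) for (n_o in 1:3) for (n_c in 1:3) {
    for (rep in 1:2) {
      cfg <- random_config(n_o, n_c)
      votes <- random_votes(cfg, n_s)
      m <- build_matrix(cfg, votes, k = 1)
      oracle <- brute_force_matrix(cfg, votes)
      expect_equal(m$options$total, oracle$totals, tolerance = 1e-12)
      expect_equal(m$options$rank, oracle$rank)
      key_m <- paste(m$cells$option, m$cells$criterion)
      key_o <- paste(oracle$cells$option, oracle$cells$criterion)
      idx <- match(key_o, key_m)
      expect_equal(m$cells$mean[idx], oracle$cells$mean, tolerance = 1e-12)
      expect_equal(m$cells$weighted[idx], oracle$cells$weighted,
                   tolerance = 1e-12)
      expect_equal(m$cells$satisfice_met[idx], oracle$cells$satisfice_met)
    }
  }
})

test_that("vote validation pinpoints bad rows", {
  cfg <- ems_poc_criteria()
  ok <- tibble::tibble(stakeholder = "s1", option = "troponin_ami",
                       criterion = "care_pathway", score = 3)
  expect_silent(validate_votes(ok, cfg))
  bad <- ok; bad$score <- 7
  expect_error(validate_votes(bad, cfg), "row 1")
  dup <- dplyr::bind_rows(ok, ok)
  expect_error(validate_votes(dup, cfg), "duplicate")
  unk <- ok; unk$option <- "nope"
  expect_error(validate_votes(unk, cfg), "unknown option")
})

test_that("printed-matrix verification flags the irreconcilable weighting row", {
  cfg <- ems_poc_criteria()
  pm <- ems_poc_printed_matrix()
  v <- verify_printed_matrix(cfg, pm$cells, pm$totals)
  bad <- v$criteria[!v$criteria$consistent, ]
  expect_equal(bad$criterion, "care_pathway")
  expect_equal(bad$n_inconsistent, 5L)
  expect_equal(bad$implied_weight, 9.59, tolerance = 0.01)
  expect_true(all(v$criteria$consistent[v$criteria$criterion != "care_pathway"]))
  expect_true(all(v$totals$consistent))  # totals reconcile with rounding slack
})
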