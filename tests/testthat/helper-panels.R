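# Random-panel generators and an independent brute-force oracle.
# The oracle deliberately uses nothing from the package's scoring path:
# plain nested loops, base arithmetic, its own tail logic.

random_config <- function(n_options = 3, n_criteria = 3,
                          with_satisfice = TRUE) {
  criteria <- lapply(seq_len(n_criteria), function(i) {
    n_levels <- sample(3:5, 1)
    scale <- rating_scale(0:(n_levels - 1))
    sat <- satisfice_rule()
    if (with_satisfice && runif(1) < 0.4) {
      if (runif(1) < 0.5) {
        sat <- satisfice_rule(0:sample(0:(n_levels - 2), 1))
      } else {
        sat <- satisfice_rule(sample(1:(n_levels - 1), 1):(n_levels - 1))
      }
    }
    criterion(paste0("c", i), scale = scale,
              weight = round(runif(1, 0.1, 10), 2), satisfice = sat)
  })
  decision_config(criteria, paste0("o", seq_len(n_options)),
                  top_k = sample(seq_len(n_options), 1))
}

random_votes <- function(cfg, n_stakeholders = 4, participation = 1) {
  rows <- list()
  for (s in seq_len(n_stakeholders)) {
    for (o in cfg$options$id) {
      for (cr in cfg$criteria) {
        # stakeholder 1 always votes so no cell is ever empty
        if (s == 1 || runif(1) < participation) {
          rows[[length(rows) + 1]] <- data.frame(
            stakeholder = paste0("s", s), option = o, criterion = cr$id,
            score = sample(cr$scale$codes, 1)
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

# independent recomputation: means, weighted scores, totals, ranks, satisfice
brute_force_matrix <- function(cfg, votes) {
  opts <- cfg$options$id
  totals <- numeric(length(opts))
  cells <- list()
  for (i in seq_along(opts)) {
    for (cr in cfg$criteria) {
      scores <- c()
      for (r in seq_len(nrow(votes))) {
        if (votes$option[r] == opts[i] && votes$criterion[r] == cr$id) {
          scores <- c(scores, votes$score[r])
        }
      }
      m <- sum(scores) / length(scores)
      set <- cr$satisfice$excluded_codes
      met <- FALSE
      if (length(set) > 0) {
        if (min(cr$scale$codes) %in% set) {
          met <- m <= max(set)
        } else {
          met <- m >= min(set)
        }
      }
      f <- cr$weight * m
      totals[i] <- totals[i] + f
      cells[[length(cells) + 1]] <- data.frame(
        option = opts[i], criterion = cr$id, n = length(scores),
        mean = m, satisfice_met = met, weighted = f
      )
    }
  }
  # ranks by repeated max extraction, ties resolved to earliest index
  remaining <- seq_along(opts)
  rank <- integer(length(opts))
  pos <- 1
  while (length(remaining) > 0) {
    best <- remaining[which.max(totals[remaining])]
    rank[best] <- pos
    remaining <- setdiff(remaining, best)
    pos <- pos + 1
  }
  list(cells = do.call(rbind, cells), totals = totals, rank = rank)
}

# analytic mean of the clamp-then-round ordinal response model: category
# probabilities from normal mass between scale midpoints (tails collapse to
# the end codes). Independent of the generator's sampling path.
expected_ordinal_mean <- function(mu, sigma, codes) {
  mids <- (codes[-length(codes)] + codes[-1]) / 2
  p <- diff(stats::pnorm(c(-Inf, mids, Inf), mean = mu, sd = sigma))
  sum(codes * p)
}

ems_printed_means <- function() {
  pm <- ems_poc_printed_matrix()
  pm$cells[, c("option", "criterion", "mean")]
}
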