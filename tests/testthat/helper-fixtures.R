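# Shared fixture builders and independent oracles for the test suite.

make_participants <- function(n_more, n_less, prefix = "P") {
  n <- n_more + n_less
  data.frame(
    id = sprintf("%s%02d", prefix, seq_len(n)),
    laxity_label = c(rep("more", n_more), rep("less", n_less)),
    apparent_age = as.integer(seq(30, 60, length.out = n)),
    stringsAsFactors = FALSE)
}

# default-geometry cohort + schedule + responses, built once per session
.run_cache <- new.env(parent = emptyenv())

cached_pipeline_run <- function(seed = 1L) {
  key <- paste0("run_", seed)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_laxity_pipeline(laxity_config(), seed = seed)
  }
  .run_cache[[key]]
}

# independent tally oracle for collapse_orders: count, per pair, responses
# whose chosen participant is the "more"-labeled one
brute_tally <- function(responses, schedule, participants) {
  lab <- setNames(participants$laxity_label, participants$id)
  out <- list()
  for (r in seq_len(nrow(responses))) {
    ev <- schedule[schedule$event_id == responses$event_id[r], ]
    chosen <- if (responses$choice[r] == "A") ev$left_id else ev$right_id
    key <- ev$pair_key
    if (is.null(out[[key]])) out[[key]] <- c(k = 0, n = 0)
    out[[key]]["n"] <- out[[key]]["n"] + 1
    if (lab[[chosen]] == "more") out[[key]]["k"] <- out[[key]]["k"] + 1
  }
  out
}

# dense two-stage grid search maximizing the (penalized) Bradley-Terry
# log-likelihood for 3 items with s1 fixed at 0; independent of the Newton
# fitter. Returns the maximizing (s2, s3).
bt_grid_oracle_3 <- function(wins, lambda = 0, width = 4, step = 0.02) {
  ll <- function(s2, s3) {
    s <- c(0, s2, s3)
    P <- 1 / (1 + exp(-outer(s, s, "-")))
    idx <- wins > 0
    val <- sum(wins[idx] * log(P[idx]))
    if (lambda > 0) {
      sc <- s - mean(s)   # penalty on centered log-worths
      val <- val - lambda * sum(sc^2)
    }
    val
  }
  best <- c(0, 0)
  for (st in c(step, step / 10)) {
    g2 <- seq(best[1] - width, best[1] + width, by = st)
    g3 <- seq(best[2] - width, best[2] + width, by = st)
    vals <- outer(g2, g3, Vectorize(ll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(g2[ix[1]], g3[ix[2]])
    width <- 2 * st
  }
  best
}
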