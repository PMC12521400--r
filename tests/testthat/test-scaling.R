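make_summary <- function(pair_key, target, other, k, n,
                         correction = "haldane") {
  lg <- choice_logit(k, n, correction = correction)
  out <- data.frame(pair_key = pair_key, target_id = target,
                    nontarget_id = other, n_resp = n, k_t = k,
                    p_t = lg$p_t, logit_t = lg$logit_t,
                    binom_p = pair_binomial_test(k, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_summary", "data.frame")
  out
}

test_that("comparison data redistributes counts by the sigmoid of the corrected logit", {
  s <- make_summary("A|B", "A", "B", 72, 144)
  d <- build_comparison_data(s, mode = "sigmoid")
  expect_equal(d$wins["A", "B"], 72)
  expect_equal(d$wins["B", "A"], 72)

  # interior pair: both modes give the raw counts (sigma(log 3) = 0.75)
  s2 <- make_summary("A|B", "A", "B", 108, 144)
  for (m in c("sigmoid", "counts")) {
    d2 <- build_comparison_data(s2, mode = m)
    expect_equal(d2$wins["A", "B"], 108)
    expect_equal(d2$wins["B", "A"], 36)
  }

  # unanimous pair under Haldane: effective wins pulled off the boundary
  s3 <- make_summary("A|B", "A", "B", 144, 144)
  d3 <- build_comparison_data(s3, mode = "sigmoid")
  expect_gt(d3$wins["A", "B"], 143)
  expect_lt(d3$wins["A", "B"], 144)
  expect_equal(d3$raw_wins["A", "B"], 144)

  expect_error(build_comparison_data(rbind(s, s)), "duplicate pair_key")
})

test_that("two-item Bradley-Terry fit equals the closed-form win-odds", {
  s <- make_summary("A|B", "A", "B", 3, 4, correction = "none")
  d <- build_comparison_data(s, mode = "counts")
  fit <- fit_bradley_terry(d, prior_strength = 0)
  expect_equal(unname(fit$log_worth["A"] - fit$log_worth["B"]), log(3),
               tolerance = 1e-6)
  expect_equal(unname(fit$worth["A"] / fit$worth["B"]), 3, tolerance = 1e-5)
  expect_equal(mean(fit$log_worth), 0, tolerance = 1e-12)
})

test_that("balanced comparisons give all-zero log-worths", {
  s <- rbind(make_summary("A|B", "A", "B", 72, 144),
             make_summary("B|C", "B", "C", 72, 144),
             make_summary("A|C", "A", "C", 72, 144))
  fit <- fit_bradley_terry(build_comparison_data(s), prior_strength = 0.5)
  expect_equal(unname(fit$log_worth), c(0, 0, 0), tolerance = 1e-8)
})

test_that("three-item estimates match a dense grid-search oracle in probability space", {
  s <- rbind(make_summary("A|B", "A", "B", 9, 12, correction = "none"),
             make_summary("B|C", "B", "C", 8, 12, correction = "none"),
             make_summary("A|C", "A", "C", 10, 12, correction = "none"))
  d <- build_comparison_data(s, mode = "counts")

  for (lam in c(0, 0.5)) {
    fit <- fit_bradley_terry(d, prior_strength = lam)
    grid <- bt_grid_oracle_3(d$wins, lambda = lam)
    s_fit <- fit$log_worth - fit$log_worth["A"]
    p_fit <- stats::plogis(outer(s_fit, s_fit, "-"))
    s_gr <- c(A = 0, B = grid[1], C = grid[2])
    p_gr <- stats::plogis(outer(s_gr, s_gr, "-"))
    expect_lt(max(abs(p_fit - p_gr)), 1e-3)
  }
})

test_that("penalized log-likelihood ascends across iterations", {
  run <- cached_pipeline_run(1)
  trace <- attr(run$scale, "fit")$ll_trace
  expect_true(all(diff(trace) >= -1e-9))
  expect_true(attr(run$scale, "fit")$converged)
})

test_that("separation is detected exactly as zero-loss / zero-win raw records", {
  set.seed(17)
  for (rep in 1:5) {
    k <- 6
    ids <- LETTERS[1:k]
    rows <- list()
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      w <- sample(0:10, 1)
      rows[[length(rows) + 1]] <- make_summary(
        paste(ids[i], ids[j], sep = "|"), ids[i], ids[j], w, 10,
        correction = "haldane")
    }
    s <- do.call(rbind, rows)
    d <- build_comparison_data(s)
    fit <- fit_bradley_terry(d, prior_strength = 1)
    wins <- rowSums(d$raw_wins)
    losses <- colSums(d$raw_wins)
    expect_setequal(fit$separated_ids, ids[wins == 0 | losses == 0])
    expect_true(all(is.finite(fit$log_worth)))
  }
})

test_that("unpenalized fitting refuses separated data with guidance", {
  s <- make_summary("A|B", "A", "B", 10, 10, correction = "none")
  d <- build_comparison_data(s, mode = "counts")
  expect_error(fit_bradley_terry(d, prior_strength = 0), "separated")
})

test_that("FSLI is the affine transform of log-worth and preserves ranking", {
  s <- make_summary("A|B", "A", "B", 3, 4, correction = "none")
  fit <- fit_bradley_terry(build_comparison_data(s, mode = "counts"),
                           prior_strength = 0)
  expect_equal(compute_fsli(fit), fit$log_worth)

  f2 <- compute_fsli(fit, offset = 0.4, scale = 0.01)
  expect_equal(unname(f2["A"] - f2["B"]), 0.01 * log(3), tolerance = 1e-6)
  expect_identical(order(f2), order(fit$worth))
  expect_error(compute_fsli(fit, scale = 0), "degenerate")
})

test_that("laxity_scale marks separated items and applies the retention policy", {
  run <- cached_pipeline_run(1)
  sc <- run$scale
  expect_identical(nrow(sc), 64L)
  expect_equal(mean(sc$log_worth), 0, tolerance = 1e-6)
  expect_equal(sc$worth, exp(sc$log_worth))
  expect_identical(sc$retained, !sc$separated)
})
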