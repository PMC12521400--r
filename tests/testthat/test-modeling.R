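test_that("VIF screen keeps orthogonal columns and matches an independent oracle", {
  # exactly orthogonal, mean-centered columns: all VIFs are 1
  Q <- unclass(stats::poly(1:200, 4))
  tab <- data.frame(id = sprintf("P%03d", 1:200), A = Q[, 1], B = Q[, 2],
                    C = Q[, 3], D = Q[, 4])
  scr <- vif_screen(tab, a_priori_exclusions = character(0))
  expect_equal(unname(scr$vif), rep(1, 4), tolerance = 1e-10)
  expect_identical(scr$dropped, character(0))

  # one column is (almost) the sum of two others: large VIF, dropped; the
  # reported VIFs equal the closed-form 1/(1 - R^2) from the correlation
  # matrix inverse (independent of the per-column regression route)
  set.seed(6)
  n <- 150
  X <- data.frame(id = sprintf("P%03d", 1:n), A = rnorm(n), B = rnorm(n),
                  C = rnorm(n), D = rnorm(n))
  X$E <- X$A + X$B + rnorm(n, sd = 0.1)
  vifs_oracle <- diag(solve(stats::cor(as.matrix(X[-1]))))
  scr2 <- vif_screen(X, threshold = 5, a_priori_exclusions = character(0))
  expect_true("E" %in% scr2$dropped || "A" %in% scr2$dropped ||
                "B" %in% scr2$dropped)
  expect_gt(max(vifs_oracle), 5)
  # before any removal the implementation's VIFs equal the oracle
  impl <- laxipair:::.compute_vifs(as.matrix(X[-1]))
  expect_equal(unname(impl), unname(vifs_oracle), tolerance = 1e-8)
  expect_true(all(scr2$vif < 5))
})

test_that("an exactly duplicated column gets infinite VIF and one copy is dropped", {
  set.seed(7)
  n <- 60
  tab <- data.frame(id = sprintf("P%02d", 1:n), A1 = rnorm(n), B = rnorm(n),
                    C = rnorm(n))
  tab$A2 <- tab$A1
  scr <- vif_screen(tab, a_priori_exclusions = character(0))
  expect_identical(scr$dropped, "A1")   # alphabetical tie-break
  expect_true("A2" %in% scr$retained)
})

test_that("a-priori exclusions are removed before screening", {
  run <- cached_pipeline_run(1)
  scr <- vif_screen(run$table)
  expect_identical(scr$dropped[1:2], c("F3", "R5"))
  expect_false(any(c("F3", "R5") %in% scr$retained))
  expect_true(all(scr$vif < 5))
})

test_that("a noise-free linear target is recovered almost perfectly", {
  set.seed(11)
  n <- 40
  tab <- data.frame(id = sprintf("P%02d", 1:n), X1 = rnorm(n, sd = 3),
                    X2 = rnorm(n))
  fsli <- setNames(tab$X1, tab$id)
  fit <- fit_fsli_model(tab, fsli, features = "X1")
  expect_gt(fit$r_squared, 0.99)
  expect_gt(fit$pearson_r, 0.99)
  expect_lt(fit$pearson_p, 1e-10)
})

test_that("degenerate targets and zero-variance features are flagged", {
  set.seed(12)
  n <- 20
  tab <- data.frame(id = sprintf("P%02d", 1:n), X1 = rnorm(n), X2 = 1)
  const <- setNames(rep(0.5, n), tab$id)
  expect_warning(
    fit0 <- fit_fsli_model(tab[c("id", "X1")], const, features = "X1"),
    "degenerate target")
  expect_lte(fit0$r_squared, 0)

  fsli <- setNames(tab$X1 + rnorm(n, sd = 0.1), tab$id)
  expect_warning(fit_fsli_model(tab, fsli, features = c("X1", "X2")),
                 "zero-variance")
  expect_error(fit_fsli_model(tab[1:2, ], fsli[1:2], features = "X1"),
               "insufficient")
})

test_that("LOO predictions are invariant to row order and to feature rescaling", {
  set.seed(13)
  n <- 30
  tab <- data.frame(id = sprintf("P%02d", 1:n), X1 = rnorm(n), X2 = rnorm(n))
  fsli <- setNames(tab$X1 - 0.5 * tab$X2 + rnorm(n, sd = 0.2), tab$id)
  fit <- fit_fsli_model(tab, fsli, features = c("X1", "X2"))

  perm <- sample.int(n)
  fit_p <- fit_fsli_model(tab[perm, ], fsli, features = c("X1", "X2"))
  expect_equal(fit_p$loo_predictions[names(fit$loo_predictions)],
               fit$loo_predictions, tolerance = 1e-9)

  tab2 <- tab
  tab2$X1 <- tab2$X1 * 1000
  fit_s <- fit_fsli_model(tab2, fsli, features = c("X1", "X2"))
  expect_equal(fit_s$loo_predictions, fit$loo_predictions, tolerance = 1e-3)
})

test_that("forward selection respects the collinearity screen and the physiological signs hold", {
  run <- cached_pipeline_run(1)
  scr <- run$vif
  expect_true(all(run$fit$feature_names %in% scr$retained))
  expect_identical(length(run$fit$feature_names), 8L)

  # laxity is negatively associated with elasticity R2, positively with F4
  tab <- run$table
  fsli <- setNames(run$scale$fsli, run$scale$id)
  expect_lt(cor(fsli[tab$id], tab$R2, method = "spearman"), 0)
  expect_gt(cor(fsli[tab$id], tab$F4, method = "spearman"), 0)
})

test_that("distribution report matches hand computation and flags untestable columns", {
  v <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  tab <- data.frame(id = paste0("P", 1:5), A = v, B = rep(2, 5))
  rep_ <- distribution_report(tab)
  a <- rep_[rep_$parameter == "A", ]
  expect_equal(a$mean, mean(v))
  expect_equal(a$sd, sqrt(sum((v - mean(v))^2) / 4))
  expect_true(a$normality_tested)
  b <- rep_[rep_$parameter == "B", ]
  expect_false(b$normality_tested)
  expect_true(is.na(b$shapiro_p))
})

test_that("the normality test holds its level under the null and rejects a skewed alternative", {
  set.seed(21)
  null_p <- replicate(100, {
    x <- rnorm(5000)
    distribution_report(data.frame(id = seq_along(x), A = x))$shapiro_p
  })
  expect_gte(mean(null_p > 0.05), 0.90)

  set.seed(22)
  alt_p <- replicate(100, {
    x <- rexp(500)
    distribution_report(data.frame(id = seq_along(x), A = x))$shapiro_p
  })
  expect_gte(mean(alt_p < 0.01), 0.95)
})
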