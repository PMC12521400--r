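test_that("choice logit matches direct evaluation and stays finite at the boundary", {
  expect_equal(choice_logit(72, 144)$logit_t, 0)
  expect_equal(choice_logit(108, 144)$logit_t, log(3), tolerance = 1e-12)

  # unanimous pair under the Haldane-Anscombe correction:
  # P = 144.5/145, odds = 289
  un <- choice_logit(144, 144)
  expect_equal(un$p_t, 144.5 / 145)
  expect_equal(un$logit_t, log(289), tolerance = 1e-12)
  expect_true(is.finite(choice_logit(0, 144)$logit_t))

  # interior pairs untouched by the default correction
  expect_equal(choice_logit(100, 144)$p_t, 100 / 144)

  # 'always' perturbs interior pairs, 'clamp' clips, 'none' diverges
  expect_equal(choice_logit(108, 144, "always")$p_t, 108.5 / 145)
  expect_equal(choice_logit(144, 144, "clamp", eps = 0.01)$p_t, 0.99)
  expect_identical(choice_logit(144, 144, "none")$logit_t, Inf)

  expect_error(choice_logit(1, 0), "n_resp")
  expect_error(choice_logit(5, 4), "k_t")
})

test_that("logit is antisymmetric and sigmoid inverts it for every count", {
  n <- 144L
  for (corr in c("haldane", "always", "clamp")) {
    res <- choice_logit(0:n, rep(n, n + 1L), correction = corr)
    expect_equal(res$logit_t, -rev(res$logit_t), tolerance = 1e-12)
    expect_equal(stats::plogis(res$logit_t), res$p_t, tolerance = 1e-12)
    expect_true(all(is.finite(res$logit_t)))
  }
})

test_that("per-pair binomial test agrees with exact tail enumeration", {
  expect_equal(pair_binomial_test(10, 20), 1)
  expect_equal(pair_binomial_test(20, 20), 2 * 0.5^20, tolerance = 1e-12)

  # two-tailed p at k = 15, n = 20: sum of pmf values no larger than dbinom(15)
  pmf <- dbinom(0:20, 20, 0.5)
  oracle <- sum(pmf[pmf <= dbinom(15, 20, 0.5) * (1 + 1e-7)])
  expect_equal(pair_binomial_test(15, 20), oracle, tolerance = 1e-10)
})

test_that("collapsing orders pools both presentations into position-independent counts", {
  p <- make_participants(2, 2)
  p$group_id <- 1L
  sched <- presentation_schedule(p, seed = 3)
  expect_identical(nrow(sched), 8L)

  # one evaluator always choosing the 'more' member twice per pair
  lab <- setNames(p$laxity_label, p$id)
  resp <- data.frame(
    evaluator_id = "E1", background = "lay", event_id = sched$event_id,
    choice = ifelse(lab[sched$left_id] == "more", "A", "B"),
    stringsAsFactors = FALSE)
  summ <- collapse_orders(resp, sched, p)
  expect_identical(nrow(summ), 4L)
  expect_true(all(summ$n_resp == 2L))
  expect_true(all(summ$k_t == 2L))

  expect_error(
    collapse_orders(transform(resp, event_id = "ZZZ"), sched, p),
    "unknown event")
})

test_that("pooled counts equal an independent brute-force tally on a random fixture", {
  set.seed(99)
  p <- make_participants(3, 3)
  p$group_id <- 1L
  sched <- presentation_schedule(p, seed = 5)
  ev_ids <- rep(sched$event_id, times = 5)
  resp <- data.frame(
    evaluator_id = rep(sprintf("E%d", 1:5), each = nrow(sched)),
    background = "lay", event_id = ev_ids,
    choice = sample(c("A", "B"), 5 * nrow(sched), replace = TRUE),
    stringsAsFactors = FALSE)
  summ <- collapse_orders(resp, sched, p)
  oracle <- brute_tally(resp, sched, p)
  for (i in seq_len(nrow(summ))) {
    expect_equal(unname(oracle[[summ$pair_key[i]]]["k"]), summ$k_t[i])
    expect_equal(unname(oracle[[summ$pair_key[i]]]["n"]), summ$n_resp[i])
  }

  # pooling is invariant to response-row order
  shuffled <- resp[sample.int(nrow(resp)), ]
  expect_equal(collapse_orders(shuffled, sched, p), summ)
})

test_that("evaluator kappa is 1 on perfect agreement and 0 at chance-level agreement", {
  p <- make_participants(2, 2)
  p$group_id <- 1L
  sched <- presentation_schedule(p, seed = 3)
  lab <- setNames(p$laxity_label, p$id)
  key <- ifelse(lab[sched$left_id] == "more", "A", "B")

  perfect <- data.frame(evaluator_id = "E1", background = "professional",
                        event_id = sched$event_id, choice = unname(key),
                        stringsAsFactors = FALSE)
  res <- evaluator_kappa(perfect, sched, p)
  expect_equal(res$per_evaluator$kappa, 1)

  # agree on half the events with balanced margins: kappa exactly 0
  # flip half of the A-events and half of the B-events: observed agreement
  # 0.5 with 4/4 margins on both sides, so expected agreement is also 0.5
  half <- key
  a_idx <- which(key == "A")
  b_idx <- which(key == "B")
  half[a_idx[1:2]] <- "B"
  half[b_idx[1:2]] <- "A"
  chance <- data.frame(evaluator_id = "E1", background = "professional",
                       event_id = sched$event_id, choice = unname(half),
                       stringsAsFactors = FALSE)
  res0 <- evaluator_kappa(chance, sched, p)
  expect_equal(res0$per_evaluator$kappa, 0)
})

test_that("kappa stays in [-1, 1], the CI brackets the mean, and identical subgroups do not differ", {
  run <- cached_pipeline_run(1)
  conc <- run$concordance
  expect_true(all(conc$per_evaluator$kappa >= -1 & conc$per_evaluator$kappa <= 1))
  expect_lte(conc$ci95[1], conc$mean_kappa)
  expect_gte(conc$ci95[2], conc$mean_kappa)
  expect_identical(nrow(conc$per_evaluator), 72L)

  # same kappa vector in both backgrounds: rank test cannot separate them
  p <- make_participants(2, 2)
  p$group_id <- 1L
  sched <- presentation_schedule(p, seed = 3)
  lab <- setNames(p$laxity_label, p$id)
  key <- ifelse(lab[sched$left_id] == "more", "A", "B")
  resp <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(evaluator_id = paste0("E", i),
               background = if (i <= 2) "professional" else "lay",
               event_id = sched$event_id, choice = unname(key),
               stringsAsFactors = FALSE)
  }))
  same <- evaluator_kappa(resp, sched, p)
  expect_gte(same$subgroup_p, 0.99)
})
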