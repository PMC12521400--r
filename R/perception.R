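#' Log-odds of selecting the target in a pooled 2-AFC pair
#'
#' Converts pooled choice counts for one pair into the choice probability
#' \eqn{P_T} and its logit
#' \deqn{\mathrm{Logit}(T) = \ln\!\left(\frac{P_T}{1-P_T}\right),}
#' the log odds of selecting the target (the "more facial skin laxity"
#' member of the pair). Unanimous pairs would give infinite logits, so a
#' boundary correction is applied:
#' \describe{
#'   \item{`"haldane"`}{(default) the Haldane-Anscombe correction
#'     \eqn{P_T = (k_T + 0.5)/(n + 1)}, applied only when
#'     \eqn{k_T \in \{0, n\}}; interior pairs are untouched.}
#'   \item{`"always"`}{the same pseudo-count correction applied to every pair.}
#'   \item{`"clamp"`}{\eqn{P_T = k_T/n} clipped to \eqn{[\epsilon, 1-\epsilon]}.}
#'   \item{`"none"`}{raw proportion; unanimous pairs yield infinite logits.}
#' }
#'
#' @param k_t number of responses selecting the target, `0 <= k_t <= n_resp`.
#' @param n_resp total pooled responses for the pair (both presentation
#'   orders), at least 1. Vectorized over `k_t`/`n_resp`.
#' @param correction boundary-correction rule, see Details.
#' @param eps clip width for `correction = "clamp"`.
#' @return data frame with columns `p_t` and `logit_t`.
#' @examples
#' choice_logit(108, 144)   # P_T = 0.75, logit = log(3)
#' choice_logit(144, 144)   # unanimous: finite via Haldane-Anscombe
#' @export
choice_logit <- function(k_t, n_resp,
                         correction = c("haldane", "always", "clamp", "none"),
                         eps = 0.005) {
  correction <- match.arg(correction)
  if (any(n_resp < 1L)) stop("empty pair: n_resp must be at least 1")
  if (any(k_t < 0L) || any(k_t > n_resp)) {
    stop("k_t must lie in [0, n_resp]")
  }
  p <- k_t / n_resp
  p <- switch(correction,
    haldane = ifelse(k_t == 0L | k_t == n_resp,
                     (k_t + 0.5) / (n_resp + 1), p),
    always = (k_t + 0.5) / (n_resp + 1),
    clamp = pmin(pmax(p, eps), 1 - eps),
    none = p)
  data.frame(p_t = p, logit_t = log(p / (1 - p)))
}

#' Exact two-tailed binomial test of a pooled pair against chance
#'
#' Tests whether the pooled choice count for a pair departs from the
#' no-difference probability 0.5, using the exact binomial distribution.
#'
#' @param k_t,n_resp pooled target-choice count and total (vectorized).
#' @return vector of two-tailed p-values.
#' @export
pair_binomial_test <- function(k_t, n_resp) {
  if (any(n_resp < 1L)) stop("empty pair: n_resp must be at least 1")
  mapply(function(k, n) stats::binom.test(k, n, p = 0.5)$p.value, k_t, n_resp)
}

#' Pool 2-AFC responses over presentation orders into per-pair summaries
#'
#' Maps each positional choice (A/B) back to a participant id via the
#' schedule, then pools the normal-order and swapped-order responses of each
#' pair into a single count pair \eqn{(k_T, n)}: position-independent
#' averaging of the two orders. For the default geometry (72 evaluators x
#' 256 events) this produces 128 pair summaries of 144 responses each.
#'
#' @param responses data frame with columns `evaluator_id`, `background`,
#'   `event_id`, `choice` (`"A"` = left judged more lax, `"B"` = right).
#' @param schedule presentation schedule from [presentation_schedule()].
#' @param participants participant table with `id` and `laxity_label`,
#'   used to designate the target (the "more"-labeled member) of each pair.
#' @param correction,eps passed to [choice_logit()].
#' @return data frame of class `pair_summary` with one row per pair:
#'   `pair_key`, `target_id`, `nontarget_id`, `n_resp`, `k_t`, `p_t`,
#'   `logit_t`, `binom_p`.
#' @export
collapse_orders <- function(responses, schedule, participants,
                            correction = "haldane", eps = 0.005) {
  .check_participants(participants)
  req <- c("evaluator_id", "event_id", "choice")
  miss <- setdiff(req, names(responses))
  if (length(miss)) {
    stop("response table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(responses$choice %in% c("A", "B"))) {
    stop("choice must be 'A' or 'B'")
  }
  orphan <- setdiff(unique(responses$event_id), schedule$event_id)
  if (length(orphan)) {
    stop("responses reference unknown event(s): ",
         paste(orphan, collapse = ", "))
  }
  if (anyDuplicated(responses[c("evaluator_id", "event_id")])) {
    stop("duplicate (evaluator_id, event_id) response rows")
  }
  idx <- match(responses$event_id, schedule$event_id)
  chosen <- ifelse(responses$choice == "A",
                   schedule$left_id[idx], schedule$right_id[idx])
  pair_key <- schedule$pair_key[idx]

  label_of <- stats::setNames(participants$laxity_label, participants$id)
  # target of a pair = its "more"-labeled member
  keys <- unique(schedule$pair_key)
  left_lab <- label_of[schedule$left_id[match(keys, schedule$pair_key)]]
  target <- ifelse(left_lab == "more",
                   schedule$left_id[match(keys, schedule$pair_key)],
                   schedule$right_id[match(keys, schedule$pair_key)])
  other <- ifelse(left_lab == "more",
                  schedule$right_id[match(keys, schedule$pair_key)],
                  schedule$left_id[match(keys, schedule$pair_key)])

  n_resp <- as.integer(table(factor(pair_key, keys)))
  k_t <- as.integer(table(factor(pair_key[chosen == target[match(pair_key, keys)]],
                                 keys)))
  lg <- choice_logit(k_t, n_resp, correction = correction, eps = eps)
  out <- data.frame(pair_key = keys, target_id = unname(target),
                    nontarget_id = unname(other),
                    n_resp = n_resp, k_t = k_t,
                    p_t = lg$p_t, logit_t = lg$logit_t,
                    binom_p = pair_binomial_test(k_t, n_resp),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pair_key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_summary", "data.frame")
  out
}

# Cohen's kappa for two binary ratings; convention: degenerate identical
# margins with perfect agreement give kappa = 1.
.cohen_kappa <- function(rating, key) {
  stopifnot(length(rating) == length(key))
  n <- length(rating)
  po <- mean(rating == key)
  lev <- unique(c(rating, key))
  pe <- sum(vapply(lev, function(l) mean(rating == l) * mean(key == l),
                   numeric(1)))
  if (1 - pe < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Consumer-expert concordance via per-evaluator Cohen's kappa
#'
#' For each evaluator, compares their positional choices against the expert
#' "standard answer" key (the position of the "more"-labeled participant in
#' each event) with Cohen's kappa, then summarizes across evaluators with a
#' mean and t-based 95% confidence interval, per-background means, and a
#' two-tailed Mann-Whitney U comparison of the professional and lay groups.
#'
#' @inheritParams collapse_orders
#' @param conf_level confidence level for the t interval across evaluators.
#' @return object of class `concordance_result`: list with
#'   `per_evaluator` (data frame: `evaluator_id`, `background`, `n_events`,
#'   `kappa`), `mean_kappa`, `ci95`, `subgroup_means`, `subgroup_p`.
#' @export
evaluator_kappa <- function(responses, schedule, participants,
                            conf_level = 0.95) {
  .check_participants(participants)
  label_of <- stats::setNames(participants$laxity_label, participants$id)
  key <- ifelse(label_of[schedule$left_id] == "more", "A", "B")
  names(key) <- schedule$event_id

  split_resp <- split(responses, responses$evaluator_id)
  rows <- lapply(split_resp, function(df) {
    if (nrow(df) < 2L) {
      warning("evaluator '", df$evaluator_id[1L],
              "' judged fewer than 2 events; excluded from kappa analysis")
      return(NULL)
    }
    data.frame(evaluator_id = df$evaluator_id[1L],
               background = if ("background" %in% names(df))
                 df$background[1L] else NA_character_,
               n_events = nrow(df),
               kappa = .cohen_kappa(df$choice, unname(key[df$event_id])),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(per) <- NULL
  m <- mean(per$kappa)
  if (nrow(per) >= 2L) {
    se <- stats::sd(per$kappa) / sqrt(nrow(per))
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = nrow(per) - 1L)
    ci <- c(m - tq * se, m + tq * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  sub_means <- tapply(per$kappa, per$background, mean)
  groups <- split(per$kappa, per$background)
  sub_p <- NA_real_
  if (length(groups) == 2L) {
    exact <- min(lengths(groups)) < 8L
    sub_p <- suppressWarnings(
      stats::wilcox.test(groups[[1L]], groups[[2L]],
                         alternative = "two.sided", exact = exact,
                         correct = !exact)$p.value)
    # fully tied samples defeat the normal approximation; report the
    # rank test's maximal value
    if (is.na(sub_p)) sub_p <- 1
  }
  structure(
    list(per_evaluator = per, mean_kappa = m, ci95 = ci,
         subgroup_means = sub_means, subgroup_p = sub_p),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Consumer-expert concordance over %d evaluators\n",
              nrow(x$per_evaluator)))
  if (!anyNA(x$ci95)) {
    cat(sprintf("  mean Cohen's kappa = %.3f, 95%% CI [%.3f, %.3f]\n",
                x$mean_kappa, x$ci95[1L], x$ci95[2L]))
  } else {
    cat(sprintf("  mean Cohen's kappa = %.3f\n", x$mean_kappa))
  }
  if (length(x$subgroup_means)) {
    for (b in names(x$subgroup_means)) {
      cat(sprintf("  %-12s mean kappa = %.3f\n", b, x$subgroup_means[[b]]))
    }
    cat(sprintf("  background difference: Mann-Whitney U p = %.3g\n",
                x$subgroup_p))
  }
  invisible(x)
}
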