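#' Assemble Bradley-Terry comparison data from pair summaries
#'
#' Converts pooled pair summaries into the win/loss structure the
#' Bradley-Terry model consumes. Two modes are available:
#' \describe{
#'   \item{`"sigmoid"`}{(default) the pooled count of each pair is
#'     redistributed by the sigmoid of the (boundary-corrected) logit:
#'     effective wins are \eqn{n \,\sigma(\mathrm{Logit}(T))} and
#'     \eqn{n\,(1-\sigma(\mathrm{Logit}(T)))}. Because
#'     \eqn{\sigma(\mathrm{Logit}(T)) = P_T}, this equals the raw counts
#'     whenever no boundary correction fired, and pulls unanimous pairs
#'     slightly off the boundary when one did.}
#'   \item{`"counts"`}{raw integer wins \eqn{(k_T,\; n-k_T)}.}
#' }
#' The raw counts are always retained alongside for separation detection.
#'
#' @param summaries `pair_summary` data frame from [collapse_orders()].
#' @param mode `"sigmoid"` or `"counts"`.
#' @return object of class `comparison_data`: list with `items` (ids),
#'   `wins` (matrix of effective wins, `wins[i, j]` = i judged more lax than
#'   j), and `raw_wins` (uncorrected integer counts).
#' @export
build_comparison_data <- function(summaries, mode = c("sigmoid", "counts")) {
  mode <- match.arg(mode)
  if (nrow(summaries) == 0L) stop("no pair summaries supplied")
  if (anyDuplicated(summaries$pair_key)) {
    stop("duplicate pair_key in summaries; aggregate before scaling")
  }
  items <- sort(unique(c(summaries$target_id, summaries$nontarget_id)))
  k <- length(items)
  wins <- matrix(0, k, k, dimnames = list(items, items))
  raw <- matrix(0, k, k, dimnames = list(items, items))
  ti <- match(summaries$target_id, items)
  oi <- match(summaries$nontarget_id, items)
  p_eff <- if (mode == "sigmoid") stats::plogis(summaries$logit_t)
           else summaries$k_t / summaries$n_resp
  wins[cbind(ti, oi)] <- summaries$n_resp * p_eff
  wins[cbind(oi, ti)] <- summaries$n_resp * (1 - p_eff)
  raw[cbind(ti, oi)] <- summaries$k_t
  raw[cbind(oi, ti)] <- summaries$n_resp - summaries$k_t
  structure(list(items = items, wins = wins, raw_wins = raw),
            class = "comparison_data")
}

.bt_loglik <- function(s, wins, lambda) {
  P <- stats::plogis(outer(s, s, "-"))
  idx <- wins > 0
  sum(wins[idx] * log(P[idx])) - lambda * sum(s^2)
}

#' Fit the (ridge-penalized) Bradley-Terry model
#'
#' Maximizes the Bradley-Terry log-likelihood
#' \deqn{\ell(s) = \sum_{i \ne j} w_{ij} \ln \frac{\pi_i}{\pi_i + \pi_j},
#'   \qquad \pi_i = e^{s_i},}
#' optionally plus a Gaussian ridge penalty \eqn{-\lambda \sum_i s_i^2} on
#' the log-worths, by damped Newton iteration with an ascent guarantee.
#' With \eqn{\lambda = 0} the solution is pinned by centering the
#' log-worths to mean zero; with \eqn{\lambda > 0} the penalty itself pins
#' the location (the optimum has mean-zero log-worths) and keeps all
#' estimates finite even for separated items.
#'
#' Items that win every comparison or lose every comparison (by raw counts)
#' have an infinite unpenalized maximum-likelihood estimate; they are
#' reported in `separated_ids`, and the fit refuses to run with
#' `prior_strength = 0` in their presence.
#'
#' @param data `comparison_data` from [build_comparison_data()].
#' @param prior_strength ridge weight \eqn{\lambda \ge 0}; `NULL` (default)
#'   uses \eqn{0.01 \times} the mean number of comparisons per item.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @return object of class `laxity_scale_result`: list with `items`,
#'   `worth` (\eqn{\pi_i}), `log_worth` (mean zero over all items), `fsli`
#'   (identity transform of `log_worth`; see [compute_fsli()]), `converged`,
#'   `n_iterations`, `ll_trace` (penalized log-likelihood per iteration),
#'   `separated_ids`, `prior_strength`.
#' @export
fit_bradley_terry <- function(data, prior_strength = NULL, tol = 1e-8,
                              max_iter = 1000L) {
  stopifnot(inherits(data, "comparison_data"))
  W <- data$wins
  k <- length(data$items)
  if (k < 2L) stop("need at least 2 items to scale")
  N <- W + t(W)
  if (is.null(prior_strength)) prior_strength <- 0.01 * mean(rowSums(N))
  if (prior_strength < 0) stop("prior_strength must be >= 0")
  lambda <- prior_strength

  raw_w <- rowSums(data$raw_wins)
  raw_l <- colSums(data$raw_wins)
  separated <- data$items[(raw_w == 0 | raw_l == 0) & (raw_w + raw_l) > 0]
  if (lambda == 0 && length(separated)) {
    stop("separated item(s) with infinite unpenalized estimates: ",
         paste(separated, collapse = ", "),
         "; use prior_strength > 0 or exclude them")
  }

  s <- rep(0, k)
  ll <- .bt_loglik(s, W, lambda)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    P <- stats::plogis(outer(s, s, "-"))
    diag(P) <- 0
    g <- rowSums(W) - rowSums(N * P) - 2 * lambda * s
    g_chk <- if (lambda == 0) g - mean(g) else g
    if (max(abs(g_chk)) < tol) {
      converged <- TRUE
      break
    }
    Hoff <- N * P * t(P)
    H <- Hoff
    diag(H) <- -rowSums(Hoff)
    H <- H - diag(2 * lambda, k)
    if (lambda == 0) {
      # remove the null (common-shift) direction; the step is recentered below
      H <- H - (mean(abs(diag(H))) + 1) / k
    }
    delta <- solve(-H, g)
    step <- 1
    repeat {
      s_new <- s + step * delta
      if (lambda == 0) s_new <- s_new - mean(s_new)
      ll_new <- .bt_loglik(s_new, W, lambda)
      if (ll_new >= ll - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    s <- s_new
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
  }
  if (!converged) {
    stop("Bradley-Terry fit did not converge in ", max_iter,
         " iterations (last penalized log-likelihood ", format(ll), ")")
  }
  if (lambda == 0) s <- s - mean(s)
  names(s) <- data$items
  structure(
    list(items = data$items, worth = exp(s), log_worth = s, fsli = s,
         converged = converged, n_iterations = iter, ll_trace = ll_trace,
         separated_ids = separated, prior_strength = lambda),
    class = "laxity_scale_result")
}

#' @export
print.laxity_scale_result <- function(x, ...) {
  cat(sprintf("Bradley-Terry laxity scale: %d items, lambda = %.4g\n",
              length(x$items), x$prior_strength))
  cat(sprintf("  converged in %d iterations; penalized log-likelihood %.4f\n",
              x$n_iterations, x$ll_trace[length(x$ll_trace)]))
  cat(sprintf("  log-worth range [%.3f, %.3f]\n",
              min(x$log_worth), max(x$log_worth)))
  if (length(x$separated_ids)) {
    cat("  separated (always-winning/always-losing) items: ",
        paste(x$separated_ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Facial Skin Laxity Index from Bradley-Terry worths
#'
#' The FSLI is an affine transform of the log Bradley-Terry worth,
#' \eqn{\mathrm{FSLI}_i = \mathrm{offset} + \mathrm{scale} \cdot \ln \pi_i}.
#' The defaults (offset 0, scale 1) make the FSLI the centered log-worth;
#' any positive scale preserves the convention that higher FSLI means more
#' facial skin laxity.
#'
#' @param result `laxity_scale_result` from [fit_bradley_terry()].
#' @param offset,scale affine transform parameters; `scale` must be nonzero.
#' @return named numeric vector of FSLI values.
#' @export
compute_fsli <- function(result, offset = 0, scale = 1) {
  stopifnot(inherits(result, "laxity_scale_result"))
  if (scale == 0) stop("degenerate transform: scale must be nonzero")
  if (any(!is.finite(result$worth)) || any(result$worth <= 0)) {
    stop("worths must be positive and finite")
  }
  offset + scale * log(result$worth)
}

#' One-call scaling of pair summaries into FSLI values
#'
#' Convenience wrapper: [build_comparison_data()] then
#' [fit_bradley_terry()] then [compute_fsli()], with the separation policy
#' applied. Policy `"drop"` (default) marks separated items so downstream
#' modeling can exclude them; `"shrink"` retains every item under the ridge
#' prior.
#'
#' @inheritParams build_comparison_data
#' @inheritParams fit_bradley_terry
#' @param separation `"drop"` or `"shrink"`.
#' @param offset,scale passed to [compute_fsli()].
#' @return data frame with columns `id`, `worth`, `log_worth`, `fsli`,
#'   `separated`, `retained`; the fit object is attached as attribute
#'   `"fit"`.
#' @export
laxity_scale <- function(summaries, mode = "sigmoid", prior_strength = NULL,
                         separation = c("drop", "shrink"),
                         offset = 0, scale = 1, tol = 1e-8,
                         max_iter = 1000L) {
  separation <- match.arg(separation)
  data <- build_comparison_data(summaries, mode = mode)
  fit <- fit_bradley_terry(data, prior_strength = prior_strength,
                           tol = tol, max_iter = max_iter)
  fsli <- compute_fsli(fit, offset = offset, scale = scale)
  sep <- fit$items %in% fit$separated_ids
  out <- data.frame(id = fit$items, worth = unname(fit$worth),
                    log_worth = unname(fit$log_worth),
                    fsli = unname(fsli), separated = sep,
                    retained = if (separation == "drop") !sep else TRUE,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "separation") <- separation
  out
}
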