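#' Minimum number of evaluators for a one-sided 2-AFC discrimination test
#'
#' Computes the minimum evaluator count for a paired-comparison
#' (two-alternative forced choice) test from the normal approximation of the
#' binomial distribution,
#' \deqn{n \approx \left(\frac{z_{1-\alpha}\sqrt{p_0(1-p_0)} +
#'   z_{1-\beta}\sqrt{p_1(1-p_1)}}{p_1 - p_0}\right)^2,}
#' where \eqn{p_0 = 0.5} is the probability of a correct choice when the two
#' stimuli do not differ and \eqn{p_1 = p_d + (1-p_d) \cdot 0.5} is the
#' probability of a correct choice when they do, given that a proportion
#' \eqn{p_d} of evaluators can detect the difference (the remainder guess).
#'
#' @param alpha one-sided false-positive rate, in (0, 1).
#' @param beta false-negative rate, in [0, 1). `beta = 0.5` gives
#'   \eqn{z_{1-\beta} = 0}.
#' @param pd proportion of discriminators, in (0, 1]. `pd = 0` makes
#'   \eqn{p_1 = p_0} and is rejected as degenerate.
#' @param exact_quantiles logical; if `FALSE` (default) normal quantiles are
#'   rounded to two decimals (e.g. \eqn{z_{0.95} = 1.64}), the convention used
#'   in sensory-evaluation practice. If `TRUE`, full-precision
#'   [stats::qnorm()] quantiles are used.
#'
#' @return An object of class `sample_size_spec`: a list with fields
#'   `alpha`, `beta`, `pd`, `p0`, `p1`, `z_alpha`, `z_beta`, `n_raw`
#'   (unrounded evaluator count) and `n_min` (`ceiling(n_raw)`).
#'
#' @examples
#' minimum_evaluators(alpha = 0.05, beta = 0.5, pd = 0.20)
#' @export
minimum_evaluators <- function(alpha = 0.05, beta = 0.5, pd = 0.20,
                               exact_quantiles = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(pd), length(pd) == 1L)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (beta < 0 || beta >= 1) stop("'beta' must lie in [0, 1)")
  if (pd < 0 || pd > 1) stop("'pd' must lie in [0, 1]")
  if (pd == 0) {
    stop("degenerate input: pd = 0 makes p1 = p0 and the formula divides by zero")
  }
  z_alpha <- stats::qnorm(1 - alpha)
  z_beta <- stats::qnorm(1 - beta)
  if (!exact_quantiles) {
    z_alpha <- round(z_alpha, 2)
    z_beta <- round(z_beta, 2)
  }
  p0 <- 0.5
  p1 <- pd + (1 - pd) * 0.5
  n_raw <- ((z_alpha * sqrt(p0 * (1 - p0)) + z_beta * sqrt(p1 * (1 - p1))) /
              (p1 - p0))^2
  structure(
    list(alpha = alpha, beta = beta, pd = pd, p0 = p0, p1 = p1,
         z_alpha = z_alpha, z_beta = z_beta,
         n_raw = n_raw, n_min = as.integer(ceiling(n_raw))),
    class = "sample_size_spec")
}

#' @export
print.sample_size_spec <- function(x, ...) {
  cat("2-AFC evaluator sample size (one-sided binomial approximation)\n")
  cat(sprintf("  alpha = %g, beta = %g, pd = %g  (p0 = %g, p1 = %g)\n",
              x$alpha, x$beta, x$pd, x$p0, x$p1))
  cat(sprintf("  z[1-alpha] = %g, z[1-beta] = %g\n", x$z_alpha, x$z_beta))
  cat(sprintf("  n_raw = %.4f  ->  minimum evaluators n_min = %d\n",
              x$n_raw, x$n_min))
  invisible(x)
}

.check_participants <- function(participants) {
  req <- c("id", "laxity_label")
  miss <- setdiff(req, names(participants))
  if (length(miss)) {
    stop("participant table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(participants$id)) stop("participant ids must be unique")
  bad <- setdiff(unique(participants$laxity_label), c("more", "less"))
  if (length(bad)) {
    stop("laxity_label must be 'more' or 'less'; found: ",
         paste(bad, collapse = ", "))
  }
  invisible(participants)
}

#' Randomly assign participants to label-balanced groups
#'
#' Shuffles participants within each laxity-label class and deals them into
#' `n_groups` groups, so that every group receives the same number of "more"
#' and the same number of "less" participants. The default study geometry is
#' 64 participants (32 per label) in 8 groups of 4 + 4.
#'
#' @param participants data frame with columns `id` and `laxity_label`
#'   (values `"more"`/`"less"`); other columns are carried through.
#' @param n_groups number of groups; must divide both label counts.
#' @param seed integer seed; the assignment is reproducible from it.
#'
#' @return The participant data frame with an integer `group_id` column.
#' @export
assign_groups <- function(participants, n_groups = 8L, seed = 1L) {
  .check_participants(participants)
  n_groups <- as.integer(n_groups)
  stopifnot(n_groups >= 1L)
  counts <- table(factor(participants$laxity_label, c("more", "less")))
  for (lab in names(counts)) {
    if (counts[[lab]] %% n_groups != 0L) {
      stop(sprintf(
        "cannot balance groups: %d participants labeled '%s' not divisible by %d groups",
        counts[[lab]], lab, n_groups))
    }
  }
  participants$group_id <- NA_integer_
  set.seed(seed)
  for (lab in c("more", "less")) {
    idx <- which(participants$laxity_label == lab)
    idx <- idx[sample.int(length(idx))]
    participants$group_id[idx] <- rep_len(seq_len(n_groups), length(idx))
  }
  participants[order(participants$group_id, participants$id), , drop = FALSE]
}

.pair_key <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "|")
}

#' Enumerate all cross-label pairs within one group
#'
#' Comprehensively pairs every "more facial skin laxity" participant with
#' every "less facial skin laxity" participant of the group (m x l pairs);
#' same-label pairs are never formed.
#'
#' @param group data frame with columns `id` and `laxity_label` for a single
#'   group.
#' @return data frame with columns `pair_key`, `more_id`, `less_id`.
#' @export
enumerate_pairs <- function(group) {
  .check_participants(group)
  more <- group$id[group$laxity_label == "more"]
  less <- group$id[group$laxity_label == "less"]
  if (length(more) == 0L || length(less) == 0L) {
    stop("group must contain at least one participant of each laxity label")
  }
  grid <- expand.grid(more_id = more, less_id = less,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(pair_key = .pair_key(grid$more_id, grid$less_id),
             more_id = grid$more_id, less_id = grid$less_id,
             stringsAsFactors = FALSE)
}

#' Build the order-swapped 2-AFC presentation schedule
#'
#' Each cross-label pair of every group is shown twice, once in each left /
#' right position (one exchange of position), and the full event list is
#' shuffled globally. For the default geometry of 8 groups of 4 + 4 this
#' yields 32 events per group and 256 events in total, collapsing to 128
#' unique pairs.
#'
#' @param participants grouped participant data frame (see [assign_groups()]),
#'   with columns `id`, `laxity_label`, `group_id`.
#' @param seed integer seed for the global shuffle.
#'
#' @return data frame of presentation events with columns `event_id`,
#'   `group_id`, `left_id`, `right_id`, `pair_key`, `order_flag`
#'   (`"normal"`: the "more"-labeled participant on the left / position A;
#'   `"swapped"`: mirrored).
#' @export
presentation_schedule <- function(participants, seed = 1L) {
  .check_participants(participants)
  if (!"group_id" %in% names(participants) || anyNA(participants$group_id)) {
    stop("participants must carry a complete 'group_id'; run assign_groups() first")
  }
  events <- do.call(rbind, lapply(split(participants, participants$group_id),
    function(grp) {
      pairs <- enumerate_pairs(grp)
      rbind(
        data.frame(group_id = grp$group_id[1L],
                   left_id = pairs$more_id, right_id = pairs$less_id,
                   pair_key = pairs$pair_key, order_flag = "normal",
                   stringsAsFactors = FALSE),
        data.frame(group_id = grp$group_id[1L],
                   left_id = pairs$less_id, right_id = pairs$more_id,
                   pair_key = pairs$pair_key, order_flag = "swapped",
                   stringsAsFactors = FALSE))
    }))
  rownames(events) <- NULL
  set.seed(seed)
  events <- events[sample.int(nrow(events)), , drop = FALSE]
  events <- cbind(
    event_id = sprintf("E%03d", seq_len(nrow(events))),
    events, stringsAsFactors = FALSE)
  rownames(events) <- NULL
  events
}
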