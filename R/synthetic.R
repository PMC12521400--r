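#' Published marginal distributions of the skin parameters
#'
#' Mean and standard deviation of each noninvasive measurement (and expert
#' apparent age) in a 142-subject Chinese female cohort aged 18-60; the
#' synthetic generator anchors its column marginals to these values. Units:
#' H in C.U., TEWL in g/(h.m^2), DT and ET in micrometers, DD in percent,
#' AGEs in AU, wrinkle perimeters/depths in mm, areas in mm^2, volumes in
#' mm^3, AA in years; Cutometer readouts and the rest dimensionless.
#'
#' @return data frame with columns `parameter`, `mean`, `sd`.
#' @export
parameter_marginals <- function() {
  data.frame(
    parameter = c("H", "TEWL", "SG", "CC2", "AGEs", "DT", "DD", "F3", "F4",
                  "Q1", "R2", "R5", "UEW_P", "UEW_V", "UEW_D", "ML_A",
                  "ML_V", "ML_D", "NF_A", "NF_V", "NF_D", "DEJ", "ET", "AA"),
    mean = c(33.323, 12.389, 4.844, 130.693, 2.393, 1575.047, 13.230,
             5.006, 11.965, 0.499, 0.542, 0.564, 72.200, 0.339, -0.033,
             8.354, 0.530, -0.037, 6.962, 0.406, -0.036, 3.191, 42.704,
             48.469),
    sd = c(6.547, 3.569, 0.611, 20.817, 0.625, 214.109, 2.116, 0.863,
           1.658, 0.462, 0.046, 0.054, 40.840, 0.387, 0.015, 4.337, 0.471,
           0.018, 4.752, 0.401, 0.012, 0.859, 6.502, 7.464),
    stringsAsFactors = FALSE)
}

#' Default signed loadings of the latent laxity trait on each parameter
#'
#' Signed association (|loading| < 1) between the latent laxity trait and
#' each measurement column. Signs follow skin-aging physiology: elasticity
#' (R2, Q1), collagen (CC2), epidermal/dermal structure (ET, DD, DT, DEJ),
#' glossiness and hydration decline with laxity (negative); the Cutometer
#' F4 suction area, wrinkle perimeters/areas/volumes, glycation products,
#' barrier loss and apparent age increase with it (positive); wrinkle
#' depths, being negative-valued, become more negative (negative loading).
#'
#' For the eight signal parameters of the published model (see
#' [table4_features()]) only the sign and the zero/nonzero status are used:
#' their strength is governed by the generator's `signal_reliability` and
#' `signal_weight` (the implied marginal correlation with the latent is
#' about `signal_weight * signal_reliability / sqrt(8)` = 0.30 at the
#' defaults). Non-signal columns use the loading directly as a correlation.
#' F3 and R5 are not listed: they are generated as near-copies of F4 and R2
#' (correlation `duplicate_r`) to reproduce their collinearity.
#'
#' @return named numeric vector of loadings.
#' @export
default_loadings <- function() {
  c(CC2 = -0.3, F4 = 0.3, Q1 = -0.3, R2 = -0.3, UEW_V = 0.3, ML_V = 0.3,
    NF_V = 0.3, ET = -0.3, AA = 0.3,
    H = -0.1, TEWL = 0.1, SG = -0.1, AGEs = 0.1, DT = -0.1, DD = -0.1,
    UEW_P = 0.1, UEW_D = -0.1, ML_A = 0.1, ML_D = -0.1, NF_A = 0.1,
    NF_D = -0.1, DEJ = -0.1)
}

#' Configuration of the synthetic laxity-study generator
#'
#' Bundles every knob of the synthetic cohort, response, and efficacy-study
#' generators. Defaults mirror the reference study geometry: 64
#' participants in 8 groups, 72 evaluators, a 15-subject pre/post study.
#'
#' @param n_participants cohort size (even; split 50/50 into the two
#'   laxity-label classes by median latent score).
#' @param n_groups number of comparison groups.
#' @param n_evaluators number of 2-AFC evaluators (half professional,
#'   half lay background).
#' @param evaluator_noise Thurstonian choice temperature: the probability
#'   of judging i more lax than j is
#'   \eqn{\sigma((\ell_i - \ell_j)/\mathrm{noise})}. The default 0.5 makes
#'   unanimous pairs occur for well-separated pairs, exercising the
#'   boundary-correction path.
#' @param loadings named signed loadings, see [default_loadings()].
#' @param marginals data frame of per-parameter mean/sd, see
#'   [parameter_marginals()].
#' @param duplicate_r correlation at which F3 duplicates F4 and R5
#'   duplicates R2.
#' @param signal_set parameters that carry their own aging component; the
#'   latent laxity trait is built by aggregating these components, so each
#'   signal parameter holds unique information about the trait. Defaults to
#'   the eight-parameter composition of the published model.
#' @param signal_reliability correlation between a signal column and its
#'   own aging component (measurement reliability of the instrument).
#' @param signal_weight weight of the aggregated signal components in the
#'   latent trait; together with `latent_age_slope` it must satisfy
#'   `latent_age_slope^2 + signal_weight^2 <= 1` (the remainder is
#'   trait-specific residual).
#' @param age_range chronological age interval (years) sampled uniformly.
#' @param latent_age_slope correlation of the latent laxity score with
#'   standardized age.
#' @param efficacy_n paired efficacy-study sample size.
#' @param efficacy_effect named vector of follow-up shifts in natural
#'   units; `NULL` builds the default: each endpoint moves 0.15 marginal SD
#'   in its improvement direction, and the FSLI decreases by 0.05.
#' @param efficacy_noise_frac paired (visit-to-visit) noise SD as a
#'   fraction of each endpoint's marginal SD.
#' @param fsli_paired_sd paired noise SD of the FSLI endpoint (the index
#'   has no marginal-SD anchor; the default 0.05 makes the default FSLI
#'   shift a one-SD paired effect).
#' @param seed default integer seed used by the generators.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 64L, n_groups = 8L,
                             n_evaluators = 72L, evaluator_noise = 0.5,
                             loadings = default_loadings(),
                             marginals = parameter_marginals(),
                             duplicate_r = 0.97,
                             signal_set = table4_features(),
                             signal_reliability = 0.95, signal_weight = 0.95,
                             age_range = c(18, 60), latent_age_slope = 0.3,
                             efficacy_n = 15L, efficacy_effect = NULL,
                             efficacy_noise_frac = 0.15,
                             fsli_paired_sd = 0.05, seed = 1L) {
  stopifnot(all(marginals$sd > 0), evaluator_noise > 0,
            abs(latent_age_slope) <= 1, all(abs(loadings) < 1),
            signal_reliability >= 0, signal_reliability <= 1,
            signal_weight >= 0,
            latent_age_slope^2 + signal_weight^2 <= 1)
  if (is.null(efficacy_effect)) {
    dirs <- efficacy_endpoints()
    sds <- stats::setNames(marginals$sd, marginals$parameter)
    eps <- setdiff(names(dirs), "FSLI")
    efficacy_effect <- c(
      FSLI = -0.05,
      stats::setNames(ifelse(dirs[eps] == "increase", 1, -1) * 0.15 * sds[eps],
                      eps))
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_groups = as.integer(n_groups),
         n_evaluators = as.integer(n_evaluators),
         evaluator_noise = evaluator_noise, loadings = loadings,
         marginals = marginals, duplicate_r = duplicate_r,
         signal_set = signal_set, signal_reliability = signal_reliability,
         signal_weight = signal_weight,
         age_range = age_range, latent_age_slope = latent_age_slope,
         efficacy_n = as.integer(efficacy_n),
         efficacy_effect = efficacy_effect,
         efficacy_noise_frac = efficacy_noise_frac,
         fsli_paired_sd = fsli_paired_sd, seed = as.integer(seed)),
    class = "generator_config")
}

# Draw a latent laxity score and the full parameter table for n subjects.
# Hierarchical trait model: each signal parameter p has its own aging
# component u_p, measured at reliability alpha (z_p = sign * (alpha u_p +
# noise)); the latent laxity trait aggregates the signed components plus an
# age axis plus residual. Non-signal columns are single-factor:
# z = loading * latent + sqrt(1-loading^2) * noise. On the value scale every
# column is marginal mean + sd * z.
.draw_tables <- function(n, config) {
  b <- config$latent_age_slope
  age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  z_age <- (age - mean(config$age_range)) /
    (diff(config$age_range) / sqrt(12))
  sig <- intersect(config$signal_set, names(config$loadings))
  sig <- sig[config$loadings[sig] != 0]
  alpha <- config$signal_reliability
  w_sig <- if (length(sig)) config$signal_weight else 0
  w_res <- sqrt(max(0, 1 - b^2 - w_sig^2))

  u <- matrix(stats::rnorm(n * length(sig)), nrow = n,
              dimnames = list(NULL, sig))
  s_p <- sign(config$loadings[sig])
  agg <- if (length(sig)) rowSums(u) / sqrt(length(sig)) else 0
  latent <- b * z_age + w_sig * agg + w_res * stats::rnorm(n)

  marg <- config$marginals
  mu <- stats::setNames(marg$mean, marg$parameter)
  sdv <- stats::setNames(marg$sd, marg$parameter)
  z <- list()
  for (p in names(config$loadings)) {
    if (p %in% sig) {
      z[[p]] <- s_p[[p]] * (alpha * u[, p] +
                              sqrt(1 - alpha^2) * stats::rnorm(n))
    } else {
      rho <- config$loadings[[p]]
      z[[p]] <- rho * latent + sqrt(1 - rho^2) * stats::rnorm(n)
    }
  }
  for (p in setdiff(setdiff(parameter_columns(), c("F3", "R5")),
                    names(z))) {
    z[[p]] <- stats::rnorm(n)    # unlisted columns: pure noise
  }
  r <- config$duplicate_r
  z[["F3"]] <- r * z[["F4"]] + sqrt(1 - r^2) * stats::rnorm(n)
  z[["R5"]] <- r * z[["R2"]] + sqrt(1 - r^2) * stats::rnorm(n)

  tab <- data.frame(id = sprintf("P%02d", seq_len(n)),
                    stringsAsFactors = FALSE)
  n_clipped <- 0L
  for (p in parameter_columns()) {
    x <- mu[[p]] + sdv[[p]] * z[[p]]
    if (mu[[p]] < 0) {              # wrinkle depths: keep negative support
      clip <- x > -1e-4
      x[clip] <- -1e-4
    } else {                        # physiological columns: positive support
      clip <- x < 1e-3
      x[clip] <- 1e-3
    }
    n_clipped <- n_clipped + sum(clip)
    tab[[p]] <- x
  }
  attr(tab, "n_clipped") <- n_clipped
  list(latent = latent, age = age, table = tab)
}

#' Generate a synthetic study cohort
#'
#' Draws a latent laxity score per participant (increasing in age on
#' average and aggregating the signal parameters' own aging components),
#' builds the 24-column measurement table from the configured marginals and
#' loadings, and assigns the expert laxity labels by a balanced median
#' split of the latent score, so every "more"-labeled participant's latent
#' exceeds every "less"-labeled one's.
#'
#' @param config [generator_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `participants` (data frame: `id`, `laxity_label`,
#'   `apparent_age`, `latent_score`) and `table` (measurement data frame
#'   keyed by `id`; attribute `n_clipped` counts support-clipped cells).
#' @export
generate_cohort <- function(config = generator_config(), seed = config$seed) {
  n <- config$n_participants
  if (n %% 2L != 0L) {
    stop("n_participants must be even for a balanced 50/50 label split")
  }
  set.seed(seed)
  drawn <- .draw_tables(n, config)
  lab <- ifelse(rank(drawn$latent, ties.method = "first") > n / 2,
                "more", "less")
  participants <- data.frame(
    id = drawn$table$id, laxity_label = lab,
    apparent_age = as.integer(round(drawn$table$AA)),
    latent_score = drawn$latent, stringsAsFactors = FALSE)
  list(participants = participants, table = drawn$table)
}

#' Simulate 2-AFC consumer responses from latent laxity scores
#'
#' Every evaluator judges every scheduled event independently; the left
#' image is chosen with probability
#' \eqn{\sigma((\ell_\mathrm{left} - \ell_\mathrm{right})/\mathrm{noise})}
#' (the Bradley-Terry / Thurstonian link). Evaluator backgrounds are half
#' `"professional"`, half `"lay"`.
#'
#' @param schedule presentation schedule from [presentation_schedule()].
#' @param latent named numeric vector of latent scores covering every
#'   scheduled participant id.
#' @param config [generator_config()] (supplies `n_evaluators` and
#'   `evaluator_noise`).
#' @param seed integer seed; defaults to `config$seed`.
#' @return response data frame: `evaluator_id`, `background`, `event_id`,
#'   `choice`.
#' @export
simulate_responses <- function(schedule, latent,
                               config = generator_config(),
                               seed = config$seed) {
  miss <- setdiff(unique(c(schedule$left_id, schedule$right_id)),
                  names(latent))
  if (length(miss)) {
    stop("latent score missing for participant(s): ",
         paste(miss, collapse = ", "))
  }
  set.seed(seed)
  n_ev <- config$n_evaluators
  noise <- max(config$evaluator_noise, 1e-6)
  p_left <- stats::plogis(
    (latent[schedule$left_id] - latent[schedule$right_id]) / noise)
  n_event <- nrow(schedule)
  u <- matrix(stats::runif(n_ev * n_event), nrow = n_ev)
  choice <- ifelse(u < matrix(p_left, nrow = n_ev, ncol = n_event,
                              byrow = TRUE), "A", "B")
  data.frame(
    evaluator_id = rep(sprintf("C%02d", seq_len(n_ev)), each = n_event),
    background = rep(ifelse(seq_len(n_ev) <= n_ev / 2, "professional", "lay"),
                     each = n_event),
    event_id = rep(schedule$event_id, times = n_ev),
    choice = as.vector(t(choice)), stringsAsFactors = FALSE)
}

#' Simulate a paired pre/post efficacy study
#'
#' Draws a baseline cohort of `efficacy_n` subjects (baseline FSLI is the
#' latent laxity score — the index lives on the centered log-worth scale),
#' then builds the follow-up visit as baseline plus the configured
#' per-endpoint shift plus paired Gaussian noise. Default shifts move every
#' panel endpoint in its improvement direction; columns that are not
#' configured endpoints are carried over unchanged.
#'
#' @param config [generator_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `baseline` and `followup` data frames (columns `id`,
#'   `FSLI`, and the measurement columns).
#' @export
simulate_efficacy_study <- function(config = generator_config(),
                                    seed = config$seed) {
  n <- config$efficacy_n
  if (n < 3L) stop("efficacy_n must be at least 3")
  set.seed(seed)
  drawn <- .draw_tables(n, config)
  base <- cbind(drawn$table[, "id", drop = FALSE],
                FSLI = drawn$latent,
                drawn$table[, setdiff(names(drawn$table), "id"),
                            drop = FALSE])
  fol <- base
  sds <- stats::setNames(config$marginals$sd, config$marginals$parameter)
  for (ep in names(config$efficacy_effect)) {
    if (!ep %in% names(fol)) next
    noise_sd <- if (ep == "FSLI") config$fsli_paired_sd
                else config$efficacy_noise_frac * sds[[ep]]
    fol[[ep]] <- base[[ep]] + config$efficacy_effect[[ep]] +
      stats::rnorm(n, 0, noise_sd)
  }
  list(baseline = base, followup = fol)
}
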