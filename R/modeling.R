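#' Names of the noninvasive skin parameter columns
#'
#' The 23 instrument measurements (hydration, barrier, glossiness, collagen,
#' glycation, dermis, Cutometer elasticity readouts, wrinkle morphometry,
#' confocal epidermis measures) plus expert apparent age `AA`.
#' @return character vector of column names.
#' @export
parameter_columns <- function() {
  c("H", "TEWL", "SG", "CC2", "AGEs", "DT", "DD", "F3", "F4", "Q1", "R2",
    "R5", "UEW_P", "UEW_V", "UEW_D", "ML_A", "ML_V", "ML_D", "NF_A", "NF_V",
    "NF_D", "DEJ", "ET", "AA")
}

#' The eight-parameter composition of the published laxity model
#' @return character vector of feature names.
#' @export
table4_features <- function() {
  c("CC2", "F4", "Q1", "R2", "UEW_V", "ML_V", "NF_V", "ET")
}

.vif_one <- function(j, mat) {
  # perfect collinearity triggers benign perfect-fit warnings; the R^2 >= 1
  # branch below handles that case explicitly
  fit <- suppressWarnings(
    stats::lm(mat[, j] ~ ., data = as.data.frame(mat[, -j, drop = FALSE])))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

.compute_vifs <- function(mat) {
  if (ncol(mat) < 2L) return(stats::setNames(rep(1, ncol(mat)), colnames(mat)))
  stats::setNames(vapply(seq_len(ncol(mat)), .vif_one, numeric(1), mat = mat),
                  colnames(mat))
}

#' Iterative variance-inflation-factor collinearity screen
#'
#' Computes the VIF of each column, \eqn{\mathrm{VIF}_j = 1/(1-R_j^2)} with
#' \eqn{R_j^2} from regressing column j on all the others, and iteratively
#' removes the highest-VIF column until all remaining VIFs fall below the
#' threshold. Exactly collinear columns get an infinite VIF; ties are broken
#' alphabetically so the screen is deterministic. With
#' `a_priori_exclusions` (default: the Cutometer F3 and R5 readouts, which
#' duplicate the information in F4 and R2) those columns are removed before
#' any VIF is computed.
#'
#' @param table data frame of numeric measurement columns keyed by an `id`
#'   column (ignored for screening) — see [parameter_columns()].
#' @param threshold VIF cutoff; columns are retained while `VIF < threshold`.
#' @param a_priori_exclusions columns removed up front; `character(0)` to
#'   disable.
#' @return list with `retained` (column names), `dropped` (in removal
#'   order, a-priori exclusions first), and `vif` (final VIFs of retained
#'   columns).
#' @export
vif_screen <- function(table, threshold = 5,
                       a_priori_exclusions = c("F3", "R5")) {
  num <- vapply(table, is.numeric, logical(1))
  X <- as.matrix(table[, setdiff(names(table)[num], "id"), drop = FALSE])
  if (ncol(X) < 2L) stop("need at least 2 numeric columns for a VIF screen")
  if (nrow(X) <= ncol(X)) {
    warning("fewer rows than columns; VIF estimates are unstable")
  }
  dropped <- intersect(a_priori_exclusions, colnames(X))
  X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  repeat {
    vifs <- .compute_vifs(X)
    worst <- max(vifs)
    if (worst < threshold || ncol(X) <= 2L) break
    # alphabetical tie-break among maximal (possibly infinite) VIFs
    cand <- sort(names(vifs)[vifs == worst])
    dropped <- c(dropped, cand[1L])
    X <- X[, setdiff(colnames(X), cand[1L]), drop = FALSE]
  }
  list(retained = colnames(X), dropped = dropped, vif = vifs)
}

.loo_svr <- function(X, y, cost, epsilon, kernel = "linear",
                     gamma = NULL) {
  n <- nrow(X)
  preds <- numeric(n)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    if (stats::sd(y[-i]) == 0) {   # constant training target
      preds[i] <- y[-i][1L]
      next
    }
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    trs <- scale(tr, center = mu, scale = sdv)
    tes <- scale(X[i, , drop = FALSE], center = mu, scale = sdv)
    fit <- e1071::svm(x = trs, y = y[-i], type = "eps-regression",
                      kernel = kernel, cost = cost, epsilon = epsilon,
                      gamma = gamma, scale = FALSE)
    preds[i] <- stats::predict(fit, tes)
  }
  preds
}

.loo_metrics <- function(actual, pred) {
  sse <- sum((actual - pred)^2)
  sst <- sum((actual - mean(actual))^2)
  r2 <- if (sst == 0) -Inf else 1 - sse / sst
  ct <- if (stats::sd(pred) > 0 && stats::sd(actual) > 0) {
    stats::cor.test(actual, pred)
  } else NULL
  list(r_squared = r2, rmse = sqrt(mean((actual - pred)^2)),
       pearson_r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       pearson_p = if (is.null(ct)) NA_real_ else ct$p.value)
}

#' Support-vector regression of the FSLI on skin parameters
#'
#' Fits an epsilon-insensitive support-vector regression of the Facial
#' Skin Laxity Index on noninvasive skin parameters,
#' validated by leave-one-out (LOO): each participant is predicted by a
#' model trained on all the others, with feature standardization re-derived
#' inside every training fold so no information leaks from the held-out row.
#' Reported metrics are the predictive \eqn{R^2 = 1 - SSE/SST} computed on
#' the LOO predictions, the LOO RMSE, and the Pearson correlation of
#' predicted vs actual values; the in-sample (training) \eqn{R^2} of the
#' final model is reported alongside.
#'
#' With `features = "auto"`, greedy forward selection picks features one at
#' a time to minimize LOO RMSE, up to the model-size cap `max_features`
#' (default 8, the size of the published composition); the per-step RMSE
#' path is recorded so smaller compositions remain inspectable. An explicit
#' character vector of features (e.g. [table4_features()]) is used verbatim.
#'
#' @param table measurement data frame with an `id` column.
#' @param fsli named numeric vector of FSLI values (names = participant ids).
#' @param features `"auto"` or a character vector of column names.
#' @param candidates candidate pool for forward selection; defaults to all
#'   numeric columns of `table` (run [vif_screen()] first and pass its
#'   `retained` set to respect the collinearity screen).
#' @param kernel SVR kernel: `"linear"` (default; the published model is
#'   described as linear) or `"radial"`.
#' @param cost,epsilon,gamma SVR hyperparameters; `gamma` (radial kernel
#'   only) `NULL` uses 1 / (number of features) on the standardized scale.
#' @param max_features cap for forward selection.
#' @return object of class `regression_fit`: list with `feature_names`,
#'   `hyperparameters`, `loo_predictions` (named), `actual` (named),
#'   `r_squared` (LOO), `rmse` (LOO), `pearson_r`, `pearson_p`,
#'   `r_squared_train`, `selection_path` (when auto), `n`.
#' @export
fit_fsli_model <- function(table, fsli, features = "auto",
                           candidates = NULL, kernel = c("linear", "radial"),
                           cost = 1, epsilon = 0.1, gamma = NULL,
                           max_features = 8L) {
  kernel <- match.arg(kernel)
  stopifnot(!is.null(names(fsli)))
  ids <- intersect(table$id, names(fsli))
  if (length(ids) < 3L) stop("insufficient data: need at least 3 matched participants")
  tab <- table[match(ids, table$id), , drop = FALSE]
  y <- unname(fsli[ids])
  if (stats::sd(y) == 0) {
    warning("degenerate target: FSLI constant across participants")
  }
  num_cols <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], "id")
  if (is.null(candidates)) candidates <- num_cols
  candidates <- intersect(candidates, num_cols)
  zero_var <- candidates[vapply(candidates, function(cl) stats::sd(tab[[cl]]) == 0,
                                logical(1))]
  if (length(zero_var)) {
    warning("dropping zero-variance feature(s): ",
            paste(zero_var, collapse = ", "))
    candidates <- setdiff(candidates, zero_var)
  }

  selection_path <- NULL
  if (identical(features, "auto")) {
    # greedy forward selection to the model-size cap; the per-step LOO RMSE
    # path is recorded so smaller compositions remain inspectable
    selected <- character(0)
    path <- list()
    while (length(selected) < max_features && length(candidates)) {
      rmses <- vapply(candidates, function(cand) {
        X <- as.matrix(tab[, c(selected, cand), drop = FALSE])
        preds <- .loo_svr(X, y, cost, epsilon, kernel, gamma)
        sqrt(mean((y - preds)^2))
      }, numeric(1))
      best <- sort(names(rmses)[rmses == min(rmses)])[1L]
      selected <- c(selected, best)
      candidates <- setdiff(candidates, best)
      path[[length(path) + 1L]] <- list(feature = best,
                                        loo_rmse = unname(rmses[[best]]))
    }
    if (!length(selected)) stop("forward selection found no usable feature")
    features <- selected
    selection_path <- path
  } else {
    miss <- setdiff(features, num_cols)
    if (length(miss)) {
      stop("requested feature(s) absent from table: ",
           paste(miss, collapse = ", "))
    }
    features <- setdiff(features, zero_var)
  }

  X <- as.matrix(tab[, features, drop = FALSE])
  g <- if (is.null(gamma)) 1 / ncol(X) else gamma
  preds <- .loo_svr(X, y, cost, epsilon, kernel, g)
  met <- .loo_metrics(y, preds)

  sst <- sum((y - mean(y))^2)
  if (sst > 0) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    final <- e1071::svm(x = scale(X, mu, sdv), y = y, type = "eps-regression",
                        kernel = kernel, cost = cost, epsilon = epsilon,
                        gamma = g, scale = FALSE)
    train_pred <- stats::predict(final, scale(X, mu, sdv))
    r2_train <- 1 - sum((y - train_pred)^2) / sst
  } else {
    r2_train <- -Inf
  }

  structure(
    list(feature_names = features,
         hyperparameters = list(kernel = kernel, cost = cost,
                                epsilon = epsilon, gamma = g),
         loo_predictions = stats::setNames(preds, ids),
         actual = stats::setNames(y, ids),
         r_squared = met$r_squared, rmse = met$rmse,
         pearson_r = met$pearson_r, pearson_p = met$pearson_p,
         r_squared_train = r2_train, selection_path = selection_path,
         n = length(ids)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("SVR fit of FSLI on %d participants (leave-one-out validated)\n",
              x$n))
  cat("  features: ", paste(x$feature_names, collapse = ", "), "\n", sep = "")
  cat(sprintf("  LOO R^2 = %.3f, LOO RMSE = %.4f (train R^2 = %.3f)\n",
              x$r_squared, x$rmse, x$r_squared_train))
  cat(sprintf("  predicted vs actual: Pearson r = %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Descriptive distribution report with Shapiro-Wilk normality tests
#'
#' Per-column mean, standard deviation, and Shapiro-Wilk W statistic with
#' its p-value. Columns with fewer than 3 non-missing values or zero
#' variance are reported with the test skipped (`normality_tested = FALSE`).
#'
#' @param table data frame; non-numeric columns and `id` are ignored.
#' @return data frame with columns `parameter`, `n`, `mean`, `sd`,
#'   `shapiro_w`, `shapiro_p`, `normality_tested`.
#' @export
distribution_report <- function(table) {
  cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], "id")
  rows <- lapply(cols, function(cl) {
    x <- table[[cl]]
    x <- x[!is.na(x)]
    tested <- length(x) >= 3L && length(x) <= 5000L && stats::sd(x) > 0
    sw <- if (tested) stats::shapiro.test(x) else NULL
    data.frame(parameter = cl, n = length(x), mean = mean(x),
               sd = stats::sd(x),
               shapiro_w = if (tested) unname(sw$statistic) else NA_real_,
               shapiro_p = if (tested) sw$p.value else NA_real_,
               normality_tested = tested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
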