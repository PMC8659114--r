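#' Goodness-of-fit metrics for surrogate profiles
#'
#' Computes, for a target series `y` and prediction `yhat` of length `N`:
#' mean squared error; mean absolute deviation `MAD = mean(|y - yhat|)`;
#' Theil's inequality coefficient
#' `TIC = sqrt(mean((y-yhat)^2)) / (sqrt(mean(y^2)) + sqrt(mean(yhat^2)))`;
#' Nash--Sutcliffe efficiency and its complement `ENSE = 1 - NSE`; and the
#' Pearson correlation `r`.
#'
#' Two NSE denominators are offered. The default (`nse_form =
#' "prediction-mean"`) centres the denominator on the mean of the
#' predictions, `NSE = 1 - sum((y-yhat)^2) / sum((y - mean(yhat))^2)`; the
#' conventional hydrological form (`"observation-mean"`) centres on the
#' mean of the observations. The prediction-mean form is the contract the
#' rest of the package reports.
#'
#' @param target target (reference) values.
#' @param predicted predicted values, same length.
#' @param nse_form which NSE denominator to use (see Details).
#' @return Object of class `fit_metrics`: list with `mse`, `mad`, `tic`,
#'   `nse`, `ense`, `r`. A zero denominator in TIC or NSE yields `NaN`
#'   (flagged undefined), never a silent zero.
#' @export
#' @examples
#' fit_metrics(c(1, 2, 3), c(1, 2, 4))
fit_metrics <- function(target, predicted,
                        nse_form = c("prediction-mean", "observation-mean")) {
  nse_form <- match.arg(nse_form)
  stopifnot(length(target) == length(predicted), length(target) >= 2,
            all(is.finite(target)), all(is.finite(predicted)))
  N <- length(target)
  err <- target - predicted
  mse <- mean(err^2)
  mad <- mean(abs(err))
  denom_tic <- sqrt(mean(target^2)) + sqrt(mean(predicted^2))
  tic <- if (denom_tic == 0) NaN else sqrt(mse) / denom_tic
  centre <- if (nse_form == "prediction-mean") mean(predicted) else mean(target)
  denom_nse <- sum((target - centre)^2)
  nse <- if (denom_nse == 0) NaN else 1 - sum(err^2) / denom_nse
  r <- if (stats::sd(target) == 0 || stats::sd(predicted) == 0) NaN else
    stats::cor(target, predicted)
  structure(list(mse = mse, mad = mad, tic = tic,
                 nse = nse, ense = 1 - nse, r = r),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf(
    "fit metrics: MSE = %.4e, MAD = %.4e, TIC = %.4e, NSE = %.6f, ENSE = %.4e, r = %.6f\n",
    x$mse, x$mad, x$tic, x$nse, x$ense, x$r))
  invisible(x)
}

#' @export
as.data.frame.fit_metrics <- function(x, ...) {
  data.frame(mse = x$mse, mad = x$mad, tic = x$tic,
             nse = x$nse, ense = x$ense, r = x$r)
}

#' Histogram of prediction errors
#'
#' Uniform bins spanning `[min(errors), max(errors)]`; bins are
#' right-open except the last, which is closed, so every error is counted
#' exactly once. Degenerate all-equal input produces a single populated
#' bin.
#'
#' @param errors error values (nonempty).
#' @param n_bins number of bins (>= 1).
#' @return List with `bin_edges` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`, summing to `length(errors)`).
#' @export
error_histogram <- function(errors, n_bins = 20) {
  if (length(errors) == 0) stop("empty error vector")
  stopifnot(n_bins >= 1, all(is.finite(errors)))
  lo <- min(errors)
  hi <- max(errors)
  if (lo == hi) hi <- lo + max(abs(lo), 1) * 1e-12
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- pmin(findInterval(errors, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(bin_edges = edges, counts = counts)
}

#' Multi-run training stability study
#'
#' Retrains the surrogate `n_runs` times with seeds `base_seed ..
#' base_seed + n_runs - 1` (each seed drives both the data split and the
#' weight initialization) on the same reference dataset, scores each run's
#' fit on the full grid against the reference solution, and aggregates
#' min / mean / sd for MSE, MAD, TIC and ENSE — plus the per-run
#' best-validation MSE. Aborting runs are excluded and reported.
#'
#' @param params [model_params()] for the case studied.
#' @param target `"S"` or `"H"`: which profile component to fit.
#' @param n_runs number of runs (>= 2).
#' @param base_seed first seed.
#' @param n_points dataset size (profile grid points).
#' @param n_hidden hidden units.
#' @param fractions train/val/test fractions for [split_dataset()].
#' @param cfg [lm_config()].
#' @param opts [solver_options()] for dataset generation (grid size is
#'   overridden by `n_points`).
#' @param eval_on `"full"` scores on every grid point, `"test"` on the test
#'   split only.
#' @return Object of class `stability_report`: list with `summary` (data
#'   frame metric x min/mean/sd), `runs` (per-run metric data frame,
#'   including `best_val_mse`), `seeds`, `n_runs`, `failed` (seeds of
#'   aborted runs).
#' @export
stability_study <- function(params, target = c("S", "H"), n_runs = 20,
                            base_seed = 1, n_points = 1143, n_hidden = 60,
                            fractions = c(0.70, 0.15, 0.15),
                            cfg = lm_config(), opts = solver_options(),
                            eval_on = c("full", "test")) {
  target <- match.arg(target)
  eval_on <- match.arg(eval_on)
  stopifnot(n_runs >= 2)
  opts$n <- as.integer(n_points)
  prof <- solve_profile(params, opts)
  y <- if (target == "S") prof$S else prof$H
  ds0 <- make_dataset(prof$grid$R, y)
  seeds <- base_seed + seq_len(n_runs) - 1
  rows <- list()
  failed <- integer(0)
  for (s in seeds) {
    res <- tryCatch({
      ds <- split_dataset(ds0, fractions, seed = s)
      fit <- lm_train(mlp_init(n_hidden, params$q, seed = s), ds, cfg)
      keep <- if (eval_on == "full") rep(TRUE, nrow(ds)) else ds$split == "test"
      m <- fit_metrics(ds$target[keep], mlp_forward(fit$net, ds$R[keep]))
      cbind(seed = s, as.data.frame(m),
            best_val_mse = fit$record$best_val_mse)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, s) else rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("all stability runs failed")
  runs <- do.call(rbind, rows)
  agg <- function(v) c(min = min(v), mean = mean(v), sd = stats::sd(v))
  summary <- as.data.frame(t(vapply(
    runs[c("mse", "mad", "tic", "ense", "best_val_mse")], agg, numeric(3))))
  summary <- cbind(metric = rownames(summary), summary)
  rownames(summary) <- NULL
  structure(list(summary = summary, runs = runs, seeds = seeds,
                 n_runs = length(rows), failed = failed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability study over %d runs (seeds %d..%d)\n",
              x$n_runs, min(x$seeds), max(x$seeds)))
  print(x$summary, digits = 4)
  if (length(x$failed)) {
    cat("failed seeds:", paste(x$failed, collapse = ", "), "\n")
  }
  invisible(x)
}
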