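#' Initialize a single-hidden-layer perceptron surrogate
#'
#' Builds a 1-H-1 network: one radial input, `n_hidden` log-sigmoid hidden
#' units, one linear output. Hidden weights and biases use the
#' Nguyen--Widrow scheme over the scaled input range (inputs are mapped
#' affinely from `[1, q]` to `[-1, 1]`; the map is stored in the network so
#' prediction is self-contained). Initialization is deterministic given
#' `seed`.
#'
#' @param n_hidden number of hidden units (>= 1; 60 for the reference
#'   experiments).
#' @param q radius ratio defining the input range `[1, q]`.
#' @param seed integer RNG seed.
#' @return Object of class `mlp_surrogate` with fields `w_in`, `b_hidden`,
#'   `w_out`, `b_out`, `input_scale` (center, half-width), `n_hidden`.
#' @export
mlp_init <- function(n_hidden, q, seed) {
  stopifnot(n_hidden >= 1, q > 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  H <- as.integer(n_hidden)
  beta <- 0.7 * H  # Nguyen-Widrow magnitude for 1 input: 0.7 * H^(1/1)
  w_in <- beta * sign(stats::runif(H, -1, 1))
  b_hidden <- beta * seq(-1, 1, length.out = H) * sign(w_in)
  if (H == 1) b_hidden <- stats::runif(1, -beta, beta)
  w_out <- stats::runif(H, -0.5, 0.5) / sqrt(H)
  b_out <- stats::runif(1, -0.5, 0.5)
  structure(list(w_in = w_in, b_hidden = b_hidden,
                 w_out = w_out, b_out = b_out,
                 input_scale = c(center = (1 + q) / 2,
                                 half_width = (q - 1) / 2),
                 n_hidden = H),
            class = "mlp_surrogate")
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat(sprintf("MLP surrogate: 1-%d-1, log-sigmoid hidden, linear output (%d parameters)\n",
              x$n_hidden, 3 * x$n_hidden + 1))
  invisible(x)
}

logsig <- function(x) 1 / (1 + exp(-x))

mlp_n_params <- function(net) 3L * net$n_hidden + 1L

# flatten / restore the trainable parameter vector
mlp_get_theta <- function(net) {
  c(net$w_in, net$b_hidden, net$w_out, net$b_out)
}

mlp_set_theta <- function(net, theta) {
  H <- net$n_hidden
  net$w_in <- theta[seq_len(H)]
  net$b_hidden <- theta[H + seq_len(H)]
  net$w_out <- theta[2 * H + seq_len(H)]
  net$b_out <- theta[3 * H + 1]
  net
}

mlp_scale_input <- function(net, R) {
  (R - net$input_scale[["center"]]) / net$input_scale[["half_width"]]
}

#' Evaluate the surrogate
#'
#' `out = b_out + sum_j w_out[j] * logsig(w_in[j] * x + b_hidden[j])` with
#' `x` the affinely scaled input.
#'
#' @param net an [mlp_init()] network (trained or not).
#' @param R radial input values.
#' @return Predicted values, same length as `R`.
#' @export
mlp_forward <- function(net, R) {
  stopifnot(all(is.finite(R)))
  x <- mlp_scale_input(net, R)
  A <- logsig(outer(x, net$w_in) +
                matrix(net$b_hidden, length(x), net$n_hidden, byrow = TRUE))
  drop(A %*% net$w_out) + net$b_out
}

#' @export
predict.mlp_surrogate <- function(object, R, ...) mlp_forward(object, R)

# hidden activations and the N x P Jacobian of predictions w.r.t. theta
mlp_jacobian <- function(net, R) {
  x <- mlp_scale_input(net, R)
  A <- logsig(outer(x, net$w_in) +
                matrix(net$b_hidden, length(x), net$n_hidden, byrow = TRUE))
  pred <- drop(A %*% net$w_out) + net$b_out
  D <- A * (1 - A)                               # logsig'
  Dw <- sweep(D, 2, net$w_out, `*`)              # dpred/d(pre-activation_j)
  J <- cbind(Dw * x,                             # d/d w_in
             Dw,                                 # d/d b_hidden
             A,                                  # d/d w_out
             1)                                  # d/d b_out
  list(pred = pred, J = J)
}

#' Levenberg--Marquardt training configuration
#'
#' Controls the damped Gauss--Newton loop: a proposed step solves
#' `(J'J + mu I) delta = J'e`; acceptance (training MSE decreased)
#' multiplies `mu` by `mu_dec`, rejection by `mu_inc` with a retry.
#' Training stops on a small gradient, `mu` exceeding `mu_max`, the epoch
#' cap, or `max_val_fail` consecutive epochs of rising validation MSE.
#'
#' @param mu0 initial damping.
#' @param mu_inc rejection multiplier (> 1).
#' @param mu_dec acceptance multiplier in (0, 1).
#' @param mu_max damping value at which training aborts.
#' @param grad_tol infinity-norm tolerance on the MSE gradient.
#' @param max_epochs epoch cap.
#' @param max_val_fail consecutive validation failures allowed.
#' @return Object of class `lm_config`.
#' @export
lm_config <- function(mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1, mu_max = 1e10,
                      grad_tol = 1e-7, max_epochs = 1000, max_val_fail = 6) {
  stopifnot(mu_inc > 1, mu_dec > 0, mu_dec < 1, grad_tol > 0,
            max_epochs >= 1, max_val_fail >= 1, mu0 > 0, mu_max > mu0)
  structure(list(mu0 = mu0, mu_inc = mu_inc, mu_dec = mu_dec,
                 mu_max = mu_max, grad_tol = grad_tol,
                 max_epochs = as.integer(max_epochs),
                 max_val_fail = as.integer(max_val_fail)),
            class = "lm_config")
}

#' Build a regression dataset from a solved profile component
#'
#' @param inputs radial input values.
#' @param targets matching target values (a solved `S` or `H` component).
#' @return Object of class `mlp_dataset`: data frame with columns `R`,
#'   `target` and (after [split_dataset()]) `split`.
#' @export
make_dataset <- function(inputs, targets) {
  stopifnot(length(inputs) == length(targets), all(is.finite(targets)))
  structure(data.frame(R = inputs, target = targets),
            class = c("mlp_dataset", "data.frame"))
}

#' Randomly split a dataset into train / validation / test
#'
#' Disjoint random assignment, deterministic given `seed`; counts are within
#' one point of `fraction * n`. Fractions are normalized to sum to 1.
#'
#' @param ds an [make_dataset()] dataset.
#' @param fractions length-3 positive vector `(train, val, test)`.
#' @param seed integer RNG seed.
#' @return The dataset with a `split` factor column in
#'   `{"train","val","test"}`.
#' @export
split_dataset <- function(ds, fractions = c(0.70, 0.15, 0.15), seed) {
  stopifnot(length(fractions) == 3, all(fractions > 0))
  n <- nrow(ds)
  if (n < 3) stop("need at least 3 points to split")
  fractions <- fractions / sum(fractions)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_val <- min(n_val, n - n_train - 1)
  lab <- rep("test", n)
  lab[perm[seq_len(n_train)]] <- "train"
  lab[perm[n_train + seq_len(n_val)]] <- "val"
  ds$split <- factor(lab, levels = c("train", "val", "test"))
  ds
}

#' Train the surrogate by Levenberg--Marquardt with early stopping
#'
#' Minimizes training MSE over the full parameter vector (hidden weights
#' and biases, output weights and bias) using the analytic Jacobian of the
#' per-point errors. Validation MSE is monitored each epoch; the returned
#' network carries the weights with the best validation MSE seen.
#'
#' @param net an initialized [mlp_init()] network.
#' @param ds a [split_dataset()] dataset.
#' @param cfg an [lm_config()].
#' @return List with `net` (best-validation weights) and `record`, a
#'   `training_record`: data frame `epochs` (per-epoch mse_train, mse_val,
#'   mse_test, mu, grad) plus `stop_reason` in
#'   `{"grad_tol","mu_max","max_epochs","val_fail"}`, `best_val_mse`,
#'   `final_grad`, `final_mu`, `epochs_run`.
#' @export
lm_train <- function(net, ds, cfg = lm_config()) {
  stopifnot(inherits(net, "mlp_surrogate"), "split" %in% names(ds))
  idx_tr <- ds$split == "train"
  idx_va <- ds$split == "val"
  idx_te <- ds$split == "test"
  R_tr <- ds$R[idx_tr]; t_tr <- ds$target[idx_tr]
  R_va <- ds$R[idx_va]; t_va <- ds$target[idx_va]
  R_te <- ds$R[idx_te]; t_te <- ds$target[idx_te]
  N <- length(R_tr)
  P <- mlp_n_params(net)
  theta <- mlp_get_theta(net)
  mu <- cfg$mu0
  fj <- mlp_jacobian(mlp_set_theta(net, theta), R_tr)
  e <- t_tr - fj$pred
  mse_tr <- mean(e^2)
  mse_of <- function(th, R, t) {
    if (length(R) == 0) return(NA_real_)
    mean((t - mlp_forward(mlp_set_theta(net, th), R))^2)
  }
  best_val <- mse_of(theta, R_va, t_va)
  best_theta <- theta
  val_fail <- 0L
  stop_reason <- "max_epochs"
  hist <- vector("list", cfg$max_epochs)
  epoch <- 0L
  grad_inf <- Inf
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    JtJ <- crossprod(fj$J)
    Jte <- crossprod(fj$J, e)
    grad_inf <- 2 * max(abs(Jte)) / N
    if (!is.finite(mse_tr)) stop("non-finite training loss")
    if (grad_inf <= cfg$grad_tol) {
      stop_reason <- "grad_tol"
      epoch <- epoch - 1L
      break
    }
    accepted <- FALSE
    while (mu <= cfg$mu_max) {
      step <- tryCatch({
        Rchol <- chol(JtJ + diag(mu, P))
        backsolve(Rchol, forwardsolve(t(Rchol), Jte))
      }, error = function(err) NULL)
      if (!is.null(step)) {
        theta_try <- theta + drop(step)
        mse_try <- mse_of(theta_try, R_tr, t_tr)
        if (is.finite(mse_try) && mse_try < mse_tr) {
          theta <- theta_try
          mse_tr <- mse_try
          mu <- max(mu * cfg$mu_dec, 1e-300)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * cfg$mu_inc
    }
    if (!accepted) {
      stop_reason <- "mu_max"
    }
    fj <- mlp_jacobian(mlp_set_theta(net, theta), R_tr)
    e <- t_tr - fj$pred
    mse_va <- mse_of(theta, R_va, t_va)
    mse_te <- mse_of(theta, R_te, t_te)
    hist[[epoch]] <- c(mse_train = mse_tr, mse_val = mse_va,
                       mse_test = mse_te, mu = mu, grad = grad_inf)
    if (!is.na(mse_va)) {
      if (mse_va < best_val || is.na(best_val)) {
        best_val <- mse_va
        best_theta <- theta
        val_fail <- 0L
      } else {
        val_fail <- val_fail + 1L
        if (val_fail >= cfg$max_val_fail) {
          stop_reason <- "val_fail"
          break
        }
      }
    }
    if (!accepted) break
  }
  epochs_df <- as.data.frame(do.call(rbind, hist[seq_len(epoch)]))
  if (is.na(best_val)) {  # no validation points: fall back to final weights
    best_theta <- theta
    best_val <- NA_real_
  }
  record <- structure(list(epochs = epochs_df,
                           stop_reason = stop_reason,
                           best_val_mse = best_val,
                           final_train_mse = mse_tr,
                           final_grad = grad_inf,
                           final_mu = mu,
                           epochs_run = epoch),
                      class = "training_record")
  list(net = mlp_set_theta(net, best_theta), record = record)
}

#' @export
print.training_record <- function(x, ...) {
  cat(sprintf(
    "LM training: %d epochs, stop = %s\n  best val MSE = %.3e, final train MSE = %.3e\n  final gradient = %.3e, final mu = %.3e\n",
    x$epochs_run, x$stop_reason, x$best_val_mse, x$final_train_mse,
    x$final_grad, x$final_mu))
  invisible(x)
}

#' Write / read a trained network as CSV
#'
#' Plain-text exchange format: one row per named parameter
#' (`w_in_1 ... b_out`, plus the two input-scale constants).
#'
#' @param net an `mlp_surrogate`.
#' @param path file path.
#' @export
write_mlp_csv <- function(net, path) {
  H <- net$n_hidden
  df <- data.frame(
    name = c(paste0("w_in_", seq_len(H)), paste0("b_hidden_", seq_len(H)),
             paste0("w_out_", seq_len(H)), "b_out",
             "input_center", "input_half_width"),
    value = sprintf("%.17g", c(net$w_in, net$b_hidden, net$w_out, net$b_out,
                               net$input_scale)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mlp_csv
#' @export
read_mlp_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  val <- function(pat) df$value[grep(paste0("^", pat, "_[0-9]+$"), df$name)]
  one <- function(nm) df$value[df$name == nm]
  H <- length(val("w_in"))
  structure(list(w_in = val("w_in"), b_hidden = val("b_hidden"),
                 w_out = val("w_out"), b_out = one("b_out"),
                 input_scale = c(center = one("input_center"),
                                 half_width = one("input_half_width")),
                 n_hidden = H),
            class = "mlp_surrogate")
}
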