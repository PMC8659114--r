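#' Scenario specification
#'
#' A scenario fixes the film geometry (`q`) and dataset size, and lists the
#' `(alpha, gamma_E, gamma_S)` cases studied on it.
#'
#' @param name label.
#' @param q radius ratio (> 1).
#' @param n_points dataset / grid size (>= 3).
#' @param cases list of numeric triples `c(alpha, gamma_E, gamma_S)`.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, q, n_points, cases) {
  stopifnot(q > 1, n_points >= 3, length(cases) >= 1)
  cases <- lapply(cases, function(cs) {
    stopifnot(length(cs) == 3, all(cs >= 0))
    c(alpha = unname(cs[1]), gamma_E = unname(cs[2]), gamma_S = unname(cs[3]))
  })
  structure(list(name = name, q = q, n_points = as.integer(n_points),
                 cases = cases),
            class = "scenario_spec")
}

#' The two reference scenarios
#'
#' Scenario I: thick film, `q = 5`, 1143-point dataset. Scenario II: thin
#' film, `q = 1.5`, 1251-point dataset. Each carries three cases
#' `(alpha, gamma_E) = (100, 30), (50, 20), (10, 10)`, with
#' `gamma_S = gamma_E` (equal substrate/peroxide diffusivities) by default.
#'
#' @return List of two [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  cases <- list(c(100, 30, 30), c(50, 20, 20), c(10, 10, 10))
  list(scenario_spec("I", q = 5, n_points = 1143, cases = cases),
       scenario_spec("II", q = 1.5, n_points = 1251, cases = cases))
}

case_params <- function(spec, case) {
  cs <- spec$cases[[case]]
  model_params(gamma_E = cs[["gamma_E"]], gamma_S = cs[["gamma_S"]],
               alpha = cs[["alpha"]], q = spec$q)
}

#' Generate surrogate training datasets from the reference solver
#'
#' Solves the coupled problem on an `n_points` uniform grid over `[1, q]`
#' and emits the `(R, S)` and `(R, H)` regression datasets. Deterministic.
#'
#' @param params [model_params()].
#' @param n_points grid size (>= 3).
#' @param opts [solver_options()] (its `n` is overridden by `n_points`).
#' @return List with elements `S` and `H`, each a [make_dataset()] dataset,
#'   plus `profile`, the solved [concentration_profile()].
#' @export
generate_dataset <- function(params, n_points, opts = solver_options()) {
  stopifnot(n_points >= 3)
  opts$n <- as.integer(n_points)
  prof <- solve_profile(params, opts)
  list(S = make_dataset(prof$grid$R, prof$S),
       H = make_dataset(prof$grid$R, prof$H),
       profile = prof)
}

#' Side-by-side comparison of approximations at tabulated radii
#'
#' For each case of a scenario and each radius in `R_list`, reports the
#' MADM and HAM closed forms, the reference numerical solution, and — when
#' trained surrogates are supplied — the surrogate prediction for the
#' substrate profile.
#'
#' @param spec a [scenario_spec()].
#' @param R_list radii to tabulate (within `[1, q]`); default 9 evenly
#'   spaced values.
#' @param ham_h HAM convergence-control parameter.
#' @param surrogates optional list (one per case) of trained
#'   `mlp_surrogate` networks for the S profile.
#' @param opts [solver_options()] for the numerical columns.
#' @return Data frame with columns `case`, `alpha`, `gamma_E`, `R`,
#'   `madm`, `ham`, `numerical` and (if supplied) `surrogate`.
#' @export
comparison_table <- function(spec, R_list = NULL, ham_h = -1,
                             surrogates = NULL, opts = solver_options()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(R_list)) R_list <- seq(1, spec$q, length.out = 9)
  if (any(R_list < 1 | R_list > spec$q)) stop("R_list must lie in [1, q]")
  if (!is.null(surrogates) && length(surrogates) != length(spec$cases)) {
    warning("surrogate list length does not match cases; column omitted")
    surrogates <- NULL
  }
  rows <- list()
  for (k in seq_along(spec$cases)) {
    p <- case_params(spec, k)
    prof <- solve_substrate(p, opts)
    S_num <- stats::approx(prof$grid$R, prof$S, xout = R_list)$y
    madm <- madm_profiles(p, prof$grid)
    ham <- ham_profiles(p, prof$grid, h = ham_h)
    row <- data.frame(
      case = k, alpha = p$alpha, gamma_E = p$gamma_E, R = R_list,
      madm = stats::approx(prof$grid$R, madm$S, xout = R_list)$y,
      ham = stats::approx(prof$grid$R, ham$S, xout = R_list)$y,
      numerical = S_num)
    if (!is.null(surrogates)) {
      row$surrogate <- mlp_forward(surrogates[[k]], R_list)
    }
    rows[[k]] <- row
  }
  do.call(rbind, rows)
}

#' Run a full scenario: solve, train, score, export
#'
#' For every case of the scenario: solves the coupled problem on the
#' scenario grid, trains one surrogate for `S` and one for `H`
#' (Levenberg--Marquardt, validation early stopping), computes fit metrics
#' on the full grid, and — when `out_dir` is given — writes
#' `profile.csv`, `dataset_S.csv`, `dataset_H.csv`, `net_S.csv`,
#' `net_H.csv`, `training_S.csv`, `training_H.csv` and `metrics.csv` under
#' `out_dir/case-<k>/`. Fully reproducible given `seed`.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed; case `k`, target `S`/`H` derive their seeds
#'   from it deterministically.
#' @param n_hidden hidden units per surrogate.
#' @param fractions train/val/test split fractions.
#' @param cfg [lm_config()].
#' @param opts [solver_options()].
#' @param out_dir optional output directory.
#' @return Object of class `scenario_result`: list with `metrics` (one row
#'   per case x target), `nets`, `records`, `profiles`, `failed` (case
#'   labels of failed fits).
#' @export
run_scenario <- function(spec, seed = 1, n_hidden = 60,
                         fractions = c(0.70, 0.15, 0.15),
                         cfg = lm_config(), opts = solver_options(),
                         out_dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  metrics <- list()
  nets <- list()
  records <- list()
  profiles <- list()
  failed <- character(0)
  for (k in seq_along(spec$cases)) {
    p <- case_params(spec, k)
    case_dir <- if (!is.null(out_dir)) {
      d <- file.path(out_dir, sprintf("case-%d", k))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      d
    } else NULL
    dat <- generate_dataset(p, spec$n_points, opts)
    profiles[[k]] <- dat$profile
    if (!is.null(case_dir)) {
      write_profile_csv(dat$profile, file.path(case_dir, "profile.csv"))
    }
    for (tg in c("S", "H")) {
      label <- sprintf("%s/case-%d/%s", spec$name, k, tg)
      res <- tryCatch({
        case_seed <- (seed + 1000L * k + 100L * (tg == "H")) %% .Machine$integer.max
        ds <- split_dataset(dat[[tg]], fractions, seed = case_seed)
        fit <- lm_train(mlp_init(n_hidden, spec$q, seed = case_seed), ds, cfg)
        m <- fit_metrics(ds$target, mlp_forward(fit$net, ds$R))
        if (!is.null(case_dir)) {
          utils::write.csv(ds, file.path(case_dir, sprintf("dataset_%s.csv", tg)),
                           row.names = FALSE)
          write_mlp_csv(fit$net, file.path(case_dir, sprintf("net_%s.csv", tg)))
          utils::write.csv(fit$record$epochs,
                           file.path(case_dir, sprintf("training_%s.csv", tg)),
                           row.names = FALSE)
        }
        list(metrics = cbind(scenario = spec$name, case = k, target = tg,
                             as.data.frame(m),
                             best_val_mse = fit$record$best_val_mse,
                             epochs = fit$record$epochs_run,
                             stop_reason = fit$record$stop_reason),
             net = fit$net, record = fit$record)
      }, error = function(e) {
        warning(sprintf("case %s failed: %s", label, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) {
        failed <- c(failed, label)
      } else {
        metrics[[label]] <- res$metrics
        nets[[label]] <- res$net
        records[[label]] <- res$record
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  structure(list(metrics = metrics, nets = nets, records = records,
                 profiles = profiles, failed = failed, spec = spec),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario %s: %d fits (%d failed)\n", x$spec$name,
              nrow(x$metrics), length(x$failed)))
  print(x$metrics[c("case", "target", "mse", "mad", "tic", "ense", "r",
                    "best_val_mse", "epochs")], digits = 4)
  invisible(x)
}

#' Read / print a plain-text key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys
#' (all optional, defaults shown by [print_config()]): `scenario`, `q`,
#' `n_points`, `cases` (semicolon-separated `alpha,gamma_e,gamma_s`
#' triples), `hidden`, `split` (comma-separated fractions), `mu0`,
#' `mu_inc`, `mu_dec`, `mu_max`, `grad_tol`, `max_epochs`, `max_val_fail`,
#' `n`, `newton_tol`, `ham_h`.
#'
#' @param path config file path.
#' @return Named list of parsed values merged over the defaults.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad config line: ", ln)
      key <- trimws(kv[1])
      val <- trimws(kv[2])
      cfg[[key]] <- switch(key,
        scenario = val,
        cases = lapply(strsplit(strsplit(val, ";")[[1]], ","),
                       function(x) as.numeric(trimws(x))),
        split = as.numeric(strsplit(val, ",")[[1]]),
        as.numeric(val))
    }
  }
  cfg
}

default_config <- function() {
  list(scenario = "I", q = 5, n_points = 1143,
       cases = list(c(100, 30, 30), c(50, 20, 20), c(10, 10, 10)),
       hidden = 60, split = c(0.70, 0.15, 0.15),
       mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1, mu_max = 1e10,
       grad_tol = 1e-7, max_epochs = 1000, max_val_fail = 6,
       n = 4001, newton_tol = 1e-12, ham_h = -1)
}

#' @rdname read_config
#' @param cfg a config list.
#' @export
print_config <- function(cfg = default_config()) {
  for (key in names(cfg)) {
    val <- cfg[[key]]
    if (key == "cases") {
      val <- paste(vapply(val, paste, "", collapse = ","), collapse = "; ")
    } else if (length(val) > 1) {
      val <- paste(val, collapse = ",")
    }
    cat(sprintf("%s = %s\n", key, val))
  }
  invisible(cfg)
}
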