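# Shared fixtures: the six reference cases and a coarse solver option set
# used where full reference resolution is unnecessary.

all_default_cases <- function() {
  out <- list()
  for (sc in default_scenarios()) {
    for (k in seq_along(sc$cases)) {
      cs <- sc$cases[[k]]
      out[[length(out) + 1]] <- list(
        scenario = sc$name, case = k, n_points = sc$n_points,
        params = model_params(gamma_E = cs[["gamma_E"]],
                              gamma_S = cs[["gamma_S"]],
                              alpha = cs[["alpha"]], q = sc$q))
    }
  }
  out
}

coarse_opts <- function(n = 401) solver_options(n = n)

# small parameter sample reused by boundary-identity tests
param_sample <- function() {
  list(model_params(30, 30, 100, 5),
       model_params(20, 20, 50, 5),
       model_params(10, 10, 10, 1.5),
       model_params(1, 2, 0.5, 2),
       model_params(0.3, 0.7, 5, 3))
}
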