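# Shared simulation fixtures, computed once per test run and reused across
# files (the N = 1000 replicate sets are the expensive part of the suite).
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache, inherits = FALSE)
}

# 20-replicate equilibrium runs at N = 1000, U = 0.01, VS = 1: the reference
# cells for the genetic-variance, mean-fitness and mean-phenotype-fluctuation
# checks.
sim_n1000 <- function(vm) {
  key <- paste0("n1000_vm", vm)
  cached(key, run_simulation(sim_config(
    n = 1000, u = 0.01, vm = vm, vs = 1, replicates = 20,
    seed = if (vm == 1e-4) 301L else 302L
  )))
}

# Small-vs-large population comparison under an architecture with a small
# fitness-maximizing size (U = 0.2, VM = 0.02 gives Ne* ~ 6.3).
headline_sims <- function() {
  cached("headline", list(
    small = run_simulation(sim_config(
      n = 6, u = 0.2, vm = 0.02, vs = 1, burn_in = 1000, replicates = 6,
      seed = 61L
    )),
    large = run_simulation(sim_config(
      n = 600, u = 0.2, vm = 0.02, vs = 1, replicates = 6, seed = 62L
    ))
  ))
}

# The 20-replicate validation grid at N = 500 used for the coverage checks.
acceptance_grid <- function() {
  cached("grid500", run_sweep(sweep_grid(
    ne_values = 500, u_values = c(0.005, 0.01),
    vm_values = c(1e-4, 1e-3), vs = 1, replicates = 20, base_seed = 101L
  )))
}
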