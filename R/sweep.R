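#' Build a simulation-validation grid
#'
#' Expands population sizes, mutation rates and mutational variances into the
#' full factorial grid of cells used to validate the closed-form predictions
#' against simulation, with a deterministic seed per cell derived from
#' `base_seed` and the cell index (so reordering the grid does not change any
#' cell's result).
#'
#' @param ne_values Population sizes to simulate.
#' @param u_values Per-gamete mutation rates.
#' @param vm_values Effect-size variances of new mutations.
#' @param vs Inverse strength of stabilizing selection (fixed across the
#'   grid).
#' @param ve Environmental variance (fixed across the grid).
#' @param replicates Replicates per cell.
#' @param n_samples Recorded samples per replicate.
#' @param base_seed Integer seed from which all per-cell seeds derive.
#' @return A tibble with one row per `(ne, u, vm)` cell, plus `vs`, `ve`,
#'   `replicates`, `n_samples`, `cell` (index) and `seed`.
#' @export
sweep_grid <- function(ne_values, u_values, vm_values, vs = 1, ve = 0,
                       replicates = 20L, n_samples = 20L, base_seed = 1L) {
  stopifnot(length(ne_values) >= 1, length(u_values) >= 1,
            length(vm_values) >= 1)
  if (any(ne_values < 2) || any(u_values < 0) || any(vm_values <= 0)) {
    stop("grid values must be positive (ne >= 2, u >= 0, vm > 0).",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(ne = sort(ne_values), u = sort(u_values),
                             vm = sort(vm_values)) |>
    dplyr::mutate(
      vs = vs, ve = ve,
      replicates = as.integer(replicates),
      n_samples = as.integer(n_samples),
      cell = dplyr::row_number(),
      seed = derive_seed(base_seed, .data$cell * 1000L)
    )
  grid
}

#' Preset validation grids
#'
#' Two ready-made grids for [run_sweep()]: `"desk"` (N in \{500, 1000\},
#' U in \{0.005, 0.01\}, VM in \{1e-4, 1e-3\}, VS = 1, 20 replicates)
#' finishes within the hour on one core;
#' `"figure"` spans the full qualitative range of a publication-style
#' validation surface (N from 100 to 10000, U up to 0.05, VM up to 1e-2) and
#' takes hours — a warning says so when it is selected.
#'
#' @param scale `"desk"` or `"figure"`.
#' @param base_seed Passed to [sweep_grid()].
#' @return A [sweep_grid()] tibble.
#' @export
sweep_grid_preset <- function(scale = c("desk", "figure"), base_seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "desk") {
    return(sweep_grid(ne_values = c(500, 1000), u_values = c(0.005, 0.01),
                      vm_values = c(1e-4, 1e-3), vs = 1, replicates = 20,
                      base_seed = base_seed))
  }
  warning("the \"figure\" grid runs hundreds of long simulations and can ",
          "take hours on one core", call. = FALSE)
  sweep_grid(ne_values = c(100, 300, 1000, 3000, 10000),
             u_values = c(0.005, 0.01, 0.05),
             vm_values = c(1e-4, 1e-3, 1e-2), vs = 1, replicates = 20,
             base_seed = base_seed)
}

# simulate one grid cell and join it to the closed-form predictions
run_sweep_cell <- function(row, engine) {
  cfg <- sim_config(
    n = row$ne, u = row$u, vm = row$vm, vs = row$vs, ve = row$ve,
    replicates = row$replicates, n_samples = row$n_samples, seed = row$seed
  )
  sim <- run_simulation(cfg, engine = engine)
  s <- sim$summary
  pick <- function(q, col) s[[col]][s$quantity == q]
  pred <- predict_fitness(model_params(ne = row$ne, u = row$u, vm = row$vm,
                                       vs = row$vs, ve = row$ve))
  pbar_var_sim <- stats::var(sim$samples$pbar)
  tibble::tibble(
    predicted = pred$expected_wbar,
    simulated = pick("mean_fitness", "mean"),
    ci_low = pick("mean_fitness", "ci_low"),
    ci_high = pick("mean_fitness", "ci_high"),
    covered = ci_low <= pred$expected_wbar & pred$expected_wbar <= ci_high,
    vg_predicted = pred$vg,
    vg_simulated = pick("vg", "mean"),
    vg_ci_low = pick("vg", "ci_low"),
    vg_ci_high = pick("vg", "ci_high"),
    vg_covered = vg_ci_low <= pred$vg & pred$vg <= vg_ci_high,
    pbar_var_predicted = (row$vs + row$ve) / (2 * row$ne),
    pbar_var_simulated = pbar_var_sim
  )
}

#' Simulate every cell of a validation grid
#'
#' For each `(ne, u, vm)` cell of a [sweep_grid()], runs the configured
#' replicate simulations and places the across-replicate mean fitness and
#' genetic variance (with 95% CIs) next to the closed-form predictions.
#' `covered` records whether the simulated CI contains the predicted mean
#' fitness — the grid analogue of overlaying simulation points on prediction
#' curves. A failing cell is flagged (`failed`, `error`) without aborting the
#' remaining cells.
#'
#' The variance of the mean phenotype over time and replicates
#' (`pbar_var_simulated`) is reported next to its predicted value
#' `(vs + ve) / (2 * ne)` for use by [breakdown_diagnostics()].
#'
#' @param grid A [sweep_grid()] tibble.
#' @param engine Simulation engine, as in [run_replicate()].
#' @return A `stabsel_sweep` tibble: the grid columns plus `predicted`,
#'   `simulated`, `ci_low`, `ci_high`, `covered`, `vg_predicted`,
#'   `vg_simulated`, `vg_ci_low`, `vg_ci_high`, `vg_covered`,
#'   `pbar_var_predicted`, `pbar_var_simulated`, `failed`, `error`.
#' @export
run_sweep <- function(grid, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    row <- grid[i, ]
    res <- tryCatch(
      dplyr::mutate(run_sweep_cell(row, engine), failed = FALSE,
                    error = NA_character_),
      error = function(e) tibble::tibble(failed = TRUE,
                                         error = conditionMessage(e))
    )
    dplyr::bind_cols(row, res)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stabsel_sweep", class(out))
  out
}

#' Flag cells where the closed-form predictions are expected to break down
#'
#' Two failure modes bracket the theory's validity: (a) in very small
#' populations the normal approximation for the fluctuations of the mean
#' phenotype around the optimum degrades — flagged when the simulated
#' variance of the mean phenotype deviates from `(vs + ve) / (2 * ne)` by
#' more than 50%; (b) for strong mutational effects and high mutation rates
#' the stochastic house-of-cards formula underestimates the genetic variance
#' — flagged when the simulated VG confidence interval lies entirely above
#' the prediction.
#'
#' Cells without mutational input (`u = 0`) are never flagged: with no
#' segregating variance neither approximation is in play.
#'
#' @param cells A [run_sweep()] result.
#' @return The input tibble with logical columns `flag_small_ne`
#'   (mean-phenotype fluctuation breakdown) and `flag_vg_underestimate`
#'   (house-of-cards VG breakdown), plus `flagged` (either).
#' @export
breakdown_diagnostics <- function(cells) {
  cells |>
    tibble::as_tibble() |>
    dplyr::mutate(
      flag_small_ne = !.data$failed & .data$u > 0 &
        abs(.data$pbar_var_simulated - .data$pbar_var_predicted) >
          0.5 * .data$pbar_var_predicted,
      flag_vg_underestimate = !.data$failed &
        .data$vg_ci_low > .data$vg_predicted,
      flagged = .data$flag_small_ne | .data$flag_vg_underestimate
    )
}

#' Verify the rise-and-fall of expected mean fitness with population size
#'
#' When the finite-optimum condition `u > vm / (8 * (vs + ve))` holds,
#' expected mean fitness increases with `ne` up to a finite peak and
#' decreases beyond it. This check evaluates the closed form on a log-spaced
#' grid, locates the grid peak, verifies both neighbours are lower, and
#' compares the peak location with the analytic optimizer.
#'
#' @param u,vm,vs,ve Model parameters.
#' @param ne_grid Population-size grid; default 200 log-spaced points from 1
#'   to 1e8.
#' @return A one-row tibble with `peak_ne` (grid), `peak_wbar`, `ne_star`
#'   (analytic), and `within_one_step` (grid peak within one grid step of
#'   `ne_star`).
#' @export
nonmonotonic_fitness_check <- function(u, vm, vs = 1, ve = 0,
                                       ne_grid = 10^seq(0, 8,
                                                        length.out = 200)) {
  params <- model_params(ne = ne_grid, u = u, vm = vm, vs = vs, ve = ve)
  cond <- finite_optimum_condition(params[1, ])
  if (!cond$finite) {
    stop(sprintf(
      "no finite fitness-maximizing population size: u = %g does not exceed vm / (8 (vs + ve)) = %g.",
      u, cond$threshold_u), call. = FALSE)
  }
  wbar <- expected_mean_fitness(params)
  i <- which.max(wbar)
  if (i == 1 || i == length(ne_grid)) {
    stop("peak lies on the boundary of `ne_grid`; widen the grid.",
         call. = FALSE)
  }
  if (wbar[i - 1] >= wbar[i] || wbar[i + 1] >= wbar[i]) {
    stop("no interior rise-and-fall peak found on `ne_grid`.", call. = FALSE)
  }
  ne_star <- optimal_ne(params[1, ])$ne_star
  step <- ne_grid[i + 1] / ne_grid[i]
  tibble::tibble(
    peak_ne = ne_grid[i], peak_wbar = wbar[i], ne_star = ne_star,
    within_one_step = ne_star / ne_grid[i] < step &
      ne_grid[i] / ne_star < step
  )
}
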