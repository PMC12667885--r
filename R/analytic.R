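#' Gaussian stabilizing-selection fitness
#'
#' Relative fitness of an individual with trait value `p` under a Gaussian
#' fitness function centred on the optimum: `exp(-(p - optimum)^2 / (2 * vs))`.
#' An individual at the optimum has fitness one. With `absorb_ve = TRUE` the
#' environmental variance is folded into the width of the fitness function
#' (`vs + ve`), which is the expected fitness of a genotypic value `p` once
#' uncorrelated environmental noise is averaged over.
#'
#' @param p Trait value(s); must be finite.
#' @param params Parameter tibble from [model_params()] (fields `vs`, `ve`,
#'   `optimum` are used; one row, or recycled against `p`).
#' @param absorb_ve If `TRUE`, use `vs + ve` as the effective width.
#' @return Relative fitness in `(0, 1]`, same length as `p`.
#' @examples
#' gaussian_fitness(0, model_params(ne = 1, u = 0, vm = 1, vs = 1))
#' @export
gaussian_fitness <- function(p, params, absorb_ve = FALSE) {
  params <- validate_params(params)
  if (any(!is.finite(p))) stop("`p` must be finite.", call. = FALSE)
  width <- if (absorb_ve) vs_effective(params) else params$vs
  exp(-(p - params$optimum)^2 / (2 * width))
}

#' Mean fitness of a Gaussian phenotype distribution
#'
#' Population mean fitness when phenotypes are normally distributed with mean
#' `pbar` and variance `vp` around an optimum at zero:
#' `sqrt(vs / (vp + vs)) * exp(-pbar^2 / (2 * (vp + vs)))`.
#' This is the Gaussian integral of the fitness function over the phenotype
#' distribution in closed form.
#'
#' @param pbar Mean phenotype (displacement from the optimum).
#' @param vp Phenotypic variance, `>= 0`.
#' @param vs Inverse strength of stabilizing selection, `> 0`.
#' @return Mean fitness in `(0, 1]`. Vectorized over all arguments.
#' @seealso [mean_fitness_numeric()] for the quadrature oracle.
#' @export
mean_fitness_at <- function(pbar, vp, vs) {
  if (any(vs <= 0)) stop("`vs` must be > 0.", call. = FALSE)
  if (any(vp < 0)) stop("`vp` must be >= 0.", call. = FALSE)
  sqrt(vs / (vp + vs)) * exp(-pbar^2 / (2 * (vp + vs)))
}

#' Expected mean fitness given the phenotypic variance
#'
#' Expectation of population mean fitness over drift-driven fluctuations of
#' the mean phenotype around the optimum. The mean phenotype's displacement is
#' normal with variance `vs / (2 * ne)`; integrating mean fitness over that
#' distribution gives
#' `sqrt(2 * ne * vs / (vs + 2 * ne * (vp + vs)))`.
#' In the limit `ne -> Inf` this recovers `sqrt(vs / (vp + vs))`.
#'
#' @param ne Effective population size, `>= 1` (may be `Inf`).
#' @param vp Phenotypic variance, `>= 0`.
#' @param vs Inverse strength of stabilizing selection, `> 0`.
#' @return Expected mean fitness in `(0, 1]`. Vectorized.
#' @seealso [expected_mean_fitness_numeric()] for the nested-quadrature oracle.
#' @export
expected_mean_fitness_given_vp <- function(ne, vp, vs) {
  if (any(vs <= 0)) stop("`vs` must be > 0.", call. = FALSE)
  if (any(vp < 0)) stop("`vp` must be >= 0.", call. = FALSE)
  if (any(ne < 1)) stop("`ne` must be >= 1.", call. = FALSE)
  # written as 1 / (1/(2 ne) + ...) so ne = Inf gives the infinite-size limit
  sqrt(vs / (vs / (2 * ne) + vp + vs))
}

#' Equilibrium genetic variance under the stochastic house-of-cards model
#'
#' Additive genetic variance at mutation-selection-drift balance,
#' interpolating between the house-of-cards regime (`4 * u * vs`, strong
#' effects) and the drift-dominated regime (`4 * ne * u * vm`, weak effects):
#' `4 * u * vs / (1 + vs / (ne * vm))`. Environmental variance is absorbed
#' into the width of the fitness function (`vs + ve`).
#'
#' @param params Parameter tibble from [model_params()].
#' @return Genetic variance (trait units squared), one value per row.
#' @export
vg_shoc <- function(params) {
  params <- validate_params(params)
  vs_eff <- vs_effective(params)
  4 * params$u * vs_eff / (1 + vs_eff / (params$ne * params$vm))
}

#' Expected mean fitness at mutation-selection-drift balance
#'
#' The central closed-form prediction: substituting the stochastic
#' house-of-cards genetic variance into the expectation of mean fitness over
#' mean-phenotype fluctuations gives
#' \deqn{E[\bar w] = \left[\frac{2 N_e}{1 + 2 N_e \left(1 +
#'   \frac{4 N_e U V_M}{N_e V_M + V_S}\right)}\right]^{1/2},}
#' with the environmental variance absorbed into `vs` (`vs + ve`).
#'
#' @param params Parameter tibble from [model_params()].
#' @return Expected mean fitness in `(0, 1]`, one value per row.
#' @seealso [load_approx()] for the small/large-size load limits,
#'   [optimal_ne()] for the size that maximizes this quantity.
#' @export
expected_mean_fitness <- function(params) {
  params <- validate_params(params)
  emf_closed_form(params$ne, params$u, params$vm, vs_effective(params))
}

# the closed form itself, valid for any ne > 0 (the optimizer probes below 1)
emf_closed_form <- function(ne, u, vm, vs_eff) {
  sqrt(2 * ne / (1 + 2 * ne * (1 + 4 * ne * u * vm / (ne * vm + vs_eff))))
}

#' Approximate genetic load
#'
#' First-order expansion of `1 - expected_mean_fitness(params)`:
#' `2 * ne * vm * u / (ne * vm + vs) + 1 / (4 * ne)` (with `vs + ve` for
#' `vs`). It makes the two limits legible: the load tends to roughly `2 * u`
#' as `ne` grows (an overestimate) and to `1 / (4 * ne)` as `u -> 0`. The
#' exact expression from [expected_mean_fitness()] remains the primary
#' prediction; this truncation is only indicative away from the limits.
#'
#' @param params Parameter tibble from [model_params()].
#' @return Approximate load (dimensionless), one value per row.
#' @export
load_approx <- function(params) {
  params <- validate_params(params)
  vs_eff <- vs_effective(params)
  ne <- params$ne
  2 * ne * params$vm * params$u / (ne * params$vm + vs_eff) + 1 / (4 * ne)
}

#' Condition for a finite fitness-maximizing population size
#'
#' Expected mean fitness is maximized at a finite population size precisely
#' when the total mutation rate exceeds `vm / (8 * (vs + ve))`. Returns the
#' condition and its thresholds: `threshold_u` on the per-gamete mutation
#' rate and, when the per-base rate `mu` is available, the equivalent
#' threshold on the mutational target size, `threshold_l = vm / (8 * mu *
#' (vs + ve))`.
#'
#' @param params Parameter tibble from [model_params()].
#' @return A tibble with columns `finite` (logical), `threshold_u`,
#'   `threshold_l` (`NA` when `mu` is not set), one row per parameter row.
#' @export
finite_optimum_condition <- function(params) {
  params <- validate_params(params)
  vs_eff <- vs_effective(params)
  threshold_u <- params$vm / (8 * vs_eff)
  threshold_l <- ifelse(is.na(params$mu), NA_real_,
                        params$vm / (8 * params$mu * vs_eff))
  tibble::tibble(
    finite = params$u > threshold_u,
    threshold_u = threshold_u,
    threshold_l = threshold_l
  )
}

#' Population size maximizing expected mean fitness
#'
#' Solves for the stationary point of [expected_mean_fitness()] in `ne`. A
#' finite maximum exists exactly when `8 * u * (vs + ve) > vm` (strict); it is
#' then
#' \deqn{N_e^* = \frac{V_S (1 + \sqrt{8 U V_S / V_M})}{8 U V_S - V_M},}
#' with `vs + ve` in place of `vs`. At or below the boundary the expected mean
#' fitness is non-decreasing in `ne` and no finite optimum exists.
#'
#' The `ne` column of `params` is ignored; the optimum is over all positive
#' sizes, treated as continuous.
#'
#' @param params Parameter tibble from [model_params()].
#' @return A tibble with columns `finite`, `ne_star` (`NA` when no finite
#'   optimum), `threshold_u`, `threshold_l`, one row per parameter row.
#' @seealso [optimal_ne_numeric()] for the numeric-maximization oracle,
#'   [nonmonotonic_fitness_check()] for a grid-based verification.
#' @export
optimal_ne <- function(params) {
  params <- validate_params(params)
  vs_eff <- vs_effective(params)
  cond <- finite_optimum_condition(params)
  denom <- 8 * params$u * vs_eff - params$vm
  ne_star <- ifelse(
    cond$finite,
    vs_eff * (1 + sqrt(8 * params$u * vs_eff / params$vm)) / denom,
    NA_real_
  )
  tibble::add_column(cond, ne_star = ne_star, .after = "finite")
}

#' All equilibrium predictions for a table of parameters
#'
#' The main tidy interface to the analytic model: takes a parameter table
#' (one row per parameter combination) and appends every closed-form
#' prediction as a column, so results pipe straight into dplyr/ggplot2.
#'
#' @param params Parameter tibble from [model_params()] (or any data frame
#'   with columns `ne`, `u`, `vm`, `vs`, and optionally `ve`, `optimum`,
#'   `mu`, `l`).
#' @return The input tibble with added columns:
#'   \describe{
#'     \item{vg}{stochastic house-of-cards genetic variance ([vg_shoc()])}
#'     \item{expected_wbar}{expected mean fitness ([expected_mean_fitness()])}
#'     \item{load}{`1 - expected_wbar`}
#'     \item{load_first_order}{the truncated expansion ([load_approx()])}
#'     \item{pbar_var}{variance of the mean-phenotype displacement,
#'       `(vs + ve) / (2 * ne)`}
#'     \item{finite, ne_star, threshold_u, threshold_l}{finite-optimum
#'       condition and optimizer ([optimal_ne()])}
#'   }
#' @examples
#' model_params(ne = c(10, 100, 1000), u = 0.01, vm = 0.01) |>
#'   predict_fitness()
#' @export
predict_fitness <- function(params) {
  params <- validate_params(params)
  opt <- optimal_ne(params)
  dplyr::mutate(
    params,
    vg = vg_shoc(params),
    expected_wbar = expected_mean_fitness(params),
    load = 1 - .data$expected_wbar,
    load_first_order = load_approx(params),
    pbar_var = vs_effective(params) / (2 * .data$ne),
    finite = opt$finite,
    ne_star = opt$ne_star,
    threshold_u = opt$threshold_u,
    threshold_l = opt$threshold_l
  )
}
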