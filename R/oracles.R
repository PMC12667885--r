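#' Mean fitness by adaptive quadrature
#'
#' Numeric oracle for [mean_fitness_at()]: integrates the Gaussian fitness
#' function against a normal phenotype distribution with
#' [stats::integrate()] over `pbar +/- 12` phenotypic standard deviations.
#' Used in tests to check the closed form; it never replaces it.
#'
#' @inheritParams mean_fitness_at
#' @param rel_tol Relative tolerance passed to the quadrature.
#' @return Mean fitness (scalar; arguments must be length one).
#' @export
mean_fitness_numeric <- function(pbar, vp, vs, rel_tol = 1e-12) {
  stopifnot(length(pbar) == 1, length(vp) == 1, length(vs) == 1, vs > 0,
            vp >= 0)
  if (vp == 0) {
    return(exp(-pbar^2 / (2 * vs)))
  }
  sd_p <- sqrt(vp)
  out <- stats::integrate(
    function(p) exp(-p^2 / (2 * vs)) * stats::dnorm(p, mean = pbar, sd = sd_p),
    lower = pbar - 12 * sd_p, upper = pbar + 12 * sd_p,
    rel.tol = rel_tol, abs.tol = 1e-14, subdivisions = 400L
  )
  if (out$message != "OK") stop("quadrature failed: ", out$message,
                                call. = FALSE)
  out$value
}

#' Expected mean fitness by nested adaptive quadrature
#'
#' Numeric oracle for [expected_mean_fitness_given_vp()]: evaluates the
#' double integral of mean fitness over both the phenotype distribution
#' (inner, via [mean_fitness_numeric()]) and the normal distribution of the
#' mean-phenotype displacement with variance `vs / (2 * ne)` (outer), each by
#' adaptive quadrature over +/- 12 standard deviations. Used only to verify
#' the closed form.
#'
#' @inheritParams expected_mean_fitness_given_vp
#' @param rel_tol Relative tolerance for both quadrature levels.
#' @return Expected mean fitness (scalar).
#' @export
expected_mean_fitness_numeric <- function(ne, vp, vs, rel_tol = 1e-10) {
  stopifnot(length(ne) == 1, length(vp) == 1, length(vs) == 1,
            ne >= 1, vp >= 0, vs > 0)
  sd_d <- sqrt(vs / (2 * ne))
  inner <- Vectorize(function(pb) mean_fitness_numeric(pb, vp, vs,
                                                       rel_tol = rel_tol))
  out <- stats::integrate(
    function(pb) stats::dnorm(pb, mean = 0, sd = sd_d) * inner(pb),
    lower = -12 * sd_d, upper = 12 * sd_d,
    rel.tol = rel_tol, abs.tol = 1e-13, subdivisions = 400L
  )
  if (out$message != "OK") stop("quadrature failed: ", out$message,
                                call. = FALSE)
  out$value
}

#' Fitness-maximizing population size by numeric maximization
#'
#' Numeric oracle for [optimal_ne()]: maximizes [expected_mean_fitness()]
#' over `log(ne)` with a coarse log-spaced bracketing scan over
#' `ne` in `[1e-2, 1e10]` followed by golden-section refinement
#' ([stats::optimize()]). The size is treated as continuous.
#'
#' @param params Parameter tibble from [model_params()]; must have one row
#'   (`ne` is ignored).
#' @param tol Relative tolerance on the maximizer.
#' @return The maximizing `ne` (scalar), or `Inf` when the scan finds the
#'   objective still increasing at the upper end of the bracket.
#' @export
optimal_ne_numeric <- function(params, tol = 1e-9) {
  params <- validate_params(params)
  stopifnot(nrow(params) == 1)
  vs_eff <- vs_effective(params)
  objective <- function(log_ne) {
    emf_closed_form(exp(log_ne), params$u, params$vm, vs_eff)
  }
  grid <- log(10^seq(-2, 10, length.out = 241))
  vals <- vapply(grid, objective, numeric(1))
  i <- which.max(vals)
  if (i == length(grid)) {
    return(Inf)
  }
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(objective, lower = lo, upper = hi, maximum = TRUE,
                         tol = tol)
  exp(opt$maximum)
}
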