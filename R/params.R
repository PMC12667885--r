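#' Build a table of model parameter combinations
#'
#' Constructs and validates the parameter bundle consumed by every analytic
#' prediction: the effective population size `ne`, the total per-gamete
#' mutation rate `u` at trait-affecting loci, the variance `vm` of the
#' effect-size distribution of new mutations, the (inverse) strength of
#' stabilizing selection `vs`, the environmental variance `ve`, and the trait
#' optimum. Arguments are recycled to a common length with
#' [vctrs::vec_recycle()] semantics (via [tibble::tibble()]), so vectors of
#' parameter values give one row per combination supplied.
#'
#' When the per-base haploid mutation rate `mu` and the mutational target size
#' `l` (in bases) are both given, they must satisfy `u = mu * l`; when `u` is
#' omitted it is filled in as `mu * l`.
#'
#' @param ne Effective population size (diploid individuals), `>= 1`.
#' @param u Total per-gamete mutation rate per generation across all
#'   trait-affecting loci, `>= 0`. May be omitted if `mu` and `l` are given.
#' @param vm Variance of the effect-size distribution of new mutations
#'   (trait units squared), `> 0`.
#' @param vs Inverse strength of stabilizing selection (trait units squared),
#'   `> 0`; larger `vs` means weaker selection.
#' @param ve Environmental variance (trait units squared), `>= 0`.
#' @param optimum Optimal trait value (trait units).
#' @param mu Optional per-base haploid mutation rate per generation.
#' @param l Optional mutational target size in bases.
#'
#' @return A tibble with one row per parameter combination and columns
#'   `ne`, `u`, `vm`, `vs`, `ve`, `optimum`, `mu`, `l` (the last two `NA`
#'   when not supplied).
#' @examples
#' model_params(ne = c(100, 1000), u = 0.01, vm = 1e-3)
#' model_params(ne = 1000, mu = 1e-8, l = 1e6, vm = 1e-3)
#' @export
model_params <- function(ne, u = NULL, vm, vs = 1, ve = 0, optimum = 0,
                         mu = NA_real_, l = NA_real_) {
  if (is.null(u)) {
    if (anyNA(mu) || anyNA(l)) {
      stop("`u` must be given unless both `mu` and `l` are supplied.",
           call. = FALSE)
    }
    u <- mu * l
  }
  params <- tibble::tibble(
    ne = as.numeric(ne), u = as.numeric(u), vm = as.numeric(vm),
    vs = as.numeric(vs), ve = as.numeric(ve), optimum = as.numeric(optimum),
    mu = as.numeric(mu), l = as.numeric(l)
  )
  validate_params(params)
}

#' Validate a parameter table
#'
#' Checks the invariants every analytic operation relies on and returns the
#' table unchanged. Called internally by [model_params()] and by every
#' function that accepts a parameter tibble, so hand-built data frames get
#' the same checks.
#'
#' @param params A data frame with at least the columns `ne`, `u`, `vm`, `vs`;
#'   missing `ve`, `optimum`, `mu`, `l` columns are filled with defaults.
#' @return The validated parameter tibble.
#' @keywords internal
#' @export
validate_params <- function(params) {
  params <- tibble::as_tibble(params)
  required <- c("ne", "u", "vm", "vs")
  missing_cols <- setdiff(required, names(params))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"ve" %in% names(params)) params$ve <- 0
  if (!"optimum" %in% names(params)) params$optimum <- 0
  if (!"mu" %in% names(params)) params$mu <- NA_real_
  if (!"l" %in% names(params)) params$l <- NA_real_

  check_field(params$ne, "ne", lower = 1)
  check_field(params$u, "u", lower = 0)
  check_field(params$vm, "vm", lower = 0, strict = TRUE)
  check_field(params$vs, "vs", lower = 0, strict = TRUE, allow_inf = TRUE)
  check_field(params$ve, "ve", lower = 0)
  if (any(!is.finite(params$optimum))) {
    stop("`optimum` must be finite.", call. = FALSE)
  }
  both <- !is.na(params$mu) & !is.na(params$l)
  if (any(both)) {
    rel <- abs(params$u[both] - params$mu[both] * params$l[both]) /
      pmax(params$u[both], .Machine$double.xmin)
    if (any(rel > 1e-12)) {
      stop("`u` must equal `mu * l` (relative tolerance 1e-12) ",
           "when both `mu` and `l` are set.", call. = FALSE)
    }
  }
  params
}

# shared numeric-range check; `allow_inf` admits vs = Inf (selection switched
# off, used by the simulator's neutral mode)
check_field <- function(x, name, lower, strict = FALSE, allow_inf = FALSE) {
  bad_na <- any(is.na(x))
  bad_inf <- if (allow_inf) FALSE else any(is.infinite(x))
  bad_range <- if (strict) any(x <= lower, na.rm = TRUE) else
    any(x < lower, na.rm = TRUE)
  if (bad_na || bad_inf || bad_range) {
    cmp <- if (strict) ">" else ">="
    stop(sprintf("`%s` must be finite and %s %s.", name, cmp, lower),
         call. = FALSE)
  }
  invisible(x)
}

# effective width of the fitness function once uncorrelated environmental
# noise is absorbed: vs + ve
vs_effective <- function(params) params$vs + params$ve
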