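#' Configure a Wright-Fisher simulation
#'
#' Bundles and validates everything one forward simulation needs: a diploid,
#' monoecious Wright-Fisher population of census size `n` (selfing allowed),
#' an additive trait with infinite-sites mutation at per-gamete rate `u` per
#' generation and effects drawn from `Normal(0, vm)`, Gaussian stabilizing
#' selection of width `vs` towards `optimum`, and optional uncorrelated
#' environmental noise of variance `ve` redrawn each generation. Mutations
#' segregate at unlinked sites (free recombination); fixed mutations are
#' folded into a phenotype offset so the drift of the population mean away
#' from the optimum is retained.
#'
#' @param n Census population size (diploid individuals), `>= 2`.
#' @param u Per-gamete mutation rate per generation, `>= 0`.
#' @param vm Effect-size variance of new mutations, `> 0`.
#' @param vs Inverse strength of stabilizing selection, `> 0`; `Inf` switches
#'   selection off (every individual has fitness one).
#' @param ve Environmental variance, `>= 0`.
#' @param optimum Trait optimum.
#' @param burn_in Generations run before any recording; default `10 * n`.
#' @param record_every Generations between recorded samples; default
#'   `max(1, round(n / 10))`.
#' @param n_samples Number of recorded samples per replicate.
#' @param replicates Number of independent replicate runs.
#' @param seed Integer seed; replicate seeds are derived from it
#'   deterministically.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, u, vm, vs = 1, ve = 0, optimum = 0,
                       burn_in = 10L * n, record_every = max(1L, round(n / 10)),
                       n_samples = 20L, replicates = 1L, seed = 1L) {
  n <- as.integer(n)
  stopifnot(length(n) == 1, length(u) == 1, length(vm) == 1, length(vs) == 1)
  if (n < 2) stop("`n` must be >= 2.", call. = FALSE)
  if (u < 0) stop("`u` must be >= 0.", call. = FALSE)
  if (vm <= 0) stop("`vm` must be > 0.", call. = FALSE)
  if (vs <= 0) stop("`vs` must be > 0.", call. = FALSE)
  if (ve < 0) stop("`ve` must be >= 0.", call. = FALSE)
  burn_in <- as.integer(burn_in)
  record_every <- as.integer(record_every)
  n_samples <- as.integer(n_samples)
  replicates <- as.integer(replicates)
  if (burn_in < 0) stop("`burn_in` must be >= 0.", call. = FALSE)
  if (record_every < 1) stop("`record_every` must be >= 1.", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be >= 1.", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1.", call. = FALSE)
  structure(
    list(n = n, u = u, vm = vm, vs = vs, ve = ve, optimum = optimum,
         burn_in = burn_in, record_every = record_every,
         n_samples = n_samples, replicates = replicates,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> Wright-Fisher, diploid N =", x$n, "\n")
  cat("  u =", x$u, " vm =", x$vm, " vs =", x$vs, " ve =", x$ve,
      " optimum =", x$optimum, "\n")
  cat("  burn_in =", x$burn_in, " record_every =", x$record_every,
      " n_samples =", x$n_samples, " replicates =", x$replicates,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Derive a child seed from a base seed and an index
#'
#' Deterministic seed stream used for replicate and sweep-cell seeding
#' (a Lehmer congruential step): the same `(base_seed, index)` pair always
#' yields the same child seed, and seeds stay within R's integer range.
#' Doubles are exact here (inputs < 2^31, product < 2^47 < 2^53) and the
#' result lies in `[1, 2^31 - 2]`.
#'
#' @param base_seed Integer base seed.
#' @param index Integer stream index (e.g. replicate number, cell number).
#' @return An integer seed.
#' @export
derive_seed <- function(base_seed, index) {
  x <- (as.numeric(base_seed) * 48271 + as.numeric(index)) %% 2147483647
  as.integer(x %% 2147483645) + 1L
}

#' Create an explicit population state
#'
#' The per-individual bookkeeping used by the pure-R engine and by the unit
#' operations [mutate_population()], [phenotypes_and_fitness()],
#' [reproduce_population()] and [prune_fixed()]: a genotype matrix of copy
#' numbers (0/1/2) for each segregating mutation, the vector of additive
#' effects, and a scalar offset carrying the summed contribution of fixed
#' mutations.
#'
#' @param n Number of diploid individuals.
#' @param genotypes Integer matrix, `n` rows, one column per segregating
#'   mutation, entries in `{0, 1, 2}`.
#' @param effects Numeric vector of additive effects, one per column.
#' @param offset Phenotypic contribution of fixed mutations.
#' @param generation Generation counter.
#' @return A `population_state` list.
#' @export
population_state <- function(n, genotypes = matrix(0L, n, 0),
                             effects = numeric(0), offset = 0,
                             generation = 0L) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(nrow(genotypes) == n, ncol(genotypes) == length(effects))
  if (length(genotypes) > 0 &&
      (min(genotypes) < 0 || max(genotypes) > 2)) {
    stop("genotype counts must be 0, 1 or 2.", call. = FALSE)
  }
  structure(list(n = as.integer(n), genotypes = genotypes,
                 effects = as.numeric(effects), offset = offset,
                 generation = as.integer(generation)),
            class = "population_state")
}

#' Genetic values of all individuals
#'
#' `offset + genotypes %*% effects`, the additive genetic value of each
#' individual.
#'
#' @param pop A [population_state()].
#' @return Numeric vector of length `n`.
#' @export
genetic_values <- function(pop) {
  if (ncol(pop$genotypes) == 0) {
    return(rep(pop$offset, pop$n))
  }
  pop$offset + as.vector(pop$genotypes %*% pop$effects)
}

#' Add new mutations to every gamete of a population
#'
#' Each of the `2n` gametes receives a `Poisson(u)` number of new mutations,
#' each at a unique new site (infinite sites) with effect drawn from
#' `Normal(0, vm)`; a new mutation enters heterozygous in its carrier. The
#' expected number of new mutations per generation is `2 * n * u`.
#'
#' @param pop A [population_state()].
#' @param cfg A [sim_config()] (fields `u`, `vm` are used).
#' @return The updated `population_state`.
#' @export
mutate_population <- function(pop, cfg) {
  if (cfg$u == 0) {
    return(pop)
  }
  k <- stats::rpois(2L * pop$n, cfg$u)
  total <- sum(k)
  if (total == 0) {
    return(pop)
  }
  carriers <- rep((seq_len(2L * pop$n) + 1L) %/% 2L, k)
  new_cols <- matrix(0L, pop$n, total)
  new_cols[cbind(carriers, seq_len(total))] <- 1L
  pop$genotypes <- cbind(pop$genotypes, new_cols)
  pop$effects <- c(pop$effects, stats::rnorm(total, 0, sqrt(cfg$vm)))
  pop
}

#' Phenotypes and fitnesses of a population
#'
#' Phenotype is the genetic value plus, when `ve > 0`, fresh
#' `Normal(0, ve)` environmental noise; fitness is the Gaussian
#' stabilizing-selection function of the phenotype.
#'
#' @param pop A [population_state()].
#' @param cfg A [sim_config()].
#' @return A list with numeric vectors `phenotypes` and `fitnesses`.
#' @export
phenotypes_and_fitness <- function(pop, cfg) {
  p <- genetic_values(pop)
  if (cfg$ve > 0) p <- p + stats::rnorm(pop$n, 0, sqrt(cfg$ve))
  w <- if (is.finite(cfg$vs)) {
    exp(-(p - cfg$optimum)^2 / (2 * cfg$vs))
  } else {
    rep(1, pop$n)
  }
  list(phenotypes = p, fitnesses = w)
}

#' One round of fitness-weighted Wright-Fisher reproduction
#'
#' Draws `n` offspring; each offspring's two parents are sampled
#' independently with probability proportional to fitness (selfing allowed).
#' Each parent transmits every mutation it carries homozygous, and each
#' heterozygous mutation with probability 1/2, independently across sites
#' (free recombination). The generation counter increments. Mutation and
#' pruning are separate steps.
#'
#' @param pop A [population_state()].
#' @param fitnesses Positive numeric vector of length `n`.
#' @param cfg A [sim_config()].
#' @return The offspring `population_state`.
#' @export
reproduce_population <- function(pop, fitnesses, cfg) {
  stopifnot(length(fitnesses) == pop$n)
  if (max(fitnesses) <= 0) {
    stop("all fitnesses underflowed to zero; use a larger vs or smaller vm.",
         call. = FALSE)
  }
  n <- pop$n
  m <- ncol(pop$genotypes)
  parents <- matrix(
    sample.int(n, 2L * n, replace = TRUE, prob = fitnesses), ncol = 2
  )
  if (m == 0) {
    pop$generation <- pop$generation + 1L
    return(pop)
  }
  gamete_from <- function(idx) {
    g <- pop$genotypes[idx, , drop = FALSE]
    (g == 2L) + (g == 1L) * matrix(stats::rbinom(n * m, 1L, 0.5), n, m)
  }
  offspring <- gamete_from(parents[, 1]) + gamete_from(parents[, 2])
  storage.mode(offspring) <- "integer"
  pop$genotypes <- offspring
  pop$generation <- pop$generation + 1L
  pop
}

#' Fold fixed mutations into the offset and drop lost ones
#'
#' Mutations present in all `2n` copies are removed from the genotype matrix
#' and `2 * effect` is added to the offset; mutations at count zero are
#' removed. No individual's genetic value changes.
#'
#' @param pop A [population_state()].
#' @return The pruned `population_state`.
#' @export
prune_fixed <- function(pop) {
  m <- ncol(pop$genotypes)
  if (m == 0) {
    return(pop)
  }
  counts <- colSums(pop$genotypes)
  fixed <- counts == 2L * pop$n
  lost <- counts == 0L
  if (any(fixed)) pop$offset <- pop$offset + 2 * sum(pop$effects[fixed])
  keep <- !(fixed | lost)
  pop$genotypes <- pop$genotypes[, keep, drop = FALSE]
  pop$effects <- pop$effects[keep]
  pop
}

# one full generation of the pure-R engine
step_population <- function(pop, cfg) {
  w <- phenotypes_and_fitness(pop, cfg)$fitnesses
  pop <- reproduce_population(pop, w, cfg)
  pop <- mutate_population(pop, cfg)
  prune_fixed(pop)
}

record_population <- function(pop, cfg) {
  g <- genetic_values(pop)
  w <- phenotypes_and_fitness(pop, cfg)$fitnesses
  c(mean_fitness = mean(w), vg = stats::var(g) * (pop$n - 1) / pop$n,
    pbar = mean(g))
}

#' Run one simulation replicate
#'
#' Runs `burn_in` generations from a mutation-free population, then records
#' the population mean fitness, the genetic variance (census variance of
#' genetic values) and the mean genetic value every `record_every`
#' generations, `n_samples` times. Fully reproducible: the RNG is seeded from
#' `seed` at the start of the replicate.
#'
#' The default `engine = "cpp"` uses the compiled core; `engine = "r"` runs
#' the same model through the step functions [mutate_population()],
#' [reproduce_population()] and [prune_fixed()] (identical model, different
#' RNG call sequence; use it for small populations only).
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for this replicate; defaults to `cfg$seed`.
#' @param engine `"cpp"` or `"r"`.
#' @return A tibble with columns `generation`, `mean_fitness`, `vg`, `pbar`.
#' @export
run_replicate <- function(cfg, seed = cfg$seed, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  set.seed(as.integer(seed))
  if (engine == "cpp") {
    res <- wf_run_cpp(cfg$n, cfg$u, cfg$vm, cfg$vs, cfg$ve, cfg$optimum,
                      cfg$burn_in, cfg$record_every, cfg$n_samples)
    return(tibble::tibble(
      generation = res$generation, mean_fitness = res$mean_fitness,
      vg = res$vg, pbar = res$pbar
    ))
  }
  pop <- population_state(cfg$n)
  for (t in seq_len(cfg$burn_in)) pop <- step_population(pop, cfg)
  out <- matrix(NA_real_, cfg$n_samples, 3)
  gens <- integer(cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    out[s, ] <- record_population(pop, cfg)
    gens[s] <- pop$generation
    if (s < cfg$n_samples) {
      for (t in seq_len(cfg$record_every)) pop <- step_population(pop, cfg)
    }
  }
  tibble::tibble(generation = gens, mean_fitness = out[, 1], vg = out[, 2],
                 pbar = out[, 3])
}

#' Run replicate Wright-Fisher simulations
#'
#' Runs `cfg$replicates` independent replicates (seeds derived
#' deterministically from `cfg$seed`) and aggregates them: per-replicate
#' means over recorded samples, and across-replicate means with
#' normal-approximation 95% confidence intervals.
#'
#' @param cfg A [sim_config()].
#' @param engine Passed to [run_replicate()].
#' @return A `wf_sim` object: a list with
#'   \describe{
#'     \item{samples}{tibble of every recorded sample
#'       (`replicate`, `generation`, `mean_fitness`, `vg`, `pbar`)}
#'     \item{replicate_means}{tibble of per-replicate time averages}
#'     \item{summary}{tibble of across-replicate mean and 95% CI per
#'       quantity (from [summarize_replicates()]); `NULL` for a single
#'       replicate}
#'     \item{config}{the `sim_config` used}
#'   }
#' @examples
#' cfg <- sim_config(n = 100, u = 0.01, vm = 1e-3, replicates = 3,
#'                   n_samples = 5, seed = 42)
#' sim <- run_simulation(cfg)
#' glance(sim)
#' @export
run_simulation <- function(cfg, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "sim_config"))
  samples <- purrr::map_dfr(seq_len(cfg$replicates), function(r) {
    dplyr::mutate(
      run_replicate(cfg, seed = derive_seed(cfg$seed, r), engine = engine),
      replicate = r, .before = 1
    )
  })
  replicate_means <- samples |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(dplyr::across(c("mean_fitness", "vg", "pbar"), mean),
                     .groups = "drop")
  summary <- if (cfg$replicates >= 2) summarize_replicates(replicate_means)
             else NULL
  structure(list(samples = samples, replicate_means = replicate_means,
                 summary = summary, config = cfg),
            class = "wf_sim")
}

#' Across-replicate means with 95% confidence intervals
#'
#' Normal-approximation intervals over replicate means:
#' `mean +/- 1.96 * se`, with `se` the standard error of the replicate means.
#'
#' @param replicate_means A data frame of per-replicate means with a
#'   `replicate` column and one column per quantity (as in
#'   `wf_sim$replicate_means`), or any data frame of replicate-level values.
#' @return A tibble with columns `quantity`, `mean`, `se`, `ci_low`,
#'   `ci_high`, `n_replicates`.
#' @export
summarize_replicates <- function(replicate_means) {
  replicate_means <- tibble::as_tibble(replicate_means)
  vals <- dplyr::select(replicate_means, -dplyr::any_of("replicate"))
  if (nrow(vals) < 2) {
    stop("at least 2 replicates are required for a confidence interval.",
         call. = FALSE)
  }
  vals |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "quantity") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_low = .data$mean - 1.96 * .data$se,
                  ci_high = .data$mean + 1.96 * .data$se) |>
    dplyr::select("quantity", "mean", "se", "ci_low", "ci_high",
                  "n_replicates")
}

#' @export
print.wf_sim <- function(x, ...) {
  cfg <- x$config
  cat("<wf_sim>", cfg$replicates, "replicate(s), N =", cfg$n,
      ", u =", cfg$u, ", vm =", cfg$vm, ", vs =", cfg$vs, "\n")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Wright-Fisher simulation
#'
#' Returns the recorded samples as a long-friendly tibble, one row per
#' replicate and recorded generation.
#'
#' @param x A `wf_sim` object.
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `generation`, `mean_fitness`,
#'   `vg`, `pbar`.
#' @export
tidy.wf_sim <- function(x, ...) x$samples

#' One-row summary of a Wright-Fisher simulation
#'
#' Across-replicate means of mean fitness, genetic variance and mean
#' phenotype, with 95% CI half-widths, next to the closed-form predictions
#' for the same parameters.
#'
#' @param x A `wf_sim` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.wf_sim <- function(x, ...) {
  cfg <- x$config
  pred <- predict_fitness(model_params(
    ne = cfg$n, u = cfg$u, vm = cfg$vm,
    vs = if (is.finite(cfg$vs)) cfg$vs else 1e12, ve = cfg$ve
  ))
  rm <- x$replicate_means
  ci_hw <- function(v) {
    if (nrow(rm) < 2) NA_real_
    else 1.96 * stats::sd(v) / sqrt(length(v))
  }
  tibble::tibble(
    n = cfg$n, u = cfg$u, vm = cfg$vm, vs = cfg$vs, ve = cfg$ve,
    replicates = cfg$replicates,
    mean_fitness = mean(rm$mean_fitness),
    mean_fitness_ci = ci_hw(rm$mean_fitness),
    vg = mean(rm$vg), vg_ci = ci_hw(rm$vg),
    pbar = mean(rm$pbar),
    predicted_wbar = pred$expected_wbar,
    predicted_vg = pred$vg
  )
}
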