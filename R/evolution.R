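## Wright-Fisher evolution of network populations. A generation is:
## develop all organisms from the population's fixed founding state ->
## fitness -> fitness-proportional resampling with replacement ->
## recombination (optional, full-row segregation) -> sign-flip mutation.
## The compiled engine runs this loop; the exported operator functions
## below are the reference implementations used for small-scale work and
## for property tests of the operators themselves.

#' Selection model
#'
#' The four fitness regimes acting on developed attractors:
#'
#' * **model 1, selecting for stability** (`l_opt = 1`): with a `target`
#'   state and finite `sigma` (the "target" variant, `sigma = 0.1`),
#'   fixed points get `exp(-d/sigma)` where `d` is the normalized Hamming
#'   distance to the target; with `sigma = Inf` and no target (the
#'   "no-target" variant) every fixed point has fitness 1. Cycles always
#'   have fitness 0.
#' * **model 2, selecting against stability**: fitness 1 iff the attractor
#'   length equals `l_opt > 1`; 0 otherwise, including fixed points.
#' * **model 3, neutral for stability with a target**: fitness is the
#'   maximum of `exp(-d/sigma)` over all states of the attractor, any
#'   length.
#' * **model 4, random sampling**: constant fitness 1 (pure drift).
#'
#' Convenience names: `"stability-no-target"`, `"stability-target"`,
#' `"cycle"`, `"attractor-target"`, `"neutral"`.
#'
#' @param model Model id 1-4 or one of the names above.
#' @param sigma Selection strength (`exp(-d/sigma)`); smaller is stronger.
#' @param l_opt Optimal attractor length (model 2).
#' @param target Optimal expression state (models 1-target and 3).
#' @return Object of class `grn_selection_model`.
#' @export
selection_model <- function(model, sigma = NULL, l_opt = NULL,
                            target = NULL) {
  if (is.character(model)) {
    model <- match.arg(model, c("stability-no-target", "stability-target",
                                "cycle", "attractor-target", "neutral"))
    id <- switch(model, "stability-no-target" = 1L, "stability-target" = 1L,
                 "cycle" = 2L, "attractor-target" = 3L, "neutral" = 4L)
    if (model == "stability-target" && is.null(sigma)) sigma <- 0.1
    if (model == "attractor-target" && is.null(sigma)) sigma <- 0.1
  } else {
    id <- as.integer(model)
    if (!id %in% 1:4) stop("model must be 1, 2, 3 or 4", call. = FALSE)
  }
  if (is.null(sigma)) sigma <- Inf
  if (is.null(l_opt)) l_opt <- if (id == 2L) 2L else 1L
  l_opt <- as.integer(l_opt)
  if (!is.null(target)) target <- validate_state(target)
  if (id == 1L) {
    if (l_opt != 1L) stop("model 1 requires l_opt = 1", call. = FALSE)
    if (is.finite(sigma) && is.null(target))
      stop("model 1 with finite sigma (target variant) requires a target",
           call. = FALSE)
    if (is.infinite(sigma) && !is.null(target))
      stop("model 1 'no target' (sigma = Inf) forbids a target",
           call. = FALSE)
  }
  if (id == 2L) {
    if (l_opt < 2L) stop("model 2 requires l_opt > 1", call. = FALSE)
    sigma <- Inf
    target <- NULL
  }
  if (id == 3L && is.null(target))
    stop("model 3 requires a target", call. = FALSE)
  if (id == 4L) { sigma <- Inf; target <- NULL }
  if (!(sigma > 0)) stop("sigma must be positive", call. = FALSE)
  structure(list(model_id = id, sigma = sigma, l_opt = l_opt,
                 target = target),
            class = "grn_selection_model")
}

#' @export
print.grn_selection_model <- function(x, ...) {
  cat(sprintf(
    "Selection model %d (sigma = %s, l_opt = %d, %s)\n", x$model_id,
    format(x$sigma), x$l_opt,
    if (is.null(x$target)) "no target" else "with target"))
  invisible(x)
}

#' Fitness of a developed organism
#'
#' Evaluates a [selection_model()] on an attractor; see that help page for
#' the regimes.
#'
#' @param attractor A `grn_attractor` from [find_attractor()].
#' @param model A `grn_selection_model`.
#' @return Non-negative fitness value.
#' @export
fitness <- function(attractor, model) {
  stopifnot(inherits(attractor, "grn_attractor"),
            inherits(model, "grn_selection_model"))
  l <- attractor$length
  switch(model$model_id,
    { # 1: selecting for stability
      if (l != 1L) return(0)
      if (is.null(model$target)) return(1)
      exp(-hamming_normalized(attractor$cycle[1, ], model$target) /
            model$sigma)
    },
    if (l == model$l_opt) 1 else 0,  # 2: cycles of fixed length
    { # 3: best state of the attractor vs target
      d <- apply(attractor$cycle, 1, hamming_normalized, model$target)
      max(exp(-d / model$sigma))
    },
    1)  # 4: neutral
}

#' Wright-Fisher selection
#'
#' Resamples `n` organisms with replacement, with probability proportional
#' to fitness, conserving population size. If every fitness is zero the
#' population is resampled uniformly (it never goes extinct) and the event
#' is flagged in attribute `"rescued"`.
#'
#' @param pop A `grn_population`.
#' @param fitnesses Numeric vector of per-organism fitnesses.
#' @return The next `grn_population`.
#' @export
wright_fisher_select <- function(pop, fitnesses) {
  stopifnot(inherits(pop, "grn_population"), length(fitnesses) == pop$n,
            pop$n >= 1)
  rescued <- FALSE
  if (sum(fitnesses) <= 0) {
    rescued <- TRUE
    fitnesses <- rep(1, pop$n)
  }
  pick <- sample.int(pop$n, pop$n, replace = TRUE, prob = fitnesses)
  pop$networks <- pop$networks[, , pick, drop = FALSE]
  if (pop$mode == "RNRC") pop$states <- pop$states[, pick, drop = FALSE]
  attr(pop, "rescued") <- rescued
  pop
}

#' Sign-flip mutation
#'
#' Each of the `N^2` entries of each dense network independently flips
#' sign with probability `mu / N^2` (so `mu` flips per network per
#' generation in expectation); for sparse networks each non-zero entry
#' flips with probability `mu / (c N^2)` where `c` is the density, and
#' structural zeros never change.
#'
#' @param pop A `grn_population`.
#' @param mu Per-network mutation rate in `[0, 1]` (default 0.1).
#' @return The mutated population.
#' @export
mutate <- function(pop, mu = 0.1) {
  stopifnot(inherits(pop, "grn_population"), mu >= 0, mu <= 1)
  if (mu == 0) return(pop)
  N <- pop$N
  if (pop$sparse || any(pop$networks == 0L)) {
    nz <- which(pop$networks != 0L)
    cc <- length(nz) / (N * N * pop$n)
    flip <- nz[stats::runif(length(nz)) < mu / (cc * N * N)]
  } else {
    M <- length(pop$networks)
    k <- stats::rbinom(1, M, mu / (N * N))
    flip <- sample.int(M, k)
  }
  pop$networks[flip] <- -pop$networks[flip]
  pop
}

#' Row-segregation recombination
#'
#' Shuffles the population into `n/2` disjoint pairs; for each pair a
#' uniformly random subset of `N/2` row indices is drawn, offspring 1
#' takes those rows from parent A and the remaining rows from parent B,
#' offspring 2 takes the complement. Full rows segregate -- there is no
#' crossover within a row. Offspring replace their parents.
#'
#' @param pop A `grn_population` with even `n`.
#' @return The recombined population.
#' @export
recombine <- function(pop) {
  stopifnot(inherits(pop, "grn_population"))
  if (pop$n %% 2 != 0)
    stop("recombination requires an even population size", call. = FALSE)
  N <- pop$N
  ord <- sample.int(pop$n)
  half <- N %/% 2
  for (pr in seq(1, pop$n, by = 2)) {
    a <- ord[pr]; b <- ord[pr + 1]
    rows_a <- sample.int(N, half)
    Wa <- pop$networks[, , a]
    Wb <- pop$networks[, , b]
    off1 <- Wb; off1[rows_a, ] <- Wa[rows_a, ]
    off2 <- Wa; off2[rows_a, ] <- Wb[rows_a, ]
    pop$networks[, , a] <- off1
    pop$networks[, , b] <- off2
  }
  pop
}

#' Evolution run configuration
#'
#' Bundles the population and loop parameters of an evolution experiment.
#'
#' @param n Population size (default 500; must be even when recombination
#'   is on).
#' @param N Number of genes (default 10).
#' @param generations Number of Wright-Fisher generations.
#' @param mu Per-network mutation rate (default 0.1).
#' @param recombination Apply row-segregation recombination each
#'   generation (default `TRUE`).
#' @param z Number of independent populations in the set (default 1).
#' @param p0,q0 Optional founding sign composition (see
#'   [founding_population()]).
#' @param sparse,degree Evolve sparse regular networks.
#' @param scan_schedule Generations at which the expensive metrics (r,
#'   viability, robustness via mutant scans, and the interaction-strength
#'   matrix) are recorded. Default: about 20 log-spaced generations
#'   including 0 and the last. The cheap metrics (p, q, stability, mean
#'   fitness) are recorded every generation.
#' @param seed Master seed; population k uses `seed + k - 1`.
#' @return Object of class `grn_evolution_config`.
#' @export
evolution_config <- function(n = 500, N = 10, generations = 1000,
                             mu = 0.1, recombination = TRUE, z = 1,
                             p0 = NULL, q0 = NULL, sparse = FALSE,
                             degree = 2, scan_schedule = NULL,
                             seed = NULL) {
  stopifnot(n >= 1, N >= 1, generations >= 0, mu >= 0, mu <= 1, z >= 1)
  if (recombination && n %% 2 != 0)
    stop("recombination requires an even population size", call. = FALSE)
  if (is.null(scan_schedule))
    scan_schedule <- log_schedule(generations)
  scan_schedule <- sort(unique(as.integer(scan_schedule)))
  stopifnot(all(scan_schedule >= 0), all(scan_schedule <= generations))
  structure(list(n = as.integer(n), N = as.integer(N),
                 generations = as.integer(generations), mu = mu,
                 recombination = recombination, z = as.integer(z),
                 p0 = p0, q0 = q0, sparse = sparse,
                 degree = as.integer(degree),
                 scan_schedule = scan_schedule, seed = seed),
            class = "grn_evolution_config")
}

## ~20 log-spaced recording points including 0 and the final generation
log_schedule <- function(generations, points = 20) {
  if (generations == 0) return(0L)
  g <- unique(round(10^seq(0, log10(generations), length.out = points)))
  sort(unique(c(0L, as.integer(g))))
}

#' Evolve a set of populations
#'
#' Runs `z` independent RNIC populations under one selection model. Each
#' generation develops all organisms from the population's fixed founding
#' state, applies fitness-proportional Wright-Fisher resampling, optional
#' row-segregation recombination, and sign-flip mutation. Metrics `p`,
#' `q`, population stability and mean fitness are recorded every
#' generation; `r`, viability, robustness (via [single_mutant_scan()] of
#' the stable organisms) and the positive-interaction-strength matrix are
#' recorded at `config$scan_schedule`.
#'
#' @param config A [evolution_config()].
#' @param model A [selection_model()].
#' @return Object of class `grn_evolution`: list with
#'   `records` (per-population per-generation data frame),
#'   `set_mean` (per-generation set averages),
#'   `scans` (per-population scheduled-metric data frame),
#'   `scan_mean` (set averages of the scheduled metrics),
#'   `oij` (list over populations of `N^2 x n_scans` sign-frequency
#'   matrices), `final` (list of final `N x N x n` network arrays),
#'   `founding_states` (`N x z`), `rescue_events`, `config`, `model`.
#' @export
evolve <- function(config, model) {
  stopifnot(inherits(config, "grn_evolution_config"),
            inherits(model, "grn_selection_model"))
  z <- config$z
  records <- vector("list", z)
  scans <- vector("list", z)
  oij <- vector("list", z)
  final <- vector("list", z)
  founding_states <- matrix(NA_integer_, config$N, z)
  rescues <- 0L
  target <- if (is.null(model$target)) integer(0)
            else validate_state(model$target, config$N)
  for (k in seq_len(z)) {
    if (!is.null(config$seed)) set.seed(config$seed + k - 1L)
    pop <- founding_population(config$n, config$N, p0 = config$p0,
                               q0 = config$q0, sparse = config$sparse,
                               degree = config$degree)
    founding_states[, k] <- pop$state
    res <- evolve_engine_cpp(
      as.vector(pop$networks), config$N, config$n, pop$state,
      model$model_id, model$sigma, model$l_opt, target, config$mu,
      config$recombination, config$sparse || any(pop$networks == 0L),
      config$generations, config$scan_schedule,
      as.double(2^config$N + 1))
    rec <- as.data.frame(res$pergen)
    rec$population <- k
    records[[k]] <- rec
    sc <- as.data.frame(res$scans)
    sc$population <- k
    scans[[k]] <- sc
    oij[[k]] <- res$oij
    final[[k]] <- array(res$final_networks,
                        c(config$N, config$N, config$n))
    rescues <- rescues + res$rescue_events
  }
  records <- do.call(rbind, records)
  scans <- do.call(rbind, scans)
  agg <- function(df) {
    out <- aggregate(df[setdiff(names(df), c("generation", "population"))],
                     by = list(generation = df$generation), FUN = mean,
                     na.rm = TRUE)
    out[order(out$generation), , drop = FALSE]
  }
  structure(list(records = records, set_mean = agg(records),
                 scans = scans, scan_mean = agg(scans), oij = oij,
                 final = final, founding_states = founding_states,
                 rescue_events = rescues, config = config, model = model),
            class = "grn_evolution")
}

#' @importFrom stats aggregate
#' @export
print.grn_evolution <- function(x, ...) {
  cfg <- x$config
  last <- x$set_mean[nrow(x$set_mean), ]
  cat(sprintf(
    paste0("Evolution run: z = %d populations, n = %d, N = %d, ",
           "%d generations\n  final set means: p = %.3f, q = %.3f, ",
           "stability = %.3f\n"),
    cfg$z, cfg$n, cfg$N, cfg$generations, last$mean_p, last$mean_q,
    last$stability))
  invisible(x)
}

## Pure-R generation loop over the exported operators; used to
## cross-validate the compiled engine at small scale.
evolve_population_r <- function(pop, model, generations, mu = 0.1,
                                recombination = TRUE) {
  stopifnot(inherits(pop, "grn_population"), pop$mode == "RNIC")
  recs <- data.frame(generation = 0:generations, mean_p = NA_real_,
                     mean_q = NA_real_, stability = NA_real_,
                     mean_fitness = NA_real_)
  for (gen in 0:generations) {
    atts <- lapply(seq_len(pop$n), function(k)
      find_attractor(pop$networks[, , k], pop$state))
    fits <- vapply(atts, fitness, 0, model = model)
    recs$mean_p[gen + 1] <- mean(vapply(
      seq_len(pop$n), function(k) sign_autoregulation_p(pop$networks[, , k]),
      0))
    recs$mean_q[gen + 1] <- mean(vapply(
      seq_len(pop$n), function(k) sign_offdiag_q(pop$networks[, , k]), 0))
    recs$stability[gen + 1] <- mean(vapply(atts, function(a)
      a$length == 1L, NA))
    recs$mean_fitness[gen + 1] <- mean(fits)
    if (gen == generations) break
    pop <- wright_fisher_select(pop, fits)
    if (recombination) pop <- recombine(pop)
    pop <- mutate(pop, mu)
  }
  list(records = recs, population = pop)
}
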