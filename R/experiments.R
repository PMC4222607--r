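## Figure-level experiment recipes at configurable scale. Canonical
## outputs are data frames (tables); plotting is left to the caller.
## Every recipe is a pure function of the RNG state, so set.seed() before
## a call reproduces it bit-for-bit.

#' Stability as a function of the sign of autoregulation
#'
#' For each `p` on the grid, samples `n_per_bin` dense networks with
#' exactly `p * N` positive diagonal entries and random off-diagonal
#' signs, pairs each with an independent random initial state (RNRC
#' setup), develops to the attractor, and classifies the network as
#' stable (fixed point) or unstable (cycle).
#'
#' @param n_per_bin Networks sampled per `p` bin (at least 1000
#'   recommended).
#' @param N Number of genes.
#' @param p_grid Values of `p`; defaults to `0, 0.1, ..., 1`.
#' @return List with `bins` (per-bin counts and stability), and the
#'   medians of `p` among stable and unstable networks
#'   (`median_p_stable`, `median_p_unstable`).
#' @export
run_stability_vs_p <- function(n_per_bin = 10000, N = 10,
                               p_grid = seq(0, 1, by = 0.1)) {
  bins <- data.frame(p = p_grid, n = as.integer(n_per_bin),
                     n_stable = NA_integer_, stability = NA_real_)
  for (b in seq_along(p_grid)) {
    nets <- array(NA_integer_, c(N, N, n_per_bin))
    for (k in seq_len(n_per_bin))
      nets[, , k] <- network_with_sign_composition(N, p_grid[b])
    states <- matrix(sample(c(-1L, 1L), N * n_per_bin, replace = TRUE),
                     N, n_per_bin)
    dev <- develop_batch(nets, states)
    bins$n_stable[b] <- sum(dev$length == 1L)
    bins$stability[b] <- bins$n_stable[b] / n_per_bin
  }
  p_stable <- rep(bins$p, bins$n_stable)
  p_unstable <- rep(bins$p, bins$n - bins$n_stable)
  list(bins = bins,
       median_p_stable = median(p_stable),
       median_p_unstable = median(p_unstable))
}

scan_network_set <- function(nets, states) {
  n <- dim(nets)[3]
  out <- data.frame(viability = rep(NA_real_, n), robustness = NA_real_,
                    fraction_same = NA_real_, diag_viability = NA_real_,
                    offdiag_viability = NA_real_)
  N <- dim(nets)[1]
  heat <- matrix(0, N, N)
  nheat <- matrix(0, N, N)
  for (k in seq_len(n)) {
    sc <- single_mutant_scan(nets[, , k], states[, k])
    out$viability[k] <- sc$viability
    out$robustness[k] <- sc$robustness
    out$fraction_same[k] <- sc$n_same / sc$n_total
    fx <- sc$per_element_fixed
    out$diag_viability[k] <- mean(diag(fx), na.rm = TRUE)
    offd <- fx[row(fx) != col(fx)]
    out$offdiag_viability[k] <- mean(offd, na.rm = TRUE)
    ok <- !is.na(fx)
    heat[ok] <- heat[ok] + fx[ok]
    nheat <- nheat + ok
  }
  list(per_network = out, heatmap = ifelse(nheat > 0, heat / nheat, NA))
}

#' Robustness as a function of the sign of autoregulation
#'
#' For each `p` bin, samples networks with exact sign composition
#' `(p, q)` paired with random states (RNRC); with `stable_only = TRUE`
#' the sampling is rejection-filtered so that `n_per_bin` *stable*
#' networks enter each bin, otherwise `n_per_bin` draws are taken and
#' only the stable ones are scanned (the mutant scan is defined for
#' stable originals). Each scanned network contributes its single-mutant
#' viability and robustness.
#'
#' @param stable_only Pre-select stable networks per bin.
#' @param q Off-diagonal sign fraction, on the grid (default 0.5).
#' @param n_per_bin Stable networks per bin (or draws per bin when
#'   `stable_only = FALSE`).
#' @param N Number of genes.
#' @param p_grid Values of `p`.
#' @param max_draws_per_bin Rejection cap per bin.
#' @return List with `by_p` (per-bin summary: robustness conditional on
#'   viable mutants, the unconditional preserved fraction
#'   `n_same / n_total`, and viability), `by_robustness` (mean and
#'   median `p` in 5 robustness bins of width 0.2), and `per_network`.
#' @export
run_robustness_vs_p <- function(stable_only = TRUE, q = 0.5,
                                n_per_bin = 1000, N = 10,
                                p_grid = seq(0, 1, by = 0.1),
                                max_draws_per_bin = 2e6) {
  per_net <- NULL
  for (p in p_grid) {
    if (stable_only) {
      h <- harvest_stable(N, n_per_bin, p = p, q = q,
                          max_draws = max_draws_per_bin)
      nets <- h$networks; states <- h$states
    } else {
      nets <- array(NA_integer_, c(N, N, n_per_bin))
      for (k in seq_len(n_per_bin))
        nets[, , k] <- network_with_sign_composition(N, p, q)
      states <- matrix(sample(c(-1L, 1L), N * n_per_bin, replace = TRUE),
                       N, n_per_bin)
      dev <- develop_batch(nets, states)
      keep <- which(dev$length == 1L)
      nets <- nets[, , keep, drop = FALSE]
      states <- states[, keep, drop = FALSE]
    }
    if (dim(nets)[3] == 0) next
    sc <- scan_network_set(nets, states)$per_network
    sc$p <- p
    per_net <- rbind(per_net, sc)
  }
  by_p <- do.call(rbind, lapply(split(per_net, per_net$p), function(d)
    data.frame(p = d$p[1], n = nrow(d),
               mean_robustness = mean(d$robustness, na.rm = TRUE),
               median_robustness = median(d$robustness, na.rm = TRUE),
               mean_fraction_same = mean(d$fraction_same),
               mean_viability = mean(d$viability))))
  rb <- pmin(floor(per_net$robustness / 0.2), 4)
  by_rob <- do.call(rbind, lapply(split(per_net, rb), function(d)
    data.frame(robustness_bin = 0.2 * pmin(floor(d$robustness[1] / 0.2), 4),
               n = nrow(d), mean_p = mean(d$p), median_p = median(d$p))))
  list(by_p = by_p, by_robustness = by_rob, per_network = per_net)
}

#' Evolutionary time course
#'
#' Runs [evolve()] for a selection model and configuration; this is the
#' recipe behind the p/q/r/stability/robustness trajectory analyses and
#' their recombination, sparse-network and founding-composition variants
#' (set the corresponding fields of [evolution_config()]).
#'
#' @param model A [selection_model()].
#' @param config A [evolution_config()].
#' @return A `grn_evolution` object.
#' @export
run_timecourse <- function(model, config) {
  evolve(config, model)
}

#' Plot set-mean trajectories
#'
#' Base-graphics overview of the set-mean `p`, `q` and stability time
#' courses of an evolution run (log-scaled generation axis).
#'
#' @param x A `grn_evolution` object.
#' @param ... Passed to [graphics::matplot()].
#' @importFrom graphics matplot legend
#' @export
plot.grn_evolution <- function(x, ...) {
  sm <- x$set_mean
  g <- pmax(sm$generation, 1)
  matplot(g, sm[, c("mean_p", "mean_q", "stability")], type = "l",
          lty = 1, col = c("black", "blue", "red"), log = "x",
          xlab = "generation", ylab = "set mean", ylim = c(0, 1), ...)
  legend("bottomright", legend = c("p", "q", "stability"),
         col = c("black", "blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

final_stable_sets <- function(evo) {
  z <- length(evo$final)
  nets <- list(); states <- list()
  for (k in seq_len(z)) {
    s0 <- evo$founding_states[, k]
    dev <- develop_batch(evo$final[[k]], s0)
    keep <- which(dev$length == 1L)
    if (!length(keep)) next
    nets[[length(nets) + 1]] <- evo$final[[k]][, , keep, drop = FALSE]
    states[[length(states) + 1]] <-
      matrix(s0, evo$config$N, length(keep))
  }
  list(networks = as_network_array(nets),
       states = do.call(cbind, states))
}

#' Diagonal versus off-diagonal mutant viability
#'
#' Takes the stable networks of the final populations of an evolution run
#' (each developed from its population's founding state), scans all
#' single-sign-flip mutants, and splits the per-element stability map
#' into diagonal (`N` autoregulatory entries) and off-diagonal
#' (`N^2 - N`) viabilities.
#'
#' @param evo A `grn_evolution` object, or an `N x N x n` array of
#'   networks (then `states` must be given).
#' @param states Optional `N x n` matrix of initial states (one per
#'   network) when `evo` is a plain array.
#' @return List with `per_network` (viability, robustness, diagonal and
#'   off-diagonal viability per network), `heatmap` (`N x N` per-element
#'   population-level viability: the fraction of networks whose mutant at
#'   that element is viable), and `summary` (overall viability plus the
#'   medians of the heat-map cells split into the `N` diagonal and
#'   `N^2 - N` off-diagonal elements).
#' @export
run_mutant_position_analysis <- function(evo, states = NULL) {
  if (inherits(evo, "grn_evolution")) {
    fs <- final_stable_sets(evo)
    nets <- fs$networks; states <- fs$states
  } else {
    nets <- as_network_array(evo)
    stopifnot(!is.null(states))
  }
  sc <- scan_network_set(nets, states)
  pn <- sc$per_network
  heat <- sc$heatmap
  off <- row(heat) != col(heat)
  list(per_network = pn,
       summary = data.frame(
         n = nrow(pn),
         viability = mean(pn$viability),
         median_diag_viability = median(diag(heat)),
         median_offdiag_viability = median(heat[off]),
         mean_robustness = mean(pn$robustness, na.rm = TRUE)),
       heatmap = heat)
}

#' Conservation of interaction signs over evolutionary time
#'
#' Uses the positive-interaction-strength matrices recorded by [evolve()]
#' at two scheduled generations to compute per-element sign conservation
#' (see [conservation()]), averaged across the set of populations, and
#' contrasts diagonal against off-diagonal elements.
#'
#' @param evo A `grn_evolution` object.
#' @param t1,t2 Two recorded generations (`t1 < t2`); each is snapped to
#'   the nearest entry of the scan schedule.
#' @return List with `matrix` (set-average `N x N` conservation),
#'   `diag_median`, `offdiag_median`, and the generations used.
#' @export
run_conservation_analysis <- function(evo, t1, t2) {
  stopifnot(inherits(evo, "grn_evolution"))
  sched <- evo$config$scan_schedule
  g1 <- sched[which.min(abs(sched - t1))]
  g2 <- sched[which.min(abs(sched - t2))]
  if (g1 >= g2) stop("need two distinct recorded generations t1 < t2",
                     call. = FALSE)
  i1 <- match(g1, sched); i2 <- match(g2, sched)
  N <- evo$config$N
  cons <- matrix(0, N, N)
  for (k in seq_along(evo$oij)) {
    o1 <- matrix(evo$oij[[k]][, i1], N, N)
    o2 <- matrix(evo$oij[[k]][, i2], N, N)
    cons <- cons + conservation(o1, o2)
  }
  cons <- cons / length(evo$oij)
  list(matrix = cons,
       diag_median = median(diag(cons)),
       offdiag_median = median(cons[row(cons) != col(cons)]),
       t1 = g1, t2 = g2)
}

#' Engineered versus randomly sampled stable networks
#'
#' Builds "engineered" networks by combining the off-diagonal entries of
#' stable low-`p` donors (sign composition `(donor_p, donor_q)`) with a
#' high-`p` diagonal, and compares their robustness and indirect
#' autoregulation `r` against randomly sampled stable control networks
#' with matched sign composition `(diag_p, donor_q)`. Each group is
#' paired with fresh random states; only stable pairs are scanned.
#'
#' @param n_per_group Stable networks per group.
#' @param N Number of genes.
#' @param donor_p Donor sign of autoregulation (low; default 0.1).
#' @param donor_q Donor off-diagonal fraction (default 48/90, the grid
#'   value nearest the evolutionary equilibrium 0.53).
#' @param diag_p Diagonal composition of the engineered networks (0.9 or
#'   1.0).
#' @param max_draws Rejection cap per harvested group.
#' @return List with `per_network` (group, robustness, viability, r) and
#'   `summary` (medians by group).
#' @export
run_engineered_comparison <- function(n_per_group = 500, N = 10,
                                      donor_p = 0.1, donor_q = 48 / 90,
                                      diag_p = 0.9, max_draws = 5e6) {
  donors <- harvest_stable(N, n_per_group, p = donor_p, q = donor_q,
                           max_draws = max_draws)
  eng <- array(NA_integer_, dim(donors$networks))
  for (k in seq_len(n_per_group))
    eng[, , k] <- engineered_network(donors$networks[, , k], diag_p)
  ctrl <- harvest_stable(N, n_per_group, p = diag_p, q = donor_q,
                         max_draws = max_draws)

  measure <- function(nets, states, group) {
    n <- dim(nets)[3]
    dev <- develop_batch(nets, states)
    keep <- which(dev$length == 1L)
    nets <- nets[, , keep, drop = FALSE]
    states <- states[, keep, drop = FALSE]
    pn <- scan_network_set(nets, states)$per_network
    pn$r <- vapply(seq_len(dim(nets)[3]), function(k)
      indirect_autoregulation_r(nets[, , k]), 0)
    pn$group <- group
    pn$stable_fraction <- length(keep) / n
    pn
  }
  eng_states <- matrix(sample(c(-1L, 1L), N * n_per_group, replace = TRUE),
                       N, n_per_group)
  pe <- measure(eng, eng_states, "engineered")
  pc <- measure(ctrl$networks, ctrl$states, "control")
  per_net <- rbind(pe, pc)
  summ <- do.call(rbind, lapply(split(per_net, per_net$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               stable_fraction = d$stable_fraction[1],
               median_robustness = median(d$robustness, na.rm = TRUE),
               median_r = median(d$r),
               median_viability = median(d$viability))))
  list(per_network = per_net, summary = summ)
}
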