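## Summary statistics on networks, states and populations. p, q and r are
## exact rationals (integer counts over fixed denominators); for sparse
## networks the denominators are the non-zero entry counts, since a sign
## fraction is undefined on structural zeros.

#' Normalized Hamming distance
#'
#' Fraction of genes whose expression differs between two states,
#' in `[0, 1]`.
#'
#' @param S1,S2 Expression states of equal length.
#' @return Fraction of differing entries.
#' @export
hamming_normalized <- function(S1, S2) {
  S1 <- validate_state(S1)
  S2 <- validate_state(S2, length(S1))
  sum(S1 != S2) / length(S1)
}

#' Sign of autoregulation (p)
#'
#' Fraction of positive diagonal entries of the interaction matrix:
#' `p > 0.5` means predominantly positive autoregulation. For sparse
#' networks the denominator is the number of non-zero diagonal entries;
#' when no diagonal entry is non-zero the statistic is undefined and `NA`
#' is returned with a warning.
#'
#' @param W Square signed interaction matrix.
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
sign_autoregulation_p <- function(W) {
  W <- validate_network(W)
  d <- diag(W)
  nz <- sum(d != 0L)
  if (nz == 0L) {
    warning("no non-zero diagonal entries; p is undefined")
    return(NA_real_)
  }
  sum(d > 0L) / nz
}

#' Off-diagonal sign fraction (q)
#'
#' Fraction of positive off-diagonal entries (regulation of other genes).
#' Sparse networks divide by the non-zero off-diagonal count.
#'
#' @param W Square signed interaction matrix.
#' @return Fraction in `[0, 1]`, or `NA` when undefined.
#' @export
sign_offdiag_q <- function(W) {
  W <- validate_network(W)
  off <- W[row(W) != col(W)]
  nz <- sum(off != 0L)
  if (nz == 0L) {
    warning("no non-zero off-diagonal entries; q is undefined")
    return(NA_real_)
  }
  sum(off > 0L) / nz
}

#' Indirect autoregulation (r)
#'
#' Length-two autoregulatory-path statistic: the fraction of strictly
#' positive entries among the `N(N-1)/2` strictly-upper-triangle entries
#' of the integer matrix product `W W^T`. Since `W W^T` is symmetric, one
#' triangle suffices. Zero dot products (possible at even `N`) count as
#' not positive.
#'
#' @param W Square signed interaction matrix.
#' @return Fraction in `[0, 1]`.
#' @export
indirect_autoregulation_r <- function(W) {
  W <- validate_network(W)
  M <- W %*% t(W)
  up <- M[upper.tri(M)]
  sum(up > 0L) / length(up)
}

#' Population-level stability
#'
#' Fraction of organisms in a population whose development reaches a
#' fixed point.
#'
#' @param pop A `grn_population` (see [init_population()]).
#' @return Fraction in `[0, 1]`.
#' @export
population_stability <- function(pop) {
  stopifnot(inherits(pop, "grn_population"), pop$n >= 1)
  states <- if (pop$mode == "RNIC") pop$state else pop$states
  dev <- develop_batch(pop$networks, states)
  mean(dev$length == 1L)
}

#' Single-mutant viability and robustness scan
#'
#' Flips the sign of each non-zero entry of `W` in turn (all `N^2` entries
#' for dense networks), develops each mutant from `S0`, and tallies how
#' many mutants still reach a fixed point (`n_fixed`) and how many reach
#' the identical fixed point as the unmutated original (`n_same`).
#' Viability is `n_fixed / n_total`; robustness is `n_same / n_fixed`,
#' undefined (`NA`, never 0) when no mutant is viable. The per-element
#' matrices support diagonal versus off-diagonal comparisons.
#'
#' The wild type `(W, S0)` must itself reach a fixed point.
#'
#' @inheritParams find_attractor
#' @param S0 Initial expression state shared by wild type and mutants.
#' @return Object of class `grn_mutant_scan`: list with `n_total`,
#'   `n_fixed`, `n_same`, `viability`, `robustness`, `per_element_fixed`
#'   and `per_element_same` (`N x N` logical matrices, `NA` at structural
#'   zeros).
#' @export
single_mutant_scan <- function(W, S0, max_steps = 2^nrow(W) + 1) {
  W <- validate_network(W)
  S0 <- validate_state(S0, nrow(W))
  res <- mutant_scan_cpp(W, S0, as.double(max_steps))
  structure(
    list(n_total = res$n_total,
         n_fixed = res$n_fixed,
         n_same = res$n_same,
         viability = res$n_fixed / res$n_total,
         robustness = if (res$n_fixed > 0) res$n_same / res$n_fixed
                      else NA_real_,
         per_element_fixed = matrix(as.logical(res$fixed), nrow(W)),
         per_element_same = matrix(as.logical(res$same), nrow(W))),
    class = "grn_mutant_scan")
}

#' @export
print.grn_mutant_scan <- function(x, ...) {
  cat(sprintf(
    "Single-mutant scan: %d mutants, viability %.3f, robustness %s\n",
    x$n_total, x$viability,
    if (is.na(x$robustness)) "undefined" else sprintf("%.3f", x$robustness)))
  invisible(x)
}

as_network_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) {
    storage.mode(x) <- "integer"
    return(x)
  }
  if (inherits(x, "grn_population")) return(x$networks)
  if (is.list(x)) {
    arrays <- lapply(x, as_network_array)
    N <- dim(arrays[[1]])[1]
    out <- array(NA_integer_, c(N, N, sum(vapply(arrays, function(a)
      dim(a)[3], 0))))
    at <- 0L
    for (a in arrays) {
      out[, , at + seq_len(dim(a)[3])] <- a
      at <- at + dim(a)[3]
    }
    return(out)
  }
  stop("cannot interpret input as a collection of networks", call. = FALSE)
}

#' Average positive interaction strength
#'
#' For a collection of networks (a population, a list of populations, or
#' an `N x N x n` array), `o_ij` is the fraction of networks whose entry
#' `(i, j)` is `+1` -- how strongly gene `j` activates gene `i` on average
#' across the collection.
#'
#' @param networks Collection of same-size networks.
#' @param t Optional generation stamp carried along for conservation
#'   analyses.
#' @return Object of class `grn_interaction_strength`: `N x N` numeric
#'   matrix in `[0, 1]` with attribute `t`.
#' @export
interaction_strength <- function(networks, t = NA_real_) {
  a <- as_network_array(networks)
  if (dim(a)[3] < 1) stop("empty network collection", call. = FALSE)
  o <- apply(a > 0L, c(1, 2), mean)
  structure(o, t = t, class = c("grn_interaction_strength", "matrix"))
}

#' Sign conservation between two time points
#'
#' Given positive-interaction-strength matrices `o1` at `t1` and `o2` at a
#' later `t2`, the conservation of element `(i, j)` is the probability that
#' a network drawn from the population at `t1` and one drawn at `t2` carry
#' the same sign there:
#' `o1_ij * o2_ij + (1 - o1_ij) * (1 - o2_ij)`.
#' Independent (random) signs give the baseline 0.5; identical frozen
#' signs give 1. This same-sign-draw form is this package's definition of
#' the conservation statistic.
#'
#' @param o1,o2 `N x N` matrices from [interaction_strength()].
#' @return `N x N` numeric matrix of fractions in `[0, 1]`.
#' @export
conservation <- function(o1, o2) {
  if (!all(dim(o1) == dim(o2)))
    stop("interaction strength matrices must have the same shape",
         call. = FALSE)
  t1 <- attr(o1, "t")
  t2 <- attr(o2, "t")
  if (!is.null(t1) && !is.null(t2) && !any(is.na(c(t1, t2))) && t1 >= t2)
    warning("expected o1 to precede o2 in time (t1 < t2)")
  unclass(o1) * unclass(o2) + (1 - unclass(o1)) * (1 - unclass(o2))
}
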