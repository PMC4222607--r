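## Core developmental dynamics: synchronous threshold update and exact
## attractor detection. All arithmetic is integer-exact; states are
## vectors over {-1, +1} and revisit detection works on canonical bit
## encodings, so there is no tolerance anywhere in the dynamics.

#' Threshold sign function
#'
#' The transfer function of the Boolean threshold network model:
#' `threshold_sign(x)` is `+1` for `x >= 0` and `-1` for `x < 0`. Note the
#' convention `sgn(0) = +1`, which makes the update map total.
#'
#' @param x Numeric or integer vector of weighted sums.
#' @return Integer vector of the same length with entries in `c(-1L, 1L)`.
#' @examples
#' threshold_sign(c(-3, 0, 7))
#' @export
threshold_sign <- function(x) {
  ifelse(x >= 0, 1L, -1L)
}

validate_state <- function(S, N = NULL) {
  S <- as.integer(S)
  if (!all(S %in% c(-1L, 1L)))
    stop("expression states must have entries in {-1, +1}", call. = FALSE)
  if (!is.null(N) && length(S) != N)
    stop(sprintf("state length (%d) does not match network size (%d)",
                 length(S), N), call. = FALSE)
  S
}

validate_network <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("a regulatory network must be a square matrix", call. = FALSE)
  storage.mode(W) <- "integer"
  if (!all(W %in% c(-1L, 0L, 1L)))
    stop("network entries must be in {-1, 0, +1}", call. = FALSE)
  W
}

#' One synchronous development step
#'
#' Applies the threshold update `S'_i = sgn(sum_j w_ij S_j)` with
#' `sgn(0) = +1`. The update is synchronous: every gene is computed from
#' the same input state.
#'
#' @param W Square signed interaction matrix (entries in `{-1, 0, +1}`).
#' @param S Expression state, a length-`N` vector over `{-1, +1}`.
#' @return The successor state, an integer vector over `{-1, +1}`.
#' @examples
#' W <- matrix(1L, 3, 3)
#' develop_step(W, c(1, 1, 1))
#' @export
develop_step <- function(W, S) {
  W <- validate_network(W)
  S <- validate_state(S, nrow(W))
  threshold_sign(as.vector(W %*% S))
}

#' Develop to the attractor
#'
#' Iterates [develop_step()] from `S0`, recording visited states, and stops
#' at the first revisit of a previously seen state. The segment between the
#' two visits is the attractor (a fixed point when its length is 1); the
#' index of the first visit is the transient length. Because the state
#' space has `2^N` elements, `max_steps = 2^N + 1` guarantees detection by
#' pigeonhole; the default uses exactly that bound.
#'
#' @inheritParams develop_step
#' @param S0 Initial expression state.
#' @param max_steps Cap on the number of states examined. Must be at least
#'   `2^N + 1` for guaranteed detection; smaller values may raise a
#'   non-detection error.
#' @return An object of class `grn_attractor`: a list with
#'   `transient_length`, `length` (cycle length `l`), `cycle` (an `l x N`
#'   integer matrix of the cycle states in order), and `is_fixed_point`.
#' @examples
#' find_attractor(matrix(-1L, 1, 1), 1L)   # period-2 oscillation
#' @export
find_attractor <- function(W, S0, max_steps = 2^nrow(W) + 1) {
  W <- validate_network(W)
  S0 <- validate_state(S0, nrow(W))
  res <- attractor_cpp(W, S0, as.double(max_steps))
  structure(
    list(transient_length = res$transient,
         length = res$length,
         cycle = res$cycle,
         is_fixed_point = res$length == 1L),
    class = "grn_attractor")
}

#' @export
print.grn_attractor <- function(x, ...) {
  kind <- if (x$is_fixed_point) "fixed point" else
    sprintf("limit cycle of length %d", x$length)
  cat(sprintf("Attractor: %s (transient %d steps, %d genes)\n",
              kind, x$transient_length, ncol(x$cycle)))
  invisible(x)
}

#' Individual-level stability
#'
#' A `(W, S0)` pair is stable when its development reaches a fixed point
#' (attractor of length 1) rather than a limit cycle.
#'
#' @inheritParams find_attractor
#' @return `TRUE` iff the attractor is a fixed point.
#' @export
is_stable <- function(W, S0, max_steps = 2^nrow(W) + 1) {
  find_attractor(W, S0, max_steps)$length == 1L
}

## Batch development used throughout the experiment recipes: `networks` is
## an N x N x n integer array, `states` a single shared state or an N x n
## matrix. Returns attractor lengths, transients and fixed-point states.
develop_batch <- function(networks, states, max_steps = NULL) {
  stopifnot(is.array(networks), length(dim(networks)) == 3)
  N <- dim(networks)[1]
  n <- dim(networks)[3]
  if (is.null(max_steps)) max_steps <- 2^N + 1
  storage.mode(networks) <- "integer"
  shared <- is.null(dim(states))
  sm <- if (shared) matrix(validate_state(states, N), ncol = 1)
        else {
          storage.mode(states) <- "integer"
          states
        }
  batch_develop_cpp(as.vector(networks), N, n, sm, shared,
                    as.double(max_steps))
}
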