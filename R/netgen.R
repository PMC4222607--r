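## Network and population generators. Dense networks draw every entry
## from {-1, +1} with equal probability; composition-controlled networks
## place an exact count of positive entries (the study bins by discrete
## p values at N = 10, and exact counts remove binning noise). All
## randomness flows through R's RNG, so set.seed() gives reproducibility.

#' Random expression state
#'
#' Each of the `N` genes is independently `+1` or `-1` with probability
#' one half (a uniform draw from the phenotype space).
#'
#' @param N Number of genes.
#' @return Integer vector of length `N` over `{-1, +1}`.
#' @export
random_state <- function(N) {
  stopifnot(N >= 1)
  sample(c(-1L, 1L), N, replace = TRUE)
}

#' Random dense network
#'
#' Every entry of the `N x N` interaction matrix is sampled independently
#' from `{-1, +1}` with equal probability.
#'
#' @param N Number of genes.
#' @return `N x N` integer matrix with entries in `{-1, +1}`.
#' @export
random_network <- function(N) {
  stopifnot(N >= 1)
  matrix(sample(c(-1L, 1L), N * N, replace = TRUE), N, N)
}

check_on_grid <- function(x, denom, what) {
  k <- x * denom
  if (is.na(x) || x < 0 || x > 1 || abs(k - round(k)) > 1e-8)
    stop(sprintf("%s = %g is not on the grid {0, 1/%d, ..., 1}",
                 what, x, denom), call. = FALSE)
  as.integer(round(k))
}

#' Network with prescribed sign composition
#'
#' Builds a dense network with exactly `round(p * N)` positive diagonal
#' entries (the sign of autoregulation) placed uniformly at random, and --
#' when `q` is given -- exactly `round(q * N * (N - 1))` positive
#' off-diagonal entries placed uniformly at random. With `q = NULL` the
#' off-diagonal signs are independent fair coin flips.
#'
#' @param N Number of genes.
#' @param p Target fraction of positive diagonal entries; must lie on the
#'   grid `0, 1/N, ..., 1`.
#' @param q Optional target fraction of positive off-diagonal entries on
#'   the grid `0, 1/(N(N-1)), ..., 1`; `NULL` for random off-diagonal.
#' @return `N x N` integer matrix with entries in `{-1, +1}` whose measured
#'   `p` (and `q`, when requested) equal the targets exactly.
#' @export
network_with_sign_composition <- function(N, p, q = NULL) {
  stopifnot(N >= 1)
  kp <- check_on_grid(p, N, "p")
  W <- matrix(-1L, N, N)
  if (!is.null(q)) {
    kq <- check_on_grid(q, N * (N - 1), "q")
    off <- which(row(W) != col(W))
    W[sample(off, kq)] <- 1L
  } else {
    noff <- N * N - N
    W[row(W) != col(W)] <- sample(c(-1L, 1L), noff, replace = TRUE)
  }
  dpos <- if (kp > 0) sample.int(N, kp) else integer(0)
  diag(W) <- -1L
  if (kp > 0) W[cbind(dpos, dpos)] <- 1L
  W
}

## Batched rejection sampler for stable (fixed-point) networks, optionally
## with exact sign composition. Returns a list with a N x N x n_keep array,
## the paired states (N x n_keep), and the number of draws consumed.
harvest_stable <- function(N, n_target, p = NULL, q = NULL,
                           max_draws = 1e6, batch = 2000L,
                           keep_unstable = FALSE) {
  nets <- array(NA_integer_, c(N, N, n_target))
  sts <- matrix(NA_integer_, N, n_target)
  got <- 0L
  draws <- 0L
  while (got < n_target) {
    b <- as.integer(min(batch, max_draws - draws))
    if (b <= 0)
      stop(sprintf(
        "rejection sampling exhausted %g draws with %d/%d stable networks found",
        max_draws, got, n_target), call. = FALSE)
    batch_nets <- array(NA_integer_, c(N, N, b))
    if (is.null(p) && is.null(q)) {
      batch_nets[] <- sample(c(-1L, 1L), N * N * b, replace = TRUE)
    } else {
      for (k in seq_len(b))
        batch_nets[, , k] <- network_with_sign_composition(N, p, q)
    }
    batch_states <- matrix(sample(c(-1L, 1L), N * b, replace = TRUE), N, b)
    dev <- develop_batch(batch_nets, batch_states)
    ok <- which(dev$length == 1L)
    draws <- draws + b
    if (length(ok)) {
      take <- ok[seq_len(min(length(ok), n_target - got))]
      nets[, , got + seq_along(take)] <- batch_nets[, , take]
      sts[, got + seq_along(take)] <- batch_states[, take]
      got <- got + length(take)
    }
  }
  list(networks = nets, states = sts, draws = draws)
}

#' Pre-selected stable network
#'
#' Rejection-samples `(W, S0)` pairs -- random network, random state --
#' until development reaches a fixed point, and returns the accepted pair.
#' Optional `p`/`q` constrain the sign composition of the candidates.
#'
#' @param N Number of genes.
#' @param p,q Optional exact sign composition of candidates (see
#'   [network_with_sign_composition()]).
#' @param max_attempts Cap on rejection draws; exceeding it is an error.
#' @return List with `network`, `state` (the paired initial condition) and
#'   `attempts` (draws consumed).
#' @export
stable_network <- function(N, p = NULL, q = NULL, max_attempts = 1e6) {
  h <- harvest_stable(N, 1L, p = p, q = q, max_draws = max_attempts)
  list(network = h$networks[, , 1], state = h$states[, 1],
       attempts = h$draws)
}

#' Engineered network
#'
#' Combines the off-diagonal entries of a donor network (in practice a
#' stable network with low sign of autoregulation `p` and near-equilibrium
#' `q`) with a new diagonal carrying exactly `round(diag_p * N)` positive
#' entries at uniformly random positions. `q` of the result equals `q` of
#' the donor; `p` equals `diag_p`.
#'
#' @param offdiag_donor Donor network (square signed matrix).
#' @param diag_p Target fraction of positive diagonal entries on the grid
#'   `0, 1/N, ..., 1` (the study uses 0.9 or 1.0).
#' @return `N x N` integer matrix.
#' @export
engineered_network <- function(offdiag_donor, diag_p) {
  W <- validate_network(offdiag_donor)
  N <- nrow(W)
  kp <- check_on_grid(diag_p, N, "diag_p")
  diag(W) <- -1L
  if (kp > 0) {
    dpos <- sample.int(N, kp)
    W[cbind(dpos, dpos)] <- 1L
  }
  W
}

#' Sparse regular network
#'
#' Random directed graph in which every gene regulates exactly `degree`
#' genes and is regulated by exactly `degree` genes (in-degree = out-degree
#' = `degree`), built by superposing `degree` independent random
#' permutation matrices and rejecting draws that collide on a cell (or
#' place a self-loop when `allow_self_loops = FALSE`). Non-zero entries
#' get signs `+1`/`-1` with equal probability. The density is
#' `c = degree / N`; the defaults `N = 10`, `degree = 2` give `c = 0.2`.
#'
#' @param N Number of genes.
#' @param degree In- and out-degree of every gene (`1 <= degree < N`).
#' @param allow_self_loops Whether the support may include diagonal cells.
#'   Self-loops are allowed by default so that autoregulatory entries
#'   exist in sparse networks.
#' @param max_attempts Cap on rejection draws for the support.
#' @return `N x N` integer matrix with entries in `{-1, 0, +1}` and exactly
#'   `degree` non-zeros in every row and column.
#' @export
sparse_regular_network <- function(N, degree = 2, allow_self_loops = TRUE,
                                   max_attempts = 10000) {
  stopifnot(degree >= 1, degree < N)
  for (attempt in seq_len(max_attempts)) {
    cells <- matrix(NA_integer_, N * degree, 2)
    for (d in seq_len(degree)) {
      perm <- sample.int(N)
      cells[(d - 1) * N + seq_len(N), ] <- cbind(seq_len(N), perm)
    }
    if (!allow_self_loops && any(cells[, 1] == cells[, 2])) next
    if (anyDuplicated(cells)) next
    W <- matrix(0L, N, N)
    W[cells] <- sample(c(-1L, 1L), N * degree, replace = TRUE)
    return(W)
  }
  stop("could not construct a regular support within max_attempts",
       call. = FALSE)
}

#' Initialise a population of organisms
#'
#' Two canonical setups: `"RNRC"` pairs each random network with its own
#' independent random initial condition (used for non-evolving samples);
#' `"RNIC"` gives all `n` random networks one shared random initial
#' condition (used to found evolving populations).
#'
#' @param n Population size (the study uses 500).
#' @param N Number of genes (the study uses 10).
#' @param mode `"RNIC"` or `"RNRC"`.
#' @param sparse Generate sparse regular networks instead of dense ones.
#' @param degree In/out-degree for sparse networks.
#' @return An object of class `grn_population`: list with `networks`
#'   (`N x N x n` integer array), `state` (shared state, RNIC) or `states`
#'   (`N x n` matrix, RNRC), `mode`, `n`, `N`, `sparse`.
#' @export
init_population <- function(n = 500, N = 10, mode = c("RNIC", "RNRC"),
                            sparse = FALSE, degree = 2) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, N >= 1)
  networks <- array(NA_integer_, c(N, N, n))
  if (sparse) {
    for (k in seq_len(n)) networks[, , k] <- sparse_regular_network(N, degree)
  } else {
    networks[] <- sample(c(-1L, 1L), N * N * n, replace = TRUE)
  }
  pop <- list(networks = networks, mode = mode, n = as.integer(n),
              N = as.integer(N), sparse = sparse)
  if (mode == "RNIC") {
    pop$state <- random_state(N)
  } else {
    pop$states <- matrix(sample(c(-1L, 1L), N * n, replace = TRUE), N, n)
  }
  structure(pop, class = "grn_population")
}

#' @export
print.grn_population <- function(x, ...) {
  cat(sprintf("Population of %d organisms (%d genes, %s setup%s)\n",
              x$n, x$N, x$mode, if (x$sparse) ", sparse" else ""))
  invisible(x)
}

#' Founding population for evolution runs
#'
#' RNIC population whose networks either are fully random (expected
#' `p = q = 0.5`) or all carry an exact founding sign composition
#' `(p0, q0)` with independent placements per organism. All organisms
#' share one random initial expression state.
#'
#' @param n Population size.
#' @param N Number of genes.
#' @param p0,q0 Optional founding sign composition on the valid grids.
#' @param sparse,degree Sparse regular founding networks (incompatible
#'   with `p0`/`q0`).
#' @return A `grn_population` in RNIC mode.
#' @export
founding_population <- function(n = 500, N = 10, p0 = NULL, q0 = NULL,
                                sparse = FALSE, degree = 2) {
  if (sparse && (!is.null(p0) || !is.null(q0)))
    stop("founding sign composition is defined for dense networks only",
         call. = FALSE)
  pop <- init_population(n, N, mode = "RNIC", sparse = sparse,
                         degree = degree)
  if (!is.null(p0) || !is.null(q0)) {
    if (is.null(p0)) p0 <- 0.5
    for (k in seq_len(n))
      pop$networks[, , k] <- network_with_sign_composition(N, p0, q0)
  }
  pop
}
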