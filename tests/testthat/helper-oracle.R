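# Independent oracles built by exhaustive enumeration, deliberately using
# plain per-entry loops (no matrix products, no package dynamics) so they
# share no code path with the implementation under test.

# All 2^N states of an N-gene system, one per row, entries in {-1, +1}.
# Row k encodes the bits of k - 1 (bit i set -> gene i is +1), matching no
# particular package convention; only self-consistency matters here.
oracle_all_states <- function(N) {
  idx <- 0:(2^N - 1)
  t(vapply(idx, function(k)
    ifelse(bitwAnd(k, 2^(0:(N - 1))) > 0, 1L, -1L), integer(N)))
}

oracle_state_index <- function(s) {
  as.integer(sum(2^(which(s > 0) - 1))) + 1L
}

# Full state-transition map: successor index for every state, computed by
# explicit per-entry sums with the sgn(0) = +1 convention.
oracle_transition_map <- function(W) {
  N <- nrow(W)
  states <- oracle_all_states(N)
  vapply(seq_len(2^N), function(k) {
    s <- states[k, ]
    nxt <- integer(N)
    for (i in seq_len(N)) {
      acc <- 0L
      for (j in seq_len(N)) acc <- acc + W[i, j] * s[j]
      nxt[i] <- if (acc >= 0L) 1L else -1L
    }
    oracle_state_index(nxt)
  }, integer(1))
}

# Walk the transition map from s0 until the first revisit; return the
# transient length and the cycle states in trajectory order. A
# precomputed map can be passed when scanning many initial states.
oracle_attractor <- function(W, s0, map = NULL) {
  if (is.null(map)) map <- oracle_transition_map(W)
  states <- oracle_all_states(nrow(W))
  path <- integer(0)
  k <- oracle_state_index(s0)
  repeat {
    hit <- match(k, path)
    if (!is.na(hit)) {
      cyc <- path[hit:length(path)]
      return(list(transient = hit - 1L, length = length(cyc),
                  cycle = states[cyc, , drop = FALSE]))
    }
    path <- c(path, k)
    k <- map[k]
  }
}

# Re-enumerates all single-sign-flip mutants of a dense network.
oracle_mutant_scan <- function(W, s0) {
  N <- nrow(W)
  wt <- oracle_attractor(W, s0)
  stopifnot(wt$length == 1L)
  n_fixed <- 0L
  n_same <- 0L
  for (i in seq_len(N))
    for (j in seq_len(N)) {
      M <- W
      M[i, j] <- -M[i, j]
      a <- oracle_attractor(M, s0)
      if (a$length == 1L) {
        n_fixed <- n_fixed + 1L
        if (all(a$cycle[1, ] == wt$cycle[1, ])) n_same <- n_same + 1L
      }
    }
  list(n_fixed = n_fixed, n_same = n_same)
}

# Small manually-assembled RNIC population for operator tests.
make_pop <- function(networks, state, sparse = FALSE) {
  structure(list(networks = networks, state = state, mode = "RNIC",
                 n = dim(networks)[3], N = dim(networks)[1],
                 sparse = sparse),
            class = "grn_population")
}
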