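## Plain-text interchange: networks as whitespace-delimited integer TSV
## (N rows x N columns) or JSON {"n": N, "weights": [[...]]}; states as
## length-N integer rows.

#' Read / write networks and states
#'
#' Networks travel as whitespace-delimited integer matrices (`N` rows by
#' `N` columns) or as JSON objects `{"n": N, "weights": [[...]]}`; state
#' collections as files of length-`N` integer rows (one state per row).
#'
#' @param W Square signed interaction matrix.
#' @param path File path.
#' @return The readers return validated integer matrices; `read_states_tsv`
#'   returns an `N x n` matrix with one state per column.
#' @name grn_io
NULL

#' @rdname grn_io
#' @export
write_network_tsv <- function(W, path) {
  W <- validate_network(W)
  write.table(W, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_network_tsv <- function(path) {
  W <- as.matrix(read.table(path, header = FALSE))
  dimnames(W) <- NULL
  validate_network(W)
}

#' @rdname grn_io
#' @export
write_network_json <- function(W, path) {
  W <- validate_network(W)
  jsonlite::write_json(list(n = nrow(W), weights = W), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(as.integer(obj$weights), obj$n, obj$n)
  validate_network(W)
}

#' @rdname grn_io
#' @param states `N x n` matrix of states (one per column) or a single
#'   state vector.
#' @export
write_states_tsv <- function(states, path) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1)
  write.table(t(states), path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname grn_io
#' @export
read_states_tsv <- function(path) {
  m <- t(as.matrix(read.table(path, header = FALSE)))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  stopifnot(all(m %in% c(-1L, 1L)))
  m
}

#' Export a network batch with a manifest
#'
#' Writes each network of an `N x N x n` array as `net_%04d.tsv` under
#' `dir`, plus a `manifest.json` recording `n`, `N` and any generator
#' parameters supplied in `manifest` (seeds, composition, mode, ...),
#' sufficient to reproduce the batch.
#'
#' @param networks `N x N x n` integer array (or `grn_population`).
#' @param dir Output directory (created if missing).
#' @param manifest Named list of generator parameters to record.
#' @return Invisibly, the manifest path.
#' @export
write_network_batch <- function(networks, dir, manifest = list()) {
  a <- as_network_array(networks)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(a)[3]
  for (k in seq_len(n))
    write_network_tsv(a[, , k], file.path(dir, sprintf("net_%04d.tsv", k)))
  manifest$n <- n
  manifest$N <- dim(a)[1]
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}
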