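#' Inspect and drive the SMEM search tries directly
#'
#' These low-level hooks expose the cache machinery of a `cache = TRUE`
#' seeder for inspection: the forward trie stores, at each node, the
#' bi-interval of the pattern spelled from the root to the node (a child
#' edge is one forward BWT-extend); the backward trie receives exact
#' matches character by character in reverse order, which creates interim
#' nodes with unknown interval (size -1) that are filled lazily when a
#' backward extension is requested on them. Node 0 is the root (empty
#' pattern); nodes 1..4 are the precomputed single-base children.
#'
#' @param seeder An `smem_seeder` created with `cache = TRUE`.
#' @param node Node id (0 is the root).
#' @param base One of "A", "C", "G", "T".
#' @param match A match string over ACGT to insert.
#' @param interval The match's `bi_interval` (known from the forward
#'   stage).
#' @param backward Dump the backward (`TRUE`) or forward trie.
#' @return `sst_forward_query`/`sst_backward_query`: list with the child
#'   `node` id and its `interval`. `sst_backward_insert`: the terminal
#'   node id. `sst_nodes`: a data frame of all nodes (id, parent, edge
#'   label, interval, children). `batch_reset`: the seeder, invisibly.
#' @name sst
NULL

#' @rdname sst
#' @export
sst_forward_query <- function(seeder, node, base) {
  sst_forward_query_cpp(seeder$ptr, as.integer(node), base_to_code(base))
}

#' @rdname sst
#' @export
sst_backward_insert <- function(seeder, match, interval) {
  sst_backward_insert_cpp(seeder$ptr, toupper(match), as.numeric(interval))
}

#' @rdname sst
#' @export
sst_backward_query <- function(seeder, node, base) {
  sst_backward_query_cpp(seeder$ptr, as.integer(node), base_to_code(base))
}

#' @rdname sst
#' @export
sst_nodes <- function(seeder, backward = FALSE) {
  sst_nodes_cpp(seeder$ptr, isTRUE(backward))
}

#' @rdname sst
#' @export
batch_reset <- function(seeder) {
  seeder_reset_batch_cpp(seeder$ptr)
  invisible(seeder)
}

#' Resolve one suffix-array rank through the seeder's SAL provider
#'
#' Counts one SAL query; with `sal_merge = TRUE` the first request per
#' rank in a batch performs a real lookup and later requests are answered
#' from the memo, so the number of real SALs in a batch equals the size of
#' the union of all requested rank ranges.
#'
#' @param seeder An `smem_seeder`.
#' @param rank Suffix-array rank (0-based).
#' @return The text position (see [map_occurrences()]).
#' @export
sal_resolve <- function(seeder, rank) {
  sal_resolve_cpp(seeder$ptr, as.numeric(rank))
}
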