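# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (base round() goes to even).
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Deterministic 31-bit sub-seed derived from a master seed and a counter,
# so independent random streams can be re-derived without replaying others.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 7919 + 12345) %%
               2147483647)
}

# Drop any edge weight attribute; the network measures are defined on
# unweighted graphs.
as_unweighted <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  g
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
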