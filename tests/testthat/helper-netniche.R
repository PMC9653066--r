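# Small builders shared across test files.

make_cm <- function(mat, groups = NULL, pairs = NULL) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("OTU_", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  ns <- ncol(mat)
  groups <- groups %||% rep(c("A", "B"), length.out = ns)
  pairs <- pairs %||% paste0("p", rep(seq_len(ceiling(ns / 2)), each = 2)[seq_len(ns)])
  count_matrix(mat, data.frame(sample_id = colnames(mat), group = groups,
                               pair = pairs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random simple undirected graph on n nodes with edge probability p.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  igraph::sample_gnp(n, p)
}
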