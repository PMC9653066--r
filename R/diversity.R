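#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' sequences. Samples whose total is below `depth` are dropped with a
#' warning (no upsampling). Deterministic for a fixed seed.
#'
#' @param counts a [count_matrix()].
#' @param depth target depth (>= 1), e.g. a common choice is the smallest
#'   library size.
#' @param seed integer seed.
#' @return a [count_matrix()] whose retained columns each sum to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1) {
  if (!inherits(counts, "count_matrix")) stop("'counts' must be a count_matrix",
                                              call. = FALSE)
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1 ||
      depth != round(depth))
    stop("'depth' must be a positive integer", call. = FALSE)
  tot <- colSums(counts$counts)
  keep <- tot >= depth
  if (!all(keep))
    warning(sprintf("dropping %d sample(s) with total below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(counts$counts)[!keep], collapse = ", ")))
  if (!any(keep)) {
    warning("no sample reaches the rarefaction depth; returning empty matrix")
    return(structure(list(counts = counts$counts[, 0, drop = FALSE],
                          metadata = counts$metadata[0, , drop = FALSE]),
                     class = "count_matrix"))
  }
  set.seed(seed)
  cnt <- counts$counts[, keep, drop = FALSE]
  out <- apply(cnt, 2, function(x) {
    if (sum(x) == depth) return(as.integer(x))
    reads <- rep.int(seq_along(x), x)
    tabulate(reads[sample.int(length(reads), depth)], nbins = length(x))
  })
  dimnames(out) <- dimnames(cnt)
  count_matrix(out, counts$metadata[keep, , drop = FALSE])
}

# classic Chao1: S + F1^2 / (2 F2); bias-corrected fallback when F2 = 0
chao1_index <- function(x) {
  x <- x[x > 0]
  s <- length(x); f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

# ACE with the conventional rare/abundant cutoff of 10
ace_index <- function(x, cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= cutoff]
  s_abund <- sum(x > cutoff); s_rare <- length(rare)
  n_rare <- sum(rare); f1 <- sum(rare == 1)
  if (s_rare == 0) return(s_abund)
  if (n_rare == f1) return(NA_real_)           # all rare taxa are singletons
  c_ace <- 1 - f1 / n_rare
  fk <- tabulate(rare, nbins = cutoff)
  g2 <- max((s_rare / c_ace) * sum(seq_len(cutoff) * (seq_len(cutoff) - 1) * fk) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * g2
}

# Fisher's alpha: the root of alpha * log(1 + N / alpha) = S
fisher_alpha_index <- function(x) {
  x <- x[x > 0]
  s <- length(x); n <- sum(x)
  if (s <= 0 || n <= s) return(NA_real_)       # no finite solution at S = N
  f <- function(a) a * log(1 + n / a) - s
  uniroot(f, lower = 1e-10, upper = 1e10, tol = 1e-12)$root
}

# Faith's PD with the rooted convention: total branch length of the union
# of root-to-leaf paths over a sample's observed taxa. Handles polytomies
# (e.g. star trees), which rules out delegating to tools that require
# strictly binary rooted trees.
faith_pd_samples <- function(counts, tree) {
  present_any <- rownames(counts)[rowSums(counts) > 0]
  miss <- setdiff(present_any, tree$tip.label)
  if (length(miss) > 0)
    stop(sprintf("tree is missing taxon '%s'", miss[1]), call. = FALSE)
  root <- length(tree$tip.label) + 1L
  # edges on the path from the root to each tip, indexed by tip label
  parent <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  path_edges <- lapply(seq_along(tree$tip.label), function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root && parent[node] != 0) {
      out <- c(out, edge_of[node])
      node <- parent[node]
    }
    out
  })
  names(path_edges) <- tree$tip.label
  vapply(seq_len(ncol(counts)), function(j) {
    tips <- rownames(counts)[counts[, j] > 0]
    sum(tree$edge.length[unique(unlist(path_edges[tips]))])
  }, numeric(1))
}

#' Alpha diversity and coverage indices
#'
#' Computes, per sample: observed richness, classic Chao1 (with the
#' bias-corrected fallback when no doubletons exist), ACE (rare cutoff 10),
#' Shannon entropy in nats, inverse Simpson, Pielou evenness (missing when
#' only one taxon is observed), Fisher's alpha (root of
#' `alpha * log(1 + N/alpha) = S`), Good's coverage `1 - F1/N` and,
#' when a rooted tree is supplied, Faith's phylogenetic diversity (total
#' branch length of the rooted subtree spanning the observed taxa,
#' including the path to the root).
#'
#' @param counts a [count_matrix()]; every sample total must be >= 1.
#' @param tree optional rooted [ape::phylo] covering all observed taxa.
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  if (!inherits(counts, "count_matrix")) stop("'counts' must be a count_matrix",
                                              call. = FALSE)
  cnt <- counts$counts
  if (any(colSums(cnt) < 1)) stop("every sample total must be >= 1", call. = FALSE)
  one <- function(x) {
    x <- as.numeric(x)
    pos <- x[x > 0]; n <- sum(pos); s <- length(pos)
    p <- pos / n
    h <- -sum(p * log(p))
    c(observed_richness = s,
      chao1 = chao1_index(x),
      ace = ace_index(x),
      shannon = h,
      invsimpson = 1 / sum(p^2),
      pielou = if (s > 1) h / log(s) else NA_real_,
      fisher_alpha = fisher_alpha_index(x),
      goods_coverage = 1 - sum(pos == 1) / n)
  }
  res <- t(apply(cnt, 2, one))
  out <- data.frame(sample_id = colnames(cnt),
                    group = counts$metadata$group,
                    pair = counts$metadata$pair,
                    res, row.names = NULL, check.names = FALSE)
  if (!is.null(tree)) out$faith_pd <- faith_pd_samples(cnt, tree)
  out
}

#' Diversity of functional profiles
#'
#' Richness, Shannon (nats), Pielou and inverse Simpson per sample, computed
#' on column-normalized function relative abundances.
#'
#' @param table a [function_table()].
#' @return data.frame with one row per sample.
#' @export
function_diversity <- function(table) {
  if (!inherits(table, "function_table"))
    stop("'table' must be a function_table", call. = FALSE)
  vals <- unclass(table)
  zero <- colSums(vals) == 0
  if (any(zero))
    stop(sprintf("sample '%s' has an all-zero function profile",
                 colnames(vals)[which(zero)[1]]), call. = FALSE)
  one <- function(x) {
    p <- x[x > 0] / sum(x)
    s <- length(p)
    h <- -sum(p * log(p))
    c(richness = s, shannon = h,
      pielou = if (s > 1) h / log(s) else NA_real_,
      invsimpson = 1 / sum(p^2))
  }
  res <- t(apply(vals, 2, one))
  data.frame(sample_id = colnames(vals), res, row.names = NULL)
}
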