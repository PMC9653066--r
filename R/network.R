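#' Prevalence and abundance filter for network input
#'
#' Keeps taxa that appear (count > 0) in at least `min_samples` samples and
#' whose total relative abundance is at least `min_rel_abund` — by default
#' the taxon's share of the grand total count (>= 0.1%); set
#' `denominator = "mean_sample"` to threshold the mean within-sample
#' proportion instead.
#'
#' @param counts a [count_matrix()].
#' @param min_samples minimum prevalence.
#' @param min_rel_abund minimum total relative abundance (fraction).
#' @param denominator `"grand_total"` or `"mean_sample"`.
#' @return filtered [count_matrix()] (empty, with a warning, if nothing
#'   survives).
#' @export
filter_otus <- function(counts, min_samples = 2, min_rel_abund = 0.001,
                        denominator = c("grand_total", "mean_sample")) {
  denominator <- match.arg(denominator)
  cnt <- counts$counts
  prevalence <- rowSums(cnt > 0)
  share <- if (denominator == "grand_total") rowSums(cnt) / sum(cnt)
           else rowMeans(relative_abundance(counts))
  keep <- prevalence >= min_samples & share >= min_rel_abund
  if (!any(keep)) {
    warning("no taxon passes the prevalence/abundance filter")
    return(structure(list(counts = cnt[keep, , drop = FALSE],
                          metadata = counts$metadata),
                     class = "count_matrix"))
  }
  subset_counts(counts, taxa = which(keep))
}

#' Pearson co-occurrence network
#'
#' Computes the Pearson correlation of within-sample relative abundances
#' for every taxon pair, two-sided p-values from the t transform
#' `t = r * sqrt((n-2)/(1-r^2))`, Benjamini-Hochberg adjustment over all
#' pairs, and keeps an edge iff `|r| > r_threshold` and adjusted
#' `p < p_cut` (the study convention is `r > 0.8`, BH `p < 0.001`).
#' Isolated nodes are retained; taxa with constant abundance across
#' samples are excluded from correlation (with a message) but kept as
#' isolated nodes.
#'
#' @param counts a [count_matrix()] with >= 4 samples and >= 2 taxa.
#' @param r_threshold absolute-correlation threshold.
#' @param p_cut adjusted-p threshold.
#' @return object of class `co_network`: list with `graph` (igraph, vertex
#'   attributes `name` and `rel_abund`; edge attributes `r`, `p_adjusted`,
#'   `sign`), `edges` data.frame, and the thresholds.
#' @export
build_network <- function(counts, r_threshold = 0.8, p_cut = 0.001) {
  if (!inherits(counts, "count_matrix")) stop("'counts' must be a count_matrix",
                                              call. = FALSE)
  cnt <- counts$counts
  n <- ncol(cnt)
  if (n < 4) stop("need >= 4 samples to attach p-values to correlations",
                  call. = FALSE)
  if (nrow(cnt) < 2) stop("need >= 2 taxa", call. = FALSE)
  rel <- relative_abundance(counts)
  const <- apply(rel, 1, function(v) var(v) == 0)
  if (any(const))
    message(sprintf("excluding %d constant taxa from correlation: %s",
                    sum(const), paste(head(rownames(rel)[const], 5),
                                      collapse = ", ")))
  ids <- rownames(rel)
  use <- rel[!const, , drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0), r = numeric(0),
                      p_adjusted = numeric(0), sign = character(0))
  if (nrow(use) >= 2) {
    r <- cor(t(use))
    ut <- upper.tri(r)
    rv <- r[ut]
    tt <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
    pv <- 2 * pt(-abs(tt), df = n - 2)
    pv[abs(rv) >= 1] <- 0
    padj <- p.adjust(pv, method = "BH")
    idx <- which(ut, arr.ind = TRUE)
    keep <- abs(rv) > r_threshold & padj < p_cut
    if (any(keep))
      edges <- data.frame(from = rownames(use)[idx[keep, 1]],
                          to = rownames(use)[idx[keep, 2]],
                          r = rv[keep], p_adjusted = padj[keep],
                          sign = ifelse(rv[keep] > 0, "positive", "negative"),
                          stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  igraph::V(g)$rel_abund <- rowMeans(rel)[ids]
  structure(list(graph = g, edges = edges, r_threshold = r_threshold,
                 p_cut = p_cut),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network: %d nodes, %d edges (|r| > %s, BH p < %s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$r_threshold, x$p_cut))
  invisible(x)
}

#' Coerce to the underlying igraph graph
#' @param network a `co_network` or igraph graph
#' @return an igraph graph
#' @export
as_igraph <- function(network) {
  if (inherits(network, "co_network")) network$graph
  else if (inherits(network, "igraph")) network
  else stop("not a network object", call. = FALSE)
}

#' Natural connectivity
#'
#' `ln((1/N) * sum_i exp(lambda_i))` over the eigenvalues of the unweighted
#' adjacency matrix: a spectral measure of how many closed walks (of all
#' lengths) the graph supports, used as a robustness index. Computed with
#' the max-eigenvalue factored out for numerical stability.
#'
#' @param network a `co_network` or igraph graph with >= 1 node.
#' @return a single number (0 for an edgeless graph).
#' @export
natural_connectivity <- function(network) {
  g <- as_igraph(network)
  nv <- igraph::vcount(g)
  if (nv == 0) return(NA_real_)
  a <- as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g)))
  lam <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  m <- max(lam)
  m + log(mean(exp(lam - m)))
}

global_efficiency_of <- function(g) {
  nv <- igraph::vcount(g)
  if (nv < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (nv * (nv - 1))
}

#' Network property suite
#'
#' Node/edge counts and sign balance, connectance, average degree,
#' connected-component count, Newman modularity of the greedy-agglomerative
#' partition, Freeman degree centralization
#' (`sum(dmax - d_i) / ((N-1)(N-2))`, missing for N < 3), the maximum
#' entry of the unit-normalized principal eigenvector of the adjacency
#' matrix, vulnerability (largest relative drop in global efficiency over
#' single-node deletions, where global efficiency is the mean inverse
#' shortest-path length over ordered pairs with disconnected pairs
#' contributing 0), and natural connectivity.
#'
#' @param network a `co_network` or igraph graph with >= 1 node.
#' @return list of class `network_properties`.
#' @export
network_properties <- function(network) {
  g <- igraph::simplify(as_igraph(network))
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  sgn <- igraph::edge_attr(g, "sign")
  npos <- if (is.null(sgn)) NA_integer_ else sum(sgn == "positive")
  nneg <- if (is.null(sgn)) NA_integer_ else sum(sgn == "negative")
  deg <- igraph::degree(g)
  q <- if (ne > 0) {
    cl <- igraph::cluster_fast_greedy(g)
    igraph::modularity(cl)
  } else NA_real_
  centr <- if (nv >= 3) sum(max(deg) - deg) / ((nv - 1) * (nv - 2)) else NA_real_
  ce <- if (ne > 0) {
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    ev <- eigen(a, symmetric = TRUE)$vectors[, 1]
    max(abs(ev / sqrt(sum(ev^2))))
  } else NA_real_
  eff <- global_efficiency_of(g)
  vul <- if (nv >= 2 && eff > 0) {
    drops <- vapply(seq_len(nv), function(i)
      (eff - global_efficiency_of(igraph::delete_vertices(g, i))) / eff,
      numeric(1))
    max(drops)
  } else NA_real_
  structure(list(
    n_nodes = nv, n_edges = ne, n_positive = npos, n_negative = nneg,
    positive_fraction = if (ne > 0 && !is.na(npos)) npos / ne else NA_real_,
    connectance = if (nv > 1) 2 * ne / (nv * (nv - 1)) else NA_real_,
    average_degree = if (nv > 0) 2 * ne / nv else NA_real_,
    n_clusters = igraph::components(g)$no,
    modularity = q,
    degree_centralization = centr,
    central_eigen = ce,
    vulnerability = vul,
    natural_connectivity = natural_connectivity(g)),
    class = "network_properties")
}

#' @export
print.network_properties <- function(x, ...) {
  v <- unlist(x)
  cat("network properties:\n")
  print(round(v, 4))
  invisible(x)
}

#' Bootstrap distributions of node attributes
#'
#' Computes degree, harmonic closeness (normalized by `N - 1`), local
#' clustering coefficient (transitivity, 0 for nodes of degree < 2) and
#' eigenvector centrality once on the intact graph, then resamples `N`
#' nodes with replacement `n_boot` times, pooling the sampled attribute
#' values into one empirical distribution per attribute (the same node
#' draw is used for all four attributes).
#'
#' @param network a `co_network` or igraph graph.
#' @param n_boot number of bootstrap draws (>= 1).
#' @param seed integer seed.
#' @return list of class `node_attr_boot` with numeric vectors `degree`,
#'   `closeness`, `transitivity`, `eigenvector` (length `N * n_boot`) and
#'   the per-node attribute data.frame as `per_node`.
#' @export
bootstrap_node_attributes <- function(network, n_boot = 10000, seed = 1) {
  n_boot <- check_scalar_count(n_boot, "n_boot", min = 1)
  g <- igraph::simplify(as_igraph(network))
  nv <- igraph::vcount(g)
  if (nv == 0) stop("empty graph", call. = FALSE)
  per <- data.frame(
    name = igraph::V(g)$name %||% as.character(seq_len(nv)),
    degree = igraph::degree(g),
    closeness = igraph::harmonic_centrality(g, normalized = TRUE),
    transitivity = {
      tr <- igraph::transitivity(g, type = "local", isolates = "zero")
      ifelse(is.nan(tr), 0, tr)
    },
    eigenvector = if (igraph::ecount(g) > 0)
      igraph::eigen_centrality(g)$vector else rep(0, nv),
    row.names = NULL)
  set.seed(seed)
  idx <- sample.int(nv, nv * n_boot, replace = TRUE)
  structure(list(degree = per$degree[idx],
                 closeness = per$closeness[idx],
                 transitivity = per$transitivity[idx],
                 eigenvector = per$eigenvector[idx],
                 per_node = per, n_boot = n_boot),
            class = "node_attr_boot")
}

#' Two-sided Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_A - ECDF_B|` with, by default, the asymptotic two-sided
#' p-value.
#'
#' @param dist_a,dist_b non-empty numeric samples.
#' @param exact use the exact p-value (only sensible for small samples).
#' @param attribute optional label carried into the result.
#' @return list of class `ks_result` with `attribute`, `D` and `p`.
#' @export
ks_compare <- function(dist_a, dist_b, exact = FALSE, attribute = NA_character_) {
  if (length(dist_a) == 0 || length(dist_b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(ks.test(dist_a, dist_b, exact = exact))
  structure(list(attribute = attribute, D = unname(kt$statistic),
                 p = kt$p.value),
            class = "ks_result")
}

remove_and_measure <- function(g, fraction, mode) {
  if (mode == "nodes") {
    k <- floor(fraction * igraph::vcount(g))
    h <- if (k > 0)
      igraph::delete_vertices(g, sample.int(igraph::vcount(g), k)) else g
  } else {
    k <- floor(fraction * igraph::ecount(g))
    h <- if (k > 0)
      igraph::delete_edges(g, sample.int(igraph::ecount(g), k)) else g
  }
  if (igraph::vcount(h) == 0) return(c(average_degree = 0,
                                       natural_connectivity = 0))
  c(average_degree = 2 * igraph::ecount(h) / igraph::vcount(h),
    natural_connectivity = natural_connectivity(h))
}

#' Network stability after stochastic removal
#'
#' Removes `floor(fraction * N)` uniformly chosen nodes (or edges) per
#' replicate and recomputes average degree and natural connectivity on the
#' remainder, yielding replicate distributions for downstream KS and
#' Kruskal-Wallis comparisons across networks (the study removes 50% of
#' nodes). A replicate that removes every node is recorded as `(0, 0)`.
#'
#' @param network a `co_network` or igraph graph.
#' @param fraction removal fraction in (0, 1).
#' @param mode `"nodes"` or `"edges"`.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @return data.frame with `replicate`, `average_degree`,
#'   `natural_connectivity`.
#' @export
stability_after_removal <- function(network, fraction = 0.5,
                                    mode = c("nodes", "edges"),
                                    n_replicates = 1000, seed = 1) {
  mode <- match.arg(mode)
  fraction <- check_fraction(fraction, "fraction", open_lo = TRUE)
  if (fraction >= 1) abort_field("fraction", "must be < 1")
  g <- igraph::simplify(as_igraph(network))
  set.seed(seed)
  res <- t(vapply(seq_len(n_replicates),
                  function(k) remove_and_measure(g, fraction, mode),
                  numeric(2)))
  data.frame(replicate = seq_len(n_replicates), res, row.names = NULL)
}

#' Robustness curve under increasing removal
#'
#' Replicate mean and sd of average degree and natural connectivity over a
#' grid of removal fractions (fraction 0 reproduces the intact values
#' exactly), with ordinary-least-squares slope/intercept of the mean
#' decline attached for each property.
#'
#' @param network a `co_network` or igraph graph.
#' @param fractions grid of removal fractions in `[0, 1)`.
#' @param mode `"nodes"` or `"edges"`.
#' @param n_replicates replicates per non-zero fraction.
#' @param seed integer seed.
#' @return object of class `robustness_curve`: list with `curve`
#'   (data.frame `fraction`, `average_degree_mean`, `average_degree_sd`,
#'   `natural_connectivity_mean`, `natural_connectivity_sd`), `fits`
#'   (slope/intercept per property), `mode`, `n_replicates`, `seed`.
#' @export
robustness_sweep <- function(network, fractions = seq(0, 0.8, by = 0.1),
                             mode = c("nodes", "edges"), n_replicates = 50,
                             seed = 1) {
  mode <- match.arg(mode)
  if (any(fractions < 0 | fractions >= 1))
    abort_field("fractions", "grid must lie in [0, 1)")
  g <- igraph::simplify(as_igraph(network))
  intact <- c(average_degree = 2 * igraph::ecount(g) /
                max(igraph::vcount(g), 1),
              natural_connectivity = natural_connectivity(g))
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    if (f == 0)
      return(data.frame(fraction = 0,
                        average_degree_mean = intact[1],
                        average_degree_sd = 0,
                        natural_connectivity_mean = intact[2],
                        natural_connectivity_sd = 0))
    set.seed(stage_seed(seed, i))
    res <- t(vapply(seq_len(n_replicates),
                    function(k) remove_and_measure(g, f, mode), numeric(2)))
    data.frame(fraction = f,
               average_degree_mean = mean(res[, 1]),
               average_degree_sd = sd(res[, 1]),
               natural_connectivity_mean = mean(res[, 2]),
               natural_connectivity_sd = sd(res[, 2]))
  })
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  fits <- lapply(c(average_degree = "average_degree_mean",
                   natural_connectivity = "natural_connectivity_mean"),
                 function(col) {
                   fit <- lm(curve[[col]] ~ curve$fraction)
                   list(intercept = unname(coef(fit)[1]),
                        slope = unname(coef(fit)[2]))
                 })
  structure(list(curve = curve, fits = fits, mode = mode,
                 n_replicates = n_replicates, seed = seed),
            class = "robustness_curve")
}

#' High/low-degree classes and their overlap between two networks
#'
#' Within each network, "high-degree" nodes are those with degree at or
#' above the `high_q` quantile of the positive degrees, and "low-degree"
#' nodes those at or below the `low_q` quantile. Across the two networks
#' the partition cross-tabulates class-specific versus shared membership,
#' records per-shared-node degree pairs, labels class transitions
#' (high to low / low to high), and sums node relative abundance per class
#' when available.
#'
#' @param network_a,network_b `co_network` objects (or igraph graphs) over
#'   comparable taxon universes.
#' @param high_q,low_q quantiles of positive degrees; `high_q` must exceed
#'   `low_q`.
#' @return object of class `degree_classes`: list with `per_network`
#'   (thresholds and class member sets for A and B), `venn` (per class:
#'   shared/specific sets and percent specific), `shared` (data.frame
#'   `taxon`, `degree_A`, `degree_B`, `class_A`, `class_B`, `transition`)
#'   and `class_abundance`.
#' @export
degree_class_partition <- function(network_a, network_b,
                                   high_q = 0.75, low_q = 0.25) {
  if (high_q <= low_q)
    stop("high_q must exceed low_q (identical quantiles collapse the classes)",
         call. = FALSE)
  nets <- list(A = igraph::simplify(as_igraph(network_a)),
               B = igraph::simplify(as_igraph(network_b)))
  classify <- function(g) {
    deg <- igraph::degree(g)
    pos <- deg[deg > 0]
    if (length(pos) == 0)
      return(list(degrees = deg, high = character(0), low = character(0),
                  thresholds = c(high = NA_real_, low = NA_real_)))
    th_h <- unname(quantile(pos, high_q))
    th_l <- unname(quantile(pos, low_q))
    list(degrees = deg,
         high = names(deg)[deg >= th_h],
         low = names(deg)[deg > 0 & deg <= th_l],
         thresholds = c(high = th_h, low = th_l))
  }
  cls <- lapply(nets, classify)
  venn <- lapply(c(high = "high", low = "low"), function(cl) {
    a <- cls$A[[cl]]; b <- cls$B[[cl]]
    shared <- intersect(a, b)
    specific <- c(setdiff(a, b), setdiff(b, a))
    list(shared = shared, specific_A = setdiff(a, b),
         specific_B = setdiff(b, a),
         pct_specific = if (length(union(a, b)) > 0)
           100 * length(specific) / length(union(a, b)) else NA_real_)
  })
  common <- intersect(names(cls$A$degrees), names(cls$B$degrees))
  class_of <- function(side, taxon) {
    if (taxon %in% cls[[side]]$high) "high"
    else if (taxon %in% cls[[side]]$low) "low"
    else "mid"
  }
  shared <- data.frame(
    taxon = common,
    degree_A = unname(cls$A$degrees[common]),
    degree_B = unname(cls$B$degrees[common]),
    class_A = vapply(common, function(t) class_of("A", t), character(1)),
    class_B = vapply(common, function(t) class_of("B", t), character(1)),
    row.names = NULL)
  shared$transition <- ifelse(
    shared$class_A == "high" & shared$class_B == "low", "high_to_low",
    ifelse(shared$class_A == "low" & shared$class_B == "high",
           "low_to_high", "none"))
  abund <- lapply(names(nets), function(side) {
    ra <- igraph::vertex_attr(nets[[side]], "rel_abund")
    if (is.null(ra)) return(c(high = NA_real_, low = NA_real_))
    names(ra) <- igraph::V(nets[[side]])$name
    c(high = sum(ra[cls[[side]]$high]), low = sum(ra[cls[[side]]$low]))
  })
  names(abund) <- names(nets)
  structure(list(per_network = cls, venn = venn, shared = shared,
                 class_abundance = abund,
                 quantiles = c(high_q = high_q, low_q = low_q)),
            class = "degree_classes")
}
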