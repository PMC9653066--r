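#' Levins niche breadth
#'
#' Treats individual samples as resource states: with
#' `P_ij = x_ij / sum_j x_ij`, `B_i = 1 / sum_j P_ij^2` is bounded by 1
#' (taxon confined to one sample) and the number of samples (taxon spread
#' evenly). Reported unstandardized; set `standardized = TRUE` for
#' `B_A = (B - 1) / (n - 1)`.
#'
#' @param counts a [count_matrix()].
#' @param standardized return `B_A` in `[0, 1]` instead of `B`.
#' @return named numeric vector, `NA` for all-zero taxa.
#' @export
levins_breadth <- function(counts, standardized = FALSE) {
  cnt <- counts$counts
  tot <- rowSums(cnt)
  p <- cnt / ifelse(tot > 0, tot, 1)
  b <- 1 / rowSums(p^2)
  b[tot == 0] <- NA_real_
  if (standardized) b <- (b - 1) / (ncol(cnt) - 1)
  setNames(b, rownames(cnt))
}

#' Pianka niche overlap matrix
#'
#' `O_jk = sum_s P_js P_ks / sqrt(sum_s P_js^2 * sum_s P_ks^2)` — the
#' cosine similarity of two taxa's sample-usage profiles, in `[0, 1]`,
#' symmetric with unit diagonal. Rows/columns of all-zero taxa are `NA`.
#'
#' @param counts a [count_matrix()] with >= 2 taxa with positive totals.
#' @return symmetric numeric matrix.
#' @export
pianka_overlap <- function(counts) {
  cnt <- counts$counts
  tot <- rowSums(cnt)
  if (sum(tot > 0) < 2) stop("need >= 2 taxa with positive totals", call. = FALSE)
  p <- cnt / ifelse(tot > 0, tot, 1)
  norm <- sqrt(rowSums(p^2))
  u <- p / ifelse(norm > 0, norm, 1)
  o <- tcrossprod(u)
  o[tot == 0, ] <- NA_real_
  o[, tot == 0] <- NA_real_
  diag(o)[tot > 0] <- 1
  o
}

#' Generalist/specialist classification by marginal-preserving permutation
#'
#' Builds a null distribution of Levins breadth per taxon from random
#' tables that preserve both taxon totals and sample totals (fixed-fixed
#' margins; Patefield's algorithm, [stats::r2dtable()]). A taxon is a
#' generalist if its observed breadth exceeds the `1 - alpha/2` null
#' quantile, a specialist if it falls below the `alpha/2` quantile, and
#' non-significant otherwise.
#'
#' @param counts a [count_matrix()] with >= 2 samples.
#' @param n_perm number of null tables (>= 100).
#' @param alpha two-sided level.
#' @param seed integer seed.
#' @return data.frame with `taxon`, `breadth`, `null_lower`, `null_upper`,
#'   `class` (`"generalist"`, `"specialist"` or `"non_significant"`).
#' @export
classify_generalists <- function(counts, n_perm = 1000, alpha = 0.05, seed = 1) {
  n_perm <- check_scalar_count(n_perm, "n_perm", min = 100)
  cnt <- counts$counts
  if (ncol(cnt) < 2) stop("need >= 2 samples to classify niche breadth",
                          call. = FALSE)
  b_obs <- levins_breadth(counts)
  set.seed(seed)
  sims <- r2dtable(n_perm, rowSums(cnt), colSums(cnt))
  b_null <- vapply(sims, function(m) {
    tot <- rowSums(m)
    p <- m / ifelse(tot > 0, tot, 1)
    ifelse(tot > 0, 1 / rowSums(p^2), NA_real_)
  }, numeric(nrow(cnt)))
  lo <- apply(b_null, 1, quantile, probs = alpha / 2, na.rm = TRUE)
  hi <- apply(b_null, 1, quantile, probs = 1 - alpha / 2, na.rm = TRUE)
  cls <- ifelse(is.na(b_obs), NA_character_,
                ifelse(b_obs > hi, "generalist",
                       ifelse(b_obs < lo, "specialist", "non_significant")))
  data.frame(taxon = rownames(cnt), breadth = unname(b_obs),
             null_lower = unname(lo), null_upper = unname(hi),
             class = unname(cls), row.names = NULL)
}

# Shared SIMPER kernel: mean over between-group sample pairs of
# |x_i - y_i| / sum_t (x_t + y_t). `values` is taxa x samples.
simper_kernel <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  if (length(ia) < 1 || length(ib) < 1)
    stop("each group needs >= 1 sample", call. = FALSE)
  contrib <- numeric(nrow(values))
  for (i in ia) for (j in ib) {
    tot <- sum(values[, i]) + sum(values[, j])
    if (tot > 0) contrib <- contrib + abs(values[, i] - values[, j]) / tot
  }
  contrib / (length(ia) * length(ib))
}

#' Per-taxon SIMPER contribution profile
#'
#' Decomposes between-group Bray-Curtis dissimilarity into per-taxon
#' contributions on within-sample relative abundances, averaged over all
#' between-group sample pairs, sorted in decreasing order and normalized
#' to sum 1.
#'
#' @param counts a [count_matrix()] with exactly 2 groups.
#' @param groups optional explicit labels (defaults to the metadata group).
#' @return data.frame with `taxon`, `contribution` (raw mean pairwise
#'   contribution) and `normalized`, sorted decreasing.
#' @export
simper_contributions <- function(counts, groups = NULL) {
  groups <- groups %||% counts$metadata$group
  rel <- relative_abundance(counts)
  contrib <- simper_kernel(rel, groups)
  ord <- order(-contrib, seq_along(contrib))
  s <- sum(contrib)
  # zero between-group dissimilarity: the profile is uniform by convention
  norm <- if (s > 0) contrib[ord] / s else rep(1 / length(contrib),
                                               length(contrib))
  data.frame(taxon = rownames(rel)[ord], contribution = contrib[ord],
             normalized = norm, row.names = NULL)
}

# Ranked (sorted, normalized, positive) binary SIMPER profile
ranked_profile <- function(m, groups) {
  contrib <- simper_kernel(m, groups)
  s <- sum(contrib)
  if (s > 0) contrib <- contrib / s
  sort(contrib[contrib > 0], decreasing = TRUE)
}

# Squared log10 deviation between ranked profiles over common ranks
e_statistic <- function(obs, perm) {
  k <- min(length(obs), length(perm))
  if (k == 0) return(0)
  sum((log10(obs[seq_len(k)]) - log10(perm[seq_len(k)]))^2)
}

#' Dispersal-niche continuum permutation test
#'
#' Compares how well constrained permutation null models reproduce the
#' observed ranked SIMPER profile of a presence/absence matrix, following
#' the PER-SIMPER construction: the "dispersal-controlled" model shuffles
#' each species' presences across samples (preserving species occurrence
#' totals), the "niche-controlled" model shuffles within samples
#' (preserving sample richness), and the "both" model preserves both
#' margins (curveball algorithm). For each of `n_perm` permuted matrices
#' the goodness-of-fit statistic is
#' `E = sum_ranks (log10 observed - log10 permuted)^2` on the ranked,
#' normalized profiles; the assembly regime whose null has the lower mean
#' E (dispersal- vs niche-controlled) is selected. Species present in
#' every sample (unshuffleable) or in none are dropped with a warning.
#' This is a reconstruction of the published dispersal-niche continuum
#' index restricted to regime selection by E comparison.
#'
#' @param counts a [count_matrix()] (binarized internally) or a
#'   presence/absence matrix, species in rows.
#' @param groups two group labels per sample (defaults to the metadata
#'   group for a `count_matrix`), >= 2 samples each.
#' @param n_perm permuted matrices per null model.
#' @param seed integer seed.
#' @return object of class `dnci_result`: list with `E` (per-model numeric
#'   vectors: `dispersal`, `niche`, `both`), `mean_E`, and
#'   `selected_regime` (`"dispersal"` or `"niche"`).
#' @export
dnci_test <- function(counts, groups = NULL, n_perm = 100, seed = 1) {
  if (inherits(counts, "count_matrix")) {
    groups <- groups %||% counts$metadata$group
    m <- (counts$counts > 0) * 1L
  } else {
    m <- (as.matrix(counts) > 0) * 1L
    if (is.null(groups)) stop("'groups' is required for a plain matrix",
                              call. = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2 || any(table(groups) < 2))
    stop("need 2 groups with >= 2 samples each", call. = FALSE)
  occ <- rowSums(m)
  drop <- occ == 0 | occ == ncol(m)
  if (any(drop)) {
    warning(sprintf("dropping %d species present in every sample or in none",
                    sum(drop)))
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) < 2 || all(m == m[1, 1]))
    stop("presence/absence matrix is degenerate", call. = FALSE)
  obs <- ranked_profile(m, groups)

  e <- list(dispersal = numeric(n_perm), niche = numeric(n_perm),
            both = numeric(n_perm))
  nm <- vegan::nullmodel(m, "curveball")
  sims <- simulate(nm, nsim = n_perm, burnin = 10 * sum(m), thin = sum(m),
                   seed = stage_seed(seed, 1))
  set.seed(stage_seed(seed, 2))
  for (k in seq_len(n_perm)) {
    md <- t(apply(m, 1, sample))                  # fix species occurrences
    mn <- apply(m, 2, sample)                     # fix sample richness
    e$dispersal[k] <- e_statistic(obs, ranked_profile(md, groups))
    e$niche[k] <- e_statistic(obs, ranked_profile(mn, groups))
    e$both[k] <- e_statistic(obs, ranked_profile(sims[, , k], groups))
  }
  mean_e <- vapply(e, mean, numeric(1))
  structure(list(E = e, mean_E = mean_e,
                 selected_regime = if (mean_e[["niche"]] < mean_e[["dispersal"]])
                   "niche" else "dispersal"),
            class = "dnci_result")
}

#' @export
print.dnci_result <- function(x, ...) {
  cat("dispersal-niche continuum test\n")
  cat(sprintf("  mean E: dispersal %.4f | niche %.4f | both %.4f\n",
              x$mean_E[["dispersal"]], x$mean_E[["niche"]], x$mean_E[["both"]]))
  cat(sprintf("  selected regime: %s\n", x$selected_regime))
  invisible(x)
}
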