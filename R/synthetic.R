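#' Configuration for the paired synthetic community generator
#'
#' Describes a paired two-group design (each pair holds one sample per
#' group), a heavy-tailed compositional baseline, optional planted
#' differential taxa, and optional planted correlation blocks driven by a
#' shared latent factor. The defaults mirror a small paired soil survey:
#' three pairs, two groups, one thousand taxa, library sizes around 10^4.
#'
#' @param n_taxa number of taxa (>= 10).
#' @param n_pairs number of sample pairs (>= 2); the design has
#'   `2 * n_pairs` samples.
#' @param group_labels character vector of length 2.
#' @param depth_mean mean library size; per-sample depths are Poisson.
#' @param abundance_shape lognormal sigma of the baseline log-abundances
#'   (controls how heavy-tailed the community is).
#' @param diff_taxa data.frame with columns `taxon` (1-based index), `lfc`
#'   (log2 fold-change) and `group` (which group carries the shift), or
#'   `NULL` for none.
#' @param corr_blocks list of blocks, each a list with `members` (taxon
#'   indices), `loading` (in `[0, 1]`) and `sign` (+1 or -1), or `NULL`.
#' @param assembly_mode `"niche"`, `"dispersal"` or `"mixed"`; recorded in
#'   the ground truth (the paired generator itself is assembly-neutral; use
#'   [generate_assembly_scenario()] for assembly-structured metacommunities).
#' @param seed integer master seed.
#' @param pair_sd standard deviation of the pair-level random intercept on
#'   log-abundance (the paired-design signal).
#' @param noise_sd standard deviation of the per-taxon, per-sample residual
#'   log-abundance noise.
#' @param factor_sd scale of the latent block factor before loading.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 1000, n_pairs = 3,
                             group_labels = c("control", "treatment"),
                             depth_mean = 10000, abundance_shape = 2,
                             diff_taxa = NULL, corr_blocks = NULL,
                             assembly_mode = c("mixed", "niche", "dispersal"),
                             seed = 1, pair_sd = 0.5, noise_sd = 0.2,
                             factor_sd = 1) {
  n_taxa <- check_scalar_count(n_taxa, "n_taxa", min = 10)
  n_pairs <- check_scalar_count(n_pairs, "n_pairs", min = 2)
  if (!is.character(group_labels) || length(group_labels) != 2 ||
      anyDuplicated(group_labels))
    abort_field("group_labels", "must be two distinct strings")
  depth_mean <- check_scalar_count(depth_mean, "depth_mean", min = 1)
  if (!is.numeric(abundance_shape) || abundance_shape <= 0)
    abort_field("abundance_shape", "must be a positive real")
  assembly_mode <- match.arg(assembly_mode)
  seed <- check_scalar_count(seed, "seed", min = 0)
  if (!is.null(diff_taxa)) {
    if (!is.data.frame(diff_taxa) ||
        !all(c("taxon", "lfc", "group") %in% names(diff_taxa)))
      abort_field("diff_taxa", "must be a data.frame with columns taxon, lfc, group")
    if (anyDuplicated(diff_taxa$taxon))
      abort_field("diff_taxa", "taxon indices must be distinct")
    if (any(diff_taxa$taxon < 1 | diff_taxa$taxon > n_taxa |
            diff_taxa$taxon != round(diff_taxa$taxon)))
      abort_field("diff_taxa", "taxon indices must be integers in 1..n_taxa")
    if (!all(diff_taxa$group %in% group_labels))
      abort_field("diff_taxa", "direction group must be one of group_labels")
  }
  if (!is.null(corr_blocks)) {
    for (b in seq_along(corr_blocks)) {
      blk <- corr_blocks[[b]]
      if (!is.list(blk) || !all(c("members", "loading", "sign") %in% names(blk)))
        abort_field("corr_blocks", "each block needs members, loading, sign")
      if (any(blk$members < 1 | blk$members > n_taxa) ||
          anyDuplicated(blk$members) || length(blk$members) < 2)
        abort_field("corr_blocks",
                    sprintf("block %d: members must be >= 2 distinct indices in 1..n_taxa", b))
      if (blk$loading < 0 || blk$loading > 1)
        abort_field("corr_blocks", sprintf("block %d: loading must be in [0, 1]", b))
      if (!blk$sign %in% c(-1, 1))
        abort_field("corr_blocks", sprintf("block %d: sign must be +1 or -1", b))
      if (!is.null(blk$group) && !blk$group %in% group_labels)
        abort_field("corr_blocks",
                    sprintf("block %d: group must be one of group_labels", b))
    }
  }
  structure(list(n_taxa = n_taxa, n_pairs = n_pairs,
                 group_labels = group_labels, depth_mean = depth_mean,
                 abundance_shape = abundance_shape, diff_taxa = diff_taxa,
                 corr_blocks = corr_blocks, assembly_mode = assembly_mode,
                 seed = seed, pair_sd = pair_sd, noise_sd = noise_sd,
                 factor_sd = factor_sd),
            class = "synthetic_config")
}

#' Generate a paired two-group count table with known ground truth
#'
#' Log-abundances are built as
#' `baseline + pair intercept + block factor + differential shift + noise`,
#' exponentiated to compositions, and sampled as one multinomial draw per
#' sample at a Poisson library size. Taxa in a correlation block share a
#' latent Gaussian factor (scaled by `loading * factor_sd`), so their
#' cross-sample log-abundances correlate with the declared sign; negative
#' sign splits the block into two anti-correlated halves. Deterministic for
#' a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth` (list with
#'   `true_diff_taxa`, `true_edges` data.frame `from`/`to`/`sign`, and
#'   `assembly_mode`).
#' @export
generate_paired_counts <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  nt <- config$n_taxa; np <- config$n_pairs; ns <- 2L * np
  grp <- rep(config$group_labels, times = np)
  pair <- rep(paste0("pair", seq_len(np)), each = 2L)
  sample_id <- paste0(pair, "_", grp)

  mu <- rnorm(nt, 0, config$abundance_shape)        # heavy-tailed baseline
  logl <- matrix(mu, nt, ns)
  pair_int <- matrix(rnorm(nt * np, 0, config$pair_sd), nt, np)
  if (!is.null(config$corr_blocks)) {
    for (blk in config$corr_blocks) {
      # A block is a coherent module: members share a latent factor and,
      # scaled by the loading, their pair-level response. Pearson r on the
      # raw (proportion) scale of a lognormal pair decays like
      # exp(-idiosyncratic log-variance), so shared variation must cover
      # the pair effect for loading-1 blocks to be detectable at r > 0.8.
      f <- rnorm(ns) * config$factor_sd * blk$loading
      half <- rep(1, length(blk$members))
      if (blk$sign < 0)  # anti-correlated halves
        half[seq_len(floor(length(blk$members) / 2))] <- -1
      blk_pair <- rnorm(np, 0, config$pair_sd)
      pair_int[blk$members, ] <- blk$loading * rep(blk_pair, each = length(blk$members)) +
        sqrt(1 - blk$loading^2) * pair_int[blk$members, , drop = FALSE]
      if (!is.null(blk$group)) {
        # group-specific association: the factor acts only on that group's
        # samples, so the block's edges exist in one network only. With
        # the shared pair intercept the other group's members still
        # correlate at ~ pair_sd^2 / (pair_sd^2 + noise_sd^2) on the log
        # scale; keep pair_sd <= 0.3 if that leak must stay below r = 0.8.
        f[grp != blk$group] <- 0
      }
      logl[blk$members, ] <- logl[blk$members, ] + outer(half, f)
    }
  }
  logl <- logl + pair_int[, rep(seq_len(np), each = 2L)]
  if (!is.null(config$diff_taxa)) {
    for (k in seq_len(nrow(config$diff_taxa))) {
      d <- config$diff_taxa[k, ]
      logl[d$taxon, grp == d$group] <- logl[d$taxon, grp == d$group] +
        d$lfc * log(2)
    }
  }
  logl <- logl + matrix(rnorm(nt * ns, 0, config$noise_sd), nt, ns)

  prob <- exp(sweep(logl, 2, apply(logl, 2, max), "-"))
  prob <- sweep(prob, 2, colSums(prob), "/")
  depth <- pmax(rpois(ns, config$depth_mean), 1L)
  cnt <- vapply(seq_len(ns),
                function(j) rmultinom(1, depth[j], prob[, j])[, 1],
                integer(nt))
  dimnames(cnt) <- list(paste0("OTU_", seq_len(nt)), sample_id)
  md <- data.frame(sample_id = sample_id, group = grp, pair = pair,
                   stringsAsFactors = FALSE)

  edges <- NULL
  if (!is.null(config$corr_blocks)) {
    edges <- do.call(rbind, lapply(config$corr_blocks, function(blk) {
      pr <- t(combn(sort(blk$members), 2))
      half <- rep(1, length(blk$members))
      if (blk$sign < 0) half[seq_len(floor(length(blk$members) / 2))] <- -1
      names(half) <- sort(blk$members)
      data.frame(from = paste0("OTU_", pr[, 1]), to = paste0("OTU_", pr[, 2]),
                 sign = half[as.character(pr[, 1])] * half[as.character(pr[, 2])],
                 group = blk$group %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL
  }
  truth <- list(true_diff_taxa = if (is.null(config$diff_taxa)) integer(0) else
                  sort(config$diff_taxa$taxon),
                true_edges = edges, assembly_mode = config$assembly_mode)
  list(counts = count_matrix(cnt, md), truth = truth)
}

#' Generate a random rooted binary tree over given taxa
#'
#' Supports Faith's phylogenetic diversity on synthetic communities. Branch
#' lengths are positive; the topology is a random rooted binary tree.
#'
#' @param taxon_ids character vector of leaf names (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] rooted binary tree.
#' @export
generate_tree <- function(taxon_ids, seed = 1) {
  if (length(taxon_ids) < 2) stop("need at least 2 taxa", call. = FALSE)
  if (anyDuplicated(taxon_ids)) stop("taxon ids must be unique", call. = FALSE)
  set.seed(stage_seed(seed, 2))
  tr <- ape::rtree(length(taxon_ids), rooted = TRUE)
  tr$tip.label <- taxon_ids
  tr
}

#' Generate a mock predicted-function table from a count matrix
#'
#' Draws a sparse random taxon-to-function incidence (each function maps
#' each taxon independently with probability `map_density`; empty functions
#' get one random taxon so every function is defined) and sets each
#' function's abundance in a sample to the summed relative abundance of its
#' mapped taxa.
#'
#' @param counts a [count_matrix()].
#' @param n_functions number of functions (>= 1).
#' @param map_density probability a taxon maps to a function, in (0, 1].
#' @param seed integer seed.
#' @return a [function_table()]; the incidence matrix is attached as
#'   attribute `"incidence"`.
#' @export
generate_function_table <- function(counts, n_functions = 50,
                                    map_density = 0.1, seed = 1) {
  if (!inherits(counts, "count_matrix")) stop("'counts' must be a count_matrix",
                                              call. = FALSE)
  n_functions <- check_scalar_count(n_functions, "n_functions", min = 1)
  map_density <- check_fraction(map_density, "map_density", open_lo = TRUE)
  set.seed(stage_seed(seed, 3))
  nt <- nrow(counts$counts)
  inc <- matrix(rbinom(n_functions * nt, 1, map_density), n_functions, nt)
  empty <- rowSums(inc) == 0
  if (any(empty))
    inc[cbind(which(empty), sample.int(nt, sum(empty), replace = TRUE))] <- 1
  dimnames(inc) <- list(paste0("FUN_", seq_len(n_functions)),
                        rownames(counts$counts))
  vals <- inc %*% relative_abundance(counts)
  ft <- function_table(vals)
  attr(ft, "incidence") <- inc
  ft
}

#' Generate a niche- or dispersal-assembled metacommunity
#'
#' Two contrasting occurrence processes over `n_sites` sites split evenly
#' into groups A and B:
#' \describe{
#'   \item{niche}{every species occupies the same number of sites (60% of
#'     sites) but species differ in how strongly their occurrences
#'     concentrate in their preferred group (specificity uniform on
#'     `[0.5, 1]`): the sorting signal is which sites a species is in, not
#'     how many.}
#'   \item{dispersal}{species differ in prevalence (Beta-distributed
#'     occupancy probability with the same mean occupancy as the niche
#'     mode) and occurrences are placed independently of group identity.}
#' }
#' Abundances at occupied sites are lognormal counts, so marginal richness
#' is comparable across modes. Deterministic for a fixed seed.
#'
#' @param mode `"niche"` or `"dispersal"`.
#' @param n_sites number of sites, even, >= 4.
#' @param n_species number of species, >= 10.
#' @param seed integer seed.
#' @param occupancy expected fraction of sites occupied per species.
#' @return a [count_matrix()] with groups `"A"`/`"B"` and sites paired
#'   across groups.
#' @export
generate_assembly_scenario <- function(mode, n_sites = 20, n_species = 40,
                                       seed = 1, occupancy = 0.6) {
  if (!is.character(mode) || length(mode) != 1 ||
      !mode %in% c("niche", "dispersal"))
    stop("mode must be \"niche\" or \"dispersal\"", call. = FALSE)
  n_sites <- check_scalar_count(n_sites, "n_sites", min = 4)
  if (n_sites %% 2 != 0) abort_field("n_sites", "must be even (two equal groups)")
  n_species <- check_scalar_count(n_species, "n_species", min = 10)
  set.seed(stage_seed(seed, 4))
  half <- n_sites / 2
  grp <- rep(c("A", "B"), each = half)
  occ <- matrix(0L, n_species, n_sites)
  if (mode == "niche") {
    k <- max(2L, round(occupancy * n_sites))
    pref <- rep(c("A", "B"), length.out = n_species)
    for (s in seq_len(n_species)) {
      w <- runif(1, 0.5, 1)                      # group specificity
      n_in <- min(round(w * k), half)
      inside <- sample(which(grp == pref[s]), n_in)
      outside <- sample(which(grp != pref[s]), k - n_in)
      occ[s, c(inside, outside)] <- 1L
    }
  } else {
    prev <- rbeta(n_species, 4 * occupancy, 4 * (1 - occupancy))
    for (s in seq_len(n_species)) occ[s, ] <- rbinom(n_sites, 1, prev[s])
  }
  empty <- colSums(occ) == 0                     # no all-zero samples
  if (any(empty))
    occ[cbind(sample.int(n_species, sum(empty), replace = TRUE), which(empty))] <- 1L
  cnt <- occ * matrix(pmax(1L, round(rlnorm(n_species * n_sites,
                                            meanlog = log(50), sdlog = 1))),
                      n_species, n_sites)
  dimnames(cnt) <- list(paste0("SP_", seq_len(n_species)),
                        paste0("site", seq_len(n_sites), "_", grp))
  md <- data.frame(sample_id = colnames(cnt), group = grp,
                   pair = paste0("pair", rep(seq_len(half), times = 2)),
                   stringsAsFactors = FALSE)
  count_matrix(cnt, md)
}
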