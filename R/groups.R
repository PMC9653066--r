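#' Normality/homoscedasticity-gated group comparison
#'
#' Applies the conventional test-selection logic: Shapiro-Wilk normality in
#' every group and Levene's homoscedasticity across groups, both at
#' `alpha`; if all gates pass, a parametric test is used (Student's t for
#' two groups, one-way ANOVA otherwise), else the rank-based counterpart
#' (Wilcoxon rank-sum for two groups, Kruskal-Wallis otherwise). Groups
#' smaller than 3 cannot be tested for normality and fall through to the
#' rank-based branch.
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels, same length as `values`, >= 2 levels with
#'   >= 2 members each.
#' @param alpha gate level for both screening tests.
#' @param variable optional variable id carried into the result.
#' @return list of class `group_test` with fields `variable`,
#'   `method_used`, `statistic`, `p`, `p_adjusted` (`NA` here; see
#'   [bh_adjust()]), `normality_p` (minimum across groups) and
#'   `homoscedasticity_p`.
#' @export
auto_group_test <- function(values, groups, alpha = 0.05, variable = NA_character_) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs >= 2 values", call. = FALSE)
  if (length(values) != length(groups))
    stop("'values' and 'groups' lengths differ", call. = FALSE)
  if (all(tapply(values, groups, function(v) var(v) == 0)))
    stop("constant values in all groups: no variance to test", call. = FALSE)

  shap <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || var(v) == 0) NA_real_ else shapiro.test(v)$p.value
  }, numeric(1))
  lev <- tryCatch(car::leveneTest(values ~ groups, center = mean)[1, "Pr(>F)"],
                  error = function(e) NA_real_)
  normal_ok <- !anyNA(shap) && all(shap > alpha)
  homo_ok <- !is.na(lev) && lev > alpha

  if (normal_ok && homo_ok) {
    if (nlevels(groups) == 2) {
      tt <- t.test(values ~ groups, var.equal = TRUE)
      method <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      fit <- anova(aov(values ~ groups))
      method <- "anova"; statistic <- fit[1, "F value"]; p <- fit[1, "Pr(>F)"]
    }
  } else {
    if (nlevels(groups) == 2) {
      wt <- suppressWarnings(wilcox.test(values ~ groups))
      method <- "wilcoxon"; statistic <- unname(wt$statistic); p <- wt$p.value
    } else {
      kt <- kruskal.test(values, groups)
      method <- "kruskal_wallis"; statistic <- unname(kt$statistic); p <- kt$p.value
    }
  }
  structure(list(variable = variable, method_used = method,
                 statistic = statistic, p = p, p_adjusted = NA_real_,
                 normality_p = suppressWarnings(min(shap)),
                 homoscedasticity_p = lev),
            class = "group_test")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Bray-Curtis or Jaccard distance matrix
#'
#' Bray-Curtis on counts (`sum |x - y| / sum (x + y)`); Jaccard on
#' presence/absence (`1 - |A intersect B| / |A union B|`). Both via
#' [vegan::vegdist()].
#'
#' @param counts a [count_matrix()] with >= 2 samples.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return symmetric numeric matrix with zero diagonal, values in `[0, 1]`.
#' @export
distance_matrix <- function(counts, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  if (!inherits(counts, "count_matrix")) stop("'counts' must be a count_matrix",
                                              call. = FALSE)
  cnt <- t(counts$counts)
  if (nrow(cnt) < 2) stop("need >= 2 samples", call. = FALSE)
  zero <- rowSums(cnt) == 0
  if (any(zero))
    stop(sprintf("sample '%s' has zero total count", rownames(cnt)[which(zero)[1]]),
         call. = FALSE)
  d <- if (metric == "bray_curtis") vegan::vegdist(cnt, method = "bray")
       else vegan::vegdist(cnt, method = "jaccard", binary = TRUE)
  as.matrix(d)
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2); a <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  f <- if (ss_within <= 0 && ss_among <= 0) 0
       else (ss_among / (a - 1)) / (ss_within / (n - a))
  list(f = f, r2 = if (ss_total > 0) ss_among / ss_total else 0)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F from among/within sums of squared distances (Anderson's
#' formulation) with a label-permutation p-value
#' `(1 + #(F_perm >= F_obs)) / (1 + n_permutations)`. For two groups, when
#' the number of distinct label arrangements is at most `n_permutations`,
#' all arrangements are enumerated and the p-value is the exact fraction of
#' arrangements with `F >= F_obs`. Labels are permuted freely by default;
#' passing `pairs` restricts permutations to within-pair label swaps for
#' the paired design.
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @param groups group labels, >= 2 levels with >= 2 members each.
#' @param n_permutations number of random permutations (the study
#'   convention is 9,999).
#' @param seed integer seed.
#' @param pairs optional pair labels; restricts permutations to label swaps
#'   within each pair.
#' @param distance_name label stored in the result.
#' @return list of class `permanova` with `distance_name`, `R2`,
#'   `pseudo_F`, `p`, `n_permutations` (arrangements actually used) and
#'   `method` (`"exhaustive"` or `"sampled"`).
#' @export
permanova <- function(dist, groups, n_permutations = 9999, seed = 1,
                      pairs = NULL, distance_name = "distance") {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) || any(d < 0))
    stop("'dist' must be a symmetric non-negative distance matrix", call. = FALSE)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("groups must have >= 2 levels with >= 2 members each", call. = FALSE)
  n <- nrow(d)
  if (length(groups) != n) stop("label length must match matrix size", call. = FALSE)
  d2 <- d^2
  obs <- permanova_f(d2, groups)

  f_perm <- NULL
  method <- "sampled"
  if (is.null(pairs) && nlevels(groups) == 2 &&
      choose(n, sum(groups == levels(groups)[1])) <= n_permutations) {
    idx <- combn(n, sum(groups == levels(groups)[1]))
    f_perm <- apply(idx, 2, function(i) {
      g <- factor(replace(rep(levels(groups)[2], n), i, levels(groups)[1]),
                  levels = levels(groups))
      permanova_f(d2, g)$f
    })
    method <- "exhaustive"
    p <- mean(f_perm >= obs$f - 1e-12)
    n_used <- length(f_perm)
  } else if (!is.null(pairs) && 2^length(unique(pairs)) <= n_permutations &&
             nlevels(groups) == 2) {
    pairs <- as.character(pairs)
    up <- unique(pairs)
    flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(up))))
    f_perm <- apply(flips, 1, function(fl) {
      g <- as.character(groups)
      for (k in seq_along(up)) if (fl[k]) {
        i <- pairs == up[k]
        g[i] <- rev(g[i])
      }
      permanova_f(d2, factor(g, levels = levels(groups)))$f
    })
    method <- "exhaustive"
    p <- mean(f_perm >= obs$f - 1e-12)
    n_used <- length(f_perm)
  } else {
    set.seed(seed)
    f_perm <- numeric(n_permutations)
    for (k in seq_len(n_permutations)) {
      g <- if (is.null(pairs)) groups[sample.int(n)] else {
        gg <- as.character(groups)
        for (u in unique(pairs)) if (runif(1) < 0.5) {
          i <- pairs == u
          gg[i] <- rev(gg[i])
        }
        factor(gg, levels = levels(groups))
      }
      f_perm[k] <- permanova_f(d2, g)$f
    }
    p <- (1 + sum(f_perm >= obs$f - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }
  if (obs$f == 0) p <- 1      # fully degenerate: all samples identical
  structure(list(distance_name = distance_name, R2 = obs$r2,
                 pseudo_F = obs$f, p = p, n_permutations = n_used,
                 method = method),
            class = "permanova")
}

#' Partition taxa into group-unique and shared sets (Venn)
#'
#' A taxon is unique to a group iff its total count in the other group is
#' zero and positive in that group. The sequence fraction of each unique
#' set is its summed count divided by the group's total sequence count
#' (set `denominator = "grand_total"` for the pooled denominator).
#'
#' @param counts a [count_matrix()] with exactly 2 groups.
#' @param denominator `"per_group"` or `"grand_total"`.
#' @return list of class `venn_partition` with `unique_to_A`, `unique_to_B`,
#'   `shared` (character vectors), `fraction_A`, `fraction_B` and the group
#'   labels.
#' @export
venn_partition <- function(counts, denominator = c("per_group", "grand_total")) {
  denominator <- match.arg(denominator)
  grp <- factor(counts$metadata$group)
  if (nlevels(grp) != 2) stop("venn_partition needs exactly 2 groups", call. = FALSE)
  la <- levels(grp)[1]; lb <- levels(grp)[2]
  cnt <- counts$counts
  tot_a <- rowSums(cnt[, grp == la, drop = FALSE])
  tot_b <- rowSums(cnt[, grp == lb, drop = FALSE])
  observed <- tot_a + tot_b > 0
  ua <- rownames(cnt)[tot_a > 0 & tot_b == 0]
  ub <- rownames(cnt)[tot_b > 0 & tot_a == 0]
  sh <- rownames(cnt)[tot_a > 0 & tot_b > 0]
  den_a <- if (denominator == "per_group") sum(tot_a) else sum(cnt)
  den_b <- if (denominator == "per_group") sum(tot_b) else sum(cnt)
  structure(list(groups = c(la, lb),
                 unique_to_A = ua, unique_to_B = ub, shared = sh,
                 fraction_A = if (den_a > 0) sum(tot_a[ua]) / den_a else 0,
                 fraction_B = if (den_b > 0) sum(tot_b[ub]) / den_b else 0,
                 n_observed = sum(observed)),
            class = "venn_partition")
}

#' Random-forest differential-taxon screen
#'
#' Trains a random-forest classifier of group membership on within-sample
#' relative abundances (stratified bootstrap), ranks taxa by mean decrease
#' in Gini impurity, and attaches a per-taxon Kruskal-Wallis p-value. The
#' discriminating set is conventionally read off as taxa with
#' `kw_p < alpha`.
#'
#' @param counts a [count_matrix()] with >= 2 samples per group.
#' @param n_trees number of trees (a large forest stabilises Gini ranks at
#'   small sample sizes).
#' @param seed integer seed.
#' @param alpha level used for the `discriminating` flag.
#' @return data.frame with columns `taxon`, `mean_decrease_gini`, `rank`
#'   (1 = most important, ties broken by taxon order), `kw_p` and
#'   `discriminating`.
#' @export
rf_screen <- function(counts, n_trees = 10000, seed = 1, alpha = 0.05) {
  grp <- factor(counts$metadata$group)
  if (nlevels(grp) < 2) stop("labels have a single class", call. = FALSE)
  if (any(table(grp) < 2)) stop("need >= 2 samples per group", call. = FALSE)
  rel <- relative_abundance(counts)
  x <- t(rel)
  set.seed(stage_seed(seed, 5))
  fit <- randomForest::randomForest(
    x = x, y = grp, ntree = n_trees,
    strata = grp, sampsize = rep(min(table(grp)), nlevels(grp)))
  gini <- fit$importance[, "MeanDecreaseGini"]
  kw <- apply(rel, 1, function(v) kruskal.test(v, grp)$p.value)
  ord <- order(-gini, seq_along(gini))
  rank <- integer(length(gini)); rank[ord] <- seq_along(gini)
  data.frame(taxon = rownames(rel), mean_decrease_gini = unname(gini),
             rank = rank, kw_p = unname(kw),
             discriminating = unname(kw) < alpha, row.names = NULL)
}

#' Welch's t-test for every function row
#'
#' Two-sided Welch's t (unequal variances, Welch-Satterthwaite degrees of
#' freedom) per function, with BH adjustment across functions. Functions
#' with zero variance in both groups are reported with missing statistics.
#'
#' @param table a [function_table()].
#' @param groups two group labels per sample, >= 2 samples each.
#' @return data.frame with `function_id`, `statistic`, `df`, `p`,
#'   `p_adjusted`, `mean_A`, `mean_B`.
#' @export
welch_compare <- function(table, groups) {
  vals <- unclass(table)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("welch_compare needs exactly 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("need >= 2 samples per group", call. = FALSE)
  ia <- groups == levels(groups)[1]; ib <- !ia
  one <- function(v) {
    if (var(v[ia]) == 0 && var(v[ib]) == 0)
      return(c(NA_real_, NA_real_, NA_real_, mean(v[ia]), mean(v[ib])))
    tt <- t.test(v[ia], v[ib])
    c(unname(tt$statistic), unname(tt$parameter), tt$p.value,
      mean(v[ia]), mean(v[ib]))
  }
  res <- t(apply(vals, 1, one))
  out <- data.frame(function_id = rownames(vals), statistic = res[, 1],
                    df = res[, 2], p = res[, 3], p_adjusted = NA_real_,
                    mean_A = res[, 4], mean_B = res[, 5], row.names = NULL)
  ok <- !is.na(out$p)
  out$p_adjusted[ok] <- bh_adjust(out$p[ok])
  out
}
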