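#' Ordinary least-squares regression
#'
#' Simple linear regression with the two-sided slope p-value, as used to
#' relate network degree to niche width and degree change to niche
#' overlap.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` non-constant.
#' @return list of class `regression_result` with `slope`, `intercept`,
#'   `r_squared`, `p`, `n`.
#' @export
fit_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete observations", call. = FALSE)
  if (sd(x) == 0) stop("'x' is constant", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(x)),
            class = "regression_result")
}

#' Per-node degree change between two networks
#'
#' For every node present in both networks, the absolute (default) or
#' signed difference `degree_B - degree_A`.
#'
#' @param classes a [degree_class_partition()] result.
#' @param signed return the signed difference instead of the absolute one.
#' @return named numeric vector over shared nodes.
#' @export
delta_degree <- function(classes, signed = FALSE) {
  if (!inherits(classes, "degree_classes"))
    stop("'classes' must come from degree_class_partition()", call. = FALSE)
  sh <- classes$shared
  if (nrow(sh) == 0) stop("no shared nodes between the networks", call. = FALSE)
  d <- sh$degree_B - sh$degree_A
  if (!signed) d <- abs(d)
  setNames(d, sh$taxon)
}

# One Gibbs chain for y = X beta + eps, beta ~ N(0, tau2 I),
# sigma2 ~ IG(a0, b0). Returns draws of beta (iter x p) and sigma2.
gibbs_lm <- function(x, y, n_iter, tau2 = 100, a0 = 0.001, b0 = 0.001) {
  p <- ncol(x); n <- nrow(x)
  xtx <- crossprod(x); xty <- crossprod(x, y)
  beta <- matrix(0, n_iter, p)
  sigma2 <- numeric(n_iter)
  s2 <- var(y)
  if (!is.finite(s2) || s2 <= 0) s2 <- 1
  b <- rep(0, p)
  for (it in seq_len(n_iter)) {
    prec <- xtx / s2 + diag(1 / tau2, p)
    ch <- chol(prec)
    mu <- backsolve(ch, forwardsolve(t(ch), xty / s2))
    b <- mu + backsolve(ch, rnorm(p))
    resid <- y - x %*% b
    s2 <- 1 / rgamma(1, a0 + n / 2, b0 + sum(resid^2) / 2)
    beta[it, ] <- b
    sigma2[it] <- s2
  }
  list(beta = beta, sigma2 = sigma2)
}

split_rhat <- function(draws) {
  # draws: iterations x chains
  half <- floor(nrow(draws) / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(sub); n <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  w <- mean(vars)
  b <- n * var(means)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Bayesian path (mediation) model by conjugate Gibbs sampling
#'
#' Fits the two-equation path model
#' `M = alpha0 + a T + e1`, `Y = beta0 + b M + c T + e2`
#' with Normal(0, 10^2) priors on coefficients and
#' Inverse-Gamma(0.001, 0.001) priors on the residual variances, by
#' conjugate Gibbs sampling over multiple chains. By default all three
#' variables are standardized so the coefficients are comparable
#' standardized path estimates. A pathway is flagged accepted iff its
#' central 95% credible interval excludes 0; the indirect effect is the
#' posterior of `a * b`. Convergence is monitored by split-R-hat; a run
#' with any R-hat above 1.1 is flagged (with a warning), never silently
#' returned.
#'
#' @param treatment binary labels (two levels), length n >= 6.
#' @param mediator,outcome numeric vectors of length n.
#' @param n_chains,n_iter,burn_in sampler settings.
#' @param seed integer seed (chains use derived subseeds).
#' @param standardize z-score all variables before fitting.
#' @param level credible level for the interval rule.
#' @return object of class `path_model`: list with `summary` (data.frame
#'   per pathway `a`, `b`, `c`, `indirect`: posterior mean, sd, CI bounds,
#'   `accepted`), `draws` (matrix of pooled post-burn-in draws),
#'   `diagnostics` (`n_chains`, `n_iter`, `burn_in`, per-parameter split
#'   R-hat, `converged`).
#' @export
fit_path_model <- function(treatment, mediator, outcome, n_chains = 4,
                           n_iter = 5000, burn_in = 1000, seed = 1,
                           standardize = TRUE, level = 0.95) {
  tf <- factor(treatment)
  if (nlevels(tf) != 2) stop("treatment must have exactly two levels", call. = FALSE)
  t_num <- as.numeric(tf) - 1
  n <- length(t_num)
  if (n < 6) stop("need n >= 6 observations", call. = FALSE)
  if (length(mediator) != n || length(outcome) != n)
    stop("treatment, mediator and outcome lengths differ", call. = FALSE)
  if (anyNA(mediator) || anyNA(outcome))
    stop("mediator and outcome must not contain missing values", call. = FALSE)
  if (sd(mediator) == 0 || sd(outcome) == 0)
    stop("mediator and outcome must not be constant", call. = FALSE)
  if (burn_in >= n_iter) stop("burn_in must be below n_iter", call. = FALSE)
  zs <- function(v) (v - mean(v)) / sd(v)
  if (standardize) {
    t_num <- zs(t_num); mediator <- zs(mediator); outcome <- zs(outcome)
  }
  x1 <- cbind(1, t_num)
  x2 <- cbind(1, mediator, t_num)
  keep <- (burn_in + 1):n_iter
  per_chain <- lapply(seq_len(n_chains), function(ch) {
    set.seed(stage_seed(seed, 100 + ch))
    f1 <- gibbs_lm(x1, mediator, n_iter)
    f2 <- gibbs_lm(x2, outcome, n_iter)
    cbind(a = f1$beta[keep, 2], b = f2$beta[keep, 2], c = f2$beta[keep, 3])
  })
  params <- c("a", "b", "c")
  rhat <- vapply(params, function(p) {
    split_rhat(vapply(per_chain, function(m) m[, p],
                      numeric(length(keep))))
  }, numeric(1))
  converged <- all(rhat <= 1.1)
  if (!converged)
    warning(sprintf("sampler may not have converged (max split R-hat %.3f)",
                    max(rhat)))
  draws <- do.call(rbind, per_chain)
  draws <- cbind(draws, indirect = draws[, "a"] * draws[, "b"])
  lo_p <- (1 - level) / 2
  summ <- do.call(rbind, lapply(colnames(draws), function(p) {
    v <- draws[, p]
    ci <- unname(quantile(v, c(lo_p, 1 - lo_p)))
    data.frame(pathway = p, mean = mean(v), sd = sd(v),
               ci_lower = ci[1], ci_upper = ci[2],
               accepted = ci[1] > 0 | ci[2] < 0)
  }))
  rownames(summ) <- NULL
  structure(list(summary = summ, draws = draws,
                 diagnostics = list(n_chains = n_chains, n_iter = n_iter,
                                    burn_in = burn_in, rhat = rhat,
                                    converged = converged),
                 level = level, standardized = standardize),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Bayesian path model (%d chains x %d iterations, burn-in %d)\n",
              x$diagnostics$n_chains, x$diagnostics$n_iter,
              x$diagnostics$burn_in))
  print(transform(x$summary,
                  mean = round(mean, 4), sd = round(sd, 4),
                  ci_lower = round(ci_lower, 4), ci_upper = round(ci_upper, 4)))
  cat(sprintf("max split R-hat: %.3f (%s)\n", max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  invisible(x)
}
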