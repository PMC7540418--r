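# Group-comparison layer: binomial likelihood-ratio tests (with aggregation
# to the nesting unit in place of random effects), permutation and
# permutation-KS tests (optionally cluster-permuted at the clone/individual
# level), and classical correlation/variance/location/contingency tests.

.testResult <- function(method, statistic = NA_real_, df = NA_real_,
                        n_perm = NA_integer_, p_value = NA_real_,
                        estimate = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, seed = NA_integer_) {
  data.frame(method = method, statistic = unname(statistic),
             df = unname(df), n_perm = n_perm, p_value = unname(p_value),
             estimate = unname(estimate), ci_lo = ci_lo, ci_hi = ci_hi,
             seed = seed, stringsAsFactors = FALSE)
}

#' Binomial likelihood-ratio test of group proportions
#'
#' Fits binomial GLMs with and without the group term and compares them by a
#' likelihood-ratio test. Non-independence within nesting units (clones,
#' individuals) is handled by aggregating successes and totals to the unit
#' before fitting, in place of a random effect.
#'
#' @param successes,totals integer vectors (e.g. nonsynonymous and total SNP
#'   counts per unit).
#' @param group factor of group labels (>= 2 levels).
#' @param nest optional nesting labels; counts are summed per unit.
#' @return one-row data.frame (statistic = 2 x delta log-likelihood, df,
#'   p_value; estimate = proportion difference for two groups).
#' @export
binomialLRT <- function(successes, totals, group, nest = NULL) {
  stopifnot(length(successes) == length(totals),
            length(group) == length(successes),
            all(successes <= totals))
  df0 <- data.frame(s = successes, t = totals, g = as.character(group))
  if (!is.null(nest)) {
    agg <- stats::aggregate(cbind(s, t) ~ nest + g,
                            data = cbind(df0, nest = as.character(nest)),
                            FUN = sum)
    df0 <- agg
  }
  empty <- tapply(df0$t, df0$g, sum) == 0L
  if (any(empty)) {
    warning("dropping group(s) with zero totals: ",
            paste(names(empty)[empty], collapse = ", "))
    df0 <- df0[!(df0$g %in% names(empty)[empty]), ]
  }
  if (length(unique(df0$g)) < 2L) stop("need at least two non-empty groups")
  df0 <- df0[df0$t > 0L, ]
  full <- stats::glm(cbind(s, t - s) ~ g, family = stats::binomial, data = df0)
  null <- stats::glm(cbind(s, t - s) ~ 1, family = stats::binomial, data = df0)
  lr <- as.numeric(2 * (stats::logLik(full) - stats::logLik(null)))
  lr <- max(lr, 0)
  ddf <- length(unique(df0$g)) - 1L
  est <- if (ddf == 1L) {
    p <- tapply(df0$s, df0$g, sum) / tapply(df0$t, df0$g, sum)
    unname(diff(p))
  } else NA_real_
  .testResult("binomial_lrt", statistic = lr, df = ddf,
              p_value = stats::pchisq(lr, ddf, lower.tail = FALSE),
              estimate = est)
}

.permIndices <- function(labels, cluster) {
  if (is.null(cluster)) return(sample(labels))
  # permute group labels at the cluster level
  cl <- unique(cluster)
  cl_lab <- labels[match(cl, cluster)]
  new_lab <- sample(cl_lab)
  new_lab[match(cluster, cl)]
}

#' Two-group permutation test
#'
#' The observed statistic is compared with its distribution under random
#' reassignment of group labels; the p-value uses the add-one correction
#' \eqn{p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})} and so never returns 0.
#' With \code{cluster} given, labels are permuted at the cluster level
#' (cluster permutation), preserving within-cluster dependence.
#'
#' @param values numeric vector.
#' @param labels group labels (exactly 2 non-empty groups).
#' @param statistic_fn \code{function(values, labels)} returning a scalar
#'   oriented so that larger = more extreme; default absolute difference of
#'   group means.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param cluster optional cluster labels (constant within cluster).
#' @return one-row data.frame.
#' @export
permutationTest <- function(values, labels, statistic_fn = NULL,
                            n_perm = 999L, seed = 1L, cluster = NULL) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L || min(table(labels)) == 0L)
    stop("need exactly two non-empty groups")
  if (is.null(statistic_fn))
    statistic_fn <- function(v, l) {
      m <- tapply(v, l, mean)
      abs(m[1L] - m[2L])
    }
  # canonical ordering: p-values are invariant to row order
  ord <- if (is.null(cluster)) order(values, labels)
         else order(cluster, values, labels)
  values <- values[ord]; labels <- labels[ord]
  if (!is.null(cluster)) cluster <- cluster[ord]
  set.seed(.normSeed(seed))
  obs <- statistic_fn(values, labels)
  perm <- vapply(seq_len(n_perm), function(i)
    statistic_fn(values, .permIndices(labels, cluster)), 0)
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  .testResult("permutation", statistic = obs, n_perm = as.integer(n_perm),
              p_value = p, seed = as.integer(seed))
}

.ksStat <- function(a, b) {
  # max |ECDF_a - ECDF_b| over the pooled support
  pts <- sort(unique(c(a, b)))
  fa <- findInterval(pts, sort(a)) / length(a)
  fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Permutation Kolmogorov-Smirnov test
#'
#' Compares two empirical distributions (e.g. oocyte diameters of old vs
#' young clones) by the maximum CDF distance, with the null distribution
#' generated by permuting sample membership. Exact under exchangeability and
#' valid with ties, unlike the asymptotic KS test.
#'
#' @param dist_a,dist_b numeric samples.
#' @param n_perm permutations (>= 99).
#' @param seed integer seed.
#' @return one-row data.frame.
#' @export
ksPermutation <- function(dist_a, dist_b, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  if (!length(dist_a) || !length(dist_b)) stop("empty sample")
  set.seed(.normSeed(seed))
  obs <- .ksStat(dist_a, dist_b)
  pool <- sort(c(dist_a, dist_b))   # canonical: invariant to input order
  na <- length(dist_a)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    .ksStat(pool[idx], pool[-idx])
  }, 0)
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  .testResult("ks_permutation", statistic = obs,
              n_perm = as.integer(n_perm), p_value = p,
              seed = as.integer(seed))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors.
#' @return one-row data.frame (estimate = r, ci from the Fisher-z transform,
#'   p from the t distribution).
#' @export
pearsonCI <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  .testResult("pearson", statistic = ct$statistic, df = ct$parameter,
              p_value = ct$p.value, estimate = ct$estimate,
              ci_lo = ct$conf.int[1L], ci_hi = ct$conf.int[2L])
}

#' F test of equal variances
#'
#' @param a,b numeric samples.
#' @return one-row data.frame (estimate = variance ratio).
#' @export
varianceFTest <- function(a, b) {
  ft <- stats::var.test(a, b)
  .testResult("f_test", statistic = ft$statistic,
              df = unname(ft$parameter[1L]), p_value = ft$p.value,
              estimate = ft$estimate, ci_lo = ft$conf.int[1L],
              ci_hi = ft$conf.int[2L])
}

#' Welch two-sample t test
#'
#' @param a,b numeric samples.
#' @return one-row data.frame (estimate = mean difference).
#' @export
welchT <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE)
  .testResult("welch_t", statistic = tt$statistic, df = tt$parameter,
              p_value = tt$p.value,
              estimate = unname(tt$estimate[1L] - tt$estimate[2L]),
              ci_lo = tt$conf.int[1L], ci_hi = tt$conf.int[2L])
}

#' Contingency-table test
#'
#' Fisher's exact test for 2 x 2 tables, chi-square otherwise.
#'
#' @param table a matrix of counts.
#' @return one-row data.frame.
#' @export
contingencyTest <- function(table) {
  table <- as.matrix(table)
  if (all(dim(table) == 2L)) {
    ft <- stats::fisher.test(table)
    .testResult("fisher_exact", p_value = ft$p.value,
                estimate = unname(ft$estimate),
                ci_lo = ft$conf.int[1L], ci_hi = ft$conf.int[2L])
  } else {
    ct <- stats::chisq.test(table)
    .testResult("chi_square", statistic = ct$statistic, df = ct$parameter,
                p_value = ct$p.value)
  }
}
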