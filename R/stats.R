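#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of `x` against a normal distribution with mean and SD
#' estimated from `x` itself. Used only as a gate for choosing between
#' parametric and rank-based group comparisons; parameter estimation makes the
#' test conservative (Lilliefors situation), which is acceptable for gating.
#'
#' @param x numeric vector, length >= 3.
#' @return p-value of the KS statistic; `0` for constant input (a point mass
#'   is maximally non-normal for gating purposes).
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("need >= 3 finite values for a normality check")
  s <- stats::sd(x)
  if (s == 0) return(0)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s)$p.value)
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments.
# Handles ties (uses midranks); feasible when choose(nA+nB, nA) is small.
mw_exact_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  combos <- utils::combn(n, length(a))
  sums <- colSums(matrix(r[combos], nrow = length(a)))
  obs <- sum(r[seq_along(a)])
  mu <- length(a) * (n + 1) / 2
  # two-sided: assignments at least as far from the null mean rank-sum
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

#' Two-group comparison with the normality-gated test choice
#'
#' Student's t-test when both groups pass the KS normality gate at 0.05,
#' otherwise Mann-Whitney U. `method` can force either branch. For small
#' samples the Mann-Whitney p-value is exact by enumeration (ties included);
#' identical distributions give p = 1, and zero-variance groups with equal
#' values are treated as indistinguishable (p = 1) rather than erroring.
#'
#' @param a,b numeric vectors, each length >= 2.
#' @param method "auto", "t" or "wilcox".
#' @param exact_limit enumerate the Mann-Whitney null exactly when
#'   `choose(nA+nB, nA)` does not exceed this; otherwise use the normal
#'   approximation with continuity correction.
#' @return list with `p`, `method` (the test actually used) and `statistic`.
#' @export
two_group_test <- function(a, b, method = c("auto", "t", "wilcox"),
                           exact_limit = 100000) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (method == "auto") {
    norm_ok <- length(a) >= 3L && length(b) >= 3L &&
      ks_normality(a) > 0.05 && ks_normality(b) > 0.05
    method <- if (norm_ok) "t" else "wilcox"
  }
  if (stats::sd(c(a, b)) == 0) {
    return(list(p = 1, method = method, statistic = NA_real_))
  }
  if (method == "t") {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # distinct constants: infinitely separated under the t model
      return(list(p = 0, method = "t", statistic = Inf))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    return(list(p = unname(ht$p.value), method = "t",
                statistic = unname(ht$statistic)))
  }
  u <- sum(rank(c(a, b))[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (choose(length(a) + length(b), length(a)) <= exact_limit) {
    p <- mw_exact_p(a, b)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  list(p = unname(p), method = "wilcox", statistic = unname(u))
}

# Dunn's post hoc z-tests on pooled midranks, with tie correction.
dunn_posthoc <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  r <- rank(values)
  n <- length(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  mr <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    (mr[pr[1]] - mr[pr[2]]) / se
  })
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = p_adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = as.numeric(z), p = pmin(as.numeric(p), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-group comparison (>= 3 arms) with the normality-gated test choice
#'
#' One-way ANOVA followed by Tukey's HSD when every group passes the KS
#' normality gate at 0.05; otherwise Kruskal-Wallis followed by Dunn's
#' post hoc z-tests (tie-corrected, unadjusted by default since the upstream
#' analysis applied no multiplicity correction).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, one per observation, >= 3 levels.
#' @param p_adjust adjustment for the Dunn pairwise p-values.
#' @return list with `omnibus_p`, `method` ("anova_tukey" or
#'   "kruskal_dunn") and `pairwise` (data.frame group1, group2, p).
#' @export
multi_group_test <- function(values, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 3L) stop("use two_group_test() for two groups")
  split_vals <- split(values, groups)
  if (any(lengths(split_vals) < 2L)) stop("need >= 2 values per group")
  norm_ok <- all(vapply(split_vals, function(v) {
    length(v) >= 3L && ks_normality(v) > 0.05
  }, logical(1)))
  if (norm_ok) {
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(
      group1 = vapply(nm, `[`, "", 2L),
      group2 = vapply(nm, `[`, "", 1L),
      p = unname(tk[, "p adj"]), stringsAsFactors = FALSE)
    list(omnibus_p = summary(fit)[[1]][["Pr(>F)"]][1],
         method = "anova_tukey", pairwise = pairwise)
  } else {
    kw <- stats::kruskal.test(values, groups)
    dn <- dunn_posthoc(values, groups, p_adjust = p_adjust)
    list(omnibus_p = unname(kw$p.value), method = "kruskal_dunn",
         pairwise = dn[, c("group1", "group2", "p")])
  }
}

#' Choose the group-comparison test the way the study's statistics prescribe
#'
#' Two groups: t-test if all pass KS normality at 0.05, else Mann-Whitney U.
#' Three or more: ANOVA + Tukey if all pass, else Kruskal-Wallis + Dunn.
#' Groups too small for a normality check (< 3 values) force the
#' nonparametric branch with a warning.
#'
#' @param value_list list of numeric vectors, one per group.
#' @return list with `family` ("two_sample"/"multi_sample"), `test` name, and
#'   `normal` logical per group.
#' @export
choose_test <- function(value_list) {
  if (length(value_list) < 2L) stop("need >= 2 groups")
  too_small <- vapply(value_list, length, 1L) < 3L
  if (any(too_small)) {
    warning("group(s) with < 3 observations: falling back to nonparametric")
    normal <- rep(FALSE, length(value_list))
  } else {
    normal <- vapply(value_list, function(v) ks_normality(v) > 0.05,
                     logical(1))
  }
  family <- if (length(value_list) == 2L) "two_sample" else "multi_sample"
  test <- if (family == "two_sample") {
    if (all(normal)) "t" else "mann_whitney"
  } else {
    if (all(normal)) "anova_tukey" else "kruskal_dunn"
  }
  list(family = family, test = test, normal = normal)
}
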