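#' Hedges' g standardized mean difference
#'
#' `g = (m1 - m2) / delta` with `delta` the pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`. With
#' `correct = TRUE` (default) the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2) - 9)` is applied. Accepts either raw samples
#' or summary statistics directly.
#'
#' @param x1,x2 numeric samples (each of length >= 2), or `NULL` when
#'   summaries are supplied.
#' @param m1,s1,n1,m2,s2,n2 group summary statistics (mean, SD, size);
#'   used when `x1`/`x2` are `NULL`.
#' @param correct apply the small-sample correction factor.
#' @return the (dimensionless) standardized mean difference.
#' @examples
#' hedges_g(m1 = 58.177, s1 = 10.223, n1 = 270,
#'          m2 = 62.363, s2 = 8.899, n2 = 138, correct = FALSE)
#' @export
hedges_g <- function(x1 = NULL, x2 = NULL, m1, s1, n1, m2, s2, n2,
                     correct = TRUE) {
  if (!is.null(x1)) {
    x1 <- x1[!is.na(x1)]
    x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L)
      pd_stop("hedges_g: need at least 2 observations per group")
    m1 <- mean(x1); s1 <- sd(x1); n1 <- length(x1)
    m2 <- mean(x2); s2 <- sd(x2); n2 <- length(x2)
  }
  if (n1 < 2L || n2 < 2L) pd_stop("hedges_g: need n1, n2 >= 2")
  pooled <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (pooled <= 0)
    pd_stop("hedges_g: pooled variance is zero; SMD undefined")
  g <- (m1 - m2) / sqrt(pooled)
  if (correct) g <- g * (1 - 3 / (4 * (n1 + n2) - 9))
  g
}

#' Percentile bootstrap confidence interval for the SMD
#'
#' Resamples each group independently with replacement `B` times,
#' recomputes [hedges_g()] on every resample, and returns the percentile
#' interval of the bootstrap distribution.
#'
#' @param x1,x2 raw group samples (summaries are insufficient here).
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @param correct passed to [hedges_g()].
#' @return named numeric `c(lower, upper)`.
#' @export
bootstrap_smd_ci <- function(x1, x2, B = 3000L, level = 0.95, seed = 1L,
                             correct = TRUE) {
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L)
    pd_stop("bootstrap_smd_ci: need at least 2 observations per group")
  J <- if (correct) 1 - 3 / (4 * (n1 + n2) - 9) else 1
  g <- with_seed(seed, {
    R1 <- matrix(x1[sample.int(n1, n1 * B, replace = TRUE)], nrow = n1)
    R2 <- matrix(x2[sample.int(n2, n2 * B, replace = TRUE)], nrow = n2)
    m1 <- colMeans(R1); m2 <- colMeans(R2)
    v1 <- (colMeans(R1^2) - m1^2) * n1 / (n1 - 1)
    v2 <- (colMeans(R2^2) - m2^2) * n2 / (n2 - 1)
    pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    J * (m1 - m2) / sqrt(pooled)
  })
  a <- (1 - level) / 2
  ci <- unname(quantile(g, c(a, 1 - a), na.rm = TRUE))
  c(lower = ci[1L], upper = ci[2L])
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks are used for ties. The p-value is exact (full enumeration of
#' rank assignments) when `n1 + n2 <= 16` and the pooled sample is
#' tie-free; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x1,x2 numeric samples (each non-empty).
#' @param method `"auto"` (the policy above), `"exact"`, or `"approx"`.
#' @return list with `statistic` (the Mann-Whitney U of the first
#'   sample), `p_value`, and the `method` used.
#' @export
wilcoxon_rank_sum <- function(x1, x2, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  x1 <- x1[!is.na(x1)]
  x2 <- x2[!is.na(x2)]
  if (!length(x1) || !length(x2))
    pd_stop("wilcoxon_rank_sum: empty sample")
  ties <- anyDuplicated(c(x1, x2)) > 0L
  use_exact <- switch(method,
    auto = (length(x1) + length(x2) <= 16L) && !ties,
    exact = TRUE,
    approx = FALSE)
  if (use_exact && ties)
    pd_stop("wilcoxon_rank_sum: exact method requires tie-free data")
  ht <- suppressWarnings(
    wilcox.test(x1, x2, exact = use_exact, correct = TRUE,
                alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Family-wise comparison policy with Bonferroni threshold
#'
#' @param family family name (e.g. `"clinical"`, `"imaging"`, `"csf"`).
#' @param members character vector of member variable names.
#' @param level family-wise significance level.
#' @return object of class `family_policy` with the per-comparison
#'   `alpha = level / length(members)` at full precision.
#' @export
family_policy <- function(family, members, level = 0.05) {
  if (length(members) < 1L) pd_stop("family_policy: need >= 1 member")
  structure(list(family = family, members = members, level = level,
                 alpha = level / length(members)),
            class = "family_policy")
}

#' @rdname family_policy
#' @param policy a `family_policy`.
#' @export
bonferroni_alpha <- function(policy) policy$level / length(policy$members)

#' Per-variable two-group comparison table
#'
#' For every member variable of the family: per-group descriptives on
#' pairwise-complete observations, Hedges' g with a percentile bootstrap
#' confidence interval, the Wilcoxon rank-sum p-value, and a significance
#' flag at the family's Bonferroni-corrected threshold. Group 1 is the
#' first subtype in `levels` order (the milder subtype for a fitted
#' model), so negative SMDs on severity scales mean group 1 is less
#' affected.
#'
#' @param data feature data.frame (missing values allowed; each variable
#'   uses its own complete observations, so per-variable n can vary, as
#'   in biomarker families).
#' @param assignments subtype label per row of `data` (character or
#'   factor), or a data.frame `patient_id`/`subtype` to merge by id.
#' @param policy a [family_policy()].
#' @param seed integer seed for the bootstrap.
#' @param B bootstrap resamples per variable.
#' @param level confidence level of the SMD interval.
#' @param correct small-sample correction for [hedges_g()].
#' @return data.frame, one row per member variable: `variable`, `family`,
#'   `n1`, `m1`, `s1`, `n2`, `m2`, `s2`, `smd`, `ci_lower`, `ci_upper`,
#'   `statistic`, `p_value`, `alpha`, `significant`.
#' @export
compare_groups <- function(data, assignments, policy, seed = 1L, B = 3000L,
                           level = 0.95, correct = TRUE) {
  if (is.data.frame(assignments)) {
    idx <- match(data$patient_id, assignments$patient_id)
    assignments <- assignments$subtype[idx]
  }
  grp <- if (is.factor(assignments)) assignments
         else factor(assignments, levels = sort(unique(assignments[!is.na(assignments)])))
  keep <- !is.na(grp)
  data <- data[keep, , drop = FALSE]
  grp <- droplevels(grp[keep])
  if (nlevels(grp) != 2L)
    pd_stop("compare_groups: exactly 2 subtypes required")
  g1 <- levels(grp)[1L]; g2 <- levels(grp)[2L]
  miss <- setdiff(policy$members, names(data))
  if (length(miss))
    pd_stop("compare_groups: data lacks variable(s): ",
            paste(miss, collapse = ", "))
  alpha <- bonferroni_alpha(policy)
  seeds <- spawn_seeds(seed, length(policy$members))
  rows <- lapply(seq_along(policy$members), function(i) {
    v <- policy$members[i]
    x1 <- data[[v]][grp == g1 & !is.na(data[[v]])]
    x2 <- data[[v]][grp == g2 & !is.na(data[[v]])]
    smd <- ci <- c(NA_real_, NA_real_)
    smd <- tryCatch(hedges_g(x1, x2, correct = correct),
                    error = function(e) NA_real_)
    ci <- if (is.na(smd)) c(NA_real_, NA_real_)
          else bootstrap_smd_ci(x1, x2, B = B, level = level,
                                seed = seeds[i], correct = correct)
    wt <- wilcoxon_rank_sum(x1, x2)
    data.frame(variable = v, family = policy$family,
               n1 = length(x1), m1 = mean(x1), s1 = sd(x1),
               n2 = length(x2), m2 = mean(x2), s2 = sd(x2),
               smd = smd, ci_lower = ci[1L], ci_upper = ci[2L],
               statistic = wt$statistic, p_value = wt$p_value,
               alpha = alpha, significant = wt$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped;
#'   at least 3 complete pairs and non-zero variance required.
#' @return list with `rho`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) pd_stop("pearson_correlation: need >= 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    pd_stop("pearson_correlation: zero variance")
  ht <- cor.test(x, y, method = "pearson")
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
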