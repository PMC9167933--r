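test_that("Hedges' g matches direct evaluation of the pooled-SD formula", {
  # published age-of-onset summaries: direct formula evaluation gives
  # -0.4274 uncorrected / -0.4266 with the small-sample factor
  g_unc <- hedges_g(m1 = 58.177, s1 = 10.223, n1 = 270,
                    m2 = 62.363, s2 = 8.899, n2 = 138, correct = FALSE)
  g_cor <- hedges_g(m1 = 58.177, s1 = 10.223, n1 = 270,
                    m2 = 62.363, s2 = 8.899, n2 = 138, correct = TRUE)
  expect_lt(abs(g_unc - (-0.427)), 0.001)
  expect_lt(abs(g_cor - (-0.426)), 0.001)
  # summary and raw-sample interfaces agree
  set.seed(5)
  x1 <- rnorm(40, 1, 2)
  x2 <- rnorm(25, 0, 2)
  expect_equal(hedges_g(x1, x2),
               hedges_g(m1 = mean(x1), s1 = sd(x1), n1 = 40,
                        m2 = mean(x2), s2 = sd(x2), n2 = 25))
  # antisymmetry is exact
  expect_equal(hedges_g(x1, x2), -hedges_g(x2, x1))
  # affine invariance: x -> a x + b leaves g unchanged
  expect_equal(hedges_g(3.7 * x1 + 11, 3.7 * x2 + 11), hedges_g(x1, x2),
               tolerance = 1e-12)
  expect_equal(hedges_g(c(1, 2), c(1, 2)), 0)
  expect_error(hedges_g(c(2, 2), c(5, 5)), "pooled variance")
  expect_error(hedges_g(m1 = 1, s1 = 1, n1 = 1, m2 = 0, s2 = 1, n2 = 5),
               "n1, n2")
})

test_that("bootstrap SMD interval is seeded and shrinks with sample size", {
  set.seed(13)
  x1 <- rnorm(60, 1)
  x2 <- rnorm(60)
  ci <- bootstrap_smd_ci(x1, x2, B = 500, seed = 3)
  expect_identical(ci, bootstrap_smd_ci(x1, x2, B = 500, seed = 3))
  expect_lt(ci[["lower"]], ci[["upper"]])
  expect_error(bootstrap_smd_ci(1, c(1, 2)), "at least 2")
  width_at <- function(n) {
    mean(vapply(1:25, function(r) {
      a <- rnorm(n, 1)
      b <- rnorm(n)
      ci <- bootstrap_smd_ci(a, b, B = 400, seed = r)
      ci[["upper"]] - ci[["lower"]]
    }, numeric(1)))
  }
  w <- c(width_at(20), width_at(80), width_at(320))
  expect_true(all(diff(w) < 0))
})

test_that("rank-sum p-values: exact enumeration and approximation policy", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  # identical multisets: no evidence of a shift
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  # approximate path within 0.01 of the enumerated p at 8 vs 8
  set.seed(19)
  x1 <- rnorm(8)
  x2 <- rnorm(8)
  expect_lt(abs(wilcoxon_rank_sum(x1, x2, method = "approx")$p_value -
                  enumerated_wilcoxon_p(x1, x2)), 0.01)
  # ties force the approximation under auto
  expect_equal(wilcoxon_rank_sum(c(1, 1, 2), c(2, 3, 4))$method,
               "normal approximation")
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
  expect_error(wilcoxon_rank_sum(c(1, 1), c(1, 2), method = "exact"),
               "tie-free")
})

test_that("Bonferroni thresholds divide the family level by member count", {
  expect_equal(bonferroni_alpha(family_policy("csf", paste0("v", 1:10))),
               0.005)
  expect_equal(bonferroni_alpha(family_policy("x", "only")), 0.05)
  pol22 <- family_policy("clinical", paste0("v", 1:22))
  expect_equal(bonferroni_alpha(pol22), 0.05 / 22)
  # full-precision threshold decides flags: 0.001 in, 0.003 out
  expect_true(0.001 < bonferroni_alpha(pol22))
  expect_false(0.003 < bonferroni_alpha(pol22))
  expect_error(family_policy("bad", character(0)), "1 member")
})

test_that("group comparison reproduces the expected effect-size ordering", {
  fx <- default_fit_fixture()
  truth <- fx$cohort$labels
  pol <- family_policy("clinical", clustering_variables(fx$spec$schema))
  tab <- compare_groups(fx$cohort$data, truth, pol, seed = 3, B = 200)
  expect_equal(nrow(tab), 22L)
  expect_equal(unique(tab$alpha), 0.05 / 22)
  expect_true(all(tab$significant == (tab$p_value < tab$alpha)))
  expect_true(all(tab$ci_lower <= tab$smd & tab$smd <= tab$ci_upper))
  # variables generated with near-identical group moments stay quiet while
  # strongly separated ones dominate
  expect_false(tab$significant[tab$variable == "tremor"])
  expect_false(tab$significant[tab$variable == "hallucination"])
  expect_true(tab$significant[tab$variable == "scopa_total"])
  expect_gt(abs(tab$smd[tab$variable == "scopa_total"]),
            abs(tab$smd[tab$variable == "tremor"]))
  # single-variable family
  one <- compare_groups(fx$cohort$data, truth,
                        family_policy("clinical", "age_onset"),
                        seed = 1, B = 100)
  expect_equal(nrow(one), 1L)
  expect_equal(one$alpha, 0.05)
})

test_that("per-variable n follows the missingness of biomarker families", {
  fx <- default_fit_fixture()
  with_na <- inject_missingness(fx$cohort$data, fx$spec$schema,
                                c(csf = 0.05), seed = 9)
  pol <- family_policy("csf",
                       fx$spec$schema$name[fx$spec$schema$category == "csf"])
  tab <- compare_groups(with_na, fx$cohort$labels, pol, seed = 2, B = 100)
  expect_equal(unique(tab$alpha), 0.005)
  expect_true(all(tab$n1 < 270) && all(tab$n1 > 220))
  expect_true(all(tab$n2 < 138) && all(tab$n2 > 110))
})

test_that("rank-sum type-I error matches its nominal level under the null", {
  set.seed(29)
  p <- vapply(1:400, function(i)
    wilcoxon_rank_sum(rnorm(30), rnorm(30))$p_value, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("Pearson correlation matches the closed-form fixture", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$rho, 1)
  fix <- list(x = c(0, 1, 2, 3), y = c(0, 1, 0, 1))
  expect_equal(pearson_correlation(fix$x, fix$y)$rho, 1 / sqrt(5))
  # symmetry
  expect_equal(pearson_correlation(fix$x, fix$y)$rho,
               pearson_correlation(fix$y, fix$x)$rho)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "3 complete pairs")
})
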