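test_that("patients without any follow-up symptom data are excluded", {
  fx <- default_fit_fixture()
  ids <- fx$cohort$labels$patient_id
  keep <- exclude_no_followup(fx$longitudinal, ids)
  expect_equal(length(keep$retained_ids), 391L)
  expect_equal(keep$n_dropped, 17L)
  # everyone with Y1 data: nobody dropped
  rec <- data.frame(patient_id = rep(c("a", "b"), each = 2),
                    visit = rep(c("Y0", "Y1"), 2), hy = 1, moca = 28)
  expect_equal(exclude_no_followup(rec, c("a", "b"))$n_dropped, 0L)
  # a single Y2 MoCA value is enough to stay in
  rec2 <- data.frame(patient_id = c("a", "a", "b"),
                     visit = c("Y0", "Y2", "Y0"),
                     hy = c(1, NA, 1), moca = c(28, 27, 28))
  keep2 <- exclude_no_followup(rec2, c("a", "b"))
  expect_equal(keep2$retained_ids, "a")
  expect_equal(keep2$n_dropped, 1L)
})

test_that("interval rates difference the right visits and stay additive", {
  rec <- data.frame(
    patient_id = rep("p", 4), visit = c("Y0", "Y1", "Y2", "Y3"),
    hy = c(1, 1.5, 1.8, 2), moca = c(28, 27, NA, 26))
  r <- progression_rates(rec)
  hy <- r[r$measure == "hy", ]
  expect_equal(hy$early, 0.5)
  expect_equal(hy$secondary, 0.5)
  expect_equal(hy$long_term, 1.0)
  expect_identical(hy$long_term, hy$early + hy$secondary) # exact
  mo <- r[r$measure == "moca", ]
  expect_equal(mo$early, -1)
  expect_equal(mo$long_term, -2)
  # missing Y3: secondary and long-term undefined, early still there
  rec2 <- rec[rec$visit != "Y3", ]
  r2 <- progression_rates(rec2)
  expect_equal(r2$early[r2$measure == "hy"], 0.5)
  expect_true(all(is.na(r2$secondary)))
  expect_true(all(is.na(r2$long_term)))
  expect_error(progression_rates(rbind(rec, rec[1, ])), "duplicate")
})

test_that("additivity holds exactly across a generated cohort", {
  fx <- default_fit_fixture()
  r <- progression_rates(fx$longitudinal)
  full <- !is.na(r$early) & !is.na(r$secondary)
  expect_identical(r$long_term[full], r$early[full] + r$secondary[full])
})

test_that("progression summary reproduces degenerate configured means", {
  spec <- toy_spec(longitudinal = toy_longitudinal())
  cohort <- generate_baseline(spec)
  lng <- generate_longitudinal(cohort$labels, spec)
  r <- progression_rates(lng)
  ps <- progression_summary(r, cohort$labels)
  cell <- function(sub, m, iv)
    ps$mean[ps$subtype == sub & ps$measure == m & ps$interval == iv]
  expect_equal(cell("MMNS", "hy", "early"), 0.228)
  expect_equal(cell("SMNS", "hy", "secondary"), 0.169)
  expect_equal(cell("MMNS", "moca", "long_term"), -0.693 + 0.254)
  expect_true(all(ps$n == 5L))
  # a patient set with no defined Y3 rate: undefined cell with n = 0
  rec <- data.frame(patient_id = c("a", "a"), visit = c("Y0", "Y1"),
                    hy = c(1, 1.2), moca = c(28, 28))
  ps2 <- progression_summary(progression_rates(rec),
                             data.frame(patient_id = "a", subtype = "S"))
  lt <- ps2[ps2$interval == "long_term" & ps2$measure == "hy", ]
  expect_true(is.na(lt$mean))
  expect_equal(lt$n, 0L)
})

test_that("time-plot grid shows a stable severity ordering across visits", {
  fx <- default_fit_fixture()
  tp <- timeplot_data(fx$longitudinal, fx$cohort$labels)
  expect_equal(nrow(tp), 2L * 4L * 2L)
  for (v in c("Y0", "Y1", "Y2", "Y3")) {
    hy_m <- tp$mean[tp$measure == "hy" & tp$visit == v]
    names(hy_m) <- tp$subtype[tp$measure == "hy" & tp$visit == v]
    expect_gte(hy_m[["SMNS"]], hy_m[["MMNS"]])
    mo_m <- tp$mean[tp$measure == "moca" & tp$visit == v]
    names(mo_m) <- tp$subtype[tp$measure == "moca" & tp$visit == v]
    expect_lte(mo_m[["SMNS"]], mo_m[["MMNS"]])
  }
  # single patient: n = 1 cells
  one <- fx$longitudinal[fx$longitudinal$patient_id ==
                           fx$longitudinal$patient_id[1], ]
  tp1 <- timeplot_data(one, fx$cohort$labels)
  expect_true(all(tp1$n[!is.na(tp1$mean)] == 1L))
  # a visit nobody attended is undefined
  tp2 <- timeplot_data(one[one$visit != "Y2", ], fx$cohort$labels)
  expect_true(all(is.na(tp2$mean[tp2$visit == "Y2"])))
})

test_that("ANCOVA F statistics match the reference Type II computation", {
  set.seed(37)
  for (rep in 1:6) {
    n <- 40
    ids <- sprintf("p%03d", 1:n)
    sub <- sample(c("MMNS", "SMNS"), n, replace = TRUE)
    age <- rnorm(n, 60, 8)
    rec <- expand.grid(patient_id = ids, visit = c("Y0", "Y1", "Y2", "Y3"),
                       stringsAsFactors = FALSE)
    i <- match(rec$patient_id, ids)
    rec$hy <- 1.5 + 0.2 * (sub[i] == "SMNS") +
      0.1 * as.integer(factor(rec$visit)) + 0.01 * age[i] + rnorm(nrow(rec), 0, 0.4)
    rec$moca <- 27 - 0.5 * (sub[i] == "SMNS") -
      0.3 * as.integer(factor(rec$visit)) - 0.02 * age[i] + rnorm(nrow(rec), 0, 2)
    res <- ancova(rec, setNames(sub, ids), setNames(age, ids))
    for (m in c("hy", "moca")) {
      d <- data.frame(score = rec[[m]], subtype = factor(sub[i]),
                      visit = factor(rec$visit), age = age[i])
      ref <- car::Anova(lm(score ~ subtype + visit + age, data = d),
                        type = 2)
      for (term in c("subtype", "visit")) {
        got <- res[res$measure == m & res$term ==
                     ifelse(term == "subtype", "subtype", "visit"), ]
        expect_equal(got$F, ref[term, "F value"], tolerance = 1e-8)
        expect_equal(got$p_value, ref[term, "Pr(>F)"], tolerance = 1e-8)
      }
    }
  }
})

test_that("ANCOVA handles degenerate and deficient designs", {
  rec <- expand.grid(patient_id = c("a", "b", "c", "d"),
                     visit = c("Y0", "Y1"), stringsAsFactors = FALSE)
  rec$hy <- 2
  rec$moca <- 25
  sub <- setNames(c("MMNS", "MMNS", "SMNS", "SMNS"), c("a", "b", "c", "d"))
  age <- setNames(c(50, 55, 60, 65), c("a", "b", "c", "d"))
  res <- ancova(rec, sub, age)
  expect_true(all(res$F[res$term %in% c("subtype", "visit")] == 0))
  # age collinear with subtype membership (constant within each level and
  # only two patients) still fits; but a single visit level errors
  rec1 <- rec[rec$visit == "Y0", ]
  expect_error(ancova(rec1, sub, age), "2 subtypes and >= 2 visits")
})

test_that("the subtype contrast in motor staging is detectable at cohort size", {
  spec <- default_cohort_spec()
  hits <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    cohort <- generate_baseline(spec, seed = 4000 + s)
    lng <- generate_longitudinal(cohort$labels, spec, seed = 8000 + s)
    keep <- exclude_no_followup(lng, cohort$labels$patient_id)
    lng <- lng[lng$patient_id %in% keep$retained_ids, ]
    age <- setNames(cohort$data$age_onset, cohort$data$patient_id)
    res <- ancova(lng, cohort$labels, age)
    p <- res$p_value[res$measure == "hy" & res$term == "subtype"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})
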