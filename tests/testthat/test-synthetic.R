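test_that("degenerate noise reproduces the subtype mean vectors exactly", {
  spec <- toy_spec() # all SDs zero, n = 5 per subtype
  cohort <- generate_baseline(spec)
  expect_equal(nrow(cohort$data), 10L)
  for (lab in c("MMNS", "SMNS")) {
    rows <- cohort$data[cohort$labels$subtype == lab, rownames(spec$means)]
    for (v in rownames(spec$means))
      expect_true(all(rows[[v]] == spec$means[v, lab]))
  }
})

test_that("generation is deterministic and conserves per-subtype counts", {
  spec <- default_cohort_spec()
  a <- generate_baseline(spec, seed = 5)
  b <- generate_baseline(spec, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$data, generate_baseline(spec, seed = 6)$data))
  expect_equal(as.vector(table(a$labels$subtype)[spec$subtypes$label]),
               spec$subtypes$n)
})

test_that("generated values respect scale bounds, rounding and CLT moments", {
  spec <- default_cohort_spec()
  cohort <- generate_baseline(spec, seed = 2)
  dat <- cohort$data
  sc <- spec$schema
  for (i in seq_len(nrow(sc))) {
    v <- sc$name[i]
    expect_true(all(dat[[v]] >= sc$min[i] & dat[[v]] <= sc$max[i]),
                info = v)
    if (sc$integer[i]) expect_true(all(dat[[v]] == round(dat[[v]])), info = v)
  }
  expect_true(all(dat$moca <= 30))
  # CLT bound on a stratum mean: age of onset in the mild subtype
  age_m <- dat$age_onset[cohort$labels$subtype == "MMNS"]
  expect_lt(abs(mean(age_m) - 58.177), 3 * 10.223 / sqrt(270))
})

test_that("stratum moments are recovered within 4 SE when clamping is inactive", {
  n <- c(MMNS = 1500L, SMNS = 1200L)
  means <- rbind(age_onset = c(50, 60), m1 = c(4, 6), nm1 = c(5, 7),
                 nm_rev = c(20, 12))
  sds <- rbind(age_onset = c(8, 7), m1 = c(1, 1), nm1 = c(1.5, 2),
               nm_rev = c(3, 3))
  spec <- toy_spec(n = n, means = means, sds = sds,
                   maxs = c(Inf, 100, 100, 100), seed = 3L)
  cohort <- generate_baseline(spec)
  for (lab in names(n)) for (v in rownames(means)) {
    x <- cohort$data[[v]][cohort$labels$subtype == lab]
    se <- sds[v, if (lab == "MMNS") 1 else 2] / sqrt(n[[lab]])
    expect_lt(abs(mean(x) - means[v, if (lab == "MMNS") 1 else 2]), 4 * se)
  }
})

test_that("invalid specs are rejected with the offending field named", {
  spec <- toy_spec()
  bad <- spec
  bad$sds["m1", "MMNS"] <- -1
  expect_error(validate_cohort_spec(bad), "sds")
  bad <- spec
  bad$subtypes$label <- c("A", "A")
  expect_error(cohort_spec(bad$subtypes, spec$schema, spec$means, spec$sds),
               "unique")
  bad_schema <- spec$schema
  bad_schema$min[2] <- 99 # above max = 10
  expect_error(cohort_spec(spec$subtypes, bad_schema, spec$means, spec$sds),
               "min")
})

test_that("degenerate longitudinal increments give exact interval changes", {
  spec <- toy_spec(longitudinal = toy_longitudinal())
  cohort <- generate_baseline(spec)
  lng <- generate_longitudinal(cohort$labels, spec)
  wide <- reshape(lng, idvar = "patient_id", timevar = "visit",
                  direction = "wide")
  expect_equal(unique(wide$hy.Y1 - wide$hy.Y0), 0.228)
  expect_equal(unique(wide$hy.Y3 - wide$hy.Y1), 0.169)
  expect_equal(unique(wide$moca.Y1 - wide$moca.Y0), -0.693)
  # Y2 interpolates the Y1 -> Y3 segment when its noise SD is zero
  expect_equal(wide$hy.Y2, wide$hy.Y1 + 0.169 / 2)
})

test_that("exactly `dropout` patients lose all follow-up visits", {
  fx <- default_fit_fixture()
  lng <- fx$longitudinal
  fu <- unique(lng$patient_id[lng$visit != "Y0"])
  expect_equal(length(fu), 408L - 17L)
  expect_equal(length(unique(lng$patient_id)), 408L) # Y0 kept for everyone
  expect_error(generate_longitudinal(
    data.frame(patient_id = "X1", subtype = "NOPE"), fx$spec),
    "unknown subtype")
})

test_that("interval increment moments are recovered at large n (mid-scale)", {
  lng_spec <- toy_longitudinal(
    hy_base = c(1.7, 0.5), hy_early = c(0.171, 0.528),
    hy_sec = c(0.178, 0.509), moca_base = c(15, 2.316),
    moca_early = c(-1.031, 2.783), moca_sec = c(-0.274, 2.571))
  spec <- toy_spec(n = c(MMNS = 10L, SMNS = 5000L),
                   longitudinal = lng_spec, seed = 9L)
  cohort <- generate_baseline(spec)
  lng <- generate_longitudinal(cohort$labels, spec)
  rates <- progression_rates(lng)
  smns <- cohort$labels$patient_id[cohort$labels$subtype == "SMNS"]
  lt <- rates$long_term[rates$measure == "moca" &
                          rates$patient_id %in% smns]
  # long-term change composes the two configured interval increments, so
  # its mean recovers their sum (SD adds in quadrature)
  expect_lt(abs(mean(lt, na.rm = TRUE) - (-1.031 - 0.274)),
            4 * sqrt(2.783^2 + 2.571^2) / sqrt(5000))
  e <- rates$early[rates$measure == "moca" & rates$patient_id %in% smns]
  expect_lt(abs(mean(e, na.rm = TRUE) - (-1.031)), 4 * 2.783 / sqrt(5000))
})

test_that("missingness injection is MCAR per category, seeded, non-destructive", {
  spec <- default_cohort_spec()
  cohort <- generate_baseline(spec, seed = 4)
  # rate 0 everywhere: identity
  out0 <- inject_missingness(cohort$data, spec$schema,
                             c(imaging = 0, csf = 0), seed = 1)
  expect_identical(out0, cohort$data)
  # rate 1 for CSF: every CSF cell missing, everything else untouched
  out1 <- inject_missingness(cohort$data, spec$schema, c(csf = 1), seed = 1)
  csf_vars <- spec$schema$name[spec$schema$category == "csf"]
  expect_true(all(is.na(out1[, csf_vars])))
  expect_identical(out1[, setdiff(names(out1), csf_vars)],
                   cohort$data[, setdiff(names(out1), csf_vars)])
  expect_false(anyNA(cohort$data)) # input unmodified
  # binomial bound: ~0.1 * 1000 clustering cells hit
  sub <- cohort$data[1:100, ] # 100 rows x 10 nonmotor vars used below
  nm10 <- nonmotor_variables(spec$schema)[1:10]
  hit <- inject_missingness(sub, spec$schema, c(nonmotor = 0.1), seed = 8)
  n_missing <- sum(is.na(hit[, nm10]))
  expect_lt(abs(n_missing - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  expect_error(inject_missingness(sub, spec$schema, c(bogus = 0.1)),
               "unknown category")
  expect_identical(inject_missingness(sub, spec$schema, c(nonmotor = 0.1),
                                      seed = 8), hit)
})
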