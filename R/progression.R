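#' Exclude patients without any follow-up symptom data
#'
#' A patient stays in the longitudinal analysis set as soon as any
#' follow-up visit (Y1, Y2 or Y3) carries at least one non-missing score
#' on either measure; patients with only baseline data are removed and
#' counted.
#'
#' @param records longitudinal data.frame (`patient_id`, `visit`, `hy`,
#'   `moca`).
#' @param baseline_ids patient ids of the baseline (cluster-analysis)
#'   cohort.
#' @return list with `retained_ids` and `n_dropped`.
#' @export
exclude_no_followup <- function(records, baseline_ids) {
  fu <- records[records$visit != "Y0" &
                  (!is.na(records$hy) | !is.na(records$moca)), ]
  retained <- intersect(baseline_ids, unique(fu$patient_id))
  list(retained_ids = retained,
       n_dropped = length(baseline_ids) - length(retained))
}

#' Per-patient progression rates over three intervals
#'
#' Early progression is the Y1 - Y0 score change, secondary progression
#' Y3 - Y1, and long-term progression Y3 - Y0, for each of the Hoehn &
#' Yahr and MoCA measures. A rate is `NA` when either endpoint visit is
#' missing; whenever all three are defined,
#' `long_term = early + secondary` holds exactly (the same stored scores
#' are differenced).
#'
#' @param records longitudinal data.frame (`patient_id`, `visit`, `hy`,
#'   `moca`); at most one record per patient and visit.
#' @return data.frame `patient_id`, `measure` (`"hy"`/`"moca"`), `early`,
#'   `secondary`, `long_term`.
#' @export
progression_rates <- function(records) {
  if (anyDuplicated(records[, c("patient_id", "visit")]))
    pd_stop("progression_rates: duplicate (patient, visit) records")
  ids <- unique(records$patient_id)
  score_at <- function(measure, visit) {
    sub <- records[records$visit == visit, ]
    sub[[measure]][match(ids, sub$patient_id)]
  }
  out <- lapply(c("hy", "moca"), function(m) {
    y0 <- score_at(m, "Y0"); y1 <- score_at(m, "Y1"); y3 <- score_at(m, "Y3")
    early <- y1 - y0
    secondary <- y3 - y1
    # summing the two interval changes (rather than re-differencing y3 - y0)
    # keeps long_term = early + secondary exact in floating point
    long_term <- ifelse(is.na(early) | is.na(secondary),
                        y3 - y0, early + secondary)
    data.frame(patient_id = ids, measure = m,
               early = early, secondary = secondary, long_term = long_term,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-subtype progression-rate summary
#'
#' Mean (SD) of each interval rate per subtype and measure, with the
#' number of patients contributing to each cell (undefined rates are
#' excluded cell-wise).
#'
#' @param rates output of [progression_rates()].
#' @param assignments subtype per patient: named character vector (names
#'   = patient ids) or data.frame `patient_id`/`subtype`.
#' @return data.frame `subtype`, `measure`, `interval`, `mean`, `sd`, `n`.
#' @export
progression_summary <- function(rates, assignments) {
  sub <- lookup_subtype(rates$patient_id, assignments)
  grid <- expand.grid(subtype = unique(sub[!is.na(sub)]),
                      measure = c("hy", "moca"),
                      interval = c("early", "secondary", "long_term"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- rates[[grid$interval[i]]][sub == grid$subtype[i] &
                                     rates$measure == grid$measure[i]]
    x <- x[!is.na(x)]
    data.frame(grid[i, ], mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) sd(x) else NA_real_, n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Visit-wise score summary per subtype (time-plot data)
#'
#' Mean, SD and n of each measure at each visit within each subtype --
#' the grid behind the longitudinal time plot that shows whether the
#' severity ordering of the subtypes is stable across follow-up.
#'
#' @inheritParams progression_summary
#' @param records longitudinal data.frame (`patient_id`, `visit`, `hy`,
#'   `moca`).
#' @return data.frame `subtype`, `visit`, `measure`, `mean`, `sd`, `n`.
#' @export
timeplot_data <- function(records, assignments) {
  sub <- lookup_subtype(records$patient_id, assignments)
  grid <- expand.grid(subtype = unique(sub[!is.na(sub)]),
                      visit = c("Y0", "Y1", "Y2", "Y3"),
                      measure = c("hy", "moca"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- records[[grid$measure[i]]][sub == grid$subtype[i] &
                                      records$visit == grid$visit[i]]
    x <- x[!is.na(x)]
    data.frame(grid[i, ], mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1L) sd(x) else NA_real_, n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ANCOVA on longitudinal scores: subtype and visit effects, age-adjusted
#'
#' Fits, per measure, the pooled-observation linear model
#' `score ~ subtype + visit + age_at_onset` over all (patient, visit)
#' records (visit as a categorical factor, main effects only), and tests
#' each factor with partial (Type II) F statistics:
#' `F = [(RSS_reduced - RSS_full) / d_df] / [RSS_full / df_residual]`.
#'
#' @param records longitudinal data.frame (`patient_id`, `visit`, `hy`,
#'   `moca`).
#' @param assignments subtype per patient (named vector or data.frame as
#'   in [progression_summary()]).
#' @param age_at_onset age at symptom onset per patient: named numeric
#'   vector or data.frame `patient_id`/`age_onset`.
#' @return data.frame, one row per measure and factor: `measure`, `term`,
#'   `df`, `F`, `p_value`, `df_residual`, plus the fitted `age_coef` on
#'   rows where `term == "age_at_onset"`.
#' @export
ancova <- function(records, assignments, age_at_onset) {
  sub <- lookup_subtype(records$patient_id, assignments)
  if (is.data.frame(age_at_onset)) {
    age_col <- setdiff(names(age_at_onset), "patient_id")[1L]
    age <- age_at_onset[[age_col]][match(records$patient_id,
                                         age_at_onset$patient_id)]
  } else {
    age <- unname(age_at_onset[records$patient_id])
  }
  out <- lapply(c("hy", "moca"), function(m) {
    d <- data.frame(score = records[[m]], subtype = factor(sub),
                    visit = factor(records$visit), age = age)
    d <- d[stats::complete.cases(d), ]
    d$subtype <- droplevels(d$subtype)
    d$visit <- droplevels(d$visit)
    if (nlevels(d$subtype) < 2L || nlevels(d$visit) < 2L)
      pd_stop("ancova: need >= 2 subtypes and >= 2 visits with data")
    full <- lm(score ~ subtype + visit + age, data = d)
    if (anyNA(coef(full))) {
      bad <- names(coef(full))[is.na(coef(full))][1L]
      pd_stop("ancova: rank-deficient design (collinear term: ", bad, ")")
    }
    rss_full <- sum(residuals(full)^2)
    df_res <- full$df.residual
    zero_tol <- 1e-12 * (sum(d$score^2) + 1) # numerically-zero RSS guard
    partial_f <- function(reduced_formula, ddf) {
      red <- lm(reduced_formula, data = d)
      delta <- max(sum(residuals(red)^2) - rss_full, 0)
      f <- if (rss_full < zero_tol) { if (delta < zero_tol) 0 else Inf }
           else (delta / ddf) / (rss_full / df_res)
      c(F = f, p = pf(f, ddf, df_res, lower.tail = FALSE))
    }
    fs <- partial_f(score ~ visit + age, nlevels(d$subtype) - 1L)
    fv <- partial_f(score ~ subtype + age, nlevels(d$visit) - 1L)
    fa <- partial_f(score ~ subtype + visit, 1L)
    data.frame(
      measure = m,
      term = c("subtype", "visit", "age_at_onset"),
      df = c(nlevels(d$subtype) - 1L, nlevels(d$visit) - 1L, 1L),
      F = c(fs["F"], fv["F"], fa["F"]),
      p_value = c(fs["p"], fv["p"], fa["p"]),
      df_residual = df_res,
      age_coef = c(NA_real_, NA_real_, unname(coef(full)["age"])),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# internal: resolve per-row subtype labels from either representation
lookup_subtype <- function(ids, assignments) {
  if (is.data.frame(assignments))
    return(assignments$subtype[match(ids, assignments$patient_id)])
  unname(assignments[ids])
}
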