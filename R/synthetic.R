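#' Generate a synthetic baseline feature table
#'
#' Draws one row per patient from the per-subtype Gaussian profile of a
#' [cohort_spec()]: each variable is sampled independently as
#' `N(mean, sd)`, clamped to its clinical scale `[min, max]`, and rounded
#' to the nearest integer when the schema marks it integer-valued. A `sex`
#' column is generated from the per-subtype male fraction (when present)
#' but is never a clustering variable. The true generating subtype of each
#' row is returned alongside.
#'
#' Clamping after sampling slightly biases the realized moments of
#' variables whose mean sits within about one SD of a bound (floor effects
#' in rare-symptom items such as hallucination or apathy); see the package
#' vignette.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `data` (data.frame: `patient_id`, optional `sex`, one
#'   column per schema variable) and `labels` (data.frame: `patient_id`,
#'   `subtype`).
#' @examples
#' spec <- default_cohort_spec(seed = 42)
#' cohort <- generate_baseline(spec)
#' table(cohort$labels$subtype)
#' @export
generate_baseline <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  st <- spec$subtypes
  sc <- spec$schema
  n_tot <- sum(st$n)
  ids <- sprintf("P%04d", seq_len(n_tot))
  subtype <- rep(st$label, st$n)
  with_seed(seed, {
    cols <- lapply(seq_len(nrow(sc)), function(v) {
      x <- rnorm(n_tot, mean = spec$means[v, subtype], sd = spec$sds[v, subtype])
      x <- clamp(x, sc$min[v], sc$max[v])
      if (sc$integer[v]) x <- round(x)
      x
    })
    names(cols) <- sc$name
    dat <- data.frame(patient_id = ids, cols, stringsAsFactors = FALSE)
    if (!is.null(st$male_fraction) && !anyNA(st$male_fraction)) {
      mf <- setNames(st$male_fraction, st$label)
      male <- rbinom(n_tot, 1L, mf[subtype]) == 1L
      dat <- data.frame(patient_id = ids, sex = ifelse(male, "M", "F"),
                        cols, stringsAsFactors = FALSE)
    }
    list(data = dat,
         labels = data.frame(patient_id = ids, subtype = subtype,
                             stringsAsFactors = FALSE))
  })
}

#' Generate synthetic longitudinal follow-up records
#'
#' Builds Hoehn & Yahr and MoCA trajectories over the visits Y0 (baseline),
#' Y1, Y2 and Y3 (12/24/36 months). Per patient and measure a latent
#' trajectory is built: the baseline is drawn from the subtype's baseline
#' moments, Y1 adds the early (Y1-Y0) increment draw and Y3 adds the
#' secondary (Y3-Y1) increment draw; Y2 is the midpoint of the latent Y1
#' to Y3 segment plus Gaussian noise with the secondary-interval SD scaled
#' by `sqrt(1/2)` (Y2 is plotted but never enters the interval progression
#' rates). Each *observed* score is the latent value clamped to the
#' measure's scale -- a measurement floor/ceiling, so the latent increments
#' keep their configured moments while recorded scores respect the scale.
#' Near a bound (MoCA baselines sit close to the ceiling of 30) the
#' observed changes are attenuated; see the vignette. Exactly `dropout`
#' patients, chosen uniformly at random, retain only their baseline
#' record.
#'
#' @param labels data.frame `patient_id`, `subtype` as returned by
#'   [generate_baseline()].
#' @param spec a [cohort_spec()] with a `longitudinal` block.
#' @param seed integer seed; defaults to `spec$seed + 1`.
#' @return data.frame with columns `patient_id`, `visit` (`"Y0".."Y3"`),
#'   `hy`, `moca`; dropout patients contribute only a `Y0` row.
#' @export
generate_longitudinal <- function(labels, spec, seed = spec$seed + 1L) {
  lg <- spec$longitudinal
  if (is.null(lg)) pd_stop("spec has no longitudinal block")
  bad <- setdiff(unique(labels$subtype), spec$subtypes$label)
  if (length(bad)) pd_stop("unknown subtype label in `labels`: ", bad[1L])
  n <- nrow(labels)
  sub <- labels$subtype
  moments <- function(m, blk, what)
    vapply(sub, function(s) lg[[m]][[blk]][[s]][[what]], numeric(1L))
  with_seed(seed, {
    score <- list()
    for (m in c("hy", "moca")) {
      lo <- lg[[m]]$scale$min
      hi <- lg[[m]]$scale$max
      y0 <- rnorm(n, moments(m, "baseline", "mean"),
                  moments(m, "baseline", "sd"))
      e <- rnorm(n, moments(m, "early", "mean"), moments(m, "early", "sd"))
      s <- rnorm(n, moments(m, "secondary", "mean"), moments(m, "secondary", "sd"))
      y1 <- y0 + e
      y3 <- y1 + s
      y2 <- y1 + s / 2 + rnorm(n, 0, moments(m, "secondary", "sd") * sqrt(0.5))
      score[[m]] <- cbind(Y0 = clamp(y0, lo, hi), Y1 = clamp(y1, lo, hi),
                          Y2 = clamp(y2, lo, hi), Y3 = clamp(y3, lo, hi))
    }
    drop_ids <- if (lg$dropout > 0)
      labels$patient_id[sample.int(n, lg$dropout)] else character(0)
    out <- data.frame(
      patient_id = rep(labels$patient_id, each = 4L),
      visit = rep(c("Y0", "Y1", "Y2", "Y3"), times = n),
      hy = as.vector(t(score$hy)),
      moca = as.vector(t(score$moca)),
      stringsAsFactors = FALSE)
    out[out$visit == "Y0" | !(out$patient_id %in% drop_ids), , drop = FALSE]
  })
}

#' Inject missing values completely at random, per variable category
#'
#' Sets each data cell of a variable to `NA` independently with the
#' probability configured for the variable's category. The input table is
#' left unmodified; a fresh copy is returned.
#'
#' @param table a feature data.frame (non-schema columns such as
#'   `patient_id` are untouched).
#' @param schema schema data.frame mapping variables to categories.
#' @param rates named numeric vector of per-category probabilities in
#'   `[0, 1]`; categories absent from `rates` get rate 0.
#' @param seed integer seed.
#' @return the table with missing cells injected.
#' @export
inject_missingness <- function(table, schema, rates, seed = 1L) {
  bad <- setdiff(names(rates), unique(schema$category))
  if (length(bad)) pd_stop("unknown category in `rates`: ", bad[1L])
  if (any(rates < 0 | rates > 1)) pd_stop("rates must lie in [0, 1]")
  out <- table
  with_seed(seed, {
    for (v in intersect(schema$name, names(table))) {
      r <- rates[schema$category[schema$name == v]]
      if (is.na(r) || r == 0) next
      hit <- stats::runif(nrow(out)) < r
      out[[v]][hit] <- NA
    }
    out
  })
}
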