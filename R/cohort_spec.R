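#' Cohort specification for the synthetic patient generator
#'
#' A `cohort_spec` bundles everything the generator needs: a variable schema
#' (clinical scale bounds, integer flags, severity direction, category), the
#' per-subtype Gaussian profile (mean and SD per variable), per-category
#' missingness probabilities, the longitudinal model (baseline and
#' per-interval increment moments for Hoehn & Yahr and MoCA, plus a
#' follow-up dropout count), and a seed.
#'
#' @param subtypes data.frame with columns `label`, `n` and optionally
#'   `male_fraction`.
#' @param schema data.frame with columns `name`, `category` (one of
#'   `"age"`, `"motor"`, `"nonmotor"`, `"imaging"`, `"csf"`), `min`, `max`,
#'   `integer` (logical) and `direction` (`"higher_worse"` or
#'   `"higher_better"`).
#' @param means,sds numeric matrices, one row per schema variable (rownames
#'   = variable names), one column per subtype (colnames = labels), on the
#'   clinical scale of each variable.
#' @param missingness named numeric vector of per-category missing-cell
#'   probabilities.
#' @param longitudinal list with elements `dropout` (integer) and, for each
#'   of `hy` and `moca`, a list holding `scale` (`min`, `max`) and
#'   per-subtype `baseline`, `early` (Y1-Y0) and `secondary` (Y3-Y1)
#'   moments, each a list of `mean`/`sd` pairs keyed by subtype label.
#' @param seed default integer seed used by the generator operations.
#' @return an object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [read_cohort_spec()],
#'   [generate_baseline()]
#' @export
cohort_spec <- function(subtypes, schema, means, sds,
                        missingness = NULL, longitudinal = NULL, seed = 1L) {
  spec <- structure(
    list(subtypes = as.data.frame(subtypes), schema = as.data.frame(schema),
         means = as.matrix(means), sds = as.matrix(sds),
         missingness = missingness, longitudinal = longitudinal,
         seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' Checks the structural invariants: unique subtype labels, sizes >= 1,
#' male fractions and missingness probabilities in `[0, 1]`, `min < max`
#' for every variable with finite bounds, non-negative SDs, known
#' categories and severity directions, and (when a longitudinal block is
#' present) a dropout count not exceeding the cohort size.
#'
#' @param spec a [cohort_spec()].
#' @return `spec`, invisibly; otherwise an error naming the offending field.
#' @export
validate_cohort_spec <- function(spec) {
  st <- spec$subtypes
  sc <- spec$schema
  if (anyDuplicated(st$label)) pd_stop("subtypes: labels must be unique")
  if (any(st$n < 1)) pd_stop("subtypes: n must be >= 1")
  if (!is.null(st$male_fraction) &&
      any(st$male_fraction < 0 | st$male_fraction > 1))
    pd_stop("subtypes: male_fraction must lie in [0, 1]")
  need <- c("name", "category", "min", "max", "integer", "direction")
  miss <- setdiff(need, names(sc))
  if (length(miss)) pd_stop("schema: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(sc$name)) pd_stop("schema: variable names must be unique")
  bad <- !sc$category %in% c("age", "motor", "nonmotor", "imaging", "csf")
  if (any(bad)) pd_stop("schema: unknown category for ", sc$name[bad][1L])
  bad <- !sc$direction %in% c("higher_worse", "higher_better")
  if (any(bad)) pd_stop("schema: unknown direction for ", sc$name[bad][1L])
  bad <- is.finite(sc$min) & is.finite(sc$max) & !(sc$min < sc$max)
  if (any(bad)) pd_stop("schema: min must be < max for ", sc$name[bad][1L])
  if (!all(rownames(spec$means) == sc$name) ||
      !all(rownames(spec$sds) == sc$name))
    pd_stop("means/sds: rownames must match schema variable order")
  if (!all(colnames(spec$means) == st$label) ||
      !all(colnames(spec$sds) == st$label))
    pd_stop("means/sds: colnames must match subtype labels")
  if (any(spec$sds < 0)) pd_stop("sds: standard deviations must be >= 0")
  if (!is.null(spec$missingness)) {
    mr <- spec$missingness
    bad <- setdiff(names(mr), unique(sc$category))
    if (length(bad)) pd_stop("missingness: unknown category ", bad[1L])
    if (any(mr < 0 | mr > 1)) pd_stop("missingness: rates must lie in [0, 1]")
  }
  lg <- spec$longitudinal
  if (!is.null(lg)) {
    if (lg$dropout < 0 || lg$dropout > sum(st$n))
      pd_stop("longitudinal: dropout must lie in [0, cohort size]")
    for (m in c("hy", "moca")) for (blk in c("baseline", "early", "secondary"))
      for (lab in st$label) {
        mo <- lg[[m]][[blk]][[lab]]
        if (is.null(mo)) pd_stop("longitudinal: missing ", m, " ", blk, " for ", lab)
        if (mo$sd < 0) pd_stop("longitudinal: ", m, " ", blk, " sd must be >= 0")
      }
  }
  invisible(spec)
}

#' Read a cohort specification from a YAML file
#'
#' The file layout mirrors [cohort_spec()]: `subtypes`, `variables` (each
#' with `name`, `category`, `min`/`max`, `integer`, `direction` and
#' per-subtype `mean`/`sd` maps), `missingness` and `longitudinal`
#' sections. See the packaged default
#' `system.file("extdata", "ppmi_like_cohort.yaml", package = "pdsubtype")`
#' for a complete example.
#'
#' @param path path to a YAML cohort file.
#' @param seed default seed stored in the spec.
#' @return a [cohort_spec()].
#' @export
read_cohort_spec <- function(path, seed = 1L) {
  y <- yaml::read_yaml(path)
  st <- do.call(rbind, lapply(y$subtypes, function(s)
    data.frame(label = s$label, n = as.integer(s$n),
               male_fraction = if (is.null(s$male_fraction)) NA_real_ else s$male_fraction)))
  labs <- st$label
  sc <- do.call(rbind, lapply(y$variables, function(v)
    data.frame(name = v$name, category = v$category,
               min = as.numeric(v$min), max = as.numeric(v$max),
               integer = isTRUE(v$integer), direction = v$direction)))
  means <- t(vapply(y$variables, function(v) unlist(v$mean)[labs], numeric(length(labs))))
  sds <- t(vapply(y$variables, function(v) unlist(v$sd)[labs], numeric(length(labs))))
  dimnames(means) <- dimnames(sds) <- list(sc$name, labs)
  mr <- if (is.null(y$missingness)) NULL else unlist(y$missingness)
  cohort_spec(st, sc, means, sds, missingness = mr,
              longitudinal = y$longitudinal, seed = seed)
}

#' The packaged PPMI-like two-subtype cohort specification
#'
#' Default parameters of the synthetic generator: a 22-variable clustering
#' schema (age of symptom onset, 5 motor and 16 non-motor features) plus 28
#' imaging and 10 CSF variables, two subtypes of 270 (MMNS) and 138 (SMNS)
#' patients with published per-variable means/SDs, per-category missingness,
#' and the Table-style longitudinal increment model with 17 follow-up
#' dropouts.
#'
#' @param seed default seed stored in the spec.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L) {
  read_cohort_spec(system.file("extdata", "ppmi_like_cohort.yaml",
                               package = "pdsubtype", mustWork = TRUE),
                   seed = seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  subtypes: ", paste0(x$subtypes$label, " (n=", x$subtypes$n, ")",
                             collapse = ", "), "\n", sep = "")
  tab <- table(x$schema$category)
  cat("  variables:", paste0(names(tab), "=", tab, collapse = ", "), "\n")
  if (!is.null(x$longitudinal))
    cat("  longitudinal: hy + moca over Y0..Y3, dropout =",
        x$longitudinal$dropout, "\n")
  invisible(x)
}

#' Variable subsets of a schema
#'
#' `clustering_variables()` returns the age + motor + non-motor variable
#' names (the set the subtyping model is fitted on); `motor_variables()`
#' and `nonmotor_variables()` the two composite-score families;
#' `reversed_variables()` the reversed-severity (higher = better) members
#' of a set.
#'
#' @param schema a schema data.frame (see [cohort_spec()]).
#' @return character vector of variable names.
#' @export
clustering_variables <- function(schema) {
  schema$name[schema$category %in% c("age", "motor", "nonmotor")]
}

#' @rdname clustering_variables
#' @export
motor_variables <- function(schema) schema$name[schema$category == "motor"]

#' @rdname clustering_variables
#' @export
nonmotor_variables <- function(schema) schema$name[schema$category == "nonmotor"]

#' @rdname clustering_variables
#' @export
reversed_variables <- function(schema) {
  schema$name[schema$direction == "higher_better"]
}

#' Default clinical variable schema
#'
#' The 22-variable clustering schema (plus imaging and CSF families) of the
#' packaged default cohort specification.
#'
#' @return a schema data.frame.
#' @export
pd_schema <- function() default_cohort_spec()$schema
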