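#' Motor and non-motor composite severity scores
#'
#' The two composites summarise a normalized patient row as one motor and
#' one non-motor coordinate, so cluster memberships can be displayed in a
#' two-dimensional severity plane. The motor composite is the arithmetic
#' mean of the normalized motor variables (UPDRS-III total plus the
#' tremor, rigidity, bradykinesia and axial subscores in the default
#' schema). The non-motor composite averages the normalized non-motor
#' variables after replacing the reversed-severity scales (MoCA, UPSIT) by
#' `1 - value`, so that *higher always means more severe*. Age belongs to
#' neither composite. Rows from the min-max fit cohort yield scores in
#' `[0, 1]`.
#'
#' @param normalized data.frame or matrix of min-max normalized values
#'   (one or more rows).
#' @param schema schema data.frame (see [cohort_spec()]); defines the
#'   motor/non-motor families and the reversed-severity variables.
#' @return numeric vector, one score per row.
#' @examples
#' spec <- default_cohort_spec()
#' cohort <- generate_baseline(spec, seed = 1)
#' vars <- clustering_variables(spec$schema)
#' prm <- fit_minmax(cohort$data, vars)
#' z <- apply_minmax(cohort$data, prm)
#' summary(motor_composite(z, spec$schema))
#' @export
motor_composite <- function(normalized, schema) {
  vars <- motor_variables(schema)
  composite_mean(normalized, vars, character(0))
}

#' @rdname motor_composite
#' @export
nonmotor_composite <- function(normalized, schema) {
  vars <- nonmotor_variables(schema)
  composite_mean(normalized, vars, intersect(reversed_variables(schema), vars))
}

# internal: row mean over `vars`, reversing `reversed` as 1 - value
composite_mean <- function(normalized, vars, reversed) {
  normalized <- as.data.frame(normalized)
  miss <- setdiff(vars, names(normalized))
  if (length(miss))
    pd_stop("composite: missing variable(s): ", paste(miss, collapse = ", "))
  M <- as.matrix(normalized[, vars, drop = FALSE])
  for (v in reversed) M[, v] <- 1 - M[, v]
  rowMeans(M)
}

#' Cluster memberships in the motor/non-motor severity plane
#'
#' Computes per-patient composite coordinates and the subtype label
#' assigned by the model's nearest-centroid rule -- the data behind the
#' membership scatter display (severe-subtype patients sit towards the
#' top-right of the plane).
#'
#' @param table feature data.frame, complete on the model's clustering
#'   variables.
#' @param model a fitted [pd_subtype()] model.
#' @return data.frame `patient_id`, `motor_composite`,
#'   `nonmotor_composite`, `subtype`.
#' @export
membership_scatter <- function(table, model) {
  z <- apply_minmax(table, model$scaling)
  pred <- predict(model, table)
  data.frame(
    patient_id = if ("patient_id" %in% names(table)) table$patient_id
                 else seq_len(nrow(table)),
    motor_composite = motor_composite(z, model$schema),
    nonmotor_composite = nonmotor_composite(z, model$schema),
    subtype = pred$subtype,
    stringsAsFactors = FALSE)
}
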