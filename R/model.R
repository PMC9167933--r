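#' Fit a Parkinson's disease subtyping model
#'
#' The standardized subtyping procedure: select the complete cases on the
#' clustering variables, min-max normalize them (parameters are persisted
#' with the model), run restart-controlled Lloyd k-means, and -- unless
#' `k` is fixed -- pick the number of subtypes by the Calinski-Harabasz
#' pseudo-F over `k_range`. Subtypes are ordered by ascending centroid
#' composite severity (motor + non-motor composite of each centroid); for
#' the two-subtype solution they are labelled `MMNS` (mild
#' motor-non-motor subtype) and `SMNS` (severe), otherwise `S1..Sk`.
#'
#' The fitted object carries everything the nearest-centroid
#' classification rule needs (rescaling parameters and centroids), so new
#' patients can be classified with [predict.pd_subtype()] without access
#' to the training data.
#'
#' @param data baseline feature data.frame (rows = patients; a
#'   `patient_id` column is used when present).
#' @param variables clustering variable names; defaults to the schema's
#'   age + motor + non-motor set intersected with `names(data)`.
#' @param schema schema data.frame (see [cohort_spec()]).
#' @param k fixed number of subtypes; `NULL` (default) selects over
#'   `k_range`.
#' @param k_range candidate cluster numbers for selection.
#' @param n_restarts random restarts per `k`.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param tol centroid-movement convergence tolerance (normalized units).
#' @param seed master seed; restart initializations derive from it.
#' @param init_method `"forgy"` or `"kmeans++"` initialization.
#' @return an object of class `pd_subtype`; see [build_model()] for its
#'   fields.
#' @examples
#' spec <- default_cohort_spec()
#' cohort <- generate_baseline(spec, seed = 7)
#' fit <- pd_subtype(cohort$data, schema = spec$schema,
#'                   k_range = 2:4, n_restarts = 10, seed = 7)
#' fit
#' @export
pd_subtype <- function(data, variables = NULL, schema = pd_schema(),
                       k = NULL, k_range = 2:10, n_restarts = 100L,
                       max_iter = 100L, tol = 1e-6, seed = 1L,
                       init_method = c("forgy", "kmeans++")) {
  init_method <- match.arg(init_method)
  if (is.null(variables))
    variables <- intersect(clustering_variables(schema), names(data))
  if (length(variables) < 2L)
    pd_stop("pd_subtype: need at least 2 clustering variables in `data`")
  n_input <- nrow(data)
  cc <- suppressMessages(complete_cases(data, variables))
  params <- fit_minmax(cc, variables)
  z <- apply_minmax(cc, params)
  X <- as.matrix(z[, variables, drop = FALSE])
  if (is.null(k)) {
    sel <- select_k(X, k_range = k_range, n_restarts = n_restarts,
                    max_iter = max_iter, seed = seed, tol = tol,
                    init_method = init_method)
    fit <- sel$fits[[as.character(sel$selected)]]
    trace <- sel$trace
    selected <- sel$selected
  } else {
    fit <- kmeans_restarts(X, k, n_restarts = n_restarts,
                           max_iter = max_iter, seed = seed, tol = tol,
                           init_method = init_method)
    ch <- if (k >= 2L && nrow(X) > k) calinski_harabasz(X, fit$assignment)
          else NA_real_
    trace <- data.frame(k = k, wss = fit$wss, ch = ch)
    selected <- k
  }
  model <- build_model(cc, schema, params, fit, trace,
                       selected = selected, variables = variables,
                       seed = seed)
  model$n_input <- n_input
  model$call <- match.call()
  model
}

#' Assemble a cluster model from a k-means fit
#'
#' Orders the fitted clusters by ascending composite severity of their
#' centroids (motor composite + non-motor composite when the schema's two
#' families are among the clustering variables; otherwise the
#' severity-oriented mean of all normalized centroid coordinates), labels
#' them (`MMNS`/`SMNS` for k = 2, else `S1..Sk`), and bundles the
#' rescaling parameters, centroids (normalized and clinical-scale),
#' cluster sizes, selection trace and training assignment into one
#' portable object. Severity ties fall back to cluster size (descending),
#' then to the lexicographic order of centroid coordinates.
#'
#' @param data the complete-case training data (raw clinical units).
#' @param schema schema data.frame.
#' @param params [fit_minmax()] parameters fitted on `data`.
#' @param fit a [lloyd_kmeans()] / [kmeans_restarts()] fit computed on
#'   `apply_minmax(data, params)`.
#' @param trace per-k selection data.frame (`k`, `wss`, `ch`).
#' @param selected the selected k.
#' @param variables clustering variable names (column order of the fit).
#' @param seed the master seed used for fitting.
#' @return an object of class `pd_subtype` with fields `k`, `variables`,
#'   `schema`, `scaling`, `centroids` (normalized, rows named by subtype),
#'   `centroids_clinical`, `labels`, `sizes`, `assignment` (named by
#'   patient id), `membership` (training composite coordinates),
#'   `selection` (`trace`, `selected`), `wss`, `iterations`, `converged`,
#'   `seed`, `n_complete`.
#' @export
build_model <- function(data, schema, params, fit, trace, selected = fit$k,
                        variables = params$variable, seed = NA_integer_) {
  k <- fit$k
  C <- fit$centroids
  colnames(C) <- variables
  sizes <- tabulate(fit$assignment, k)
  key <- centroid_severity(C, schema, variables)
  if (anyDuplicated(key))
    message("build_model: severity tie between centroids; ",
            "falling back to size, then lexicographic order")
  ord <- do.call(order, c(list(key, -sizes), asplit(C, 2L)))
  labels <- if (k == 2L) c("MMNS", "SMNS") else paste0("S", seq_len(k))
  C <- C[ord, , drop = FALSE]
  rownames(C) <- labels
  sizes <- setNames(sizes[ord], labels)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assignment <- labels[relabel[fit$assignment]]
  ids <- if ("patient_id" %in% names(data)) data$patient_id
         else as.character(seq_len(nrow(data)))
  names(assignment) <- ids
  Cdf <- as.data.frame(C)
  clinical <- invert_minmax(Cdf, params)
  model <- structure(
    list(k = k, variables = variables, schema = schema, scaling = params,
         centroids = C, centroids_clinical = as.matrix(clinical),
         labels = labels, sizes = sizes, assignment = assignment,
         selection = list(trace = trace, selected = selected),
         wss = fit$wss, iterations = fit$iterations,
         converged = fit$converged, seed = seed,
         n_complete = nrow(data)),
    class = "pd_subtype")
  model$membership <- tryCatch(membership_scatter(data, model),
                               error = function(e) NULL)
  model
}

# internal: composite severity ordering key of normalized centroids
centroid_severity <- function(centroids, schema, variables) {
  cdf <- as.data.frame(centroids)
  names(cdf) <- variables
  mv <- motor_variables(schema)
  nv <- nonmotor_variables(schema)
  if (length(mv) && length(nv) && all(c(mv, nv) %in% variables))
    return(motor_composite(cdf, schema) + nonmotor_composite(cdf, schema))
  rev <- intersect(reversed_variables(schema), variables)
  composite_mean(cdf, variables, rev)
}

#' Classify patients with a fitted subtype model
#'
#' The nearest-centroid rule: (a) normalize the patient's clinical values
#' with the model's stored rescaling parameters (values outside the
#' training range are *not* clipped); (b) compute the squared Euclidean
#' distance to each subtype centroid in normalized space; (c) assign the
#' subtype with the smaller distance (ties go to the first subtype in
#' model order, i.e. the milder one).
#'
#' @param object a fitted [pd_subtype()] model.
#' @param newdata data.frame providing every model variable, without
#'   missing values.
#' @param ... unused.
#' @return data.frame with `patient_id`, `subtype`, and one squared
#'   distance column `dist_<label>` per subtype.
#' @export
predict.pd_subtype <- function(object, newdata, ...) {
  vars <- object$variables
  miss <- setdiff(vars, names(newdata))
  if (length(miss))
    pd_stop("predict: missing variable(s): ", paste(miss, collapse = ", "))
  for (v in vars) if (anyNA(newdata[[v]]))
    pd_stop("predict: missing values in variable '", v, "'")
  z <- apply_minmax(newdata, object$scaling)
  X <- as.matrix(z[, vars, drop = FALSE])
  C <- object$centroids
  D <- vapply(seq_len(nrow(C)),
              function(j) rowSums(sweep(X, 2L, C[j, ])^2),
              numeric(nrow(X)))
  D <- matrix(D, nrow = nrow(X),
              dimnames = list(NULL, paste0("dist_", object$labels)))
  nearest <- max.col(-D, ties.method = "first")
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(newdata)) newdata$patient_id
                 else as.character(seq_len(nrow(newdata))),
    subtype = object$labels[nearest], stringsAsFactors = FALSE)
  cbind(out, as.data.frame(D))
}

#' @rdname predict.pd_subtype
#' @param model a fitted [pd_subtype()] model.
#' @export
classify <- function(model, newdata) predict(model, newdata)

#' @export
print.pd_subtype <- function(x, ...) {
  cat("Parkinson's disease subtyping model (k-means, k =", x$k, ")\n")
  cat("  variables:", length(x$variables),
      "| fit cohort n =", x$n_complete, "\n")
  cat("  subtypes: ",
      paste0(x$labels, " (n=", x$sizes, ")", collapse = ", "), "\n", sep = "")
  ch <- x$selection$trace$ch[x$selection$trace$k == x$k]
  cat("  Calinski-Harabasz =", format(ch, digits = 4),
      "| WSS =", format(x$wss, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.pd_subtype <- function(object, ...) {
  structure(list(k = object$k, sizes = object$sizes,
                 selection = object$selection,
                 centroids_clinical = object$centroids_clinical,
                 n_complete = object$n_complete),
            class = "summary.pd_subtype")
}

#' @export
print.summary.pd_subtype <- function(x, ...) {
  cat("Subtype model summary: k =", x$k, "on n =", x$n_complete, "patients\n\n")
  cat("Selection trace:\n")
  print(x$selection$trace, row.names = FALSE)
  cat("\nCentroid profiles (clinical scales):\n")
  print(round(t(x$centroids_clinical), 3))
  invisible(x)
}

#' @export
coef.pd_subtype <- function(object, normalized = FALSE, ...) {
  if (normalized) object$centroids else object$centroids_clinical
}

#' @export
fitted.pd_subtype <- function(object, ...) object$assignment

#' Membership scatter plot in the motor/non-motor severity plane
#'
#' @param x a fitted [pd_subtype()] model.
#' @param newdata optional feature data.frame to display instead of the
#'   training cohort.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pd_subtype <- function(x, newdata = NULL, ...) {
  ms <- if (is.null(newdata)) x$membership else membership_scatter(newdata, x)
  if (is.null(ms)) pd_stop("plot: no membership coordinates available")
  cols <- setNames(c("#3B6FB6", "#C0392B", "#27AE60", "#8E44AD",
                     "#E67E22", "#16A085", "#7F8C8D", "#D35400",
                     "#2C3E50", "#F39C12")[seq_along(x$labels)], x$labels)
  plot(ms$motor_composite, ms$nonmotor_composite,
       col = adjustcolor(cols[ms$subtype], 0.7), pch = 16,
       xlab = "motor composite score", ylab = "non-motor composite score",
       ...)
  legend("topleft", legend = x$labels, col = cols, pch = 16, bty = "n")
  invisible(ms)
}

#' Write / read a cluster model as JSON
#'
#' The model file stores the variable list, rescaling parameters,
#' centroids (normalized and clinical-scale), subtype labels and sizes,
#' the selection trace, schema and seed at full double precision, so that
#' write -> read -> write reproduces the file byte for byte and a read
#' model classifies exactly like the fitted one. The training assignment
#' is not part of the file (the model file is the portable classification
#' artifact).
#'
#' @param model a fitted [pd_subtype()] model.
#' @param path output (input) file path.
#' @return `write_pd_model()` returns `path` invisibly; `read_pd_model()`
#'   a `pd_subtype` object without training assignment.
#' @export
write_pd_model <- function(model, path) {
  payload <- list(
    format = "pdsubtype-model", schema_version = 1L,
    k = model$k, variables = model$variables, labels = model$labels,
    sizes = as.integer(model$sizes),
    scaling = data.frame(variable = model$scaling$variable,
                         min = model$scaling$min, max = model$scaling$max,
                         degenerate = model$scaling$degenerate),
    scaling_n = attr(model$scaling, "n"),
    centroids_normalized = unclass(as.data.frame(model$centroids)),
    centroids_clinical = unclass(as.data.frame(model$centroids_clinical)),
    selection = list(trace = model$selection$trace,
                     selected = model$selection$selected),
    schema = model$schema, seed = model$seed,
    wss = model$wss, n_complete = model$n_complete)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_pd_model
#' @export
read_pd_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "pdsubtype-model"))
    pd_stop("read_pd_model: not a pdsubtype model file")
  scaling <- as.data.frame(p$scaling)
  attr(scaling, "n") <- p$scaling_n
  class(scaling) <- c("minmax_params", "data.frame")
  Cn <- as.matrix(as.data.frame(p$centroids_normalized))
  Cc <- as.matrix(as.data.frame(p$centroids_clinical))
  rownames(Cn) <- rownames(Cc) <- p$labels
  structure(
    list(k = p$k, variables = p$variables, schema = as.data.frame(p$schema),
         scaling = scaling, centroids = Cn, centroids_clinical = Cc,
         labels = p$labels, sizes = setNames(p$sizes, p$labels),
         assignment = NULL,
         selection = list(trace = as.data.frame(p$selection$trace),
                          selected = p$selection$selected),
         wss = p$wss, iterations = NA_integer_, converged = NA,
         seed = p$seed, n_complete = p$n_complete),
    class = "pd_subtype")
}
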