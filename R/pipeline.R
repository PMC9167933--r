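#' Run the full subtyping analysis end to end
#'
#' Orchestrates simulate (or load) -> complete-case selection -> min-max
#' normalization -> restart-controlled k-means with Calinski-Harabasz
#' selection -> composite scores -> per-family group comparisons ->
#' longitudinal progression and ANCOVA, writing every artifact as CSV (or
#' JSON for the model and manifest) under `outdir`. A master seed spawns
#' per-stage sub-seeds so single stages can be reproduced in isolation;
#' the whole run is deterministic for a fixed configuration.
#'
#' @param outdir output directory (created if absent).
#' @param spec a [cohort_spec()]; supplies the variable schema and -- when
#'   `input` is `NULL` -- the simulation parameters.
#' @param input optional named list of CSV paths (`baseline`,
#'   `longitudinal`) to analyse instead of simulating; exactly one of
#'   simulation and `input` is used.
#' @param seed master integer seed.
#' @param k_range,n_restarts,max_iter clustering controls (see
#'   [pd_subtype()]).
#' @param B bootstrap resamples for SMD confidence intervals.
#' @return invisibly, a list with the fitted `model` and every artifact
#'   table, plus the output file paths.
#' @export
run_pipeline <- function(outdir, spec = default_cohort_spec(), input = NULL,
                         seed = 1L, k_range = 2:10, n_restarts = 100L,
                         max_iter = 100L, B = 3000L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(seed, 5L) # baseline, missingness, longitudinal,
                                 # clustering, bootstrap
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(outdir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    df
  }

  if (is.null(input)) {
    cohort <- generate_baseline(spec, seed = seeds[1L])
    baseline <- cohort$data
    if (!is.null(spec$missingness))
      baseline <- inject_missingness(baseline, spec$schema,
                                     spec$missingness, seed = seeds[2L])
    longitudinal <- generate_longitudinal(cohort$labels, spec,
                                          seed = seeds[3L])
    emit(baseline, "baseline")
    emit(cohort$labels, "true_labels")
    emit(longitudinal, "longitudinal")
    true_labels <- cohort$labels
  } else {
    baseline <- read.csv(input$baseline, stringsAsFactors = FALSE)
    longitudinal <- if (!is.null(input$longitudinal))
      read.csv(input$longitudinal, stringsAsFactors = FALSE) else NULL
    true_labels <- NULL
  }

  vars <- intersect(clustering_variables(spec$schema), names(baseline))
  message("pipeline: ", nrow(baseline), " baseline rows")
  model <- pd_subtype(baseline, variables = vars, schema = spec$schema,
                      k_range = k_range, n_restarts = n_restarts,
                      max_iter = max_iter, seed = seeds[4L])
  message("pipeline: ", model$n_complete,
          " complete cases entered the cluster analysis; selected k = ",
          model$k)
  write_pd_model(model, file.path(outdir, "model.json"))
  paths$model <- file.path(outdir, "model.json")

  analytic <- suppressMessages(complete_cases(baseline, vars))
  assignments <- data.frame(patient_id = names(model$assignment),
                            subtype = unname(model$assignment),
                            stringsAsFactors = FALSE)
  emit(assignments, "assignments")
  emit(membership_scatter(analytic, model), "composites")
  emit(model$selection$trace, "selection_trace")

  families <- list(
    clinical = vars,
    imaging = intersect(spec$schema$name[spec$schema$category == "imaging"],
                        names(baseline)),
    csf = intersect(spec$schema$name[spec$schema$category == "csf"],
                    names(baseline)))
  boot_seeds <- spawn_seeds(seeds[5L], length(families))
  comparisons <- list()
  for (i in seq_along(families)) {
    fam <- names(families)[i]
    if (!length(families[[fam]])) next
    comparisons[[fam]] <- emit(
      compare_groups(baseline, assignments,
                     family_policy(fam, families[[fam]]),
                     seed = boot_seeds[i], B = B),
      paste0("compare_", fam))
  }

  progression <- NULL
  if (!is.null(longitudinal)) {
    keep <- exclude_no_followup(longitudinal, assignments$patient_id)
    message("pipeline: ", length(keep$retained_ids),
            " patients entered the longitudinal analysis (",
            keep$n_dropped, " without follow-up data)")
    lrec <- longitudinal[longitudinal$patient_id %in% keep$retained_ids, ]
    rates <- emit(progression_rates(lrec), "progression_rates")
    psum <- emit(progression_summary(rates, assignments),
                 "progression_summary")
    tp <- emit(timeplot_data(lrec, assignments), "timeplot")
    age <- baseline[, c("patient_id", "age_onset")]
    anc <- emit(ancova(lrec, assignments, age), "ancova")
    progression <- list(retained = keep, rates = rates, summary = psum,
                        timeplot = tp, ancova = anc)
  }

  manifest <- list(
    package = "pdsubtype",
    version = as.character(packageVersion("pdsubtype")),
    seed = as.integer(seed),
    n_baseline = nrow(baseline), n_complete = model$n_complete,
    n_longitudinal = if (is.null(progression)) NA_integer_
                     else length(progression$retained$retained_ids),
    selected_k = model$k,
    config_hash = unname(tools::md5sum(file.path(outdir, "model.json"))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  paths$manifest <- file.path(outdir, "manifest.json")

  artifacts <- list(model = model, baseline = baseline,
                    assignments = assignments, true_labels = true_labels,
                    comparisons = comparisons, progression = progression,
                    manifest = manifest, paths = paths, outdir = outdir)
  write_report(artifacts, file.path(outdir, "report.md"))
  invisible(artifacts)
}

#' Write a human-readable analysis summary
#'
#' One markdown file listing subtype sizes, the cluster-number selection
#' trace, centroid profiles on clinical scales, the significant variables
#' of each comparison family, and the progression summary (or a note that
#' the longitudinal stage was not run).
#'
#' @param artifacts the list returned by [run_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(artifacts, path = file.path(artifacts$outdir,
                                                     "report.md")) {
  m <- artifacts$model
  if (is.null(m)) pd_stop("write_report: missing model artifact")
  ln <- c("# PD subtyping run summary", "",
          paste0("- complete cases: ", m$n_complete),
          paste0("- selected k: ", m$k, " (Calinski-Harabasz)"),
          paste0("- subtype sizes: ",
                 paste0(m$labels, " = ", m$sizes, collapse = ", ")),
          "", "## Selection trace", "",
          paste0("    k=", m$selection$trace$k,
                 "  WSS=", signif(m$selection$trace$wss, 6),
                 "  CH=", signif(m$selection$trace$ch, 5)),
          "", "## Centroid profiles (clinical scales)", "")
  cc <- m$centroids_clinical
  ln <- c(ln, paste0("    ", colnames(cc), ": ",
                     apply(round(cc, 3), 2L, function(col)
                       paste0(rownames(cc), "=", col, collapse = "  "))))
  for (fam in names(artifacts$comparisons)) {
    tab <- artifacts$comparisons[[fam]]
    sig <- tab$variable[tab$significant]
    ln <- c(ln, "", paste0("## Family: ", fam,
                           " (alpha = ", signif(tab$alpha[1L], 3), ")"), "",
            if (length(sig)) paste0("- significant: ",
                                    paste(sig, collapse = ", "))
            else "- no significant variables")
  }
  if (is.null(artifacts$progression)) {
    ln <- c(ln, "", "## Progression", "",
            "- longitudinal stage not run (no follow-up records provided)")
  } else {
    ps <- artifacts$progression$summary
    ln <- c(ln, "", "## Progression (mean change per interval)", "",
            paste0("    ", ps$subtype, " ", ps$measure, " ", ps$interval,
                   ": ", round(ps$mean, 3), " (sd ", round(ps$sd, 3),
                   ", n=", ps$n, ")"))
    anc <- artifacts$progression$ancova
    ln <- c(ln, "", "## ANCOVA (score ~ subtype + visit + age at onset)", "",
            paste0("    ", anc$measure, " ", anc$term, ": F = ",
                   round(anc$F, 2), ", p = ", signif(anc$p_value, 3)))
  }
  writeLines(ln, path)
  invisible(path)
}
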