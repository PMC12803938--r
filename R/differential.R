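# Differential flux calling: per-reaction comparison of feasible flux
# ranges between two condition-parameterized models, with subsystem
# roll-ups. A reaction shows "altered flux" when its lower or upper
# feasible bound differs between conditions beyond tolerance.

bound_differs <- function(a, b, abs_tol, rel_tol) {
  abs(a - b) > pmax(abs_tol, rel_tol * pmax(abs(a), abs(b)))
}

#' Compare feasible flux ranges between two conditions
#'
#' A bound pair (a, b) counts as different iff
#' |a - b| > max(abs_tol, rel_tol * max(|a|, |b|)); a reaction is `altered`
#' if either its lower or its upper bound differs. Direction summarizes the
#' signed movement of the bounds from A to B: `decreased` when at least one
#' bound moved down and none moved up, `increased` for the mirror image,
#' `mixed` when bounds moved both ways, `unchanged` otherwise. The rule is
#' antisymmetric: swapping A and B exchanges increased and decreased.
#'
#' @param range_a,range_b `flux_range` objects over the same reaction set.
#' @param abs_tol absolute bound-comparison tolerance (default 1e-6).
#' @param rel_tol relative bound-comparison tolerance (default 1e-4).
#' @param conditions length-2 character vector naming conditions A and B.
#' @return An object of class `flux_diff`: a list with `table` (data.frame
#'   reaction_id, subsystem, min_a, max_a, min_b, max_b, lower_changed,
#'   upper_changed, altered, direction), the tolerances, condition labels,
#'   and the FVA settings of each input range.
#' @export
compare_ranges <- function(range_a, range_b, abs_tol = 1e-6, rel_tol = 1e-4,
                           conditions = c("A", "B")) {
  stopifnot(inherits(range_a, "flux_range"), inherits(range_b, "flux_range"))
  ids_a <- range_a$ranges$reaction_id
  ids_b <- range_b$ranges$reaction_id
  if (!setequal(ids_a, ids_b)) {
    only_a <- setdiff(ids_a, ids_b)
    only_b <- setdiff(ids_b, ids_a)
    stop(sprintf("reaction sets differ between ranges (only in A: %s; only in B: %s)",
                 paste(only_a, collapse = ","), paste(only_b, collapse = ",")),
         call. = FALSE)
  }
  a <- range_a$ranges
  b <- range_b$ranges[match(ids_a, ids_b), ]
  lower_changed <- bound_differs(a$min, b$min, abs_tol, rel_tol)
  upper_changed <- bound_differs(a$max, b$max, abs_tol, rel_tol)
  up <- (upper_changed & b$max > a$max) | (lower_changed & b$min > a$min)
  down <- (upper_changed & b$max < a$max) | (lower_changed & b$min < a$min)
  direction <- rep("unchanged", length(up))
  direction[down & !up] <- "decreased"
  direction[up & !down] <- "increased"
  direction[up & down] <- "mixed"
  structure(list(
    table = data.frame(
      reaction_id = a$reaction_id, subsystem = a$subsystem,
      min_a = a$min, max_a = a$max, min_b = b$min, max_b = b$max,
      lower_changed = lower_changed, upper_changed = upper_changed,
      altered = lower_changed | upper_changed, direction = direction,
      stringsAsFactors = FALSE),
    abs_tol = abs_tol, rel_tol = rel_tol, conditions = conditions,
    settings_a = range_a$settings, settings_b = range_b$settings,
    optimum_a = range_a$optimum, optimum_b = range_b$optimum),
    class = "flux_diff")
}

#' @export
print.flux_diff <- function(x, ...) {
  tab <- x$table
  cat(sprintf("flux_diff: %s vs %s, %d reactions, %d altered (%d decreased, %d increased, %d mixed)\n",
              x$conditions[1], x$conditions[2], nrow(tab), sum(tab$altered),
              sum(tab$direction == "decreased"), sum(tab$direction == "increased"),
              sum(tab$direction == "mixed")))
  cat(sprintf("tolerances: abs %g, rel %g; biomass optima %.6g / %.6g\n",
              x$abs_tol, x$rel_tol, x$optimum_a, x$optimum_b))
  invisible(x)
}

#' @export
as.data.frame.flux_diff <- function(x, ...) x$table

#' @export
summary.flux_diff <- function(object, ...) summarize_subsystems(object)

#' Subsystem-level roll-up of a differential flux report
#'
#' Counts reactions per subsystem by altered status and direction --
#' operationalizing pathway-level statements such as "decreased flux
#' capability of the pentose phosphate pathway" as the count of its
#' reactions called decreased.
#'
#' @param report A `flux_diff` object.
#' @return data.frame with one row per subsystem: `subsystem`,
#'   `n_reactions`, `n_altered`, `n_decreased`, `n_increased`, `n_mixed`,
#'   `fraction_altered`.
#' @export
summarize_subsystems <- function(report) {
  stopifnot(inherits(report, "flux_diff"))
  tab <- report$table
  subs <- sort(unique(tab$subsystem))
  out <- do.call(rbind, lapply(subs, function(s) {
    t <- tab[tab$subsystem == s, ]
    data.frame(subsystem = s, n_reactions = nrow(t), n_altered = sum(t$altered),
               n_decreased = sum(t$direction == "decreased"),
               n_increased = sum(t$direction == "increased"),
               n_mixed = sum(t$direction == "mixed"),
               fraction_altered = sum(t$altered) / nrow(t),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Differential flux analysis between two metabolomics-defined conditions
#'
#' The end-to-end procedure: add artificial exchanges for mapped
#' metabolites, compute a parsimonious reference flux distribution, scale
#' the measured exchanges' bounds per condition by reference flux x
#' abundance ratio, run flux variability analysis on each parameterized
#' model, and call per-reaction altered flux between the two. Deterministic
#' for fixed inputs.
#'
#' @param model base `metabolic_model`.
#' @param ratios `ratio_table` holding both conditions.
#' @param mapping measured-name to model-metabolite mapping data.frame.
#' @param condition_a,condition_b condition labels in `ratios`.
#' @param settings [fva_settings()] used for both models.
#' @param abs_tol,rel_tol bound-comparison tolerances, see
#'   [compare_ranges()].
#' @param zero_reference_policy see [parameterize()].
#' @param shared_optimum if `TRUE`, both FVA runs are constrained by the
#'   base model's biomass optimum instead of each parameterized model's own
#'   (sensitivity switch; default `FALSE`).
#' @return A `flux_diff` object; its `reference`, `model_a` and `model_b`
#'   elements carry the intermediate pFBA reference and parameterized
#'   models.
#' @export
run_differential <- function(model, ratios, mapping, condition_a, condition_b,
                             settings = fva_settings(), abs_tol = 1e-6,
                             rel_tol = 1e-4,
                             zero_reference_policy = "leave",
                             shared_optimum = FALSE) {
  model2 <- ensure_exchanges(model, mapping)
  reference <- pfba(model2)
  model_a <- parameterize(model2, reference, ratios, condition_a, mapping,
                          zero_reference_policy = zero_reference_policy)
  model_b <- parameterize(model2, reference, ratios, condition_b, mapping,
                          zero_reference_policy = zero_reference_policy)
  opt <- if (shared_optimum) fba(model2)$objective_value else NULL
  range_a <- fva(model_a, settings, optimum = opt)
  range_b <- fva(model_b, settings, optimum = opt)
  report <- compare_ranges(range_a, range_b, abs_tol = abs_tol,
                           rel_tol = rel_tol,
                           conditions = c(condition_a, condition_b))
  report$reference <- reference
  report$model_a <- model_a
  report$model_b <- model_b
  report
}

#' Write a differential flux report (TSV + JSON mirror)
#'
#' Emits `report.tsv` (per reaction), `summary.tsv` (per subsystem), and
#' `report.json` (both tables plus the full settings block). Output is
#' deterministic: identical reports yield byte-identical files.
#'
#' @param report A `flux_diff` object.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "flux_diff"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.tsv"),
             summary = file.path(dir, "summary.tsv"),
             json = file.path(dir, "report.json"))
  utils::write.table(report$table, paths[["report"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summarize_subsystems(report), paths[["summary"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    conditions = report$conditions,
    settings = list(
      fraction_of_optimum = report$settings_a$fraction_of_optimum,
      pfba_factor = report$settings_a$pfba_factor,
      loopless = report$settings_a$loopless,
      abs_tol = report$abs_tol, rel_tol = report$rel_tol),
    biomass_optimum = list(a = report$optimum_a, b = report$optimum_b),
    reactions = report$table,
    subsystems = summarize_subsystems(report))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             paths[["json"]])
  invisible(paths)
}
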