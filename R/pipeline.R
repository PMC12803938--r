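# Reproducible end-to-end pipeline: config object, file-based run, and
# provenance. The command-line interface (inst/cli/dfva.R) is a thin layer
# over these functions.

#' Pipeline configuration
#'
#' Collects all inputs and settings of a differential flux run. Defaults
#' mirror the package's standard analysis configuration:
#' fraction_of_optimum 0.9, pfba_factor 1.1, loopless on, timepoints
#' 20 h vs 0 h.
#'
#' @param model path to the metabolic model file.
#' @param abundance,metadata,mapping paths to the abundance table, sample
#'   metadata and metabolite mapping.
#' @param model_format `"auto"`, `"json"` or `"sbml"`.
#' @param condition_a,condition_b condition labels (defaults `"flfl"`,
#'   `"r26"`).
#' @param t_num,t_den ratio timepoints in hours (defaults 20 and 0).
#' @param fraction_of_optimum,pfba_factor,loopless FVA settings, see
#'   [fva_settings()].
#' @param abs_tol,rel_tol bound-comparison tolerances, see
#'   [compare_ranges()].
#' @param zero_reference_policy see [parameterize()].
#' @param shared_optimum see [run_differential()].
#' @param out_dir output directory.
#' @param seed integer seed (used by the simulate subcommand only).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(model, abundance, metadata, mapping,
                            model_format = "auto",
                            condition_a = "flfl", condition_b = "r26",
                            t_num = 20, t_den = 0,
                            fraction_of_optimum = 0.9, pfba_factor = 1.1,
                            loopless = TRUE,
                            abs_tol = 1e-6, rel_tol = 1e-4,
                            zero_reference_policy = "leave",
                            shared_optimum = FALSE,
                            out_dir = ".", seed = 1L) {
  settings <- fva_settings(fraction_of_optimum = fraction_of_optimum,
                           pfba_factor = pfba_factor, loopless = loopless)
  structure(list(model = model, abundance = abundance, metadata = metadata,
                 mapping = mapping, model_format = model_format,
                 condition_a = condition_a, condition_b = condition_b,
                 t_num = t_num, t_den = t_den, settings = settings,
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 zero_reference_policy = zero_reference_policy,
                 shared_optimum = shared_optimum,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognized keys match the arguments of [pipeline_config()]; unknown keys
#' abort. `overrides` (a named list, e.g. from CLI flags) wins over file
#' values.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @param overrides named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the differential flux pipeline from files
#'
#' Reads the model, abundance table and mapping; computes per-condition
#' 20h-vs-0h ratios; runs [run_differential()]; and writes `report.tsv`,
#' `summary.tsv`, `report.json`, `ratios.tsv` and `provenance.json` to the
#' configured output directory. Outputs carry no timestamps, so identical
#' configurations give byte-identical files.
#'
#' @param config A `pipeline_config`.
#' @return The `flux_diff` report, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  model <- stage("read_model", read_model(config$model, config$model_format))
  ab <- stage("read_abundance", read_abundance(config$abundance, config$metadata))
  mapping <- stage("read_mapping", read_mapping(config$mapping))
  ratios <- stage("compute_ratios",
                  compute_ratios(ab, t_num = config$t_num, t_den = config$t_den))
  report <- stage("run_differential", run_differential(
    model, ratios, mapping, config$condition_a, config$condition_b,
    settings = config$settings, abs_tol = config$abs_tol,
    rel_tol = config$rel_tol,
    zero_reference_policy = config$zero_reference_policy,
    shared_optimum = config$shared_optimum))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_report(report, config$out_dir)
  write_ratios(ratios, file.path(config$out_dir, "ratios.tsv"))
  prov <- list(
    tool = "dfva",
    version = as.character(utils::packageVersion("dfva")),
    config = unclass(config)[setdiff(names(unclass(config)), "settings")],
    settings = unclass(config$settings),
    input_md5 = as.list(tools::md5sum(c(model = config$model,
                                        abundance = config$abundance,
                                        metadata = config$metadata,
                                        mapping = config$mapping))))
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(config$out_dir, "provenance.json"))
  invisible(report)
}
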