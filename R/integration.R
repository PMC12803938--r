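# Metabolomics integration: abundance tables, per-condition timepoint
# ratios, artificial exchanges, and condition-specific bound
# parameterization (reference pFBA flux x abundance ratio on the active
# side of each measured metabolite's exchange reaction).

#' Construct a targeted-metabolomics abundance table
#'
#' @param values numeric matrix, metabolites (rows, rownames = measured
#'   names) x samples (columns, colnames = sample ids); nonnegative
#'   instrument units.
#' @param sample_meta data.frame with columns `sample`, `condition`,
#'   `timepoint_h`, `replicate`, one row per column of `values`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, sample_meta) {
  values <- as.matrix(values)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- setdiff(c("sample", "condition", "timepoint_h", "replicate"),
                  names(sample_meta))
  if (length(need)) {
    stop("sample_meta lacks column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(values)) || is.null(rownames(values))) {
    stop("values must carry metabolite rownames and sample colnames",
         call. = FALSE)
  }
  missing_meta <- setdiff(colnames(values), sample_meta$sample)
  if (length(missing_meta)) {
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("abundances must be finite and nonnegative", call. = FALSE)
  }
  grp <- table(sample_meta$condition, sample_meta$timepoint_h)
  if (any(grp[grp > 0] < 1)) stop("empty (condition, timepoint) group", call. = FALSE)
  structure(list(values = values, sample_meta = sample_meta),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d metabolites x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(condition = x$sample_meta$condition,
              timepoint_h = x$sample_meta$timepoint_h))
  invisible(x)
}

#' Read an abundance table and its sample metadata
#'
#' The abundance file's first column holds metabolite names; the remaining
#' columns are samples. The metadata file has columns `sample`,
#' `condition`, `timepoint_h`, `replicate`. Delimiter is taken from the
#' extension (`.csv` = comma, otherwise tab).
#'
#' @param path abundance file.
#' @param meta_path sample-metadata file.
#' @return An `abundance_table`.
#' @export
read_abundance <- function(path, meta_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    sep <- if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
    utils::read.table(p, sep = sep, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  ab <- rd(path)
  if (ncol(ab) < 2) stop(sprintf("abundance table %s has no sample columns", path),
                         call. = FALSE)
  vals <- as.matrix(ab[, -1, drop = FALSE])
  rownames(vals) <- ab[[1]]
  abundance_table(vals, rd(meta_path))
}

#' Write an abundance table and its metadata as TSV
#'
#' @param table An `abundance_table`.
#' @param path abundance output file.
#' @param meta_path metadata output file.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, meta_path) {
  df <- data.frame(metabolite = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-condition metabolite abundance ratios between two timepoints
#'
#' For every condition and metabolite, ratio = mean abundance at `t_num`
#' divided by mean abundance at `t_den` (replicate means). Metabolites whose
#' denominator mean is nonpositive -- or whose ratio would be nonpositive --
#' are dropped with a warning and recorded in the provenance table, keeping
#' all retained ratios strictly positive and finite.
#'
#' @param table An `abundance_table`.
#' @param t_num numerator timepoint in hours (default 20).
#' @param t_den denominator timepoint in hours (default 0).
#' @return An object of class `ratio_table`: a data.frame with columns
#'   `condition`, `metabolite`, `mean_t_den`, `mean_t_num`, `n_t_den`,
#'   `n_t_num`, `ratio`, plus a `dropped` attribute listing removed
#'   (condition, metabolite) pairs.
#' @export
compute_ratios <- function(table, t_num = 20, t_den = 0) {
  stopifnot(inherits(table, "abundance_table"))
  meta <- table$sample_meta
  if (!nrow(meta) || !nrow(table$values)) stop("empty abundance table", call. = FALSE)
  conditions <- unique(meta$condition)
  rows <- list()
  dropped <- list()
  for (cond in conditions) {
    num_s <- meta$sample[meta$condition == cond & meta$timepoint_h == t_num]
    den_s <- meta$sample[meta$condition == cond & meta$timepoint_h == t_den]
    if (!length(num_s) || !length(den_s)) {
      stop(sprintf("condition '%s' lacks timepoint %s h", cond,
                   if (!length(num_s)) t_num else t_den), call. = FALSE)
    }
    m_num <- rowMeans(table$values[, num_s, drop = FALSE])
    m_den <- rowMeans(table$values[, den_s, drop = FALSE])
    for (met in rownames(table$values)) {
      rec <- data.frame(condition = cond, metabolite = met,
                        mean_t_den = m_den[[met]], mean_t_num = m_num[[met]],
                        n_t_den = length(den_s), n_t_num = length(num_s),
                        ratio = NA_real_, stringsAsFactors = FALSE)
      if (m_den[[met]] <= 0 || m_num[[met]] <= 0 ||
          !is.finite(m_num[[met]] / m_den[[met]])) {
        warning(sprintf("dropping metabolite '%s' (condition '%s'): nonpositive mean abundance",
                        met, cond), call. = FALSE)
        dropped[[length(dropped) + 1L]] <- rec
      } else {
        rec$ratio <- m_num[[met]] / m_den[[met]]
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, dropped = if (length(dropped)) do.call(rbind, dropped) else NULL,
            class = c("ratio_table", "data.frame"))
}

ratio_lookup <- function(ratios, condition) {
  stopifnot(inherits(ratios, "ratio_table") || is.data.frame(ratios))
  sel <- ratios$condition == condition
  if (!any(sel)) {
    stop(sprintf("condition '%s' absent from ratio table (has: %s)", condition,
                 paste(unique(ratios$condition), collapse = ", ")), call. = FALSE)
  }
  setNames(ratios$ratio[sel], ratios$metabolite[sel])
}

#' Write a ratio table as TSV
#'
#' @param ratios A `ratio_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ratios <- function(ratios, path) {
  utils::write.table(as.data.frame(ratios), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a measured-metabolite to model-metabolite mapping
#'
#' Tab-separated file with columns `measured_name` and
#' `model_metabolite_id`. Mapping is explicit by design: no fuzzy name
#' matching is attempted, since silent mis-mapping is the dominant failure
#' mode when wiring metabolomics into a model.
#'
#' @param path mapping TSV.
#' @return data.frame with columns `measured_name`, `model_metabolite_id`.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop(sprintf("mapping file not found: %s", path), call. = FALSE)
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- setdiff(c("measured_name", "model_metabolite_id"), names(map))
  if (length(need)) {
    stop(sprintf("mapping %s lacks column(s): %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  map
}

exchange_for_metabolite <- function(model, met) {
  hits <- vapply(model$reactions$id, function(rid) {
    model$reactions$is_exchange[model$reactions$id == rid] &&
      identical(names(model$stoichiometry[[rid]]), met)
  }, TRUE)
  model$reactions$id[hits]
}

#' Ensure every mapped metabolite has an exchange reaction
#'
#' Metabolites measured in the metabolomics but lacking an exchange in the
#' model receive an artificial exchange reaction (id
#' `EX_<metabolite>_synthetic`, bounds +/- `default_bound`, subsystem
#' `"Exchange"`, flagged `is_artificial`), enabling simulated consumption
#' or secretion. Idempotent: existing exchanges (artificial or not) are
#' left alone.
#'
#' @param model A valid `metabolic_model`.
#' @param mapping data.frame as returned by [read_mapping()].
#' @return A `metabolic_model` copy with the required exchanges present.
#' @export
ensure_exchanges <- function(model, mapping) {
  stop_if_invalid(model)
  for (met in unique(mapping$model_metabolite_id)) {
    if (!met %in% model$metabolites$id) {
      stop(sprintf("mapped metabolite '%s' absent from model", met), call. = FALSE)
    }
    if (length(exchange_for_metabolite(model, met))) next
    rid <- sprintf("EX_%s_synthetic", met)
    model$reactions <- rbind(model$reactions, data.frame(
      id = rid, lb = -model$default_bound, ub = model$default_bound,
      subsystem = "Exchange", is_exchange = TRUE, is_artificial = TRUE,
      stringsAsFactors = FALSE))
    model$stoichiometry[[rid]] <- setNames(-1, met)
  }
  model
}

#' Parameterize exchange bounds from reference fluxes and abundance ratios
#'
#' Condition-specific model construction: for each measured metabolite m
#' with exchange reaction e and reference flux v* (from a pFBA reference on
#' the same model), the bound on the active side of e is rescaled to
#' v* x ratio(condition, m) -- the lower bound if v* < 0 (uptake), the
#' upper bound if v* > 0 (secretion); the opposite bound is untouched so
#' the exchange keeps a feasible range rather than a pinned flux.
#' Metabolites with |v*| below the solver tolerance are handled per
#' `zero_reference_policy` and recorded in the returned model's
#' `provenance` field.
#'
#' @param model the model on which `reference` was computed (after
#'   [ensure_exchanges()]).
#' @param reference A `flux_distribution`, normally `pfba(model)`.
#' @param ratios A `ratio_table` from [compute_ratios()], keyed by measured
#'   metabolite name.
#' @param condition condition label to pull ratios for.
#' @param mapping measured-name to model-metabolite mapping data.frame.
#' @param zero_reference_policy what to do when v* = 0: `"leave"` keeps the
#'   bounds (default), `"clamp"` closes the exchange to \[0, 0\],
#'   `"epsilon"` opens a small symmetric window of 1e-6 x default_bound.
#' @param tol flux magnitude below which v* counts as zero.
#' @return A `metabolic_model` with rescaled exchange bounds and a
#'   `provenance` list (`condition`, `zero_reference`, `unmeasured`,
#'   `scaled`).
#' @export
parameterize <- function(model, reference, ratios, condition, mapping,
                         zero_reference_policy = c("leave", "clamp", "epsilon"),
                         tol = 1e-9) {
  zero_reference_policy <- match.arg(zero_reference_policy)
  stopifnot(inherits(reference, "flux_distribution"))
  rl <- ratio_lookup(ratios, condition)
  prov <- list(condition = condition, zero_reference = character(0),
               unmeasured = character(0), scaled = character(0))
  for (i in seq_len(nrow(mapping))) {
    measured <- mapping$measured_name[i]
    met <- mapping$model_metabolite_id[i]
    ex <- exchange_for_metabolite(model, met)
    if (!length(ex)) {
      stop(sprintf("metabolite '%s' has no exchange reaction; run ensure_exchanges() first",
                   met), call. = FALSE)
    }
    ex <- ex[1]
    if (!measured %in% names(rl)) {
      prov$unmeasured <- c(prov$unmeasured, measured)
      next
    }
    ratio <- rl[[measured]]
    vstar <- reference$fluxes[[ex]]
    j <- match(ex, model$reactions$id)
    if (abs(vstar) <= tol) {
      prov$zero_reference <- c(prov$zero_reference, met)
      if (zero_reference_policy == "clamp") {
        model$reactions$lb[j] <- 0
        model$reactions$ub[j] <- 0
      } else if (zero_reference_policy == "epsilon") {
        eps <- 1e-6 * model$default_bound
        model$reactions$lb[j] <- -eps
        model$reactions$ub[j] <- eps
      }
      next
    }
    b <- vstar * ratio
    if (vstar < 0) model$reactions$lb[j] <- b else model$reactions$ub[j] <- b
    if (model$reactions$lb[j] > model$reactions$ub[j]) {
      stop(sprintf("parameterization of '%s' yields lb > ub (%g > %g); opposite bound too tight",
                   ex, model$reactions$lb[j], model$reactions$ub[j]), call. = FALSE)
    }
    prov$scaled <- c(prov$scaled, ex)
  }
  model$provenance <- prov
  model
}
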