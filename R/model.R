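#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` holds an ordered set of metabolites, an ordered set of
#' reactions with signed stoichiometry and finite flux bounds, and a linear
#' biomass objective. Fluxes follow the usual convention
#' (mmol gDW^-1 h^-1 in genome-scale models, dimensionless in toy models);
#' for exchange reactions negative flux is uptake and positive flux is
#' secretion. "Unbounded" reactions carry bounds of magnitude
#' `default_bound`.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `subsystem`,
#'   `is_exchange`, `is_artificial`.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param objective named numeric vector of reaction coefficients (the
#'   biomass objective).
#' @param default_bound positive magnitude standing in for "unbounded".
#' @return An object of class `metabolic_model`.
#' @seealso [validate_model()], [build_toy_model()], [read_model()]
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            objective = numeric(0), default_bound = 1000) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(reactions$is_exchange)) {
    reactions$is_exchange <- vapply(stoichiometry[reactions$id], length, 1L) == 1L |
      startsWith(reactions$id, "EX_")
  }
  if (is.null(reactions$is_artificial)) reactions$is_artificial <- FALSE
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  model <- structure(
    list(metabolites = metabolites,
         reactions = reactions[, c("id", "lb", "ub", "subsystem",
                                   "is_exchange", "is_artificial")],
         stoichiometry = stoichiometry[reactions$id],
         objective = objective,
         default_bound = default_bound),
    class = "metabolic_model")
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions (%d exchanges, %d artificial)\n",
              nrow(x$metabolites), nrow(x$reactions),
              sum(x$reactions$is_exchange), sum(x$reactions$is_artificial)))
  if (length(x$objective)) {
    cat("objective:", paste(sprintf("%g*%s", x$objective, names(x$objective)),
                            collapse = " + "), "\n")
  } else {
    cat("objective: (empty)\n")
  }
  subs <- sort(unique(x$reactions$subsystem))
  cat("subsystems:", paste(subs, collapse = ", "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix S (metabolites x reactions), rownames =
#'   metabolite ids, colnames = reaction ids.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$stoichiometry[[rxns[j]]]
    S[names(st), j] <- unname(st)
  }
  S
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique nonempty ids, resolvable
#' stoichiometry, lb <= ub, exchange reactions touching exactly one
#' metabolite, objective referencing existing reactions. Dead-end
#' metabolites (never produced or never consumed by any reaction, exchanges
#' included) and orphan reactions (empty stoichiometry on a non-exchange)
#' are reported as warnings, not errors.
#'
#' @param model A `metabolic_model`.
#' @return A list of class `model_validation` with character vectors
#'   `errors` and `warnings`; valid iff `errors` is empty.
#' @export
validate_model <- function(model) {
  errors <- character(0)
  warnings <- character(0)
  mets <- model$metabolites
  rxns <- model$reactions
  if (any(!nzchar(mets$id))) errors <- c(errors, "empty metabolite id")
  if (anyDuplicated(mets$id)) {
    errors <- c(errors, sprintf("duplicated metabolite id: %s",
                                paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }
  if (any(!nzchar(mets$compartment))) {
    errors <- c(errors, sprintf("empty compartment for metabolite: %s",
                                paste(mets$id[!nzchar(mets$compartment)], collapse = ", ")))
  }
  if (any(!nzchar(rxns$id))) errors <- c(errors, "empty reaction id")
  if (anyDuplicated(rxns$id)) {
    errors <- c(errors, sprintf("duplicated reaction id: %s",
                                paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  }
  bad_bounds <- rxns$id[rxns$lb > rxns$ub]
  if (length(bad_bounds)) {
    errors <- c(errors, sprintf("lower bound exceeds upper bound in reaction: %s",
                                paste(bad_bounds, collapse = ", ")))
  }
  for (rid in rxns$id) {
    st <- model$stoichiometry[[rid]]
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown)) {
      errors <- c(errors, sprintf("reaction %s references unknown metabolite: %s",
                                  rid, paste(unknown, collapse = ", ")))
    }
    is_ex <- rxns$is_exchange[rxns$id == rid]
    if (!length(st) && !is_ex) {
      warnings <- c(warnings, sprintf("orphan reaction (empty stoichiometry): %s", rid))
    }
    if (is_ex && length(st) != 1L) {
      errors <- c(errors, sprintf(
        "exchange reaction %s must touch exactly one metabolite (touches %d)",
        rid, length(st)))
    }
  }
  missing_obj <- setdiff(names(model$objective), rxns$id)
  if (length(missing_obj)) {
    errors <- c(errors, sprintf("objective references unknown reaction: %s",
                                paste(missing_obj, collapse = ", ")))
  }
  if (!length(model$objective)) {
    warnings <- c(warnings, "empty objective: FBA-type analyses will fail")
  }
  if (!is.numeric(model$default_bound) || model$default_bound <= 0) {
    errors <- c(errors, "default_bound must be a positive number")
  }
  if (!length(errors)) {
    S <- stoich_matrix(model)
    produced <- rowSums(S > 0) > 0 | rowSums(S[, rxns$is_exchange, drop = FALSE] != 0) > 0
    consumed <- rowSums(S < 0) > 0
    dead <- rownames(S)[!(produced & consumed)]
    if (length(dead)) {
      warnings <- c(warnings, sprintf("dead-end metabolite: %s",
                                      paste(dead, collapse = ", ")))
    }
  }
  structure(list(errors = errors, warnings = warnings), class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  cat(sprintf("model validation: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

stop_if_invalid <- function(model) {
  v <- validate_model(model)
  if (length(v$errors)) {
    stop("invalid metabolic model:\n  ", paste(v$errors, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(model)
}

#' Bundled toy central-carbon model
#'
#' A deterministic, hand-analyzable single-compartment network standing in
#' for a genome-scale reconstruction: glucose uptake (bound -10), lumped
#' glycolysis, an oxidative pentose phosphate branch producing a
#' reducing-equivalent pseudo-metabolite (NADPH) and regenerating a
#' glycolytic intermediate through a lumped non-oxidative step, a TCA cycle
#' with anaplerosis, amino-acid exchanges (glutamine, glycine, serine,
#' arginine; uptake bounds -5), a biomass reaction consuming precursors plus
#' NADPH, and one deliberately loop-forming irreversible reaction pair
#' (`ACON_F`/`ACON_B`) whose intermediate is otherwise dead-ended, used to
#' exercise loopless analysis.
#'
#' The biomass optimum is 10, limited jointly by glucose (carbon for
#' pyruvate and NADPH/ribulose-5-phosphate via the oxidative PPP) and
#' glutamine (alpha-ketoglutarate demand).
#'
#' @return A valid `metabolic_model` with 16 metabolites and 20 reactions.
#' @export
build_toy_model <- function() {
  mets <- data.frame(
    id = c("glc", "g6p", "gap", "pyr", "accoa", "oaa", "cit", "icit", "akg",
           "ru5p", "nadph", "co2", "gln", "gly", "ser", "arg"),
    name = c("D-glucose", "glucose 6-phosphate", "glyceraldehyde 3-phosphate",
             "pyruvate", "acetyl-CoA", "oxaloacetate", "citrate", "isocitrate",
             "2-oxoglutarate", "ribulose 5-phosphate", "NADPH", "CO2",
             "L-glutamine", "glycine", "L-serine", "L-arginine"),
    compartment = "c",
    stringsAsFactors = FALSE)
  rx <- function(id, st, lb, ub, subsystem) {
    list(id = id, st = st, lb = lb, ub = ub, subsystem = subsystem)
  }
  defs <- list(
    rx("EX_glc", c(glc = -1), -10, 1000, "Exchange"),
    rx("EX_gln", c(gln = -1), -5, 1000, "Exchange"),
    rx("EX_gly", c(gly = -1), -5, 1000, "Exchange"),
    rx("EX_ser", c(ser = -1), -5, 1000, "Exchange"),
    rx("EX_arg", c(arg = -1), -5, 1000, "Exchange"),
    rx("EX_co2", c(co2 = -1), 0, 1000, "Exchange"),
    rx("HEX1", c(glc = -1, g6p = 1), 0, 1000, "Glycolysis"),
    rx("PGI_PFK", c(g6p = -1, gap = 2), 0, 1000, "Glycolysis"),
    rx("PYK", c(gap = -1, pyr = 1), 0, 1000, "Glycolysis"),
    rx("G6PD", c(g6p = -1, ru5p = 1, nadph = 2, co2 = 1), 0, 1000,
       "Pentose phosphate pathway"),
    rx("TKT", c(ru5p = -1, gap = 1), 0, 1000, "Pentose phosphate pathway"),
    rx("PDH", c(pyr = -1, accoa = 1, co2 = 1), 0, 1000, "TCA cycle"),
    rx("CS", c(accoa = -1, oaa = -1, cit = 1), 0, 1000, "TCA cycle"),
    rx("ICDH", c(cit = -1, akg = 1, co2 = 1), 0, 1000, "TCA cycle"),
    rx("AKGD_MDH", c(akg = -1, oaa = 1, co2 = 1), 0, 1000, "TCA cycle"),
    rx("PC", c(pyr = -1, co2 = -1, oaa = 1), 0, 1000, "TCA cycle"),
    rx("GLS_GDH", c(gln = -1, akg = 1), 0, 1000, "Amino acid metabolism"),
    rx("ACON_F", c(cit = -1, icit = 1), 0, 1000, "TCA cycle"),
    rx("ACON_B", c(icit = -1, cit = 1), 0, 1000, "TCA cycle"),
    rx("BIOMASS", c(pyr = -1, ru5p = -0.5, nadph = -1, akg = -0.5,
                    gly = -0.2, ser = -0.2, arg = -0.1), 0, 1000, "Biomass"))
  rxns <- data.frame(
    id = vapply(defs, `[[`, "", "id"),
    lb = vapply(defs, `[[`, 0, "lb"),
    ub = vapply(defs, `[[`, 0, "ub"),
    subsystem = vapply(defs, `[[`, "", "subsystem"),
    stringsAsFactors = FALSE)
  rxns$is_exchange <- startsWith(rxns$id, "EX_")
  rxns$is_artificial <- FALSE
  st <- lapply(defs, `[[`, "st")
  names(st) <- rxns$id
  metabolic_model(mets, rxns, st, objective = c(BIOMASS = 1), default_bound = 1000)
}

#' Diamond fixture network
#'
#' Minimal network with two alternative routes from A to B: a direct
#' one-step route and a two-step route through C. Used to exercise
#' parsimonious FBA route selection (the short route minimizes total flux:
#' 10 uptake + 10 conversion + 10 export = 30) and total-flux-cap algebra in
#' FVA.
#'
#' @return A valid `metabolic_model` with 3 metabolites and 5 reactions.
#' @export
build_diamond_model <- function() {
  mets <- data.frame(id = c("A", "B", "C"),
                     name = c("A", "B", "C"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_A", "R1", "R2", "R3", "SINK_B"),
    lb = c(0, 0, 0, 0, 0),
    ub = c(10, 1000, 1000, 1000, 1000),
    subsystem = c("Exchange", "Core", "Core", "Core", "Exchange"),
    is_exchange = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    is_artificial = FALSE,
    stringsAsFactors = FALSE)
  st <- list(EX_A = c(A = 1), R1 = c(A = -1, B = 1), R2 = c(A = -1, C = 1),
             R3 = c(C = -1, B = 1), SINK_B = c(B = -1))
  metabolic_model(mets, rxns, st, objective = c(SINK_B = 1), default_bound = 1000)
}
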