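# Synthetic targeted-metabolomics generator.
#
# Emulates the study design the pipeline expects: two genotype conditions,
# two timepoints (0 h and 20 h), 3-4 replicates per group, strictly
# positive abundances with multiplicative log-normal replicate noise, and
# genotype-specific 20h/0h fold changes. Mean-corrected noise:
# eps ~ N(-sigma^2/2, sigma^2) with sigma^2 = log(1 + cv^2), so
# E[exp(eps)] = 1 and the multiplicative coefficient of variation equals
# noise_cv.

#' Measured-metabolite mapping of the bundled toy model
#'
#' @return data.frame mapping measured names (glucose, glutamine, glycine,
#'   serine, arginine) to toy-model metabolite ids.
#' @export
toy_mapping <- function() {
  data.frame(
    measured_name = c("glucose", "glutamine", "glycine", "serine", "arginine"),
    model_metabolite_id = c("glc", "gln", "gly", "ser", "arg"),
    stringsAsFactors = FALSE)
}

#' Define a synthetic metabolomics scenario
#'
#' @param metabolites measured metabolite names; defaults to the toy
#'   model's mapped metabolites.
#' @param conditions two condition labels (default `"flfl"`, `"r26"`).
#' @param n_replicates replicates per (condition, timepoint), >= 2
#'   (default 4).
#' @param baseline_means named positive baseline abundances (instrument
#'   units) at 0 h; a default spanning typical targeted-panel intensities
#'   is supplied for the toy metabolites.
#' @param fold_changes named list per condition of named per-metabolite
#'   true 20h/0h ratios (default all 1).
#' @param noise_cv coefficient of variation of the multiplicative
#'   replicate noise (default 0.2, a typical targeted LC/GC-MS replicate
#'   spread).
#' @param seed integer RNG seed.
#' @return An object of class `flux_scenario`.
#' @export
flux_scenario <- function(metabolites = toy_mapping()$measured_name,
                          conditions = c("flfl", "r26"),
                          n_replicates = 4,
                          baseline_means = NULL,
                          fold_changes = NULL,
                          noise_cv = 0.2,
                          seed = 1L) {
  stopifnot(length(conditions) == 2, n_replicates >= 2, noise_cv >= 0)
  if (is.null(baseline_means)) {
    defaults <- c(glucose = 100, glutamine = 80, glycine = 50,
                  serine = 50, arginine = 30)
    baseline_means <- ifelse(metabolites %in% names(defaults),
                             defaults[metabolites], 50)
    names(baseline_means) <- metabolites
  }
  if (is.null(fold_changes)) {
    fold_changes <- setNames(
      rep(list(setNames(rep(1, length(metabolites)), metabolites)), 2),
      conditions)
  }
  stopifnot(all(metabolites %in% names(baseline_means)),
            all(conditions %in% names(fold_changes)))
  for (cond in conditions) {
    fc <- fold_changes[[cond]]
    stopifnot(all(metabolites %in% names(fc)), all(fc > 0))
  }
  stopifnot(all(baseline_means[metabolites] > 0))
  structure(list(metabolites = metabolites, conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 baseline_means = baseline_means,
                 fold_changes = fold_changes,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "flux_scenario")
}

#' @export
print.flux_scenario <- function(x, ...) {
  cat(sprintf("flux_scenario: %d metabolites, conditions %s, %d replicates, noise CV %g, seed %d\n",
              length(x$metabolites), paste(x$conditions, collapse = "/"),
              x$n_replicates, x$noise_cv, x$seed))
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic abundance table from a scenario
#'
#' Sample abundance = baseline mean x (fold change if the sample is at
#' 20 h, else 1) x exp(eps), with mean-corrected log-normal noise so the
#' expected abundance equals the deterministic part. Fully determined by
#' the scenario's seed.
#'
#' @param scenario A [flux_scenario()].
#' @return An `abundance_table` with samples named
#'   `<condition>_t<timepoint>_r<replicate>`.
#' @export
generate_abundance <- function(scenario) {
  stopifnot(inherits(scenario, "flux_scenario"))
  sigma2 <- log(1 + scenario$noise_cv^2)
  timepoints <- c(0, 20)
  meta <- expand.grid(replicate = seq_len(scenario$n_replicates),
                      timepoint_h = timepoints,
                      condition = scenario$conditions,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("condition", "timepoint_h", "replicate")]
  meta$sample <- sprintf("%s_t%d_r%d", meta$condition, meta$timepoint_h,
                         meta$replicate)
  vals <- with_seed(scenario$seed, {
    m <- matrix(0, length(scenario$metabolites), nrow(meta),
                dimnames = list(scenario$metabolites, meta$sample))
    for (j in seq_len(nrow(meta))) {
      fc <- scenario$fold_changes[[meta$condition[j]]][scenario$metabolites]
      mu <- scenario$baseline_means[scenario$metabolites] *
        (if (meta$timepoint_h[j] == 20) fc else 1)
      eps <- stats::rnorm(length(mu), mean = -sigma2 / 2, sd = sqrt(sigma2))
      m[, j] <- mu * exp(eps)
    }
    m
  })
  abundance_table(vals, meta[, c("sample", "condition", "timepoint_h", "replicate")])
}

# Per-reaction altered/direction ground truth of the toy-model glucose
# knockdown under default analysis settings (fraction_of_optimum 0.9,
# pfba_factor 1.1, loopless). Valid for any knockdown strength in (0, 1)
# whose deviation from 1 exceeds the bound-comparison tolerances: every
# nonzero flux bound scales linearly with the glucose-limited biomass
# optimum, so the altered set does not depend on the strength. Derived by
# exhaustive LP analysis of the toy network with an independent solver;
# the pentose phosphate branch (G6PD) and the glycolysis/biomass axis
# scale with the reduced glucose uptake, while uptake exchange bounds
# (negative fluxes) move up toward zero.
toy_knockdown_truth <- function() {
  data.frame(
    reaction_id = c("EX_glc", "EX_gln", "EX_gly", "EX_ser", "EX_arg",
                    "EX_co2", "HEX1", "PGI_PFK", "PYK", "G6PD", "PDH", "CS",
                    "ICDH", "AKGD_MDH", "PC", "GLS_GDH", "BIOMASS"),
    direction = c("increased", "increased", "increased", "increased",
                  "increased", "decreased", "decreased", "decreased",
                  "decreased", "decreased", "decreased", "decreased",
                  "decreased", "decreased", "decreased", "decreased",
                  "decreased"),
    stringsAsFactors = FALSE)
}

#' Glucose-knockdown scenario with ground truth
#'
#' Returns a scenario over the toy model's measured metabolites in which
#' condition B's 20h/0h fold change for glucose -- the metabolite feeding
#' glycolysis and the pentose phosphate branch -- is multiplied by
#' `strength`, while condition A keeps fold changes of 1. The attached
#' `truth` element lists the reactions whose feasible flux ranges differ
#' between the two parameterized toy models under default analysis
#' settings, with their direction calls (empty when `strength = 1`).
#'
#' @param strength positive multiplier on condition B's glucose fold
#'   change; values below 1 emulate a genotype that fails to sustain
#'   glucose turnover (default 0.5).
#' @param n_replicates,noise_cv,seed passed to [flux_scenario()].
#' @return A `flux_scenario` with an extra `truth` element: a list with
#'   `perturbed_metabolites` and `expected_altered` (data.frame
#'   reaction_id, direction).
#' @export
knockdown_scenario <- function(strength = 0.5, n_replicates = 4,
                               noise_cv = 0.2, seed = 1L) {
  stopifnot(is.numeric(strength), length(strength) == 1, strength > 0)
  mets <- toy_mapping()$measured_name
  fc_a <- setNames(rep(1, length(mets)), mets)
  fc_b <- fc_a
  fc_b[["glucose"]] <- strength
  sc <- flux_scenario(metabolites = mets, n_replicates = n_replicates,
                      fold_changes = list(flfl = fc_a, r26 = fc_b),
                      noise_cv = noise_cv, seed = seed)
  truth <- if (abs(strength - 1) < 1e-12) {
    data.frame(reaction_id = character(0), direction = character(0),
               stringsAsFactors = FALSE)
  } else {
    toy_knockdown_truth()
  }
  sc$truth <- list(perturbed_metabolites = "glucose",
                   expected_altered = truth)
  sc
}

#' Write scenario outputs (abundance, metadata, ground truth)
#'
#' @param scenario A `flux_scenario`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ab <- generate_abundance(scenario)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_abundance(ab, paths[["abundance"]], paths[["metadata"]])
  truth <- scenario$truth
  if (is.null(truth)) {
    truth <- list(perturbed_metabolites = character(0),
                  expected_altered = data.frame(reaction_id = character(0),
                                                direction = character(0)))
  }
  writeLines(jsonlite::toJSON(
    list(perturbed_metabolites = truth$perturbed_metabolites,
         expected_altered_reactions = truth$expected_altered),
    auto_unbox = FALSE, digits = NA, pretty = TRUE), paths[["truth"]])
  invisible(paths)
}
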