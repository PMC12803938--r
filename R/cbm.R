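# Constraint-based analyses: FBA, parsimonious FBA, flux variability
# analysis with biomass-fraction and total-flux constraints, and
# cycle-free (loopless) post-processing.
#
# All absolute-value terms are handled by forward/reverse flux splitting
# (v = p - q, p,q >= 0) with per-variable bounds chosen so the split range
# projects exactly onto [lb, ub]; the split keeps every problem a pure LP.

ZERO_CUTOFF <- 1e-6  # flux magnitudes below this are treated as zero

model_objective_vector <- function(model) {
  cvec <- setNames(numeric(nrow(model$reactions)), model$reactions$id)
  cvec[names(model$objective)] <- model$objective
  unname(cvec)
}

split_bounds <- function(lb, ub) {
  list(p_lb = pmax(lb, 0), p_ub = pmax(ub, 0),
       q_lb = pmax(-ub, 0), q_ub = pmax(-lb, 0))
}

new_flux_distribution <- function(model, v, objective_value) {
  structure(list(fluxes = setNames(v, model$reactions$id),
                 objective_value = objective_value,
                 total_flux = sum(abs(v))),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("flux_distribution: %d reactions, objective = %.6g, total |flux| = %.6g\n",
              length(x$fluxes), x$objective_value, x$total_flux))
  nz <- x$fluxes[abs(x$fluxes) > ZERO_CUTOFF]
  cat(sprintf("nonzero fluxes (%d):\n", length(nz)))
  print(round(nz, 6))
  invisible(x)
}

#' @export
as.data.frame.flux_distribution <- function(x, ...) {
  data.frame(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
             stringsAsFactors = FALSE)
}

lp_failure <- function(status, what) {
  if (status == "infeasible") {
    stop(sprintf("%s: the linear program is infeasible (solver status '%s'); check bounds and steady-state constraints", what, status),
         call. = FALSE)
  }
  stop(sprintf("%s: solver failure (status '%s')", what, status), call. = FALSE)
}

#' Flux balance analysis
#'
#' Maximizes the biomass objective c'v over steady-state flux vectors:
#' max c'v subject to S v = 0 and lb <= v <= ub.
#'
#' @param model A valid `metabolic_model` with a nonempty objective.
#' @return A `flux_distribution` with fields `fluxes` (named vector),
#'   `objective_value`, and `total_flux` (sum of |v|). When alternate
#'   optima exist only `objective_value` is uniquely determined; use
#'   [pfba()] for a canonical representative.
#' @export
fba <- function(model) {
  stop_if_invalid(model)
  if (!length(model$objective)) stop("model has an empty objective", call. = FALSE)
  S <- stoich_matrix(model)
  cvec <- model_objective_vector(model)
  res <- lp_solve(cvec, A_eq = S, b_eq = rep(0, nrow(S)),
                  lb = model$reactions$lb, ub = model$reactions$ub,
                  maximize = TRUE)
  if (res$status != "optimal") lp_failure(res$status, "fba")
  new_flux_distribution(model, res$x, res$objective)
}

# minimum total |flux| subject to c'v >= target; returns split solution
min_total_flux <- function(model, target) {
  S <- stoich_matrix(model)
  n <- ncol(S)
  cvec <- model_objective_vector(model)
  sb <- split_bounds(model$reactions$lb, model$reactions$ub)
  res <- lp_solve(rep(1, 2 * n),
                  A_eq = cbind(S, -S), b_eq = rep(0, nrow(S)),
                  A_le = matrix(c(-cvec, cvec), nrow = 1), b_le = -target,
                  lb = c(sb$p_lb, sb$q_lb), ub = c(sb$p_ub, sb$q_ub))
  if (res$status != "optimal") return(res)
  p <- res$x[seq_len(n)]
  q <- res$x[n + seq_len(n)]
  list(status = "optimal", v = p - q, total = sum(p) + sum(q))
}

#' Parsimonious flux balance analysis
#'
#' Two-stage optimization: (1) compute the FBA optimum z*; (2) minimize the
#' total absolute flux sum |v| (via forward/reverse flux splitting) subject
#' to c'v >= fraction_of_optimum * z*. Returns the stage-2 solution, whose
#' `total_flux` equals the stage-2 objective.
#'
#' @inheritParams fba
#' @param fraction_of_optimum fraction of the FBA optimum the biomass
#'   objective must retain in stage 2, in \[0, 1\] (default 1.0).
#' @return A `flux_distribution`.
#' @export
pfba <- function(model, fraction_of_optimum = 1.0) {
  stopifnot(is.numeric(fraction_of_optimum), length(fraction_of_optimum) == 1,
            fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  z <- fba(model)$objective_value
  res <- min_total_flux(model, fraction_of_optimum * z)
  if (res$status != "optimal") lp_failure(res$status, "pfba")
  cvec <- model_objective_vector(model)
  out <- new_flux_distribution(model, res$v, sum(cvec * res$v))
  out$total_flux <- res$total
  out
}

#' FVA settings
#'
#' Settings object for [fva()]. The defaults are the conventional
#' metabolomics-integration configuration: the biomass objective must stay
#' within 90% of its optimum, total flux may exceed the parsimonious
#' minimum by at most 10%, and loopless (cycle-free) post-processing is on.
#'
#' @param fraction_of_optimum real in (0, 1\]; the biomass constraint
#'   c'v >= fraction_of_optimum * z*.
#' @param pfba_factor real >= 1, or `NULL` to disable the total-flux cap;
#'   when set, sum |v| <= pfba_factor * (minimum total flux at the same
#'   biomass fraction).
#' @param loopless logical; post-process each per-reaction optimum so
#'   reported bounds are attainable without thermodynamically infeasible
#'   internal cycles.
#' @param solver_tolerance positive pivot/feasibility tolerance of the LP
#'   kernel.
#' @return An object of class `fva_settings`.
#' @export
fva_settings <- function(fraction_of_optimum = 0.9, pfba_factor = 1.1,
                         loopless = TRUE, solver_tolerance = 1e-9) {
  stopifnot(is.numeric(fraction_of_optimum), length(fraction_of_optimum) == 1,
            fraction_of_optimum > 0, fraction_of_optimum <= 1)
  if (!is.null(pfba_factor)) {
    stopifnot(is.numeric(pfba_factor), length(pfba_factor) == 1, pfba_factor >= 1)
  }
  stopifnot(is.logical(loopless), length(loopless) == 1)
  stopifnot(is.numeric(solver_tolerance), solver_tolerance > 0)
  structure(list(fraction_of_optimum = fraction_of_optimum,
                 pfba_factor = pfba_factor, loopless = loopless,
                 solver_tolerance = solver_tolerance),
            class = "fva_settings")
}

#' @export
print.fva_settings <- function(x, ...) {
  cat(sprintf("fva_settings: fraction_of_optimum = %g, pfba_factor = %s, loopless = %s\n",
              x$fraction_of_optimum,
              if (is.null(x$pfba_factor)) "none" else format(x$pfba_factor),
              x$loopless))
  invisible(x)
}

# Cycle-free L1 minimization (CycleFreeFlux): exchange fluxes fixed at the
# reference, internal fluxes restricted to the reference sign and magnitude,
# minimize the internal L1 norm. Optional extra rows keep the biomass
# fraction / total-flux cap of an enclosing FVA active; `pin` fixes one
# reaction at its reference flux; `A_eq_extra` can impose objective equality.
cycle_free_min <- function(model, v_ref, frac = NULL, cap = NULL, pin = NULL,
                           objective_equal = FALSE) {
  S <- stoich_matrix(model)
  n <- ncol(S)
  rxns <- model$reactions
  sgn <- ifelse(v_ref >= 0, 1, -1)
  lo <- ifelse(rxns$is_exchange, v_ref,
               ifelse(v_ref >= 0, pmax(0, rxns$lb), pmax(v_ref, rxns$lb)))
  hi <- ifelse(rxns$is_exchange, v_ref,
               ifelse(v_ref >= 0, pmin(v_ref, rxns$ub), pmin(0, rxns$ub)))
  if (!is.null(pin)) {
    j <- match(pin, rxns$id)
    lo[j] <- v_ref[j]
    hi[j] <- v_ref[j]
  }
  obj <- ifelse(rxns$is_exchange, 0, sgn)
  A_eq <- S
  b_eq <- rep(0, nrow(S))
  cvec <- model_objective_vector(model)
  if (objective_equal && length(model$objective)) {
    A_eq <- rbind(A_eq, cvec)
    b_eq <- c(b_eq, sum(cvec * v_ref))
  }
  A_le <- NULL
  b_le <- NULL
  if (!is.null(frac)) {
    A_le <- rbind(A_le, -cvec)
    b_le <- c(b_le, -frac)
  }
  if (!is.null(cap)) {
    A_le <- rbind(A_le, sgn)
    b_le <- c(b_le, cap)
  }
  res <- lp_solve(obj, A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le,
                  lb = lo, ub = hi, maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x
}

#' Remove thermodynamically infeasible cycles from a flux distribution
#'
#' Cycle-free post-processing: returns a flux distribution with identical
#' exchange fluxes and identical objective value, in which every internal
#' flux keeps the sign of (or drops to zero from) the input flux and the
#' total internal absolute flux is minimal. Any circulation in the
#' nullspace of S restricted to internal reactions is thereby stripped.
#'
#' @param model A valid `metabolic_model`.
#' @param solution A `flux_distribution` feasible for `model`.
#' @param pinned_reaction optional reaction id whose flux must stay at its
#'   input value (used when scoring that reaction's variability).
#' @return A `flux_distribution` without internal-cycle components.
#' @export
remove_loops <- function(model, solution, pinned_reaction = NULL) {
  stopifnot(inherits(solution, "flux_distribution"))
  v <- unname(solution$fluxes[model$reactions$id])
  if (!is.null(pinned_reaction) && !pinned_reaction %in% model$reactions$id) {
    stop(sprintf("unknown pinned_reaction '%s'", pinned_reaction), call. = FALSE)
  }
  out <- cycle_free_min(model, v, pin = pinned_reaction, objective_equal = TRUE)
  if (is.null(out)) {
    stop("loop removal subproblem infeasible; the input solution is inconsistent with the model",
         call. = FALSE)
  }
  cvec <- model_objective_vector(model)
  new_flux_distribution(model, out, sum(cvec * out))
}

#' Flux variability analysis
#'
#' For each reaction r, computes the minimum and maximum of v_r subject to
#' S v = 0, the flux bounds, the biomass constraint
#' c'v >= fraction_of_optimum * z*, and (when `pfba_factor` is set) the
#' total-flux cap sum |v| <= pfba_factor * (minimum total flux at that
#' biomass fraction). With `loopless = TRUE` each per-reaction optimum is
#' post-processed cycle-free: if the optimum is only attainable through an
#' internal cycle, the cycle's loop-partner reactions are closed and the
#' subproblem re-optimized, so reported bounds are loop-free feasible.
#'
#' @param model A valid, feasible `metabolic_model`.
#' @param settings An [fva_settings()] object.
#' @param optimum optional externally supplied biomass optimum z* (e.g. a
#'   base model's optimum for shared-optimum comparisons); default is the
#'   model's own FBA optimum.
#' @param reactions optional character vector restricting the analysis to a
#'   subset of reaction ids.
#' @return An object of class `flux_range`: a list with `ranges` (data.frame
#'   reaction_id, subsystem, min, max), `settings`, and `optimum`.
#' @export
fva <- function(model, settings = fva_settings(), optimum = NULL,
                reactions = NULL) {
  stopifnot(inherits(settings, "fva_settings"))
  stop_if_invalid(model)
  rxns <- model$reactions
  if (is.null(reactions)) reactions <- rxns$id
  missing_r <- setdiff(reactions, rxns$id)
  if (length(missing_r)) {
    stop(sprintf("unknown reaction(s): %s", paste(missing_r, collapse = ", ")),
         call. = FALSE)
  }
  z <- if (is.null(optimum)) fba(model)$objective_value else optimum
  thr <- settings$fraction_of_optimum * z
  cap <- NULL
  if (!is.null(settings$pfba_factor)) {
    mt <- min_total_flux(model, thr)
    if (mt$status != "optimal") lp_failure(mt$status, "fva (total-flux minimum)")
    cap <- settings$pfba_factor * mt$total
  }

  S <- stoich_matrix(model)
  n <- ncol(S)
  cvec <- model_objective_vector(model)
  sb <- split_bounds(rxns$lb, rxns$ub)
  make_lp <- function(lb_v, ub_v) {
    sbx <- split_bounds(lb_v, ub_v)
    A_le <- matrix(c(-cvec, cvec), nrow = 1)
    b_le <- -thr
    if (!is.null(cap)) {
      A_le <- rbind(A_le, rep(1, 2 * n))
      b_le <- c(b_le, cap)
    }
    list(A_eq = cbind(S, -S), b_eq = rep(0, nrow(S)),
         A_le = A_le, b_le = b_le,
         lb = c(sbx$p_lb, sbx$q_lb), ub = c(sbx$p_ub, sbx$q_ub))
  }
  base_lp <- make_lp(rxns$lb, rxns$ub)
  solve_dir <- function(lp, j, maximize) {
    obj <- numeric(2 * n)
    obj[j] <- 1
    obj[n + j] <- -1
    res <- lp_solve(obj, A_eq = lp$A_eq, b_eq = lp$b_eq,
                    A_le = lp$A_le, b_le = lp$b_le,
                    lb = lp$lb, ub = lp$ub, maximize = maximize,
                    tol = settings$solver_tolerance)
    if (res$status != "optimal") {
      lp_failure(res$status, sprintf("fva subproblem for reaction '%s'", rxns$id[j]))
    }
    list(value = res$objective, v = res$x[seq_len(n)] - res$x[n + seq_len(n)])
  }

  score <- function(j, maximize) {
    opt <- solve_dir(base_lp, j, maximize)
    if (!settings$loopless || rxns$is_exchange[j]) return(opt$value)
    cur <- opt$value
    cf1 <- cycle_free_min(model, opt$v, frac = thr, cap = cap)
    if (is.null(cf1)) return(cur)            # defensive: accept the LP optimum
    if (abs(cf1[j] - cur) < ZERO_CUTOFF) return(cur)
    cf2 <- cycle_free_min(model, opt$v, frac = thr, cap = cap, pin = rxns$id[j])
    if (is.null(cf2)) return(cf1[j])
    partners <- which(abs(cf1) < ZERO_CUTOFF & abs(cf2) > ZERO_CUTOFF)
    lb2 <- rxns$lb
    ub2 <- rxns$ub
    for (k in partners) {
      lo <- max(0, lb2[k]); hi <- min(0, ub2[k])
      if (lo <= hi) { lb2[k] <- lo; ub2[k] <- hi }
    }
    solve_dir(make_lp(lb2, ub2), j, maximize)$value
  }

  idx <- match(reactions, rxns$id)
  mn <- vapply(idx, score, 0, maximize = FALSE)
  mx <- vapply(idx, score, 0, maximize = TRUE)
  # clamp solver jitter: enforce min <= max when the violation is numerical
  flip <- mn > mx & (mn - mx) < 1e-9
  if (any(flip)) {
    mid <- (mn[flip] + mx[flip]) / 2
    mn[flip] <- mid
    mx[flip] <- mid
  }
  structure(list(
    ranges = data.frame(reaction_id = rxns$id[idx],
                        subsystem = rxns$subsystem[idx],
                        min = mn, max = mx, stringsAsFactors = FALSE),
    settings = settings, optimum = z),
    class = "flux_range")
}

#' @export
print.flux_range <- function(x, ...) {
  cat(sprintf("flux_range: %d reactions (biomass optimum %.6g)\n",
              nrow(x$ranges), x$optimum))
  print(x$settings)
  df <- x$ranges
  df$min <- round(df$min, 6)
  df$max <- round(df$max, 6)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.flux_range <- function(x, ...) x$ranges

#' Write a flux distribution or flux range as TSV
#'
#' @param x A `flux_distribution` or `flux_range`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
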