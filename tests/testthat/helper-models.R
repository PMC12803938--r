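# Small fixture networks built in code.

# linear chain: uptake (ub 10) -> A -> B -> export (objective)
build_chain_model <- function() {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("UP", "CONV", "OUT"),
                     lb = 0, ub = c(10, 1000, 1000),
                     subsystem = "Core",
                     is_exchange = c(TRUE, FALSE, TRUE),
                     is_artificial = FALSE, stringsAsFactors = FALSE)
  st <- list(UP = c(A = 1), CONV = c(A = -1, B = 1), OUT = c(B = -1))
  metabolic_model(mets, rxns, st, objective = c(OUT = 1))
}

zero_bound_model <- function() {
  m <- build_chain_model()
  m$reactions$lb[] <- 0
  m$reactions$ub[] <- 0
  m
}

range_lookup <- function(fr, what = c("min", "max")) {
  what <- match.arg(what)
  setNames(fr$ranges[[what]], fr$ranges$reaction_id)
}
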