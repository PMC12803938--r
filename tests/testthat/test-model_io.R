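# Model structures, validation, and JSON/SBML input-output.

test_that("bundled toy model is valid, deterministic, and fully labelled", {
  m <- build_toy_model()
  v <- validate_model(m)
  expect_length(v$errors, 0)
  expect_identical(m, build_toy_model())
  expect_true(all(nzchar(m$reactions$subsystem)))
  expect_setequal(unique(m$reactions$subsystem),
                  c("Exchange", "Glycolysis", "Pentose phosphate pathway",
                    "TCA cycle", "Amino acid metabolism", "Biomass"))
})

test_that("bundled toy JSON fixture re-reads with the authored dimensions", {
  path <- system.file("extdata", "toy_model.json", package = "dfva")
  m <- read_model(path, "json")
  expect_equal(nrow(m$metabolites), 16)
  expect_equal(nrow(m$reactions), 20)
  expect_identical(m, build_toy_model())
})

test_that("stoichiometric matrix has model shape and reaction-wise sparsity", {
  m <- build_toy_model()
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  nnz <- colSums(S != 0)
  expect_equal(unname(nnz),
               unname(vapply(m$stoichiometry, length, 1L)))
})

test_that("validation flags broken invariants and degenerate structure", {
  m <- build_toy_model()

  bad <- m
  bad$stoichiometry$HEX1 <- c(glc = -1, nonexistent = 1)
  v <- validate_model(bad)
  expect_match(v$errors, "unknown metabolite", all = FALSE)
  expect_match(v$errors, "HEX1", all = FALSE)

  bad <- m
  bad$reactions$lb[bad$reactions$id == "PYK"] <- 5
  bad$reactions$ub[bad$reactions$id == "PYK"] <- -5
  expect_match(validate_model(bad)$errors, "PYK", all = FALSE)

  # metabolite produced but never consumed -> dead-end warning
  dead <- m
  dead$metabolites <- rbind(dead$metabolites,
                            data.frame(id = "junk", name = "junk",
                                       compartment = "c"))
  dead$reactions <- rbind(dead$reactions, data.frame(
    id = "MAKE_JUNK", lb = 0, ub = 10, subsystem = "Core",
    is_exchange = FALSE, is_artificial = FALSE))
  dead$stoichiometry$MAKE_JUNK <- c(pyr = -1, junk = 1)
  v <- validate_model(dead)
  expect_length(v$errors, 0)
  expect_match(v$warnings, "dead-end.*junk", all = FALSE)

  noobj <- m
  noobj$objective <- numeric(0)
  expect_match(validate_model(noobj)$warnings, "empty objective", all = FALSE)
})

test_that("reading a model with lb > ub fails naming the reaction", {
  m <- build_toy_model()
  m$reactions$lb[m$reactions$id == "CS"] <- 7
  m$reactions$ub[m$reactions$id == "CS"] <- 2
  p <- tempfile(fileext = ".json")
  write_model(m, p, "json")
  expect_error(read_model(p, "json"), "CS")
  p2 <- tempfile(fileext = ".xml")
  write_model(m, p2, "sbml")
  expect_error(read_model(p2, "sbml"), "CS")
})

test_that("JSON round trip is byte-identical and numerically exact", {
  m <- build_toy_model()
  # awkward doubles must survive exactly
  m$reactions$ub[m$reactions$id == "PDH"] <- 1 / 3
  m$reactions$lb[m$reactions$id == "EX_gln"] <- -1e-7
  m$stoichiometry$BIOMASS[["nadph"]] <- -0.123456789012345
  p1 <- tempfile(fileext = ".json")
  write_model(m, p1, "json")
  m2 <- read_model(p1, "json")
  expect_identical(m$reactions$ub, m2$reactions$ub)
  expect_identical(m$reactions$lb, m2$reactions$lb)
  expect_identical(m$stoichiometry, m2$stoichiometry)
  p2 <- tempfile(fileext = ".json")
  write_model(m2, p2, "json")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("artificial-exchange flag survives the JSON dialect", {
  m <- ensure_exchanges(build_toy_model(),
                        data.frame(measured_name = "pyruvate",
                                   model_metabolite_id = "pyr"))
  p <- tempfile(fileext = ".json")
  write_model(m, p, "json")
  m2 <- read_model(p, "json")
  expect_true(m2$reactions$is_artificial[m2$reactions$id == "EX_pyr_synthetic"])
})

test_that("SBML round trip preserves the model within float tolerance", {
  m <- build_toy_model()
  m$reactions$ub[m$reactions$id == "PDH"] <- 1 / 3
  p <- tempfile(fileext = ".xml")
  write_model(m, p, "sbml")
  m2 <- read_model(p, "sbml")
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_identical(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$reactions$lb, m$reactions$lb, tolerance = 1e-12)
  expect_equal(m2$reactions$ub, m$reactions$ub, tolerance = 1e-12)
  expect_identical(m2$reactions$subsystem, m$reactions$subsystem)
  expect_identical(m2$objective, m$objective)
  for (rid in m$reactions$id) {
    a <- m$stoichiometry[[rid]]
    b <- m2$stoichiometry[[rid]]
    expect_equal(b[names(a)], a, tolerance = 1e-12)
  }
})

test_that("unsupported SBML constructs are ignored with a warning", {
  p <- tempfile(fileext = ".xml")
  write_model(build_toy_model(), p, "sbml")
  txt <- readLines(p)
  i <- grep("<listOfCompartments>", txt)[1]
  txt <- append(txt, "    <listOfRules></listOfRules>", after = i - 1)
  writeLines(txt, p)
  expect_warning(read_model(p, "sbml"), "listOfRules")
})

test_that("empty-objective model writes, and read-back warns", {
  m <- build_toy_model()
  m$objective <- numeric(0)
  p <- tempfile(fileext = ".json")
  write_model(m, p, "json")
  expect_warning(m2 <- read_model(p, "json"), "empty objective")
  expect_length(m2$objective, 0)
})

test_that("exchange detection uses single-metabolite topology and EX_ prefix", {
  mets <- data.frame(id = c("x", "y"), name = c("x", "y"), compartment = "c")
  rxns <- data.frame(id = c("EX_x", "DRAIN", "CONV"),
                     lb = c(-5, 0, 0), ub = c(5, 5, 5), subsystem = "s")
  st <- list(EX_x = c(x = -1), DRAIN = c(y = -1), CONV = c(x = -1, y = 1))
  m <- metabolic_model(mets, rxns, st, objective = c(DRAIN = 1))
  expect_true(all(m$reactions$is_exchange[m$reactions$id %in% c("EX_x", "DRAIN")]))
  expect_false(m$reactions$is_exchange[m$reactions$id == "CONV"])
})
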