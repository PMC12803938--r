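# Abundance tables, ratios, artificial exchanges, parameterization.

make_table <- function(values0, values20, conditions = "flfl") {
  mets <- rownames(values0)
  vals <- NULL
  meta <- NULL
  for (cond in conditions) {
    for (tp in c(0, 20)) {
      v <- if (tp == 0) values0 else values20
      cn <- sprintf("%s_t%d_r%d", cond, tp, seq_len(ncol(v)))
      colnames(v) <- cn
      vals <- cbind(vals, v)
      meta <- rbind(meta, data.frame(sample = cn, condition = cond,
                                     timepoint_h = tp,
                                     replicate = seq_len(ncol(v))))
    }
  }
  abundance_table(vals, meta)
}

test_that("ratios are ratios of replicate means per condition", {
  v0 <- matrix(2, 1, 3, dimnames = list("m", NULL))
  v20 <- matrix(4, 1, 3, dimnames = list("m", NULL))
  rt <- compute_ratios(make_table(v0, v20))
  expect_equal(rt$ratio, 2.0)
  expect_equal(rt$n_t_den, 3)
  # identical distributions -> ratio 1
  rt <- compute_ratios(make_table(v0, v0))
  expect_equal(rt$ratio, 1.0)
})

test_that("nonpositive denominator means drop the metabolite with a warning", {
  v0 <- matrix(c(0, 5), 2, 3, dimnames = list(c("a", "b"), NULL))
  v20 <- matrix(c(4, 10), 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_warning(rt <- compute_ratios(make_table(v0, v20)), "'a'")
  expect_identical(rt$metabolite, "b")
  expect_equal(rt$ratio, 2.0)
  expect_identical(attr(rt, "dropped")$metabolite, "a")
})

test_that("ratios are invariant to sample ordering", {
  sc <- knockdown_scenario(0.5, noise_cv = 0.2, seed = 11)
  ab <- generate_abundance(sc)
  perm <- sample(ncol(ab$values))
  ab2 <- abundance_table(ab$values[, perm], ab$sample_meta[perm, ])
  r1 <- compute_ratios(ab)
  r2 <- compute_ratios(ab2)
  key <- paste(r1$condition, r1$metabolite)
  expect_equal(r2$ratio[match(key, paste(r2$condition, r2$metabolite))],
               r1$ratio)
})

test_that("missing timepoints and empty tables are errors", {
  v0 <- matrix(2, 1, 3, dimnames = list("m", NULL))
  ab <- make_table(v0, v0)
  keep <- ab$sample_meta$timepoint_h == 0
  ab0 <- abundance_table(ab$values[, keep, drop = FALSE], ab$sample_meta[keep, ])
  expect_error(compute_ratios(ab0), "lacks timepoint")
})

test_that("abundance files round-trip through TSV", {
  ab <- generate_abundance(knockdown_scenario(0.5, seed = 3))
  p <- tempfile(fileext = ".tsv")
  pm <- tempfile(fileext = ".tsv")
  write_abundance(ab, p, pm)
  ab2 <- read_abundance(p, pm)
  expect_equal(ab2$values, ab$values, tolerance = 1e-12)
  expect_identical(ab2$sample_meta$condition, ab$sample_meta$condition)
})

test_that("ensure_exchanges adds flagged exchanges exactly once", {
  m <- build_toy_model()
  map <- rbind(toy_mapping(),
               data.frame(measured_name = "pyruvate", model_metabolite_id = "pyr"))
  m2 <- ensure_exchanges(m, map)
  # existing exchanges untouched, one synthetic exchange appended
  expect_equal(nrow(m2$reactions), nrow(m$reactions) + 1)
  new <- m2$reactions[m2$reactions$id == "EX_pyr_synthetic", ]
  expect_true(new$is_artificial && new$is_exchange)
  expect_equal(c(new$lb, new$ub), c(-1000, 1000))
  expect_identical(new$subsystem, "Exchange")
  expect_length(validate_model(m2)$errors, 0)
  # idempotent
  m3 <- ensure_exchanges(m2, map)
  expect_identical(m3$reactions$id, m2$reactions$id)
  # unknown metabolite is an error naming it
  expect_error(ensure_exchanges(m, data.frame(measured_name = "x",
                                              model_metabolite_id = "nope")),
               "nope")
})

test_that("parameterize rescales the active-side bound by the ratio", {
  m <- build_toy_model()
  ref <- pfba(m)  # EX_gln reference flux -5
  rt <- data.frame(condition = "c1",
                   metabolite = c("glucose", "glutamine", "glycine",
                                  "serine", "arginine"),
                   ratio = c(1, 2, 1, 1, 1))
  class(rt) <- c("ratio_table", "data.frame")
  m2 <- parameterize(m, ref, rt, "c1", toy_mapping())
  expect_equal(m2$reactions$lb[m2$reactions$id == "EX_gln"], -10)
  expect_equal(m2$reactions$ub[m2$reactions$id == "EX_gln"], 1000)  # untouched
  rt$ratio[rt$metabolite == "glutamine"] <- 0.5
  m3 <- parameterize(m, ref, rt, "c1", toy_mapping())
  expect_equal(m3$reactions$lb[m3$reactions$id == "EX_gln"], -2.5)
  expect_error(parameterize(m, ref, rt, "no_such_condition", toy_mapping()),
               "no_such_condition")
})

test_that("zero-reference exchanges follow the configured policy", {
  m <- build_toy_model()
  # isocitrate import buys nothing under parsimony, so its artificial
  # exchange carries zero reference flux
  map <- rbind(toy_mapping(),
               data.frame(measured_name = "isocitrate", model_metabolite_id = "icit"))
  m2 <- ensure_exchanges(m, map)
  ref <- pfba(m2)
  expect_equal(unname(ref$fluxes[["EX_icit_synthetic"]]), 0, tolerance = 1e-9)
  rt <- data.frame(condition = "c1", metabolite = map$measured_name, ratio = 3)
  class(rt) <- c("ratio_table", "data.frame")

  leave <- parameterize(m2, ref, rt, "c1", map)
  j <- leave$reactions$id == "EX_icit_synthetic"
  expect_equal(c(leave$reactions$lb[j], leave$reactions$ub[j]), c(-1000, 1000))
  expect_identical(leave$provenance$zero_reference, "icit")

  clamp <- parameterize(m2, ref, rt, "c1", map, zero_reference_policy = "clamp")
  expect_equal(c(clamp$reactions$lb[j], clamp$reactions$ub[j]), c(0, 0))

  eps <- parameterize(m2, ref, rt, "c1", map, zero_reference_policy = "epsilon")
  expect_equal(c(eps$reactions$lb[j], eps$reactions$ub[j]), c(-1e-3, 1e-3))
})

test_that("parameterization preserves exchange directionality", {
  m <- build_toy_model()
  ref <- pfba(m)
  for (r in c(0.25, 0.5, 1, 2, 4)) {
    rt <- data.frame(condition = "c1", metabolite = toy_mapping()$measured_name,
                     ratio = r)
    class(rt) <- c("ratio_table", "data.frame")
    m2 <- parameterize(m, ref, rt, "c1", toy_mapping())
    # uptake-capable stays uptake-capable, secretion side untouched
    ex <- m2$reactions[m2$reactions$is_exchange, ]
    base <- m$reactions[m$reactions$is_exchange, ]
    expect_true(all(sign(pmin(ex$lb, 0)) == sign(pmin(base$lb, 0))))
    expect_identical(ex$ub, base$ub)
    expect_length(validate_model(m2)$errors, 0)
  }
})

test_that("unit ratios leave all FVA ranges unchanged", {
  m <- build_toy_model()
  rt <- data.frame(condition = rep(c("a", "b"), each = 5),
                   metabolite = rep(toy_mapping()$measured_name, 2),
                   ratio = 1)
  class(rt) <- c("ratio_table", "data.frame")
  rep <- run_differential(m, rt, toy_mapping(), "a", "b")
  expect_equal(sum(rep$table$altered), 0)
  expect_true(all(rep$table$direction == "unchanged"))
})
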