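# Independent reference oracle: COBRApy (GLPK backend) run through the
# python interpreter on models serialized in the package JSON dialect.
# Used only to cross-check the R implementation on tiny fixtures.

cobra_oracle <- function(model, task) {
  mj <- tempfile(fileext = ".json")
  write_model(model, mj, "json")
  tj <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(task, auto_unbox = TRUE, null = "null"), tj)
  out <- tempfile(fileext = ".json")
  status <- suppressWarnings(
    system2("python", c(testthat::test_path("cobra_oracle.py"), mj, tj, out),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L)) {
    stop("cobra oracle invocation failed with status ", status)
  }
  jsonlite::fromJSON(out)
}
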