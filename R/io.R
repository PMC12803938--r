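# Model input/output.
#
# The canonical interchange format is a small JSON dialect:
#   {metabolites:[{id,name,compartment}],
#    reactions:[{id,stoichiometry:{met:coef},lb,ub,subsystem,
#                is_exchange,is_artificial}],
#    objective:{rxn:coef}, default_bound}
# Writing is canonical (fixed key order, full-precision numbers), so
# write -> read -> write is byte-identical. SBML support is a read/write
# subset of Level 3 + FBC v2: species, reactions, flux-bound parameters and
# one active objective; anything else is ignored with a warning.

fmt_num <- function(x) {
  # shortest decimal representation that round-trips the double exactly
  s <- sprintf("%.15g", x)
  if (as.numeric(s) != x) s <- sprintf("%.17g", x)
  s
}

json_escape <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub("\"", "\\\\\"", s)
  s <- gsub("\n", "\\\\n", s)
  s
}

model_to_json <- function(model) {
  met_lines <- apply(model$metabolites, 1, function(m) {
    sprintf('    {"id": "%s", "name": "%s", "compartment": "%s"}',
            json_escape(m[["id"]]), json_escape(m[["name"]]),
            json_escape(m[["compartment"]]))
  })
  rxn_lines <- vapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    st_body <- if (length(st)) {
      paste(sprintf('"%s": %s', json_escape(names(st)),
                    vapply(unname(st), fmt_num, "")), collapse = ", ")
    } else ""
    sprintf(paste0('    {"id": "%s", "stoichiometry": {%s}, "lb": %s, "ub": %s, ',
                   '"subsystem": "%s", "is_exchange": %s, "is_artificial": %s}'),
            json_escape(r$id), st_body, fmt_num(r$lb), fmt_num(r$ub),
            json_escape(r$subsystem),
            if (r$is_exchange) "true" else "false",
            if (r$is_artificial) "true" else "false")
  }, "")
  obj_body <- if (length(model$objective)) {
    paste(sprintf('"%s": %s', json_escape(names(model$objective)),
                  vapply(unname(model$objective), fmt_num, "")), collapse = ", ")
  } else ""
  paste0(
    "{\n",
    '  "metabolites": [\n', paste(met_lines, collapse = ",\n"), "\n  ],\n",
    '  "reactions": [\n', paste(rxn_lines, collapse = ",\n"), "\n  ],\n",
    '  "objective": {', obj_body, "},\n",
    '  "default_bound": ', fmt_num(model$default_bound), "\n",
    "}\n")
}

model_from_json <- function(txt, path = "<json>") {
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("JSON parse failure in %s: %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  need <- setdiff(c("metabolites", "reactions"), names(doc))
  if (length(need)) {
    stop(sprintf("JSON model %s lacks element(s): %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = if (is.null(m$name)) m$id else m$name,
               compartment = m$compartment, stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    for (f in c("id", "lb", "ub")) {
      if (is.null(r[[f]])) {
        stop(sprintf("JSON model %s: reaction record lacks field '%s'", path, f),
             call. = FALSE)
      }
    }
    data.frame(id = r$id, lb = as.numeric(r$lb), ub = as.numeric(r$ub),
               subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
               is_exchange = isTRUE(r$is_exchange) ||
                 (is.null(r$is_exchange) && NA),
               is_artificial = isTRUE(r$is_artificial),
               stringsAsFactors = FALSE)
  }))
  st <- lapply(doc$reactions, function(r) {
    s <- r$stoichiometry
    if (is.null(s) || !length(s)) return(setNames(numeric(0), character(0)))
    setNames(vapply(s, as.numeric, 0), names(s))
  })
  names(st) <- rxns$id
  if (anyNA(rxns$is_exchange)) {
    miss <- is.na(rxns$is_exchange)
    rxns$is_exchange[miss] <- vapply(st[miss], length, 1L) == 1L |
      startsWith(rxns$id[miss], "EX_")
  }
  objective <- if (length(doc$objective)) {
    setNames(vapply(doc$objective, as.numeric, 0), names(doc$objective))
  } else numeric(0)
  default_bound <- if (is.null(doc$default_bound)) 1000 else as.numeric(doc$default_bound)
  metabolic_model(mets, rxns, st, objective = objective,
                  default_bound = default_bound)
}

#' Read a metabolic model
#'
#' @param path file path.
#' @param format `"json"` (the package dialect) or `"sbml"` (Level 3 + FBC
#'   v2 subset: species, reactions, flux-bound parameters, one active
#'   objective). Defaults to the file extension.
#' @return A validated `metabolic_model`. Validation errors abort; validation
#'   warnings (e.g. an empty objective) are emitted as R warnings.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  model <- if (format == "json") {
    model_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"), path)
  } else {
    model_from_sbml(path)
  }
  v <- validate_model(model)
  if (length(v$errors)) {
    stop(sprintf("model %s failed validation:\n  %s", path,
                 paste(v$errors, collapse = "\n  ")), call. = FALSE)
  }
  for (w in v$warnings) warning(w, call. = FALSE)
  model
}

#' Write a metabolic model
#'
#' JSON output is canonical: re-reading and re-writing reproduces the file
#' byte for byte. SBML output re-reads to an equal model within floating
#' round-trip tolerance.
#'
#' @param model A valid `metabolic_model`.
#' @param path output file path.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  txt <- if (format == "json") model_to_json(model) else model_to_sbml(model)
  ok <- tryCatch({
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(txt), con)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write model to %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

model_to_sbml <- function(model) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s)
    s <- gsub("<", "&lt;", s)
    gsub(">", "&gt;", s)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    '  <model id="model" fbc:strict="true">',
    "    <listOfCompartments>")
  for (cmp in unique(model$metabolites$compartment)) {
    lines <- c(lines, sprintf('      <compartment id="%s" constant="true"/>', esc(cmp)))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    lines <- c(lines, sprintf(
      '      <species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m$id), esc(m$name), esc(m$compartment)))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lines <- c(lines,
      sprintf('      <parameter id="lb_%s" value="%s" constant="true"/>', esc(r$id), fmt_num(r$lb)),
      sprintf('      <parameter id="ub_%s" value="%s" constant="true"/>', esc(r$id), fmt_num(r$ub)))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    lines <- c(lines, sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
      esc(r$id), if (r$lb < 0) "true" else "false", esc(r$id), esc(r$id)))
    lines <- c(lines,
      "        <notes>",
      sprintf('          <body xmlns="%s">', XHTML_NS),
      sprintf("            <p>subsystem: %s</p>", esc(r$subsystem)),
      sprintf("            <p>artificial: %s</p>",
              if (r$is_artificial) "true" else "false"),
      "          </body>",
      "        </notes>")
    reac <- st[st < 0]
    prod <- st[st > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>")
      for (k in seq_along(reac)) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          esc(names(reac)[k]), fmt_num(-reac[[k]])))
      }
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (k in seq_along(prod)) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          esc(names(prod)[k]), fmt_num(prod[[k]])))
      }
      lines <- c(lines, "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (length(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>")
    for (k in seq_along(model$objective)) {
      lines <- c(lines, sprintf(
        '          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="%s"/>',
        esc(names(model$objective)[k]), fmt_num(model$objective[[k]])))
    }
    lines <- c(lines,
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  paste0(paste(lines, collapse = "\n"), "\n")
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

# attribute in the fbc namespace, tolerating documents that declare a
# different (or no) prefix for it
fbc_attr <- function(node, name, ns) {
  val <- xml2::xml_attr(node, paste0("fbc:", name), ns)
  if (is.null(val) || all(is.na(val))) val <- xml2::xml_attr(node, name)
  val
}

model_from_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("SBML parse failure in %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop(sprintf("SBML file %s: no <model> element", path), call. = FALSE)
  }
  supported <- c("listOfCompartments", "listOfSpecies", "listOfParameters",
                 "listOfReactions", "listOfObjectives", "notes", "annotation")
  kids <- xml2::xml_name(xml2::xml_children(mdl))
  unknown <- setdiff(kids, supported)
  if (length(unknown)) {
    warning(sprintf("SBML %s: ignoring unsupported construct(s): %s",
                    path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop(sprintf("SBML %s: no species", path), call. = FALSE)
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop(sprintf("SBML %s: no reactions", path), call. = FALSE)
  recs <- lapply(rx, function(node) {
    rid <- strip_prefix(xml2::xml_attr(node, "id"), "R_")
    lb_ref <- fbc_attr(node, "lowerFluxBound", ns)
    ub_ref <- fbc_attr(node, "upperFluxBound", ns)
    if (is.na(lb_ref) || is.na(ub_ref) ||
        !lb_ref %in% names(parval) || !ub_ref %in% names(parval)) {
      stop(sprintf("SBML reaction %s: missing FBC flux bound(s)", rid),
           call. = FALSE)
    }
    get_side <- function(xp, sgn) {
      refs <- xml2::xml_find_all(node, xp, ns)
      if (!length(refs)) return(setNames(numeric(0), character(0)))
      setNames(sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               strip_prefix(xml2::xml_attr(refs, "species"), "M_"))
    }
    st <- c(get_side("./s:listOfReactants/s:speciesReference", -1),
            get_side("./s:listOfProducts/s:speciesReference", 1))
    notes <- xml2::xml_text(
      xml2::xml_find_all(node, "./s:notes//*[local-name()='p']", ns))
    sub_line <- grep("^\\s*subsystem:", notes, value = TRUE)
    art_line <- grep("^\\s*artificial:", notes, value = TRUE)
    list(id = rid,
         lb = unname(parval[[lb_ref]]), ub = unname(parval[[ub_ref]]),
         subsystem = if (length(sub_line)) {
           trimws(sub("^\\s*subsystem:", "", sub_line[1]))
         } else "",
         is_artificial = length(art_line) > 0 &&
           grepl("true", art_line[1], fixed = TRUE),
         st = st)
  })
  rxns <- data.frame(
    id = vapply(recs, `[[`, "", "id"),
    lb = vapply(recs, `[[`, 0, "lb"),
    ub = vapply(recs, `[[`, 0, "ub"),
    subsystem = vapply(recs, `[[`, "", "subsystem"),
    is_artificial = vapply(recs, `[[`, FALSE, "is_artificial"),
    stringsAsFactors = FALSE)
  st <- lapply(recs, `[[`, "st")
  names(st) <- rxns$id
  rxns$is_exchange <- vapply(st, length, 1L) == 1L | startsWith(rxns$id, "EX_")
  fo <- xml2::xml_find_all(mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (!length(fo)) {
    stop(sprintf("SBML %s: no FBC objective", path), call. = FALSE)
  }
  objective <- setNames(as.numeric(fbc_attr(fo, "coefficient", ns)),
                        strip_prefix(fbc_attr(fo, "reaction", ns), "R_"))
  metabolic_model(mets, rxns, st, objective = objective,
                  default_bound = max(abs(c(rxns$lb, rxns$ub, 1000))))
}
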