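#' Read a stoichiometric model
#'
#' Two dialects are supported. `"tsv"` is the package's fixture dialect: a
#' pair of tab-separated tables `<stem>.reactions.tsv` and
#' `<stem>.metabolites.tsv` (see Details). `"sbml"` reads the SBML Level 3
#' subset written by [write_model()] and the corresponding core of
#' user-supplied genome-scale models (compartments, species, reactions,
#' stoichiometry, reversibility, fbc-style flux bounds and objective).
#'
#' @details The TSV reactions table has columns `id`, `name`, `equation`,
#' `lower_bound`, `upper_bound`, `enzyme_ids` (semicolon-separated EC
#' numbers), `subsystem`, `objective_weight`. The equation grammar is
#' `"2 A + 0.5 B -> C + D"` (`<->` is accepted and equivalent; reversibility
#' is carried by the bounds). An empty side denotes an exchange, e.g.
#' `"co2_ext ->"`. The metabolites table has columns `id`, `name`,
#' `compartment`, `formula`, `is_exchange_species`. A comment line
#' `# model_label: <label>` may precede the reactions header. Bounds absent
#' in the file default to +/-1000 mmol/gDW/hr.
#'
#' @param path File path. For `"tsv"`, the common stem of the two tables or
#'   the path of either table.
#' @param dialect `"tsv"` or `"sbml"`.
#' @return A validated [stoich_model()].
#' @export
read_model <- function(path, dialect = c("tsv", "sbml")) {
  dialect <- match.arg(dialect)
  switch(dialect, tsv = read_model_tsv(path), sbml = read_model_sbml(path))
}

#' Write a stoichiometric model
#'
#' Inverse of [read_model()]: `read_model(write_model(m, p), d)` reproduces
#' `m` up to row ordering.
#'
#' @param model A valid `stoich_model`.
#' @param path Output path (stem for `"tsv"`).
#' @param dialect `"tsv"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("tsv", "sbml")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  switch(dialect, tsv = write_model_tsv(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

tsv_paths <- function(path) {
  stem <- sub("\\.(reactions|metabolites)\\.tsv$", "", path)
  list(rxn = paste0(stem, ".reactions.tsv"),
       met = paste0(stem, ".metabolites.tsv"))
}

read_model_tsv <- function(path) {
  p <- tsv_paths(path)
  if (!file.exists(p$rxn)) stop("no such file: ", p$rxn)
  if (!file.exists(p$met)) stop("no such file: ", p$met)
  head1 <- readLines(p$rxn, n = 1)
  label <- if (grepl("^# model_label:", head1)) {
    trimws(sub("^# model_label:", "", head1))
  } else "user"
  rxn <- utils::read.delim(p$rxn, comment.char = "#", stringsAsFactors = FALSE)
  met <- utils::read.delim(p$met, comment.char = "#", stringsAsFactors = FALSE)
  met$formula[is.na(met$formula)] <- ""
  eq <- lapply(rxn$equation, parse_equation)
  sto <- dplyr::bind_rows(purrr::map2(rxn$id, eq, function(id, e) {
    tibble::tibble(reaction_id = id, metabolite_id = e$metabolite_id,
                   coefficient = e$coefficient)
  }))
  obj <- NULL
  if ("objective_weight" %in% names(rxn)) {
    keep <- !is.na(rxn$objective_weight) & rxn$objective_weight != 0
    obj <- tibble::tibble(reaction_id = rxn$id[keep],
                          weight = rxn$objective_weight[keep])
  }
  enz <- if ("enzyme_ids" %in% names(rxn)) {
    lapply(rxn$enzyme_ids, function(s) {
      if (is.na(s) || !nzchar(s)) character() else
        trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  } else rep(list(character()), nrow(rxn))
  reactions <- tibble::tibble(
    id = rxn$id, name = rxn$name,
    lower_bound = if ("lower_bound" %in% names(rxn)) rxn$lower_bound else NA_real_,
    upper_bound = if ("upper_bound" %in% names(rxn)) rxn$upper_bound else NA_real_,
    enzyme_ids = enz,
    subsystem = if ("subsystem" %in% names(rxn)) {
      ifelse(is.na(rxn$subsystem), "", rxn$subsystem)
    } else "")
  stoich_model(met, reactions, sto, obj, model_label = label)
}

# "2 A + 0.5 B -> C"; empty side = exchange
parse_equation <- function(eq) {
  sides <- strsplit(eq, "<->|->", perl = TRUE)[[1]]
  if (length(sides) > 2) stop("malformed equation: ", eq)
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) == 2) sides[2] else ""
  one_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) {
      return(tibble::tibble(metabolite_id = character(), coefficient = numeric()))
    }
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    parts <- lapply(terms, function(t) {
      tok <- strsplit(t, "\\s+")[[1]]
      if (length(tok) == 1) c(1, tok) else c(as.numeric(tok[1]), tok[2])
    })
    tibble::tibble(
      metabolite_id = vapply(parts, `[`, character(1), 2),
      coefficient = sign * as.numeric(vapply(parts, `[`, character(1), 1)))
  }
  out <- dplyr::bind_rows(one_side(lhs, -1), one_side(rhs, +1))
  # collapse duplicated species (A -> A-type entries would cancel)
  out <- dplyr::summarise(dplyr::group_by(out, .data$metabolite_id),
                          coefficient = sum(.data$coefficient), .groups = "drop")
  out[out$coefficient != 0, ]
}

format_equation <- function(sto) {
  fmt_side <- function(d) {
    if (nrow(d) == 0) return("")
    co <- abs(d$coefficient)
    paste(ifelse(co == 1, d$metabolite_id,
                 paste(sprintf("%.17g", co), d$metabolite_id)),
          collapse = " + ")
  }
  d <- sto[order(sto$metabolite_id), ]
  paste(fmt_side(d[d$coefficient < 0, ]), "->", fmt_side(d[d$coefficient > 0, ]))
}

write_model_tsv <- function(model, path) {
  p <- tsv_paths(path)
  sp <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  rxn <- model$reactions
  obj <- stats::setNames(rep(0, nrow(rxn)), rxn$id)
  obj[model$objective$reaction_id] <- model$objective$weight
  out <- data.frame(
    id = rxn$id, name = rxn$name,
    equation = vapply(rxn$id, function(id) format_equation(sp[[id]]), character(1)),
    lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
    enzyme_ids = vapply(rxn$enzyme_ids, paste, character(1), collapse = ";"),
    subsystem = rxn$subsystem,
    objective_weight = unname(obj),
    stringsAsFactors = FALSE)
  con <- file(p$rxn, "w")
  writeLines(paste0("# model_label: ", model$model_label), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  met <- model$metabolites
  utils::write.table(
    data.frame(id = met$id, name = met$name, compartment = met$compartment,
               formula = met$formula, is_exchange_species = met$is_exchange_species),
    p$met, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- SBML Level 3 subset -------------------------------------------------

# SBML SIds cannot contain '.'; the cell-prefix convention uses them.
sbml_id <- function(x) gsub(".", "__", x, fixed = TRUE)
unsbml_id <- function(x) gsub("__", ".", x, fixed = TRUE)
xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_model_sbml <- function(model, path) {
  met <- model$metabolites
  rxn <- model$reactions
  sp <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  comps <- sort(unique(met$compartment))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="false">', sbml_id(model$model_label)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>', sbml_id(comps)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="%s" name="%s" compartment="%s" ',
                   'boundaryCondition="%s" hasOnlySubstanceUnits="false" ',
                   'constant="false"%s/>'),
            sbml_id(met$id), xml_esc(met$name), sbml_id(met$compartment),
            tolower(as.character(met$is_exchange_species)),
            ifelse(is.na(met$formula) | !nzchar(met$formula), "",
                   sprintf(' fbc:chemicalFormula="%s"', met$formula))),
    '    </listOfSpecies>',
    '    <listOfParameters>')
  for (i in seq_len(nrow(rxn))) {
    lines <- c(lines, sprintf(
      '      <parameter id="lb_%s" value="%.12g" constant="true"/>',
      sbml_id(rxn$id[i]), rxn$lower_bound[i]), sprintf(
      '      <parameter id="ub_%s" value="%.12g" constant="true"/>',
      sbml_id(rxn$id[i]), rxn$upper_bound[i]))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (i in seq_len(nrow(rxn))) {
    id <- rxn$id[i]
    d <- sp[[id]]
    ec <- rxn$enzyme_ids[[i]]
    notes <- if (length(ec) || nzchar(rxn$subsystem[i])) {
      paste0('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
             if (length(ec)) sprintf('<p>EC: %s</p>', paste(ec, collapse = "; ")) else "",
             if (nzchar(rxn$subsystem[i]))
               sprintf('<p>SUBSYSTEM: %s</p>', xml_esc(rxn$subsystem[i])) else "",
             '</body></notes>')
    } else NULL
    side <- function(d, tag) {
      if (nrow(d) == 0) return(character())
      c(sprintf('        <listOf%ss>', tag),
        sprintf(paste0('          <speciesReference species="%s" ',
                       'stoichiometry="%.12g" constant="true"/>'),
                sbml_id(d$metabolite_id), abs(d$coefficient)),
        sprintf('        </listOf%ss>', tag))
    }
    lines <- c(lines,
      sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                     'fast="false" fbc:lowerFluxBound="lb_%s" ',
                     'fbc:upperFluxBound="ub_%s">'),
              sbml_id(id), xml_esc(rxn$name[i]),
              tolower(as.character(rxn$lower_bound[i] < 0)),
              sbml_id(id), sbml_id(id)),
      notes,
      side(d[d$coefficient < 0, ], "Reactant"),
      side(d[d$coefficient > 0, ], "Product"),
      '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (nrow(model$objective) > 0) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
                     'fbc:coefficient="%.12g"/>'),
              sbml_id(model$objective$reaction_id), model$objective$weight),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  attr1 <- function(node, name) {
    a <- xml2::xml_attrs(node)
    hit <- which(names(a) == name | endsWith(names(a), paste0(":", name)))
    if (length(hit)) unname(a[hit[1]]) else NA_character_
  }
  label <- attr1(xml2::xml_find_first(doc, ".//model"), "id")
  if (is.na(label)) label <- "user"
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met <- tibble::tibble(
    id = unsbml_id(xml2::xml_attr(sp_nodes, "id")),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           unsbml_id(xml2::xml_attr(sp_nodes, "id"))),
    compartment = unsbml_id(xml2::xml_attr(sp_nodes, "compartment")),
    formula = vapply(sp_nodes, attr1, character(1), "chemicalFormula"),
    is_exchange_species =
      dplyr::coalesce(xml2::xml_attr(sp_nodes, "boundaryCondition"),
                      "false") == "true")
  met$formula[is.na(met$formula)] <- ""
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rows <- lapply(rx_nodes, function(nd) {
    id <- unsbml_id(xml2::xml_attr(nd, "id"))
    lb_ref <- attr1(nd, "lowerFluxBound")
    ub_ref <- attr1(nd, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) pval[[lb_ref]] else {
      if (identical(xml2::xml_attr(nd, "reversible"), "true")) -1000 else 0
    }
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) pval[[ub_ref]] else 1000
    paras <- xml2::xml_text(xml2::xml_find_all(nd, ".//notes//*[local-name()='p']"))
    ec <- character(); subsystem <- ""
    for (p in paras) {
      if (startsWith(p, "EC: ")) {
        ec <- trimws(strsplit(sub("^EC: ", "", p), ";")[[1]])
      } else if (startsWith(p, "SUBSYSTEM: ")) {
        subsystem <- sub("^SUBSYSTEM: ", "", p)
      }
    }
    reac <- xml2::xml_find_all(nd, "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(nd, "./listOfProducts/speciesReference")
    sto <- tibble::tibble(
      reaction_id = id,
      metabolite_id = unsbml_id(c(xml2::xml_attr(reac, "species"),
                                  xml2::xml_attr(prod, "species"))),
      coefficient = c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      as.numeric(xml2::xml_attr(prod, "stoichiometry"))))
    list(rxn = tibble::tibble(
      id = id,
      name = dplyr::coalesce(xml2::xml_attr(nd, "name"), id),
      lower_bound = lb, upper_bound = ub,
      enzyme_ids = list(ec), subsystem = subsystem), sto = sto)
  })
  reactions <- dplyr::bind_rows(lapply(rows, `[[`, "rxn"))
  sto <- dplyr::bind_rows(lapply(rows, `[[`, "sto"))
  fo <- xml2::xml_find_all(doc, ".//*[local-name()='fluxObjective']")
  obj <- if (length(fo)) {
    tibble::tibble(
      reaction_id = unsbml_id(vapply(fo, attr1, character(1), "reaction")),
      weight = as.numeric(vapply(fo, attr1, character(1), "coefficient")))
  } else NULL
  stoich_model(met, reactions, sto, obj, model_label = label)
}
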