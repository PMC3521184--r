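#' Construct a compartmentalized stoichiometric model
#'
#' A `stoich_model` is the substrate of every downstream analysis: flux
#' balance analysis, knockout scans, flux sampling, topology and the
#' environment sweeps. It is a classed list of tibbles, so each part
#' (metabolites, reactions, stoichiometry, objective) can be inspected and
#' manipulated with ordinary dplyr verbs.
#'
#' Compartments follow a cell-prefix convention: `"M.chloroplast"`,
#' `"BS.cytosol"`, ... for mesophyll/bundle-sheath cells, and `"ext"` for the
#' extracellular space. Two-cell C4 networks are a single model whose
#' inter-cell transporters are ordinary reactions spanning prefixed
#' compartments. Reversibility is encoded purely by the bounds
#' (`lower_bound < 0`), not by a separate flag.
#'
#' @param metabolites Tibble/data frame with columns `id`, `name`,
#'   `compartment` and optionally `formula` (elemental formula used by
#'   [audit_atom_balance()]) and `is_exchange_species`.
#' @param reactions Tibble/data frame with columns `id`, `name`,
#'   `lower_bound`, `upper_bound` and optionally `enzyme_ids` (list column of
#'   EC-number character vectors) and `subsystem`. Missing bounds default to
#'   +/-1000 mmol/gDW/hr, the conventional "effectively unbounded" value in
#'   constraint-based models.
#' @param stoichiometry Long-format tibble with columns `reaction_id`,
#'   `metabolite_id`, `coefficient` (negative = consumed).
#' @param objective Named numeric vector or tibble (`reaction_id`, `weight`)
#'   giving the linear objective c in max c'v.
#' @param model_label Free label, conventionally `"C3"` or `"C4"`.
#'
#' @return An object of class `stoich_model`.
#' @seealso [validate_model()], [read_model()], [apply_overrides()], [fba()]
#' @export
stoich_model <- function(metabolites, reactions, stoichiometry,
                         objective = NULL, model_label = "user") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"is_exchange_species" %in% names(metabolites)) {
    metabolites$is_exchange_species <- metabolites$compartment == "ext"
  }
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- NA_real_
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- NA_real_
  reactions$lower_bound[is.na(reactions$lower_bound)] <- -1000
  reactions$upper_bound[is.na(reactions$upper_bound)] <- 1000
  if (!"enzyme_ids" %in% names(reactions)) {
    reactions$enzyme_ids <- rep(list(character()), nrow(reactions))
  }
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""

  if (is.null(objective)) {
    objective <- tibble::tibble(reaction_id = character(), weight = numeric())
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    objective <- tibble::tibble(reaction_id = names(objective),
                                weight = unname(objective))
  } else {
    objective <- tibble::as_tibble(objective)
  }

  m <- structure(
    list(metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry,
         objective = objective,
         model_label = model_label),
    class = "stoich_model")
  validate_model(m)
  m
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants every analysis relies on: unique ids,
#' non-empty compartments, ordered finite bounds, non-empty stoichiometries
#' with finite non-zero coefficients, resolvable metabolite and objective
#' references, and the presence of at least one exchange reaction (a
#' single-signed reaction touching an `"ext"` species). Errors name the
#' offending entity.
#'
#' @param model A `stoich_model`.
#' @return The model, invisibly, if valid; otherwise an error.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  met <- model$metabolites
  rxn <- model$reactions
  sto <- model$stoichiometry

  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite id(s): ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction id(s): ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  }
  if (any(!nzchar(met$compartment))) {
    stop("empty compartment for metabolite(s): ",
         paste(met$id[!nzchar(met$compartment)], collapse = ", "))
  }
  if (nrow(rxn) == 0) stop("model has no reactions")
  bad_b <- rxn$id[!(is.finite(rxn$lower_bound) & is.finite(rxn$upper_bound) &
                      rxn$lower_bound <= rxn$upper_bound)]
  if (length(bad_b)) {
    stop("malformed bounds (need finite lower <= upper) for reaction(s): ",
         paste(bad_b, collapse = ", "))
  }
  missing_sto <- setdiff(rxn$id, sto$reaction_id)
  if (length(missing_sto)) {
    stop("empty stoichiometry for reaction(s): ",
         paste(missing_sto, collapse = ", "))
  }
  bad_c <- !(is.finite(sto$coefficient) & sto$coefficient != 0)
  if (any(bad_c)) {
    stop("non-finite or zero stoichiometric coefficient in reaction(s): ",
         paste(unique(sto$reaction_id[bad_c]), collapse = ", "))
  }
  unresolved <- setdiff(sto$metabolite_id, met$id)
  if (length(unresolved)) {
    rids <- unique(sto$reaction_id[sto$metabolite_id %in% unresolved])
    stop("reaction(s) ", paste(rids, collapse = ", "),
         " cite undeclared species: ", paste(unresolved, collapse = ", "))
  }
  orphan_rxn <- setdiff(sto$reaction_id, rxn$id)
  if (length(orphan_rxn)) {
    stop("stoichiometry cites undeclared reaction(s): ",
         paste(orphan_rxn, collapse = ", "))
  }
  bad_obj <- setdiff(model$objective$reaction_id, rxn$id)
  if (length(bad_obj)) {
    stop("objective cites unknown reaction(s): ",
         paste(bad_obj, collapse = ", "))
  }
  ext_ids <- met$id[met$compartment == "ext"]
  if (!any(sto$metabolite_id %in% ext_ids)) {
    stop("model has no reaction touching an 'ext' species (no exchange boundary)")
  }
  invisible(model)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model '%s'>  %d metabolites, %d reactions, %d objective term(s)\n",
              x$model_label, nrow(x$metabolites), nrow(x$reactions),
              nrow(x$objective)))
  cat("compartments:", paste(sort(unique(x$metabolites$compartment)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Identify exchange reactions
#'
#' An exchange reaction has a single-signed stoichiometry (all coefficients
#' of one sign) and touches at least one species in the `"ext"` compartment.
#'
#' @param model A `stoich_model`.
#' @return Character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  ext_ids <- model$metabolites$id[model$metabolites$compartment == "ext"]
  sp <- split(model$stoichiometry, model$stoichiometry$reaction_id)
  ids <- names(sp)[vapply(sp, function(d) {
    (all(d$coefficient > 0) || all(d$coefficient < 0)) &&
      any(d$metabolite_id %in% ext_ids)
  }, logical(1))]
  ids
}

#' Dense stoichiometric matrix S
#'
#' @param model A `stoich_model`.
#' @return A numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  sto <- model$stoichiometry
  S[cbind(match(sto$metabolite_id, rownames(S)),
          match(sto$reaction_id, colnames(S)))] <- sto$coefficient
  S
}

#' Constraint overrides
#'
#' Build a tibble of bound overrides, the mechanism used to re-impose
#' biochemical knowledge on a model: e.g. opening the bundle-sheath-to-
#' mesophyll CO2 leak by lifting its upper bound, or restricting
#' mitochondrial respiration by clamping TCA-cycle reactions to
#' \eqn{[-50, 50]} mmol/gDW/hr.
#'
#' @param reaction_id Character vector of reaction ids.
#' @param new_lower,new_upper Numeric vectors (NA = leave unchanged). At
#'   least one of the two must be non-NA per row.
#' @return A tibble with class `constraint_override`.
#' @export
constraint_override <- function(reaction_id, new_lower = NA_real_,
                                new_upper = NA_real_) {
  out <- tibble::tibble(reaction_id = reaction_id,
                        new_lower = as.numeric(new_lower),
                        new_upper = as.numeric(new_upper))
  if (any(is.na(out$new_lower) & is.na(out$new_upper))) {
    stop("each override must set at least one of new_lower/new_upper")
  }
  class(out) <- c("constraint_override", class(out))
  out
}

#' Apply constraint overrides to a model
#'
#' Returns a new model in which only the named bounds are changed; the
#' operation is idempotent for a fixed override list.
#'
#' @param model A `stoich_model`.
#' @param overrides A [constraint_override()] tibble (possibly zero rows), or
#'   a data frame with the same columns (e.g. read from a TSV).
#' @return A new `stoich_model`.
#' @export
apply_overrides <- function(model, overrides) {
  overrides <- tibble::as_tibble(overrides)
  if (nrow(overrides) == 0) return(model)
  unknown <- setdiff(overrides$reaction_id, model$reactions$id)
  if (length(unknown)) {
    stop("override names unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  rxn <- model$reactions
  for (i in seq_len(nrow(overrides))) {
    j <- match(overrides$reaction_id[i], rxn$id)
    if (!is.na(overrides$new_lower[i])) rxn$lower_bound[j] <- overrides$new_lower[i]
    if (!is.na(overrides$new_upper[i])) rxn$upper_bound[j] <- overrides$new_upper[i]
    if (rxn$lower_bound[j] > rxn$upper_bound[j]) {
      stop("override for reaction '", rxn$id[j], "' inverts bounds (",
           rxn$lower_bound[j], " > ", rxn$upper_bound[j], ")")
    }
  }
  model$reactions <- rxn
  model
}

#' Set bounds on one reaction
#'
#' Convenience wrapper over [apply_overrides()].
#' @param model A `stoich_model`.
#' @param reaction_id Reaction id.
#' @param lower,upper New bounds (NA = unchanged).
#' @return A new `stoich_model`.
#' @export
set_bounds <- function(model, reaction_id, lower = NA_real_, upper = NA_real_) {
  apply_overrides(model, constraint_override(reaction_id, lower, upper))
}

#' Audit elemental balance of every internal reaction
#'
#' Using the per-metabolite `formula` column, checks conservation of the
#' elements C, H, O, N and P for every non-exchange reaction. Transport
#' reactions balance trivially when the species formulas agree across
#' compartments. Species without a formula (e.g. photons) contribute no
#' atoms.
#'
#' @param model A `stoich_model` whose metabolites carry a `formula` column.
#' @param elements Elements to audit.
#' @return Tibble with one row per reaction and element carrying the net
#'   atom imbalance (0 everywhere for a balanced model).
#' @export
audit_atom_balance <- function(model, elements = c("C", "H", "O", "N", "P")) {
  comp <- parse_formula(model$metabolites$formula, elements)
  rownames(comp) <- model$metabolites$id
  ex <- exchange_reactions(model)
  sto <- model$stoichiometry[!(model$stoichiometry$reaction_id %in% ex), ]
  net <- rowsum(sto$coefficient * comp[sto$metabolite_id, , drop = FALSE],
                group = sto$reaction_id)
  out <- tibble::as_tibble(net, rownames = "reaction_id")
  tidyr::pivot_longer(out, -"reaction_id",
                      names_to = "element", values_to = "imbalance")
}

# "C6H12O6"-style formula parser; NA/"" -> zero atoms (photon-like species).
parse_formula <- function(formula, elements = c("C", "H", "O", "N", "P")) {
  out <- matrix(0, length(formula), length(elements),
                dimnames = list(NULL, elements))
  for (i in seq_along(formula)) {
    f <- formula[i]
    if (is.na(f) || !nzchar(f)) next
    m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    for (t in toks) {
      el <- sub("^([A-Z][a-z]?).*$", "\\1", t)
      n <- sub("^[A-Z][a-z]?", "", t)
      if (el %in% elements) {
        out[i, el] <- out[i, el] + if (nzchar(n)) as.numeric(n) else 1
      }
    }
  }
  out
}
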