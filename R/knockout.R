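#' Delete one reaction or enzyme and score the objective ratio
#'
#' A reaction deletion clamps that reaction's bounds to zero. An enzyme
#' deletion is genetic: every reaction whose EC annotation contains the
#' number is clamped, across all compartments and cells. The score is the
#' ratio of the knockout optimum to the wild-type optimum; an infeasible
#' knockout problem scores 0 (no feasible steady state means no objective).
#'
#' Classes follow the objective-ratio convention: `"zero"` when the ratio
#' is at most `tol`, `"unchanged"` when it is at least `1 - tol`,
#' `"reduced_below_090"` below 0.90 and `"reduced_above_090"` otherwise
#' (exactly 0.90 is assigned upward).
#'
#' @param model A `stoich_model` with positive wild-type optimum.
#' @param target Reaction id or EC number.
#' @param kind `"reaction"` or `"enzyme"`.
#' @param wild_type Optional precomputed wild-type objective (saves a solve
#'   in scans).
#' @param tol Tolerance defining the "zero" and "unchanged" classes.
#' @return One-row tibble: `deleted_id`, `kind`, `ratio`, `class`.
#' @export
delete_and_score <- function(model, target, kind = c("reaction", "enzyme"),
                             wild_type = NULL, tol = 1e-6) {
  kind <- match.arg(kind)
  if (is.null(wild_type)) {
    wt <- fba(model)
    if (wt$status != "optimal") stop("wild-type problem is ", wt$status)
    wild_type <- wt$objective_value
  }
  if (wild_type <= tol) stop("wild-type optimum is 0; knockout ratio undefined")
  ids <- if (kind == "reaction") {
    if (!target %in% model$reactions$id) stop("unknown reaction id: ", target)
    target
  } else {
    model$reactions$id[vapply(model$reactions$enzyme_ids,
                              function(e) target %in% e, logical(1))]
  }
  m <- model
  for (id in ids) m <- set_bounds(m, id, 0, 0)
  ko <- fba(m)
  ratio <- if (ko$status == "optimal") {
    max(0, min(ko$objective_value / wild_type, 1 + tol))
  } else 0
  cls <- if (ratio <= tol) "zero"
         else if (ratio >= 1 - tol) "unchanged"
         else if (ratio < 0.90) "reduced_below_090"
         else "reduced_above_090"
  tibble::tibble(deleted_id = target, kind = kind, ratio = ratio, class = cls)
}

#' Single-deletion scan of a whole model
#'
#' Deletes every reaction (or every distinct EC number) in turn,
#' re-optimizes, and tallies the objective-ratio classes -- the robustness
#' summary of the network under the chosen objective. Deterministic
#' ordering by id.
#'
#' @param model A `stoich_model` with positive wild-type optimum.
#' @param objective_name Label stored in the report (the model's objective
#'   is used as-is; see [set_objective()]).
#' @param kind Scan reactions or enzymes.
#' @param exclude_exchanges Drop exchange reactions from a reaction scan.
#' @param tol Class tolerance, as in [delete_and_score()].
#' @return A `knockout_report`: list with `entries` (tibble), `tally`
#'   (tibble of class counts and percentages), `wild_type_objective`,
#'   `objective_name`, `model_label`.
#' @export
scan_all <- function(model, objective_name = NULL,
                     kind = c("reaction", "enzyme"),
                     exclude_exchanges = FALSE, tol = 1e-6) {
  kind <- match.arg(kind)
  wt <- fba(model)
  if (wt$status != "optimal") stop("wild-type problem is ", wt$status)
  if (wt$objective_value <= tol) stop("wild-type optimum is 0")
  targets <- if (kind == "reaction") {
    ids <- model$reactions$id
    if (exclude_exchanges) ids <- setdiff(ids, exchange_reactions(model))
    sort(ids)
  } else {
    sort(unique(unlist(model$reactions$enzyme_ids)))
  }
  entries <- dplyr::bind_rows(lapply(targets, function(t) {
    delete_and_score(model, t, kind, wild_type = wt$objective_value, tol = tol)
  }))
  lv <- c("zero", "reduced_below_090", "reduced_above_090", "unchanged")
  counts <- table(factor(entries$class, levels = lv))
  tally <- tibble::tibble(class = lv, count = as.integer(counts),
                          percentage = 100 * as.integer(counts) / nrow(entries))
  structure(list(entries = entries, tally = tally,
                 wild_type_objective = wt$objective_value,
                 objective_name = objective_name %||% wt$objective_name,
                 model_label = model$model_label),
            class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat(sprintf("<knockout_report '%s' on '%s'>  wild type %.6g, %d deletions\n",
              x$objective_name, x$model_label, x$wild_type_objective,
              nrow(x$entries)))
  print(x$tally)
  invisible(x)
}

#' @export
tidy.knockout_report <- function(x, ...) x$entries

#' @export
glance.knockout_report <- function(x, ...) {
  wide <- stats::setNames(as.list(x$tally$count), paste0("n_", x$tally$class))
  tibble::as_tibble(c(list(model_label = x$model_label,
                           objective_name = x$objective_name,
                           wild_type_objective = x$wild_type_objective,
                           n_deletions = nrow(x$entries)), wide))
}

#' Essentiality overlap between two knockout reports
#'
#' Essential = class `"zero"`. Maps report A's essential ids through
#' `id_map` and compares with report B's essential set. Ids of A without a
#' counterpart stay in the A-only set by contract.
#'
#' @param report_a,report_b `knockout_report` objects.
#' @param id_map Named character vector mapping A-ids to B-ids (e.g.
#'   [ortholog_map()]).
#' @return List with `shared`, `a_only`, `b_only` (character vectors; shared
#'   and b_only use B's id space).
#' @export
essential_overlap <- function(report_a, report_b, id_map) {
  ess_a <- report_a$entries$deleted_id[report_a$entries$class == "zero"]
  ess_b <- report_b$entries$deleted_id[report_b$entries$class == "zero"]
  mapped <- id_map[ess_a]
  a_unmapped <- ess_a[is.na(mapped)]
  mapped <- mapped[!is.na(mapped)]
  shared <- intersect(mapped, ess_b)
  a_only <- c(names(mapped)[!mapped %in% ess_b], a_unmapped)
  b_only <- setdiff(ess_b, mapped)
  list(shared = unname(shared), a_only = unname(a_only), b_only = b_only)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
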