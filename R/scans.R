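#' Light-intensity sweep
#'
#' Re-solves the model over a grid of photon-uptake bounds. Each grid value
#' becomes the magnitude of the photon exchange lower bound (uptake), the
#' model is optimized for the chosen objective, and both the biomass flux
#' and the net CO2 fixation flux of the same solution are recorded. The
#' resulting curves are piecewise linear, non-decreasing and saturate once
#' light stops being the limiting resource.
#'
#' @param model A `stoich_model` with a photon exchange reaction.
#' @param grid Ascending photon-flux bounds.
#' @param objective `"biomass"` or `"co2_fixation"`.
#' @param photon_exchange_id Id of the photon exchange reaction.
#' @return A `sweep_result` tibble with columns `variable`, `grid`,
#'   `biomass_flux`, `co2_fixation_flux`, `objective_value`, `model_label`.
#' @export
light_sweep <- function(model, grid, objective = c("biomass", "co2_fixation"),
                        photon_exchange_id = "EX_photon") {
  objective <- match.arg(objective)
  if (!photon_exchange_id %in% model$reactions$id) {
    stop("model has no photon exchange reaction '", photon_exchange_id, "'")
  }
  stopifnot(length(grid) >= 1, !is.unsorted(grid), all(grid >= 0))
  model <- set_objective(model, objective)
  rows <- lapply(grid, function(g) {
    m <- set_bounds(model, photon_exchange_id, lower = -g, upper = 0)
    sol <- fba(m)
    sweep_row("light", g, sol, model$model_label)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

sweep_row <- function(variable, g, sol, label) {
  if (sol$status != "optimal") {
    stop("sweep point ", g, " is ", sol$status)
  }
  tibble::tibble(
    variable = variable, grid = g,
    biomass_flux = max(0, unname(sol$fluxes["EX_biomass"])),
    co2_fixation_flux = max(0, -unname(sol$fluxes["EX_co2"])),
    objective_value = sol$objective_value,
    model_label = label)
}

#' Ambient-CO2 sweep
#'
#' For each ambient CO2 partial pressure on the grid, the
#' carboxylation:oxygenation ratio r is recomputed from the leaf kinetics,
#' the combined Rubisco reaction is re-installed with that r, the CO2
#' exchange uptake bound is scaled proportionally to the partial pressure
#' (`co2_scale`, mmol/gDW/hr per ubar), and the model is re-optimized. The
#' curve is the constraint-based analogue of an A-Ci response: rising while
#' CO2 limits, saturating once light takes over.
#'
#' @param model_template A `stoich_model` carrying the combined-Rubisco
#'   role species (a toy fixture or equivalent).
#' @param ca_grid Ascending ambient CO2 values (ubar), positive.
#' @param system `"c3"` or `"c4"` (selects the kinetics and the Rubisco
#'   compartment).
#' @param objective `"biomass"` or `"co2_fixation"`.
#' @param co2_scale Conversion from ubar to the CO2 exchange bound
#'   (mmol/gDW/hr per ubar).
#' @param co2_exchange_id Id of the CO2 exchange reaction.
#' @return A `sweep_result` tibble (see [light_sweep()]) with an extra `r`
#'   column recording the ratio used at each grid point.
#' @export
co2_sweep <- function(model_template, ca_grid, system = c("c3", "c4"),
                      objective = c("biomass", "co2_fixation"),
                      co2_scale = 0.1, co2_exchange_id = "EX_co2") {
  system <- match.arg(system)
  objective <- match.arg(objective)
  stopifnot(all(ca_grid > 0), !is.unsorted(ca_grid))
  target <- if (system == "c3") "M.chloroplast" else "BS.chloroplast"
  model_template <- set_objective(model_template, objective)
  rows <- lapply(ca_grid, function(ca) {
    r <- if (system == "c3") c3_ratio(ca)$r else c4_ratio(ca)$r
    m <- install_rubisco(model_template, r, target)
    m <- set_bounds(m, co2_exchange_id, lower = -co2_scale * ca)
    sol <- fba(m)
    dplyr::mutate(sweep_row("co2", ca, sol, model_template$model_label), r = r)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' C4 decarboxylation-subtype scenario
#'
#' Restricts the model to one decarboxylation subtype by bounding the two
#' non-selected decarboxylases to zero (`"ALL"` leaves all three open),
#' optimizes biomass, and reports the biomass flux, the net CO2 fixation
#' flux and the three decarboxylase fluxes of that solution.
#'
#' @param model A toy C4 `stoich_model` (or any model carrying the three
#'   decarboxylase reactions).
#' @param subtype `"NADP_ME"`, `"NAD_ME"`, `"PCK"` or `"ALL"`.
#' @param decarboxylase_ids Named ids of the three decarboxylases.
#' @return A `subtype_scenario` one-row tibble: `subtype`, `biomass_flux`,
#'   `co2_fixation_flux`, one `flux_*` column per decarboxylase, and a
#'   `blocked` list column.
#' @export
subtype_scenario <- function(model,
                             subtype = c("NADP_ME", "NAD_ME", "PCK", "ALL"),
                             decarboxylase_ids = c(NADP_ME = "R00216",
                                                   NAD_ME = "R00214",
                                                   PCK = "R00341")) {
  subtype <- match.arg(subtype)
  missing <- setdiff(decarboxylase_ids, model$reactions$id)
  if (length(missing)) {
    stop("model lacks decarboxylase reaction(s): ",
         paste(missing, collapse = ", "))
  }
  blocked <- if (subtype == "ALL") character() else
    unname(decarboxylase_ids[setdiff(names(decarboxylase_ids), subtype)])
  m <- set_objective(model, "biomass")
  for (id in blocked) m <- set_bounds(m, id, 0, 0)
  sol <- fba(m)
  if (sol$status != "optimal") stop("subtype scenario is ", sol$status)
  dec <- stats::setNames(unname(sol$fluxes[decarboxylase_ids]),
                         paste0("flux_", decarboxylase_ids))
  out <- tibble::as_tibble(c(
    list(subtype = subtype,
         biomass_flux = sol$objective_value,
         co2_fixation_flux = max(0, -unname(sol$fluxes["EX_co2"]))),
    as.list(dec)))
  out$blocked <- list(blocked)
  class(out) <- c("subtype_scenario", class(out))
  out
}

#' Plot a sweep result
#'
#' Biomass and CO2-fixation response curves against the swept variable.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("biomass_flux", "co2_fixation_flux"),
                              names_to = "response", values_to = "flux")
  xlab <- if (object$variable[1] == "light") "photon flux bound"
          else "ambient CO2 (ubar)"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$grid, y = .data$flux,
                                     colour = .data$model_label,
                                     linetype = .data$response)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = xlab, y = "flux (mmol/gDW/hr)",
                  colour = "model", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a knockout report tally
#'
#' @param object A `knockout_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knockout_report <- function(object, ...) {
  d <- object$tally
  d$class <- factor(d$class, levels = d$class)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$percentage)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = sprintf("Single deletions, %s objective (%s)",
                                  object$objective_name, object$model_label),
                  x = "objective-ratio class", y = "% of deletions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
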