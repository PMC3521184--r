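#' Flux balance analysis
#'
#' Solves the linear program
#' \deqn{\max_v\ c^T v \quad \mathrm{s.t.}\quad S v = 0,\ l \le v \le u}
#' (or the minimization) where S is the stoichiometric matrix, c the
#' model's objective weights and l, u the flux bounds. The steady-state
#' constraint Sv = 0 expresses mass balance for every internal metabolite.
#'
#' The returned flux vector is one optimal vertex; alternate optima are
#' common, so only `objective_value` is contract-stable. Infeasibility is
#' reported in `status`, never as silent zeros.
#'
#' @param model A `stoich_model` with a non-empty objective.
#' @param sense `"max"` or `"min"`.
#' @param objective_name Label recorded on the solution (default: derived
#'   from the objective reactions).
#' @return A `flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"not_converged"`), `objective_value`, `fluxes`
#'   (named vector), `objective_name`, `model_label`.
#' @examples
#' m <- make_toy_c3()
#' sol <- fba(m)
#' sol$objective_value
#' @export
fba <- function(model, sense = c("max", "min"), objective_name = NULL) {
  sense <- match.arg(sense)
  if (nrow(model$objective) == 0) stop("model objective is empty")
  S <- stoich_matrix(model)
  cvec <- stats::setNames(rep(0, ncol(S)), colnames(S))
  cvec[model$objective$reaction_id] <- model$objective$weight
  res <- solve_lp(S, cvec, model$reactions$lower_bound,
                  model$reactions$upper_bound, maximize = sense == "max")
  if (is.null(objective_name)) {
    objective_name <- paste(model$objective$reaction_id, collapse = "+")
  }
  structure(list(status = res$status,
                 objective_value = res$value,
                 fluxes = res$fluxes,
                 objective_name = objective_name,
                 model_label = model$model_label),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution '%s' on '%s'>  status: %s", x$objective_name,
              x$model_label, x$status))
  if (x$status == "optimal") cat(sprintf("  objective: %.6g", x$objective_value))
  cat("\n")
  invisible(x)
}

#' Flux variability ranges
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective is held at or above `fraction_of_optimum` times its optimum.
#' Used to tighten bounds before sampling (the "narrow range on
#' constraints" preprocessing) and to prove flux uniqueness.
#'
#' @param model A `stoich_model` with non-empty objective.
#' @param fraction_of_optimum In \[0, 1\]; 1 fixes the optimal objective,
#'   0 explores the whole feasible space.
#' @return Tibble with columns `reaction_id`, `min_flux`, `max_flux`.
#' @export
flux_ranges <- function(model, fraction_of_optimum = 1) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  cvec <- stats::setNames(rep(0, ncol(S)), colnames(S))
  cvec[model$objective$reaction_id] <- model$objective$weight
  base <- solve_lp(S, cvec, lb, ub, maximize = TRUE)
  if (base$status != "optimal") {
    stop("base FBA problem is ", base$status, "; cannot compute flux ranges")
  }
  floor_row <- if (any(cvec != 0)) {
    list(a = cvec, b = fraction_of_optimum * base$value)
  } else NULL
  n <- ncol(S)
  mins <- maxs <- numeric(n)
  for (j in seq_len(n)) {
    ej <- stats::setNames(numeric(n), colnames(S))
    ej[j] <- 1
    lo <- solve_lp(S, ej, lb, ub, maximize = FALSE, extra_ge = floor_row)
    hi <- solve_lp(S, ej, lb, ub, maximize = TRUE, extra_ge = floor_row)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("flux range subproblem for '", colnames(S)[j], "' is ", lo$status)
    }
    mins[j] <- lo$value
    maxs[j] <- hi$value
  }
  tibble::tibble(reaction_id = colnames(S),
                 min_flux = pmin(mins, maxs), max_flux = pmax(mins, maxs))
}

# LP core: max/min c'v s.t. Sv = 0, l <= v <= u, optional extra row a'v >= b
# (used by flux_ranges to hold the objective at its optimum). The extra row
# gets a surplus column so the equality-form simplex in lp.R applies.
solve_lp <- function(S, cvec, lb, ub, maximize = TRUE, extra_ge = NULL) {
  n <- ncol(S)
  A <- S
  b <- rep(0, nrow(S))
  cc <- cvec
  l <- lb
  u <- ub
  if (!is.null(extra_ge)) {
    slack_ub <- sum(abs(extra_ge$a) * pmax(abs(lb), abs(ub))) + abs(extra_ge$b) + 1
    A <- rbind(cbind(S, 0), c(extra_ge$a, -1))
    b <- c(b, extra_ge$b)
    cc <- c(cvec, 0)
    l <- c(lb, 0)
    u <- c(ub, slack_ub)
  }
  res <- lp_simplex(A, b, cc, l, u, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, n), colnames(S))))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", value = sum(cvec * v),
       fluxes = stats::setNames(v, colnames(S)))
}

#' Set the model objective by role
#'
#' The two study objectives are biomass synthesis (flux of the biomass
#' exchange) and net CO2 fixation (net CO2 uptake through the CO2 exchange;
#' uptake is a negative exchange flux, so the weight is -1 and the
#' objective value is the uptake rate, a non-negative number at optimum).
#'
#' @param model A `stoich_model`.
#' @param objective `"biomass"`, `"co2_fixation"`, or a named numeric
#'   vector of reaction weights.
#' @param biomass_id,co2_exchange_id Reaction ids used for the two named
#'   objectives; the defaults match the bundled toy models.
#' @return The model with its objective replaced.
#' @export
set_objective <- function(model, objective = c("biomass", "co2_fixation"),
                          biomass_id = "EX_biomass", co2_exchange_id = "EX_co2") {
  if (is.character(objective)) {
    objective <- match.arg(objective)
    w <- switch(objective,
                biomass = stats::setNames(1, biomass_id),
                co2_fixation = stats::setNames(-1, co2_exchange_id))
  } else {
    w <- objective
  }
  unknown <- setdiff(names(w), model$reactions$id)
  if (length(unknown)) {
    stop("objective names unknown reaction(s): ", paste(unknown, collapse = ", "))
  }
  model$objective <- tibble::tibble(reaction_id = names(w), weight = unname(w))
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flux solution into a tibble
#'
#' @param x A `flux_solution`.
#' @param nonzero_only Drop reactions with |flux| below `tol`.
#' @param tol Zero threshold.
#' @param ... Unused.
#' @return Tibble with `reaction_id`, `flux`.
#' @export
tidy.flux_solution <- function(x, nonzero_only = FALSE, tol = 1e-9, ...) {
  out <- tibble::tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes))
  if (nonzero_only) out <- out[abs(out$flux) > tol, ]
  out
}

#' One-row summary of a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(model_label = x$model_label,
                 objective_name = x$objective_name,
                 status = x$status,
                 objective_value = x$objective_value,
                 n_reactions = length(x$fluxes),
                 n_active = sum(abs(x$fluxes) > 1e-9, na.rm = TRUE))
}
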