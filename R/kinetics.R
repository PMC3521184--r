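#' Kinetic parameter sets for the carboxylation:oxygenation ratio
#'
#' `c3_kinetics()` bundles the Farquhar-type leaf parameters used for C3
#' leaves; `c4_kinetics()` bundles the two-cell (mesophyll/bundle-sheath)
#' parameters of the von Caemmerer C4 model. Defaults are the standard
#' literature values; all pressures are partial pressures.
#'
#' @param Kc Michaelis constant of Rubisco for CO2 (ubar).
#' @param Ko Michaelis constant of Rubisco for O2 (mbar).
#' @param O2 Ambient O2 partial pressure (mbar).
#' @param vo_scale Dimensionless scale on the oxygenation velocity (the
#'   relative Vomax/Vcmax factor, 0.21).
#' @param ci_fraction Intercellular:ambient CO2 ratio for C3 leaves (0.70).
#' @return A parameter list of class `c3_kinetics`.
#' @export
c3_kinetics <- function(Kc = 460, Ko = 330, O2 = 210, vo_scale = 0.21,
                        ci_fraction = 0.7) {
  stopifnot(Kc > 0, Ko > 0, O2 > 0, vo_scale > 0,
            ci_fraction > 0, ci_fraction <= 1)
  structure(list(Kc = Kc, Ko = Ko, O2 = O2, vo_scale = vo_scale,
                 ci_fraction = ci_fraction), class = "c3_kinetics")
}

#' @rdname c3_kinetics
#' @param Vpmax Maximum PEP carboxylation rate (umol/m^2/s).
#' @param Kp Michaelis constant of PEPC for CO2 (ubar).
#' @param Vpr PEP regeneration-limited rate (umol/m^2/s).
#' @param gs Bundle-sheath conductance to CO2 leakage (mmol/m^2/s/bar).
#' @param Vcmax Maximum Rubisco carboxylation rate (umol/m^2/s).
#' @param gamma Half the reciprocal of Rubisco CO2/O2 specificity
#'   (dimensionless, per ubar:ubar).
#' @param Rd Leaf mitochondrial respiration (umol/m^2/s).
#' @param Rm Mesophyll mitochondrial respiration (umol/m^2/s).
#' @param alpha Fraction of PSII activity in the bundle sheath (0 here:
#'   no photosynthetic O2 evolution in the bundle sheath, so Os = Om).
#' @param x Partitioning factor of electron transport rate.
#' @param Jmax Maximal electron transport rate (umol electron/m^2/s). The
#'   total rate Jt is taken equal to Jmax (saturating light); see the
#'   methods vignette.
#' @param Om Mesophyll O2 partial pressure (mbar).
#' @param cm_fraction Mesophyll:ambient CO2 ratio for C4 leaves (0.37).
#' @export
c4_kinetics <- function(Vpmax = 120, Kp = 80, Vpr = 80, gs = 3, Vcmax = 60,
                        gamma = 0.5 / 2590, Rd = 0.6, Rm = 0.3, alpha = 0,
                        x = 0.4, Jmax = 400, Kc = 650, Ko = 450, Om = 210,
                        cm_fraction = 0.37) {
  stopifnot(Vpmax > 0, Kp > 0, Vpr > 0, gs > 0, Vcmax > 0, gamma > 0,
            Rd >= 0, Rm >= 0, alpha >= 0, alpha <= 1, x > 0, x < 1,
            Jmax > 0, Kc > 0, Ko > 0, Om > 0,
            cm_fraction > 0, cm_fraction <= 1)
  structure(list(Vpmax = Vpmax, Kp = Kp, Vpr = Vpr, gs = gs, Vcmax = Vcmax,
                 gamma = gamma, Rd = Rd, Rm = Rm, alpha = alpha, x = x,
                 Jmax = Jmax, Kc = Kc, Ko = Ko, Om = Om,
                 cm_fraction = cm_fraction), class = "c4_kinetics")
}

#' Carboxylation:oxygenation ratio for a C3 leaf
#'
#' Evaluates the Michaelis-Menten competition of CO2 and O2 at Rubisco:
#' \deqn{V_c = \frac{C_i}{C_i + K_c (1 + O/K_o)}, \qquad
#'       V_o = 0.21\,\frac{O}{O + K_o (1 + C_i/K_c)}, \qquad r = V_c/V_o}
#' with intercellular CO2 \eqn{C_i = } `ci_fraction` \eqn{\times} `ca`
#' (ubar) and O in mbar. r is strictly increasing in ambient CO2.
#'
#' @param ca Ambient CO2 partial pressure (ubar), positive.
#' @param k A [c3_kinetics()] parameter set.
#' @return A `ratio_result`: list with `r`, `branch`
#'   (`"rubisco_limited"` for C3) and `intermediates` (Ci, Vc, Vo).
#' @examples
#' c3_ratio(380)$r  # about 4.33
#' @export
c3_ratio <- function(ca, k = c3_kinetics()) {
  if (!is.numeric(ca) || length(ca) != 1 || !is.finite(ca) || ca <= 0) {
    stop("ca must be a single positive number (ubar)")
  }
  Ci <- k$ci_fraction * ca
  Vc <- Ci / (Ci + k$Kc * (1 + k$O2 / k$Ko))
  Vo <- k$vo_scale * k$O2 / (k$O2 + k$Ko * (1 + Ci / k$Kc))
  structure(list(r = Vc / Vo, branch = "rubisco_limited",
                 intermediates = c(Ci = Ci, Vc = Vc, Vo = Vo)),
            class = "ratio_result")
}

#' Carboxylation:oxygenation ratio for a C4 leaf
#'
#' Evaluates the two-cell CO2-concentrating model. With mesophyll CO2
#' \eqn{C_m = } `cm_fraction` \eqn{\times} `ca`:
#' \deqn{V_p = \min\!\big(C_m V_{pmax}/(C_m+K_p),\ V_{pr}\big)}
#' \deqn{A_c = \min\!\big(V_p + g_s C_m - R_m,\ V_{cmax} - R_d\big), \quad
#'       A_j = (1-x)J_t/3 - R_d, \quad A = \min(A_c, A_j)}
#' If the PEP-carboxylation arm is limiting (\eqn{A_c = V_p + g_s C_m - R_m}),
#' the bundle-sheath CO2 is
#' \deqn{C_s = \frac{\gamma O_s + K_c(1+O_s/K_o)\,(A_c+R_d)/V_{cmax}}
#'                  {1-(A_c+R_d)/V_{cmax}}, \qquad r = \frac{C_s}{2\gamma O_s}}
#' otherwise (Rubisco or electron-transport limited)
#' \deqn{r = \frac{g_s C_m + V_p - A - R_m}
#'                {2\gamma(\alpha A/0.047 + O_m g_s)}.}
#' Unit convention (the one that closes the published parameterization):
#' products of `gs` with a partial pressure take the pressure in mbar
#' (equivalently bar with gs in mmol, giving umol fluxes);
#' \eqn{\gamma O_s} terms take \eqn{O_s} in ubar. With `alpha = 0` there is
#' no bundle-sheath PSII O2 evolution, so \eqn{O_s = O_m}.
#'
#' @param ca Ambient CO2 partial pressure (ubar), positive.
#' @param k A [c4_kinetics()] parameter set.
#' @param tol Relative tolerance of the branch (equality) test.
#' @return A `ratio_result`: list with `r`, `branch`
#'   (`"pep_limited_equality"`, `"rubisco_limited"` or
#'   `"electron_transport_limited"`) and `intermediates`
#'   (Cm, Vp, Ac, Aj, A, Cs, Os, Jt).
#' @examples
#' c4_ratio(380)$r  # about 70.73
#' @export
c4_ratio <- function(ca, k = c4_kinetics(), tol = 1e-9) {
  if (!is.numeric(ca) || length(ca) != 1 || !is.finite(ca) || ca <= 0) {
    stop("ca must be a single positive number (ubar)")
  }
  Cm <- k$cm_fraction * ca                      # ubar
  Vp <- min(Cm * k$Vpmax / (Cm + k$Kp), k$Vpr)
  gsCm <- k$gs * Cm * 1e-3                      # gs x pressure in mbar
  pep_arm <- Vp + gsCm - k$Rm
  Ac <- min(pep_arm, k$Vcmax - k$Rd)
  Jt <- k$Jmax                                  # saturating light
  Aj <- (1 - k$x) * Jt / 3 - k$Rd
  A <- min(Ac, Aj)
  Os <- k$Om                                    # mbar; alpha = 0 convention
  Os_ubar <- Os * 1e3
  if (abs(Ac - pep_arm) <= tol * max(1, abs(Ac))) {
    xx <- (Ac + k$Rd) / k$Vcmax
    if (abs(1 - xx) <= tol) {
      stop("pep_limited_equality branch singular: (Ac + Rd)/Vcmax = 1")
    }
    Cs <- (k$gamma * Os_ubar + k$Kc * (1 + Os / k$Ko) * xx) / (1 - xx)
    r <- Cs / (2 * k$gamma * Os_ubar)
    branch <- "pep_limited_equality"
  } else {
    denom <- 2 * k$gamma * (k$alpha * A / 0.047 + k$Om * k$gs)
    r <- (gsCm + Vp - A - k$Rm) / denom
    Cs <- r * 2 * k$gamma * Os_ubar
    branch <- if (A == Aj && Aj < Ac) "electron_transport_limited"
              else "rubisco_limited"
  }
  structure(list(r = r, branch = branch,
                 intermediates = c(Cm = Cm, Vp = Vp, Ac = Ac, Aj = Aj, A = A,
                                   Cs = Cs, Os = Os, Jt = Jt)),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result>  r = %.6g  (%s)\n", x$r, x$branch))
  invisible(x)
}

#' Carboxylation:oxygenation ratios over a CO2 grid
#'
#' Tabulates `c3_ratio()` and `c4_ratio()` over ambient CO2 values; the
#' default grid is the five standard concentrations 100-1000 ubar.
#'
#' @param ca Numeric vector of ambient CO2 partial pressures (ubar).
#' @param c3,c4 Parameter sets.
#' @return Tibble with columns `ca_ubar`, `r_c3`, `r_c4`, `branch_c4`.
#' @export
ratio_table <- function(ca = c(100, 380, 550, 800, 1000),
                        c3 = c3_kinetics(), c4 = c4_kinetics()) {
  rows <- lapply(ca, function(a) {
    r3 <- c3_ratio(a, c3)
    r4 <- c4_ratio(a, c4)
    tibble::tibble(ca_ubar = a, r_c3 = r3$r, r_c4 = r4$r,
                   branch_c4 = r4$branch)
  })
  dplyr::bind_rows(rows)
}

#' Build the combined Rubisco reaction
#'
#' Carboxylation (RuBP + CO2 + H2O -> 2 PGA) and oxygenation
#' (RuBP + O2 -> PGA + PGCA) proceed at a fixed ratio r under fixed CO2 and
#' O2 partial pressures, so they are merged into the single irreversible
#' reaction
#' \deqn{(r+1)\,\mathrm{RuBP} + r\,\mathrm{CO_2} + r\,\mathrm{H_2O} +
#'       \mathrm{O_2} \rightarrow (2r+1)\,\mathrm{PGA} + \mathrm{PGCA}}
#' which conserves C, H, O and P for any r > 0.
#'
#' @param r Carboxylation:oxygenation ratio, positive.
#' @param species_ids Named character vector mapping the roles `RuBP`,
#'   `CO2`, `H2O`, `O2`, `PGA`, `PGCA` to metabolite ids.
#' @param reaction_id,name Identifiers of the constructed reaction.
#' @param enzyme_ids EC annotation (Rubisco).
#' @return One-row reaction tibble with a `stoichiometry` list column, as
#'   consumed by [install_rubisco()].
#' @export
build_combined_rubisco <- function(r, species_ids,
                                   reaction_id = "R_rubisco",
                                   name = "Rubisco (combined carboxylation/oxygenation)",
                                   enzyme_ids = "4.1.1.39") {
  stopifnot(is.numeric(r), length(r) == 1, is.finite(r), r > 0)
  roles <- c("RuBP", "CO2", "H2O", "O2", "PGA", "PGCA")
  missing <- setdiff(roles, names(species_ids))
  if (length(missing)) {
    stop("missing role(s) in species_ids: ", paste(missing, collapse = ", "))
  }
  sto <- tibble::tibble(
    reaction_id = reaction_id,
    metabolite_id = unname(species_ids[roles]),
    coefficient = c(-(r + 1), -r, -r, -1, 2 * r + 1, 1))
  tibble::tibble(id = reaction_id, name = name,
                 lower_bound = 0, upper_bound = 1000,
                 enzyme_ids = list(enzyme_ids),
                 subsystem = "Calvin cycle",
                 stoichiometry = list(sto))
}

#' Install the combined Rubisco reaction into a model
#'
#' Removes any split carboxylase/oxygenase reactions present in the target
#' compartment (and any previously installed combined reaction, so the
#' operation is replacement, not accumulation) and inserts the combined
#' reaction parameterized by r. Role species are located in
#' `target_compartment` by conventional base names
#' (`rubp`, `co2`, `h2o`, `o2`, `pga`, `pgca`) unless `species_ids` is
#' given explicitly.
#'
#' @param model A `stoich_model`.
#' @param r Carboxylation:oxygenation ratio.
#' @param target_compartment Compartment housing Rubisco (e.g.
#'   `"M.chloroplast"` for C3, `"BS.chloroplast"` for C4).
#' @param species_ids Optional explicit role map (see
#'   [build_combined_rubisco()]).
#' @param reaction_id Id for the combined reaction.
#' @param split_ids Ids of split carboxylase/oxygenase reactions to remove
#'   if present.
#' @return A new validated `stoich_model`.
#' @export
install_rubisco <- function(model, r, target_compartment,
                            species_ids = NULL,
                            reaction_id = "R_rubisco",
                            split_ids = c("R_rubisco_c", "R_rubisco_o")) {
  if (is.null(species_ids)) {
    find_sp <- function(base) {
      hit <- model$metabolites$id[
        model$metabolites$compartment == target_compartment &
          sub("_[^_]*$", "", model$metabolites$id) == base]
      if (length(hit) != 1) {
        stop("role species '", base, "' not found (or ambiguous) in compartment '",
             target_compartment, "'")
      }
      hit
    }
    species_ids <- c(RuBP = find_sp("rubp"), CO2 = find_sp("co2"),
                     H2O = find_sp("h2o"), O2 = find_sp("o2"),
                     PGA = find_sp("pga"), PGCA = find_sp("pgca"))
  }
  drop <- intersect(c(split_ids, reaction_id), model$reactions$id)
  model$reactions <- model$reactions[!model$reactions$id %in% drop, ]
  model$stoichiometry <-
    model$stoichiometry[!model$stoichiometry$reaction_id %in% drop, ]
  model$objective <- model$objective[!model$objective$reaction_id %in% drop, ]
  new <- build_combined_rubisco(r, species_ids, reaction_id = reaction_id)
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    new[, c("id", "name", "lower_bound", "upper_bound", "enzyme_ids", "subsystem")])
  model$stoichiometry <- dplyr::bind_rows(model$stoichiometry,
                                          new$stoichiometry[[1]])
  validate_model(model)
  model
}
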