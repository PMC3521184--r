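#' Fixture specification for the toy C3/C4 generators
#'
#' Collects the knobs of the deterministic toy-model generators. The
#' defaults are the study conditions every analysis in the package assumes:
#' the combined-Rubisco ratio r computed from the leaf kinetics at ambient
#' CO2 380 ubar, a bounded (open) bundle-sheath-to-mesophyll CO2 leak, and
#' a photon supply of 1000 flux units.
#'
#' @param system `"c3"` or `"c4"`.
#' @param subtype C4 decarboxylation subtype wiring; `"ALL"` keeps all three
#'   decarboxylases open (subtype restriction is usually applied later via
#'   [subtype_scenario()]).
#' @param r Combined-Rubisco carboxylation:oxygenation ratio. `NULL` =
#'   compute from [c3_ratio()] / [c4_ratio()] at `ca`.
#' @param ca Ambient CO2 (ubar) used when `r` is `NULL`.
#' @param leak_upper Upper bound of the bundle-sheath CO2 leak (mmol/gDW/hr).
#' @param photon_bound Photon uptake bound (flux units).
#' @param include_split_rubisco Build with separate carboxylase/oxygenase
#'   reactions instead of the combined reaction (for exercising
#'   [install_rubisco()]).
#' @param oaa_cap Upper bound of the mesophyll-to-bundle-sheath oxaloacetate
#'   transfer (the PCK-subtype feed); the anatomical capacity of this
#'   shuttle is what keeps the PCK route from carrying the whole flux.
#' @param tca_bounds Bounds clamped onto TCA-cycle reactions (C3 model),
#'   the respiration restriction applied to the improved models.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(system = c("c3", "c4"),
                         subtype = c("ALL", "NADP_ME", "NAD_ME", "PCK"),
                         r = NULL, ca = 380, leak_upper = 10,
                         photon_bound = 1000, include_split_rubisco = FALSE,
                         oaa_cap = 40, tca_bounds = c(-50, 50)) {
  system <- match.arg(system)
  subtype <- match.arg(subtype)
  if (is.null(r)) {
    r <- if (system == "c3") c3_ratio(ca)$r else c4_ratio(ca)$r
  }
  stopifnot(r > 0, leak_upper >= 0, photon_bound >= 0, oaa_cap >= 0,
            tca_bounds[1] <= tca_bounds[2])
  structure(list(system = system, subtype = subtype, r = r, ca = ca,
                 leak_upper = leak_upper, photon_bound = photon_bound,
                 include_split_rubisco = include_split_rubisco,
                 oaa_cap = oaa_cap, tca_bounds = tca_bounds),
            class = "fixture_spec")
}

# Elemental formulas of the toy species (lumping convention: reduced
# cofactors carry the proton, i.e. "nadph" = NADPH + H+; photons carry no
# atoms). Frozen reference table for the atom-balance audit.
toy_formulas <- c(
  co2 = "CO2", o2 = "O2", h2o = "H2O", h2o2 = "H2O2", photon = "",
  pi = "H3O4P", ppi = "H4O7P2",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2", amp = "C10H14N5O7P",
  nadp = "C21H28N7O17P3", nadph = "C21H30N7O17P3",
  nad = "C21H27N7O14P2", nadh = "C21H29N7O14P2",
  rubp = "C5H12O11P2", pga = "C3H7O7P", gap = "C3H7O6P", pgca = "C2H5O6P",
  glyco = "C2H4O3", glyox = "C2H2O3", glyce = "C3H6O4",
  f6p = "C6H13O9P", e4p = "C4H9O7P", x5p = "C5H11O8P", r5p = "C5H11O8P",
  s7p = "C7H15O10P", ru5p = "C5H11O8P", s6p = "C12H23O14P",
  sucrose = "C12H22O11", starch = "C6H10O5",
  pyr = "C3H4O3", oaa = "C4H4O5", mal = "C4H6O5",
  cit = "C6H8O7", icit = "C6H8O7", succ = "C4H6O4", pep = "C3H5O6P",
  asp = "C4H7NO4", ala = "C3H7NO2", glu = "C5H9NO4", akg = "C5H6O5",
  nh3 = "H3N", gly = "C2H5NO2", biomass = "C12H24O17P2")

toy_compartments <- c(ext = "ext",
                      Mchl = "M.chloroplast", Mcyt = "M.cytosol",
                      Mmit = "M.mitochondrion",
                      BSchl = "BS.chloroplast", BScyt = "BS.cytosol",
                      BSmit = "BS.mitochondrion",
                      pd = "pd")

# assemble a stoich_model from rows of (id, eq, lb, ub, ec, subsystem)
assemble_toy <- function(rows, objective, label, formula_overrides = NULL) {
  rxn <- dplyr::bind_rows(rows)
  eqs <- lapply(rxn$eq, parse_equation)
  sto <- dplyr::bind_rows(purrr::map2(rxn$id, eqs, function(id, e) {
    tibble::tibble(reaction_id = id, metabolite_id = e$metabolite_id,
                   coefficient = e$coefficient)
  }))
  mid <- sort(unique(sto$metabolite_id))
  base <- sub("_[^_]*$", "", mid)
  tag <- sub("^.*_", "", mid)
  formulas <- toy_formulas
  if (!is.null(formula_overrides)) formulas[names(formula_overrides)] <- formula_overrides
  met <- tibble::tibble(
    id = mid, name = base,
    compartment = unname(toy_compartments[tag]),
    formula = unname(formulas[base]),
    is_exchange_species = tag == "ext")
  stoich_model(met,
               tibble::tibble(id = rxn$id, name = rxn$id,
                              lower_bound = rxn$lb, upper_bound = rxn$ub,
                              enzyme_ids = lapply(rxn$ec, function(e) {
                                if (is.na(e) || !nzchar(e)) character()
                                else trimws(strsplit(e, ";")[[1]])
                              }),
                              subsystem = rxn$sub),
               sto, objective, model_label = label)
}

rx <- function(id, eq, lb = 0, ub = 1000, ec = "", sub = "") {
  tibble::tibble(id = id, eq = eq, lb = lb, ub = ub, ec = ec, sub = sub)
}

# Calvin cycle + photorespiratory C2 chain, shared between the C3
# chloroplast and the C4 bundle-sheath chloroplast. `t` = compartment tag,
# `sfx` = reaction-id suffix ("" for C3, "_bs" for C4).
calvin_rows <- function(t, sfx = "") {
  s <- function(b) paste0(b, "_", t)
  list(
    rx(paste0("R_pga_red", sfx),
       sprintf("%s + %s + %s -> %s + %s + %s + %s",
               s("pga"), s("atp"), s("nadph"), s("gap"), s("adp"), s("pi"), s("nadp")),
       ec = "1.2.1.13", sub = "Calvin cycle"),
    rx(paste0("R_ald", sfx),
       sprintf("2 %s + %s -> %s + %s", s("gap"), s("h2o"), s("f6p"), s("pi")),
       ec = "4.1.2.13", sub = "Calvin cycle"),
    rx(paste0("R_tkt1", sfx),
       sprintf("%s + %s -> %s + %s", s("f6p"), s("gap"), s("x5p"), s("e4p")),
       ec = "2.2.1.1", sub = "Calvin cycle"),
    rx(paste0("R_tal", sfx),
       sprintf("%s + %s -> %s + %s", s("e4p"), s("f6p"), s("s7p"), s("gap")),
       ec = "2.2.1.2", sub = "Pentose phosphate pathway"),
    rx(paste0("R_tkt2", sfx),
       sprintf("%s + %s -> %s + %s", s("s7p"), s("gap"), s("r5p"), s("x5p")),
       ec = "2.2.1.1", sub = "Calvin cycle"),
    rx(paste0("R_rpe", sfx), sprintf("%s -> %s", s("x5p"), s("ru5p")),
       lb = -1000, ec = "5.1.3.1", sub = "Calvin cycle"),
    rx(paste0("R_rpi", sfx), sprintf("%s -> %s", s("r5p"), s("ru5p")),
       lb = -1000, ec = "5.3.1.6", sub = "Calvin cycle"),
    rx(paste0("R_prk", sfx),
       sprintf("%s + %s -> %s + %s", s("ru5p"), s("atp"), s("rubp"), s("adp")),
       ec = "2.7.1.19", sub = "Calvin cycle"),
    rx(paste0("R_starch", sfx),
       sprintf("%s + %s + %s -> %s + %s + 2 %s",
               s("f6p"), s("atp"), s("h2o"), s("starch"), s("adp"), s("pi")),
       ec = "2.4.1.18", sub = "Starch biosynthesis"),
    # photorespiratory C2 cycle; the phosphoglycolate phosphatase step has
    # a redundant unspecific-phosphatase twin, its downstream steps do not
    rx(paste0("R_pglp", sfx),
       sprintf("%s + %s -> %s + %s", s("pgca"), s("h2o"), s("glyco"), s("pi")),
       ec = "3.1.3.18", sub = "Photorespiration"),
    rx(paste0("R_pglp_alt", sfx),
       sprintf("%s + %s -> %s + %s", s("pgca"), s("h2o"), s("glyco"), s("pi")),
       sub = "Photorespiration"),
    rx(paste0("R_lox", sfx),
       sprintf("%s + %s -> %s + %s", s("glyco"), s("o2"), s("glyox"), s("h2o2")),
       ec = "1.1.3.15", sub = "Photorespiration"),
    rx(paste0("R_cat", sfx),
       sprintf("%s -> %s + 0.5 %s", s("h2o2"), s("h2o"), s("o2")),
       ec = "1.11.1.6", sub = "Photorespiration"),
    rx(paste0("R_c2", sfx),
       sprintf("2 %s + %s -> %s + %s + %s",
               s("glyox"), s("nadph"), s("glyce"), s("co2"), s("nadp")),
       sub = "Photorespiration"),
    rx(paste0("R_glyk", sfx),
       sprintf("%s + %s -> %s + %s", s("glyce"), s("atp"), s("pga"), s("adp")),
       ec = "2.7.1.31", sub = "Photorespiration"))
}

rubisco_rows <- function(t, r, split, sfx = "") {
  s <- function(b) paste0(b, "_", t)
  if (split) {
    list(
      rx("R_rubisco_c",
         sprintf("%s + %s + %s -> 2 %s", s("rubp"), s("co2"), s("h2o"), s("pga")),
         ec = "4.1.1.39", sub = "Calvin cycle"),
      rx("R_rubisco_o",
         sprintf("%s + %s -> %s + %s", s("rubp"), s("o2"), s("pga"), s("pgca")),
         ec = "4.1.1.39", sub = "Calvin cycle"))
  } else {
    co <- function(x) sprintf("%.17g", x)
    list(rx("R_rubisco",
            sprintf("%s %s + %s %s + %s %s + %s -> %s %s + %s",
                    co(r + 1), s("rubp"), co(r), s("co2"), co(r), s("h2o"),
                    s("o2"), co(2 * r + 1), s("pga"), s("pgca")),
            ec = "4.1.1.39", sub = "Calvin cycle"))
  }
}

light_rows <- function(t, sfx = "") {
  s <- function(b) paste0(b, "_", t)
  list(
    rx(paste0("R_light", sfx),
       sprintf("8 %s + 2 %s + 2 %s + 2 %s -> %s + 2 %s + 2 %s",
               s("photon"), s("nadp"), s("adp"), s("pi"),
               s("o2"), s("nadph"), s("atp")),
       sub = "Light reactions"),
    rx(paste0("R_cyclic", sfx),
       sprintf("%s + %s + %s -> %s + %s",
               s("photon"), s("adp"), s("pi"), s("atp"), s("h2o")),
       sub = "Light reactions"))
}

sucrose_rows <- function(t, sfx = "") {
  s <- function(b) paste0(b, "_", t)
  list(
    rx(paste0("R_sps", sfx),
       sprintf("4 %s + 2 %s -> %s + 3 %s", s("gap"), s("h2o"), s("s6p"), s("pi")),
       ec = "2.4.1.14", sub = "Sucrose biosynthesis"),
    rx(paste0("R_spp", sfx),
       sprintf("%s + %s -> %s + %s", s("s6p"), s("h2o"), s("sucrose"), s("pi")),
       ec = "3.1.3.24", sub = "Sucrose biosynthesis"),
    rx(paste0("R_spp_alt", sfx),
       sprintf("%s + %s -> %s + %s", s("s6p"), s("h2o"), s("sucrose"), s("pi")),
       sub = "Sucrose biosynthesis"))
}

# reversible 1:1 transporter
tr <- function(id, from, to, lb = -1000, ub = 1000, sub = "Transport") {
  rx(id, sprintf("%s -> %s", from, to), lb = lb, ub = ub, sub = sub)
}
# inter-cell transporter pair through the plasmodesmatal interface pool;
# the two-step path is what makes the two cells less closely connected
# than the interior of either cell
pd_pair <- function(id, base, from_tag, to_tag, lb = 0, ub = 1000) {
  dplyr::bind_rows(
    tr(paste0(id, "_out"), paste0(base, "_", from_tag), paste0(base, "_pd"),
       lb = lb, ub = ub),
    tr(paste0(id, "_in"), paste0(base, "_pd"), paste0(base, "_", to_tag),
       lb = lb, ub = ub))
}
# ATP/ADP antiporter between a compartment and its cytosol
antiport <- function(id, t_in, t_cyt) {
  rx(id, sprintf("atp_%s + adp_%s -> atp_%s + adp_%s", t_in, t_cyt, t_cyt, t_in),
     lb = -1000, ub = 1000, sub = "Transport")
}

#' Toy C3 stoichiometric model
#'
#' A deterministic single-cell (mesophyll) network embodying the structure
#' the comparative analysis assumes: light reactions (linear and cyclic),
#' the combined Rubisco reaction at the C3 ratio r, PGA reduction and RuBP
#' regeneration through transketolase/transaldolase/epimerase/isomerase/
#' phosphoribulokinase steps, a photorespiratory C2 cycle that releases CO2,
#' transitory starch and sucrose sinks, a TCA cycle clamped to the
#' respiration-restricting bounds, and exchanges for CO2, O2, water, photons,
#' sucrose and biomass. Reactions carry the EC numbers used by the enzyme
#' knockout panel. The fixture is feasible with positive biomass at the
#' default photon supply, and every internal reaction is elementally
#' balanced (see [audit_atom_balance()]).
#'
#' @param spec A [fixture_spec()] with `system = "c3"`.
#' @return A validated `stoich_model` labelled `"C3"` with a biomass
#'   objective.
#' @export
make_toy_c3 <- function(spec = fixture_spec("c3")) {
  stopifnot(inherits(spec, "fixture_spec"), spec$system == "c3")
  rows <- c(
    list(
      rx("EX_photon", "photon_ext ->", lb = -spec$photon_bound, ub = 0,
         sub = "Exchange"),
      rx("EX_co2", "co2_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_o2", "o2_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_h2o", "h2o_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_sucrose", "sucrose_ext ->", sub = "Exchange"),
      rx("EX_biomass", "biomass_ext ->", sub = "Exchange"),
      rx("EX_pi", "pi_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_nh3", "nh3_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      tr("T_pi_ext", "pi_ext", "pi_Mcyt"),
      tr("T_nh3", "nh3_ext", "nh3_Mcyt"),
      tr("T_photon", "photon_ext", "photon_Mchl", lb = 0),
      tr("T_co2", "co2_ext", "co2_Mcyt"),
      tr("T_co2_chl", "co2_Mcyt", "co2_Mchl"),
      tr("T_co2_mit", "co2_Mcyt", "co2_Mmit"),
      tr("T_o2", "o2_ext", "o2_Mcyt"),
      tr("T_o2_chl", "o2_Mcyt", "o2_Mchl"),
      tr("T_o2_mit", "o2_Mcyt", "o2_Mmit"),
      tr("T_h2o", "h2o_ext", "h2o_Mcyt"),
      tr("T_h2o_chl", "h2o_Mcyt", "h2o_Mchl"),
      tr("T_h2o_mit", "h2o_Mcyt", "h2o_Mmit"),
      tr("T_gap", "gap_Mchl", "gap_Mcyt"),
      antiport("T_atp_chl", "Mchl", "Mcyt"),
      tr("T_pi_chl", "pi_Mchl", "pi_Mcyt"),
      antiport("T_atp_mit", "Mmit", "Mcyt"),
      tr("T_pi_mit", "pi_Mmit", "pi_Mcyt"),
      tr("T_pyr_mit", "pyr_Mcyt", "pyr_Mmit", lb = 0),
      tr("T_suc", "sucrose_Mcyt", "sucrose_ext", lb = 0)),
    light_rows("Mchl"),
    rubisco_rows("Mchl", spec$r, spec$include_split_rubisco),
    calvin_rows("Mchl"),
    sucrose_rows("Mcyt"),
    list(
      # glycolysis split at PEP so the anaplerotic branch has its node
      rx("R_glyc",
         "gap_Mcyt + pi_Mcyt + nad_Mcyt + adp_Mcyt -> pep_Mcyt + atp_Mcyt + nadh_Mcyt + h2o_Mcyt",
         sub = "Glycolysis"),
      rx("R_pk", "pep_Mcyt + adp_Mcyt -> pyr_Mcyt + atp_Mcyt",
         ec = "2.7.1.40", sub = "Glycolysis"),
      rx("R_pepc_ana",
         "pep_Mcyt + co2_Mcyt + h2o_Mcyt -> oaa_Mcyt + pi_Mcyt",
         ec = "4.1.1.31", sub = "Anaplerosis"),
      rx("R_mdh_cyt", "oaa_Mcyt + nadh_Mcyt -> mal_Mcyt + nad_Mcyt",
         lb = -1000, ec = "1.1.1.37", sub = "Anaplerosis"),
      tr("T_mal_mit", "mal_Mcyt", "mal_Mmit"),
      rx("R_mdh_mit", "mal_Mmit + nad_Mmit -> oaa_Mmit + nadh_Mmit",
         lb = -1000, ec = "1.1.1.37", sub = "TCA cycle"),
      # glyoxylate-cycle branch tying the TCA pool to photorespiration
      rx("R_icl", "icit_Mmit -> succ_Mmit + glyox_Mmit",
         ec = "4.1.3.1", sub = "Glyoxylate and dicarboxylate metabolism"),
      rx("R_sdh", "succ_Mmit + 0.5 o2_Mmit -> mal_Mmit",
         ec = "1.3.5.1", sub = "TCA cycle"),
      tr("T_glyox_mit", "glyox_Mmit", "glyox_Mcyt", lb = 0),
      rx("R_ggat", "glyox_Mcyt + glu_Mcyt -> gly_Mcyt + akg_Mcyt",
         ec = "2.6.1.4", sub = "Nitrogen metabolism"),
      rx("R_starch_deg", "starch_Mchl + pi_Mchl -> f6p_Mchl",
         ec = "2.4.1.1", sub = "Starch degradation"),
      # nitrogen assimilation and the amino-acid biomass precursors
      rx("R_gdh", "akg_Mcyt + nh3_Mcyt + nadh_Mcyt -> glu_Mcyt + h2o_Mcyt + nad_Mcyt",
         ec = "1.4.1.2", sub = "Nitrogen metabolism"),
      rx("R_asat", "oaa_Mcyt + glu_Mcyt -> asp_Mcyt + akg_Mcyt",
         ec = "2.6.1.1", sub = "Nitrogen metabolism"),
      rx("R_alat", "pyr_Mcyt + glu_Mcyt -> ala_Mcyt + akg_Mcyt",
         ec = "2.6.1.2", sub = "Nitrogen metabolism"),
      # carboxylating malic enzyme: anaplerotic alternative to PEPC
      rx("R_me", "mal_Mcyt + nad_Mcyt -> pyr_Mcyt + co2_Mcyt + nadh_Mcyt",
         lb = -1000, ec = "1.1.1.39", sub = "Anaplerosis"),
      rx("R_pdh_cs",
         "pyr_Mmit + oaa_Mmit + nad_Mmit + h2o_Mmit -> cit_Mmit + co2_Mmit + nadh_Mmit",
         lb = spec$tca_bounds[1], ub = spec$tca_bounds[2],
         ec = "2.3.3.1", sub = "TCA cycle"),
      rx("R_aco", "cit_Mmit -> icit_Mmit",
         lb = spec$tca_bounds[1], ub = spec$tca_bounds[2],
         ec = "4.2.1.3", sub = "TCA cycle"),
      rx("R_tca2",
         "icit_Mmit + o2_Mmit + 2 nad_Mmit -> oaa_Mmit + 2 co2_Mmit + 2 nadh_Mmit",
         lb = spec$tca_bounds[1], ub = spec$tca_bounds[2],
         ec = "1.1.1.41", sub = "TCA cycle"),
      rx("R_oxphos",
         "nadh_Mmit + 0.5 o2_Mmit + 2 adp_Mmit + 2 pi_Mmit -> nad_Mmit + 2 atp_Mmit + 3 h2o_Mmit",
         sub = "Oxidative phosphorylation"),
      rx("R_ngam",
         "atp_Mcyt + h2o_Mcyt -> adp_Mcyt + pi_Mcyt",
         sub = "Maintenance"),
      rx("R_biomass",
         "2 gap_Mcyt + starch_Mchl + asp_Mcyt + ala_Mcyt + gly_Mcyt + 10 atp_Mcyt + 10 h2o_Mcyt -> biomass_ext + 10 adp_Mcyt + 10 pi_Mcyt",
         sub = "Biomass")))
  # biomass = 2 GAP + starch + Asp + Ala + Gly (amino-acid precursors)
  assemble_toy(rows, c(EX_biomass = 1), "C3",
               formula_overrides = c(biomass = "C21H43N3O25P2"))
}

#' Toy C4 stoichiometric model
#'
#' A deterministic two-cell (mesophyll + bundle sheath) network: mesophyll
#' PEPC fixes CO2 into oxaloacetate, malate (or oxaloacetate, for the PCK
#' route) moves to the bundle sheath, three decarboxylases with the
#' conventional ids `R00216` (NADP-ME, bundle-sheath chloroplast), `R00214`
#' (NAD-ME, bundle-sheath mitochondrion) and `R00341` (PCK, bundle-sheath
#' cytosol) release CO2 around Rubisco, pyruvate returns to the mesophyll
#' where PPDK regenerates PEP at a 2-ATP-equivalent cost, and the bundle
#' sheath runs the Calvin cycle with the combined Rubisco reaction at the
#' (high) C4 ratio r. The bundle-sheath light reactions are cyclic only
#' (no PSII, hence no O2 evolution there), CO2 can leak from bundle sheath
#' back to mesophyll up to `leak_upper`, starch is synthesized only in the
#' bundle sheath, and there is no direct CO2 path from the air into the
#' bundle sheath (the diffusion barrier that makes PEPC essential). A
#' PGA/triose-phosphate shuttle lets PGA be reduced in the mesophyll.
#'
#' @param spec A [fixture_spec()] with `system = "c4"`. `spec$subtype`
#'   other than `"ALL"` closes the two non-selected decarboxylases at build
#'   time.
#' @return A validated `stoich_model` labelled `"C4"` with a biomass
#'   objective.
#' @export
make_toy_c4 <- function(spec = fixture_spec("c4")) {
  stopifnot(inherits(spec, "fixture_spec"), spec$system == "c4")
  dec_ub <- function(which) {
    if (spec$subtype %in% c("ALL", which)) 1000 else 0
  }
  rows <- c(
    list(
      rx("EX_photon", "photon_ext ->", lb = -spec$photon_bound, ub = 0,
         sub = "Exchange"),
      rx("EX_co2", "co2_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_o2", "o2_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_h2o", "h2o_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_sucrose", "sucrose_ext ->", sub = "Exchange"),
      rx("EX_biomass", "biomass_ext ->", sub = "Exchange"),
      rx("EX_pi", "pi_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      rx("EX_nh3", "nh3_ext ->", lb = -1000, ub = 1000, sub = "Exchange"),
      tr("T_pi_bs", "pi_ext", "pi_BScyt"),
      tr("T_pi_cells", "pi_Mcyt", "pi_BScyt"),
      tr("T_nh3_bs", "nh3_ext", "nh3_BScyt"),
      tr("T_photon_m", "photon_ext", "photon_Mchl", lb = 0),
      tr("T_photon_bs", "photon_ext", "photon_BSchl", lb = 0),
      # mesophyll gas/water plumbing; no co2 route into the bundle sheath
      tr("T_co2_m", "co2_ext", "co2_Mcyt"),
      tr("T_o2_m", "o2_ext", "o2_Mcyt"),
      tr("T_o2_mchl", "o2_Mcyt", "o2_Mchl"),
      tr("T_h2o_m", "h2o_ext", "h2o_Mcyt"),
      tr("T_h2o_mchl", "h2o_Mcyt", "h2o_Mchl"),
      tr("T_o2_bs", "o2_ext", "o2_BScyt"),
      tr("T_h2o_bs", "h2o_ext", "h2o_BScyt"),
      # mesophyll chloroplast shuttle plumbing
      antiport("T_atp_mchl", "Mchl", "Mcyt"),
      tr("T_pi_mchl", "pi_Mchl", "pi_Mcyt"),
      tr("T_gap_mchl", "gap_Mchl", "gap_Mcyt"),
      tr("T_pga_mchl", "pga_Mcyt", "pga_Mchl"),
      tr("T_oaa_mchl", "oaa_Mcyt", "oaa_Mchl"),
      tr("T_mal_mchl", "mal_Mchl", "mal_Mcyt"),
      tr("T_pyr_mchl", "pyr_Mcyt", "pyr_Mchl", lb = 0),
      tr("T_pep_mchl", "pep_Mchl", "pep_Mcyt"),
      # inter-cell traffic through the plasmodesmatal interface
      pd_pair("T_mal_mbs", "mal", "Mcyt", "BScyt"),
      # forward (M -> BS) capacity caps the PCK feed; return flow is free
      pd_pair("T_oaa_mbs", "oaa", "Mcyt", "BScyt", lb = -1000,
              ub = spec$oaa_cap),
      pd_pair("T_pyr_bsm", "pyr", "BScyt", "Mcyt"),
      pd_pair("T_pep_bsm", "pep", "BScyt", "Mcyt"),
      # aspartate/alanine shuttle: the amino-acid counterpart of the
      # malate/pyruvate legs; the amino group cycles back via alanine
      pd_pair("T_asp_mbs", "asp", "Mcyt", "BScyt"),
      pd_pair("T_ala_bsm", "ala", "BScyt", "Mcyt"),
      pd_pair("T_pga_cells", "pga", "BScyt", "Mcyt", lb = -1000),
      pd_pair("T_gap_cells", "gap", "Mcyt", "BScyt", lb = -1000),
      rx("T_co2_leak", "co2_BScyt -> co2_Mcyt", lb = 0, ub = spec$leak_upper,
         sub = "Transport"),
      # bundle-sheath intra-cell plumbing
      antiport("T_atp_bschl", "BSchl", "BScyt"),
      tr("T_pi_bschl", "pi_BSchl", "pi_BScyt"),
      antiport("T_atp_bsmit", "BSmit", "BScyt"),
      tr("T_pi_bsmit", "pi_BSmit", "pi_BScyt"),
      tr("T_gap_bschl", "gap_BSchl", "gap_BScyt"),
      tr("T_pga_bschl", "pga_BScyt", "pga_BSchl"),
      tr("T_mal_bschl", "mal_BScyt", "mal_BSchl"),
      tr("T_oaa_bschl", "oaa_BScyt", "oaa_BSchl"),
      tr("T_pyr_bschl", "pyr_BSchl", "pyr_BScyt"),
      tr("T_co2_bschl", "co2_BScyt", "co2_BSchl"),
      tr("T_o2_bschl", "o2_BScyt", "o2_BSchl"),
      tr("T_h2o_bschl", "h2o_BScyt", "h2o_BSchl"),
      tr("T_mal_bsmit", "mal_BScyt", "mal_BSmit", lb = 0),
      tr("T_pyr_bsmit", "pyr_BSmit", "pyr_BScyt"),
      tr("T_co2_bsmit", "co2_BSmit", "co2_BScyt"),
      tr("T_o2_bsmit", "o2_BScyt", "o2_BSmit"),
      tr("T_h2o_bsmit", "h2o_BScyt", "h2o_BSmit"),
      tr("T_suc_bs", "sucrose_BScyt", "sucrose_ext", lb = 0)),
    light_rows("Mchl", "_m"),
    list(
      # mesophyll C4 cycle
      rx("R_pepc",
         "pep_Mcyt + co2_Mcyt + h2o_Mcyt -> oaa_Mcyt + pi_Mcyt",
         ec = "4.1.1.31", sub = "C4 photosynthesis"),
      rx("R_mdh_m", "oaa_Mchl + nadph_Mchl -> mal_Mchl + nadp_Mchl",
         lb = -1000, ec = "1.1.1.82", sub = "C4 photosynthesis"),
      # bundle-sheath NADP-MDH: the malate/OAA valve that carries reducing
      # power into the bundle-sheath chloroplast for the NAD-ME/PCK modes
      rx("R_mdh_bs", "oaa_BSchl + nadph_BSchl -> mal_BSchl + nadp_BSchl",
         lb = -1000, ec = "1.1.1.82", sub = "C4 photosynthesis"),
      rx("R_ppdk",
         "pyr_Mchl + atp_Mchl + pi_Mchl -> pep_Mchl + amp_Mchl + ppi_Mchl",
         ec = "2.7.9.1", sub = "C4 photosynthesis"),
      rx("R_adk_m", "amp_Mchl + atp_Mchl -> 2 adp_Mchl", lb = -1000,
         ec = "2.7.4.3", sub = "C4 photosynthesis"),
      rx("R_ppa_m", "ppi_Mchl + h2o_Mchl -> 2 pi_Mchl",
         ec = "3.6.1.1", sub = "C4 photosynthesis"),
      # mesophyll arm of the PGA/triose-phosphate shuttle
      rx("R_pga_red_m",
         "pga_Mchl + atp_Mchl + nadph_Mchl -> gap_Mchl + adp_Mchl + pi_Mchl + nadp_Mchl",
         ec = "1.2.1.13", sub = "Calvin cycle"),
      # bundle-sheath light reactions: cyclic only (alpha = 0, no PSII)
      rx("R_cyclic_bs",
         "photon_BSchl + adp_BSchl + pi_BSchl -> atp_BSchl + h2o_BSchl",
         sub = "Light reactions"),
      # the three decarboxylases
      rx("R00216",
         "mal_BSchl + nadp_BSchl -> pyr_BSchl + co2_BSchl + nadph_BSchl",
         ub = dec_ub("NADP_ME"), ec = "1.1.1.40", sub = "C4 photosynthesis"),
      rx("R00214",
         "mal_BSmit + nad_BSmit -> pyr_BSmit + co2_BSmit + nadh_BSmit",
         ub = dec_ub("NAD_ME"), ec = "1.1.1.39", sub = "C4 photosynthesis"),
      rx("R00341",
         "oaa_BScyt + atp_BScyt -> pep_BScyt + co2_BScyt + adp_BScyt",
         ub = dec_ub("PCK"), ec = "4.1.1.32", sub = "C4 photosynthesis"),
      rx("R_oxphos_bs",
         "nadh_BSmit + 0.5 o2_BSmit + 2 adp_BSmit + 2 pi_BSmit -> nad_BSmit + 2 atp_BSmit + 3 h2o_BSmit",
         sub = "Oxidative phosphorylation"),
      # bundle-sheath primary metabolism mirroring the single-cell model:
      # glycolysis, TCA (respiration-restricted), N assimilation, starch
      # turnover
      rx("R_glyc_bs",
         "gap_BScyt + pi_BScyt + nad_BScyt + adp_BScyt -> pep_BScyt + atp_BScyt + nadh_BScyt + h2o_BScyt",
         sub = "Glycolysis"),
      rx("R_pk_bs", "pep_BScyt + adp_BScyt -> pyr_BScyt + atp_BScyt",
         ec = "2.7.1.40", sub = "Glycolysis"),
      rx("R_gdh_bs",
         "akg_BScyt + nh3_BScyt + nadh_BScyt -> glu_BScyt + h2o_BScyt + nad_BScyt",
         ec = "1.4.1.2", sub = "Nitrogen metabolism"),
      rx("R_pdh_cs_bs",
         "pyr_BSmit + oaa_BSmit + nad_BSmit + h2o_BSmit -> cit_BSmit + co2_BSmit + nadh_BSmit",
         lb = spec$tca_bounds[1], ub = spec$tca_bounds[2],
         ec = "2.3.3.1", sub = "TCA cycle"),
      rx("R_aco_bs", "cit_BSmit -> icit_BSmit",
         lb = spec$tca_bounds[1], ub = spec$tca_bounds[2],
         ec = "4.2.1.3", sub = "TCA cycle"),
      rx("R_tca2_bs",
         "icit_BSmit + o2_BSmit + 2 nad_BSmit -> oaa_BSmit + 2 co2_BSmit + 2 nadh_BSmit",
         lb = spec$tca_bounds[1], ub = spec$tca_bounds[2],
         ec = "1.1.1.41", sub = "TCA cycle"),
      rx("R_mdh_mit_bs", "mal_BSmit + nad_BSmit -> oaa_BSmit + nadh_BSmit",
         lb = -1000, ec = "1.1.1.37", sub = "TCA cycle"),
      rx("R_icl_bs", "icit_BSmit -> succ_BSmit + glyox_BSmit",
         ec = "4.1.3.1", sub = "Glyoxylate and dicarboxylate metabolism"),
      rx("R_sdh_bs", "succ_BSmit + 0.5 o2_BSmit -> mal_BSmit",
         ec = "1.3.5.1", sub = "TCA cycle"),
      tr("T_glyox_bsmit", "glyox_BSmit", "glyox_BScyt", lb = 0),
      rx("R_ggat_bs", "glyox_BScyt + glu_BScyt -> gly_BScyt + akg_BScyt",
         ec = "2.6.1.4", sub = "Nitrogen metabolism"),
      rx("R_starch_deg_bs", "starch_BSchl + pi_BSchl -> f6p_BSchl",
         ec = "2.4.1.1", sub = "Starch degradation"),
      rx("R_asat_m", "oaa_Mcyt + glu_Mcyt -> asp_Mcyt + akg_Mcyt",
         lb = -1000, ec = "2.6.1.1", sub = "C4 photosynthesis"),
      rx("R_alat_m", "ala_Mcyt + akg_Mcyt -> pyr_Mcyt + glu_Mcyt",
         lb = -1000, ec = "2.6.1.2", sub = "C4 photosynthesis"),
      rx("R_asat_bs", "asp_BScyt + akg_BScyt -> oaa_BScyt + glu_BScyt",
         lb = -1000, ec = "2.6.1.1", sub = "C4 photosynthesis"),
      rx("R_alat_bs", "pyr_BScyt + glu_BScyt -> ala_BScyt + akg_BScyt",
         lb = -1000, ec = "2.6.1.2", sub = "C4 photosynthesis"),
      rx("R_ngam_m",
         "atp_Mcyt + h2o_Mcyt -> adp_Mcyt + pi_Mcyt",
         sub = "Maintenance"),
      rx("R_ngam_bs",
         "atp_BScyt + h2o_BScyt -> adp_BScyt + pi_BScyt",
         sub = "Maintenance"),
      rx("R_biomass",
         "2 gap_BScyt + starch_BSchl + asp_BScyt + ala_BScyt + gly_BScyt + 10 atp_BScyt + 10 h2o_BScyt -> biomass_ext + 10 adp_BScyt + 10 pi_BScyt",
         sub = "Biomass")),
    rubisco_rows("BSchl", spec$r, spec$include_split_rubisco),
    calvin_rows("BSchl", "_bs"),
    sucrose_rows("BScyt", "_bs"))
  assemble_toy(rows, c(EX_biomass = 1), "C4",
               formula_overrides = c(biomass = "C21H43N3O25P2"))
}

#' Ortholog map between the toy C3 and C4 models
#'
#' Deterministic injective map from toy-C3 reaction ids to their toy-C4
#' counterparts, covering the shared core (exchanges, light reactions,
#' Rubisco and the Calvin/photorespiration chain -- the C3 mesophyll
#' chloroplast maps onto the C4 bundle-sheath chloroplast -- and the
#' sucrose branch). C4-specific reactions (PEPC, PPDK, decarboxylases,
#' inter-cell transporters) have no preimage.
#'
#' Reactions whose role is duplicated across the two C4 cells (PGA
#' reduction, cyclic photophosphorylation, aspartate transaminase) are
#' omitted: a one-to-one map cannot represent a one-to-many ortholog
#' relation, and pairing them with either copy would misstate essentiality.
#'
#' @return Named character vector: names are C3 reaction ids, values C4
#'   reaction ids.
#' @export
ortholog_map <- function() {
  core <- c("EX_photon", "EX_co2", "EX_o2", "EX_h2o", "EX_pi", "EX_nh3",
            "EX_sucrose", "EX_biomass", "R_rubisco", "R_biomass")
  calvin <- c("R_ald", "R_tkt1", "R_tal", "R_tkt2", "R_rpe",
              "R_rpi", "R_prk", "R_starch", "R_pglp", "R_pglp_alt", "R_lox",
              "R_cat", "R_c2", "R_glyk")
  sucrose <- c("R_sps", "R_spp", "R_spp_alt")
  primary <- c("R_glyc", "R_pk", "R_gdh", "R_ggat",
               "R_pdh_cs", "R_aco", "R_tca2", "R_mdh_mit", "R_icl", "R_sdh",
               "R_starch_deg")
  c(stats::setNames(core, core),
    stats::setNames(paste0(calvin, "_bs"), calvin),
    stats::setNames(paste0(sucrose, "_bs"), sucrose),
    stats::setNames(paste0(primary, "_bs"), primary),
    c(R_alat = "R_alat_bs", R_oxphos = "R_oxphos_bs",
      T_glyox_mit = "T_glyox_bsmit",
      R_light = "R_light_m", R_ngam = "R_ngam_bs",
      T_photon = "T_photon_m", T_co2 = "T_co2_m", T_o2 = "T_o2_m",
      T_h2o = "T_h2o_m", T_nh3 = "T_nh3_bs", T_suc = "T_suc_bs"))
}
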