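#' Pipeline configuration
#'
#' Flat, typed key-value configuration for [run_pipeline()]. Unknown keys
#' are errors, which keeps silent typos out of scientific settings; every
#' value is validated before any stage runs.
#'
#' @param ca Ambient CO2 (ubar) for the ratio stage and fixture r values.
#' @param photon_bound Photon uptake bound of the fixtures.
#' @param leak_upper Bundle-sheath CO2 leak upper bound.
#' @param n_warmup,n_points,seed Sampler settings.
#' @param coset_threshold Correlated-set absolute-correlation threshold.
#' @param knockout_tol Knockout class tolerance.
#' @param light_grid,ca_grid Sweep grids.
#' @param out_dir Report directory (created if absent).
#' @param table2_only Run only the ratio stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(ca = 380, photon_bound = 1000, leak_upper = 10,
                       n_warmup = 5000, n_points = 2000, seed = 1,
                       coset_threshold = 1 - 1e-8, knockout_tol = 1e-6,
                       light_grid = seq(0, 2000, by = 250),
                       ca_grid = c(100, 380, 550, 800, 1000),
                       out_dir = tempfile("photoflux_run_"),
                       table2_only = FALSE) {
  cfg <- list(ca = ca, photon_bound = photon_bound, leak_upper = leak_upper,
              n_warmup = n_warmup, n_points = n_points, seed = seed,
              coset_threshold = coset_threshold, knockout_tol = knockout_tol,
              light_grid = light_grid, ca_grid = ca_grid, out_dir = out_dir,
              table2_only = table2_only)
  stopifnot(ca > 0, photon_bound >= 0, leak_upper >= 0,
            n_warmup >= 2, n_points > 1, is.numeric(seed),
            coset_threshold > 0, coset_threshold <= 1,
            knockout_tol > 0, knockout_tol < 0.5,
            all(light_grid >= 0), !is.unsorted(light_grid),
            all(ca_grid > 0), !is.unsorted(ca_grid),
              is.character(out_dir), is.logical(table2_only))
  structure(cfg, class = "run_config")
}

#' Run the full comparison pipeline
#'
#' Orchestrates the whole workflow on the bundled toy fixtures: ratio
#' table, fixture generation, FBA summaries for both objectives, reaction
#' and enzyme knockout scans with tallies, a key-enzyme panel, ACHR
#' sampling and correlated reaction sets, the topology panel, light and
#' CO2 sweeps, and the C4 subtype scenarios. Every stage writes its
#' artifact into `cfg$out_dir` (TSV for tables, JSON for panels) plus a
#' run log recording the seed and every default; a failing stage halts
#' with its name while earlier artifacts remain on disk, and a MANIFEST
#' lists what completed.
#'
#' @param cfg A [run_config()].
#' @return The report directory path, invisibly.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character()
  logline <- character()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    tryCatch(writer(path), error = function(e) {
      writeLines(c(manifest, paste0("INCOMPLETE at ", name)),
                 file.path(cfg$out_dir, "MANIFEST"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest <<- c(manifest, name)
    invisible(path)
  }
  wtsv <- function(d) function(p) utils::write.table(
    d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  wjson <- function(x) function(p) jsonlite::write_json(
    x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  logline <- c(logline,
               paste0("seed: ", cfg$seed),
               paste0("ca: ", cfg$ca, " ubar"),
               paste0("coset_threshold: ", format(cfg$coset_threshold)),
               paste0("knockout_tol: ", cfg$knockout_tol),
               "Jt policy: Jt = Jmax (saturating light)",
               paste0("currency exclusions: ",
                      paste(eval(formals(build_graph)$currency_exclusions),
                            collapse = ", ")))

  rt <- ratio_table(cfg$ca_grid)
  emit("ratio_table.tsv", wtsv(rt))
  if (cfg$table2_only) {
    writeLines(manifest, file.path(cfg$out_dir, "MANIFEST"))
    writeLines(logline, file.path(cfg$out_dir, "run_log.txt"))
    return(invisible(cfg$out_dir))
  }

  m3 <- make_toy_c3(fixture_spec("c3", ca = cfg$ca,
                                 photon_bound = cfg$photon_bound))
  m4 <- make_toy_c4(fixture_spec("c4", ca = cfg$ca,
                                 leak_upper = cfg$leak_upper,
                                 photon_bound = cfg$photon_bound))
  emit("toy_c3.reactions.tsv", function(p) write_model(
    m3, sub("\\.reactions\\.tsv$", "", p), "tsv"))
  emit("toy_c4.reactions.tsv", function(p) write_model(
    m4, sub("\\.reactions\\.tsv$", "", p), "tsv"))

  objs <- c("biomass", "co2_fixation")
  fba_summary <- dplyr::bind_rows(lapply(list(m3, m4), function(m) {
    dplyr::bind_rows(lapply(objs, function(o) {
      glance(fba(set_objective(m, o), objective_name = o))
    }))
  }))
  emit("fba_summary.tsv", wtsv(fba_summary))

  reports <- list()
  for (m in list(m3, m4)) for (o in objs) {
    rep <- scan_all(set_objective(m, o), objective_name = o,
                    tol = cfg$knockout_tol)
    key <- paste0(tolower(m$model_label), "_", o)
    reports[[key]] <- rep
    emit(paste0("knockout_", key, ".tsv"), wtsv(tidy(rep)))
    emit(paste0("knockout_", key, "_tally.tsv"), wtsv(rep$tally))
  }

  panel_ecs <- c(Rubisco = "4.1.1.39", RPI = "5.3.1.6", PRK = "2.7.1.19",
                 RPE = "5.1.3.1", TKT = "2.2.1.1", TAL = "2.2.1.2",
                 LOX = "1.1.3.15", PGLP = "3.1.3.18", SPP = "3.1.3.24",
                 starch_branching = "2.4.1.18", PEPC = "4.1.1.31",
                 PPDK = "2.7.9.1")
  panel <- dplyr::bind_rows(lapply(names(panel_ecs), function(enz) {
    row <- tibble::tibble(enzyme = enz, ec = panel_ecs[[enz]])
    for (m in list(m3, m4)) for (o in objs) {
      wt <- fba(set_objective(m, o))
      sc <- delete_and_score(set_objective(m, o), panel_ecs[[enz]], "enzyme",
                             wild_type = wt$objective_value,
                             tol = cfg$knockout_tol)
      row[[paste0("ratio_", tolower(m$model_label), "_", o)]] <- sc$ratio
    }
    row
  }))
  emit("key_enzyme_panel.tsv", wtsv(panel))

  for (m in list(m3, m4)) {
    ens <- achr_sample(m, n_warmup = cfg$n_warmup, n_points = cfg$n_points,
                       seed = cfg$seed)
    cs <- correlated_sets(ens, threshold = cfg$coset_threshold)
    key <- tolower(m$model_label)
    emit(paste0("cosets_", key, ".tsv"), wtsv(tidy(cs)))
    emit(paste0("cosets_", key, "_summary.tsv"), wtsv(glance(cs)))
  }

  topo <- dplyr::bind_rows(
    dplyr::mutate(metric_panel(build_graph(m3)), model_label = "C3"),
    dplyr::mutate(metric_panel(build_graph(m4)), model_label = "C4"))
  emit("topology.json", wjson(topo))

  for (m in list(m3, m4)) for (o in objs) {
    sw <- light_sweep(m, cfg$light_grid, o)
    emit(sprintf("sweep_light_%s_%s.tsv", tolower(m$model_label), o), wtsv(sw))
  }
  emit("sweep_co2_c3.tsv", wtsv(co2_sweep(m3, cfg$ca_grid, "c3")))
  emit("sweep_co2_c4.tsv", wtsv(co2_sweep(m4, cfg$ca_grid, "c4")))

  subt <- dplyr::bind_rows(lapply(c("NADP_ME", "NAD_ME", "PCK", "ALL"),
                                  function(s) {
    d <- subtype_scenario(m4, s)
    d$blocked <- vapply(d$blocked, paste, character(1), collapse = ";")
    d
  }))
  emit("subtype.json", wjson(subt))

  writeLines(manifest, file.path(cfg$out_dir, "MANIFEST"))
  writeLines(logline, file.path(cfg$out_dir, "run_log.txt"))
  invisible(cfg$out_dir)
}
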