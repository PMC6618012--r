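# Gas-exchange tables: CSV I/O and the synthetic-data generator that
# emulates the standard measurement designs (CO2- and light-response curves
# under photorespiratory O = 21 kPa and nonphotorespiratory O = 2 kPa) with
# known true parameters.

GE_HEADER <- c("dataset_id", "leaf_id", "curve_type", "regime",
               "Iinc_umol_m2_s", "Ca_Pa", "Ci_Pa", "O_kPa",
               "AN_umol_m2_s", "Phi2", "gs_umol_m2_s_Pa")

GE_CANONICAL <- c("dataset_id", "leaf_id", "curve_type", "regime",
                  "Iinc", "Ca", "Ci", "O", "AN", "Phi2", "gs")

GE_NUMERIC <- c("Iinc", "Ca", "Ci", "O", "AN", "Phi2", "gs")

#' Read a gas-exchange table from CSV
#'
#' Expects the canonical header
#' `dataset_id,leaf_id,curve_type,regime,Iinc_umol_m2_s,Ca_Pa,Ci_Pa,O_kPa,AN_umol_m2_s,Phi2,gs_umol_m2_s_Pa`
#' (unit suffixes are part of the contract and are validated). Unknown extra
#' columns are preserved. Records with O2 pressure outside the standard
#' `{21, 2}` kPa regimes are accepted with a warning.
#'
#' @param path Path to a CSV file.
#' @return A tibble with canonical column names (`Iinc`, `Ca`, `Ci`, `O`,
#'   `AN`, `Phi2`, `gs`, plus identifiers), one row per record.
#' @export
read_gas_exchange <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(GE_HEADER, names(raw))
  if (length(missing) > 0) {
    stop("gas-exchange table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), GE_HEADER)
  out <- raw[, GE_HEADER]
  names(out) <- GE_CANONICAL
  for (col in GE_NUMERIC) {
    v <- out[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & v != "NA" & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column %s at row %d",
                   v[bad[1]], col, bad[1]), call. = FALSE)
    }
    out[[col]] <- num
  }
  out <- tibble::as_tibble(out)
  if (length(extra) > 0) {
    for (col in extra) {
      num <- suppressWarnings(as.numeric(raw[[col]]))
      out[[col]] <- if (all(is.na(num) == is.na(raw[[col]]) |
                              raw[[col]] == "")) num else raw[[col]]
    }
  }
  nonstandard <- !is.na(out$O) & !out$O %in% c(21, 2)
  if (any(nonstandard)) {
    warning(sprintf("%d record(s) with non-standard O2 regime (O not in {21, 2} kPa)",
                    sum(nonstandard)))
  }
  out
}

#' Write a gas-exchange table to CSV
#'
#' Inverse of [read_gas_exchange()]: writes the canonical unit-suffixed
#' header, preserving extra columns after the mandatory ones, so that
#' `read_gas_exchange(write_gas_exchange(t))` round-trips.
#'
#' @param table A gas-exchange tibble with canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(table, path) {
  missing <- setdiff(GE_CANONICAL, names(table))
  if (length(missing) > 0) {
    stop("table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(table[, GE_CANONICAL])
  names(out) <- GE_HEADER
  extra <- setdiff(names(table), GE_CANONICAL)
  for (col in extra) out[[col]] <- table[[col]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' True parameter set for the synthetic gas-exchange generator
#'
#' Defines the generating model for synthetic measurement campaigns: FvCB
#' parameters per regime (day respiration may differ between
#' photorespiratory and nonphotorespiratory conditions), anatomy, transport,
#' release scenario, the declining PSII-yield sub-model
#' `Phi2(Iinc) = phi2_max / (1 + Iinc / i_half)`, the saturating stomatal
#' sub-model `gs(Iinc) = gs_min + (gs_max - gs_min) Iinc / (Iinc + i_g)`,
#' and Gaussian measurement noise on AN and Phi2.
#'
#' The defaults reproduce the standard low-light electron transport rates:
#' with `s_cal = 0.5`, `phi2_max = 0.8` and `i_half = 1000`, J at
#' Iinc = 150, 100, 50 and 25 umol m-2 s-1 is 52.2, 36.4, 19.0 and
#' 9.8 umol m-2 s-1.
#'
#' @param rd_pr,rd_npr True day respiration under O = 21 and O = 2 kPa
#'   (umol m-2 s-1).
#' @param vcmax True maximum carboxylation rate (umol m-2 s-1).
#' @param tp True triose-phosphate utilization rate (umol m-2 s-1).
#' @param s_cal True fluorescence calibration factor.
#' @param anatomy A [leaf_anatomy()] object.
#' @param transport A [transport_params()] object.
#' @param scenario Release scenario used by the generator.
#' @param phi2_max,i_half PSII-yield sub-model parameters.
#' @param gs_min,gs_max,i_g Stomatal sub-model parameters
#'   (umol m-2 s-1 Pa-1 and umol m-2 s-1).
#' @param sd_an,sd_phi2 Measurement noise standard deviations.
#' @param kmc,kmo,sco Rubisco constants.
#' @param seed Default RNG seed for [synth_gas_exchange()].
#' @return An object of class `synth_truth`.
#' @export
synth_truth <- function(rd_pr = 1.5, rd_npr = 1.2, vcmax = 120, tp = 10,
                        s_cal = 0.5,
                        anatomy = fixture_anatomy("ho_default"),
                        transport = transport_params(),
                        scenario = "inner",
                        phi2_max = 0.8, i_half = 1000,
                        gs_min = 0.3, gs_max = 3.0, i_g = 200,
                        sd_an = 0.15, sd_phi2 = 0.005,
                        kmc = 26.7, kmo = 16.4, sco = 2.6, seed = 42L) {
  stopifnot(sd_an >= 0, sd_phi2 >= 0, scenario %in% SCENARIOS)
  structure(list(rd_pr = rd_pr, rd_npr = rd_npr, vcmax = vcmax, tp = tp,
                 s_cal = s_cal, anatomy = anatomy, transport = transport,
                 scenario = scenario, phi2_max = phi2_max, i_half = i_half,
                 gs_min = gs_min, gs_max = gs_max, i_g = i_g,
                 sd_an = sd_an, sd_phi2 = sd_phi2,
                 kmc = kmc, kmo = kmo, sco = sco, seed = as.integer(seed)),
            class = "synth_truth")
}

phi2_submodel <- function(truth, iinc) truth$phi2_max / (1 + iinc / truth$i_half)

gs_submodel <- function(truth, iinc) {
  truth$gs_min + (truth$gs_max - truth$gs_min) * iinc / (iinc + truth$i_g)
}

# Standard measurement-design grids.
CA_GRID <- c(5, 10, 15, 20, 25, 30, 40, 60, 80, 100)
IINC_GRID <- c(25, 50, 75, 100, 125, 150, 200, 350, 500, 1000, 1500)

#' Condition grids of the standard measurement designs
#'
#' The four standard designs: CO2-response (A-Ca) curves at saturating light
#' (Iinc = 1500 umol m-2 s-1) under O = 21 kPa (`aca_pr`) or O = 2 kPa
#' (`aca_npr`), and light-response (A-Iinc) curves at Ca = 40 Pa, O = 21 kPa
#' (`ai_pr`) or Ca = 100 Pa, O = 2 kPa (`ai_npr`).
#'
#' @param design One of `"aca_pr"`, `"aca_npr"`, `"ai_pr"`, `"ai_npr"`,
#'   `"all"`.
#' @return A tibble with columns `curve_type`, `regime`, `Iinc`, `Ca`, `O`.
#' @export
design_conditions <- function(design = c("all", "aca_pr", "aca_npr",
                                         "ai_pr", "ai_npr")) {
  design <- match.arg(design)
  one <- function(d) {
    switch(d,
      aca_pr = tibble::tibble(curve_type = "ACa", regime = "PR",
                              Iinc = 1500, Ca = CA_GRID, O = 21),
      aca_npr = tibble::tibble(curve_type = "ACa", regime = "NPR",
                               Iinc = 1500, Ca = CA_GRID, O = 2),
      ai_pr = tibble::tibble(curve_type = "AI", regime = "PR",
                             Iinc = IINC_GRID, Ca = 40, O = 21),
      ai_npr = tibble::tibble(curve_type = "AI", regime = "NPR",
                              Iinc = IINC_GRID, Ca = 100, O = 2))
  }
  if (design == "all") {
    purrr::map_dfr(c("aca_pr", "aca_npr", "ai_pr", "ai_npr"), one)
  } else {
    one(design)
  }
}

#' Generate a synthetic gas-exchange table
#'
#' Runs the forward reaction-diffusion model (stomata-coupled, `ca_driven`)
#' over a measurement design, using the truth's PSII-yield and stomatal
#' sub-models to supply Phi2 and gs at each grid point, then adds seeded
#' Gaussian measurement noise to AN and to the recorded Phi2. The noiseless
#' forward values are kept in `AN_true` and `Phi2_true` so that recovery
#' studies can compare against truth.
#'
#' @param truth A [synth_truth()] object.
#' @param design A design name for [design_conditions()] or a custom tibble
#'   with columns `curve_type`, `regime`, `Iinc`, `Ca`, `O`.
#' @param seed RNG seed (defaults to `truth$seed`). The same seed gives a
#'   bit-identical table.
#' @param control A [solver_control()]; its `nx`, `ny` set the mesh.
#' @return A gas-exchange tibble (canonical columns plus `AN_true`,
#'   `Phi2_true`), with the truth attached as attribute `"truth"`.
#' @export
synth_gas_exchange <- function(truth, design = "all", seed = truth$seed,
                               control = solver_control()) {
  stopifnot(inherits(truth, "synth_truth"))
  cond <- if (is.character(design)) design_conditions(design) else
    tibble::as_tibble(design)
  req <- c("curve_type", "regime", "Iinc", "Ca", "O")
  if (!all(req %in% names(cond))) {
    stop("custom design must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  geom <- build_unit_cell(truth$anatomy, truth$scenario)
  mesh <- generate_mesh(geom, c(control$nx, control$ny))
  ctx <- build_solver_context(mesh, truth$transport)

  n <- nrow(cond)
  an <- ci <- rep(NA_real_, n)
  phi2 <- phi2_submodel(truth, cond$Iinc)
  gs <- gs_submodel(truth, cond$Iinc)
  warm <- NULL
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    j <- electron_transport(truth$s_cal, cond$Iinc[i], phi2[i])
    rd <- if (cond$regime[i] == "PR") truth$rd_pr else truth$rd_npr
    kin <- kinetic_params(vcmax = truth$vcmax, j = j, rd = rd, tp = truth$tp,
                          s_cal = truth$s_cal, kmc = truth$kmc,
                          kmo = truth$kmo, sco = truth$sco)
    bc <- boundary_condition("ca_driven", ca = cond$Ca[i], gs = gs[i],
                             o = cond$O[i])
    sol <- tryCatch(
      solve_steady_state(ctx, kin, boundary = bc, scenario = truth$scenario,
                         control = control, init = warm),
      error = function(e) e)
    if (inherits(sol, "error")) {
      ok[i] <- FALSE
      warning(sprintf("dropping grid point %d (%s)", i, conditionMessage(sol)))
      next
    }
    warm <- sol$internals$c
    an[i] <- sol$an
    ci[i] <- sol$ci
  }
  if (mean(ok) < 0.8) {
    stop("more than 20% of design grid points failed to solve", call. = FALSE)
  }
  out <- tibble::tibble(
    dataset_id = "synthetic", leaf_id = "synthetic_leaf",
    curve_type = cond$curve_type, regime = cond$regime,
    Iinc = cond$Iinc, Ca = cond$Ca, Ci = ci, O = cond$O,
    AN = an, Phi2 = phi2, gs = gs,
    AN_true = an, Phi2_true = phi2
  )[ok, ]
  set.seed(seed)
  out$AN <- out$AN + stats::rnorm(nrow(out), 0, truth$sd_an)
  out$Phi2 <- pmin(pmax(out$Phi2 +
                          stats::rnorm(nrow(out), 0, truth$sd_phi2),
                        1e-6), 1)
  attr(out, "truth") <- truth
  out
}
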