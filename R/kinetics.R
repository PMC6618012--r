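#' Photosynthetic kinetic parameters
#'
#' Leaf-area based FvCB parameters plus the Rubisco constants shared by all
#' leaf types: the Michaelis-Menten constants for carboxylation
#' (`kmc` = 26.7 Pa) and oxygenation (`kmo` = 16.4 kPa) and the Rubisco
#' specificity (`sco` = 2.6 kPa Pa-1).
#'
#' @param vcmax Maximum Rubisco carboxylation rate (umol m-2 s-1 leaf).
#' @param j Linear electron transport rate (umol m-2 s-1 leaf); usually
#'   computed per record as `J = s_cal * Iinc * Phi2`, see
#'   [electron_transport()].
#' @param rd Day respiration rate (umol m-2 s-1 leaf).
#' @param tp Triose-phosphate utilization rate (umol m-2 s-1 leaf), or `NULL`
#'   for no TPU cap.
#' @param s_cal Calibration factor relating `Iinc * Phi2` to J
#'   (dimensionless), or `NULL`.
#' @param kmc Michaelis-Menten constant for CO2 (Pa).
#' @param kmo Michaelis-Menten constant for O2 (kPa).
#' @param sco Rubisco CO2/O2 specificity (kPa Pa-1).
#' @return An object of class `kinetic_params` (named list).
#' @export
kinetic_params <- function(vcmax = 120, j = NULL, rd = 1.5, tp = NULL,
                           s_cal = NULL, kmc = 26.7, kmo = 16.4, sco = 2.6) {
  for (nm in c("vcmax", "rd", "kmc", "kmo", "sco")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      if (!(nm == "rd" && is.numeric(v) && v == 0)) {
        stop("`", nm, "` must be a single positive number", call. = FALSE)
      }
    }
  }
  structure(list(vcmax = vcmax, j = j, rd = rd, tp = tp, s_cal = s_cal,
                 kmc = kmc, kmo = kmo, sco = sco),
            class = "kinetic_params")
}

#' CO2 compensation point in the absence of day respiration
#'
#' `Gamma* = 0.5 * O / Sc/o`: the chloroplast CO2 partial pressure at which
#' photorespiratory CO2 release exactly balances carboxylation.
#'
#' @param o O2 partial pressure (kPa).
#' @param sco Rubisco specificity (kPa Pa-1).
#' @return Gamma* in Pa.
#' @export
#' @examples
#' gamma_star(21, 2.6)  # about 4.04 Pa
gamma_star <- function(o, sco = 2.6) {
  if (any(sco <= 0)) stop("`sco` must be positive", call. = FALSE)
  if (any(o < 0)) stop("`o` must be non-negative", call. = FALSE)
  0.5 * o / sco
}

#' Linear electron transport rate from fluorescence
#'
#' `J = s_cal * Iinc * Phi2`, where `Phi2` is the PSII operating efficiency
#' from chlorophyll fluorescence and `s_cal` is the lumped calibration
#' factor obtained by regression under nonphotorespiratory conditions
#' (see [fit_calibration_s()]).
#'
#' @param s_cal Calibration factor (dimensionless).
#' @param iinc Incident irradiance (umol m-2 s-1).
#' @param phi2 PSII quantum yield, in `[0, 1]`.
#' @return J (umol m-2 s-1), vectorized over the inputs.
#' @export
electron_transport <- function(s_cal, iinc, phi2) {
  if (any(s_cal < 0) || any(iinc < 0) || any(phi2 < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  if (any(phi2 > 1)) stop("`phi2` must be <= 1", call. = FALSE)
  s_cal * iinc * phi2
}

#' Limitation state of carboxylation
#'
#' Resolves the `(X1, X2)` pair of the FvCB rate expression
#' `AN = (Cc - Gamma*) * X1 / (Cc + X2) - Rd` for a given limitation:
#' Rubisco-limited (`X1 = Vcmax`, `X2 = KmC (1 + O/KmO)`) or electron
#' transport-limited (`X1 = J/4`, `X2 = 2 Gamma*`).
#'
#' @param params A [kinetic_params()] object.
#' @param limitation `"rubisco"` or `"electron_transport"`.
#' @param o O2 partial pressure (kPa).
#' @param j Electron transport rate (umol m-2 s-1); defaults to `params$j`.
#' @return A list with `limitation`, `x1` (umol m-2 s-1) and `x2` (Pa).
#' @export
limitation_state <- function(params, limitation = c("rubisco",
                                                    "electron_transport"),
                             o = 21, j = params$j) {
  limitation <- match.arg(limitation)
  gs <- gamma_star(o, params$sco)
  if (limitation == "rubisco") {
    list(limitation = "rubisco", x1 = params$vcmax,
         x2 = params$kmc * (1 + o / params$kmo))
  } else {
    if (is.null(j)) stop("electron-transport limitation requires `j`",
                         call. = FALSE)
    list(limitation = "electron_transport", x1 = j / 4, x2 = 2 * gs)
  }
}

#' Leaf-level FvCB net assimilation
#'
#' Evaluates `AN = (Cc - Gamma*) X1 / (Cc + X2) - Rd` for the active
#' limitation. With `limitation = "dynamic"` the minimum of the Rubisco and
#' electron-transport gross rates is taken (pointwise), and a TPU cap
#' `AN <= 3 Tp - Rd` is applied when `params$tp` is set. With
#' `limitation = "tpu"` the plateau `AN = 3 Tp - Rd` is returned regardless
#' of `Cc`.
#'
#' @param cc Chloroplast CO2 partial pressure (Pa), vectorized.
#' @param params A [kinetic_params()] object.
#' @param limitation One of `"dynamic"`, `"rubisco"`, `"electron_transport"`,
#'   `"tpu"`.
#' @param o O2 partial pressure (kPa).
#' @param j Electron transport rate; defaults to `params$j`.
#' @return AN (umol m-2 s-1 leaf), uptake positive.
#' @export
#' @examples
#' p <- kinetic_params(vcmax = 100, rd = 1)
#' fvcb_assimilation(20, p, "rubisco", o = 21)  # about 18.7
fvcb_assimilation <- function(cc, params,
                              limitation = c("dynamic", "rubisco",
                                             "electron_transport", "tpu"),
                              o = 21, j = params$j) {
  limitation <- match.arg(limitation)
  if (any(cc <= 0)) stop("`cc` must be positive", call. = FALSE)
  gs <- gamma_star(o, params$sco)
  if (limitation == "tpu") {
    if (is.null(params$tp)) stop("TPU limitation requires `tp`", call. = FALSE)
    return(rep(3 * params$tp - params$rd, length(cc)))
  }
  one_branch <- function(lim) {
    st <- limitation_state(params, lim, o = o, j = j)
    if (any(cc + st$x2 <= 0)) stop("Cc + X2 must be positive", call. = FALSE)
    (cc - gs) * st$x1 / (cc + st$x2)
  }
  gross <- switch(limitation,
    rubisco = one_branch("rubisco"),
    electron_transport = one_branch("electron_transport"),
    dynamic = {
      g <- one_branch("rubisco")
      if (!is.null(j)) g <- pmin(g, one_branch("electron_transport"))
      g
    })
  an <- gross - params$rd
  if (limitation == "dynamic" && !is.null(params$tp)) {
    an <- pmin(an, 3 * params$tp - params$rd)
  }
  an
}

#' Carboxylation resistance
#'
#' The resistance-analogue of the carboxylation sink,
#' `rcx = (Cc + X2) / X1` (Pa per umol m-2 s-1).
#'
#' @param cc Chloroplast CO2 partial pressure (Pa).
#' @param lim A limitation state from [limitation_state()] (or any list with
#'   `x1`, `x2`).
#' @return Resistance (Pa umol-1 m2 s).
#' @export
carbox_resistance <- function(cc, lim) {
  if (lim$x1 == 0) stop("X1 must be positive", call. = FALSE)
  (cc + lim$x2) / lim$x1
}

#' Local volumetric rate laws in the stroma
#'
#' The stroma-volume rate laws the reaction-diffusion solver applies
#' pointwise: Rubisco-limited carboxylation
#' `w_c = Vmax_vol C / (C + KmC (1 + O/KmO))`, electron-transport-limited
#' carboxylation `w_j = (Jvol/4) C / (C + 2 Gamma*)`, their pointwise
#' minimum `w`, and the photorespiratory CO2 release per unit carboxylation
#' `Gamma*/C` (from Vo/Vc = 2 Gamma*/C and 0.5 CO2 released per
#' oxygenation).
#'
#' @param c_pa Local CO2 partial pressure (Pa), vectorized.
#' @param vmax_vol Volumetric Vcmax (umol m-3 s-1), from [area_scaling()].
#' @param jvol Volumetric J (umol m-3 s-1), or `NULL` to disable the
#'   electron-transport branch.
#' @param o O2 partial pressure (kPa).
#' @param kmc,kmo,sco Rubisco constants as in [kinetic_params()].
#' @return A tibble with columns `c_pa`, `w_c`, `w_j`, `w`,
#'   `release_per_carboxylation` and `release` (= `w * Gamma*/C`), all
#'   volumetric (umol m-3 s-1).
#' @export
local_rates <- function(c_pa, vmax_vol, jvol = NULL, o = 21,
                        kmc = 26.7, kmo = 16.4, sco = 2.6) {
  if (any(c_pa <= 0)) stop("local CO2 pressure must be positive", call. = FALSE)
  gs <- gamma_star(o, sco)
  kmc_eff <- kmc * (1 + o / kmo)
  w_c <- vmax_vol * c_pa / (c_pa + kmc_eff)
  w_j <- if (is.null(jvol)) rep(Inf, length(c_pa)) else
    (jvol / 4) * c_pa / (c_pa + 2 * gs)
  w <- pmin(w_c, w_j)
  tibble::tibble(
    c_pa = c_pa, w_c = w_c, w_j = w_j, w = w,
    release_per_carboxylation = gs / c_pa,
    release = w * gs / c_pa
  )
}

#' Triose-phosphate utilization rate from the high-CO2 plateau
#'
#' Under TPU limitation the net assimilation plateau is `Ap = 3 Tp - Rd`, so
#' `Tp = (Ap + Rd) / 3` where `Ap` is the mean observed AN at the highest Ca
#' of the photorespiratory CO2-response curve. The alternative grouping
#' `Tp = Ap + Rd/3` (inconsistent with the plateau expression but sometimes
#' seen) is selectable via `grouping`.
#'
#' @param ap Plateau net assimilation (umol m-2 s-1).
#' @param rd Day respiration (umol m-2 s-1).
#' @param grouping `"plateau"` for `(Ap + Rd)/3` (default) or `"literal"`
#'   for `Ap + Rd/3`.
#' @return Tp (umol m-2 s-1).
#' @export
tp_from_ap <- function(ap, rd, grouping = c("plateau", "literal")) {
  grouping <- match.arg(grouping)
  if (ap + rd <= 0) stop("`ap + rd` must be positive", call. = FALSE)
  if (grouping == "plateau") (ap + rd) / 3 else ap + rd / 3
}
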