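#' Leaf anatomical parameters for the mesophyll unit cell
#'
#' Bundles the measured microstructural quantities that define the simplified
#' two-dimensional mesophyll unit cell: cell-wall, cytosol and stroma layer
#' thicknesses, the chloroplast surface coverage of the mesophyll
#' (`sc_sm` = Sc/Sm) and the mesophyll-to-leaf surface area ratio
#' (`sm_s` = Sm/S). All lengths are in metres (SI).
#'
#' @param twall Cell-wall thickness (m).
#' @param tcyt Outer cytosol layer thickness (m), between plasma membrane and
#'   chloroplast envelope.
#' @param tstr Stroma (chloroplast) thickness (m).
#' @param sc_sm Fraction of the mesophyll surface covered by chloroplasts
#'   (Sc/Sm), in (0, 1].
#' @param sm_s Ratio of exposed mesophyll surface area to leaf area (Sm/S),
#'   >= 1.
#' @param tcyt_inner Inner cytosol layer thickness (m), between chloroplast
#'   and tonoplast. Defaults to `tcyt`.
#' @param lchl Lateral chloroplast half-width of the unit cell (m). The
#'   lateral extent only matters through `sc_sm` (which sets the relative gap
#'   width); the default 5 um is a typical chloroplast dimension.
#'
#' @return An object of class `leaf_anatomy` (a named list).
#' @export
#' @examples
#' leaf_anatomy(twall = 120e-9, tcyt = 250e-9, tstr = 2.5e-6,
#'              sc_sm = 0.9, sm_s = 16)
leaf_anatomy <- function(twall, tcyt, tstr, sc_sm, sm_s,
                         tcyt_inner = tcyt, lchl = 5e-6) {
  lens <- c(twall = twall, tcyt = tcyt, tstr = tstr,
            tcyt_inner = tcyt_inner, lchl = lchl)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all anatomical lengths must be positive and finite", call. = FALSE)
  }
  if (!is.finite(sc_sm) || sc_sm <= 0 || sc_sm > 1) {
    stop("`sc_sm` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(sm_s) || sm_s < 1) {
    stop("`sm_s` must be >= 1", call. = FALSE)
  }
  structure(
    list(twall = twall, tcyt = tcyt, tstr = tstr, tcyt_inner = tcyt_inner,
         sc_sm = sc_sm, sm_s = sm_s, lchl = lchl),
    class = "leaf_anatomy"
  )
}

#' @export
print.leaf_anatomy <- function(x, ...) {
  cat("<leaf_anatomy>\n")
  cat(sprintf("  wall %.0f nm | cytosol %.0f nm | stroma %.2f um | inner cytosol %.0f nm\n",
              x$twall * 1e9, x$tcyt * 1e9, x$tstr * 1e6, x$tcyt_inner * 1e9))
  cat(sprintf("  Sc/Sm = %.2f, Sm/S = %.1f, chloroplast half-width %.1f um\n",
              x$sc_sm, x$sm_s, x$lchl * 1e6))
  invisible(x)
}

#' Named fixture anatomies
#'
#' `"ho_default"` returns the standard tomato mesophyll parameter set used
#' when no leaf-specific anatomical measurements are available: wall 120 nm,
#' cytosol 250 nm, stroma 2.5 um, Sc/Sm = 0.90, Sm/S = 16. `"custom"`
#' requires all fields to be supplied via `...` (forwarded to
#' [leaf_anatomy()]).
#'
#' @param name One of `"ho_default"`, `"custom"`.
#' @param ... For `"custom"`, the arguments of [leaf_anatomy()].
#' @return A [leaf_anatomy()] object.
#' @export
fixture_anatomy <- function(name = c("ho_default", "custom"), ...) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("ho_default", "custom")) {
    stop("unknown anatomy fixture; options are 'ho_default', 'custom'",
         call. = FALSE)
  }
  if (name == "ho_default") {
    return(leaf_anatomy(twall = 120e-9, tcyt = 250e-9, tstr = 2.5e-6,
                        sc_sm = 0.90, sm_s = 16))
  }
  args <- list(...)
  required <- c("twall", "tcyt", "tstr", "sc_sm", "sm_s")
  missing <- setdiff(required, names(args))
  if (length(missing) > 0) {
    stop("custom anatomy requires fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(leaf_anatomy, args)
}

#' Area-scaling factors between leaf, mesophyll and stroma bases
#'
#' Rates in gas exchange are expressed per unit leaf area; inside the unit
#' cell they act per unit exposed mesophyll area (divide by Sm/S) or per unit
#' stroma volume (divide additionally by the stroma volume per mesophyll
#' area, `tstr * sc_sm`). The returned factors are exact inverses of each
#' other, so a round trip is the identity.
#'
#' @param anatomy A [leaf_anatomy()] object.
#' @return A named list with multiplicative factors `leaf_to_mesophyll`,
#'   `mesophyll_to_leaf`, `leaf_to_stroma_volume` (umol m-2 s-1 leaf to
#'   umol m-3 s-1 stroma) and `stroma_volume_to_leaf`.
#' @export
#' @examples
#' sc <- area_scaling(fixture_anatomy("ho_default"))
#' 100 * sc$leaf_to_mesophyll  # 6.25 umol m-2 s-1 mesophyll
area_scaling <- function(anatomy) {
  stopifnot(inherits(anatomy, "leaf_anatomy"))
  v_str <- anatomy$tstr * anatomy$sc_sm  # stroma volume per mesophyll area
  list(
    leaf_to_mesophyll = 1 / anatomy$sm_s,
    mesophyll_to_leaf = anatomy$sm_s,
    leaf_to_stroma_volume = 1 / (anatomy$sm_s * v_str),
    stroma_volume_to_leaf = anatomy$sm_s * v_str
  )
}
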