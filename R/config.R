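# Structured-text configuration. The file format is the flat
# section/key = value subset of TOML: `[section]` headers, `key = value`
# pairs with numeric, boolean or quoted-string values, and `#` comments.

#' Read a model configuration file
#'
#' Parses a flat TOML-style config with sections `[anatomy]`,
#' `[transport]`, `[kinetics]`, `[solver]`, `[fit]`, `[synth]`. Anatomy
#' lengths use the unit-suffixed keys `twall_nm`, `tcyt_nm`,
#' `tcyt_inner_nm`, `tstr_um`, `lchl_um` plus the dimensionless `sc_sm`,
#' `sm_s`.
#'
#' @param path Path to the config file.
#' @return A named list of sections, each a named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[[A-Za-z0-9_]+\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) {
        stop("config key outside of a [section]: ", ln, call. = FALSE)
      }
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      out[[section]][[key]] <-
        if (grepl('^".*"$', val) || grepl("^'.*'$", val)) {
          substr(val, 2, nchar(val) - 1)
        } else if (tolower(val) %in% c("true", "false")) {
          tolower(val) == "true"
        } else {
          num <- suppressWarnings(as.numeric(val))
          if (is.na(num)) stop("cannot parse config value: ", ln,
                               call. = FALSE)
          num
        }
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  out
}

#' Build model objects from a configuration
#'
#' @param cfg A list from [read_config()].
#' @return `config_anatomy()` a [leaf_anatomy()], `config_transport()` a
#'   [transport_params()], `config_control()` a [solver_control()].
#' @export
config_anatomy <- function(cfg) {
  a <- cfg$anatomy
  if (is.null(a)) return(fixture_anatomy("ho_default"))
  grab <- function(key, default) if (is.null(a[[key]])) default else a[[key]]
  leaf_anatomy(
    twall = grab("twall_nm", 120) * 1e-9,
    tcyt = grab("tcyt_nm", 250) * 1e-9,
    tcyt_inner = grab("tcyt_inner_nm", grab("tcyt_nm", 250)) * 1e-9,
    tstr = grab("tstr_um", 2.5) * 1e-6,
    sc_sm = grab("sc_sm", 0.90), sm_s = grab("sm_s", 16),
    lchl = grab("lchl_um", 5) * 1e-6
  )
}

#' @rdname config_anatomy
#' @export
config_transport <- function(cfg) {
  tr <- cfg$transport
  args <- formals(transport_params)
  if (is.null(tr)) return(transport_params())
  do.call(transport_params,
          utils::modifyList(lapply(args, eval), tr[names(tr) %in% names(args)]))
}

#' @rdname config_anatomy
#' @export
config_control <- function(cfg) {
  sv <- cfg$solver
  args <- formals(solver_control)
  if (is.null(sv)) return(solver_control())
  do.call(solver_control,
          utils::modifyList(lapply(args, eval), sv[names(sv) %in% names(args)]))
}
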