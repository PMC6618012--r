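# Shared fixtures. Everything is generated in code; heavier objects are
# built lazily once per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

quick_ctrl <- function(...) solver_control(nx = 8L, ny = 24L, ...)

ho_anatomy <- function() fixture_anatomy("ho_default")

# A solver context per (scenario, label), cached.
quick_ctx <- function(scenario = "inner", transport = transport_params(),
                      ctrl = quick_ctrl(), label = "default") {
  key <- paste(scenario, label, ctrl$nx, ctrl$ny, sep = "/")
  if (is.null(.fixture_env[[key]])) {
    geom <- build_unit_cell(ho_anatomy(), scenario)
    mesh <- generate_mesh(geom, c(ctrl$nx, ctrl$ny))
    .fixture_env[[key]] <- build_solver_context(mesh, transport)
  }
  .fixture_env[[key]]
}

quick_truth <- function(...) {
  synth_truth(sd_an = 0, sd_phi2 = 0, seed = 101L, ...)
}

# Noiseless synthetic dataset over all four standard designs (cached).
base_synth <- function() {
  if (is.null(.fixture_env$base_synth)) {
    .fixture_env$base_synth <-
      suppressWarnings(synth_gas_exchange(quick_truth(), "all",
                                          control = quick_ctrl()))
  }
  .fixture_env$base_synth
}

# Fresh measurement noise on the noiseless base table.
with_noise <- function(data, sd_an = 0.15, sd_phi2 = 0.005, seed = 1L) {
  set.seed(seed)
  out <- data
  out$AN <- out$AN_true + stats::rnorm(nrow(out), 0, sd_an)
  out$Phi2 <- pmin(pmax(out$Phi2_true + stats::rnorm(nrow(out), 0, sd_phi2),
                        1e-6), 1)
  out
}
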