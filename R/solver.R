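# Steady-state finite-volume reaction-diffusion solver on the unit cell.
#
# Concentrations are stored as Pa-equivalents; Henry's-law solubility closes
# the units when converting volumetric reaction rates and boundary fluxes to
# mol-based rates. The discretization is cell-centered finite volume with
# harmonic averaging of diffusivity at faces; membrane interfaces add a
# series resistance 1/P on the shared face. The Michaelis-Menten sink is
# handled by Picard iteration on the frozen first-order coefficient
# k = w(C)/C (which keeps the operator an M-matrix, hence the field
# positive), with damping 0.5 on k and on the photorespiratory release Rp.

#' CO2 transport constants
#'
#' Diffusion and solubility constants of the mesophyll compartments. The
#' defaults are literature-typical values at 25 C: free diffusivity of CO2
#' in water, relative effective diffusivities of the wall, cytosol and
#' stroma, membrane permeabilities of plasma membrane and chloroplast
#' envelope, and Henry's-law solubility.
#'
#' @param d_water CO2 diffusivity in water (m2 s-1).
#' @param f_wall,f_cyt,f_str Relative effective diffusivities (<= 1) of the
#'   cell wall, cytosol (outer, gap and inner) and stroma.
#' @param p_pm,p_env Permeabilities of the plasma membrane and chloroplast
#'   envelope (m s-1).
#' @param henry Henry's-law solubility (mol m-3 Pa-1).
#' @param temperature Temperature (K); recorded, not used in the defaults.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(d_water = 1.79e-9, f_wall = 1.0, f_cyt = 0.3,
                             f_str = 0.3, p_pm = 3.5e-3, p_env = 3.5e-3,
                             henry = 3.3e-4, temperature = 298.15) {
  vals <- c(d_water = d_water, f_wall = f_wall, f_cyt = f_cyt, f_str = f_str,
            p_pm = p_pm, p_env = p_env, henry = henry)
  if (any(vals <= 0)) stop("all transport constants must be positive",
                           call. = FALSE)
  if (any(c(f_wall, f_cyt, f_str) > 1)) {
    stop("relative diffusivities must be <= 1", call. = FALSE)
  }
  structure(list(d_water = d_water, f_wall = f_wall, f_cyt = f_cyt,
                 f_str = f_str, p_pm = p_pm, p_env = p_env, henry = henry,
                 temperature = temperature),
            class = "transport_params")
}

#' Boundary condition at the intercellular airspace
#'
#' Either `ca_driven` (ambient CO2 `ca` plus stomatal conductance `gs`; the
#' airspace pressure Ci is solved from the stomatal balance
#' `AN = gs (Ca - Ci)`) or `ci_driven` (Ci imposed directly, as when
#' simulating the conditions of the Laisk method or driving the model with
#' measured Ci).
#'
#' @param mode `"ca_driven"` or `"ci_driven"`.
#' @param ca Ambient CO2 partial pressure (Pa), `ca_driven` only.
#' @param gs Stomatal conductance (umol m-2 s-1 Pa-1, leaf), `ca_driven`.
#' @param ci Intercellular CO2 partial pressure (Pa), `ci_driven` only.
#' @param o O2 partial pressure (kPa).
#' @return An object of class `boundary_condition`.
#' @export
boundary_condition <- function(mode = c("ci_driven", "ca_driven"),
                               ca = NULL, gs = NULL, ci = NULL, o = 21) {
  mode <- match.arg(mode)
  if (o < 0) stop("`o` must be non-negative", call. = FALSE)
  if (mode == "ca_driven") {
    if (is.null(ca) || is.null(gs)) {
      stop("ca_driven mode requires `ca` and `gs`", call. = FALSE)
    }
    if (!is.null(ci)) stop("ca_driven mode does not take `ci`", call. = FALSE)
    if (ca < 0 || gs <= 0) stop("need ca >= 0 and gs > 0", call. = FALSE)
  } else {
    if (is.null(ci)) stop("ci_driven mode requires `ci`", call. = FALSE)
    if (!is.null(ca) || !is.null(gs)) {
      stop("ci_driven mode takes only `ci` and `o`", call. = FALSE)
    }
    if (ci < 0) stop("`ci` must be non-negative", call. = FALSE)
  }
  structure(list(mode = mode, ca = ca, gs = gs, ci = ci, o = o),
            class = "boundary_condition")
}

#' Solver controls
#'
#' @param nx,ny Default mesh resolution used by the higher-level drivers
#'   (fits, sweeps, generators) when they build a mesh internally.
#' @param tol_an Nonlinear convergence tolerance on |delta AN|
#'   (umol m-2 s-1).
#' @param tol_k Relative convergence tolerance on the frozen sink
#'   coefficient between Picard iterations (guards against premature stops
#'   when the sink is weak and AN barely responds to it).
#' @param max_iter Maximum Picard iterations.
#' @param damping Damping factor on the frozen sink coefficient and Rp.
#' @param ci_tol Tolerance on Ci for the ca_driven stomatal balance (Pa).
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(nx = 12L, ny = 40L, tol_an = 1e-6,
                           tol_k = 1e-6, max_iter = 200L, damping = 0.5,
                           ci_tol = 1e-6) {
  structure(list(nx = as.integer(nx), ny = as.integer(ny), tol_an = tol_an,
                 tol_k = tol_k, max_iter = as.integer(max_iter),
                 damping = damping, ci_tol = ci_tol),
            class = "solver_control")
}

# Assemble the constant part of the finite-volume operator from raw arrays.
# dx, dy: grid spacings; D: ny x nx cell diffusivities (m2 s-1);
# hmemb: (ny+1) x nx membrane codes on horizontal faces (0/1/2);
# vmemb: ny x (nx+1) codes on vertical faces. Code 1 -> p_pm, 2 -> p_env.
# Top boundary (face row 1) is a Dirichlet coupling; all other outer
# boundaries are no-flux (symmetry planes and tonoplast).
assemble_operator <- function(dx, dy, D, hmemb, vmemb, p_pm, p_env) {
  nx <- length(dx); ny <- length(dy); N <- nx * ny
  idx <- function(i, j) i + (j - 1L) * ny
  memb_res <- function(code) {
    ifelse(code == 1L, 1 / p_pm, ifelse(code == 2L, 1 / p_env, 0))
  }
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(N)
  add_face <- function(a, b, g) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); vv <<- c(vv, -g, -g)
    diag_acc[a] <<- diag_acc[a] + g
    diag_acc[b] <<- diag_acc[b] + g
  }
  # vertical faces between row i and i+1 (shared horizontal face, area dx_j)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny - 1L)) {
      r <- dy[i] / (2 * D[i, j]) + dy[i + 1L] / (2 * D[i + 1L, j]) +
        memb_res(hmemb[i + 1L, j])
      add_face(idx(i, j), idx(i + 1L, j), dx[j] / r)
    }
  }
  # horizontal faces between column j and j+1 (area dy_i)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx - 1L)) {
      r <- dx[j] / (2 * D[i, j]) + dx[j + 1L] / (2 * D[i, j + 1L]) +
        memb_res(vmemb[i, j + 1L])
      add_face(idx(i, j), idx(i, j + 1L), dy[i] / r)
    }
  }
  # top Dirichlet faces (airspace side of the wall)
  gtop <- dx / (dy[1L] / (2 * D[1L, ]))
  top_idx <- idx(1L, seq_len(nx))
  diag_acc[top_idx] <- diag_acc[top_idx] + gtop
  A0 <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                             x = c(vv, diag_acc), dims = c(N, N))
  # positions of the diagonal entries in A0@x, for fast sink updates
  diag_pos <- integer(N)
  for (j in seq_len(N)) {
    p <- (A0@p[j] + 1L):A0@p[j + 1L]
    diag_pos[j] <- p[A0@i[p] == j - 1L]
  }
  list(A0 = A0, gtop = gtop, top_idx = top_idx, diag_pos = diag_pos)
}

#' Build a reusable solver context
#'
#' Precomputes the sparse finite-volume operator, face conductances and
#' index sets for a mesh and transport parameter set, so that repeated
#' solves (curve fitting, response sweeps) do not reassemble the operator.
#' [solve_steady_state()] accepts either a mesh or a prebuilt context.
#'
#' @param mesh A [generate_mesh()] object.
#' @param transport A [transport_params()] object.
#' @return An object of class `solver_context`.
#' @export
build_solver_context <- function(mesh, transport = transport_params()) {
  stopifnot(inherits(mesh, "cell_mesh"), inherits(transport, "transport_params"))
  f_by_layer <- c(wall = transport$f_wall, outer_cytosol = transport$f_cyt,
                  stroma = transport$f_str, gap_cytosol = transport$f_cyt,
                  inner_cytosol = transport$f_cyt)
  D <- matrix(transport$d_water *
                f_by_layer[LAYER_LEVELS[mesh$layer]],
              nrow = mesh$ny, ncol = mesh$nx)
  op <- assemble_operator(mesh$dx, mesh$dy, D, mesh$hface, mesh$vface,
                          transport$p_pm, transport$p_env)
  area <- as.vector(outer(mesh$dy, mesh$dx))  # column-major: i + (j-1)*ny
  layer_vec <- LAYER_LEVELS[as.vector(mesh$layer)]
  structure(
    list(A0 = op$A0, gtop = op$gtop, top_idx = op$top_idx,
         diag_pos = op$diag_pos,
         area = area, layer = layer_vec,
         stroma_idx = which(layer_vec == "stroma"),
         source_idx = list(
           inner = which(layer_vec == "inner_cytosol"),
           gaps  = which(layer_vec == "gap_cytosol"),
           outer = which(layer_vec == "outer_cytosol")),
         nx = mesh$nx, ny = mesh$ny, W2 = mesh$W2,
         anatomy = mesh$anatomy, transport = transport, mesh = mesh),
    class = "solver_context"
  )
}

# Linear steady solve with a fixed first-order sink coefficient k (1/s per
# cell), a fixed volumetric source (Pa/s per cell), and airspace pressure
# ci_top (Pa). Returns the field and the boundary efflux bookkeeping.
# (Also used directly for the frozen-coefficient reassimilation tracer and
# for the one-dimensional slab verification problems.)
solve_linear_field <- function(ctx, k, source, ci_top) {
  A <- ctx$A0
  A@x[ctx$diag_pos] <- A@x[ctx$diag_pos] + k * ctx$area
  b <- source * ctx$area
  b[ctx$top_idx] <- b[ctx$top_idx] + ctx$gtop * ci_top
  cvec <- as.numeric(Matrix::solve(A, b))
  influx <- sum(ctx$gtop * (ci_top - cvec[ctx$top_idx]))  # Pa m2 s-1
  list(c = cvec, influx = influx)
}

# Single-layer slab context for verification: thickness L, n cells,
# diffusivity d, Dirichlet at y = 0, no-flux at y = L, unit width.
slab_context <- function(L, d, n, transport = transport_params()) {
  dx <- 1
  dy <- rep(L / n, n)
  D <- matrix(d, nrow = n, ncol = 1)
  hmemb <- matrix(0L, nrow = n + 1L, ncol = 1)
  vmemb <- matrix(0L, nrow = n, ncol = 2)
  op <- assemble_operator(dx, dy, D, hmemb, vmemb, transport$p_pm,
                          transport$p_env)
  structure(
    list(A0 = op$A0, gtop = op$gtop, top_idx = op$top_idx,
         diag_pos = op$diag_pos,
         area = dy, layer = rep("stroma", n),
         stroma_idx = seq_len(n),
         source_idx = list(inner = integer(0), gaps = integer(0),
                           outer = integer(0)),
         nx = 1L, ny = n, W2 = 1, anatomy = NULL, transport = transport,
         yc = cumsum(dy) - dy / 2),
    class = "solver_context"
  )
}

# Core nonlinear solve at fixed airspace pressure Ci.
solve_at_ci <- function(ctx, kin, o, ci, scenario, limitation, control,
                        init = NULL) {
  an <- ctx$anatomy
  conv <- ctx$transport$henry * 1e6      # umol m-3 per Pa
  # leaf-area rate (umol m-2 s-1) -> total per unit depth (Pa m2 s-1)
  leaf_to_cell <- ctx$W2 / (an$sm_s * conv)
  A_str <- sum(ctx$area[ctx$stroma_idx])
  src_idx <- ctx$source_idx[[scenario]]
  if (length(src_idx) == 0) {
    stop("scenario '", scenario, "' has an empty source region on this mesh",
         call. = FALSE)
  }
  A_src <- sum(ctx$area[src_idx])

  g_star <- gamma_star(o, kin$sco)
  kmc_eff <- kin$kmc * (1 + o / kin$kmo)
  vmax_pa <- kin$vcmax * leaf_to_cell / A_str    # Pa/s at saturation
  jvol_pa <- if (is.null(kin$j)) NULL else kin$j * leaf_to_cell / A_str
  rd_flux <- kin$rd * leaf_to_cell               # Pa m2 s-1

  n_cells <- length(ctx$area)
  cvec <- if (is.null(init)) rep(max(ci, g_star, 1), n_cells) else init
  k <- numeric(n_cells)
  rp <- 0
  an_prev <- NA_real_
  residuals <- numeric(0)
  converged <- FALSE
  damping <- control$damping

  sink_coef <- function(cstr) {
    k_c <- vmax_pa / (cstr + kmc_eff)
    k_j <- if (is.null(jvol_pa)) Inf else (jvol_pa / 4) / (cstr + 2 * g_star)
    switch(limitation,
           dynamic = pmin(k_c, k_j),
           rubisco = k_c,
           electron_transport = {
             if (is.null(jvol_pa)) {
               stop("electron-transport limitation requires `j`", call. = FALSE)
             }
             k_j
           })
  }

  for (iter in seq_len(control$max_iter)) {
    k_new <- numeric(n_cells)
    k_new[ctx$stroma_idx] <- sink_coef(cvec[ctx$stroma_idx])
    rp_new <- g_star * sum(k_new[ctx$stroma_idx] * ctx$area[ctx$stroma_idx])
    k_settled <- max(abs(k - k_new)) <= control$tol_k * (max(k_new) + 1e-300)
    if (iter == 1L) {
      k <- k_new; rp <- rp_new
    } else {
      k <- damping * k + (1 - damping) * k_new
      rp <- damping * rp + (1 - damping) * rp_new
    }
    source <- numeric(n_cells)
    source[src_idx] <- (rd_flux + rp) / A_src
    sol <- solve_linear_field(ctx, k, source, ci)
    cnew <- sol$c
    halvings <- 0L
    while (any(cnew < 0) && halvings < 8L) {
      cnew <- 0.5 * (cnew + cvec)
      halvings <- halvings + 1L
    }
    if (any(cnew < 0)) {
      stop("negative concentrations persisted after step halving",
           call. = FALSE)
    }
    cvec <- cnew
    an_mes <- sol$influx / ctx$W2 * conv           # umol m-2 s-1 mesophyll
    an_leaf <- an_mes * an$sm_s
    residuals <- c(residuals, if (is.na(an_prev)) NA_real_
                   else abs(an_leaf - an_prev))
    if (!is.na(an_prev) && abs(an_leaf - an_prev) < control$tol_an &&
        k_settled && iter >= 3L) {
      converged <- TRUE
      an_prev <- an_leaf
      break
    }
    an_prev <- an_leaf
  }
  if (!converged) {
    stop(sprintf("Picard iteration did not converge in %d iterations (last |dAN| = %.3g)",
                 control$max_iter, utils::tail(residuals, 1)),
         call. = FALSE)
  }
  cell_to_leaf <- 1 / leaf_to_cell
  vc_tot <- sum(k * cvec * ctx$area) * cell_to_leaf
  rp_tot <- rp * cell_to_leaf
  cc <- sum(cvec[ctx$stroma_idx] * ctx$area[ctx$stroma_idx]) / A_str
  list(c = cvec, an = an_prev, ci = ci, cc = cc,
       vc_tot = vc_tot, rp_tot = rp_tot, vo_tot = 2 * rp_tot,
       k = k, rp_cell = rp, rd_flux = rd_flux, src_idx = src_idx,
       A_src = A_src, iterations = iter,
       residual = utils::tail(residuals, 1), residual_history = residuals)
}

#' Solve the steady-state reaction-diffusion problem on the unit cell
#'
#' Solves `div(D_eff grad C) - sink(C) + source = 0` on the meshed unit
#' cell. The Michaelis-Menten carboxylation sink acts in the stroma; all
#' (photo)respiratory release `Rd + Rp` is injected uniformly into the
#' scenario's source region, with the photorespiratory part
#' `Rp = Gamma* * integral(w/C)` updated by damped fixed-point iteration.
#' Under `ca_driven` boundary conditions the airspace pressure Ci is solved
#' from the stomatal balance `AN = gs (Ca - Ci)` by root bracketing.
#'
#' @param mesh A [generate_mesh()] mesh or a prebuilt
#'   [build_solver_context()] (the latter avoids reassembly in loops).
#' @param kinetics A [kinetic_params()] object; `j` must be set unless the
#'   electron-transport branch is to be disabled.
#' @param transport A [transport_params()] object (ignored when `mesh` is
#'   already a context).
#' @param boundary A [boundary_condition()] object.
#' @param scenario Release scenario, `"inner"`, `"gaps"` or `"outer"`;
#'   defaults to the scenario the mesh was built with.
#' @param limitation Local limitation rule: `"dynamic"` (pointwise minimum
#'   of the Rubisco and electron-transport rates), `"rubisco"`, or
#'   `"electron_transport"`.
#' @param control A [solver_control()] object.
#' @param tracer If `TRUE`, also run the frozen-coefficient tracer solve and
#'   store the reassimilated fraction `freass` in the result.
#' @param init Optional initial concentration field (vector of length
#'   nx*ny), e.g. from a previous solve at nearby conditions.
#' @return An object of class `rd_solve` with elements `an` (net
#'   assimilation, umol m-2 s-1 leaf, TPU-capped when `tp` is set),
#'   `an_uncapped`, `ci`, `cc` (stroma volume-mean, Pa), `vc_tot`, `vo_tot`,
#'   `rp_tot`, `gm` (apparent mesophyll conductance), `freass` (if
#'   requested), the concentration `field` (ny x nx, Pa), `iterations`,
#'   `residual`, and internals for [flux_report()] and
#'   [reassimilation_fraction()].
#' @export
solve_steady_state <- function(mesh, kinetics, transport = transport_params(),
                               boundary, scenario = NULL,
                               limitation = c("dynamic", "rubisco",
                                              "electron_transport"),
                               control = solver_control(), tracer = FALSE,
                               init = NULL) {
  limitation <- match.arg(limitation)
  stopifnot(inherits(kinetics, "kinetic_params"),
            inherits(boundary, "boundary_condition"))
  ctx <- if (inherits(mesh, "solver_context")) mesh
         else build_solver_context(mesh, transport)
  if (is.null(scenario)) scenario <- ctx$mesh$scenario
  if (!scenario %in% SCENARIOS) {
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  }
  o <- boundary$o

  if (boundary$mode == "ci_driven") {
    sol <- solve_at_ci(ctx, kinetics, o, boundary$ci, scenario, limitation,
                       control, init = init)
  } else {
    warm <- init
    f <- function(ci) {
      s <- solve_at_ci(ctx, kinetics, o, ci, scenario, limitation, control,
                       init = warm)
      warm <<- s$c
      s$an - boundary$gs * (boundary$ca - ci)
    }
    upper <- max(boundary$ca * 1.5, boundary$ca + 5)
    root <- stats::uniroot(f, lower = 0, upper = upper,
                           tol = control$ci_tol)
    sol <- solve_at_ci(ctx, kinetics, o, root$root, scenario, limitation,
                       control, init = warm)
  }

  an_uncapped <- sol$an
  tpu_capped <- FALSE
  an <- an_uncapped
  if (!is.null(kinetics$tp)) {
    cap <- 3 * kinetics$tp - kinetics$rd
    if (an > cap) {
      an <- cap
      tpu_capped <- TRUE
    }
  }
  gm <- if (abs(sol$ci - sol$cc) > 1e-9) an_uncapped / (sol$ci - sol$cc)
        else NA_real_

  res <- structure(
    list(an = an, an_uncapped = an_uncapped, tpu_capped = tpu_capped,
         ci = sol$ci, cc = sol$cc, vc_tot = sol$vc_tot, vo_tot = sol$vo_tot,
         rp_tot = sol$rp_tot, rd = kinetics$rd, gm = gm, freass = NA_real_,
         o = o, scenario = scenario, limitation = limitation,
         field = matrix(sol$c, nrow = ctx$ny, ncol = ctx$nx),
         iterations = sol$iterations, residual = sol$residual,
         residual_history = sol$residual_history,
         boundary = boundary,
         internals = list(ctx = ctx, k = sol$k, rp_cell = sol$rp_cell,
                          rd_flux = sol$rd_flux, src_idx = sol$src_idx,
                          A_src = sol$A_src, c = sol$c)),
    class = "rd_solve"
  )
  if (tracer) res$freass <- reassimilation_fraction(res)
  res
}

#' @export
print.rd_solve <- function(x, ...) {
  cat(sprintf("<rd_solve> scenario '%s', %s boundary\n", x$scenario,
              x$boundary$mode))
  cat(sprintf("  AN = %.4f umol m-2 s-1 (Ci = %.3f Pa, Cc = %.3f Pa)\n",
              x$an, x$ci, x$cc))
  cat(sprintf("  Vc = %.4f, Rp = %.4f, Rd = %.4f, gm = %.4f%s\n",
              x$vc_tot, x$rp_tot, x$rd, x$gm,
              if (is.na(x$freass)) "" else sprintf(", freass = %.3f", x$freass)))
  cat(sprintf("  %d Picard iterations, |dAN| = %.2g%s\n", x$iterations,
              x$residual, if (x$tpu_capped) " [TPU-capped]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rd_solve <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario, an = x$an, ci = x$ci, cc = x$cc,
    vc_tot = x$vc_tot, vo_tot = x$vo_tot, rp_tot = x$rp_tot, rd = x$rd,
    gm = x$gm, freass = x$freass, tpu_capped = x$tpu_capped,
    iterations = x$iterations
  )
}

#' Conservation audit of a converged solve
#'
#' Checks the discrete flux balance of the converged (uncapped) solution:
#' boundary influx must equal total carboxylation minus total release
#' (`Rp + Rd`), i.e. `AN = Vc - Rp - Rd`.
#'
#' @param result An [solve_steady_state()] result.
#' @param rd Day respiration used in the solve; defaults to the stored one.
#' @return A one-row tibble with `influx`, `carboxylation`, `release`
#'   (all umol m-2 s-1 leaf) and the relative `closure_error`.
#' @export
flux_report <- function(result, rd = result$rd) {
  stopifnot(inherits(result, "rd_solve"))
  influx <- result$an_uncapped
  carbox <- result$vc_tot
  release <- result$rp_tot + rd
  closure <- abs(influx - (carbox - release)) / max(abs(influx), 1)
  tibble::tibble(influx = influx, carboxylation = carbox, release = release,
                 closure_error = closure)
}

#' Apparent mesophyll conductance
#'
#' `gm = AN / (Ci - Cc)` with `Cc` the stroma volume-mean CO2 pressure of
#' the converged field.
#'
#' @param result An [solve_steady_state()] result.
#' @return gm (umol m-2 s-1 Pa-1, leaf area).
#' @export
apparent_gm <- function(result) {
  stopifnot(inherits(result, "rd_solve"))
  if (abs(result$ci - result$cc) < 1e-9) {
    stop("Ci and Cc coincide; apparent gm is undefined", call. = FALSE)
  }
  result$an_uncapped / (result$ci - result$cc)
}

#' Fraction of (photo)respired CO2 that is reassimilated
#'
#' Runs a linear tracer solve on the frozen-coefficient linearization of the
#' converged state: the carboxylation sink is fixed at `k(x) = w(x)/C(x)`,
#' the tracer source is the total release `Rp + Rd` in the scenario's source
#' region, and the airspace boundary is held at zero tracer pressure. The
#' reassimilated fraction is `1 - efflux / (Rp + Rd)`; tracer conservation
#' (consumption + efflux = source) holds to the linear-solver accuracy.
#'
#' @param result An [solve_steady_state()] result.
#' @param rd Day respiration used in the solve; defaults to the stored one.
#' @return `freass` in `[0, 1]`.
#' @export
reassimilation_fraction <- function(result, rd = result$rd) {
  stopifnot(inherits(result, "rd_solve"))
  int <- result$internals
  ctx <- int$ctx
  rd_flux <- if (identical(rd, result$rd)) int$rd_flux
             else int$rd_flux * rd / result$rd
  s_tot <- rd_flux + int$rp_cell
  # release in cell units is O(1e-9) for leaf rates of order 1; treat
  # anything below 1e-18 as an absent source
  if (s_tot <= 1e-18) {
    stop("no (photo)respiratory release; freass is undefined", call. = FALSE)
  }
  source <- numeric(length(ctx$area))
  source[int$src_idx] <- s_tot / int$A_src
  tr <- solve_linear_field(ctx, int$k, source, ci_top = 0)
  efflux <- -tr$influx                      # outward across the wall surface
  consumed <- sum(int$k * tr$c * ctx$area)
  if (abs((consumed + efflux - s_tot) / s_tot) > 1e-8) {
    warning("tracer conservation residual above 1e-8")
  }
  1 - efflux / s_tot
}
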