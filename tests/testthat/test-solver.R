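test_that("equilibrium: no sources, no sink gives a uniform field", {
  ctx <- quick_ctx("inner")
  kin <- kinetic_params(vcmax = 1e-12, j = 1e-12, rd = 0)
  bc <- boundary_condition("ci_driven", ci = 30, o = 21)
  sol <- solve_steady_state(ctx, kin, boundary = bc)
  expect_lt(max(abs(sol$field - 30)), 1e-8)
  expect_lt(abs(sol$an), 1e-8)
  expect_equal(sol$cc, 30, tolerance = 1e-9)
})

test_that("1D slab with first-order sink matches the cosh closed form", {
  L <- 2.5e-6
  d <- 5.37e-10
  k <- d * (1.5 / L)^2  # moderate Thiele modulus
  c0 <- 20
  ctx <- mesodiff:::slab_context(L, d, 40)
  sol <- mesodiff:::solve_linear_field(ctx, rep(k, 40), rep(0, 40), c0)
  exact <- slab_cosh_profile(ctx$yc, L, d, k, c0)
  expect_lt(max(abs(sol$c - exact) / exact), 1e-3)
  # second-order convergence under refinement
  ctx2 <- mesodiff:::slab_context(L, d, 80)
  sol2 <- mesodiff:::solve_linear_field(ctx2, rep(k, 80), rep(0, 80), c0)
  exact2 <- slab_cosh_profile(ctx2$yc, L, d, k, c0)
  err1 <- max(abs(sol$c - exact) / exact)
  err2 <- max(abs(sol2$c - exact2) / exact2)
  expect_lt(err2, err1 / 3)
})

test_that("well-mixed limit reproduces the leaf-level FvCB rate", {
  tr <- transport_params(d_water = 1.79e-9 * 1e6, p_pm = 3.5e3, p_env = 3.5e3)
  mesh <- generate_mesh(build_unit_cell(ho_anatomy(), "inner"), c(8, 24))
  ctx <- build_solver_context(mesh, tr)
  kin <- kinetic_params(vcmax = 120, j = 160, rd = 1.5)
  for (ci in c(5, 20)) {
    bc <- boundary_condition("ci_driven", ci = ci, o = 21)
    sol <- solve_steady_state(ctx, kin, boundary = bc)
    expect_equal(sol$an, fvcb_assimilation(ci, kin, "dynamic", o = 21),
                 tolerance = 5e-3)
  }
})

test_that("flux balance closes for converged solves", {
  ctx <- quick_ctx("inner")
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 1.5)
  bc <- boundary_condition("ci_driven", ci = 25, o = 21)
  sol <- solve_steady_state(ctx, kin, boundary = bc)
  rep <- flux_report(sol)
  expect_lt(rep$closure_error, 1e-6)
  expect_equal(sol$vo_tot, 2 * sol$rp_tot)
  # zero-kinetics solve reports zero everywhere
  kin0 <- kinetic_params(vcmax = 1e-12, j = 1e-12, rd = 0)
  rep0 <- flux_report(solve_steady_state(ctx, kin0, boundary = bc))
  expect_lt(abs(rep0$carboxylation), 1e-9)
  expect_lt(abs(rep0$release), 1e-9)
})

test_that("mesh refinement changes AN by less than half a percent", {
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 1.5)
  bc <- boundary_condition("ci_driven", ci = 25, o = 21)
  geom <- build_unit_cell(ho_anatomy(), "inner")
  s1 <- solve_steady_state(generate_mesh(geom, c(8, 24)), kin, boundary = bc)
  s2 <- solve_steady_state(generate_mesh(geom, c(16, 48)), kin, boundary = bc)
  expect_lt(abs(s2$an - s1$an) / abs(s2$an), 5e-3)
})

test_that("ca_driven mode satisfies the stomatal balance", {
  ctx <- quick_ctx("inner")
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 1.5)
  bc <- boundary_condition("ca_driven", ca = 40, gs = 1.5, o = 21)
  sol <- solve_steady_state(ctx, kin, boundary = bc)
  expect_equal(sol$an, 1.5 * (40 - sol$ci), tolerance = 1e-4)
  expect_lt(sol$ci, 40)
})

test_that("solves are deterministic", {
  ctx <- quick_ctx("inner")
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 1.5)
  bc <- boundary_condition("ci_driven", ci = 25, o = 21)
  s1 <- solve_steady_state(ctx, kin, boundary = bc)
  s2 <- solve_steady_state(ctx, kin, boundary = bc)
  expect_identical(s1$field, s2$field)
  expect_identical(s1$an, s2$an)
})

test_that("apparent gm follows AN/(Ci - Cc) and guards the degenerate case", {
  ctx <- quick_ctx("inner")
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 1.5)
  bc <- boundary_condition("ci_driven", ci = 25, o = 21)
  sol <- solve_steady_state(ctx, kin, boundary = bc)
  expect_equal(apparent_gm(sol), sol$an_uncapped / (sol$ci - sol$cc))
  # equilibrium solve: Ci = Cc, conductance undefined
  kin0 <- kinetic_params(vcmax = 1e-12, j = 1e-12, rd = 0)
  sol0 <- solve_steady_state(ctx, kin0, boundary = bc)
  expect_error(apparent_gm(sol0), "undefined")
})

test_that("scenario orderings of gm and freass hold at matched inputs", {
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 1.5)
  bc <- boundary_condition("ci_driven", ci = 25, o = 21)
  sols <- lapply(c("inner", "gaps", "outer"), function(sc) {
    solve_steady_state(quick_ctx(sc), kin, boundary = bc, scenario = sc,
                       tracer = TRUE)
  })
  gms <- vapply(sols, function(s) s$gm, 0)
  fr <- vapply(sols, function(s) s$freass, 0)
  expect_true(gms[1] > gms[2] && gms[2] > gms[3])
  expect_true(fr[1] >= fr[3])
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("freass tracer limits: no sink gives 0, sealed membrane gives 1", {
  bc <- boundary_condition("ci_driven", ci = 25, o = 21)
  # carboxylation disabled: all respired CO2 escapes
  kin0 <- kinetic_params(vcmax = 1e-12, j = 1e-12, rd = 2)
  sol0 <- solve_steady_state(quick_ctx("inner"), kin0, boundary = bc,
                             tracer = TRUE)
  expect_equal(sol0$freass, 0, tolerance = 1e-6)
  # near-sealed plasma membrane with an active sink: nothing escapes
  tr_seal <- transport_params(p_pm = 1e-12)
  mesh <- generate_mesh(build_unit_cell(ho_anatomy(), "inner"), c(8, 24))
  ctx_seal <- build_solver_context(mesh, tr_seal)
  kin <- kinetic_params(vcmax = 120, j = 200, rd = 0.5)
  sol1 <- solve_steady_state(ctx_seal, kin, boundary = bc, tracer = TRUE)
  expect_gt(sol1$freass, 0.999)
  # undefined when there is no release at all
  kinr0 <- kinetic_params(vcmax = 1e-12, j = 1e-12, rd = 0)
  solr0 <- solve_steady_state(quick_ctx("inner"), kinr0, boundary = bc)
  expect_error(reassimilation_fraction(solr0), "undefined")
})

test_that("freass tracer agrees with the random-walk particle oracle", {
  ctx <- quick_ctx("inner", ctrl = solver_control(nx = 6, ny = 20),
                   label = "coarse")
  kin <- kinetic_params(vcmax = 120, j = 150, rd = 1.5)
  bc <- boundary_condition("ci_driven", ci = 20, o = 21)
  sol <- solve_steady_state(ctx, kin, boundary = bc, tracer = TRUE)
  mc <- rw_freass(sol, n_walkers = 2e4, seed = 11L)
  expect_equal(mc, sol$freass, tolerance = 0.02)
})

test_that("boundary condition constructor enforces its mode contract", {
  expect_error(boundary_condition("ca_driven", ca = 40), "requires")
  expect_error(boundary_condition("ci_driven"), "requires")
  expect_error(boundary_condition("ci_driven", ci = 20, ca = 40), "only")
  expect_error(boundary_condition("ci_driven", ci = -5), "non-negative")
  expect_error(transport_params(f_str = 1.5), "<= 1")
})
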