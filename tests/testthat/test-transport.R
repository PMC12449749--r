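# a single-constituent system whose only form is neutral (conjugate acid of
# an extremely strong base), transported by diffusion alone
neutral_tracer_system <- function(mobility = 2.50) {
  ce_system(list(ce_constituent("tracer", "weak-base", mobility, -10)))
}

gaussian_column <- function(system, n = 2000, L = 10, x0 = 5, sigma = 0.5,
                            amp = 1, constituent = "tracer") {
  dx <- L / n
  x <- (seq_len(n) - 0.5) * dx
  totals <- matrix(amp * exp(-(x - x0)^2 / (2 * sigma^2)), nrow = 1,
                   dimnames = list(constituent, NULL))
  structure(list(x_mm = x, dx_mm = dx, totals = totals, length_mm = L,
                 boundary_width = 0, system = system),
            class = "ce_column")
}

profile_variance <- function(x_mm, c) {
  m <- sum(c * x_mm) / sum(c)
  sum(c * (x_mm - m)^2) / sum(c)     # mm^2
}

test_that("a uniform column under voltage is a stationary solution", {
  zones <- list(ce_zone(0, 50, bge_composition()))
  col <- build_column(zones, the_system, n_cells = 500)
  out <- step_state(col, dt = 1e-3, voltage = 400)
  expect_identical(out$totals, col$totals)  # machine-exact
})

test_that("fluxes vanish for a uniform profile at zero field", {
  zones <- list(ce_zone(0, 50, bge_composition()))
  col <- build_column(zones, the_system, n_cells = 300)
  fd <- field_solve(col, voltage = 0)
  fl <- constituent_fluxes(col, fd)
  expect_equal(max(abs(fl)), 0)
})

test_that("a fully ionized anion advects as a plug at -u c E", {
  # uniform sodium chloride column: chloride flux is -u_Cl c E everywhere,
  # sodium flux is +u_Na c E
  zones <- list(ce_zone(0, 50, c(sodium = 10, chloride = 10)))
  col <- build_column(zones, the_system, n_cells = 300)
  fd <- field_solve(col, voltage = 400)
  fl <- constituent_fluxes(col, fd)
  E <- fd$E[1]
  expect_equal(unname(fl["chloride", 150]), -7.91e-8 * 10 * E,
               tolerance = 1e-6)
  expect_equal(unname(fl["sodium", 150]), 5.19e-8 * 10 * E,
               tolerance = 1e-6)
})

test_that("the stable step obeys the CFL and diffusion bounds", {
  sc <- scenario("fig2_base", the_system, n_cells = 1000)
  fd <- field_solve(sc$state)
  dt1 <- stable_dt(sc$state, fd)
  sc2 <- scenario("fig2_base", the_system, n_cells = 2000)
  fd2 <- field_solve(sc2$state)
  dt2 <- stable_dt(sc2$state, fd2)
  # halving dx at most halves an advection-limited step
  expect_lte(dt2, dt1 / 2 * (1 + 1e-6))
  # zero field: the diffusion bound alone
  fd0 <- field_solve(sc$state, voltage = 0)
  ft <- cesim:::form_table(the_system)
  dx <- sc$state$dx_mm * 1e-3
  expect_equal(stable_dt(sc$state, fd0), 0.4 * dx^2 / (2 * max(ft$D)),
               tolerance = 1e-12)
  # the advection-limited case is CFL-limited, not diffusion-limited
  vmax <- max(abs(ft$su)) * max(fd$E)
  expect_lt(dx / vmax, dx^2 / (2 * max(ft$D)))
})

test_that("a neutral Gaussian spreads by 2 D t at zero voltage", {
  sys <- neutral_tracer_system()
  D <- ce_constants()$gas_constant * 298.15 / 96485.33212 * 2.50e-8  # m^2/s
  col <- gaussian_column(sys, n = 2000)
  run <- run_simulation(col, until = 100, voltage = 0,
                        snapshot_times = c(0, 100))
  v0 <- profile_variance(col$x_mm, col$totals[1, ])
  v1 <- profile_variance(run$x_mm, run$snapshots[[2]][1, ])
  growth_mm2 <- v1 - v0
  expect_equal(growth_mm2 * 1e-6, 2 * D * 100, tolerance = 0.01)
})

test_that("interior mass is conserved exactly by the finite-volume update", {
  sc <- scenario("fig2_base", the_system, n_cells = 500)
  before <- rowSums(sc$state$totals)
  out <- step_state(sc$state, dt = 5e-4, boundary = "closed")
  after <- rowSums(out$totals)
  expect_equal(after, before, tolerance = 1e-12)
  # and over many closed-box steps
  run <- run_simulation(sc, until = 2, n_cells = 500, boundary = "closed",
                        snapshot_times = c(0, 2))
  expect_equal(rowSums(run$snapshots[[2]]), before, tolerance = 1e-10)
})

test_that("a requested step beyond the stable limit is refused", {
  sc <- scenario("fig2_base", the_system, n_cells = 500)
  fd <- field_solve(sc$state)
  expect_error(step_state(sc$state, dt = 100 * stable_dt(sc$state, fd)),
               "stable")
})

test_that("the two-ion moving boundary matches an independent brute-force solver", {
  # sodium chloride zone ahead of a sodium formate zone: the anion boundary
  # migrates anodically at the local chloride velocity
  n <- 400; L <- 0.02
  zones <- list(ce_zone(0, 10, c(sodium = 10, chloride = 10)),
                ce_zone(10, 20, c(sodium = 10, formic = 10)))
  col <- build_column(zones, the_system, n_cells = n, boundary_width = 0)
  t_end <- 4
  run <- run_simulation(col, until = t_end, voltage = 400,
                        snapshot_times = c(0, t_end / 2, t_end),
                        limiter = "none")
  x <- col$x_mm
  c1_0 <- col$totals["chloride", ]
  c1_T <- run$snapshots[[3]]["chloride", ]
  b0 <- half_cross(x, c1_0, 5)
  bT <- half_cross(x, c1_T, 5)
  v_engine <- (bT - b0) / t_end                      # mm/s, negative = anodic

  o_T <- two_ion_oracle(c1 = col$totals["chloride", ],
                        c2 = col$totals["formic", ], n = n, L_m = L,
                        voltage = 400, t_end = t_end,
                        u1 = 7.91e-8, u2 = 5.66e-8, uNa = 5.19e-8)
  v_oracle <- (half_cross(x, o_T, 5) - b0) / t_end
  expect_equal(v_engine, v_oracle, tolerance = 0.02)

  # classical moving-boundary equation: the boundary travels at the chloride
  # velocity of the leading zone, v = -u_Cl E1 (E1 time-averaged by Simpson
  # over the run as the current decays)
  E1 <- vapply(1:3, function(k) {
    st <- col; st$totals <- run$snapshots[[k]]
    fd <- field_solve(st, voltage = 400)
    fd$E[which.min(abs(x - 2))]
  }, 0)
  v_mbe <- -7.91e-8 * sum(E1 * c(1, 4, 1)) / 6 * 1e3   # mm/s
  expect_equal(v_engine, v_mbe, tolerance = 0.05)
})

test_that("all analytes move cathodically at low selector concentration", {
  run <- cached("cd1pct_30", run_simulation(
    "cd_1pct", until = 30, n_cells = 1000, snapshot_times = seq(0, 30, 2)))
  for (a in analyte_names(the_system)) {
    com <- vapply(run$snapshots, function(s)
      sum(s[a, ] * run$x_mm) / sum(s[a, ]), 0)
    expect_true(all(diff(com) > -run$dx_mm / 2))
  }
})
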