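test_that("the packaged scenario library is complete and parameterized as stated", {
  expect_setequal(scenario_names(),
                  c("fig2_base", "cd_plug_5mm", "cd_plug_10mm", "sample_2mm",
                    "shallow_gradient", "wide_boundaries_0p5mm",
                    "matrix_bge_1to10", "matrix_bge_1to2", "matrix_bge_full",
                    "cd_2pct", "cd_1pct", "cd_0p5pct"))
  base <- scenario("fig2_base", the_system, n_cells = 500)
  expect_equal(base$config$sample_mm, c(24.5, 25.5))
  expect_equal(diff(base$config$plug_mm), 15)
  expect_equal(base$config$voltage, 400)
  # selector plug plateau at 19 mM with 247 mM sodium
  mid <- which.min(abs(base$state$x_mm - mean(base$config$plug_mm)))
  expect_equal(unname(base$state$totals["hs-g-cd", mid]), 19)
  expect_equal(unname(base$state$totals["sodium", mid]), 247)
  # catholyte: selector-free, sodium-free, same buffer otherwise
  endc <- ncol(base$state$totals)
  expect_equal(unname(base$state$totals["hs-g-cd", endc]), 0)
  expect_equal(unname(base$state$totals["sodium", endc]), 0)
  expect_equal(unname(base$state$totals["formic", endc]), 2380)
  # reduced-selector scenario: 7.6 mM selector with 98.8 mM NaOH
  p2 <- scenario("cd_2pct", the_system, n_cells = 500)
  expect_equal(p2$config$cd_mM, 7.6)
  expect_equal(p2$config$naoh_mM, 98.8)
  mid2 <- which.min(abs(p2$state$x_mm - mean(p2$config$plug_mm)))
  expect_equal(unname(p2$state$totals["sodium", mid2]), 98.8)
  # matrix scenario: ten-fold diluted BGE carries 1.9 mM selector
  mx <- scenario("matrix_bge_1to10", the_system, n_cells = 500)
  smid <- which.min(abs(mx$state$x_mm - 25))
  expect_equal(unname(mx$state$totals["hs-g-cd", smid]), 1.9)
  expect_error(scenario("no_such_thing"), "available")
})

test_that("zone integrals match the analytic amounts", {
  sc <- scenario("fig2_base", the_system, n_cells = 2000)
  # 1 mm of 20 uM analyte, regardless of the boundary smoothing
  amt <- zone_amount(sc$state, "S-ketamine")
  expect_equal(amt, 0.020 * 1e-3, tolerance = 1e-3)
  # selector: 24.5 mm of BGE plus 15 mm of plug
  cd <- zone_amount(sc$state, "hs-g-cd")
  expect_equal(cd, 19 * (24.5 + 15) * 1e-3, tolerance = 1e-3)
})

test_that("sampled analyte amounts are identical across zone-geometry variants", {
  a1 <- zone_amount(scenario("fig2_base", the_system, 1000)$state,
                    "R-hydroxynorketamine")
  a2 <- zone_amount(scenario("sample_2mm", the_system, 1000)$state,
                    "R-hydroxynorketamine")
  a3 <- zone_amount(scenario("wide_boundaries_0p5mm", the_system, 1000)$state,
                    "R-hydroxynorketamine")
  expect_equal(a2, a1, tolerance = 1e-3)
  expect_equal(a3, a1, tolerance = 1e-3)
})

test_that("grid refinement leaves zone integrals unchanged", {
  a <- zone_amount(scenario("fig2_base", the_system, 2000)$state, "hs-g-cd")
  b <- zone_amount(scenario("fig2_base", the_system, 4000)$state, "hs-g-cd")
  expect_equal(b, a, tolerance = 1e-4)
})

test_that("zero boundary width recovers exact step profiles", {
  zones <- list(ce_zone(0, 20, c(formic = 100, sodium = 50)),
                ce_zone(20, 50, c(formic = 10, sodium = 5)))
  col <- build_column(zones, the_system, n_cells = 500, boundary_width = 0)
  expect_true(all(col$totals["formic", ] %in% c(100, 10)))
  expect_identical(unname(col$totals["formic", col$x_mm < 20]),
                   rep(100, sum(col$x_mm < 20)))
})

test_that("a linear ramp zone produces a straight gradient", {
  zones <- list(ce_zone(0, 10, c(formic = 0)),
                ce_zone(10, 20, c(formic = 0), ramp = "linear"),
                ce_zone(20, 30, c(formic = 100)))
  col <- build_column(zones, the_system, n_cells = 300, boundary_width = 0)
  inside <- col$x_mm > 10 & col$x_mm < 20
  f <- col$totals["formic", inside]
  expect_equal(max(abs(diff(diff(f)))), 0, tolerance = 1e-10)  # straight line
  expect_equal(f[1], 100 * (col$x_mm[inside][1] - 10) / 10, tolerance = 1e-6)
})

test_that("malformed zone layouts are rejected", {
  z1 <- ce_zone(0, 10, c(formic = 1))
  z2 <- ce_zone(12, 20, c(formic = 2))
  expect_error(build_column(list(z1, z2), the_system, 500), "tile")
  z3 <- ce_zone(10, 11, c(formic = 2))
  z4 <- ce_zone(11, 20, c(formic = 3))
  expect_error(build_column(list(z1, z3, z4), the_system, 500,
                            boundary_width = 2), "exceeds")
  expect_error(build_column(list(z1), the_system, n_cells = 50), "n_cells")
  expect_error(ce_zone(5, 3, c(formic = 1)))
})

test_that("every scenario's initial state is cell-wise electroneutral after speciation", {
  for (nm in c("fig2_base", "cd_2pct", "matrix_bge_1to2", "shallow_gradient")) {
    st <- scenario(nm, the_system, n_cells = 300)$state
    sp <- cesim:::cpp_speciate(st$totals, the_system$cpp)
    # recompute the net charge per cell from closed-form fractions
    worst <- 0
    for (j in seq_len(ncol(st$totals))) {
      h <- sp$h[j]
      g <- 1000 * (h - 1e-14 / h)
      scale <- 1000 * (h + 1e-14 / h)
      for (nm_i in rownames(st$totals)) {
        z <- the_system$constituents[[nm_i]]
        Ka <- 10^(-z$pKa)
        zb <- switch(z$kind, "weak-base" = h / (h + Ka),
                     "weak-acid" = -Ka / (Ka + h),
                     "multi-site-anion" = -z$site_count * Ka / (Ka + h))
        g <- g + zb * st$totals[nm_i, j]
        scale <- scale + abs(zb) * st$totals[nm_i, j]
      }
      worst <- max(worst, abs(g) / scale)
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("system configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(c(path, path2)), add = TRUE)
  write_system_yaml(the_system, path)
  back <- read_system_yaml(path)
  expect_equal(back$cpp, the_system$cpp, tolerance = 1e-12)
  # idempotence: emit -> parse -> emit reproduces the document
  path2 <- tempfile(fileext = ".yaml")
  write_system_yaml(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
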