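test_that("the selector BGE recipe equilibrates at the reported pH", {
  eq <- solve_equilibrium(bge_composition(), the_system)
  expect_equal(eq$pH, 1.90, tolerance = 0.01 / 1.90)
  expect_gt(eq$conductivity, 0)
  # charge balance recomputed from the species table
  resid <- sum(eq$species$charge * eq$species$concentration)
  expect_lt(abs(resid),
            1e-9 * sum(abs(eq$species$charge) * eq$species$concentration))
})

test_that("pure water shows autoprotolysis symmetry", {
  k <- ce_constants()
  eq <- solve_equilibrium(c(), the_system)
  expect_equal(eq$pH, 7, tolerance = 1e-9)
  expect_equal(eq$conductivity,
               k$faraday * 1e-4 * (k$h_mobility + k$oh_mobility),
               tolerance = 1e-6)
})

test_that("the acetic sample matrix pH matches the closed-form oracle", {
  # analyte and chloride terms cancel in the charge balance, leaving the
  # mono-protic weak-acid quadratic
  eq <- solve_equilibrium(sample_composition(), the_system)
  expect_equal(eq$pH, quadratic_acid_pH(0.083, 4.76), tolerance = 1e-6)
  expect_equal(eq$pH, 2.92, tolerance = 0.01 / 2.92)
})

test_that("the 1:1 bound fraction follows the binding isotherm", {
  st <- solve_equilibrium(c(bge_composition(), "S-ketamine" = 1e-6),
                          the_system)
  bound <- st$complexes[["S-ketamine.hs-g-cd"]] / 1e-6
  # closed form K cL / (1 + K cL) with cL = 19 mM and K = 579 1/M
  expect_equal(bound, 579 * 0.019 / (1 + 579 * 0.019), tolerance = 1e-3)
  # and exactly, with the solved free-ligand concentration
  cL <- st$cfree[["hs-g-cd"]] / 1000
  expect_equal(bound, 579 * cL / (1 + 579 * cL), tolerance = 1e-12)
})

test_that("conductivity is the hand-summed species contribution", {
  # neutralized selector solution: 247 mM Na+ against 19 mM of a -13 ion
  eq <- solve_equilibrium(c(sodium = 247, "hs-g-cd" = 19), the_system)
  hand <- 96485.33212 * (247 * 5.19e-8 + 13 * 19 * 2.0e-8)
  expect_equal(conductivity(eq), hand, tolerance = 1e-3)
  # additivity: kappa equals the sum over charged species at fixed speciation
  sp <- eq$species
  expect_equal(conductivity(eq),
               eq$system$constants$faraday *
                 sum(abs(sp$charge) * sp$concentration * abs(sp$mobility)),
               tolerance = 1e-12)
})

test_that("charge and mass balance hold on random compositions", {
  set.seed(42)
  nm <- constituent_names(the_system)
  worst_charge <- worst_mass <- 0
  for (i in 1:1000) {
    conc <- stats::runif(length(nm), 0, 50)
    conc[stats::runif(length(nm)) < 0.3] <- 0   # sparse mixtures too
    comp <- stats::setNames(conc, nm)
    eq <- solve_equilibrium(comp, the_system)
    sp <- eq$species
    scale <- sum(abs(sp$charge) * sp$concentration)
    worst_charge <- max(worst_charge,
                        abs(sum(sp$charge * sp$concentration)) / scale)
    # per-constituent mass balance: free forms plus complex-bound amounts
    for (nm_i in nm[comp > 0]) {
      tot <- sum(sp$concentration[sp$constituent == nm_i]) +
        if (nm_i == "hs-g-cd") sum(eq$complexes) else 0
      worst_mass <- max(worst_mass, abs(tot - comp[[nm_i]]) / comp[[nm_i]])
    }
  }
  expect_lt(worst_charge, 1e-9)
  expect_lt(worst_mass, 1e-9)
})

test_that("selector sites are fully dissociated at working pH", {
  for (pH in c(1, 1.9, 3, 7)) {
    h <- 10^(-pH)
    f <- 10^3 / (10^3 + h)  # per-site fraction at pKa -3
    expect_gte(f, 0.9999)
  }
  # and the solver agrees: net selector charge within 0.01% of -13
  eq <- solve_equilibrium(c(sodium = 247, "hs-g-cd" = 19, formic = 2380),
                          the_system)
  zsel <- eq$species$charge[grepl("hs-g-cd", eq$species$species)][1]
  expect_equal(zsel, -13, tolerance = 1e-4)
})

test_that("adding strong base never decreases the pH", {
  base <- c(formic = 500, acetic = 50, "hs-g-cd" = 5)
  last <- -Inf
  for (na in seq(0, 600, by = 50)) {
    eq <- solve_equilibrium(c(base, sodium = na), the_system)
    expect_gte(eq$pH, last - 1e-10)
    last <- eq$pH
  }
})

test_that("solver pH matches direct bisection for two-constituent systems", {
  set.seed(7)
  pairs <- list(c("formic", "sodium"), c("acetic", "ammonia"),
                c("chloride", "sodium"), c("hs-g-cd", "sodium"))
  for (p in pairs) {
    for (i in 1:5) {
      comp <- stats::setNames(stats::runif(2, 0.1, 100), p)
      eq <- solve_equilibrium(comp, the_system)
      expect_equal(eq$pH, bisect_pH(comp, the_system), tolerance = 1e-6)
    }
  }
})

test_that("the complexation-free limit is recovered as K -> 0", {
  cons <- list(
    ce_constituent("formic", "weak-acid", 5.66, 3.75),
    ce_constituent("base", "weak-base", 2.50, 7.50),
    ce_constituent("cd", "multi-site-anion", 2.00, -3, 13),
    ce_constituent("sodium", "weak-base", 5.19, 13.7))
  with_k0 <- ce_system(cons, list(ce_complexation("base", "cd", 0, -1.34)))
  without <- ce_system(cons)
  comp <- c(formic = 2380, base = 0.02, cd = 19, sodium = 247)
  a <- solve_equilibrium(comp, with_k0)
  b <- solve_equilibrium(comp, without)
  expect_equal(a$pH, b$pH, tolerance = 1e-12)
  expect_equal(a$conductivity, b$conductivity, tolerance = 1e-12)
  expect_equal(effective_mobility("base", a), effective_mobility("base", b),
               tolerance = 1e-12)
})

test_that("effective mobilities match the tabulated and closed-form values", {
  st0 <- solve_equilibrium(c(bge_composition(cd = 0, naoh = 0),
                             "S-ketamine" = 1e-6), the_system)
  expect_equal(effective_mobility("S-ketamine", st0) * 1e8, 2.50,
               tolerance = 2e-4)  # fully protonated free base at pH 1.9
  st <- solve_equilibrium(c(bge_composition(), "S-ketamine" = 1e-6),
                          the_system)
  expect_equal(effective_mobility("S-ketamine", st) * 1e8, -1.020,
               tolerance = 1e-3)  # (u_f + u_c K cL) / (1 + K cL) at 19 mM
  expect_error(effective_mobility("S-norketamine",
                                  solve_equilibrium(bge_composition(),
                                                    the_system)),
               "zero total")
})

test_that("invalid compositions are rejected", {
  expect_error(solve_equilibrium(c(unobtainium = 1), the_system), "unknown")
  expect_error(solve_equilibrium(c(formic = -1), the_system), ">= 0")
  expect_error(composition(c(1, 2), the_system), "named")
})
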