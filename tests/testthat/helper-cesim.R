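# Shared fixtures: the packaged system, memoized heavy runs, independent
# oracles, and synthetic run objects.

the_system <- ketamine_cd_system()

# memoized simulation runs shared across test files (the suite's heavy runs
# are computed once and reused by every property that needs them)
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

fig2_run_2000 <- function() cached("fig2_2000", run_simulation(
  "fig2_base", until = 120, n_cells = 2000, snapshot_times = seq(0, 120, 1)))

fig2_run_1000 <- function() cached("fig2_1000", run_simulation(
  "fig2_base", until = 120, n_cells = 1000, snapshot_times = c(0, 120)))

fig2_run_4000 <- function() cached("fig2_4000", run_simulation(
  "fig2_base", until = 120, n_cells = 4000, snapshot_times = c(0, 120)))

plug10_run <- function() cached("plug10", run_simulation(
  "cd_plug_10mm", until = 100, n_cells = 2000, snapshot_times = seq(0, 100, 1)))

cd2pct_run <- function() cached("cd2pct", run_simulation(
  "cd_2pct", until = 130, n_cells = 2000, snapshot_times = seq(0, 130, 1)))

# independent single-acid pH oracle: h^2 + Ka h - Ka c = 0 (concentrations
# in mol/L), analyte/counter-ion terms cancelling in the charge balance
quadratic_acid_pH <- function(c_molar, pKa) {
  Ka <- 10^(-pKa)
  -log10((-Ka + sqrt(Ka^2 + 4 * Ka * c_molar)) / 2)
}

# independent scalar-bisection pH oracle for arbitrary compositions of the
# packaged constituents (closed-form protonation fractions, no complexation)
bisect_pH <- function(comp, system, lo = -2, hi = 16) {
  cs <- system$constituents
  G <- function(pH) {
    h <- 10^(-pH)
    g <- 1000 * (h - system$constants$water_ion_product / h)
    for (nm in names(comp)) {
      z <- cs[[nm]]
      Ka <- 10^(-z$pKa)
      zb <- switch(z$kind,
                   "weak-base" = h / (h + Ka),
                   "weak-acid" = -Ka / (Ka + h),
                   "multi-site-anion" = -z$site_count * Ka / (Ka + h))
      g <- g + zb * comp[[nm]]
    }
    g
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (G(mid) > 0) lo <- mid else hi <- mid  # G decreasing in pH
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

# independent brute-force solver for a strong anion / weak-acid anion /
# strong cation column under the same electroneutral local-equilibrium
# formulation as the engine (water ions slaved to the charge balance and
# conducting, ionic forms advected first-order upwind, no diffusion).
# Vectorized bisection pH solve per cell; returns the anion-1 profile.
two_ion_oracle <- function(c1, c2, n, L_m, voltage, t_end, u1, u2, uNa,
                           pKa2 = 3.75, FF = 96485.33212,
                           uH = 362.5e-9, uOH = 205.5e-9, Kw = 1e-14) {
  dx <- L_m / n
  cNa <- c1 + c2
  r1 <- c(c1[1], c1[n]); r2 <- c(c2[1], c2[n]); rNa <- c(cNa[1], cNa[n])
  Ka <- 10^(-pKa2)
  pH_solve <- function(c1, c2, cNa) {
    lo <- rep(-16, n); hi <- rep(2, n)   # log10 [H+]
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      h <- 10^mid
      G <- 1000 * (h - Kw / h) + cNa - c1 - c2 * Ka / (Ka + h)
      up <- G > 0
      hi[up] <- mid[up]; lo[!up] <- mid[!up]
    }
    10^((lo + hi) / 2)
  }
  t <- 0
  repeat {
    h <- pH_solve(c1, c2, cNa)
    f2 <- Ka / (Ka + h)                  # ionized fraction of the weak acid
    kappa <- FF * (u1 * c1 + u2 * f2 * c2 + uNa * cNa +
                   1000 * (h * uH + Kw / h * uOH))
    j <- voltage / sum(dx / kappa)
    vmax <- max(u1, u2, uNa) * j / min(kappa)
    dt <- min(0.4 * dx / vmax, t_end - t)
    Ef <- j * (kappa[-n] + kappa[-1]) / (2 * kappa[-n] * kappa[-1])
    # conservative first-order upwind: anions move toward the anode
    # (negative x, upwind cell on the right), the cation toward the cathode
    upd <- function(cc, u, sgn) {
      Ff <- if (sgn < 0) -u * Ef * cc[-1] else u * Ef * cc[-n]
      dcc <- c(-Ff[1], -diff(Ff), Ff[n - 1])     # F_left - F_right per cell
      cc + dcc * dt / dx
    }
    c1 <- upd(c1, u1, -1)
    c2m <- upd(f2 * c2, u2, -1) + (1 - f2) * c2   # only the anion form moves
    c2 <- c2m
    cNa <- upd(cNa, uNa, +1)
    c1[c(1, n)] <- r1; c2[c(1, n)] <- r2; cNa[c(1, n)] <- rNa
    t <- t + dt
    if (t >= t_end - 1e-12) break
  }
  c1
}

# half-maximum crossing position (mm) of a decreasing-to-zero profile
half_cross <- function(x, cc, level) {
  k <- which(cc < level)[1]
  if (is.na(k) || k == 1) return(NA_real_)
  x[k - 1] + (level - cc[k - 1]) / (cc[k] - cc[k - 1]) * (x[k] - x[k - 1])
}

# synthetic ce_run with Gaussian peaks following prescribed trajectories
synthetic_run <- function(times, centers, sigma = 0.3, height = 1,
                          L = 50, n = 1000, analyte = "S-ketamine",
                          cd_profile = NULL) {
  x <- (seq_len(n) - 0.5) * L / n
  snaps <- lapply(seq_along(times), function(k) {
    m <- matrix(0, nrow = 2, ncol = n,
                dimnames = list(c(analyte, "hs-g-cd"), NULL))
    m[analyte, ] <- height * exp(-(x - centers[k])^2 / (2 * sigma^2))
    if (!is.null(cd_profile)) m["hs-g-cd", ] <- cd_profile(x, times[k])
    m
  })
  structure(list(times = times, snapshots = snaps, x_mm = x, dx_mm = L / n,
                 trace = data.frame(t_s = times, I_uA = 1),
                 system = the_system,
                 config = list(name = "synthetic", n_cells = n),
                 steps = 0),
            class = "ce_run")
}
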