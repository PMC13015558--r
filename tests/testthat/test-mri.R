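test_that("Stejskal-Tanner gradient amplitude follows the closed form", {
  g <- gradient_amplitude(400, 4, 10)
  gam <- 2.675e8
  expect_equal(g, sqrt(400e6 / (gam^2 * 0.004^2 * (0.010 - 0.004 / 3))),
               tolerance = 1e-12)
  expect_equal(g, 0.2008, tolerance = 1e-3)
  expect_equal(gradient_amplitude(0, 4, 10), 0)
  expect_equal(gradient_amplitude(1600, 4, 10), 2 * g, tolerance = 1e-12)
  expect_error(gradient_amplitude(400, 10, 4), "delta")
})

test_that("gradient direction sets are unit, spread and deterministic", {
  d <- uniform_directions(12)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 12), tolerance = 1e-12)
  expect_gt(attr(d, "min_angle_deg"), 25)
  expect_identical(unname(uniform_directions(12)), unname(d))
  expect_error(uniform_directions(4), "6")
})

test_that("pgse_sequence validates its invariants", {
  sq <- pgse_sequence()
  expect_equal(sq$gradient_amplitude, gradient_amplitude(400, 4, 10))
  expect_error(pgse_sequence(delta = 12, Delta = 10), "delta")
  expect_error(pgse_sequence(te = 10), "te")
  bad <- rbind(diag(3), diag(3), c(1, 0, 0), c(0, 1, 0))
  expect_error(pgse_sequence(directions = bad), "collinear")
})

test_that("free diffusion reproduces exp(-bD) in both compartments", {
  sq <- pgse_sequence()
  for (cc in list(c(0L, 2), c(1L, 1))) {
    dom <- homogeneous_domain(cc[1])
    cfg <- solver_config(dom, n_walkers = 1e5, seed = 100 + cc[1])
    dwi <- simulate_dwi(dom, seq = sq, cfg = cfg)
    adc <- -log(dwi$signals / dwi$s0) / 0.4
    expect_lt(max(abs(adc - cc[2])) / cc[2], 0.02)
  }
})

test_that("b0 equals the relaxation-weighted density sum", {
  sq <- pgse_sequence()
  dom <- cylinder_domain(d = 20, n = 30L, nz = 24L)
  cfg <- solver_config(dom, n_walkers = 2e5, seed = 11)
  s0 <- simulate_signal(dom, seq = sq, direction = "b0", cfg = cfg)
  expect_lt(abs(s0 - b0_oracle(dom)) / b0_oracle(dom), 0.005)
})

test_that("impermeable compartments superpose: total = fiber-only + interstitial-only", {
  sq <- pgse_sequence()
  dom <- cylinder_domain(d = 18, n = 26L, nz = 20L)
  comps <- tendon_compartments()
  cfg <- solver_config(dom, comps, n_walkers = 3e4, seed = 5)
  full <- simulate_dwi(dom, comps, sq, cfg)
  only <- function(label) {
    cc <- comps
    cc$water_fraction[cc$label != label] <- 0
    simulate_dwi(dom, cc, sq, cfg)
  }
  fib <- only(1L); int <- only(0L)
  # identical trajectories (same seed), disjoint weights: b0 superposes
  # exactly; weighted magnitudes only up to the residual imaginary parts
  expect_equal(full$s0, fib$s0 + int$s0, tolerance = 1e-12)
  expect_equal(full$signals, fib$signals + int$signals, tolerance = 1e-4)
})

test_that("signals are invariant under direction relabeling and 90-degree rotation", {
  sq <- pgse_sequence()
  dom <- cylinder_domain(d = 16, n = 24L, nz = 24L)
  cfg <- solver_config(dom, n_walkers = 1e5, seed = 17)
  dwi <- simulate_dwi(dom, seq = sq, cfg = cfg)
  perm <- sample(12)
  sq2 <- pgse_sequence(directions = sq$directions[perm, ])
  dwi2 <- simulate_dwi(dom, seq = sq2, cfg = cfg)
  expect_equal(dwi2$signals, dwi$signals[perm], tolerance = 1e-12)
  m1 <- compute_metrics(fit_tensor(dwi))
  m2 <- compute_metrics(fit_tensor(dwi2))
  expect_equal(m1$fa, m2$fa, tolerance = 1e-10)

  # rotate domain x<->z jointly with the directions: metrics must agree
  rot <- voxel_domain(aperm(dom$labels, c(3, 2, 1)), dom$dx)
  sq_rot <- pgse_sequence(directions = sq$directions[, c(3, 2, 1)])
  cfg_rot <- solver_config(rot, n_walkers = 1e5, seed = 18)
  m_rot <- compute_metrics(fit_tensor(simulate_dwi(rot, seq = sq_rot, cfg = cfg_rot)))
  m_ref <- compute_metrics(fit_tensor(dwi))
  expect_equal(m_rot$md, m_ref$md, tolerance = 0.02)
  expect_equal(m_rot$fa, m_ref$fa, tolerance = 0.1)
})

test_that("aligned-fiber axial signal matches the biexponential oracle", {
  sq <- pgse_sequence()
  dom <- cylinder_domain(d = 24, n = 30L, nz = 24L)
  cfg <- solver_config(dom, n_walkers = 2e5, seed = 23)
  s0 <- simulate_signal(dom, seq = sq, direction = "b0", cfg = cfg)
  sz <- simulate_signal(dom, seq = sq, direction = c(0, 0, 1), cfg = cfg)
  adc <- -log(sz / s0) / 0.4
  expect_lt(abs(adc - biexp_adc_oracle(volume_fraction(dom))) /
              biexp_adc_oracle(volume_fraction(dom)), 0.02)
})

test_that("radial restriction error shrinks as the time step is refined", {
  # restricted radial diffusion inside a cylinder is where the step length
  # (hence dt) controls boundary fidelity; compare against a fine-dt run
  sq <- pgse_sequence()
  dom <- cylinder_domain(d = 16, n = 20L, nz = 16L)
  comps <- tendon_compartments()
  radial <- function(dt, seed) {
    cfg <- suppressWarnings(
      solver_config(dom, comps, dt = dt, n_walkers = 1.5e5, seed = seed))
    cc <- comps; cc$water_fraction[cc$label == 0] <- 0
    s0 <- simulate_signal(dom, cc, sq, "b0", cfg)
    sx <- simulate_signal(dom, cc, sq, c(1, 0, 0), cfg)
    -log(sx / s0) / 0.4
  }
  ref <- radial(0.005, 31)               # near-converged reference
  err_coarse <- abs(radial(0.08, 32) - ref)
  err_fine <- abs(radial(0.02, 33) - ref)
  expect_lt(err_fine, err_coarse)
})

test_that("aligned fibers attenuate least along the most orthogonal direction", {
  sq <- pgse_sequence()
  dom <- cylinder_domain(d = 20, n = 26L, nz = 20L)
  cfg <- solver_config(dom, n_walkers = 1e5, seed = 41)
  dwi <- simulate_dwi(dom, seq = sq, cfg = cfg)
  gz2 <- dwi$directions[, 3]^2
  # restriction is transverse: signal increases as the direction leaves z
  expect_gt(cor(dwi$signals, -gz2, method = "spearman"), 0.8)
  expect_gt(mean(dwi$signals[gz2 < median(gz2)]),
            mean(dwi$signals[gz2 > median(gz2)]))
})

test_that("DWI signals round-trip through CSV + JSON", {
  sq <- pgse_sequence()
  dom <- homogeneous_domain(0L, n = 10L)
  cfg <- solver_config(dom, n_walkers = 5e3, seed = 3)
  dwi <- simulate_dwi(dom, seq = sq, cfg = cfg)
  f <- tempfile(fileext = ".csv")
  write_dwi_csv(dwi, f)
  back <- read_dwi_csv(f)
  expect_equal(back$s0, dwi$s0, tolerance = 1e-12)
  expect_equal(back$signals, dwi$signals, tolerance = 1e-12)
  ref_dirs <- dwi$directions
  attr(ref_dirs, "min_angle_deg") <- NULL
  expect_equal(unname(back$directions), unname(ref_dirs), tolerance = 1e-12)
  m1 <- compute_metrics(fit_tensor(dwi))
  m2 <- compute_metrics(fit_tensor(back))
  expect_equal(m1$md, m2$md, tolerance = 1e-10)
  unlink(c(f, paste0(f, ".json")))
})
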