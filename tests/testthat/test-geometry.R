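test_that("SHG parameter sampler reproduces the reference moments and stays positive", {
  set.seed(42)
  s <- sample_shg_params(1e4)
  ref <- shg_reference_parameters()
  se_d <- 22.3 / sqrt(1e4)
  expect_lt(abs(mean(s$diameter) - 51), 3 * se_d)
  se_h <- 3.2 / sqrt(2 * 1e4)  # SE of an SD estimate, approx sd/sqrt(2n)
  expect_lt(abs(sd(s$crimp_height) - 3.2), 3 * se_h)
  s1 <- sample_shg_params(1)
  expect_true(all(unlist(s1) > 0))
  expect_error(sample_shg_params(0), "positive")
})

test_that("unit cell volume fraction matches the analytic area ratio", {
  dom <- suppressMessages(build_unit_cell(50, 10, 64.3, 10.9))
  expect_equal(volume_fraction(dom), pi * 50^2 / (4 * 60^2), tolerance = 0.01)
  # crimp translates the cross-section: per-slice area fraction is constant
  # up to voxelization jitter of the shifted circle
  per_slice <- apply(dom$labels, 3, mean)
  expect_lt(diff(range(per_slice)) / mean(per_slice), 0.02)
})

test_that("zero crimp gives a straight cylinder (identical slices)", {
  dom <- build_unit_cell(30, 10, 60, 0)
  ref <- dom$labels[, , 1]
  for (k in seq_len(dom$dims[3]))
    expect_identical(dom$labels[, , k], ref)
})

test_that("square-lattice volume fraction never exceeds pi/4 (plus discretization)", {
  set.seed(7)
  for (i in 1:100) {
    d <- runif(1, 20, 80); s <- runif(1, 5, 15)
    lam <- runif(1, 50, 80); h <- runif(1, 5, 15)
    dom <- suppressMessages(build_unit_cell(d, s, lam, h))
    tol_vox <- 4 * dom$dx / (d + s)   # one-voxel perimeter error
    expect_lte(volume_fraction(dom), pi / 4 + tol_vox)
  }
})

test_that("kappa <-> von Mises concentration mapping round-trips and is monotone", {
  expect_equal(kappa_to_concentration(1 / 3), 0)
  expect_identical(kappa_to_concentration(0), Inf)
  for (k in c(0.02, 0.1, 0.25)) {
    b <- kappa_to_concentration(k)
    expect_lt(abs(tendondti:::kappa_of_concentration(b) - k), 1e-6)
  }
  b_vals <- vapply(c(0.05, 0.1, 0.2, 0.3), kappa_to_concentration, numeric(1))
  expect_true(all(diff(b_vals) < 0))
  expect_error(kappa_to_concentration(0.5), "1/3")
})

test_that("orientation sampler recovers kappa through (1/2) E[sin^2 theta]", {
  n <- 1e4
  for (k in seq(0, 1 / 3, length.out = 8)) {
    set.seed(1000 + round(1000 * k))
    o <- sample_orientation(n, k)
    expect_true(all(o$theta >= 0 & o$theta <= pi / 2))
    expect_true(all(o$phi >= 0 & o$phi < 2 * pi))
    khat <- mean(sin(o$theta)^2) / 2
    if (k == 0) {
      expect_identical(unique(o$theta), 0)
    } else {
      se <- sd(sin(o$theta)^2 / 2) / sqrt(n)
      expect_lt(abs(khat - k), 3 * se + 1e-4)
    }
  }
})

test_that("dispersed domains hit the target volume fraction and kappa", {
  set.seed(202)
  dom <- build_dispersed_domain(20, 0.6, 0.2, dims = c(80, 80, 120), dx = 2)
  expect_gte(volume_fraction(dom), 0.59)
  expect_lte(volume_fraction(dom), 0.61)
  fib <- attr(dom, "fibers")
  expect_gt(nrow(fib), 10)
  khat <- mean(sin(fib$theta)^2) / 2
  se <- sd(sin(fib$theta)^2 / 2) / sqrt(nrow(fib))
  expect_lt(abs(khat - 0.2), 3 * se + 0.02)
})

test_that("aligned dispersed domains are z-invariant and reproducible", {
  set.seed(77)
  dom <- build_dispersed_domain(16, 0.4, 0, dims = c(48, 48, 48), dx = 1)
  ref <- dom$labels[, , 1]
  for (k in seq_len(dom$dims[3]))
    expect_identical(dom$labels[, , k], ref)
  set.seed(77)
  dom2 <- build_dispersed_domain(16, 0.4, 0, dims = c(48, 48, 48), dx = 1)
  expect_identical(dom$labels, dom2$labels)
})

test_that("infeasible placement requests error out", {
  set.seed(5)
  expect_error(
    build_dispersed_domain(40, 0.99, 0, dims = c(50, 50, 50), dx = 2,
                           tol = 1e-4, max_consecutive_rejects = 20L),
    "volume fraction")
})

test_that("volume_fraction handles degenerate domains", {
  expect_equal(volume_fraction(homogeneous_domain(0L)), 0)
  expect_equal(volume_fraction(homogeneous_domain(1L)), 1)
  expect_error(voxel_domain(array(2L, dim = c(2, 2, 2)), 1), "labels")
})

test_that("domains round-trip through the text serialization", {
  set.seed(88)
  dom <- build_dispersed_domain(16, 0.4, 0.1, dims = c(40, 40, 40), dx = 2)
  f <- tempfile(fileext = ".txt")
  write_domain(dom, f)
  back <- read_domain(f)
  expect_identical(back$labels, dom$labels)
  expect_equal(back$dx, dom$dx)
  expect_identical(back$periodic, dom$periodic)
  unlink(f)
})
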