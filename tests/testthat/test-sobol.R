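test_that("the Sobol sequence starts with the canonical points", {
  X <- sobol_sequence(8, 3)
  expect_equal(X[, 1], c(0, 0.5, 0.75, 0.25, 0.375, 0.875, 0.625, 0.125))
  expect_equal(X[, 2], c(0, 0.5, 0.25, 0.75, 0.375, 0.875, 0.125, 0.625))
  expect_true(all(X >= 0 & X < 1))
  # digital shift preserves balance: first 2^k points still stratify halves
  set.seed(1)
  S <- sobol_sequence(256, 5, scramble = TRUE)
  expect_equal(colMeans(S < 0.5), rep(0.5, 5))
})

test_that("Saltelli design has the prescribed shape and coverage", {
  ref <- shg_reference_parameters()
  ref <- ref[1:4, ]
  pr <- sensitivity_problem(ref$parameter, cbind(ref$lower, ref$upper), N = 1024L)
  set.seed(2)
  M <- saltelli_sample(pr)
  expect_equal(nrow(M), 10240L)   # 2 N (p + 1)
  expect_equal(ncol(M), 4L)
  for (j in 1:4) {
    expect_gte(min(M[, j]), ref$lower[j])
    expect_lte(max(M[, j]), ref$upper[j])
    # uniform coverage: empirical extremes approach the bounds
    expect_lt(min(M[, j]) - ref$lower[j], (ref$upper[j] - ref$lower[j]) * 0.01)
    expect_lt(ref$upper[j] - max(M[, j]), (ref$upper[j] - ref$lower[j]) * 0.01)
  }
  pr4 <- sensitivity_problem(ref$parameter, cbind(ref$lower, ref$upper), N = 4L)
  set.seed(2)
  expect_equal(nrow(saltelli_sample(pr4)), 40L)  # 2 * 4 * 5
  expect_error(
    sensitivity_problem(ref$parameter, cbind(ref$lower, ref$upper), N = 1000L),
    "power of two")
})

test_that("Ishigami indices match the analytic values", {
  pr <- sensitivity_problem(c("x1", "x2", "x3"),
                            cbind(rep(-pi, 3), rep(pi, 3)), N = 2^13)
  set.seed(4)
  M <- saltelli_sample(pr)
  y <- sin(M[, 1]) + 7 * sin(M[, 2])^2 + 0.1 * M[, 3]^4 * sin(M[, 1])
  res <- sobol_indices(y, pr, n_bootstrap = 500)
  a <- 7; b <- 0.1
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  S1 <- c(0.5 * (1 + b * pi^4 / 5)^2 / V, a^2 / 8 / V, 0)
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  ST <- c(S1[1] + V13 / V, S1[2], V13 / V)
  fo <- res$first_order
  expect_lt(max(abs(fo$S1 - S1)), max(3 * fo$S1_conf, 0.02))
  expect_lt(max(abs(fo$ST - ST)), max(3 * fo$ST_conf, 0.02))
  s2_13 <- res$second_order$S2[res$second_order$i == "x1" &
                                 res$second_order$j == "x3"]
  expect_equal(s2_13, V13 / V, tolerance = 0.15)
})

test_that("additive models have ST = S1 and vanishing S2", {
  pr <- sensitivity_problem(c("a", "b", "c"), cbind(rep(0, 3), rep(1, 3)),
                            N = 2^12)
  set.seed(6)
  M <- saltelli_sample(pr)
  y <- 2 * M[, 1] + 5 * M[, 2] + 0.5 * M[, 3]
  res <- sobol_indices(y, pr, n_bootstrap = 300)
  fo <- res$first_order
  expect_lt(max(abs(fo$ST - fo$S1)), 0.02)
  expect_lt(sum(abs(fo$S1)) - 1, 0.03)          # sum S1 ~ 1
  expect_gt(sum(fo$S1), 0.97)
  expect_lt(max(abs(res$second_order$S2)), 0.05)
})

test_that("indices are invariant to affine output rescaling", {
  pr <- sensitivity_problem(c("a", "b"), cbind(c(0, 0), c(1, 1)), N = 2^10)
  set.seed(8)
  M <- saltelli_sample(pr)
  y <- M[, 1] + 3 * M[, 2] * M[, 1]
  r1 <- sobol_indices(y, pr, n_bootstrap = 50)
  r2 <- sobol_indices(100 * y - 7, pr, n_bootstrap = 50)
  expect_equal(r1$first_order$S1, r2$first_order$S1, tolerance = 1e-10)
  expect_equal(r1$first_order$ST, r2$first_order$ST, tolerance = 1e-10)
})

test_that("constant outputs yield all-zero indices", {
  pr <- sensitivity_problem(c("a", "b"), cbind(c(0, 0), c(1, 1)), N = 64L)
  set.seed(10)
  M <- saltelli_sample(pr)
  res <- sobol_indices(rep(3.5, nrow(M)), pr, n_bootstrap = 20)
  expect_equal(res$first_order$S1, c(0, 0))
  expect_equal(res$first_order$ST, c(0, 0))
  expect_equal(res$second_order$S2, 0)
})

test_that("bootstrap half-widths shrink roughly as 1/sqrt(N)", {
  widths <- sapply(c(6, 8, 10, 12), function(k) {
    pr <- sensitivity_problem(c("x1", "x2", "x3"),
                              cbind(rep(-pi, 3), rep(pi, 3)), N = 2^k)
    set.seed(k)
    M <- saltelli_sample(pr)
    y <- sin(M[, 1]) + 7 * sin(M[, 2])^2 + 0.1 * M[, 3]^4 * sin(M[, 1])
    mean(sobol_indices(y, pr, n_bootstrap = 200)$first_order$S1_conf)
  })
  expect_true(all(diff(widths) < 0))
  # quadrupling N should at least halve the half-width on average
  expect_lt(widths[4] / widths[1], 0.5)
})

test_that("sensitivity results write to CSV", {
  pr <- sensitivity_problem(c("a", "b"), cbind(c(0, 0), c(1, 1)), N = 256L)
  set.seed(12)
  M <- saltelli_sample(pr)
  res <- sobol_indices(M[, 1] + M[, 2], pr, n_bootstrap = 20)
  f <- tempfile(fileext = ".csv")
  write_sensitivity_csv(res, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.csv$", "_S2.csv", f)))
  expect_equal(read.csv(f)$S1, res$first_order$S1, tolerance = 1e-9)
  unlink(c(f, sub("\\.csv$", "_S2.csv", f)))
})
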