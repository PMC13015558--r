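## Saltelli sampling and Sobol index estimation.
##
## The quasi-random generator is a Sobol sequence (Gray-code construction,
## primitive-polynomial direction numbers for up to 10 dimensions) with an
## optional random digital-shift scramble; no installed package provides
## one, and the estimators below need its block structure anyway.

# direction-number table: s (degree), a (polynomial), m_i (initial values)
.sobol_dirs <- list(
  list(s = 1, a = 0, m = 1),
  list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)))

#' Sobol low-discrepancy sequence
#'
#' First `n` points of a (optionally digitally scrambled) Sobol sequence in
#' `[0, 1)^dim`, built by the Gray-code recursion. The scramble XORs each
#' dimension with an independent random 31-bit word, which preserves the
#' sequence's equidistribution while randomizing point locations;
#' scrambling draws from R's RNG, so wrap calls in `set.seed()` for
#' reproducibility.
#'
#' @param n number of points.
#' @param dim dimension (at most 10).
#' @param scramble apply a random digital shift?
#' @return An `n x dim` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim, scramble = FALSE) {
  if (dim < 1 || dim > 10) stop("`dim` must be between 1 and 10")
  nbits <- 31L
  V <- matrix(0, nbits, dim)  # direction integers, scaled by 2^-nbits later
  V[, 1] <- bitwShiftL(1L, nbits - seq_len(nbits))  # van der Corput
  if (dim > 1) for (d in 2:dim) {
    p <- .sobol_dirs[[d - 1]]
    s <- p$s
    m <- p$m
    v <- integer(nbits)
    v[seq_len(s)] <- bitwShiftL(m, nbits - seq_len(s))
    if (nbits > s) for (i in (s + 1):nbits) {
      vi <- bitwXor(v[i - s], bitwShiftR(v[i - s], s))
      if (s > 1) for (k in seq_len(s - 1))
        if (bitwAnd(bitwShiftR(p$a, s - 1 - k), 1L) == 1L)
          vi <- bitwXor(vi, v[i - k])
      v[i] <- vi
    }
    V[, d] <- v
  }
  X <- matrix(0L, n, dim)
  x <- integer(dim)
  for (i in seq_len(n)) {
    X[i, ] <- x
    # Gray-code: flip the direction of the lowest zero bit of i-1
    c <- 1L
    ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c <- c + 1L }
    x <- bitwXor(x, V[c, ])
  }
  if (scramble) {
    shift <- as.integer(floor(stats::runif(dim) * 2^nbits))
    for (d in seq_len(dim)) X[, d] <- bitwXor(X[, d], shift[d])
  }
  X / 2^nbits
}

#' Define a global sensitivity problem
#'
#' @param names parameter names.
#' @param bounds `p x 2` matrix (or data.frame) of lower/upper bounds.
#' @param N base sample count; must be a power of two for the Sobol design.
#' @param second_order estimate second-order indices? When `TRUE` the
#'   Saltelli design has `2 N (p + 1)` rows, otherwise `N (p + 2)`.
#' @return A list of class `sensitivity_problem`.
#' @export
sensitivity_problem <- function(names, bounds, N = 1024L, second_order = TRUE) {
  bounds <- as.matrix(bounds)
  if (length(names) != nrow(bounds) || ncol(bounds) != 2L)
    stop("`bounds` must have one row per name and two columns")
  if (any(!is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be finite with lower < upper")
  if (N < 2 || bitwAnd(as.integer(N), as.integer(N - 1)) != 0L)
    stop("`N` must be a power of two (the Sobol design loses balance otherwise)")
  structure(list(names = names, bounds = bounds, p = length(names),
                 N = as.integer(N), second_order = isTRUE(second_order)),
            class = "sensitivity_problem")
}

#' Saltelli radial sample of a sensitivity problem
#'
#' Builds the radial Saltelli design on a digitally scrambled Sobol
#' sequence in `2p` dimensions: base blocks A and B plus the cross blocks
#' `AB_i` (A with column i from B) and, with second-order estimation,
#' `BA_i`. Row order is A, B, AB_1..AB_p (, BA_1..BA_p). Every value lies
#' inside the parameter bounds. Uses R's RNG for the scramble, so
#' `set.seed()` gives a deterministic design.
#'
#' @param problem a [sensitivity_problem()].
#' @return A `2N(p+1) x p` (or `N(p+2) x p`) matrix with attribute
#'   `problem`.
#' @export
saltelli_sample <- function(problem) {
  stopifnot(inherits(problem, "sensitivity_problem"))
  p <- problem$p
  N <- problem$N
  U <- sobol_sequence(N, 2 * p, scramble = TRUE)
  A <- U[, seq_len(p), drop = FALSE]
  B <- U[, p + seq_len(p), drop = FALSE]
  blocks <- list(A, B)
  for (i in seq_len(p)) { AB <- A; AB[, i] <- B[, i]; blocks[[2 + i]] <- AB }
  if (problem$second_order)
    for (i in seq_len(p)) { BA <- B; BA[, i] <- A[, i]; blocks[[2 + p + i]] <- BA }
  M <- do.call(rbind, blocks)
  lo <- problem$bounds[, 1]
  hi <- problem$bounds[, 2]
  M <- sweep(sweep(M, 2, hi - lo, "*"), 2, lo, "+")
  colnames(M) <- problem$names
  attr(M, "problem") <- problem
  M
}

split_blocks <- function(y, problem) {
  p <- problem$p
  N <- problem$N
  nb <- if (problem$second_order) 2 + 2 * p else 2 + p
  if (length(y) != nb * N) stop("output length does not match the design")
  lapply(seq_len(nb), function(i) y[(i - 1) * N + seq_len(N)])
}

# point estimators on pre-split blocks (list: A, B, AB_1.., BA_1..)
sobol_point <- function(bl, p, second_order) {
  fA <- bl[[1]]; fB <- bl[[2]]
  V <- stats::var(c(fA, fB))
  if (V == 0)
    return(list(S1 = rep(0, p), ST = rep(0, p),
                S2 = if (second_order) matrix(0, p, p) else NULL))
  S1 <- ST <- numeric(p)
  for (i in seq_len(p)) {
    fAB <- bl[[2 + i]]
    S1[i] <- (V - mean((fB - fAB)^2) / 2) / V   # Jansen 1999
    ST[i] <- mean((fA - fAB)^2) / 2 / V         # Jansen 1999
  }
  S2 <- NULL
  if (second_order) {
    S2 <- matrix(NA_real_, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      fBAi <- bl[[2 + p + i]]
      fABj <- bl[[2 + j]]
      Vij <- mean(fBAi * fABj) - mean(fA * fB)  # Saltelli 2002
      S2[i, j] <- Vij / V - S1[i] - S1[j]
    }
  }
  list(S1 = S1, ST = ST, S2 = S2)
}

#' Estimate Sobol sensitivity indices from Saltelli-sampled outputs
#'
#' First-order and total-order indices by the Jansen (1999) estimators and
#' second-order indices by the Saltelli (2002) estimator, with percentile
#' bootstrap confidence intervals over resampled base rows. Small negative
#' estimates are reported as-is (estimator noise). Draws bootstrap indices
#' from R's RNG (`set.seed()` for reproducibility).
#'
#' @param y numeric outputs aligned with the rows of [saltelli_sample()].
#' @param problem the [sensitivity_problem()] (taken from the sample matrix
#'   attribute if `y` has one).
#' @param n_bootstrap bootstrap resamples for the confidence intervals.
#' @param conf confidence level.
#' @return An object of class `sensitivity_result`: list with `first_order`
#'   (data.frame: parameter, S1, S1_conf, ST, ST_conf), `second_order`
#'   (long data.frame: i, j, S2, S2_conf; `NULL` unless estimated) and
#'   `variance`.
#' @export
sobol_indices <- function(y, problem = attr(y, "problem"),
                          n_bootstrap = 1000L, conf = 0.95) {
  stopifnot(inherits(problem, "sensitivity_problem"))
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("outputs must be finite")
  p <- problem$p
  bl <- split_blocks(y, problem)
  est <- sobol_point(bl, p, problem$second_order)

  alpha <- (1 - conf) / 2
  npair <- if (problem$second_order) p * (p - 1) / 2 else 0
  boot <- matrix(0, n_bootstrap, 2 * p + npair)
  for (r in seq_len(n_bootstrap)) {
    idx <- sample.int(problem$N, replace = TRUE)
    blr <- lapply(bl, function(v) v[idx])
    er <- sobol_point(blr, p, problem$second_order)
    row <- c(er$S1, er$ST)
    if (npair) row <- c(row, er$S2[upper.tri(er$S2)])
    boot[r, ] <- row
  }
  half <- function(col) diff(stats::quantile(boot[, col], c(alpha, 1 - alpha),
                                             names = FALSE)) / 2
  first <- data.frame(
    parameter = problem$names,
    S1 = est$S1, S1_conf = vapply(seq_len(p), half, numeric(1)),
    ST = est$ST, ST_conf = vapply(p + seq_len(p), half, numeric(1)),
    stringsAsFactors = FALSE)
  second <- NULL
  if (npair) {
    ut <- which(upper.tri(est$S2), arr.ind = TRUE)
    ut <- ut[order(ut[, "col"], ut[, "row"]), , drop = FALSE]
    second <- data.frame(
      i = problem$names[ut[, "row"]], j = problem$names[ut[, "col"]],
      S2 = est$S2[upper.tri(est$S2)],
      S2_conf = vapply(2 * p + seq_len(npair), half, numeric(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(first_order = first, second_order = second,
                 variance = stats::var(c(bl[[1]], bl[[2]]))),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sobol sensitivity indices (95% bootstrap half-widths):\n")
  df <- x$first_order
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  if (!is.null(x$second_order)) {
    cat("second-order:\n")
    s2 <- x$second_order
    s2[c("S2", "S2_conf")] <- lapply(s2[c("S2", "S2_conf")], round, 4)
    print(s2, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.sensitivity_result <- function(x, which = "ST", ...) {
  df <- x$first_order
  v <- pmax(df[[which]], 0)
  ci <- df[[paste0(which, "_conf")]]
  bp <- graphics::barplot(v, names.arg = df$parameter, ylab = which,
                          ylim = c(0, max(v + ci) * 1.1), ...)
  graphics::arrows(bp, pmax(v - ci, 0), bp, v + ci, angle = 90, code = 3,
                   length = 0.05)
  invisible(x)
}

#' Write sensitivity indices as CSV
#'
#' @param result a `sensitivity_result`.
#' @param path CSV path for the first/total-order table; second-order rows
#'   go to `<path base>_S2.csv` when present.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(result, path) {
  utils::write.csv(result$first_order, path, row.names = FALSE)
  if (!is.null(result$second_order))
    utils::write.csv(result$second_order,
                     sub("(\\.csv)?$", "_S2.csv", path, perl = TRUE),
                     row.names = FALSE)
  invisible(path)
}
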