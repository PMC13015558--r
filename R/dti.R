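#' Fit a diffusion tensor from DWI signals
#'
#' Ordinary (log-domain) least squares on the single-shell Stejskal-Tanner
#' model `ln(S_i / S0) = -b g_i' D g_i` over the six unique elements of the
#' symmetric tensor D. At least six pairwise non-collinear directions are
#' required; signals must be strictly positive.
#'
#' @param dwi a `dwi_signals` object from [simulate_dwi()] (or
#'   [read_dwi_csv()]), or a numeric vector of weighted signals if
#'   `directions`, `s0` and `b_value` are given.
#' @param directions,s0,b_value used only when `dwi` is a bare vector:
#'   `n x 3` unit directions, the b0 signal, and the b-value (s/mm^2).
#' @return An object of class `dti_tensor`: list with `tensor` (3x3,
#'   um^2/ms), `eigenvalues` (descending), `eigenvectors` (columns) and
#'   `principal_direction`.
#' @export
fit_tensor <- function(dwi, directions = NULL, s0 = NULL, b_value = NULL) {
  if (inherits(dwi, "dwi_signals")) {
    signals <- dwi$signals
    directions <- dwi$directions
    s0 <- dwi$s0
    b_value <- dwi$seq$b_value
  } else {
    signals <- dwi
  }
  if (nrow(directions) < 6L) stop("at least 6 directions are required")
  if (any(signals <= 0) || s0 <= 0) stop("signals must be strictly positive")
  b <- b_value * 1e-3  # ms/um^2
  g <- directions
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  if (qr(X)$rank < 6L) stop("singular design matrix: directions too collinear")
  y <- -log(signals / s0) / b
  beta <- qr.solve(X, y)
  D <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  e <- eigen(D, symmetric = TRUE)   # eigen() sorts descending for symmetric
  structure(list(tensor = D, eigenvalues = e$values,
                 eigenvectors = e$vectors,
                 principal_direction = e$vectors[, 1]),
            class = "dti_tensor")
}

#' @export
print.dti_tensor <- function(x, ...) {
  cat("Diffusion tensor (um^2/ms):\n")
  print(round(x$tensor, 5))
  cat("eigenvalues:", paste(format(x$eigenvalues, digits = 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.dti_tensor <- function(object, ...) object$tensor

#' @export
summary.dti_tensor <- function(object, ...) {
  m <- compute_metrics(object)
  cat("DTI metrics: MD =", format(m$md, digits = 4),
      " AD =", format(m$ad, digits = 4),
      " RD =", format(m$rd, digits = 4),
      " FA =", format(m$fa, digits = 4), "\n")
  invisible(m)
}

#' Scalar DTI metrics from a diffusion tensor
#'
#' Computes mean diffusivity `MD = (l1 + l2 + l3) / 3`, axial diffusivity
#' `AD = l1`, radial diffusivity `RD = (l2 + l3) / 2` and fractional
#' anisotropy
#' `FA = sqrt(1/2) sqrt(((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / (l1^2+l2^2+l3^2))`
#' from the sorted eigenvalues. A zero tensor has FA 0 by convention;
#' negative eigenvalues (possible only through solver noise) are clamped to
#' zero for FA with a warning.
#'
#' @param tensor a `dti_tensor`, or a numeric vector of 3 eigenvalues.
#' @return A list of class `dti_metrics` with `md`, `ad`, `rd`, `fa`.
#' @export
compute_metrics <- function(tensor) {
  ev <- if (inherits(tensor, "dti_tensor")) tensor$eigenvalues
        else sort(as.numeric(tensor), decreasing = TRUE)
  stopifnot(length(ev) == 3L)
  md <- mean(ev)
  ad <- ev[1]
  rd <- (ev[2] + ev[3]) / 2
  ef <- ev
  if (any(ef < 0)) {
    warning("negative eigenvalue(s) clamped to 0 for FA")
    ef[ef < 0] <- 0
  }
  ss <- sum(ef^2)
  fa <- if (ss == 0) 0 else
    sqrt(0.5 * ((ef[1] - ef[2])^2 + (ef[2] - ef[3])^2 + (ef[3] - ef[1])^2) / ss)
  structure(list(md = md, ad = ad, rd = rd, fa = min(fa, 1)),
            class = "dti_metrics")
}

#' @export
print.dti_metrics <- function(x, ...) {
  cat("MD =", format(x$md, digits = 4), "um^2/ms;",
      "AD =", format(x$ad, digits = 4), ";",
      "RD =", format(x$rd, digits = 4), ";",
      "FA =", format(x$fa, digits = 4), "\n")
  invisible(x)
}

#' Write DTI metrics and tensor summary to CSV
#'
#' @param tensor a `dti_tensor`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(tensor, path) {
  m <- compute_metrics(tensor)
  df <- data.frame(md = m$md, ad = m$ad, rd = m$rd, fa = m$fa,
                   l1 = tensor$eigenvalues[1], l2 = tensor$eigenvalues[2],
                   l3 = tensor$eigenvalues[3],
                   e1x = tensor$principal_direction[1],
                   e1y = tensor$principal_direction[2],
                   e1z = tensor$principal_direction[3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
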