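#' Closed-form FA versus fiber dispersion: direct mapping
#'
#' The direct mapping assumes radial diffusivity vanishes for perfectly
#' aligned fibers: `AD/RD = (1 - 2 kappa) / kappa`, so
#' `FA = (beta - 1) / sqrt(beta^2 + 2)` with `beta = AD/RD`. The
#' `kappa = 0` limit is FA = 1.
#'
#' @param kappa dispersion value(s) in \[0, 1/3\].
#' @return FA value(s) in \[0, 1\].
#' @export
direct_mapping_fa <- function(kappa) {
  if (any(kappa < 0 | kappa > 1 / 3 + 1e-12))
    stop("`kappa` must lie in [0, 1/3]")
  out <- numeric(length(kappa))
  z <- kappa == 0
  out[z] <- 1
  beta <- (1 - 2 * kappa[!z]) / kappa[!z]
  out[!z] <- (beta - 1) / sqrt(beta^2 + 2)
  out
}

#' Closed-form FA versus fiber dispersion: dispersed Maxwell-Garnett
#'
#' For aligned fibers the radial diffusivity of the interstitial matrix
#' around insulating cylinders follows the Maxwell-Garnett effective-medium
#' estimate, giving `AD/RD = 3 kappa + (1 + nu) (1 - 3 kappa)` with `nu` the
#' collagen volume fraction, and `FA = (alpha - 1) / sqrt(alpha^2 + 2)` with
#' `alpha = AD/RD`.
#'
#' @param kappa dispersion value(s) in \[0, 1/3\].
#' @param nu collagen volume fraction in \[0, 1).
#' @return FA value(s) in \[0, 1\].
#' @export
dispersed_mg_fa <- function(kappa, nu) {
  if (any(kappa < 0 | kappa > 1 / 3 + 1e-12))
    stop("`kappa` must lie in [0, 1/3]")
  if (any(nu < 0 | nu >= 1)) stop("`nu` must lie in [0, 1)")
  alpha <- 3 * kappa + (1 + nu) * (1 - 3 * kappa)
  (alpha - 1) / sqrt(alpha^2 + 2)
}

#' Evaluate both FA-dispersion model curves on a kappa grid
#'
#' @param nu collagen volume fraction for the dispersed Maxwell-Garnett
#'   model.
#' @param kappa grid of dispersion values; the default is 50 log-spaced
#'   points plus the endpoints 0 and 1/3 (semi-log plots emphasize low
#'   dispersion).
#' @return A data.frame of class `fa_model_curves` with columns `kappa`,
#'   `fa_direct`, `fa_dispersed_mg`.
#' @export
fa_model_curves <- function(nu, kappa = NULL) {
  if (is.null(kappa))
    kappa <- c(0, exp(seq(log(1e-3), log(1 / 3), length.out = 50)))
  kappa <- sort(unique(pmin(kappa, 1 / 3)))
  out <- data.frame(kappa = kappa,
                    fa_direct = direct_mapping_fa(kappa),
                    fa_dispersed_mg = dispersed_mg_fa(kappa, nu))
  attr(out, "nu") <- nu
  class(out) <- c("fa_model_curves", "data.frame")
  out
}

#' @export
plot.fa_model_curves <- function(x, add_sim = NULL, ...) {
  k <- pmax(x$kappa, min(x$kappa[x$kappa > 0]) / 2)
  graphics::plot(k, x$fa_direct, type = "l", log = "x", col = "darkorange",
                 lwd = 2, xlab = expression(kappa), ylab = "FA",
                 ylim = c(0, 1), ...)
  graphics::lines(k, x$fa_dispersed_mg, col = "grey40", lwd = 2)
  if (!is.null(add_sim))
    graphics::points(pmax(add_sim$kappa, min(k)), add_sim$fa_mean,
                     col = "steelblue", pch = 19)
  graphics::legend("topright", bty = "n", lwd = 2, pch = c(NA, NA, 19),
                   lty = c(1, 1, NA),
                   col = c("darkorange", "grey40", "steelblue"),
                   legend = c("direct mapping", "dispersed Maxwell-Garnett",
                              "simulation"))
  invisible(x)
}
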