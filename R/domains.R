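#' Voxelized biphasic fiber domain
#'
#' Container shared between the geometry generators and the diffusion
#' simulator: a 3-D grid of compartment labels (0 = interstitial water,
#' 1 = collagen fiber) with an isotropic voxel edge length and per-axis
#' periodicity flags.
#'
#' @param labels integer 3-D array containing only 0 and 1.
#' @param dx voxel edge length (micrometres).
#' @param periodic logical vector of length 3; whether each axis is treated
#'   as periodic by the simulator.
#' @return An object of class `voxel_domain`: a list with elements `labels`,
#'   `dx`, `dims` and `periodic`.
#' @export
voxel_domain <- function(labels, dx, periodic = c(TRUE, TRUE, TRUE)) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0)
    stop("`dx` must be a single positive length")
  storage.mode(labels) <- "integer"
  u <- unique(as.vector(labels))
  if (!all(u %in% c(0L, 1L)))
    stop("`labels` may contain only 0 (interstitial) and 1 (fiber)")
  structure(
    list(labels = labels, dx = dx, dims = dim(labels),
         periodic = rep_len(as.logical(periodic), 3L)),
    class = "voxel_domain")
}

#' @export
print.voxel_domain <- function(x, ...) {
  ext <- x$dims * x$dx
  cat("Voxel domain:", paste(x$dims, collapse = " x "), "voxels, dx =",
      format(x$dx, digits = 4), "um\n")
  cat("  physical extent:", paste(format(ext, digits = 5), collapse = " x "),
      "um\n")
  cat("  fiber volume fraction:", format(volume_fraction(x), digits = 4), "\n")
  cat("  periodic:", paste(x$periodic, collapse = ", "), "\n")
  invisible(x)
}

#' Fiber volume fraction of a voxel domain
#'
#' Fraction of voxels labelled as fiber, mirroring the pixel-count area
#' fraction used for binarized microscopy images.
#'
#' @param domain a [voxel_domain()].
#' @return A fraction in \[0, 1\].
#' @export
volume_fraction <- function(domain) {
  stopifnot(inherits(domain, "voxel_domain"))
  n <- length(domain$labels)
  if (n == 0L) stop("empty domain")
  sum(domain$labels == 1L) / n
}

#' Reference microstructural parameters of tendon collagen fibers
#'
#' Second-harmonic-generation (SHG) microscopy derived summary statistics of
#' porcine digital flexor tendon microstructure: per-parameter mean, standard
#' deviation and the uniform range used for the square-lattice sensitivity
#' study. Units are micrometres throughout; `area_fraction` is dimensionless
#' and has no sensitivity-study range (it informs the dispersed-network
#' volume fractions only).
#'
#' @return A data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
shg_reference_parameters <- function() {
  data.frame(
    parameter = c("diameter", "spacing", "crimp_wavelength", "crimp_height",
                  "area_fraction"),
    mean  = c(51, 10.6, 64.3, 10.9, 0.872),
    sd    = c(22.3, 4.3, 15.9, 3.2, 0.069),
    lower = c(20, 5, 50, 5, NA),
    upper = c(80, 15, 80, 15, NA),
    stringsAsFactors = FALSE)
}

#' Sample microstructural parameter sets emulating the SHG measurements
#'
#' Draws fiber diameter, spacing, crimp wavelength and crimp height
#' independently from normal distributions with the SHG reference mean/SD,
#' truncated below at a small positive floor (0.1 um) to respect physical
#' positivity.
#'
#' @param n number of parameter sets to draw.
#' @param floor lower truncation bound (um).
#' @return A data.frame with `n` rows and columns `diameter`, `spacing`,
#'   `crimp_wavelength`, `crimp_height` (um).
#' @export
sample_shg_params <- function(n, floor = 0.1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count")
  n <- as.integer(n)
  ref <- shg_reference_parameters()
  ref <- ref[ref$parameter != "area_fraction", ]
  draw <- function(mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= floor))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  out <- lapply(seq_len(nrow(ref)), function(i) draw(ref$mean[i], ref$sd[i]))
  names(out) <- ref$parameter
  as.data.frame(out)
}

#' Build a crimped square-lattice unit cell
#'
#' Voxelizes one collagen fiber over a single crimp wavelength inside a
#' periodic cell of cross-section `(d + s) x (d + s)`. Crimp is a sine wave:
#' the circular fiber cross-section of diameter `d` is displaced along x by
#' `(crimp_height / 2) * sin(2 * pi * z / wavelength)` (crimp height is the
#' peak-to-peak transverse excursion). The cross-section is tested under the
#' minimum-image convention so the fiber unions with its periodic images.
#'
#' The grid is chosen so that between `nodes[1]` and `nodes[2]` voxels span
#' each cross-section axis (about 1 um edge length); the z extent is rounded
#' to a whole number of voxels and the sine period is taken over that
#' rounded extent so the cell stays exactly periodic.
#'
#' @param diameter fiber diameter d (um).
#' @param spacing surface-to-surface fiber spacing s (um).
#' @param crimp_wavelength crimp wavelength (um).
#' @param crimp_height peak-to-peak crimp excursion (um).
#' @param nodes admissible range of voxel counts per cross-section axis.
#' @return A [voxel_domain()], periodic on all axes.
#' @export
build_unit_cell <- function(diameter, spacing, crimp_wavelength, crimp_height,
                            nodes = c(40L, 60L)) {
  if (any(c(diameter, spacing, crimp_wavelength) <= 0) || crimp_height < 0)
    stop("diameter, spacing and crimp wavelength must be positive; crimp height non-negative")
  cell <- diameter + spacing
  if (diameter >= cell) stop("fiber cross-section exceeds the unit cell")
  n_cross <- as.integer(min(max(round(cell), nodes[1]), nodes[2]))
  dx <- cell / n_cross
  nz <- max(1L, as.integer(round(crimp_wavelength / dx)))
  lambda_eff <- nz * dx
  if (diameter + crimp_height > cell)
    message("crimp excursion overlaps periodic images (d + h > d + s); overlap is unioned")

  amp <- crimp_height / 2
  r2 <- (diameter / 2)^2
  xc <- ((seq_len(n_cross) - 0.5) * dx)
  # minimum-image distance to the (moving) centre, centre of cell at cell/2
  dy <- abs(xc - cell / 2)
  dy <- pmin(dy, cell - dy)
  dy2 <- dy^2
  labels <- array(0L, dim = c(n_cross, n_cross, nz))
  for (k in seq_len(nz)) {
    zc <- (k - 0.5) * dx
    cx <- cell / 2 + amp * sin(2 * pi * zc / lambda_eff)
    ddx <- abs(xc - cx)
    ddx <- pmin(ddx, cell - ddx)
    slice <- outer(ddx^2, dy2, "+") <= r2
    labels[, , k] <- labels[, , k] + slice
  }
  voxel_domain(labels, dx, periodic = c(TRUE, TRUE, TRUE))
}

# -- fiber dispersion: HGO kappa <-> von Mises concentration ---------------

# kappa(b) under the transversely isotropic convention:
#   rho(theta) = exp(b cos 2 theta) / C,  C = (1/2) Int_0^pi rho sin theta
#   kappa      = (1/4) Int_0^pi rho sin^3 theta dtheta
# Integrands are damped by exp(-b) for numerical stability at large b.
kappa_of_concentration <- function(b) {
  if (!is.finite(b)) return(0)
  f_num <- function(th) exp(b * (cos(2 * th) - 1)) * sin(th)^3
  f_den <- function(th) exp(b * (cos(2 * th) - 1)) * sin(th)
  num <- stats::integrate(f_num, 0, pi, rel.tol = 1e-10)$value
  den <- stats::integrate(f_den, 0, pi, rel.tol = 1e-10)$value
  0.5 * num / den
}

#' Map HGO dispersion to von Mises concentration
#'
#' Inverts the transversely isotropic relation
#' `kappa = (1/4) Int rho(theta) sin^3(theta) dtheta` with
#' `rho(theta) ~ exp(b cos 2 theta)` normalized over the sphere, by a
#' bracketed root find. `kappa = 1/3` (isotropy) maps to `b = 0`;
#' `kappa = 0` (perfect alignment) maps to `Inf`.
#'
#' @param kappa dispersion in \[0, 1/3\].
#' @param tol absolute tolerance on the recovered kappa.
#' @return The von Mises concentration `b >= 0` (possibly `Inf`).
#' @export
kappa_to_concentration <- function(kappa, tol = 1e-6) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0 || kappa > 1 / 3 + 1e-12)
    stop("`kappa` must lie in [0, 1/3]")
  if (kappa >= 1 / 3 - tol / 10) return(0)
  if (kappa == 0) return(Inf)
  hi <- 1
  while (kappa_of_concentration(hi) > kappa) hi <- hi * 2
  stats::uniroot(function(b) kappa_of_concentration(b) - kappa,
                 lower = 0, upper = hi, tol = tol / 10)$root
}

#' Sample fiber orientations for a given dispersion
#'
#' Azimuth `phi` is uniform on \[0, 2 pi); the polar angle `theta` from the
#' longitudinal z axis is drawn from the solid-angle-weighted density
#' `p(theta) ~ exp(b cos 2 theta) sin(theta)` on \[0, pi/2\] (fibers are
#' unsigned axes, folded onto the hemisphere), with `b` from
#' [kappa_to_concentration()]. Under this convention
#' `(1/2) E[sin^2 theta] = kappa` exactly. Sampling uses a numerically
#' inverted CDF in `u = cos(theta)`.
#'
#' @param n number of orientations.
#' @param kappa dispersion in \[0, 1/3\].
#' @return A data.frame with columns `theta` and `phi` (radians).
#' @export
sample_orientation <- function(n, kappa) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count")
  n <- as.integer(n)
  phi <- stats::runif(n, 0, 2 * pi)
  if (kappa == 0) {
    theta <- rep(0, n)
  } else {
    b <- kappa_to_concentration(kappa)
    # density in u = cos(theta) on [0, 1] is proportional to exp(2 b u^2)
    grid <- seq(0, 1, length.out = 4097L)
    wdens <- exp(2 * b * (grid^2 - 1))
    cdf <- c(0, cumsum((wdens[-1] + wdens[-length(wdens)]) / 2))
    cdf <- cdf / cdf[length(cdf)]
    u <- stats::approx(cdf, grid, xout = stats::runif(n), ties = "ordered")$y
    theta <- acos(pmin(1, pmax(0, u)))
  }
  data.frame(theta = theta, phi = phi)
}

#' Build a dispersed intersecting-cylinder voxel domain
#'
#' Places straight cylinders of fixed diameter at uniformly random seed
#' points with orientations from [sample_orientation()], extended until they
#' exit the domain, and allowed to intersect (overlap is unioned). Fibers
#' are added until the voxelized fiber volume fraction lies within `tol` of
#' the target; a candidate that would overshoot the band is rejected and
#' redrawn. All axes are flagged periodic (the simulator applies
#' phase-consistent periodic boundaries) although the cylinders themselves
#' terminate at the faces.
#'
#' @param diameter fiber diameter (um).
#' @param volume_fraction target fiber volume fraction in (0, 1).
#' @param kappa HGO dispersion in \[0, 1/3\].
#' @param dims physical domain extents (um), length 3.
#' @param dx voxel edge length (um).
#' @param tol half-width of the acceptance band around the target fraction.
#' @param max_attempts cap on total candidate placements.
#' @param max_consecutive_rejects abort after this many rejected candidates
#'   in a row (signals a geometrically infeasible request).
#' @return A [voxel_domain()] with attributes `fibers` (data.frame of seed
#'   points and angles of the accepted fibers) and `params`.
#' @export
build_dispersed_domain <- function(diameter, volume_fraction, kappa,
                                   dims = c(150, 150, 300), dx = 2,
                                   tol = 0.01, max_attempts = 1e6,
                                   max_consecutive_rejects = 1000L) {
  if (volume_fraction <= 0 || volume_fraction >= 1)
    stop("`volume_fraction` must lie in (0, 1)")
  if (kappa < 0 || kappa > 1 / 3 + 1e-12) stop("`kappa` must lie in [0, 1/3]")
  if (any(dims < diameter)) stop("domain extents must exceed the fiber diameter")
  nvox <- as.integer(round(dims / dx))
  labels <- array(0L, dim = nvox)
  ntot <- prod(nvox)
  radius <- diameter / 2

  placed <- list()
  vf <- 0
  attempts <- 0L
  rejects <- 0L
  while (vf < volume_fraction - tol) {
    if (attempts >= max_attempts || rejects >= max_consecutive_rejects)
      stop("could not reach the target volume fraction (", volume_fraction,
           " +/- ", tol, "): infeasible placement after ", attempts,
           " attempts")
    attempts <- attempts + 1L
    p0 <- stats::runif(3) * dims
    o <- sample_orientation(1L, kappa)
    ax <- c(sin(o$theta) * cos(o$phi), sin(o$theta) * sin(o$phi), cos(o$theta))
    add <- cpp_cylinder_coverage(labels, nvox, dx, p0, ax, radius, FALSE)
    if (vf + add / ntot <= volume_fraction + tol) {
      cpp_cylinder_coverage(labels, nvox, dx, p0, ax, radius, TRUE)
      vf <- vf + add / ntot
      placed[[length(placed) + 1L]] <-
        data.frame(x = p0[1], y = p0[2], z = p0[3],
                   theta = o$theta, phi = o$phi)
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
    }
  }
  dom <- voxel_domain(labels, dx, periodic = c(TRUE, TRUE, TRUE))
  attr(dom, "fibers") <- do.call(rbind, placed)
  attr(dom, "params") <- list(diameter = diameter,
                              volume_fraction = volume_fraction,
                              kappa = kappa, dims = dims, dx = dx, tol = tol)
  dom
}

#' Write / read a voxel domain as plain text
#'
#' Serializes the label grid together with its voxel size and periodicity
#' flags to a small text format (header lines then one run-length-encoded
#' label stream), so domains survive text-only storage.
#'
#' @param domain a [voxel_domain()].
#' @param path file path.
#' @return `write_domain` returns `path` invisibly; `read_domain` returns
#'   the reconstructed [voxel_domain()].
#' @export
write_domain <- function(domain, path) {
  stopifnot(inherits(domain, "voxel_domain"))
  v <- as.vector(domain$labels)
  r <- rle(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("dims", paste(domain$dims, collapse = " ")),
    paste("dx", format(domain$dx, digits = 17)),
    paste("periodic", paste(as.integer(domain$periodic), collapse = " ")),
    paste(r$lengths, r$values, collapse = " ")), con)
  invisible(path)
}

#' @rdname write_domain
#' @export
read_domain <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(ln[1], " ")[[1]][-1])
  dx <- as.numeric(strsplit(ln[2], " ")[[1]][2])
  periodic <- as.logical(as.integer(strsplit(ln[3], " ")[[1]][-1]))
  rl <- as.integer(strsplit(ln[4], " ")[[1]])
  n <- length(rl) / 2
  v <- inverse.rle(list(lengths = rl[2 * seq_len(n) - 1],
                        values = rl[2 * seq_len(n)]))
  voxel_domain(array(v, dim = dims), dx, periodic)
}
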