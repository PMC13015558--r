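## PGSE diffusion-MRI simulation of biphasic voxel domains.
## Units: lengths um, times ms, diffusivity um^2/ms, gradient T/m (user
## facing; T/um internally), gamma in rad s^-1 T^-1.

GAMMA_H <- 2.675e8  # gyromagnetic ratio of 1H, rad s^-1 T^-1

#' MR properties of the two tendon water compartments
#'
#' Default compartment table: interfibrillar water inside collagen fibers
#' (label 1) and interstitial water between fibers (label 0). Tropocollagen
#' and collagen-bound water have T2 values short enough that their signal is
#' negligible at the echo times simulated here and are not modelled.
#'
#' @return A data.frame with one row per label (ordered by `label`) and
#'   columns `label`, `name`, `diffusivity` (um^2/ms), `t2` (ms),
#'   `water_fraction`.
#' @export
tendon_compartments <- function() {
  data.frame(
    label = c(0L, 1L),
    name = c("interstitial water", "collagen fiber"),
    diffusivity = c(2, 1),
    t2 = c(62, 20),
    water_fraction = c(1, 0.22),
    stringsAsFactors = FALSE)
}

check_compartments <- function(compartments) {
  need <- c("label", "diffusivity", "t2", "water_fraction")
  if (!is.data.frame(compartments) || !all(need %in% names(compartments)))
    stop("`compartments` must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(compartments$diffusivity <= 0) || any(compartments$t2 <= 0) ||
      any(compartments$water_fraction < 0) || any(compartments$water_fraction > 1))
    stop("compartment parameters out of range")
  compartments[order(compartments$label), , drop = FALSE]
}

#' Stejskal-Tanner gradient amplitude
#'
#' Solves `b = gamma^2 G^2 delta^2 (Delta - delta/3)` for the gradient
#' amplitude G of a PGSE pair.
#'
#' @param b_value diffusion weighting (s/mm^2).
#' @param delta gradient lobe duration (ms).
#' @param Delta gradient lobe separation (ms).
#' @return Gradient amplitude in T/m.
#' @export
gradient_amplitude <- function(b_value, delta, Delta) {
  if (b_value < 0 || delta <= 0 || Delta <= 0 || delta >= Delta)
    stop("need b_value >= 0 and 0 < delta < Delta")
  b <- b_value * 1e-3                      # ms / um^2
  gam <- GAMMA_H * 1e-3                    # rad ms^-1 T^-1
  g_per_um <- sqrt(b / (gam^2 * delta^2 * (Delta - delta / 3)))  # T/um
  g_per_um * 1e6                           # T/m
}

#' Uniformly spread gradient directions
#'
#' Deterministic electrostatic-repulsion optimization of `n` unit vectors on
#' the hemisphere (each point repels both every other point and its
#' antipode, so the set is well spread for an antipodally symmetric
#' measurement). Initialized from an internal seeded stream; fixed seed and
#' iteration count make the set reproducible.
#'
#' @param n number of directions (>= 6 for tensor estimation).
#' @param seed integer seed for the initial configuration.
#' @param n_iter gradient-descent iterations.
#' @return An `n x 3` matrix of unit row vectors with attribute
#'   `min_angle_deg`, the minimum pairwise (axial) angular separation.
#' @export
uniform_directions <- function(n, seed = 1L, n_iter = 600L) {
  if (n < 6) stop("at least 6 directions are required to determine a tensor")
  # private RNG stream so the caller's RNG state is untouched
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  v[v[, 3] < 0, ] <- -v[v[, 3] < 0, , drop = FALSE]
  lr <- 0.1
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(-v[-i, , drop = FALSE], 2, v[i, ], "+")   # v_i - v_j
      d2 <- sweep(v[-i, , drop = FALSE], 2, v[i, ], "+")    # v_i + v_j
      r1 <- pmax(rowSums(d1^2), 1e-12)^1.5
      r2 <- pmax(rowSums(d2^2), 1e-12)^1.5
      f[i, ] <- colSums(d1 / r1) + colSums(d2 / r2)
    }
    v <- v + lr * f
    v <- v / sqrt(rowSums(v^2))
    lr <- lr * 0.99
  }
  v[v[, 3] < 0, ] <- -v[v[, 3] < 0, , drop = FALSE]
  g <- abs(v %*% t(v))
  diag(g) <- 0
  attr(v, "min_angle_deg") <- acos(min(1, max(g[upper.tri(g)]))) * 180 / pi
  v
}

#' PGSE diffusion-encoding description
#'
#' Bundles the pulse-sequence parameters: lobe duration `delta`, lobe
#' separation `Delta`, b-value, echo time and the gradient direction set.
#' The gradient amplitude is derived from the Stejskal-Tanner relation.
#' Defaults reproduce the reference protocol: delta 4 ms, Delta 10 ms,
#' b 400 s/mm^2, TE 18 ms, 12 directions.
#'
#' @param delta gradient lobe duration (ms).
#' @param Delta gradient lobe separation (ms).
#' @param b_value diffusion weighting (s/mm^2).
#' @param te echo time (ms); must satisfy `te >= Delta + delta`.
#' @param n_directions number of diffusion-encoding directions.
#' @param directions optional `n x 3` matrix of unit directions; defaults to
#'   [uniform_directions()].
#' @return An object of class `pgse_sequence`.
#' @export
pgse_sequence <- function(delta = 4, Delta = 10, b_value = 400, te = 18,
                          n_directions = 12L, directions = NULL) {
  if (delta >= Delta) stop("`delta` must be smaller than `Delta`")
  if (te < Delta + delta) stop("`te` must be at least Delta + delta")
  if (is.null(directions)) directions <- uniform_directions(n_directions)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("`directions` must be n x 3")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("`directions` must be unit vectors")
  gg <- abs(directions %*% t(directions))
  diag(gg) <- 0
  if (any(gg > 1 - 1e-8)) stop("`directions` must be pairwise non-collinear")
  structure(
    list(delta = delta, Delta = Delta, b_value = b_value, te = te,
         n_directions = nrow(directions), directions = directions,
         gradient_amplitude = gradient_amplitude(b_value, delta, Delta),
         gyromagnetic_ratio = GAMMA_H),
    class = "pgse_sequence")
}

#' @export
print.pgse_sequence <- function(x, ...) {
  cat("PGSE sequence: delta =", x$delta, "ms, Delta =", x$Delta,
      "ms, b =", x$b_value, "s/mm^2, TE =", x$te, "ms\n")
  cat("  G =", format(x$gradient_amplitude, digits = 4), "T/m,",
      x$n_directions, "directions (min axial separation",
      format(attr(x$directions, "min_angle_deg"), digits = 3), "deg)\n")
  invisible(x)
}

#' Solver settings for the random-walk simulator
#'
#' The time step defaults to `dx^2 / (24 * Dmax)` (per-step RMS displacement
#' `sqrt(6 D dt) = dx/2`), capped at 125 us; for 1-um grids this gives
#' ~20.8 us, inside the 20-125 us operating band.
#'
#' @param domain a [voxel_domain()] (for the default time step).
#' @param compartments compartment table (for the default time step).
#' @param dt time step (ms); computed from the stability rule when `NULL`.
#' @param n_walkers number of random walkers.
#' @param seed integer seed for the walker stream; drawn from R's RNG when
#'   `NULL` (so `set.seed()` makes runs reproducible).
#' @return A list with class `solver_config`.
#' @export
solver_config <- function(domain, compartments = tendon_compartments(),
                          dt = NULL, n_walkers = 1e5, seed = NULL) {
  compartments <- check_compartments(compartments)
  dmax <- max(compartments$diffusivity)
  if (is.null(dt)) dt <- min(0.125, domain$dx^2 / (24 * dmax))
  if (sqrt(6 * dmax * dt) > domain$dx / 2 + 1e-9)
    warning("per-step RMS displacement exceeds dx/2; boundary fidelity degrades")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  structure(list(dt = dt, n_walkers = as.integer(n_walkers),
                 seed = as.integer(seed), scheme = "random-walk"),
            class = "solver_config")
}

# One trajectory pass; returns the ingredients for any direction's signal.
walk_domain <- function(domain, compartments, seq, cfg) {
  compartments <- check_compartments(compartments)
  labs <- sort(unique(as.vector(domain$labels)))
  if (!all(labs %in% compartments$label))
    stop("domain contains labels without a compartment entry")
  res <- cpp_walk_pgse(domain$labels, as.integer(domain$dims), domain$dx,
                       compartments$diffusivity, cfg$n_walkers, cfg$dt,
                       seq$delta, seq$Delta, as.double(cfg$seed))
  idx <- match(res$comp, compartments$label)
  w <- compartments$water_fraction[idx] * exp(-seq$te / compartments$t2[idx])
  list(F = res$F, w = w)
}

signal_from_walk <- function(walk, seq, direction) {
  if (is.null(direction)) return(sum(walk$w))         # b0: G = 0
  q <- seq$gyromagnetic_ratio * 1e-3 * seq$gradient_amplitude * 1e-6  # rad/(ms um)
  phi <- q * as.vector(walk$F %*% direction)
  sqrt(sum(walk$w * cos(phi))^2 + sum(walk$w * sin(phi))^2)
}

#' Simulate one PGSE signal
#'
#' Transverse magnetization evolves under compartment-wise diffusion with
#' impermeable (zero-flux) fiber-interstitium membranes, T2 decay over the
#' full echo time, and phase accrual from the two gradient lobes with a sign
#' flip at the refocusing pulse midway between them. Positions entering the
#' phase are unwrapped, so periodic boundary crossings accrue the phase of
#' an infinite periodic medium. Returns the voxel-integrated signal
#' magnitude, normalized per walker (signal per unit volume).
#'
#' @param domain a [voxel_domain()].
#' @param compartments compartment table, see [tendon_compartments()].
#' @param seq a [pgse_sequence()].
#' @param direction a unit 3-vector, an index into `seq$directions`, or
#'   `"b0"` for the non-diffusion-weighted measurement.
#' @param cfg a [solver_config()]; built with defaults when `NULL`.
#' @return Signal magnitude per unit volume (arbitrary units).
#' @export
simulate_signal <- function(domain, compartments = tendon_compartments(),
                            seq = pgse_sequence(), direction = "b0",
                            cfg = NULL) {
  if (is.null(cfg)) cfg <- solver_config(domain, compartments)
  walk <- walk_domain(domain, compartments, seq, cfg)
  dir <- NULL
  if (!identical(direction, "b0")) {
    dir <- if (length(direction) == 1L) seq$directions[direction, ] else direction
    dir <- dir / sqrt(sum(dir^2))
  }
  signal_from_walk(walk, seq, dir) / cfg$n_walkers
}

#' Simulate a full DWI acquisition
#'
#' One b0 measurement (zero gradient, pure relaxation weighting) plus one
#' diffusion-weighted signal per gradient direction, all sharing the same
#' walker trajectories and solver settings.
#'
#' @inheritParams simulate_signal
#' @return An object of class `dwi_signals`: list with `s0`, `signals`
#'   (length `n_directions`), `directions`, `seq`, `cfg`.
#' @export
simulate_dwi <- function(domain, compartments = tendon_compartments(),
                         seq = pgse_sequence(), cfg = NULL) {
  if (is.null(cfg)) cfg <- solver_config(domain, compartments)
  walk <- walk_domain(domain, compartments, seq, cfg)
  s0 <- signal_from_walk(walk, seq, NULL) / cfg$n_walkers
  sig <- vapply(seq_len(seq$n_directions), function(i)
    signal_from_walk(walk, seq, seq$directions[i, ]) / cfg$n_walkers,
    numeric(1))
  structure(list(s0 = s0, signals = sig, directions = seq$directions,
                 seq = seq, cfg = cfg),
            class = "dwi_signals")
}

#' @export
print.dwi_signals <- function(x, ...) {
  cat("DWI signals: S0 =", format(x$s0, digits = 5), "and",
      length(x$signals), "weighted directions\n")
  cat("  S/S0 range:",
      paste(format(range(x$signals / x$s0), digits = 4), collapse = " - "), "\n")
  invisible(x)
}

#' Write / read DWI signals as CSV (+ JSON metadata)
#'
#' The CSV holds one row per measurement (`direction` 0 is the b0 row with a
#' zero gradient vector); sequence and solver parameters go to a JSON
#' sidecar `<path>.json`.
#'
#' @param dwi a `dwi_signals` object.
#' @param path CSV file path.
#' @return `write_dwi_csv` returns `path` invisibly; `read_dwi_csv` returns
#'   a `dwi_signals` object (sequence rebuilt from the metadata).
#' @export
write_dwi_csv <- function(dwi, path) {
  stopifnot(inherits(dwi, "dwi_signals"))
  df <- data.frame(
    direction = 0:length(dwi$signals),
    gx = c(0, dwi$directions[, 1]), gy = c(0, dwi$directions[, 2]),
    gz = c(0, dwi$directions[, 3]),
    signal = c(dwi$s0, dwi$signals))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(delta_ms = dwi$seq$delta, Delta_ms = dwi$seq$Delta,
               b_s_per_mm2 = dwi$seq$b_value, te_ms = dwi$seq$te,
               n_directions = dwi$seq$n_directions,
               dt_us = dwi$cfg$dt * 1e3, n_walkers = dwi$cfg$n_walkers,
               seed = dwi$cfg$seed, scheme = dwi$cfg$scheme)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dwi_csv
#' @export
read_dwi_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dirs <- as.matrix(df[df$direction > 0, c("gx", "gy", "gz")])
  dimnames(dirs) <- NULL
  sq <- pgse_sequence(meta$delta_ms, meta$Delta_ms, meta$b_s_per_mm2,
                      meta$te_ms, directions = dirs)
  structure(list(s0 = df$signal[df$direction == 0],
                 signals = df$signal[df$direction > 0],
                 directions = dirs, seq = sq,
                 cfg = structure(list(dt = meta$dt_us / 1e3,
                                      n_walkers = meta$n_walkers,
                                      seed = meta$seed, scheme = meta$scheme),
                                 class = "solver_config")),
            class = "dwi_signals")
}
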