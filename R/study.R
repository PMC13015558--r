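## Orchestration of the two in-silico experiments and the model comparison.
##
## Reference (paper-scale) designs: Saltelli N = 1024 over the four
## square-lattice parameters (10,240 unit cells); dispersed networks on a
## 5 x 5 x 10 grid (diameter 30-70 um, volume fraction 0.75-0.95, kappa in
## [0, 1/3]) with 5 replicate 500 x 500 x 2000 um domains at 1 um
## resolution. Desk-scale defaults below shrink N, domain size and
## replicate count so a single CPU finishes in minutes.

#' Reference study designs
#'
#' Returns the full-scale experiment settings (documented defaults) and the
#' desk-scale preset actually used by the package defaults.
#'
#' @return A list with elements `sensitivity` and `dispersion`, each holding
#'   `paper` and `desk` parameter lists.
#' @export
study_presets <- function() {
  list(
    sensitivity = list(
      paper = list(N = 1024L, n_walkers = 1e5),
      desk = list(N = 128L, n_walkers = 1e4)),
    dispersion = list(
      paper = list(dims = c(500, 500, 2000), dx = 1, n_replicates = 5L,
                   diameters = seq(30, 70, by = 10),
                   volume_fractions = seq(0.75, 0.95, by = 0.05),
                   kappas = seq(0, 1 / 3, length.out = 10)),
      desk = list(dims = c(150, 150, 300), dx = 2, n_replicates = 2L,
                  diameters = 50, volume_fractions = 0.85,
                  kappas = c(0, 0.05, 0.1, 0.2, 1 / 3))))
}

unit_cell_metrics <- function(diameter, spacing, crimp_wavelength,
                              crimp_height, compartments, seq, n_walkers,
                              walker_seed) {
  # overlap of crimped fibers with their periodic images is routine over the
  # sampled ranges; the per-cell log message would flood a study run
  dom <- suppressMessages(
    build_unit_cell(diameter, spacing, crimp_wavelength, crimp_height))
  cfg <- solver_config(dom, compartments, n_walkers = n_walkers,
                       seed = walker_seed %% 2147483647)
  dwi <- simulate_dwi(dom, compartments, seq, cfg)
  compute_metrics(fit_tensor(dwi))
}

#' Run the square-lattice global sensitivity study
#'
#' Saltelli-samples the four microstructural parameters (fiber diameter,
#' spacing, crimp wavelength, crimp height) over their reference ranges,
#' builds each crimped unit cell, simulates the PGSE protocol, fits the
#' tensor, and estimates Sobol indices of MD, AD, RD and FA. With
#' `second_order = TRUE` the design has `2 N (p + 1)` rows (10,240 at the
#' reference N = 1024).
#'
#' @param N base sample count (power of two).
#' @param n_walkers random walkers per simulation.
#' @param seed study seed (design scramble, walker streams, bootstrap).
#' @param compartments compartment table.
#' @param seq a [pgse_sequence()].
#' @param n_bootstrap bootstrap resamples for index confidence intervals.
#' @param checkpoint optional CSV path; completed rows are appended there
#'   and re-used on restart, making long runs resumable.
#' @param verbose print per-row progress?
#' @return A list of class `sensitivity_study`: `samples` (design matrix),
#'   `metrics` (per-row data.frame), `indices` (list of
#'   [sobol_indices()] results per metric), `failed_rows`.
#' @export
run_sensitivity_study <- function(N = 128L, n_walkers = 1e4, seed = 1L,
                                  compartments = tendon_compartments(),
                                  seq = pgse_sequence(), n_bootstrap = 1000L,
                                  checkpoint = NULL, verbose = FALSE) {
  ref <- shg_reference_parameters()
  ref <- ref[match(c("diameter", "spacing", "crimp_wavelength",
                     "crimp_height"), ref$parameter), ]
  problem <- sensitivity_problem(ref$parameter,
                                 cbind(ref$lower, ref$upper), N = N)
  set.seed(seed)
  M <- saltelli_sample(problem)
  n <- nrow(M)

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
    if (verbose) message("resuming: ", nrow(done), "/", n, " rows on file")
  }
  rows <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    if (!is.null(done) && i <= nrow(done)) {
      rows[[i]] <- done[i, c("md", "ad", "rd", "fa")]
      next
    }
    t0 <- proc.time()[3]
    m <- tryCatch(
      unit_cell_metrics(M[i, 1], M[i, 2], M[i, 3], M[i, 4], compartments,
                        seq, n_walkers,
                        walker_seed = as.numeric(seed) * 1e6 + i),
      error = function(e) e)
    if (inherits(m, "error")) {
      failed <- c(failed, i)
      rows[[i]] <- data.frame(md = NA_real_, ad = NA_real_, rd = NA_real_,
                              fa = NA_real_)
    } else {
      rows[[i]] <- data.frame(md = m$md, ad = m$ad, rd = m$rd, fa = m$fa)
    }
    if (verbose)
      message(sprintf("row %d/%d  d=%.1f s=%.1f lam=%.1f h=%.1f  [%.2fs]",
                      i, n, M[i, 1], M[i, 2], M[i, 3], M[i, 4],
                      proc.time()[3] - t0))
    if (!is.null(checkpoint)) {
      df <- cbind(as.data.frame(M[i, , drop = FALSE]), rows[[i]])
      utils::write.table(df, checkpoint, sep = ",", append = file.exists(checkpoint),
                         col.names = !file.exists(checkpoint), row.names = FALSE)
    }
  }
  metrics <- cbind(as.data.frame(M), do.call(rbind, rows))
  if (length(failed))
    warning(length(failed), " simulation row(s) failed and were excluded")
  ok <- stats::complete.cases(metrics)
  indices <- NULL
  if (all(ok)) {
    indices <- lapply(c(md = "md", ad = "ad", rd = "rd", fa = "fa"),
                      function(v) sobol_indices(metrics[[v]], problem,
                                                n_bootstrap = n_bootstrap))
  }
  structure(list(samples = M, metrics = metrics, indices = indices,
                 failed_rows = failed, problem = problem, seed = seed),
            class = "sensitivity_study")
}

#' @export
print.sensitivity_study <- function(x, ...) {
  cat("Sensitivity study: N =", x$problem$N, "->", nrow(x$samples),
      "unit-cell simulations;", length(x$failed_rows), "failed\n")
  if (!is.null(x$indices)) {
    cat("total-order indices:\n")
    ST <- sapply(x$indices, function(r) round(r$first_order$ST, 3))
    rownames(ST) <- x$problem$names
    print(ST)
  }
  invisible(x)
}

#' Run the dispersed-fiber-network study
#'
#' For every combination of fiber diameter, volume fraction and dispersion,
#' generates `n_replicates` independent dispersed cylinder domains,
#' simulates the PGSE protocol, fits the tensor, and aggregates per-metric
#' mean and standard deviation across replicates.
#'
#' @param diameters,volume_fractions,kappas grid levels; defaults are the
#'   desk-scale preset (see [study_presets()]).
#' @param n_replicates replicate domains per combination.
#' @param dims,dx domain extents and resolution (um).
#' @param n_walkers random walkers per simulation.
#' @param seed study seed.
#' @param compartments compartment table.
#' @param seq a [pgse_sequence()].
#' @param verbose print per-condition progress?
#' @return A data.frame of class `dispersion_study` with one row per
#'   combination: grid values, `n_replicates`, and `<metric>_mean`,
#'   `<metric>_sd` for md/ad/rd/fa. Per-replicate values are in
#'   `attr(, "replicates")`.
#' @export
run_dispersion_study <- function(diameters = 50, volume_fractions = 0.85,
                                 kappas = c(0, 0.05, 0.1, 0.2, 1 / 3),
                                 n_replicates = 2L, dims = c(150, 150, 300),
                                 dx = 2, n_walkers = 2e5, seed = 1L,
                                 compartments = tendon_compartments(),
                                 seq = pgse_sequence(), verbose = FALSE) {
  grid <- expand.grid(diameter = diameters, volume_fraction = volume_fractions,
                      kappa = kappas, KEEP.OUT.ATTRS = FALSE)
  raw <- vector("list", nrow(grid) * n_replicates)
  agg <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    t0 <- proc.time()[3]
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      set.seed((as.numeric(seed) * 7919 + g * 131 + r) %% 2147483647)
      dom <- build_dispersed_domain(grid$diameter[g], grid$volume_fraction[g],
                                    grid$kappa[g], dims = dims, dx = dx)
      cfg <- solver_config(dom, compartments, n_walkers = n_walkers,
                           seed = (as.numeric(seed) * 1e6 + g * 100 + r) %% 2147483647)
      m <- compute_metrics(fit_tensor(simulate_dwi(dom, compartments, seq, cfg)))
      reps[[r]] <- data.frame(diameter = grid$diameter[g],
                              volume_fraction = grid$volume_fraction[g],
                              kappa = grid$kappa[g], replicate = r,
                              measured_vf = volume_fraction(dom),
                              md = m$md, ad = m$ad, rd = m$rd, fa = m$fa)
      raw[[(g - 1) * n_replicates + r]] <- reps[[r]]
    }
    rr <- do.call(rbind, reps)
    agg[[g]] <- data.frame(
      grid[g, , drop = FALSE], n_replicates = n_replicates,
      md_mean = mean(rr$md), md_sd = stats::sd(rr$md),
      ad_mean = mean(rr$ad), ad_sd = stats::sd(rr$ad),
      rd_mean = mean(rr$rd), rd_sd = stats::sd(rr$rd),
      fa_mean = mean(rr$fa), fa_sd = stats::sd(rr$fa))
    if (verbose)
      message(sprintf(
        "d=%g vf=%g kappa=%.3f: MD=%.3f AD=%.3f RD=%.3f FA=%.3f  [%.1fs]",
        grid$diameter[g], grid$volume_fraction[g], grid$kappa[g],
        agg[[g]]$md_mean, agg[[g]]$ad_mean, agg[[g]]$rd_mean,
        agg[[g]]$fa_mean, proc.time()[3] - t0))
  }
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "replicates") <- do.call(rbind, raw)
  class(out) <- c("dispersion_study", "data.frame")
  out
}

#' Compare simulated FA against the closed-form dispersion models
#'
#' Joins the `(volume fraction, diameter)` slice of a dispersion-study
#' table with the direct-mapping and dispersed Maxwell-Garnett FA curves on
#' the same kappa grid.
#'
#' @param dispersion_table a [run_dispersion_study()] result.
#' @param nu volume fraction of the slice (also fed to the
#'   Maxwell-Garnett model).
#' @param diameter fiber diameter of the slice (um).
#' @return A data.frame with columns `kappa`, `fa_sim_mean`, `fa_sim_sd`,
#'   `fa_direct`, `fa_dispersed_mg` and the differences model - simulation.
#' @export
compare_fa_models <- function(dispersion_table, nu = 0.85, diameter = 50) {
  sl <- dispersion_table[dispersion_table$volume_fraction == nu &
                           dispersion_table$diameter == diameter, ]
  if (nrow(sl) == 0)
    stop("no rows at volume_fraction = ", nu, ", diameter = ", diameter)
  sl <- sl[order(sl$kappa), ]
  data.frame(
    kappa = sl$kappa,
    fa_sim_mean = sl$fa_mean, fa_sim_sd = sl$fa_sd,
    fa_direct = direct_mapping_fa(sl$kappa),
    fa_dispersed_mg = dispersed_mg_fa(sl$kappa, nu),
    diff_direct = direct_mapping_fa(sl$kappa) - sl$fa_mean,
    diff_dispersed_mg = dispersed_mg_fa(sl$kappa, nu) - sl$fa_mean)
}

#' Write a study run manifest
#'
#' Records the configuration, seed and session versions of a study run as
#' JSON next to its outputs.
#'
#' @param path JSON file path.
#' @param config named list of configuration values.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config) {
  info <- list(config = config,
               r_version = R.version.string,
               package_version = as.character(utils::packageVersion("tendondti")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
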