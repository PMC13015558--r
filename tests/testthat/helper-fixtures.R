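# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the full suite stays fast.

homogeneous_domain <- function(label = 0L, n = 16L, dx = 1) {
  voxel_domain(array(as.integer(label), dim = c(n, n, n)), dx = dx)
}

# straight z-aligned cylinder of diameter d centred in an n x n x nz box
cylinder_domain <- function(d = 20, n = 32L, nz = 32L, dx = 1) {
  ctr <- n * dx / 2
  xc <- (seq_len(n) - 0.5) * dx
  sl <- outer((xc - ctr)^2, (xc - ctr)^2, "+") <= (d / 2)^2
  voxel_domain(array(rep(as.integer(sl), nz), dim = c(n, n, nz)), dx = dx)
}

# deterministic small aligned dispersed network for oracle tests
aligned_network <- function(seed = 101, vf = 0.85) {
  set.seed(seed)
  build_dispersed_domain(30, vf, 0, dims = c(90, 90, 90), dx = 1.5)
}

# relaxation-weighted signal density per unit volume at TE for a domain
b0_oracle <- function(domain, compartments = tendon_compartments(), te = 18) {
  vf <- volume_fraction(domain)
  comp <- compartments[order(compartments$label), ]
  w <- comp$water_fraction * exp(-te / comp$t2)
  (1 - vf) * w[1] + vf * w[2]
}

# two-compartment biexponential apparent diffusivity for free axial diffusion
biexp_adc_oracle <- function(vf, b = 0.4, te = 18,
                             compartments = tendon_compartments()) {
  comp <- compartments[order(compartments$label), ]
  w <- comp$water_fraction * exp(-te / comp$t2) * c(1 - vf, vf)
  s <- sum(w * exp(-b * comp$diffusivity))
  -log(s / sum(w)) / b
}

random_spd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  lam <- sort(stats::runif(3, 0.1, 3), decreasing = TRUE)
  Q %*% diag(lam) %*% t(Q)
}

# noiseless DWI signals from a ground-truth tensor over a direction set
synth_signals <- function(D, dirs, b = 0.4, s0 = 1) {
  adc <- rowSums((dirs %*% D) * dirs)
  structure(list(s0 = s0, signals = s0 * exp(-b * adc), directions = dirs,
                 seq = pgse_sequence(directions = dirs),
                 cfg = list(dt = NA, n_walkers = NA, seed = NA, scheme = "synthetic")),
            class = "dwi_signals")
}
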