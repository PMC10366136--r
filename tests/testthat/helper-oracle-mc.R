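# Independent continuous-space Monte Carlo oracle for a homogeneous slab.
#
# Deliberately shares no code with the voxel transport kernel: photons move in
# continuous (x, y, z), the slab is laterally infinite, the refractive index
# is matched (no Fresnel events) and absorption is tallied into depth bins.
# Vectorized over photons so 2e4 packets run in seconds.
slab_mc_oracle <- function(n_photons, mu_a, mu_s, g, L, bin_width,
                           roulette_threshold = 1e-3, roulette_p = 0.1,
                           seed = 1) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  mt <- mu_a + mu_s
  frac_a <- mu_a / mt
  nb <- as.integer(ceiling(L / bin_width))
  dep <- numeric(nb)
  escaped <- 0
  z <- rep(0, n_photons)
  ux <- rep(0, n_photons); uy <- rep(0, n_photons); uz <- rep(1, n_photons)
  w <- rep(1, n_photons)
  active <- rep(TRUE, n_photons)
  while (any(active)) {
    idx <- which(active)
    s <- -log(runif(length(idx))) / mt
    z[idx] <- z[idx] + uz[idx] * s
    out <- z[idx] < 0 | z[idx] > L
    escaped <- escaped + sum(w[idx[out]])
    active[idx[out]] <- FALSE
    idx <- idx[!out]
    if (!length(idx)) break
    b <- pmin(floor(z[idx] / bin_width) + 1L, nb)
    a <- w[idx] * frac_a
    add <- tapply(a, factor(b, levels = seq_len(nb)), sum, default = 0)
    dep <- dep + as.numeric(add)
    w[idx] <- w[idx] - a
    # Henyey-Greenstein deflection, vectorized rotation
    m <- length(idx)
    ct <- if (g == 0) 2 * runif(m) - 1 else {
      tmp <- (1 - g^2) / (1 - g + 2 * g * runif(m))
      pmin(pmax((1 + g^2 - tmp^2) / (2 * g), -1), 1)
    }
    st <- sqrt(1 - ct^2)
    phi <- 2 * pi * runif(m)
    cp <- cos(phi); sp <- sin(phi)
    x <- ux[idx]; y <- uy[idx]; zz <- uz[idx]
    vert <- abs(zz) > 0.99999
    den <- sqrt(pmax(1 - zz^2, 1e-30))
    nx <- ifelse(vert, st * cp, st * (x * zz * cp - y * sp) / den + x * ct)
    ny <- ifelse(vert, st * sp, st * (y * zz * cp + x * sp) / den + y * ct)
    nz <- ifelse(vert, sign(zz) * ct, -st * cp * den + zz * ct)
    nrm <- sqrt(nx^2 + ny^2 + nz^2)
    ux[idx] <- nx / nrm; uy[idx] <- ny / nrm; uz[idx] <- nz / nrm
    # roulette
    low <- w[idx] < roulette_threshold
    if (any(low)) {
      li <- idx[low]
      u <- runif(length(li))
      survive <- u < roulette_p
      w[li[survive]] <- w[li[survive]] / roulette_p
      active[li[!survive]] <- FALSE
    }
  }
  list(absorbed_per_bin = dep / n_photons,
       escaped = escaped / n_photons,
       bin_edges = seq(0, nb) * bin_width)
}
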