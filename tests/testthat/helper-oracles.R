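# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (explicit loops, direct lattice sums, plane
# sampling) and never call the code paths they check.

# literal double-loop non-bonded energy (non-periodic, direct Coulomb sum,
# LJ truncated at the cutoff), geometric mixing
naive_energy <- function(system, params, exclude_intramolecular = TRUE) {
  at <- system$atoms
  n <- nrow(at)
  idx <- match(at$element, params$elements$element)
  eps <- params$elements$epsilon[idx]
  sig <- params$elements$sigma[idx]
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (exclude_intramolecular && at$molecule_id[i] == at$molecule_id[j]) next
      r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
      if (r <= params$vdw_cutoff) {
        eij <- sqrt(eps[i] * eps[j]); sij <- sqrt(sig[i] * sig[j])
        sr6 <- (sij / r)^6
        e <- e + 4 * eij * (sr6^2 - sr6)
      }
      e <- e + params$coulomb_constant * at$charge[i] * at$charge[j] / r
    }
  }
  e
}

# random neutral LJ cluster for oracle-equivalence checks
random_cluster <- function(n, seed, spread = 8) {
  set.seed(seed)
  repeat {
    at <- data.frame(element = "Ar", mass = 39.95,
                     charge = round(stats::runif(n, -0.5, 0.5), 3),
                     x = stats::runif(n, 0, spread),
                     y = stats::runif(n, 0, spread),
                     z = stats::runif(n, 0, spread))
    d <- as.matrix(stats::dist(at[, c("x", "y", "z")]))
    if (min(d[upper.tri(d)]) > 0.8) break
    seed <- seed + 10000
    set.seed(seed)
  }
  at$charge <- at$charge - mean(at$charge)
  molecular_system(at)
}

# facet-area fractions by uniform sampling on each supporting plane:
# area_i = pi R^2 * P(point inside every other halfspace)
sampled_area_fractions <- function(normals, dists, groups, n_total = 1e6,
                                   seed = 1) {
  set.seed(seed)
  np <- nrow(normals)
  n_per <- ceiling(n_total / np)
  areas <- numeric(np)
  for (i in seq_len(np)) {
    ni <- normals[i, ]
    seedv <- if (abs(ni[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- seedv - sum(seedv * ni) * ni; u <- u / sqrt(sum(u^2))
    v <- c(ni[2] * u[3] - ni[3] * u[2], ni[3] * u[1] - ni[1] * u[3],
           ni[1] * u[2] - ni[2] * u[1])
    R <- 3 * max(dists)
    repeat {
      th <- stats::runif(n_per, 0, 2 * pi)
      rr <- R * sqrt(stats::runif(n_per))
      pts <- dists[i] * matrix(ni, n_per, 3, byrow = TRUE) +
        outer(rr * cos(th), u) + outer(rr * sin(th), v)
      ok <- rep(TRUE, n_per)
      for (j in seq_len(np)) {
        if (j == i) next
        ok <- ok & (pts %*% normals[j, ] <= dists[j] + 1e-12)
      }
      if (!any(ok) || max(rr[ok]) < 0.95 * R) break
      R <- 2 * R   # facet may extend past the sampling disk: enlarge
    }
    areas[i] <- pi * R^2 * mean(ok)
  }
  agg <- tapply(areas, groups, sum)
  100 * agg / sum(areas)
}

# direct lattice-sum attachment energy for a simple-cubic one-atom LJ
# crystal, (0 0 1)-type slice of one layer: interaction of one slice atom
# with the semi-infinite stack of layers on one side, truncated at the
# cutoff (matches the minimum-image evaluation).
lattice_sum_attachment <- function(a, epsilon, sigma, cutoff) {
  kmax <- ceiling(cutoff / a)
  imax <- ceiling(cutoff / a)
  e <- 0
  for (k in 1:kmax) {
    for (i in -imax:imax) {
      for (j in -imax:imax) {
        r <- a * sqrt(i^2 + j^2 + k^2)
        if (r <= cutoff) {
          sr6 <- (sigma / r)^6
          e <- e + 4 * epsilon * (sr6^2 - sr6)
        }
      }
    }
  }
  e
}

# default cutoff sits between neighbor shells of the a = 1.5 toy lattice so
# shell inclusion is not decided by floating-point ties
toy_lj_params <- function(cutoff = 3.2, epsilon = 0.25, sigma = 1.2) {
  ff_params(data.frame(element = "Ar", epsilon = epsilon, sigma = sigma),
            vdw_cutoff = cutoff)
}

optimized_cell <- function() unit_cell(19.27, 9.74, 17.05, beta = 107.99,
                                       space_group = "C2/c")

camin2_reference_forms <- function() {
  list(hkl = rbind(c(2, 0, 0), c(1, 1, 0), c(0, 0, 2), c(1, 1, -1), c(2, 0, -2)),
       e_att = c(-250.08, -266.26, -365.24, -284.40, -185.29),
       d_ref = c(9.16, 8.60, 8.11, 8.10, 7.29),
       area_ref = c(20.38, 30.96, 4.54, 9.03, 35.10))
}
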