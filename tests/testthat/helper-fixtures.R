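# Shared fixtures: small phantoms, an independent brute-force EDT, and a
# coarse-to-fine grid-search oracle for the constrained decomposition.

iodine_cs <- function() default_calibration_set("iodine")

# Organ spec whose ground-truth fractions sum to one in every voxel
# (surface fraction <= 1, no cap active), so all modes can recover it
# exactly in the noise-free case.
unit_sum_spec <- function(shape = c(32, 32, 32),
                          semiaxes = c(12, 10, 8)) {
  organ_phantom_spec(shape = shape, organ_semiaxes = semiaxes,
                     f_surface = c(heart = 1, lung = 0.8),
                     f_max = c(heart = 1, lung = 1))
}

# O(n^2) Euclidean distance oracle for small 2D/3D masks.
brute_distance <- function(mask) {
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  out <- array(0, dim(mask))
  if (nrow(bg) == 0) {
    out[mask] <- Inf
    return(out)
  }
  for (k in seq_len(nrow(fg))) {
    out[matrix(fg[k, ], 1)] <- sqrt(min(colSums((t(bg) - fg[k, ])^2)))
  }
  out
}

# Coarse-to-fine exhaustive grid search over non-negative fractions,
# minimising the same objective as the solver but by brute enumeration:
# a global 0.1-step sweep of [0, 3]^3 followed by halving refinements with
# wide (+/- 5 step) windows, down to a final step of ~4e-4. The wide
# windows matter: the objective's valley is flat along the air direction
# (its attenuation signature is nearly zero), so the grid minimiser can
# drift several coarse steps from the continuous optimum.
grid_oracle <- function(b, calset, mode = "three_material_soft", w = 1) {
  A <- basis_matrix(calset)
  s <- w * mean(abs(A))
  objective <- function(Fm) {
    att <- colSums((A %*% Fm - as.vector(b))^2)
    if (mode == "three_material_soft") att + s^2 * (colSums(Fm) - 1)^2
    else att
  }
  candidates <- function(lo, hi, step) {
    ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = step))
    if (mode == "three_material_hard") {
      gr <- expand.grid(ax[[1]], ax[[2]])
      f3 <- 1 - gr[, 1] - gr[, 2]
      keep <- f3 >= -1e-12
      t(cbind(gr[keep, , drop = FALSE], pmax(f3[keep], 0)))
    } else {
      t(as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]])))
    }
  }
  step <- 0.1
  Fm <- candidates(c(0, 0, 0), c(3, 3, 3), step)
  best <- Fm[, which.min(objective(Fm))]
  for (it in 1:8) {
    lo <- pmax(0, best - 5 * step)
    hi <- best + 5 * step
    step <- step / 2
    Fm <- candidates(lo, hi, step)
    best <- Fm[, which.min(objective(Fm))]
  }
  unname(best)
}

# Random attenuation pairs spanning the plausible range, including values
# slightly outside the basis span (negative or super-unity mixtures).
random_mu_pairs <- function(n, calset, seed) {
  withr::with_seed(seed, {
    cbind(runif(n, -0.05, 1.4 * calset$stain[1]),
          runif(n, -0.05, 1.4 * calset$stain[2]))
  })
}
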