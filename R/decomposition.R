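# Voxel-wise constrained material decomposition: express each voxel's
# (mu_LE, mu_HE) pair as a non-negative mixture of the calibration
# materials' coefficient pairs. Three modes:
#
#   two_material        NNLS on the 2x2 system in (F_stain, F_PMMA)
#   three_material_soft NNLS on the 3-row system whose third row is the
#                       sum-to-one equation, included as a weighted
#                       least-squares row (fractions may exceed 1 and the
#                       sum may deviate from 1)
#   three_material_hard minimiser over the non-negative simplex
#                       (sum of fractions exactly 1)
#
# With at most three unknowns the global constrained optimum is found
# exactly by enumerating all sign supports (subsets of materials allowed to
# be nonzero), solving the reduced least-squares problem on each support,
# and keeping the feasible candidate with the smallest objective. This is
# deterministic, independent of voxel order, and vectorises across voxels
# as a handful of 3x3 solves applied to the whole batch at once.
#
# Unit note for the soft mode: the attenuation rows are in mm^-1 while the
# sum row is dimensionless, so the sum row is scaled by the mean absolute
# basis coefficient (times the user weight w) to make the two misfits
# commensurable. This keeps the sum row a gentle tie-breaker: a voxel whose
# attenuation demands F_stain ~ 1.3 is reported near 1.3, not dragged to 1.

decomposition_modes <- c("two_material", "three_material_soft",
                         "three_material_hard")

sum_row_scale <- function(A) mean(abs(A))

# Batch NNLS by support enumeration. M: m x p design, B: m x n rhs batch.
# Returns p x n solutions minimising ||M f - b||^2 s.t. f >= 0.
nnls_batch <- function(M, B) {
  p <- ncol(M)
  n <- ncol(B)
  best_obj <- colSums(B^2)          # empty support: f = 0
  best_f <- matrix(0, nrow = p, ncol = n)
  supports <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(p, k, simplify = FALSE)
  }), recursive = FALSE)
  for (S in supports) {
    Ms <- M[, S, drop = FALSE]
    G <- crossprod(Ms)
    if (rcond(G) < 1e-12) next
    Fs <- solve(G, crossprod(Ms, B))
    feas <- colSums(Fs < -1e-9) == 0L
    if (!any(feas)) next
    Fs[Fs < 0] <- 0
    resid <- colSums((Ms %*% Fs - B)^2)
    take <- feas & (resid < best_obj - 1e-15)
    if (any(take)) {
      best_obj[take] <- resid[take]
      best_f[, take] <- 0
      best_f[S, take] <- Fs[, take]
    }
  }
  best_f
}

# Batch minimiser of ||A f - b||^2 over the simplex {f >= 0, sum f = 1},
# by enumerating simplex faces (supports). A: 2 x 3, B: 2 x n.
simplex_batch <- function(A, B) {
  p <- ncol(A)
  n <- ncol(B)
  best_obj <- rep(Inf, n)
  best_f <- matrix(0, nrow = p, ncol = n)
  supports <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(p, k, simplify = FALSE)
  }), recursive = FALSE)
  for (S in supports) {
    k <- length(S)
    As <- A[, S, drop = FALSE]
    if (k == 1L) {
      Fs <- matrix(1, nrow = 1L, ncol = n)
      resid <- colSums((As %*% Fs - B)^2)
      feas <- rep(TRUE, n)
    } else {
      # f = e1 + N z keeps sum(f) = 1; N spans the zero-sum directions
      N <- rbind(-matrix(1, 1L, k - 1L), diag(k - 1L))
      AN <- As %*% N
      G <- crossprod(AN)
      if (rcond(G) < 1e-12) next
      rhs <- B - as.vector(As[, 1L])
      Z <- solve(G, crossprod(AN, rhs))
      Fs <- matrix(0, nrow = k, ncol = n)
      Fs[1L, ] <- 1 - colSums(Z)
      Fs[-1L, ] <- Z
      feas <- colSums(Fs < -1e-9) == 0L
      if (!any(feas)) next
      Fs[Fs < 0] <- 0
      Fs <- sweep(Fs, 2L, colSums(Fs), "/")   # exact sum-to-one
      resid <- colSums((As %*% Fs - B)^2)
    }
    take <- feas & (resid < best_obj - 1e-15)
    if (any(take)) {
      best_obj[take] <- resid[take]
      best_f[, take] <- 0
      best_f[S, take] <- Fs[, take]
    }
  }
  best_f
}

# Shared worker: B is the 2 x n matrix of (mu_LE, mu_HE) voxel pairs.
decompose_batch <- function(B, calset, mode, w = 1) {
  A <- basis_matrix(calset)
  if (mode == "two_material") {
    f2 <- nnls_batch(A[, 1:2, drop = FALSE], B)
    f <- rbind(f2, 0)
  } else if (mode == "three_material_soft") {
    s <- w * sum_row_scale(A)
    M <- rbind(A, s)
    Be <- rbind(B, s)
    f <- nnls_batch(M, Be)
  } else if (mode == "three_material_hard") {
    f <- simplex_batch(A, B)
  } else {
    stop("unknown mode: ", mode, call. = FALSE)
  }
  resid <- sqrt(colSums((A %*% f - B)^2))
  rownames(f) <- c("stain", "pmma", "air")
  list(fractions = f, residual = resid)
}

#' Decompose a single voxel
#'
#' Solves the constrained material decomposition for one `(mu_LE, mu_HE)`
#' pair. See [decompose_volume()] for the modes; `solve_voxel` is the
#' single-voxel entry point used for inspection and oracle testing.
#'
#' @param mu_le,mu_he Attenuation coefficients (mm^-1); negative values are
#'   accepted (they arise from scattering) — non-negativity applies to the
#'   fractions only.
#' @param calset A [calibration_set()]; must pass [conditioning()].
#' @param mode One of `"two_material"`, `"three_material_soft"`,
#'   `"three_material_hard"`.
#' @param w Weight of the sum-to-one row in soft mode (default 1); the row
#'   is additionally scaled by the mean absolute basis coefficient so it is
#'   commensurable with the attenuation rows.
#' @return List with `fractions` (named: stain, pmma, air) and `residual`
#'   (2-norm misfit of the two attenuation rows, mm^-1).
#' @examples
#' cs <- default_calibration_set()
#' solve_voxel(cs$stain[1], cs$stain[2], cs)  # pure stain: F = (1, 0, 0)
#' @export
solve_voxel <- function(mu_le, mu_he, calset,
                        mode = c("three_material_soft", "two_material",
                                 "three_material_hard"),
                        w = 1) {
  mode <- match.arg(mode)
  if (!is.finite(mu_le) || !is.finite(mu_he)) {
    stop("attenuation inputs must be finite", call. = FALSE)
  }
  check_calset_conditioning(calset)
  res <- decompose_batch(matrix(c(mu_le, mu_he), nrow = 2L), calset, mode, w)
  list(fractions = res$fractions[, 1L], residual = res$residual[1L])
}

#' Decompose a registered dual-energy volume pair into fraction maps
#'
#' Applies [solve_voxel()]'s constrained decomposition to every in-mask
#' voxel of a registered LE/HE volume pair, producing per-voxel fractions
#' of the calibration materials (the staining map) plus a residual map.
#' Fractions are expressed relative to the calibration staining solution;
#' in soft mode they may exceed 1 where the agent accumulates above the
#' bath concentration. Out-of-mask voxels are encoded as `NaN` with the
#' accompanying `computed` validity mask.
#'
#' @param vol_le,vol_he Registered, congruent `attenuation_volume`s.
#' @param calset A [calibration_set()].
#' @param mode,w See [solve_voxel()].
#' @param mask Optional logical array restricting the computation.
#' @return An object of class `fraction_map`: arrays `f_stain`, `f_pmma`,
#'   `f_air`, `residual`, logical `computed`, plus `mode`, `w`,
#'   `voxel_size_um` and the calibration provenance.
#' @export
decompose_volume <- function(vol_le, vol_he, calset,
                             mode = c("three_material_soft", "two_material",
                                      "three_material_hard"),
                             mask = NULL, w = 1) {
  mode <- match.arg(mode)
  stopifnot(is_attenuation_volume(vol_le), is_attenuation_volume(vol_he))
  check_same_shape(vol_le, vol_he)
  check_congruent(vol_le, mask)
  check_calset_conditioning(calset)
  d <- dim(vol_le$data)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  idx <- which(mask)
  B <- rbind(vol_le$data[idx], vol_he$data[idx])
  res <- decompose_batch(B, calset, mode, w)
  blank <- array(NaN, dim = d)
  f_stain <- blank; f_pmma <- blank; f_air <- blank; residual <- blank
  f_stain[idx] <- res$fractions["stain", ]
  f_pmma[idx] <- res$fractions["pmma", ]
  f_air[idx] <- res$fractions["air", ]
  residual[idx] <- res$residual
  structure(
    list(f_stain = f_stain, f_pmma = f_pmma, f_air = f_air,
         residual = residual, computed = mask, mode = mode, w = w,
         voxel_size_um = vol_le$voxel_size_um,
         calibration = calset),
    class = "fraction_map"
  )
}

#' @export
print.fraction_map <- function(x, ...) {
  d <- dim(x$f_stain)
  n <- sum(x$computed)
  cat(sprintf("<fraction_map> %d x %d x %d voxels, %d computed, mode %s\n",
              d[1], d[2], d[3], n, x$mode))
  if (n > 0) {
    cat(sprintf("  F_stain range [%.4f, %.4f], mean residual %.3g mm^-1\n",
                min(x$f_stain[x$computed]), max(x$f_stain[x$computed]),
                mean(x$residual[x$computed])))
  }
  invisible(x)
}
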