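# The iterative dipole-screening engine: imaginary-frequency grid, Gaussian
# dipole widths, smooth interaction cutoff, the three interaction channels
# (non-directional, static directional, fluctuating directional), incremental
# screening with width updates, and the proportional polarizability partition.

#' Imaginary-frequency integration grid
#'
#' Maps the integer quadrature index `u = 1..n_points` to imaginary-frequency
#' magnitudes via
#' \deqn{\omega(u) = \Lambda\left[(N/u)^2 - 1\right],}
#' which carries \eqn{\omega \in [0,\infty)} onto \eqn{u \in (0, N]}:
#' `u = n_points` is the static point (\eqn{\omega = 0}) and \eqn{\omega}
#' increases strictly as `u` decreases. The scale \eqn{\Lambda} (hartree)
#' places the quadrature nodes; the default 0.1 gives sub-percent
#' Casimir-Polder accuracy for Lorentzian profiles with characteristic
#' frequencies in the physical 0.05-1 hartree range (see the methods
#' vignette).
#'
#' @param n_points Number of grid points (>= 2; default 16). Romberg
#'   integration requires a power of two.
#' @param scale Frequency scale \eqn{\Lambda} in hartree.
#' @return A tibble with columns `u` and `omega`, with attributes `n_points`
#'   and `scale`.
#' @export
build_imfreq_grid <- function(n_points = 16, scale = 0.1) {
  if (n_points < 2) stop("invalid-grid: n_points must be >= 2", call. = FALSE)
  u <- seq_len(n_points)
  g <- tibble::tibble(u = u, omega = scale * ((n_points / u)^2 - 1))
  attr(g, "n_points") <- as.integer(n_points)
  attr(g, "scale") <- scale
  g
}

# Internal: u recovered from omega (inverse of the grid transform).
.u_from_omega <- function(omega, n_points, scale) {
  n_points / sqrt(omega / scale + 1)
}

#' Dynamic polarizability at imaginary frequency
#'
#' One-Lorentzian model \eqn{\alpha(i\omega) = \alpha_0 /
#' (1 + (\omega/w_p)^2)}; equals the static value at \eqn{\omega = 0} and
#' half of it at \eqn{\omega = w_p}.
#'
#' @param alpha_static Static polarizability (bohr^3).
#' @param wp Characteristic frequency (hartree).
#' @param omega Imaginary-frequency magnitude (hartree, >= 0).
#' @return Polarizability at `omega` (bohr^3).
#' @export
dynamic_alpha <- function(alpha_static, wp, omega) {
  alpha_static / (1 + (omega / wp)^2)
}

#' Spherical Gaussian dipole width
#'
#' \deqn{\sigma_A(u) = \left(\sqrt{2/\pi}\,\alpha_A(u)/3\right)^{1/3}}
#' (cube-root scaling with the polarizability).
#'
#' @param alpha Polarizability (bohr^3, > 0).
#' @return Width in bohr.
#' @export
gaussian_width <- function(alpha) {
  (sqrt(2 / pi) * alpha / 3)^(1 / 3)
}

#' Pair attenuation length
#'
#' Root-sum-square combination of the two Gaussian dipole widths,
#' \eqn{\sigma_{AB} = \sqrt{\sigma_A^2 + \sigma_B^2}}.
#'
#' @param width_a,width_b Widths (bohr).
#' @return Attenuation length (bohr).
#' @export
attenuation_length <- function(width_a, width_b) {
  sqrt(width_a^2 + width_b^2)
}

#' Smooth dipole-interaction cutoff function
#'
#' \deqn{f_{cutoff}(d) = H(d_{cutoff} - d)\left[1 -
#'   e^{-20\left((d_{cutoff}-d)/d_{cutoff}\right)^3}\right]}
#' Decreases smoothly from ~1 at `d = 0` to exactly 0 at `d >= cutoff`; the
#' cubed argument makes the first and second derivatives continuous at the
#' cutoff, and the factor 20 keeps
#' \eqn{f_{cutoff}(d \le 0.5\,d_{cutoff}) \ge 0.9179}. An infinite cutoff
#' disables attenuation (returns 1).
#'
#' @param distance Distance(s) in bohr.
#' @param cutoff Cutoff length in bohr (> 0), default 50.
#' @return Dimensionless factor in [0, 1).
#' @export
f_cutoff <- function(distance, cutoff = 50) {
  if (any(cutoff <= 0)) stop("invalid-value: cutoff must be > 0", call. = FALSE)
  if (is.infinite(cutoff)) return(rep(1, length(distance)))
  ifelse(distance >= cutoff, 0,
         1 - exp(-20 * ((cutoff - distance) / cutoff)^3))
}

#' Multibody screening attenuation of fluctuating-dipole alignment
#'
#' First-order exponential decay of directional alignment between
#' fluctuating dipoles,
#' \deqn{\exp\left[-d_{Ab} / \left(MBSP\,(r^{uns}_{damp,A} +
#'   r^{uns}_{damp,B})\right)\right],}
#' equal to 1 at zero separation and halving over each additional
#' half-distance.
#'
#' @param distance Separation (bohr).
#' @param rdamp_a,rdamp_b Unscreened damping radii of the two atoms (bohr).
#' @param mbsp Multibody screening parameter (default 2.5).
#' @return Dimensionless factor in (0, 1].
#' @export
mbsp_factor <- function(distance, rdamp_a, rdamp_b, mbsp = 2.5) {
  exp(-distance / (mbsp * (rdamp_a + rdamp_b)))
}

# erf via pnorm
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Internal: Gaussian-damped dipole interaction tensor for displacement rows
# (matrix with columns dx,dy,dz,d), one 3x3 per row summed with per-row
# scalar prefactors `fac`. interaction = "gaussian" uses tau =
# -grad grad erf(d/sigma)/d; "bare" uses the point-dipole tensor
# (d^2 I - 3 r rT)/d^5.
.tau_tensor_sum <- function(dd, sigma_ab, fac, interaction = "gaussian",
                            traceless = FALSE) {
  out <- matrix(0, 3, 3)
  if (nrow(dd) == 0) return(out)
  for (k in seq_len(nrow(dd))) {
    r <- dd[k, 1:3]; d <- dd[k, 4]
    rr <- tcrossprod(r)
    bare <- (diag(3) * d^2 - 3 * rr) / d^5
    if (interaction == "bare") {
      tau <- bare
    } else {
      z <- d / sigma_ab
      b <- .erf(z) - (2 * z / sqrt(pi)) * exp(-z^2)
      tau <- b * bare + (4 / sqrt(pi)) * z^3 * exp(-z^2) * rr / d^5
      if (traceless) tau <- tau - diag(3) * (sum(diag(tau)) / 3)
    }
    out <- out + fac[k] * tau
  }
  out
}

# Internal: non-directional (orientation-independent) channel: one third of
# the trace of the Gaussian dipole tensor, summed over displacement rows.
# Identically zero for bare point dipoles (the bare tensor is traceless).
.tau_nondir_sum <- function(dd, sigma_ab, fac, interaction = "gaussian") {
  if (nrow(dd) == 0 || interaction == "bare") return(0)
  d <- dd[, 4]
  z <- d / sigma_ab
  sum(fac * (4 / (3 * sqrt(pi))) * z^3 * exp(-z^2) / d^3)
}

# Internal: scalar cutoff (and optional MBSP) prefactors for displacement rows.
.pair_factors <- function(dd, config, mbsp_len = NULL) {
  if (nrow(dd) == 0) return(numeric(0))
  d <- dd[, 4]
  fac <- if (config$smooth_cutoff) f_cutoff(d, config$cutoff) else as.numeric(d < config$cutoff)
  if (!is.null(mbsp_len)) fac <- fac * exp(-d / mbsp_len)
  fac
}

#' Proportional partition of the non-directional screening matrix
#'
#' Splits each mixed A-B contribution of the screened polarizability matrix
#' in proportion to the atoms' pre-screened polarizabilities (instead of the
#' Applequist row-sum), so atoms with larger pre-screened polarizability
#' receive a proportionally larger share:
#' \deqn{\alpha_A = P_{AA} + \sum_{B\ne A}
#'   \frac{w_A}{w_A + w_B}(P_{AB} + P_{BA}).}
#' The atom-sums of the partition equal the total contraction of `P`
#' (conservation). If both weights of a shared pair are zero the mixed term
#' is split equally (with a warning).
#'
#' @param P Natoms x Natoms screened polarizability matrix.
#' @param weights Pre-screened per-atom polarizabilities (length Natoms).
#' @return Per-atom partitioned polarizabilities (length Natoms).
#' @export
partition_nondirectional <- function(P, weights) {
  n <- length(weights)
  stopifnot(nrow(P) == n, ncol(P) == n)
  out <- diag(P)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b == a) next
      out[a] <- out[a] + .pair_weight(weights[a], weights[b]) * (P[a, b] + P[b, a])
    }
  }
  out
}

.pair_weight <- function(wa, wb) {
  s <- wa + wb
  if (s <= 0) {
    warning("degenerate-partition: both pre-screened weights are zero; splitting equally")
    return(0.5)
  }
  wa / s
}

#' Proportional partition of a directional screening matrix into AIM tensors
#'
#' Tensor analogue of [partition_nondirectional()]: each atom receives its
#' diagonal 3x3 block plus the proportional share of the symmetrized mixed
#' blocks,
#' \deqn{P^A = P^{AA} + \sum_{B \ne A} \frac{w_A}{w_A + w_B}
#'   \left(P^{AB} + P^{BA}\right),}
#' which is symmetric whenever `P` is. Used for both the fluctuating and the
#' static directional stages (they differ only in the interaction tensor
#' screened and in the weights supplied).
#'
#' @param P 3Natoms x 3Natoms screened polarizability matrix.
#' @param weights Pre-screened per-atom polarizabilities (length Natoms).
#' @return List of symmetric 3x3 per-atom polarizability tensors (bohr^3).
#' @export
partition_tensor <- function(P, weights) {
  n <- length(weights)
  stopifnot(nrow(P) == 3 * n, ncol(P) == 3 * n)
  blk <- function(a, b) P[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)]
  out <- vector("list", n)
  for (a in seq_len(n)) {
    ta <- blk(a, a)
    ta <- (ta + t(ta)) / 2
    for (b in seq_len(n)) {
      if (b == a) next
      ta <- ta + .pair_weight(weights[a], weights[b]) * (blk(a, b) + blk(b, a))
    }
    out[[a]] <- (ta + t(ta)) / 2
  }
  out
}

# Internal: Applequist row-sum contraction (the TS-SCS convention): atom A
# receives the full row of blocks; may be asymmetric.
.partition_applequist <- function(P, n) {
  blk <- function(a, b) P[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)]
  lapply(seq_len(n), function(a) {
    ta <- matrix(0, 3, 3)
    for (b in seq_len(n)) ta <- ta + blk(a, b)
    ta
  })
}

#' Screening configuration
#'
#' Collects the tunable parameters of the screening pipeline. Defaults are
#' the method's standard values: 50 bohr dipole-interaction cutoff, 16
#' imaginary-frequency points, anisotropy correction factor 0.2, multibody
#' screening parameter 2.5, buried-atom constant C = 0.4, and smooth-minimum
#' steepness 25.
#'
#' @param cutoff Dipole interaction cutoff (bohr).
#' @param n_imfreqs Number of imaginary-frequency points.
#' @param n_increments Number of equal screening increments per stage.
#' @param mixing_cf Anisotropy correction factor in [0, 1].
#' @param mbsp Multibody screening parameter.
#' @param conduction_c Buried-atom polarizability/volume-proxy constant C.
#' @param smoothmin_steepness Smooth-minimum steepness.
#' @param omega_scale Imaginary-frequency grid scale (hartree).
#' @param width_update Update Gaussian widths from the evolving
#'   polarizabilities each iteration (`TRUE`, the MCLF behaviour) or freeze
#'   them at their initial values (`FALSE`, TS-SCS-style).
#' @param interaction `"gaussian"` for Gaussian-damped dipole tensors,
#'   `"bare"` for point dipoles (testing/oracles).
#' @param smooth_cutoff Use the smooth cutoff function (`TRUE`) or a hard
#'   cutoff (`FALSE`).
#' @return A list with class `aimpol_config`.
#' @export
mclf_config <- function(cutoff = 50, n_imfreqs = 16, n_increments = 10,
                        mixing_cf = 0.2, mbsp = 2.5, conduction_c = 0.4,
                        smoothmin_steepness = 25, omega_scale = 0.1,
                        width_update = TRUE, interaction = "gaussian",
                        smooth_cutoff = TRUE) {
  if (mixing_cf < 0 || mixing_cf > 1) {
    stop("invalid-value: mixing_cf must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    cutoff = cutoff, n_imfreqs = n_imfreqs, n_increments = n_increments,
    mixing_cf = mixing_cf, mbsp = mbsp, conduction_c = conduction_c,
    smoothmin_steepness = smoothmin_steepness, omega_scale = omega_scale,
    width_update = width_update,
    interaction = match.arg(interaction, c("gaussian", "bare")),
    smooth_cutoff = smooth_cutoff
  ), class = "aimpol_config")
}

# Internal solve with a labelled error.
.solve_screen <- function(Q, j) {
  tryCatch(solve(Q), error = function(e) {
    stop("screening-singularity: singular screening matrix at iteration ", j,
         call. = FALSE)
  })
}

# Internal: one non-directional screening pass at a single frequency.
# alpha0: pre-screened (unscreened) polarizabilities at this frequency; they
# are both the starting point and the partition weights.
.screen_nondir <- function(alpha0, disp, config) {
  n <- length(alpha0)
  p_atom <- alpha0
  if (n == 1 && nrow(disp[[1]][[1]]) == 0) return(p_atom)
  delta <- rep(1 / config$n_increments, config$n_increments)
  for (j in seq_along(delta)) {
    sig_alpha <- if (config$width_update) pmax(p_atom, 1e-10) else pmax(alpha0, 1e-10)
    sig <- gaussian_width(sig_alpha)
    tau <- matrix(0, n, n)
    for (a in seq_len(n)) {
      for (b in a:n) {
        dd <- disp[[a]][[b]]
        if (nrow(dd) == 0) next
        fac <- .pair_factors(dd, config)
        v <- .tau_nondir_sum(dd, attenuation_length(sig[a], sig[b]), fac,
                             config$interaction)
        tau[a, b] <- tau[a, b] + v
        if (b != a) tau[b, a] <- tau[b, a] + v
      }
    }
    Q <- diag(1 / p_atom, n) + delta[j] * tau
    P <- .solve_screen(Q, j)
    p_atom <- partition_nondirectional(P, alpha0)
    if (any(p_atom <= 0)) {
      stop("screening-singularity: non-positive partitioned polarizability at iteration ",
           j, call. = FALSE)
    }
  }
  p_atom
}

# Internal: one directional screening pass (static or fluctuating).
# tensors0: starting per-atom 3x3 tensors; weights: pre-screened
# polarizabilities for the proportional partition; mbsp_len: per-pair decay
# lengths (n x n matrix) or NULL for the static stage.
.screen_directional <- function(tensors0, weights, disp, config,
                                mbsp_len = NULL) {
  n <- length(tensors0)
  tensors <- tensors0
  iso0 <- vapply(tensors0, function(t) sum(diag(t)) / 3, numeric(1))
  if (n == 1 && nrow(disp[[1]][[1]]) == 0) return(tensors)
  delta <- rep(1 / config$n_increments, config$n_increments)
  for (j in seq_along(delta)) {
    iso <- vapply(tensors, function(t) sum(diag(t)) / 3, numeric(1))
    sig_alpha <- if (config$width_update) pmax(iso, 1e-10) else pmax(iso0, 1e-10)
    sig <- gaussian_width(sig_alpha)
    tau <- matrix(0, 3 * n, 3 * n)
    for (a in seq_len(n)) {
      for (b in a:n) {
        dd <- disp[[a]][[b]]
        if (nrow(dd) == 0) next
        fac <- .pair_factors(dd, config,
                             mbsp_len = if (is.null(mbsp_len)) NULL else mbsp_len[a, b])
        t3 <- .tau_tensor_sum(dd, attenuation_length(sig[a], sig[b]), fac,
                              config$interaction,
                              traceless = config$interaction == "gaussian")
        ia <- (3 * a - 2):(3 * a); ib <- (3 * b - 2):(3 * b)
        tau[ia, ib] <- tau[ia, ib] + t3
        if (b != a) tau[ib, ia] <- tau[ib, ia] + t3
      }
    }
    D <- matrix(0, 3 * n, 3 * n)
    for (a in seq_len(n)) {
      ia <- (3 * a - 2):(3 * a)
      D[ia, ia] <- .solve_screen(tensors[[a]], j)
    }
    Q <- D + delta[j] * tau
    P <- .solve_screen(Q, j)
    tensors <- partition_tensor(P, weights)
  }
  tensors
}

#' Apply the conduction-limit upper bound to non-directional polarizabilities
#'
#' \eqn{\alpha^{non\mbox{-}dir}(u) = \mathrm{smooth\_min}(\alpha^{raw}(u),
#' \alpha^{upperbound})} applied per frequency point; the force-field
#' polarizability is the static point of the bounded series.
#'
#' @param alpha_raw Raw non-directionally screened polarizabilities (vector
#'   or matrix with one column per frequency point).
#' @param bound Per-atom conduction upper bound(s), recycled as needed.
#' @param steepness Smooth-minimum steepness (default 25).
#' @return Bounded polarizabilities, same shape as `alpha_raw`.
#' @export
apply_upper_bound_per_frequency <- function(alpha_raw, bound, steepness = 25) {
  if (is.matrix(alpha_raw)) {
    out <- alpha_raw
    for (k in seq_len(ncol(alpha_raw))) {
      out[, k] <- smooth_min(alpha_raw[, k], bound, steepness)
    }
    out
  } else {
    smooth_min(alpha_raw, bound, steepness)
  }
}

#' Anisotropy correction of an AIM static polarizability tensor
#'
#' The spherical-Gaussian dipole model overestimates tensor anisotropy; the
#' corrected tensor mixes the screened tensor with its isotropic part:
#' \deqn{\alpha^{corrected} = C.F.\,\alpha^{iso} I + (1 - C.F.)\,
#'   \alpha^{tensor}.}
#' The trace is preserved when `iso` is the tensor's own isotropic value.
#'
#' @param tensor Symmetric 3x3 polarizability tensor (bohr^3).
#' @param iso Isotropic polarizability; defaults to `tr(tensor)/3`.
#' @param mixing Correction factor C.F. in [0, 1] (default 0.2).
#' @return Corrected symmetric 3x3 tensor.
#' @export
anisotropy_correction <- function(tensor, iso = NULL, mixing = 0.2) {
  if (mixing < 0 || mixing > 1) {
    stop("invalid-value: mixing must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(iso)) iso <- sum(diag(tensor)) / 3
  mixing * iso * diag(3) + (1 - mixing) * tensor
}

#' Projected polarizability along a direction
#'
#' \eqn{\hat k^T \alpha \hat k}; along the internuclear direction of a bonded
#' pair this is the bond polarizability.
#'
#' @param tensor Symmetric 3x3 polarizability tensor.
#' @param direction Length-3 direction vector (normalized internally).
#' @return Scalar projection (bohr^3).
#' @export
project_polarizability <- function(tensor, direction) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("invalid-direction: zero direction vector", call. = FALSE)
  k <- direction / nrm
  drop(t(k) %*% tensor %*% k)
}

# Internal: ascending eigenvalues of a symmetric tensor.
.tensor_eigen <- function(tensor) {
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}
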