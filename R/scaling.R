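# Unscreened per-atom properties: exposure factor m, the m-scaled
# polarizability and characteristic-frequency laws, the conduction-limit
# upper bound, and the smooth minimum used to apply it.

#' Build a validated per-atom AIM descriptor table
#'
#' Wraps a data frame of atom-in-material descriptors into the canonical
#' column set and checks the invariants: positive moments and volume,
#' `m` in [0, 1], and electron-count consistency
#' \eqn{N_A = Z_A - q_A}.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (bohr),
#'   `n` (electron count), `q` (net atomic charge), `r3` (bohr^3),
#'   `r4` (bohr^4), `volume` (bohr^3), `m` (exposure, 0-1) and `rdamp`
#'   (unscreened damping radius, bohr).
#' @param tol Absolute tolerance for the `N = Z - q` cross-check. The default
#'   accommodates tables printed with ~6 significant figures.
#' @return The input as a validated tibble.
#' @export
aim_atoms <- function(atoms, tol = 1e-4) {
  needed <- c("element", "x", "y", "z", "n", "q", "r3", "r4", "volume", "m", "rdamp")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    stop("missing-field: atoms table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  atoms <- tibble::as_tibble(atoms)
  if (any(atoms$r3 <= 0) || any(atoms$r4 <= 0) || any(atoms$volume <= 0)) {
    stop("invalid-value: r3, r4 and volume must be > 0", call. = FALSE)
  }
  if (any(atoms$m < 0 | atoms$m > 1)) {
    stop("invalid-value: exposure m must lie in [0, 1]", call. = FALSE)
  }
  z <- atomic_number(atoms$element)
  dev <- abs(atoms$n - (z - atoms$q))
  if (any(dev > tol)) {
    stop("consistency-error: N differs from Z - q by up to ",
         format(max(dev)), " (rows ",
         paste(which(dev > tol), collapse = ", "), ")", call. = FALSE)
  }
  atoms
}

#' Exposure factor m from radial profiles
#'
#' Quantifies how exposed (versus buried) an atom is: the density-weighted
#' radial average of the spherically averaged stockholder weight fraction
#' \eqn{w_A/W},
#' \deqn{m_A = \frac{\int \bar\rho_A(r)\,\bar f_A(r)\, r^2 dr}
#'   {\int \bar\rho_A(r)\, r^2 dr},}
#' evaluated by trapezoidal quadrature on the supplied grid. `m = 1` for an
#' isolated atom (weight fraction identically 1) and decreases toward 0 as
#' the atom becomes buried.
#'
#' @param r Radial grid (bohr, increasing).
#' @param density Spherically averaged assigned density \eqn{\bar\rho_A(r)}
#'   (non-negative, not identically zero).
#' @param weight_fraction Spherically averaged \eqn{w_A/W} on the same grid,
#'   values in [0, 1].
#' @return Scalar m in [0, 1].
#' @export
exposure_m <- function(r, density, weight_fraction) {
  if (length(r) != length(density) || length(r) != length(weight_fraction)) {
    stop("invalid-profile: profiles must share one radial grid", call. = FALSE)
  }
  if (any(density < 0)) {
    stop("invalid-profile: density must be non-negative", call. = FALSE)
  }
  w <- density * r^2
  denom <- .trapz(r, w)
  if (denom <= 0) {
    stop("invalid-profile: zero density profile, m undefined", call. = FALSE)
  }
  .trapz(r, w * weight_fraction) / denom
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Internal: isolated-atom scaling-law value for alpha (the Omega of the
# m-scaled law) as a ratio to the neutral free-atom reference.
.isolated_alpha <- function(n, r3, r4, ref, coeffs = scaling_coefficients()) {
  cf <- coeffs[coeffs$model == "alpha", ]
  ref$alpha_ref * (n / (ref$atomic_number))^cf$n_exponent *
    (r3 / ref$r3_ref)^cf$r3_exponent * (r4 / ref$r4_ref)^cf$r4_exponent
}

.isolated_wp_ratio <- function(n, r3, r4, ref, coeffs = scaling_coefficients()) {
  cf <- coeffs[coeffs$model == "wp", ]
  (n / (ref$atomic_number))^cf$n_exponent *
    (r3 / ref$r3_ref)^cf$r3_exponent * (r4 / ref$r4_ref)^cf$r4_exponent
}

#' Unscreened AIM polarizability with m-scaling
#'
#' Geometric interpolation between the buried-atom volume law and the
#' isolated-atom scaling law:
#' \deqn{\alpha^{unscreened} = (C\langle r^3\rangle)^{1-m}\,\Omega^m,}
#' where \eqn{\Omega} is the isolated-atom scaling-law polarizability (the
#' reference value scaled by the N, \eqn{\langle r^3\rangle},
#' \eqn{\langle r^4\rangle} ratios) and \eqn{C = 0.4} is the optimized
#' buried-atom polarizability-to-\eqn{\langle r^3\rangle} ratio.
#'
#' @param aim One-row (or vectorized) atoms table from [aim_atoms()].
#' @param ref Matching reference record(s) from [get_reference()].
#' @param conduction_c Buried-atom proportionality constant C (default 0.4).
#' @return Unscreened polarizability (bohr^3).
#' @export
unscreened_alpha <- function(aim, ref, conduction_c = 0.4) {
  omega <- .isolated_alpha(aim$n, aim$r3, aim$r4, ref)
  (conduction_c * aim$r3)^(1 - aim$m) * omega^aim$m
}

#' Unscreened characteristic frequency with m-scaling
#'
#' \deqn{w_p = \zeta^{(1-m^2)/4}\,\gamma\, w_p^{ref},}
#' where \eqn{\gamma} is the isolated-atom wp scaling-law ratio and
#' \eqn{\zeta = \Omega / (C\langle r^3\rangle)} compares the isolated-atom
#' polarizability law to the buried-atom volume law. At `m = 1` this reduces
#' exactly to the isolated-atom wp law; for buried atoms it damps the
#' sensitivity of wp to the polarizability.
#'
#' @inheritParams unscreened_alpha
#' @return wp in hartree.
#' @export
unscreened_wp <- function(aim, ref, conduction_c = 0.4) {
  gamma_ <- .isolated_wp_ratio(aim$n, aim$r3, aim$r4, ref)
  omega <- .isolated_alpha(aim$n, aim$r3, aim$r4, ref)
  zeta <- omega / (conduction_c * aim$r3)
  zeta^((1 - aim$m^2) / 4) * gamma_ * ref$wp_ref
}

#' Unscreened C6 from the unscreened polarizability and frequency
#'
#' One-oscillator relation \eqn{C_6 = (3/4)\alpha^2 w_p}; see
#' [c6_from_alpha_wp()].
#'
#' @param alpha_unscreened Unscreened polarizability (bohr^3).
#' @param wp Characteristic frequency (hartree).
#' @return C6 (hartree bohr^6).
#' @export
unscreened_c6 <- function(alpha_unscreened, wp) {
  c6_from_alpha_wp(alpha_unscreened, wp)
}

#' Conduction-limit polarizability upper bound
#'
#' The maximum local polarizability of a volume element of a perfect
#' conductor (plate geometry) is \eqn{V/(2\pi)} in atomic units; applied
#' per atom with the AIM volume:
#' \deqn{\alpha^{upperbound}_A = V_A / (2\pi).}
#'
#' @param volume AIM volume \eqn{V_A} (bohr^3, > 0).
#' @return Upper bound (bohr^3).
#' @export
conduction_upper_bound <- function(volume) {
  if (any(volume <= 0)) {
    stop("invalid-value: volume must be > 0", call. = FALSE)
  }
  volume / (2 * pi)
}

#' Smooth minimum of two polarizabilities
#'
#' Smooth approximant to `max(min(a, b), 0)` used to impose the conduction
#' upper bound while keeping energy derivatives continuous:
#' \deqn{f(a,b) = \frac{a\,e^{-\Upsilon a/b} + b\,e^{-\Upsilon b/a}}
#'   {e^{-\Upsilon a/b} + e^{-\Upsilon b/a}},}
#' with steepness \eqn{\Upsilon = 25}, which keeps the relative deviation
#' from `min(a, b)` below 0.58%. If either argument is <= 0 the function
#' returns 0.
#'
#' @param a,b Values (bohr^3); vectorized.
#' @param steepness Dimensionless steepness \eqn{\Upsilon} (default 25).
#' @return Smooth minimum, same length as the inputs.
#' @examples
#' smooth_min(3, 10)
#' smooth_min(-1, 5)  # 0
#' @export
smooth_min <- function(a, b, steepness = 25) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  ok <- a > 0 & b > 0
  if (any(ok)) {
    aa <- a[ok]; bb <- b[ok]
    # subtract the common max exponent for numerical stability
    ea <- -steepness * aa / bb
    eb <- -steepness * bb / aa
    mx <- pmax(ea, eb)
    wa <- exp(ea - mx); wb <- exp(eb - mx)
    out[ok] <- (aa * wa + bb * wb) / (wa + wb)
  }
  out
}

#' Per-atom unscreened state
#'
#' Convenience wrapper computing, for every atom, the unscreened
#' polarizability, characteristic frequency, unscreened C6 and the
#' conduction-limit upper bound.
#'
#' @param atoms Validated atoms table ([aim_atoms()]).
#' @param reference Reference table ([read_reference_table()]).
#' @param conduction_c Buried-atom constant C (default 0.4).
#' @return The atoms tibble with columns `alpha_unscreened`, `wp`,
#'   `c6_unscreened`, `alpha_upper_bound` appended.
#' @export
unscreened_state <- function(atoms, reference = read_reference_table(),
                             conduction_c = 0.4) {
  atoms <- aim_atoms(atoms)
  refs <- .atom_references(atoms, reference)
  alpha <- unscreened_alpha(atoms, refs, conduction_c)
  wp <- unscreened_wp(atoms, refs, conduction_c)
  dplyr::mutate(atoms,
    alpha_unscreened = alpha,
    wp = wp,
    c6_unscreened = unscreened_c6(alpha, wp),
    alpha_upper_bound = conduction_upper_bound(atoms$volume)
  )
}
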