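# Quantum Drude oscillator (QDO) parameterization and higher-order
# dispersion coefficients C8, C9, C10 with their mixing rules.
#
# Each atom carries one QDO: a charged pseudoparticle bound harmonically to a
# pseudonucleus. Its l-pole polarizability is
#   alpha_l = alpha_1 * ((2l-1)!! / (2 m wp))^(l-1)     (atomic units)
# and its l-pole dynamic polarizability is a Lorentzian resonant at l*wp
# (an l-pole excitation is an l-quantum excitation of the oscillator). All
# dispersion coefficients below follow from Casimir-Polder integrals of
# these Lorentzians in closed form.

#' Atomic C8 from the fitted moment correlation
#'
#' \deqn{C_{8,A} = e^{1.7327}\, C^{non\mbox{-}dir}_{6,A}
#'   \left(\langle r^4\rangle/\langle r^3\rangle\right)^{0.8305}}
#' with the published slope (0.8305) and intercept (1.7327) of the log-log
#' fit linking the dipole-quadrupole coefficient to the dipole-dipole one
#' through the AIM radial moments. The underlying fit has a mean absolute
#' relative error of ~15% against correlated-wavefunction references.
#'
#' @param c6_nondir Non-directionally screened C6 (hartree bohr^6, > 0).
#' @param r3 AIM \eqn{\langle r^3\rangle} (bohr^3, > 0).
#' @param r4 AIM \eqn{\langle r^4\rangle} (bohr^4, > 0).
#' @param slope,intercept Fit coefficients.
#' @return C8 in hartree bohr^8.
#' @export
c8_atom <- function(c6_nondir, r3, r4, slope = 0.8305, intercept = 1.7327) {
  if (any(c(c6_nondir, r3, r4) <= 0)) {
    stop("invalid-value: all inputs must be > 0", call. = FALSE)
  }
  exp(intercept) * c6_nondir * (r4 / r3)^slope
}

#' Parameterize a quantum Drude oscillator from alpha, C6 and C8
#'
#' Inverts the one-oscillator relations
#' \deqn{w_p = 4 C_6 / (3\alpha^2),\qquad
#'   m = \tfrac{15}{2}\,\alpha^2 / C_8,\qquad
#'   q = w_p \sqrt{m\,\alpha}}
#' (atomic units) so that the QDO reproduces the force-field polarizability,
#' the non-directional C6, and the atomic C8 exactly.
#'
#' @param alpha_ff Force-field polarizability (bohr^3, > 0).
#' @param c6_nondir Non-directionally screened C6 (> 0).
#' @param c8 Atomic C8 (> 0).
#' @return A tibble with columns `wp_qdo` (hartree), `m_qdo` (electron
#'   masses) and `q_qdo` (elementary charges).
#' @export
qdo_parameterize <- function(alpha_ff, c6_nondir, c8) {
  if (any(c(alpha_ff, c6_nondir, c8) <= 0)) {
    stop("qdo-infeasible: inputs must be > 0", call. = FALSE)
  }
  wp <- 4 * c6_nondir / (3 * alpha_ff^2)
  m <- 7.5 * alpha_ff^2 / c8
  q <- wp * sqrt(m * alpha_ff)
  if (any(!is.finite(c(wp, m, q))) || any(c(wp, m, q) <= 0)) {
    stop("qdo-infeasible: inputs yield non-positive QDO parameters",
         call. = FALSE)
  }
  tibble::tibble(wp_qdo = wp, m_qdo = m, q_qdo = q)
}

# Internal: l-pole static polarizability of a QDO.
.qdo_alpha_l <- function(alpha1, m, wp, l) {
  dfact <- c(1, 3, 15)[l]  # (2l-1)!!
  alpha1 * (dfact / (2 * m * wp))^(l - 1)
}

# Internal: Casimir-Polder cross integral of two Lorentzians with
# resonances wa, wb: (1/pi) * Int a/(1+(w/wa)^2) * b/(1+(w/wb)^2) dw
# = a*b*wa*wb / (2*(wa+wb)).
.lorentzian_cross <- function(a, b, wa, wb) {
  a * b * wa * wb / (2 * (wa + wb))
}

#' Higher-order dispersion coefficients from QDO parameters
#'
#' Closed-form Casimir-Polder combinations of the QDO multipole
#' Lorentzians (the l-pole resonance sits at \eqn{l\,w_p}):
#' \deqn{C_{8,AB} = \tfrac{15}{2}\left[G(1_A,2_B) + G(2_A,1_B)\right],\quad
#'   C_{10,AB} = 35\,G(2_A,2_B) + 14\left[G(1_A,3_B) + G(3_A,1_B)\right],}
#' with \eqn{G(l_A,l'_B) = \frac{1}{\pi}\int
#' \alpha_{l,A}(i\omega)\alpha_{l',B}(i\omega)\,d\omega}. Homoatomic values
#' reduce to \eqn{C_8 = 5 w_p \alpha_1\alpha_2} and \eqn{C_{10} =
#' \tfrac{35}{2} w_p \alpha_2^2 + \tfrac{21}{2} w_p \alpha_1\alpha_3}. The
#' triple-dipole coefficient uses the Pade-type rule
#' \deqn{C_{9,ABC} = \tfrac{3}{2}\,\alpha_A\alpha_B\alpha_C\,
#'   \frac{w_A w_B w_C\,(w_A + w_B + w_C)}
#'        {(w_A + w_B)(w_B + w_C)(w_A + w_C)}.}
#'
#' @param params Tibble of QDO parameters ([qdo_parameterize()]) with one
#'   row per atom, plus a column `alpha_ff`.
#' @param pairs Return pair matrices `c8_ab`, `c10_ab` (default TRUE).
#' @param triples Return the Natoms^3-scaling `c9_abc` array (default
#'   FALSE).
#' @return A list with `atom` (tibble: `c8`, `c9`, `c10`, `alpha2`,
#'   `alpha3`) and optionally `c8_ab`, `c10_ab` matrices and `c9_abc` array.
#' @export
higher_order_coefficients <- function(params, pairs = TRUE, triples = FALSE) {
  stopifnot(all(c("wp_qdo", "m_qdo", "alpha_ff") %in% names(params)))
  wp <- params$wp_qdo; m <- params$m_qdo; a1 <- params$alpha_ff
  a2 <- .qdo_alpha_l(a1, m, wp, 2)
  a3 <- .qdo_alpha_l(a1, m, wp, 3)
  n <- length(wp)
  c8_ab_fun <- function(i, j) {
    7.5 * (.lorentzian_cross(a1[i], a2[j], wp[i], 2 * wp[j]) +
             .lorentzian_cross(a2[i], a1[j], 2 * wp[i], wp[j]))
  }
  c10_ab_fun <- function(i, j) {
    35 * .lorentzian_cross(a2[i], a2[j], 2 * wp[i], 2 * wp[j]) +
      14 * (.lorentzian_cross(a1[i], a3[j], wp[i], 3 * wp[j]) +
              .lorentzian_cross(a3[i], a1[j], 3 * wp[i], wp[j]))
  }
  c9_fun <- function(i, j, k) {
    1.5 * a1[i] * a1[j] * a1[k] *
      wp[i] * wp[j] * wp[k] * (wp[i] + wp[j] + wp[k]) /
      ((wp[i] + wp[j]) * (wp[j] + wp[k]) * (wp[i] + wp[k]))
  }
  atom <- tibble::tibble(
    c8 = vapply(seq_len(n), function(i) c8_ab_fun(i, i), numeric(1)),
    c9 = vapply(seq_len(n), function(i) c9_fun(i, i, i), numeric(1)),
    c10 = vapply(seq_len(n), function(i) c10_ab_fun(i, i), numeric(1)),
    alpha2 = a2, alpha3 = a3
  )
  out <- list(atom = atom)
  if (pairs) {
    c8m <- matrix(0, n, n); c10m <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      c8m[i, j] <- c8m[j, i] <- c8_ab_fun(i, j)
      c10m[i, j] <- c10m[j, i] <- c10_ab_fun(i, j)
    }
    out$c8_ab <- c8m; out$c10_ab <- c10m
  }
  if (triples) {
    arr <- array(0, dim = c(n, n, n))
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      arr[i, j, k] <- c9_fun(i, j, k)
    }
    out$c9_abc <- arr
  }
  out
}

#' Axilrod-Teller-Muto three-body energy term
#'
#' \deqn{E_9 = C_{9,ABC}\,\frac{1 + 3\cos\angle a\,\cos\angle b\,
#'   \cos\angle c}{(R_{AB} R_{AC} R_{BC})^3}.}
#' When only the three side lengths are given the interior angles are
#' computed by the law of cosines. Note that the directional screening of
#' the dispersion polarizabilities already contains the *intramolecular*
#' triple-dipole interactions of the calculated system; force-field builders
#' should apply this term to atom triplets spanning two or more molecules
#' only, to avoid double counting.
#'
#' @param c9_abc Triple-dipole coefficient (hartree bohr^9).
#' @param r_ab,r_ac,r_bc Triangle side lengths (bohr).
#' @param angles Optional interior angles (radians) at vertices A, B, C; by
#'   default computed from the side lengths.
#' @return E9 in hartree.
#' @export
e9_term <- function(c9_abc, r_ab, r_ac, r_bc, angles = NULL) {
  sides <- c(r_ab, r_ac, r_bc)
  if (any(sides <= 0) || any(2 * max(sides) >= sum(sides) + 1e-12)) {
    stop("invalid-triangle: side lengths must form a non-degenerate triangle",
         call. = FALSE)
  }
  if (is.null(angles)) {
    cos_a <- (r_ab^2 + r_ac^2 - r_bc^2) / (2 * r_ab * r_ac)
    cos_b <- (r_ab^2 + r_bc^2 - r_ac^2) / (2 * r_ab * r_bc)
    cos_c <- (r_ac^2 + r_bc^2 - r_ab^2) / (2 * r_ac * r_bc)
  } else {
    cos_a <- cos(angles[1]); cos_b <- cos(angles[2]); cos_c <- cos(angles[3])
  }
  c9_abc * (1 + 3 * cos_a * cos_b * cos_c) / (r_ab * r_ac * r_bc)^3
}
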