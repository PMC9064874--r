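# Synthetic AIM systems with controllable properties, plus independent
# brute-force oracles (classical point-dipole inversion, Clausius-Mossotti
# and conduction references, the Lorentzian Casimir-Polder closed form).
# The oracles deliberately share no code with the screening engine.

#' Generate a synthetic AIM system
#'
#' Builds a structure plus AIM descriptor table for a toy topology. Radial
#' moments are the reference-atom moments times the perturbation factors;
#' the exposure factor is set directly (1 for gas-phase toys, < 1 for
#' buried/lattice toys). Deterministic given `seed` (used only when
#' `jitter > 0`).
#'
#' @param topology One of `"single_atom"`, `"dimer"`, `"linear_chain"`,
#'   `"cubic_lattice"`.
#' @param element Element symbol(s); recycled over atoms.
#' @param separation Nearest-neighbour separation (bohr).
#' @param n_atoms Atom count for `linear_chain`.
#' @param n_cells Edge cell count for `cubic_lattice` (atoms = n_cells^3 in
#'   a periodic cell when `periodic = TRUE`).
#' @param m Exposure factor per atom (recycled).
#' @param moment_factor Multiplier applied to reference `r3` (and, to the
#'   4/3 power, to `r4`); emulates AIM contraction/expansion.
#' @param jitter Gaussian positional noise amplitude (bohr).
#' @param periodic For `cubic_lattice`: make the cell 3D-periodic.
#' @param seed Integer seed for the jitter.
#' @param reference Reference table supplying per-element moments.
#' @return A list with `atoms` (tibble accepted by [mclf()]) and `cell`
#'   (a [unit_cell()]).
#' @export
make_toy_system <- function(topology = c("single_atom", "dimer",
                                         "linear_chain", "cubic_lattice"),
                            element = "Ar", separation = 6, n_atoms = 4,
                            n_cells = 2, m = NULL, moment_factor = 1,
                            jitter = 0, periodic = TRUE, seed = 1,
                            reference = read_reference_table()) {
  topology <- match.arg(topology)
  cell <- unit_cell()
  pos <- switch(topology,
    single_atom = matrix(0, 1, 3),
    dimer = rbind(c(0, 0, 0), c(0, 0, separation)),
    linear_chain = cbind(0, 0, separation * (seq_len(n_atoms) - 1)),
    cubic_lattice = {
      g <- expand.grid(i = 0:(n_cells - 1), j = 0:(n_cells - 1),
                       k = 0:(n_cells - 1))
      if (periodic) {
        cell <- unit_cell(diag(separation * n_cells, 3),
                          periodic = c(TRUE, TRUE, TRUE))
      }
      separation * as.matrix(g)
    }
  )
  n <- nrow(pos)
  if (jitter > 0) {
    withr_seed <- seed  # deterministic jitter without touching global RNG
    rng <- local({set.seed(withr_seed); matrix(stats::rnorm(3 * n, sd = jitter), n, 3)})
    pos <- pos + rng
  }
  if (is.null(m)) m <- if (topology == "cubic_lattice") 0.2 else 1
  element <- rep_len(element, n)
  m <- rep_len(m, n)
  moment_factor <- rep_len(moment_factor, n)
  refs <- dplyr::bind_rows(lapply(element, get_reference, table = reference))
  r3 <- refs$r3_ref * moment_factor
  r4 <- refs$r4_ref * moment_factor^(4 / 3)
  tibble_out <- tibble::tibble(
    element = element,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    n = as.numeric(refs$atomic_number),
    q = 0,
    r3 = r3, r4 = r4,
    # geometric AIM volume: a van-der-Waals-scale sphere, not the <r3>
    # density moment (which is several times smaller); keeps the conduction
    # bound from binding for exposed atoms, as for real gas-phase atoms
    volume = (4 * pi / 3) * refs$rdamp_ref^3 * moment_factor,
    m = m,
    rdamp = refs$rdamp_ref
  )
  list(atoms = aim_atoms(tibble_out), cell = cell)
}

#' Classical point-dipole (Applequist-style) molecular polarizability
#'
#' Independent dense oracle: builds the 3N x 3N matrix with
#' \eqn{1/\alpha_A} blocks on the diagonal and the chosen dipole interaction
#' off-diagonal, inverts it directly, and contracts all blocks into the
#' molecular polarizability tensor. Used as ground truth for one-shot
#' screening equivalence; it shares no code with the screening engine.
#'
#' @param positions N x 3 matrix (bohr).
#' @param alphas Isotropic per-atom polarizabilities (bohr^3).
#' @param interaction `"bare"` point dipoles or `"gaussian"`-attenuated
#'   dipoles (widths from the supplied polarizabilities).
#' @return Symmetric 3x3 molecular polarizability tensor.
#' @export
applequist_oracle <- function(positions, alphas,
                              interaction = c("bare", "gaussian")) {
  interaction <- match.arg(interaction)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n > 50) stop("oracle is intended for small systems (N <= 50)", call. = FALSE)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  M <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) {
    ia <- (3 * a - 2):(3 * a)
    M[ia, ia] <- diag(3) / alphas[a]
    for (b in seq_len(n)) {
      if (b == a) next
      r <- positions[b, ] - positions[a, ]
      d <- sqrt(sum(r^2))
      rr <- tcrossprod(r)
      tt <- (diag(3) * d^2 - 3 * rr) / d^5
      if (interaction == "gaussian") {
        sab <- sqrt(sum((sqrt(2 / pi) * alphas[c(a, b)] / 3)^(2 / 3)))
        z <- d / sab
        damp <- erf(z) - (2 * z / sqrt(pi)) * exp(-z^2)
        tt <- damp * tt + (4 / sqrt(pi)) * z^3 * exp(-z^2) * rr / d^5
      }
      ib <- (3 * b - 2):(3 * b)
      M[ia, ib] <- tt
    }
  }
  P <- tryCatch(solve(M), error = function(e) {
    stop("oracle-singularity: dipole matrix is singular", call. = FALSE)
  })
  out <- matrix(0, 3, 3)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    out <- out + P[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)]
  }
  (out + t(out)) / 2
}

#' Clausius-Mossotti and conduction-limit reference polarizabilities
#'
#' Benchmark helpers: the Clausius-Mossotti polarizability of a volume `V`
#' with dielectric constant `kappa`,
#' \deqn{\alpha_{CM} = \frac{3V}{4\pi}\,\frac{\kappa - 1}{\kappa + 2},}
#' and the conducting-sphere limit \eqn{3V/(4\pi)} (its \eqn{\kappa \to
#' \infty} limit). A benchmark reference polarizability is the smaller of
#' the two.
#'
#' @param kappa Dielectric constant (> 1 for `clausius_mossotti_reference`).
#' @param volume Volume (bohr^3).
#' @return Polarizability (bohr^3).
#' @export
clausius_mossotti_reference <- function(kappa, volume) {
  if (any(kappa <= 1)) {
    stop("invalid-dielectric: kappa must be > 1", call. = FALSE)
  }
  (3 * volume / (4 * pi)) * (kappa - 1) / (kappa + 2)
}

#' @rdname clausius_mossotti_reference
#' @export
conduction_reference <- function(volume) {
  3 * volume / (4 * pi)
}

#' Closed-form Casimir-Polder C6 of a Lorentzian profile
#'
#' \eqn{(3/4)\,\alpha_0^2\, w_p} analytically; the quadrature-free oracle
#' for [casimir_polder_c6()].
#'
#' @param alpha0 Static polarizability (bohr^3, > 0).
#' @param wp Characteristic frequency (hartree, > 0).
#' @return C6 (hartree bohr^6).
#' @export
lorentzian_c6_oracle <- function(alpha0, wp) {
  if (any(alpha0 <= 0) || any(wp <= 0)) {
    stop("invalid-value: inputs must be > 0", call. = FALSE)
  }
  0.75 * alpha0^2 * wp
}
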