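# TS and TS-SCS baseline: volume-ratio unscreened polarizabilities and
# one-shot self-consistent screening with frozen Gaussian widths, an
# Applequist row-sum contraction and a hard distance cutoff. Kept for
# side-by-side comparison with the staged method; its documented failure
# modes (asymmetric AIM tensors, occasional negative AIM polarizabilities)
# are reproduced, not repaired.

#' TS unscreened AIM polarizability
#'
#' \deqn{\alpha^{TS}_A = \alpha^{ref}
#'   \langle r^3\rangle^{AIM} / \langle r^3\rangle^{ref}.}
#'
#' @param aim Atoms table row(s) ([aim_atoms()]).
#' @param ref Matching reference record(s).
#' @return Polarizability (bohr^3).
#' @export
ts_unscreened_alpha <- function(aim, ref) {
  ref$alpha_ref * aim$r3 / ref$r3_ref
}

#' TS-SCS screening
#'
#' Builds, at each imaginary-frequency point, the many-body matrix
#' \eqn{Q = D + \tau} with \eqn{D = \mathrm{diag}(1/\alpha^{TS}_A(u))} and
#' the full Gaussian-damped dipole interaction tensor \eqn{\tau}, inverts it
#' once (no increments, widths frozen at their unscreened values), contracts
#' the inverse by Applequist row sums into per-atom tensors, and integrates
#' the isotropic series into per-atom C6 coefficients. A hard distance
#' cutoff is used, consistent with prior practice for this method.
#'
#' @param atoms Atoms table ([aim_atoms()]).
#' @param cell A [unit_cell()].
#' @param reference Reference table.
#' @param cutoff Hard dipole-interaction cutoff (bohr), default 50.
#' @param n_imfreqs Number of imaginary-frequency points (default 16).
#' @param omega_scale Grid scale (hartree).
#' @return An object of class `tsscs_result`: list with `atoms` (tibble
#'   adding `alpha_ts`, `alpha_scs`, `c6_atom` and static-tensor
#'   eigenvalues), `tensors` (per-atom static 3x3, possibly asymmetric),
#'   `alpha_u` (Natoms x n_imfreqs isotropic screened series) and `grid`.
#' @export
tsscs_screen <- function(atoms, cell = unit_cell(),
                         reference = read_reference_table(),
                         cutoff = 50, n_imfreqs = 16, omega_scale = 0.1) {
  atoms <- aim_atoms(atoms)
  n <- nrow(atoms)
  refs <- .atom_references(atoms, reference)
  alpha_ts <- ts_unscreened_alpha(atoms, refs)
  wp <- refs$wp_ref
  grid <- build_imfreq_grid(n_imfreqs, omega_scale)
  config <- mclf_config(cutoff = cutoff, smooth_cutoff = FALSE,
                        width_update = FALSE)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  disp <- .system_displacements(pos, cell, cutoff)
  alpha_u <- matrix(0, n, n_imfreqs)
  tensors <- NULL
  for (k in seq_len(n_imfreqs)) {
    a_u <- dynamic_alpha(alpha_ts, wp, grid$omega[k])
    sig <- gaussian_width(a_u)
    tau <- matrix(0, 3 * n, 3 * n)
    for (a in seq_len(n)) {
      for (b in a:n) {
        dd <- disp[[a]][[b]]
        if (nrow(dd) == 0) next
        fac <- .pair_factors(dd, config)
        t3 <- .tau_tensor_sum(dd, attenuation_length(sig[a], sig[b]), fac,
                              "gaussian", traceless = FALSE)
        ia <- (3 * a - 2):(3 * a); ib <- (3 * b - 2):(3 * b)
        tau[ia, ib] <- tau[ia, ib] + t3
        if (b != a) tau[ib, ia] <- tau[ib, ia] + t3
      }
    }
    Q <- diag(rep(1 / a_u, each = 3), 3 * n) + tau
    P <- .solve_screen(Q, 1)
    tens_u <- .partition_applequist(P, n)
    alpha_u[, k] <- vapply(tens_u, function(t) sum(diag(t)) / 3, numeric(1))
    if (k == n_imfreqs) tensors <- tens_u
  }
  c6 <- apply(alpha_u, 1, function(a) {
    if (any(a < 0)) NA_real_ else casimir_polder_c6(a, grid)
  })
  # tensors may be asymmetric; eigenvalues can in principle be complex
  ev <- t(vapply(tensors, function(t) sort(Re(eigen(t)$values)), numeric(3)))
  out <- dplyr::mutate(atoms,
    alpha_ts = alpha_ts,
    alpha_scs = alpha_u[, n_imfreqs],
    c6_atom = c6,
    lambda1 = ev[, 1], lambda2 = ev[, 2], lambda3 = ev[, 3]
  )
  structure(list(atoms = out, tensors = tensors, alpha_u = alpha_u,
                 grid = grid, cutoff = cutoff, method = "tsscs"),
            class = "tsscs_result")
}

#' @export
print.tsscs_result <- function(x, ...) {
  cat(sprintf("<tsscs_result: %d atoms>\n", nrow(x$atoms)))
  print(dplyr::select(x$atoms, "element", "alpha_ts", "alpha_scs", "c6_atom"))
  invisible(x)
}
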