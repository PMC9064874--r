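# The staged MCLF pipeline: unscreened m-scaled properties -> non-directional
# screening + conduction bound -> static directional screening + anisotropy
# correction -> fluctuating directional screening + Casimir-Polder C6 ->
# QDO block (C8, C9, C10).

#' Compute MCLF atom-in-material polarizabilities and dispersion coefficients
#'
#' Runs the full staged pipeline on a table of partitioned-atom descriptors:
#'
#' 1. unscreened polarizability, characteristic frequency and conduction
#'    upper bound per atom (m-scaled isolated-atom laws);
#' 2. non-directional screening of \eqn{\alpha(u)} at every
#'    imaginary-frequency point, with the upper bound applied through the
#'    smooth minimum; the static point is \eqn{\alpha^{force\mbox{-}field}};
#' 3. static directional screening (traceless Gaussian dipole tensors,
#'    updating widths, incremental coupling) followed by the anisotropy
#'    correction, giving the AIM static polarizability tensors;
#' 4. fluctuating directional screening at every frequency point with the
#'    multibody alignment attenuation, giving \eqn{\alpha^{screened}(u)},
#'    \eqn{\alpha^{low\_freq}} and, via Casimir-Polder integration, the
#'    per-atom C6;
#' 5. QDO parameterization from \eqn{(\alpha^{force\mbox{-}field},
#'    C_6^{non\mbox{-}dir}, C_8)} and the higher-order coefficients.
#'
#' @param atoms Data frame of AIM descriptors (see [aim_atoms()] for the
#'   column contract). Positions in bohr, atomic units throughout.
#' @param cell A [unit_cell()]; defaults to a non-periodic (molecular)
#'   system.
#' @param reference Free-atom reference table ([read_reference_table()]).
#' @param config Parameters from [mclf_config()].
#' @param membership Optional molecule label per atom (defaults to one
#'   molecule).
#' @return An object of class `mclf_result`; see [tidy.mclf_result()] and
#'   [glance.mclf_result()] for tabular views. Components include the
#'   per-atom tibble (`atoms`, with `alpha_ff`, `alpha_low_freq`,
#'   `alpha_static_iso`, eigenvalues, `c6_atom`, `c6_nondir`, `c8`, `c9`,
#'   `c10`, QDO parameters), the corrected static tensors (`tensors_static`),
#'   the frequency-resolved series (`alpha_nondir`, `alpha_screened`), and
#'   the pair matrices (`c6_pair`, `c8_pair`, `c10_pair`).
#' @examples
#' atoms <- make_toy_system("dimer", element = "Ar", separation = 7)$atoms
#' res <- mclf(atoms)
#' tidy(res)
#' @export
mclf <- function(atoms, cell = unit_cell(),
                 reference = read_reference_table(),
                 config = mclf_config(), membership = NULL) {
  atoms <- aim_atoms(atoms)
  n <- nrow(atoms)
  if (is.null(membership)) membership <- rep(1L, n)
  state <- unscreened_state(atoms, reference, config$conduction_c)
  if (any(is.na(atoms$rdamp) | atoms$rdamp <= 0)) {
    stop("missing-field: fluctuating screening requires positive damping radii",
         call. = FALSE)
  }
  grid <- build_imfreq_grid(config$n_imfreqs, config$omega_scale)
  nu <- config$n_imfreqs
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  disp <- .system_displacements(pos, cell, config$cutoff)

  # stage 1/2: non-directional screening + conduction bound, per frequency
  alpha_raw <- matrix(0, n, nu)
  for (k in seq_len(nu)) {
    a0 <- dynamic_alpha(state$alpha_unscreened, state$wp, grid$omega[k])
    alpha_raw[, k] <- .screen_nondir(a0, disp, config)
  }
  alpha_nondir <- apply_upper_bound_per_frequency(
    alpha_raw, state$alpha_upper_bound, config$smoothmin_steepness)
  alpha_ff <- alpha_nondir[, nu]

  # stage 3: static directional screening + anisotropy correction
  tensors0 <- lapply(alpha_ff, function(a) diag(a, 3))
  tensors_raw <- .screen_directional(tensors0, alpha_ff, disp, config)
  tensors_static <- lapply(tensors_raw, anisotropy_correction,
                           mixing = config$mixing_cf)

  # stage 4: fluctuating directional screening per frequency
  mbsp_len <- config$mbsp * outer(atoms$rdamp, atoms$rdamp, `+`)
  alpha_screened <- matrix(0, n, nu)
  for (k in seq_len(nu)) {
    a0 <- alpha_nondir[, k]
    tk <- .screen_directional(lapply(a0, function(a) diag(a, 3)), a0, disp,
                              config, mbsp_len = mbsp_len)
    alpha_screened[, k] <- vapply(tk, function(t) sum(diag(t)) / 3, numeric(1))
  }
  alpha_lf <- alpha_screened[, nu]
  c6_atom <- apply(alpha_screened, 1, casimir_polder_c6, grid = grid)
  c6_nondir <- apply(alpha_nondir, 1, casimir_polder_c6, grid = grid)

  # stage 5: C8 correlation and QDO block
  c8 <- c8_atom(c6_nondir, atoms$r3, atoms$r4)
  qdo <- qdo_parameterize(alpha_ff, c6_nondir, c8)
  qdo$alpha_ff <- alpha_ff
  ho <- higher_order_coefficients(qdo, pairs = TRUE)

  c6_pair <- pair_c6_matrix(c6_atom, alpha_lf)
  ev <- lapply(tensors_static, .tensor_eigen)
  out_atoms <- dplyr::mutate(state,
    alpha_ff = alpha_ff,
    alpha_low_freq = alpha_lf,
    alpha_static_iso = vapply(tensors_static, function(t) sum(diag(t)) / 3,
                              numeric(1)),
    lambda1 = vapply(ev, function(e) e$values[1], numeric(1)),
    lambda2 = vapply(ev, function(e) e$values[2], numeric(1)),
    lambda3 = vapply(ev, function(e) e$values[3], numeric(1)),
    c6_atom = c6_atom,
    c6_nondir = c6_nondir,
    c8 = c8,
    c9 = ho$atom$c9,
    c10 = ho$atom$c10,
    wp_qdo = qdo$wp_qdo,
    m_qdo = qdo$m_qdo,
    q_qdo = qdo$q_qdo,
    molecule = membership
  )
  structure(list(
    atoms = out_atoms,
    tensors_static = tensors_static,
    tensors_static_raw = tensors_raw,
    eigenvectors = lapply(ev, `[[`, "vectors"),
    alpha_nondir = alpha_nondir,
    alpha_screened = alpha_screened,
    c6_pair = c6_pair,
    c8_pair = ho$c8_ab,
    c10_pair = ho$c10_ab,
    grid = grid,
    cell = cell,
    config = config,
    method = "mclf"
  ), class = "mclf_result")
}

#' @export
print.mclf_result <- function(x, ...) {
  cat(sprintf("<mclf_result: %d atoms, %d imfreq points, cutoff %g bohr>\n",
              nrow(x$atoms), x$config$n_imfreqs, x$config$cutoff))
  print(dplyr::select(x$atoms, "element", "alpha_ff", "alpha_static_iso",
                      "alpha_low_freq", "c6_atom"))
  invisible(x)
}

#' Molecular static polarizability tensor of an MCLF result
#'
#' Sum of the per-atom static tensors; the per-atom partition redistributes
#' but never changes this total (before the anisotropy correction, which
#' preserves the trace but redistributes anisotropy per atom).
#'
#' @param result An `mclf_result`.
#' @param corrected Use anisotropy-corrected tensors (default TRUE).
#' @return Symmetric 3x3 matrix (bohr^3).
#' @export
molecular_polarizability <- function(result, corrected = TRUE) {
  tl <- if (corrected) result$tensors_static else result$tensors_static_raw
  Reduce(`+`, tl)
}
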