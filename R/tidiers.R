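# broom-style tidiers for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-atom view of an MCLF result
#'
#' @param x An `mclf_result`.
#' @param ... Unused.
#' @return A tibble with one row per atom: element, the three polarizability
#'   types, static-tensor eigenvalues, and the dispersion coefficients.
#' @method tidy mclf_result
#' @export
tidy.mclf_result <- function(x, ...) {
  dplyr::select(x$atoms, "element", "x", "y", "z",
                "alpha_unscreened", "alpha_ff", "alpha_static_iso",
                "alpha_low_freq",
                "lambda1", "lambda2", "lambda3",
                "c6_atom", "c6_nondir", "c8", "c9", "c10",
                "wp_qdo", "m_qdo", "q_qdo")
}

#' One-row summary of an MCLF result
#'
#' @param x An `mclf_result`.
#' @param ... Unused.
#' @return A tibble with the atom count, molecular static isotropic
#'   polarizability, summed force-field polarizability, and the molecular
#'   self-C6 (sum over all atom pairs of the mixed coefficients).
#' @method glance mclf_result
#' @export
glance.mclf_result <- function(x, ...) {
  mol <- molecular_polarizability(x)
  tibble::tibble(
    n_atoms = nrow(x$atoms),
    alpha_molecular_iso = sum(diag(mol)) / 3,
    alpha_ff_total = sum(x$atoms$alpha_ff),
    c6_molecular = sum(x$c6_pair)
  )
}

#' @rdname tidy.mclf_result
#' @method tidy tsscs_result
#' @export
tidy.tsscs_result <- function(x, ...) {
  dplyr::select(x$atoms, "element", "x", "y", "z", "alpha_ts", "alpha_scs",
                "lambda1", "lambda2", "lambda3", "c6_atom")
}

#' @rdname glance.mclf_result
#' @method glance tsscs_result
#' @export
glance.tsscs_result <- function(x, ...) {
  mol <- Reduce(`+`, x$tensors)
  tibble::tibble(
    n_atoms = nrow(x$atoms),
    alpha_molecular_iso = sum(diag(mol)) / 3,
    alpha_scs_total = sum(x$atoms$alpha_scs)
  )
}
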