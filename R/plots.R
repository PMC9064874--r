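# ggplot2 views of result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the per-atom polarizability types of an MCLF result
#'
#' Bar chart comparing, atom by atom, the unscreened, force-field, static
#' isotropic and low-frequency polarizabilities. The spread between the
#' types visualizes how strongly each atom is screened and how much
#' directional order contributes.
#'
#' @param object An `mclf_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mclf_result
#' @export
autoplot.mclf_result <- function(object, ...) {
  at <- dplyr::mutate(object$atoms,
                      atom = paste0(.data$element, seq_len(nrow(object$atoms))))
  long <- tidyr::pivot_longer(
    dplyr::select(at, "atom", "alpha_unscreened", "alpha_ff",
                  "alpha_static_iso", "alpha_low_freq"),
    -"atom", names_to = "type", values_to = "alpha")
  long$type <- factor(long$type,
                      levels = c("alpha_unscreened", "alpha_ff",
                                 "alpha_static_iso", "alpha_low_freq"),
                      labels = c("unscreened", "force-field", "static (iso)",
                                 "low-freq"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$atom, y = .data$alpha,
                                     fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(alpha ~ (bohr^3)),
                  fill = "polarizability") +
    ggplot2::theme_minimal()
}

#' Plot the frequency dependence of the screened polarizabilities
#'
#' Lines of \eqn{\alpha^{screened}_A(u)} against the imaginary-frequency
#' magnitude for every atom (log x past the static point).
#'
#' @param result An `mclf_result`.
#' @return A ggplot object.
#' @export
plot_alpha_imfreq <- function(result) {
  n <- nrow(result$atoms)
  df <- tidyr::expand_grid(atom = seq_len(n), u = result$grid$u)
  df$omega <- result$grid$omega[df$u]
  df$alpha <- result$alpha_screened[cbind(df$atom, df$u)]
  df$atom <- paste0(result$atoms$element[df$atom], df$atom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, y = .data$alpha,
                                   colour = .data$atom)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(omega ~ (hartree)),
                  y = expression(alpha(i * omega) ~ (bohr^3)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
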