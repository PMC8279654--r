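#' Plot a PMF profile
#'
#' Free energy versus reaction coordinate, with the ground-truth landscape
#' overlaid when supplied. Cosmetic: the CSV/JSON outputs are the contract.
#'
#' @param x a `pmf_profile`.
#' @param truth optional [true_potential_params()] to overlay.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pmf_profile <- function(x, truth = NULL, ...) {
  ok <- x$defined
  graphics::plot(x$centers[ok], x$values[ok], type = "b", pch = 16,
                 cex = 0.6, xlab = "r (nm)",
                 ylab = expression(Delta * G ~ "(kJ/mol)"), ...)
  if (!is.null(truth)) {
    grid <- seq(min(x$centers[ok]), max(x$centers[ok]), length.out = 400)
    g <- true_pmf(grid, truth)
    if (!is.null(x$reference)) g <- g - true_pmf(x$reference, truth)
    graphics::lines(grid, g, col = "grey50", lty = 2)
    graphics::legend("topleft", c("WHAM", "ground truth"),
                     lty = c(1, 2), pch = c(16, NA),
                     col = c("black", "grey50"), bty = "n")
  }
  invisible(x)
}

#' Bar plot of a decomposition record
#'
#' Free energy, enthalpy, entropy term and the three interaction
#' components at the surface minimum.
#'
#' @param x a `decomposition_record`.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.decomposition_record <- function(x, ...) {
  vals <- c(dG = x$dG, dH = x$dH, `-TdS` = x$minus_TdS,
            `dE ww` = x$dE_ww, `dE aa-w` = x$dE_aaw,
            `dE aa-aa` = x$dE_aaaa)
  graphics::barplot(vals, ylab = "kJ/mol",
                    main = sprintf("decomposition at r = %.2f nm", x$r),
                    ...)
  graphics::abline(h = 0)
  invisible(x)
}
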