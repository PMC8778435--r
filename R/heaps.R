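# Heap's-law openness fit: y = A x^B + C on the mean pan-genome
# accumulation curve. An exponent strictly between 0 and 1 marks an open
# pangenome (the pan size keeps growing as genomes are added).

#' Fit the Heap's-law power model to a pan-genome accumulation curve
#'
#' Nonlinear least squares on `y = A * x^B + C`, initialised at
#' `A = y[1], B = 0.5, C = 0`. The pangenome is called open iff
#' `0 < B < 1`. A constant curve is a degenerate case (the power-law
#' Jacobian is singular), returned in closed form as `A = 0, B = 0,
#' C = mean(y)`, closed. Non-convergence is flagged, not thrown.
#'
#' @param curve tibble with columns `x` (number of genomes) and `y`
#'   (pan-genome size); at least 4 distinct x values
#' @return a `heaps_fit` object: list with `A`, `B`, `C`, `open`,
#'   `converged`, `rss`, and the input `curve`
#' @export
#' @examples
#' curve <- tibble::tibble(x = 1:10, y = 5 * (1:10)^0.5 + 2)
#' fit_heaps(curve)
fit_heaps <- function(curve) {
  abort_if(!all(c("x", "y") %in% names(curve)),
           "`curve` needs columns `x` and `y`")
  abort_if(length(unique(curve$x)) < 4, "need at least 4 x-points")
  x <- curve$x
  y <- curve$y
  if (stats::var(y) == 0) {
    return(new_heaps_fit(0, 0, mean(y), converged = TRUE, rss = 0,
                         curve = curve))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * x^B + C,
      start = list(A = y[1], B = 0.5, C = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_heaps_fit(NA_real_, NA_real_, NA_real_, converged = FALSE,
                         rss = NA_real_, curve = curve))
  }
  cf <- stats::coef(fit)
  new_heaps_fit(cf[["A"]], cf[["B"]], cf[["C"]], converged = TRUE,
                rss = sum(stats::residuals(fit)^2), curve = curve)
}

new_heaps_fit <- function(A, B, C, converged, rss, curve) {
  structure(list(A = A, B = B, C = C,
                 open = isTRUE(converged) && !is.na(B) && B > 0 && B < 1,
                 converged = converged, rss = rss, curve = curve),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<heaps_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("<heaps_fit> y = %.4g * x^%.4g + %.4g  (%s pangenome)\n",
              x$A, x$B, x$C, if (x$open) "open" else "closed"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Heap's-law fit
#' @param x a `heaps_fit`
#' @param ... unused
#' @return tibble of parameter estimates
#' @method tidy heaps_fit
#' @export
tidy.heaps_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C"),
                 estimate = c(x$A, x$B, x$C))
}

#' One-row summary of a Heap's-law fit
#' @param x a `heaps_fit`
#' @param ... unused
#' @return tibble with `open`, `converged`, `rss`, `exponent`
#' @method glance heaps_fit
#' @export
glance.heaps_fit <- function(x, ...) {
  tibble::tibble(open = x$open, converged = x$converged,
                 rss = x$rss, exponent = x$B)
}

#' Plot an accumulation curve with its Heap's-law fit
#' @param object a `heaps_fit`
#' @param ... unused
#' @return a ggplot
#' @method autoplot heaps_fit
#' @export
autoplot.heaps_fit <- function(object, ...) {
  curve <- object$curve
  pred <- tibble::tibble(
    x = seq(min(curve$x), max(curve$x), length.out = 100))
  pred$y <- object$A * pred$x^object$B + object$C
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::labs(x = "genomes sampled", y = "pan-genome size",
                  subtitle = sprintf("y = %.3g x^%.3g + %.3g (%s)",
                                     object$A, object$B, object$C,
                                     if (object$open) "open" else "closed")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
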