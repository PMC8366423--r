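#' @export
print.nr_parameters <- function(x, ...) {
  cat("<parameter set>\n")
  df <- data.frame(value = x$values, lower = x$lower, upper = x$upper,
                   fixed = x$fixed, row.names = x$names)
  print(df, ...)
  invisible(x)
}

#' @export
print.fisher_analysis <- function(x, ...) {
  cat(sprintf("Fisher information analysis: %d parameters, %d bins\n",
              length(x$parameters$values), nrow(x$jacobian)))
  print(summary(x)$table, ...)
  invisible(x)
}

#' @export
summary.fisher_analysis <- function(object, ...) {
  eps <- if (is.null(object$uncertainties)) rep(NA_real_,
                                                length(object$parameters$values))
         else object$uncertainties
  tab <- data.frame(value = object$parameters$values,
                    uncertainty = eps,
                    fisher_info = diag(object$fisher),
                    row.names = object$parameters$names)
  out <- list(table = tab, condition_number = object$condition_number,
              n_bins = nrow(object$jacobian))
  class(out) <- "summary.fisher_analysis"
  out
}

#' @export
print.summary.fisher_analysis <- function(x, ...) {
  cat(sprintf("Fisher information analysis over %d bins\n", x$n_bins))
  print(x$table, ...)
  cat(sprintf("condition number of g: %.3g\n", x$condition_number))
  invisible(x)
}

#' @export
coef.fisher_analysis <- function(object, ...) {
  stats::setNames(object$parameters$values, object$parameters$names)
}

#' @export
vcov.fisher_analysis <- function(object, ...) {
  if (is.null(object$covariance))
    stop("information matrix is singular (condition number ",
         format(object$condition_number, digits = 3),
         "); no covariance available")
  object$covariance
}

#' Confidence intervals from the inverse Fisher information
#'
#' Normal-approximation intervals `value +/- z * epsilon`.
#'
#' @param object A `"fisher_analysis"`.
#' @param parm Parameters to include (names or indices); default all.
#' @param level Confidence level. Default 0.95.
#' @param ... Unused.
#' @export
confint.fisher_analysis <- function(object, parm = NULL, level = 0.95,
                                    ...) {
  eps <- parameter_uncertainties(object$fisher)
  v <- object$parameters$values
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(v - z * eps, v + z * eps)
  dimnames(ci) <- list(object$parameters$names,
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Plot confidence ellipses for a parameter pair
#'
#' @param x A `"fisher_analysis"`.
#' @param i,j Parameter indices or names. Defaults to the first two.
#' @param k Vector of ellipse sizes in standard deviations. Default 1:3.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fisher_analysis <- function(x, i = 1, j = 2, k = 1:3, ...) {
  ells <- lapply(k, function(kk) confidence_ellipse(x, i, j, k = kk))
  xs <- unlist(lapply(ells, function(e) e$boundary[, 1]))
  ys <- unlist(lapply(ells, function(e) e$boundary[, 2]))
  graphics::plot(range(xs), range(ys), type = "n",
                 xlab = ells[[1]]$names[1], ylab = ells[[1]]$names[2], ...)
  for (e in ells) graphics::lines(e$boundary[, 1], e$boundary[, 2])
  graphics::points(ells[[1]]$centre[1], ells[[1]]$centre[2], pch = 3)
  invisible(x)
}

#' @export
print.nr_ellipse <- function(x, ...) {
  cat(sprintf("<confidence ellipse> %s vs %s, k = %g SD\n",
              x$names[1], x$names[2], x$k))
  cat(sprintf("  centre (%.6g, %.6g); semi-axes %.4g, %.4g\n",
              x$centre[1], x$centre[2],
              sqrt(sum(x$axes[, 1]^2)), sqrt(sum(x$axes[, 2]^2))))
  invisible(x)
}

#' @export
print.nr_fit <- function(x, ...) {
  cat(sprintf("<model fit> objective %.6g after %d generations%s\n",
              x$objective, x$generations,
              if (x$converged) "" else " (not converged)"))
  print(x$parameters)
  invisible(x)
}

#' @export
coef.nr_fit <- function(object, ...) {
  stats::setNames(object$parameters$values, object$parameters$names)
}
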