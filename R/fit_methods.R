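# S3 methods for t1_fit objects.

#' @export
print.t1_fit <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Model-based %s T1 fit (%s, %s coupling, %dD regularization)\n",
              toupper(x$model$type), toupper(x$config$reg),
              x$config$coupling, x$config$reg_dim))
  cat(sprintf("  grid %d x %d x %d, %d coils, %d encodings, %d GN steps (%s)\n",
              d[1], d[2], d[3], dim(x$coils)[4], x$model$n_enc,
              nrow(x$diagnostics), x$status))
  t1 <- x$T1[x$T1 > 0]
  if (length(t1))
    cat(sprintf("  T1 over non-zero voxels: median %.0f ms, IQR %.0f-%.0f ms\n",
                stats::median(t1), stats::quantile(t1, 0.25),
                stats::quantile(t1, 0.75)))
  cat(sprintf("  final lambda = %.3g, gamma = %g, primal energy = %.6g\n",
              tail(x$diagnostics$lambda, 1), tail(x$diagnostics$gamma, 1),
              tail(x$diagnostics$energy, 1)))
  invisible(x)
}

#' Summarize a T1 fit
#'
#' Prints the Gauss-Newton diagnostics table and, when an ROI label volume
#' is attached, per-region T1 statistics.
#'
#' @param object a `t1_fit`.
#' @param ... unused.
#' @export
summary.t1_fit <- function(object, ...) {
  out <- list(fit = object, diagnostics = object$diagnostics,
              roi = if (!is.null(object$labels))
                roi_stats(object$T1, object$labels) else NULL)
  class(out) <- "summary.t1_fit"
  out
}

#' @export
print.summary.t1_fit <- function(x, ...) {
  print(x$fit)
  cat("\nGauss-Newton diagnostics:\n")
  print(x$diagnostics, row.names = FALSE, digits = 4)
  if (!is.null(x$roi)) {
    cat("\nROI T1 statistics (ms):\n")
    print(x$roi, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Extract the fitted parameter maps
#'
#' @param object a `t1_fit`.
#' @param ... unused.
#' @return list with `M0` (complex volume, input-data units) and `T1`
#'   (ms).
#' @export
coef.t1_fit <- function(object, ...) list(M0 = object$M0, T1 = object$T1)

#' Forward-project the fitted maps to k-space
#'
#' Applies the nonlinear forward operator at the fitted maps, giving the
#' model-predicted multi-coil k-space data in the units of the input data.
#'
#' @param object a `t1_fit`.
#' @param ... unused.
#' @return complex k-space array shaped like the input data.
#' @export
predict.t1_fit <- function(object, ...) {
  apply_forward_A(list(M0 = object$M0, T1 = object$T1 + 0i),
                  object$model, object$coils, object$traj)
}

#' k-space residuals of a T1 fit
#'
#' @param object a `t1_fit` reconstructed with `keep_data = TRUE`.
#' @param ... unused.
#' @return complex array `data - predict(object)`.
#' @export
residuals.t1_fit <- function(object, ...) {
  if (is.null(object$data))
    stop("fit was run with keep_data = FALSE; residuals unavailable")
  object$data - predict(object)
}

#' @export
fitted.t1_fit <- function(object, ...) predict(object, ...)

#' Display fitted parameter maps
#'
#' Shows the T1 map (and optionally |M0|) of one slice with base graphics.
#'
#' @param x a `t1_fit`.
#' @param slice slice index (default: central slice).
#' @param what `"T1"`, `"M0"` or `"both"`.
#' @param zlim_t1 display range for T1 in ms.
#' @param ... passed to [graphics::image()].
#' @export
plot.t1_fit <- function(x, slice = ceiling(x$dims[3] / 2),
                        what = c("T1", "M0", "both"),
                        zlim_t1 = c(0, 3000), ...) {
  what <- match.arg(what)
  show1 <- function(img, main, zlim = NULL) {
    graphics::image(img, asp = 1, axes = FALSE, useRaster = TRUE,
                    col = grDevices::hcl.colors(128, "viridis"),
                    zlim = zlim, ...)
    graphics::title(main)
  }
  if (what == "both") {
    op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op))
  }
  if (what %in% c("T1", "both"))
    show1(pmin(pmax(x$T1[, , slice], zlim_t1[1]), zlim_t1[2]),
          sprintf("T1 [ms], slice %d", slice), zlim_t1)
  if (what %in% c("M0", "both"))
    show1(Mod(x$M0[, , slice]), sprintf("|M0|, slice %d", slice))
  invisible(x)
}
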