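# Methods for the fitted "kdp" object.

#' @export
print.kdp <- function(x, ...) {
  k <- seq_size(x$sequence)
  cat("k-dominant point extraction\n")
  cat(sprintf("  points: %d   dominant points: %d\n", nrow(x$points), k))
  cat(sprintf("  measure: %s   confidence: %s   eps: %g\n",
              x$control$measure, x$control$confidence, x$control$eps))
  cat(sprintf("  insertions: %d   closures: %d   reductions: %d (depth %d)\n",
              x$trace$insertions, x$trace$closures, x$trace$reductions,
              x$trace$max_depth))
  invisible(x)
}

#' @export
summary.kdp <- function(object, ...) {
  r <- residuals(object)
  structure(list(n_points = nrow(object$points),
                 n_vertices = seq_size(object$sequence),
                 n_open = sum(!object$sequence$closed),
                 perimeter = confidence_length(object$sequence),
                 coverage = confidence_count(object$sequence, object$points,
                                             object$control$eps) /
                   nrow(object$points),
                 residual_quantiles = stats::quantile(r, c(.5, .9, .99, 1)),
                 trace = object$trace),
            class = "summary.kdp")
}

#' @export
print.summary.kdp <- function(x, ...) {
  cat(sprintf("Dominant points: %d (open pairs: %d)\n", x$n_vertices, x$n_open))
  cat(sprintf("Input points: %d   polyline length: %.2f px   coverage: %.1f%%\n",
              x$n_points, x$perimeter, 100 * x$coverage))
  cat("Residual sum-distance excess (px):\n")
  print(round(x$residual_quantiles, 3))
  cat(sprintf("Insertions %d, closures %d, reductions %d, recursion depth %d\n",
              x$trace$insertions, x$trace$closures, x$trace$reductions,
              x$trace$max_depth))
  invisible(x)
}

#' @export
coef.kdp <- function(object, ...) object$sequence$vertices

#' @export
as.data.frame.kdp <- function(x, ...) as.data.frame(x$sequence)

#' Residual approximation error of a kdp fit
#'
#' For every input point, the excess of its point-line-segment sum distance
#' over the segment length, minimized over the polyline edges of the fitted
#' sequence: 0 for a point lying exactly on an edge.
#'
#' @param object a fitted `"kdp"` object.
#' @param ... unused.
#' @return numeric vector, one value per input point.
#' @export
residuals.kdp <- function(object, ...) {
  seq <- object$sequence
  pr <- seq_pairs(seq)
  P <- object$points
  r <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(pr))) {
    a <- seq$vertices[pr[i, 1L], ]
    b <- seq$vertices[pr[i, 2L], ]
    r <- pmin(r, .seg_sum_dist(P, a, b) - .d(a, b))
  }
  r
}

#' Plot a kdp fit
#'
#' Draws the input points and the fitted dominant-point polygon; open pairs
#' are dashed, closed pairs solid.
#'
#' @param x a fitted `"kdp"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kdp <- function(x, ...) {
  P <- x$points
  graphics::plot(P[, 1L], -P[, 2L], pch = ".", col = "grey40", asp = 1,
                 xlab = "x", ylab = "-y (image row)", ...)
  seq <- x$sequence
  pr <- seq_pairs(seq)
  for (i in seq_len(nrow(pr))) {
    a <- seq$vertices[pr[i, 1L], ]
    b <- seq$vertices[pr[i, 2L], ]
    graphics::segments(a[1L], -a[2L], b[1L], -b[2L], col = "red3",
                       lty = if (seq$closed[i]) 1 else 2, lwd = 2)
  }
  graphics::points(seq$vertices[, 1L], -seq$vertices[, 2L], pch = 19,
                   col = "red3")
  graphics::text(seq$vertices[, 1L], -seq$vertices[, 2L],
                 labels = seq_len(seq_size(seq)), pos = 3, cex = .8)
  invisible(x)
}
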