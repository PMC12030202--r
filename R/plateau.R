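#' Fit the NNI to relative-yield linear-plateau model
#'
#' Fits the piecewise "linear platform" response
#' \deqn{RY = a \cdot NNI - b \quad (NNI < NNI_{max}), \qquad
#'       RY = c \quad (NNI \ge NNI_{max})}
#' by grid search over candidate breakpoints.  Candidates are the observed
#' NNI values; for each candidate, points strictly below it are fitted by
#' ordinary least squares and points at or above it by their mean (the
#' plateau), and the candidate minimising the total SSE wins (ties break
#' to the smallest breakpoint).  With `continuous = TRUE` the plateau is
#' tied to the line, `c = a*NNI_max - b`; the default leaves it free (the
#' two published parameterisations this model reproduces are discontinuous
#' at the breakpoint).
#'
#' @param nni NNI values (> 0).
#' @param ry relative yields.
#' @param continuous logical; force continuity at the breakpoint.
#' @return object of class `linear_plateau` with `slope` (a), `intercept`
#'   (b, subtracted), `breakpoint`, `plateau` (c), `sse`, `r2`, `n`.
#' @examples
#' nni <- seq(0.5, 1.3, by = 0.01)
#' ry <- ifelse(nni < 1.01, 1.088 * nni - 0.08, 1.01)
#' coef(fit_linear_plateau(nni, ry))
#' @export
fit_linear_plateau <- function(nni, ry, continuous = FALSE) {
  ok <- is.finite(nni) & is.finite(ry)
  nni <- nni[ok]; ry <- ry[ok]
  if (length(nni) < 5) stop("need at least 5 points")
  if (stats::sd(ry) == 0)
    stop("all relative yields identical: the linear segment is undefined")
  cand <- sort(unique(nni))
  best <- NULL
  for (bp in cand) {
    below <- nni < bp
    if (sum(below) < 2 || sum(!below) < 2) next
    if (length(unique(nni[below])) < 2) next
    fit <- stats::lm(ry[below] ~ nni[below])
    a <- stats::coef(fit)[[2]]
    if (a <= 0) next                 # the model requires a rising segment
    b <- -stats::coef(fit)[[1]]
    cc <- if (continuous) a * bp - b else mean(ry[!below])
    sse <- sum(stats::resid(fit)^2) + sum((ry[!below] - cc)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(slope = a, intercept = b, breakpoint = bp,
                   plateau = cc, sse = sse)
  }
  if (is.null(best))
    stop("no admissible breakpoint: candidates leave no points in both ",
         "regimes or no rising (positive-slope) segment")
  sst <- sum((ry - mean(ry))^2)
  structure(c(best, list(r2 = if (sst > 0) 1 - best$sse / sst else 1,
                         n = length(nni),
                         data = list(data.frame(nni = nni, ry = ry)),
                         continuous = continuous)),
            class = "linear_plateau")
}

#' @export
print.linear_plateau <- function(x, ...) {
  cat("Linear-plateau NNI to relative-yield model\n")
  cat(sprintf("  RY = %.4g * NNI - %.4g   (NNI < %.4g)\n",
              x$slope, x$intercept, x$breakpoint))
  cat(sprintf("  RY = %.4g               (NNI >= %.4g)\n",
              x$plateau, x$breakpoint))
  cat(sprintf("  n = %d, SSE = %.4g, R2 = %.3f\n", x$n, x$sse, x$r2))
  invisible(x)
}

#' @export
coef.linear_plateau <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept,
    breakpoint = object$breakpoint, plateau = object$plateau)

#' Predict relative yield from NNI
#'
#' @param nni NNI values (> 0).
#' @param model a `linear_plateau` fit (or list with `slope`,
#'   `intercept`, `breakpoint`, `plateau`).
#' @return predicted relative yield; non-decreasing in NNI for positive
#'   slope.
#' @examples
#' m <- list(slope = 1.088, intercept = 0.08, breakpoint = 1.01,
#'           plateau = 1.01)
#' predict_relative_yield(c(0.5, 1.2), m)  # 0.464, 1.01
#' @export
predict_relative_yield <- function(nni, model) {
  if (any(!is.finite(nni)) || any(nni <= 0)) stop("'nni' must be positive")
  ifelse(nni < model$breakpoint,
         model$slope * nni - model$intercept, model$plateau)
}

#' @param object,newdata,... standard predict arguments; `newdata` is a
#'   numeric NNI vector or data.frame with an `nni` column.
#' @rdname predict_relative_yield
#' @export
predict.linear_plateau <- function(object, newdata, ...) {
  nni <- if (is.data.frame(newdata)) newdata$nni else newdata
  predict_relative_yield(nni, object)
}

#' @export
plot.linear_plateau <- function(x, ...) {
  d <- x$data
  graphics::plot(d$nni, d$ry, pch = 19, xlab = "NNI",
                 ylab = "Relative yield", ...)
  grid <- seq(min(d$nni), max(d$nni), length.out = 200)
  graphics::lines(grid, predict_relative_yield(grid, x), col = 2, lwd = 2)
  graphics::abline(v = x$breakpoint, lty = 3)
  invisible(x)
}
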