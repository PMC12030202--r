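#' Non-dimensionalise series for gray relational analysis
#'
#' Divides each series by its own mean (mean-normalisation, the common
#' choice in gray relational analysis); `method = "initial"` divides by the
#' first element instead, `"none"` leaves series untouched.  Series whose
#' divisor is zero are rejected.
#'
#' @param x numeric vector or matrix/data.frame of column series.
#' @param method `"mean"`, `"initial"` or `"none"`.
#' @return object of the same shape, normalised.
#' @export
normalize_series <- function(x, method = c("mean", "initial", "none")) {
  method <- match.arg(method)
  norm1 <- function(v) {
    d <- switch(method, mean = mean(v), initial = v[1], none = 1)
    if (method != "none" && (!is.finite(d) || d == 0))
      stop("cannot normalise a series with zero ",
           if (method == "mean") "mean" else "initial value")
    v / d
  }
  if (is.null(dim(x))) norm1(x) else apply(x, 2, norm1)
}

#' Gray relational analysis (Deng)
#'
#' Computes gray relational coefficients and degrees of a set of
#' comparison series against a reference series.  With normalised
#' reference \eqn{x_0(k)} and comparisons \eqn{x_i(k)}, absolute
#' differences \eqn{\Delta_{0i}(k) = |x_0(k) - x_i(k)|}, and global
#' extrema \eqn{\Delta_{min}, \Delta_{max}} taken jointly over all
#' comparison series and all positions, the coefficient is
#' \deqn{\gamma_{0i}(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                             {\Delta_{0i}(k) + \rho\,\Delta_{max}}}
#' and the relational degree \eqn{\gamma_i} is the arithmetic mean of the
#' coefficients.  If \eqn{\Delta_{max} = 0} (every comparison identical to
#' the reference) every coefficient is defined as 1.
#'
#' @param reference numeric reference series (here: NNI).
#' @param comparisons matrix or data.frame of comparison series in columns
#'   (here: vegetation indices), same length as `reference`.
#' @param rho resolution coefficient in [0, 1]; 0.5 by convention.
#' @param normalize non-dimensionalisation method, see
#'   [normalize_series()].
#' @return object of class `gra`: `coefficients` (positions x series),
#'   `degrees` (named, sorted as given), `rank` (descending by degree),
#'   `delta_min`, `delta_max`, `rho`, `normalize`.
#' @examples
#' g <- gra(c(1, 2, 3), cbind(A = c(1, 2, 3), B = c(3, 2, 1)),
#'          normalize = "none")
#' g$degrees  # A = 1, B = 5/9
#' @export
gra <- function(reference, comparisons, rho = 0.5,
                normalize = c("mean", "initial", "none")) {
  normalize <- match.arg(normalize)
  comparisons <- as.matrix(comparisons)
  if (is.null(colnames(comparisons)))
    colnames(comparisons) <- paste0("X", seq_len(ncol(comparisons)))
  if (length(reference) != nrow(comparisons))
    stop("'reference' and 'comparisons' must have the same length")
  if (length(reference) < 2) stop("series must have length >= 2")
  if (!is.finite(rho) || rho < 0 || rho > 1)
    stop("'rho' must lie in [0, 1]")
  ref <- normalize_series(reference, normalize)
  cmp <- normalize_series(comparisons, normalize)
  delta <- abs(cmp - ref)
  dmin <- min(delta)
  dmax <- max(delta)
  gam <- if (dmax == 0) array(1, dim(delta), dimnames = dimnames(delta))
         else (dmin + rho * dmax) / (delta + rho * dmax)
  degrees <- colMeans(gam)
  structure(list(coefficients = gam, degrees = degrees,
                 rank = names(sort(degrees, decreasing = TRUE)),
                 delta_min = dmin, delta_max = dmax,
                 rho = rho, normalize = normalize),
            class = "gra")
}

#' @export
print.gra <- function(x, ...) {
  cat(sprintf("Gray relational analysis (rho = %.2f, %s-normalised)\n",
              x$rho, x$normalize))
  ord <- order(x$degrees, decreasing = TRUE)
  print(round(x$degrees[ord], 4))
  invisible(x)
}

#' Relational degree of a coefficient sequence
#'
#' The arithmetic mean of a gray relational coefficient sequence.
#'
#' @param coefficients numeric vector of coefficients in (0, 1].
#' @return scalar degree.
#' @export
relational_degree <- function(coefficients) mean(coefficients)

#' Select vegetation indices by per-stage relational degree
#'
#' An index is selected when its gray relational degree with NNI exceeds
#' `threshold` at every growth stage.  The selection is ranked by mean
#' degree across stages (descending); exact ties keep the canonical
#' column order.
#'
#' @param degrees matrix of relational degrees, stages in rows, indices in
#'   columns.
#' @param threshold selection cut (default 0.7).
#' @return list with `selected` (character, ranked), `mean_degree`
#'   (named, all indices) and `pass` (logical per index).  An empty
#'   selection triggers a warning.
#' @export
rank_and_select <- function(degrees, threshold = 0.7) {
  degrees <- as.matrix(degrees)
  pass <- apply(degrees > threshold, 2, all)
  md <- colMeans(degrees)
  # stable order: descending mean degree, canonical order on ties
  ord <- order(-md[pass], which(pass))
  selected <- colnames(degrees)[pass][ord]
  if (length(selected) == 0)
    warning("no index exceeds the relational-degree threshold in every stage")
  list(selected = selected, mean_degree = md, pass = pass)
}
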