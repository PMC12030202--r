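#' Canonical vegetation-index names
#'
#' The nine indices computed from 5-band (blue 450, green 560, red 650,
#' red-edge 730, NIR 840 nm) canopy reflectance, in their canonical order
#' (used for tie-breaking in ranking).
#' @export
VI_NAMES <- c("ndvi", "nnvi", "rvi", "nri", "rvi_1", "sr",
              "ndre", "psnd_c", "savi")

safe_ratio <- function(num, den) {
  out <- num / den
  out[!is.finite(out)] <- NA_real_
  out
}

#' Compute one vegetation index
#'
#' Formulas (reflectances \eqn{\rho}): NDVI = (NIR-R)/(NIR+R);
#' NNVI = NDVI x NIR; RVI = NIR/R; NRI = (G-R)/(G+R); RVI-1 = NIR/R - 1;
#' SR = NIR/G; PSNDc = (NIR-B)/(NIR+B); SAVI = 1.5(NIR-R)/(NIR+R+0.5).
#' NDRE has two dialects (see `ndre_dialect`): `"as_printed"` repeats the
#' NDVI formula (faithful to the source table, which lists NDRE with the
#' red band), `"red_edge"` uses (NIR-RE)/(NIR+RE).
#'
#' Undefined values (zero denominators) are returned as `NA`, never an
#' error.
#'
#' @param name one of [VI_NAMES].
#' @param bands data.frame with columns `b450`, `g560`, `r650`, `re730`,
#'   `nir840`, reflectance fractions in [0, 1].
#' @param ndre_dialect `"as_printed"` (default) or `"red_edge"`.
#' @return numeric vector of index values.
#' @export
compute_index <- function(name, bands,
                          ndre_dialect = c("as_printed", "red_edge")) {
  name <- match.arg(name, VI_NAMES)
  ndre_dialect <- match.arg(ndre_dialect)
  check_bands(bands)
  nir <- bands$nir840; r <- bands$r650; g <- bands$g560
  b <- bands$b450; re <- bands$re730
  switch(name,
         ndvi = safe_ratio(nir - r, nir + r),
         nnvi = safe_ratio(nir - r, nir + r) * nir,
         rvi = safe_ratio(nir, r),
         nri = safe_ratio(g - r, g + r),
         rvi_1 = safe_ratio(nir, r) - 1,
         sr = safe_ratio(nir, g),
         ndre = if (ndre_dialect == "red_edge")
           safe_ratio(nir - re, nir + re) else safe_ratio(nir - r, nir + r),
         psnd_c = safe_ratio(nir - b, nir + b),
         savi = 1.5 * safe_ratio(nir - r, nir + r + 0.5))
}

check_bands <- function(bands) {
  need <- c("b450", "g560", "r650", "re730", "nir840")
  miss <- setdiff(need, names(bands))
  if (length(miss))
    stop("missing reflectance bands: ", paste(miss, collapse = ", "))
  vals <- unlist(bands[need], use.names = FALSE)
  if (any(vals < 0 | vals > 1, na.rm = TRUE))
    stop("reflectance values must lie in [0, 1]")
  invisible(bands)
}

#' Compute all nine vegetation indices
#'
#' @inheritParams compute_index
#' @return data.frame with one column per index in canonical order.
#' @examples
#' compute_all_indices(data.frame(b450 = 0.3, g560 = 0.3, r650 = 0.3,
#'                                re730 = 0.3, nir840 = 0.3))
#' @export
compute_all_indices <- function(bands,
                                ndre_dialect = c("as_printed", "red_edge")) {
  ndre_dialect <- match.arg(ndre_dialect)
  out <- lapply(VI_NAMES, compute_index, bands = bands,
                ndre_dialect = ndre_dialect)
  names(out) <- VI_NAMES
  as.data.frame(out)
}

#' Mask soil-background records by an NDVI threshold
#'
#' Removes pixel or plot records whose NDVI falls below `threshold`,
#' mimicking the soil-background masking applied to early-stage canopy
#' imagery.
#'
#' @param bands band table (see [compute_index()]).
#' @param threshold NDVI cut in (-1, 1); default 0.3, a common canopy/soil
#'   boundary.
#' @return the kept rows, with attributes `kept_fraction` and `n_removed`.
#'   An empty result triggers a warning, not an error.
#' @export
mask_soil <- function(bands, threshold = 0.3) {
  if (!is.finite(threshold) || threshold < -1 || threshold >= 1)
    stop("'threshold' must lie in [-1, 1)")
  ndvi <- compute_index("ndvi", bands)
  keep <- !is.na(ndvi) & ndvi >= threshold
  out <- bands[keep, , drop = FALSE]
  if (nrow(out) == 0)
    warning("soil mask removed every record")
  attr(out, "kept_fraction") <- mean(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}
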