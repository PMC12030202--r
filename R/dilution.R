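#' Plant nitrogen accumulation from organ weights and concentrations
#'
#' Aboveground N uptake (kg N/ha) as the sum over organs of dry weight
#' times N concentration: `PNA = Lw*Ln + Sw*Sn + Pw*Pn`, with weights in
#' kg/ha and concentrations in % (converted internally to fractions so the
#' result is in kg N/ha).
#'
#' @param leaf_dm,stem_dm,panicle_dm organ dry weights (kg/ha).
#' @param leaf_n,stem_n,panicle_n organ N concentrations (%).
#' @return numeric vector, kg N/ha.
#' @examples
#' plant_n_accumulation(2000, 1.5, 3000, 0.8, 0, 0)  # 54 kg N/ha
#' @export
plant_n_accumulation <- function(leaf_dm, leaf_n, stem_dm, stem_n,
                                 panicle_dm = 0, panicle_n = 0) {
  w <- cbind(leaf_dm, stem_dm, panicle_dm)
  n <- cbind(leaf_n, stem_n, panicle_n)
  if (any(w < 0, na.rm = TRUE)) stop("organ dry weights must be >= 0")
  if (any(n < 0 | n > 10, na.rm = TRUE))
    stop("organ N concentrations must lie in [0, 10] %")
  rowSums(w * n / 100)
}

#' Partition treatments into N-limited and non-N-limited groups
#'
#' Implements the grouping step of the Justes critical-curve construction
#' for one sampling date.  Treatments are compared by one-way ANOVA on
#' shoot dry matter followed by pairwise least-significant-difference (LSD)
#' comparisons between adjacent N rates at level `alpha`.  A treatment is
#' N-limited when moving to the next-higher rate significantly increases
#' shoot DM; the remaining (top) treatments, whose DM no longer responds,
#' form the non-limited group provided their N concentration still
#' responds.
#'
#' Replicated noise-free data (zero within-group variance) is handled by
#' treating any relative mean difference above 1e-8 as significant.
#'
#' @param shoot_dm plot-level shoot dry matter (t/ha).
#' @param shoot_n plot-level shoot N concentration (%).
#' @param treatment applied N rate per plot (kg/ha).
#' @param alpha significance level of the LSD comparisons.
#' @return list with `status` (named character, "limited"/"non_limited"
#'   per treatment in increasing-rate order), `usable` (logical: can this
#'   date contribute a critical point?), `f_dm`, `p_dm` (ANOVA F and p for
#'   DM) and `step_significant` (adjacent-rate LSD results).
#' @export
classify_n_status <- function(shoot_dm, shoot_n, treatment, alpha = 0.05) {
  treatment <- as.numeric(treatment)
  rates <- sort(unique(treatment))
  if (length(rates) < 3) stop("need at least 3 treatments")
  counts <- table(treatment)
  if (any(counts < 2)) stop("need >= 2 replicate plots per treatment")

  grp <- factor(treatment, levels = rates)
  means <- tapply(shoot_dm, grp, mean)
  fit <- stats::aov(shoot_dm ~ grp)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  f_dm <- an[1, "F value"]
  p_dm <- an[1, "Pr(>F)"]

  n_per <- as.numeric(counts[as.character(rates)])
  step_sig <- logical(length(rates) - 1)
  for (i in seq_len(length(rates) - 1)) {
    diffm <- means[i + 1] - means[i]
    if (mse < 1e-12 * mean(means)^2) {
      # degenerate zero-variance case (noise-free replicates)
      step_sig[i] <- diffm > 1e-8 * max(abs(means))
    } else {
      lsd <- stats::qt(1 - alpha / 2, df) *
        sqrt(mse * (1 / n_per[i] + 1 / n_per[i + 1]))
      step_sig[i] <- diffm > lsd
    }
  }
  status <- rep("non_limited", length(rates))
  status[which(c(step_sig, FALSE))] <- "limited"
  names(status) <- as.character(rates)

  usable <- sum(status == "limited") >= 2 && any(status == "non_limited") &&
    any(step_sig)
  if (!any(step_sig))
    warning("all treatments indistinguishable in shoot DM; ",
            "date unusable for curve construction")
  list(status = status, usable = usable, f_dm = f_dm, p_dm = p_dm,
       step_significant = stats::setNames(step_sig,
                                          paste(utils::head(rates, -1),
                                                rates[-1], sep = "->")))
}

#' Critical point from the oblique/vertical intersection
#'
#' The theoretical critical point of one sampling date: the ordinate of the
#' oblique line (simple linear regression of N concentration on shoot DM
#' over the N-limited group) evaluated at the maximum shoot DM of the
#' non-limited group (the vertical line).
#'
#' @param oblique numeric of length 2, `c(slope, intercept)` of the
#'   N%-on-DM regression line.
#' @param dm_max maximum shoot DM of the non-limited group (t/ha).
#' @return list with `dm` (t/ha) and `nc` (%), class `critical_point`.
#' @export
critical_point <- function(oblique, dm_max) {
  stopifnot(length(oblique) == 2, is.finite(dm_max))
  if (dm_max <= 0) stop("'dm_max' must be positive")
  nc <- oblique[[1]] * dm_max + oblique[[2]]
  if (nc <= 0)
    stop(sprintf(paste0("intersection gives a non-positive critical N ",
                        "concentration (%.3f %%) at DM = %.3f t/ha"),
                 nc, dm_max))
  structure(list(dm = dm_max, nc = nc), class = "critical_point")
}

# one date's critical point from plot-level data: classify, fit the
# oblique line over limited plots, drop the vertical at the mean DM of the
# non-limited plots
date_critical_point <- function(shoot_dm, shoot_n, treatment, alpha = 0.05) {
  cls <- classify_n_status(shoot_dm, shoot_n, treatment, alpha)
  if (!cls$usable) return(NULL)
  lim_rates <- as.numeric(names(cls$status)[cls$status == "limited"])
  lim <- treatment %in% lim_rates
  fit <- stats::lm(shoot_n[lim] ~ shoot_dm[lim])
  dm_max <- mean(shoot_dm[!lim])
  critical_point(c(stats::coef(fit)[2], stats::coef(fit)[1]), dm_max)
}

#' Fit a critical nitrogen dilution curve
#'
#' Fits the allometric (power-law) decline of critical N concentration
#' with shoot dry matter, `Nc = a * DM^-b`, to a set of per-date critical
#' points by linear least squares in log-log space (exact on noise-free
#' power-law data).  An optional nonlinear refinement re-estimates (a, b)
#' by least squares in the original space starting from the log-log
#' solution.
#'
#' @param dm critical-point dry matter values (t/ha).
#' @param nc critical-point N concentrations (%).
#' @param component which biomass component the curve is based on
#'   (`"shoot"`, `"leaf"` or `"stem"`).
#' @param refine logical; run a nonlinear least-squares refinement pass.
#' @return an object of class `ncurve` with elements `a`, `b`, `dm_min`,
#'   `dm_max`, `r2` (in the original Nc space), `component`, `n`.
#' @seealso [critical_concentration()], [predict.ncurve()]
#' @examples
#' dm <- c(1, 2, 4, 8)
#' fit <- fit_dilution_curve(dm, 2.24 * dm^-0.35)
#' coef(fit)  # a = 2.24, b = 0.35
#' @export
fit_dilution_curve <- function(dm, nc, component = c("shoot", "leaf", "stem"),
                               refine = FALSE) {
  component <- match.arg(component)
  ok <- is.finite(dm) & is.finite(nc)
  dm <- dm[ok]; nc <- nc[ok]
  if (length(dm) < 3) stop("need at least 3 critical points")
  if (length(unique(dm)) < 3) stop("critical points must have distinct DM")
  if (any(dm <= 0) || any(nc <= 0))
    stop("critical points must have positive DM and Nc")
  fit <- stats::lm(log(nc) ~ log(dm))
  a <- exp(stats::coef(fit)[[1]])
  b <- -stats::coef(fit)[[2]]
  if (refine) {
    nls_fit <- try(stats::nls(nc ~ a * dm^(-b),
                              start = list(a = a, b = b)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      a <- stats::coef(nls_fit)[["a"]]
      b <- stats::coef(nls_fit)[["b"]]
    }
  }
  pred <- a * dm^(-b)
  sst <- sum((nc - mean(nc))^2)
  r2 <- if (sst > 0) 1 - sum((nc - pred)^2) / sst else 1
  structure(list(a = a, b = b, dm_min = min(dm), dm_max = max(dm),
                 r2 = r2, component = component, n = length(dm),
                 points = data.frame(dm = dm, nc = nc)),
            class = "ncurve")
}

#' @export
print.ncurve <- function(x, ...) {
  cat(sprintf("Critical N dilution curve (%s dry matter)\n", x$component))
  cat(sprintf("  Nc = %.4g * DM^-%.4g   (Nc in %%, DM in t/ha)\n", x$a, x$b))
  cat(sprintf("  validity: %.2f - %.2f t/ha;  R2 = %.3f;  n = %d points\n",
              x$dm_min, x$dm_max, x$r2, x$n))
  invisible(x)
}

#' @export
coef.ncurve <- function(object, ...) c(a = object$a, b = object$b)

#' Critical N concentration at a given biomass
#'
#' Evaluates a fitted dilution curve, `Nc = a * DM^-b`.  A warning (not an
#' error) is issued outside the curve's validity range.
#'
#' @param dm shoot dry matter (t/ha), positive.
#' @param curve an `ncurve` object (or any list with `a` and `b`).
#' @return critical N concentration (%).
#' @export
critical_concentration <- function(dm, curve) {
  if (any(!is.finite(dm)) || any(dm <= 0)) stop("'dm' must be positive")
  if (!is.null(curve$dm_min) &&
      any(dm < curve$dm_min | dm > curve$dm_max))
    warning(sprintf("DM outside the curve validity range [%.2f, %.2f] t/ha",
                    curve$dm_min, curve$dm_max))
  curve$a * dm^(-curve$b)
}

#' @rdname critical_concentration
#' @param object,newdata,... standard predict arguments; `newdata` is a
#'   numeric DM vector or a data.frame with a `dm` column.
#' @export
predict.ncurve <- function(object, newdata, ...) {
  dm <- if (is.data.frame(newdata)) newdata$dm else newdata
  critical_concentration(dm, object)
}

#' @export
plot.ncurve <- function(x, ...) {
  grid <- seq(x$dm_min, x$dm_max, length.out = 200)
  graphics::plot(grid, x$a * grid^(-x$b), type = "l",
                 xlab = "Shoot dry matter (t/ha)",
                 ylab = "Critical N concentration (%)", ...)
  graphics::points(x$points$dm, x$points$nc, pch = 19)
  invisible(x)
}

#' Nitrogen nutrition index
#'
#' `NNI = Na / Nc`: measured plant N concentration relative to the
#' critical concentration at the same biomass.  Values above 1 indicate
#' nitrogen surplus (non-limiting), below 1 deficiency.
#'
#' @param na measured N concentration (%), >= 0.
#' @param nc critical N concentration (%), > 0.
#' @return data.frame with `na`, `nc`, `nni` and a `status` classification
#'   (`"deficient"`, `"optimal"`, `"surplus"`).
#' @examples
#' compute_nni(2.24, 2.24)  # NNI = 1, optimal
#' @export
compute_nni <- function(na, nc) {
  if (any(!is.finite(nc)) || any(nc <= 0)) stop("'nc' must be positive")
  if (any(na < 0)) stop("'na' must be >= 0")
  nni <- na / nc
  data.frame(na = na, nc = nc, nni = nni,
             status = ifelse(nni > 1, "surplus",
                             ifelse(nni < 1, "deficient", "optimal")),
             stringsAsFactors = FALSE)
}

#' Construct a dilution curve from a full plot table
#'
#' Runs the complete per-date procedure over a plot table (as produced by
#' [simulate_trial()] or [read_plot_table()]): for every growth stage,
#' classify treatments into N-limited and non-limited groups, fit the
#' oblique line, intersect with the vertical at the non-limited group's
#' mean DM, then fit the allometric curve through the per-stage critical
#' points.
#'
#' Dates where the grouping fails (no plateau, or everything
#' indistinguishable) are skipped with a warning.
#'
#' @param plots plot table with columns `stage`, `n_rate`, `shoot_dm`,
#'   `shoot_n`.
#' @param alpha significance level for the grouping comparisons.
#' @param refine passed to [fit_dilution_curve()].
#' @return an `ncurve` fit, with the per-stage critical points attached.
#' @export
build_dilution_curve <- function(plots, alpha = 0.05, refine = FALSE) {
  stages <- unique(as.character(plots$stage))
  pts <- list()
  for (s in stages) {
    d <- plots[as.character(plots$stage) == s, ]
    cp <- tryCatch(
      suppressWarnings(date_critical_point(d$shoot_dm, d$shoot_n, d$n_rate,
                                           alpha)),
      error = function(e) NULL)
    if (is.null(cp)) {
      warning(sprintf("stage %s unusable for curve construction; skipped", s))
      next
    }
    pts[[s]] <- cp
  }
  if (length(pts) < 3)
    stop("fewer than 3 usable sampling dates; cannot fit a dilution curve")
  fit_dilution_curve(vapply(pts, `[[`, numeric(1), "dm"),
                     vapply(pts, `[[`, numeric(1), "nc"),
                     refine = refine)
}
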