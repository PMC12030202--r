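#' Yield target from relative yield
#'
#' `GY = Ymax * RY`: the in-season yield target (kg/ha) given the
#' historical maximum yield and the relative yield predicted from NNI.
#'
#' @param ry relative yield.
#' @param y_max historical maximum yield (kg/ha).
#' @return grain yield target (kg/ha).
#' @export
grain_yield <- function(ry, y_max) {
  if (any(y_max < 0) || any(ry < 0)) stop("'ry' and 'y_max' must be >= 0")
  y_max * ry
}

#' Grain nitrogen accumulation from a yield target
#'
#' `GNA = APGN * GY / 100`: plant N demand (kg N/ha) implied by a yield
#' target, using the N absorbed per 100 kg of grain at high yield.
#'
#' @param gy grain yield target (kg/ha).
#' @param apgn N absorption per 100 kg grain (kg).
#' @return grain N accumulation (kg N/ha).
#' @export
grain_n_accumulation <- function(gy, apgn) {
  if (any(gy < 0) || any(apgn < 0)) stop("'gy' and 'apgn' must be >= 0")
  apgn * gy / 100
}

#' Nitrogen-balance fertilizer requirement
#'
#' `Nr = (GNA - Ns)/NUE - Nuse`: fertilizer N still required (kg/ha)
#' given the crop N demand, the soil N supply measured as the N uptake of
#' the unfertilised control, the N use efficiency, and any N already
#' applied.  Negative requirements are clamped to zero and flagged via the
#' `"deficit"` attribute (FALSE where clamping occurred ... the soil
#' already covers demand).
#'
#' @param gna grain N accumulation, the crop demand (kg N/ha).
#' @param ns N uptake of the zero-N control (kg N/ha).
#' @param nue N use efficiency, fraction in (0, 1]; fixed at 0.426 in the
#'   source methodology.
#' @param n_applied N already applied this season (kg/ha).
#' @return required fertilizer N (kg/ha), clamped at 0, with logical
#'   attribute `deficit` (TRUE where a positive requirement remains).
#' @examples
#' required_n(210.38, 128.90)  # about 191.27 kg/ha
#' @export
required_n <- function(gna, ns, nue = 0.426, n_applied = 0) {
  if (any(!is.finite(nue)) || any(nue <= 0) || any(nue > 1))
    stop("'nue' must lie in (0, 1]")
  if (any(gna < 0) || any(ns < 0) || any(n_applied < 0))
    stop("inputs must be >= 0")
  nr <- (gna - ns) / nue - n_applied
  structure(pmax(nr, 0), deficit = nr > 0)
}

#' Stage-split topdressing plan
#'
#' Allocates the nitrogen remaining after the basal dose across topdressing
#' stages in fixed proportions (default 2:1, i.e. 40%/20% of a total in
#' which the basal dose is 40%).
#'
#' @param total_n total seasonal N (kg/ha).
#' @param basal basal (pre-transplant) dose (kg/ha), `<= total_n`.
#' @param split_ratios positive stage ratios, named by stage label.
#' @return object of class `topdressing_plan`: `basal`, `topdressing`
#'   (named kg/ha per stage), `total`, `split_ratios`.  Conservation
#'   `basal + sum(topdressing) == total` holds exactly (to 1e-9); rounding
#'   happens only at report time.
#' @examples
#' topdressing_plan(191.26, 80, c(JT = 2, HD = 1))
#' @export
topdressing_plan <- function(total_n, basal, split_ratios = c(JT = 2, HD = 1)) {
  if (basal < 0 || total_n < 0) stop("amounts must be >= 0")
  if (basal > total_n + 1e-9) stop("'basal' exceeds 'total_n'")
  if (length(split_ratios) < 1 || any(split_ratios <= 0))
    stop("'split_ratios' must be positive, with at least one stage")
  if (is.null(names(split_ratios)))
    names(split_ratios) <- paste0("stage", seq_along(split_ratios))
  top <- (total_n - basal) * split_ratios / sum(split_ratios)
  structure(list(basal = basal, topdressing = top, total = total_n,
                 split_ratios = split_ratios),
            class = "topdressing_plan")
}

#' @export
print.topdressing_plan <- function(x, ...) {
  cat("Topdressing plan (kg N/ha)\n")
  amounts <- c(basal = x$basal, x$topdressing, total = x$total)
  print(round(amounts, 2))
  invisible(x)
}

#' NNI-based topdressing recommendation
#'
#' The full nitrogen-balance chain for one treatment: predict relative
#' yield from (possibly replicated) NNI through the linear-plateau model,
#' convert to a yield target (`GY = Ymax * RY`), to crop N demand
#' (`GNA = APGN * GY/100`), to a fertilizer requirement
#' (`Nr = (GNA - Ns)/NUE - Nuse`), and split the requirement above the
#' basal dose across topdressing stages.
#'
#' `saturated_ry` governs the yield target once NNI has reached the
#' plateau: `"plateau_c"` (default) uses the fitted plateau value c,
#' `"unity"` uses RY = 1 (the historical maximum itself).  Both
#' conventions occur in published recommendation tables.
#'
#' When several replicate NNI values are supplied, amounts are reported as
#' the mean over replicates and the spread column `rmse` is the root-mean-
#' square deviation of the replicate totals around that mean.
#'
#' @param nni NNI value(s) for the treatment (replicates allowed).
#' @param plateau a `linear_plateau` fit or parameter list.
#' @param y_max historical maximum yield (kg/ha).
#' @param apgn N absorption per 100 kg grain (kg).
#' @param ns N uptake of the zero-N control (kg N/ha).
#' @param basal basal dose already planned (kg/ha).
#' @param split_ratios topdressing stage ratios, named.
#' @param nue N use efficiency.
#' @param n_applied N already applied (kg/ha).
#' @param saturated_ry `"plateau_c"` or `"unity"`.
#' @return a `topdressing_plan` (built from replicate-mean amounts) with
#'   extra fields `ry`, `gy`, `gna`, `nr` (replicate means) and `rmse`
#'   (replicate spread of the total; 0 with a single NNI).
#' @export
recommend_topdressing <- function(nni, plateau, y_max, apgn, ns,
                                  basal, split_ratios = c(JT = 2, HD = 1),
                                  nue = 0.426, n_applied = 0,
                                  saturated_ry = c("plateau_c", "unity")) {
  saturated_ry <- match.arg(saturated_ry)
  ry <- predict_relative_yield(nni, plateau)
  if (saturated_ry == "unity")
    ry[nni >= plateau$breakpoint] <- 1
  gy <- grain_yield(ry, y_max)
  gna <- grain_n_accumulation(gy, apgn)
  nr <- as.numeric(required_n(gna, ns, nue, n_applied))
  total <- basal + pmax(nr - basal, 0)   # never below the committed basal
  plan <- topdressing_plan(mean(total), basal, split_ratios)
  plan$ry <- mean(ry); plan$gy <- mean(gy); plan$gna <- mean(gna)
  plan$nr <- mean(nr)
  plan$rmse <- sqrt(mean((total - mean(total))^2))
  plan
}
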