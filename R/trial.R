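#' Configuration for a synthetic rice nitrogen-rate trial
#'
#' Builds the parameter set for [simulate_trial()]: a single-cultivar
#' nitrogen-rate experiment sampled destructively at several growth stages,
#' with a known ("true") critical nitrogen dilution curve, a known
#' linear-plateau yield response to the nitrogen nutrition index (NNI), and
#' a saturating link between applied N and NNI.
#'
#' The applied-N to NNI link is logistic,
#' \deqn{NNI(r) = M / (1 + \exp(-(r - r_0)/s)),}
#' parameterised so that under the default rates (0--200 kg N/ha) the two
#' highest rates sit at or above the plateau breakpoint while the lower
#' rates remain nitrogen-limited.  `nni_values` overrides the logistic with
#' explicit per-rate NNI targets.
#'
#' In the noise-free limit the generator reproduces the geometry assumed by
#' the Justes curve-construction procedure exactly: at each stage the
#' N-limited plots fall on a straight (oblique) line in the (dry matter,
#' N concentration) plane that passes through the stage's true critical
#' point, and the non-limited plots sit on or above the true dilution curve.
#' Running the full grouping/intersection/allometric-fit procedure on such
#' data therefore recovers `(a_true, b_true)` to machine precision.
#'
#' @param n_rates strictly increasing applied N rates (kg/ha), first = 0.
#' @param plots_per_rate replicate plots per rate (>= 2).
#' @param stages ordered growth-stage labels.
#' @param stage_dm potential shoot dry matter (t/ha) reached at each stage
#'   under non-limiting N; one value per stage.
#' @param a_true,b_true true dilution-curve parameters, `Nc = a * DM^-b`
#'   with `Nc` in % and `DM` in t/ha.
#' @param plateau_true list with `slope`, `intercept`, `breakpoint`,
#'   `plateau`: true NNI to relative-yield linear-plateau parameters
#'   (`RY = slope*NNI - intercept` below the breakpoint, else `plateau`).
#' @param y_max attainable yield (kg/ha) at relative yield 1.
#' @param apgn_true kg N absorbed per 100 kg grain at high yield.
#' @param nni_link list with `max`, `midpoint`, `scale` of the logistic
#'   applied-N to NNI link.
#' @param nni_values optional explicit NNI per rate (overrides `nni_link`).
#' @param noise list of relative noise SDs: `dm`, `n`, `reflectance`,
#'   `yield`.  DM, N% and yield noise is multiplicative lognormal
#'   (positivity); reflectance noise is additive Gaussian truncated to
#'   [0, 1].
#' @param dm_power exponent linking the dry-matter response to the
#'   relative-yield response: `DM = stage_dm * RY(NNI)^dm_power`.  Values
#'   above 1 reflect that vegetative biomass responds more steeply to N
#'   shortage than final grain yield does.
#' @param yield_stage stage whose NNI drives the yield response.
#' @param cultivar cultivar label carried through the output.
#' @param seed integer RNG seed.
#' @return an object of class `trial_config` (a validated list).
#' @seealso [simulate_trial()], [simulate_reflectance()]
#' @export
trial_config <- function(n_rates = c(0, 60, 120, 160, 200),
                         plots_per_rate = 3,
                         stages = c("TR", "JT", "HD", "FL"),
                         stage_dm = c(1, 3, 6, 8),
                         a_true = 2.24, b_true = 0.35,
                         plateau_true = list(slope = 1.088, intercept = 0.08,
                                             breakpoint = 1.01, plateau = 1.01),
                         y_max = 10573.3,
                         apgn_true = 1.97,
                         nni_link = list(max = 1.07, midpoint = -78, scale = 82.5),
                         nni_values = NULL,
                         noise = list(dm = 0.05, n = 0.03,
                                      reflectance = 0.02, yield = 0.05),
                         dm_power = 2,
                         yield_stage = "JT",
                         cultivar = "CV-1",
                         seed = 42L) {
  if (length(n_rates) < 2 || any(diff(n_rates) <= 0))
    stop("'n_rates' must be strictly increasing")
  if (n_rates[1] != 0)
    stop("'n_rates' must start at 0 (an unfertilised control is required)")
  if (plots_per_rate < 2)
    stop("'plots_per_rate' must be >= 2 (the grouping ANOVA needs replication)")
  if (length(stage_dm) != length(stages))
    stop("'stage_dm' must give one dry-matter level per stage")
  if (a_true <= 0) stop("'a_true' must be positive")
  if (b_true <= 0 || b_true >= 1) stop("'b_true' must lie in (0, 1)")
  noise <- utils::modifyList(list(dm = 0, n = 0, reflectance = 0, yield = 0),
                             as.list(noise))
  if (any(unlist(noise) < 0)) stop("noise SDs must be >= 0")
  if (!yield_stage %in% stages) stop("'yield_stage' must be one of 'stages'")
  if (!is.null(nni_values) && length(nni_values) != length(n_rates))
    stop("'nni_values' must match 'n_rates' in length")
  structure(list(n_rates = n_rates, plots_per_rate = as.integer(plots_per_rate),
                 stages = stages, stage_dm = stats::setNames(stage_dm, stages),
                 a_true = a_true, b_true = b_true,
                 plateau_true = plateau_true, y_max = y_max,
                 apgn_true = apgn_true, nni_link = nni_link,
                 nni_values = nni_values, noise = noise,
                 dm_power = dm_power,
                 yield_stage = yield_stage, cultivar = cultivar,
                 seed = as.integer(seed)),
            class = "trial_config")
}

# logistic applied-N -> NNI link (or explicit override)
nni_for_rates <- function(config) {
  if (!is.null(config$nni_values)) return(config$nni_values)
  with(config$nni_link,
       max / (1 + exp(-(config$n_rates - midpoint) / scale)))
}

# linear-plateau response used as generator truth
plateau_ry <- function(nni, p) {
  ifelse(nni < p$breakpoint, p$slope * nni - p$intercept, p$plateau)
}

# organ dry-matter fractions (leaf, stem, panicle) per stage; panicle
# appears from heading onward
organ_fractions <- function(stage) {
  switch(stage,
         TR = c(leaf = 0.55, stem = 0.45, panicle = 0.00),
         JT = c(leaf = 0.45, stem = 0.55, panicle = 0.00),
         HD = c(leaf = 0.35, stem = 0.50, panicle = 0.15),
         FL = c(leaf = 0.25, stem = 0.45, panicle = 0.30),
         c(leaf = 0.40, stem = 0.45, panicle = 0.15))
}

# relative organ N levels (leaves richest, stems poorest); scaled so the
# dry-weight-weighted mean matches the target shoot N concentration
organ_n_split <- function(shoot_n, frac) {
  rel <- c(leaf = 1.6, stem = 0.55, panicle = 1.2)
  active <- frac > 0
  scale <- shoot_n / sum(frac[active] * rel[active])
  n <- rel * scale
  n[!active] <- 0
  n
}

#' Simulate a plot-level nitrogen-rate trial
#'
#' Generates the plot x stage agronomic table (organ dry weights and N
#' concentrations, shoot totals, final yield) of a synthetic
#' nitrogen-rate trial whose truth structure — dilution curve, NNI per
#' plot, yield plateau — is known.  Deterministic for a fixed seed.
#'
#' @param config a [trial_config()].
#' @return a data.frame with one row per plot x stage and columns
#'   `plot_id`, `cultivar`, `stage`, `n_rate`, `rep`, organ dry weights
#'   (`leaf_dm`, `stem_dm`, `panicle_dm`, kg/ha), organ N concentrations
#'   (`leaf_n`, `stem_n`, `panicle_n`, %), derived `shoot_dm` (t/ha) and
#'   `shoot_n` (%), `yield` (kg/ha, final stage only, otherwise NA), and
#'   the generator truth `nni_true`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  p <- config$plateau_true
  nni_rate <- nni_for_rates(config)
  limited <- nni_rate < p$breakpoint
  rows <- list()
  for (s in config$stages) {
    resp <- pmax(plateau_ry(nni_rate, p), 0.05)^config$dm_power
    dm <- config$stage_dm[s] * resp                # t/ha, per rate
    if (any(!limited)) {
      # oblique line through the stage's true critical point, anchored at
      # the control: noise-free N-limited plots are exactly collinear
      dm_c <- config$stage_dm[s] * mean(resp[!limited])
      nc_c <- config$a_true * dm_c^(-config$b_true)
      n0 <- nni_rate[1] * config$a_true * dm[1]^(-config$b_true)
      slope <- (nc_c - n0) / (dm_c - dm[1])
      nconc <- ifelse(limited, n0 + slope * (dm - dm[1]),
                      nni_rate * config$a_true * dm^(-config$b_true))
    } else {
      nconc <- nni_rate * config$a_true * dm^(-config$b_true)
    }
    nni_true <- nconc / (config$a_true * dm^(-config$b_true))
    for (i in seq_along(config$n_rates)) {
      for (r in seq_len(config$plots_per_rate)) {
        dm_obs <- dm[i] * exp(stats::rnorm(1, 0, config$noise$dm))
        n_obs <- nconc[i] * exp(stats::rnorm(1, 0, config$noise$n))
        frac <- organ_fractions(s)
        organ_dm <- frac * dm_obs * 1000           # kg/ha
        organ_n <- organ_n_split(n_obs, frac)
        rows[[length(rows) + 1L]] <- data.frame(
          plot_id = sprintf("%s-N%d-r%d", config$cultivar,
                            which(config$n_rates == config$n_rates[i]) - 1L, r),
          cultivar = config$cultivar, stage = s,
          n_rate = config$n_rates[i], rep = r,
          leaf_dm = organ_dm[["leaf"]], stem_dm = organ_dm[["stem"]],
          panicle_dm = organ_dm[["panicle"]],
          leaf_n = organ_n[["leaf"]], stem_n = organ_n[["stem"]],
          panicle_n = organ_n[["panicle"]],
          shoot_dm = sum(organ_dm) / 1000,
          shoot_n = sum(organ_dm * organ_n) / sum(organ_dm),
          yield = NA_real_, nni_true = nni_true[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # yield responds to the NNI reached at the yield-driving stage
  ys <- config$yield_stage
  key <- paste(out$n_rate, out$rep)
  nni_y <- out$nni_true[out$stage == ys][match(key, key[out$stage == ys])]
  final <- out$stage == config$stages[length(config$stages)]
  yield_noise <- exp(stats::rnorm(sum(final), 0, config$noise$yield))
  out$yield[final] <- config$y_max *
    pmax(plateau_ry(nni_y[final], p), 0) * yield_noise
  out$stage <- factor(out$stage, levels = config$stages)
  out
}

#' Simulate 5-band canopy reflectance linked to NNI
#'
#' Emits blue/green/red/red-edge/NIR canopy reflectance for a set of plots
#' such that, before noise, NIR increases and red decreases monotonically
#' with NNI — so NDVI-family indices correlate positively with nitrogen
#' status.  This is an empirical monotone surrogate, not a
#' radiative-transfer model.
#'
#' @param nni vector of NNI values in (0, 2].
#' @param noise_sd relative SD of the additive Gaussian band noise
#'   (truncated so reflectance stays in [0, 1]).
#' @param seed integer RNG seed.
#' @return data.frame with columns `b450`, `g560`, `r650`, `re730`,
#'   `nir840`, one row per element of `nni`.
#' @export
simulate_reflectance <- function(nni, noise_sd = 0, seed = 1L) {
  if (any(!is.finite(nni)) || any(nni <= 0))
    stop("NNI values must be positive")
  set.seed(as.integer(seed))
  t <- pmin(nni, 2) / 2
  bands <- data.frame(b450 = 0.08 - 0.03 * t,
                      g560 = 0.18 - 0.08 * t,
                      r650 = 0.25 - 0.20 * t,
                      re730 = 0.20 + 0.05 * t,
                      nir840 = 0.20 + 0.40 * t)
  if (noise_sd > 0) {
    for (j in seq_along(bands)) {
      eps <- stats::rnorm(nrow(bands), 0, noise_sd * bands[[j]])
      bands[[j]] <- pmin(pmax(bands[[j]] + eps, 0), 1)
    }
  }
  bands
}
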