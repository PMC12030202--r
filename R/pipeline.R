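#' Run the full nitrogen-diagnosis and topdressing pipeline
#'
#' Orchestrates every stage for one cultivar: plot-table load (or
#' synthetic generation), dilution-curve construction, NNI computation,
#' vegetation indices, gray-relational index screening, random-forest NNI
#' inversion, linear-plateau fit of the NNI to relative-yield response,
#' and the per-treatment nitrogen-balance topdressing recommendation.
#' Every source of randomness derives from the single `seed` (substreams:
#' generator = seed, reflectance = seed + 1, split = seed + 2, forest =
#' seed + 3), so a fixed seed reproduces every output byte-for-byte.
#'
#' @param trial a [trial_config()]; its `seed` is replaced by `seed`.
#' @param plot_table optional CSV path of real plot observations (replaces
#'   the synthetic generator; the table must then carry an `nni_true` or
#'   `nni` column only if reflectance is simulated).
#' @param balance list of nitrogen-balance inputs: `ns` (control N
#'   uptake, kg/ha; measured from the control plots when NULL), `apgn`
#'   (kg N per 100 kg grain; `trial$apgn_true` when NULL), `y_max`
#'   (kg/ha; `trial$y_max` when NULL), `nue`, `basal_fraction`,
#'   `split_ratios`, `saturated_ry`.
#' @param gra_threshold per-stage relational-degree selection cut.
#' @param rho gray resolution coefficient.
#' @param spec an [inversion_spec()]; its seed is replaced by the derived
#'   substream seed.
#' @param ndre_dialect passed to [compute_all_indices()].
#' @param alpha significance level of the grouping step.
#' @param out_dir optional directory; when given, writes `plots.csv`,
#'   `indices.csv`, `gra_degrees.csv`, `recommendations.csv` and
#'   `manifest.json` there.
#' @param seed master integer seed.
#' @return list with elements `plots`, `curve`, `nni`, `indices`,
#'   `gra_degrees`, `selection`, `split`, `model`, `eval_train`,
#'   `eval_test`, `plateau`, `recommendations`, `manifest`.
#' @export
run_nni_pipeline <- function(trial = trial_config(),
                             plot_table = NULL,
                             balance = list(),
                             gra_threshold = 0.7, rho = 0.5,
                             spec = inversion_spec(),
                             ndre_dialect = "as_printed",
                             alpha = 0.05,
                             out_dir = NULL,
                             seed = 42L) {
  seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  trial$seed <- seed

  plots <- stage("data", {
    if (is.null(plot_table)) simulate_trial(trial)
    else read_plot_table(plot_table)
  })

  curve <- stage("curve", build_dilution_curve(plots, alpha = alpha))

  nni_tab <- stage("nni", {
    nc <- critical_concentration(plots$shoot_dm, curve)
    cbind(plots[c("plot_id", "cultivar", "stage", "n_rate")],
          compute_nni(plots$shoot_n, nc))
  })

  indices <- stage("spectral", {
    nni_link <- if ("nni_true" %in% names(plots)) plots$nni_true
                else nni_tab$nni
    refl <- simulate_reflectance(nni_link, trial$noise$reflectance,
                                 seed = seed + 1L)
    cbind(plots[c("plot_id", "stage", "n_rate")],
          compute_all_indices(refl, ndre_dialect = ndre_dialect))
  })

  gra_res <- stage("gca", {
    stages <- levels(factor(plots$stage))
    deg <- t(vapply(stages, function(s) {
      sel <- as.character(indices$stage) == s
      gra(nni_tab$nni[sel], indices[sel, VI_NAMES], rho = rho)$degrees
    }, numeric(length(VI_NAMES))))
    rownames(deg) <- stages
    list(degrees = deg, selection = rank_and_select(deg, gra_threshold))
  })
  features <- gra_res$selection$selected
  if (length(features) == 0) features <- VI_NAMES

  inv <- stage("inversion", {
    records <- cbind(indices, nni = nni_tab$nni)
    split <- split_dataset(records, 0.7, seed = seed + 2L)
    spec$seed <- seed + 3L
    model <- fit_nni_rf(split$train, features, spec = spec)
    list(split = split, model = model,
         eval_train = evaluate_inversion(predict(model, split$train),
                                         split$train$nni),
         eval_test = evaluate_inversion(predict(model, split$test),
                                        split$test$nni))
  })

  plateau <- stage("plateau", {
    final <- plots[!is.na(plots$yield), ]
    ys_idx <- as.character(plots$stage) == trial$yield_stage
    nni_y <- nni_tab$nni[ys_idx][match(final$plot_id, plots$plot_id[ys_idx])]
    y_max <- if (!is.null(balance$y_max)) balance$y_max else trial$y_max
    fit_linear_plateau(nni_y, final$yield / y_max)
  })

  recs <- stage("recommend", {
    bal <- utils::modifyList(
      list(y_max = trial$y_max, apgn = trial$apgn_true, ns = NULL,
           nue = 0.426, basal_fraction = 0.4,
           split_ratios = c(JT = 2, HD = 1), saturated_ry = "plateau_c"),
      balance)
    if (is.null(bal$ns)) {
      ctrl <- plots[plots$n_rate == 0 & !is.na(plots$yield), ]
      bal$ns <- mean(plant_n_accumulation(ctrl$leaf_dm, ctrl$leaf_n,
                                          ctrl$stem_dm, ctrl$stem_n,
                                          ctrl$panicle_dm, ctrl$panicle_n))
    }
    # invert NNI at the yield-driving stage from reflectance, per treatment
    rs <- as.character(indices$stage) == trial$yield_stage
    pred <- predict(inv$model, indices[rs, ])
    rates <- sort(unique(plots$n_rate))
    plans <- lapply(rates, function(r) {
      nni_r <- pred[indices$n_rate[rs] == r]
      recommend_topdressing(nni_r, plateau, y_max = bal$y_max,
                            apgn = bal$apgn, ns = bal$ns,
                            basal = bal$basal_fraction * r,
                            split_ratios = bal$split_ratios,
                            nue = bal$nue,
                            saturated_ry = bal$saturated_ry)
    })
    names(plans) <- paste0("N", seq_along(rates) - 1L)
    plans
  })

  manifest <- list(package = "riceNNI",
                   version = as.character(utils::packageVersion("riceNNI")),
                   seed = seed,
                   curve = list(a = curve$a, b = curve$b, r2 = curve$r2),
                   plateau = as.list(coef(plateau)),
                   features = features,
                   eval_test = inv$eval_test)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_plot_table(plots, file.path(out_dir, "plots.csv"))
    utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(stage = rownames(gra_res$degrees),
                                round(gra_res$degrees, 6)),
                     file.path(out_dir, "gra_degrees.csv"),
                     row.names = FALSE)
    write_recommendations(recs, file.path(out_dir, "recommendations.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(plots = plots, curve = curve, nni = nni_tab, indices = indices,
       gra_degrees = gra_res$degrees, selection = gra_res$selection,
       split = inv$split, model = inv$model,
       eval_train = inv$eval_train, eval_test = inv$eval_test,
       plateau = plateau, recommendations = recs, manifest = manifest)
}
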