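#' Read a plot-level agronomic table
#'
#' Reads the CSV dialect written by [write_plot_table()] (UTF-8, '.'
#' decimal separator) and validates schema and value ranges, reporting
#' offending rows by line number.
#'
#' @param path CSV file path.
#' @return validated data.frame of plot observations.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop("plot table not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("empty plot table: ", path)
  need <- c("plot_id", "cultivar", "stage", "n_rate",
            "leaf_dm", "stem_dm", "panicle_dm",
            "leaf_n", "stem_n", "panicle_n")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("plot table missing columns: ", paste(miss, collapse = ", "))
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stop(sprintf("%s in rows (file lines): %s", what,
                   paste(which(cond) + 1L, collapse = ", ")))
  }
  dm_cols <- c("leaf_dm", "stem_dm", "panicle_dm")
  n_cols <- c("leaf_n", "stem_n", "panicle_n")
  bad_row(Reduce(`|`, lapply(d[dm_cols], function(v) v < 0)),
          "negative organ dry weight")
  bad_row(Reduce(`|`, lapply(d[n_cols], function(v) v < 0 | v > 10)),
          "organ N concentration outside [0, 10] %")
  if (!"shoot_dm" %in% names(d))
    d$shoot_dm <- (d$leaf_dm + d$stem_dm + d$panicle_dm) / 1000
  if (!"shoot_n" %in% names(d)) {
    tot <- d$leaf_dm + d$stem_dm + d$panicle_dm
    d$shoot_n <- (d$leaf_dm * d$leaf_n + d$stem_dm * d$stem_n +
                    d$panicle_dm * d$panicle_n) / tot
  }
  d
}

#' @rdname read_plot_table
#' @param plots plot table (as from [simulate_trial()]).
#' @export
write_plot_table <- function(plots, path) {
  utils::write.csv(plots, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write topdressing recommendations
#'
#' Writes a list of [topdressing_plan()]s as a CSV report (fixed column
#' order: treatment, basal, one column per topdressing stage, total,
#' rmse), rounded to 2 decimals at write time.  Plans violating the
#' conservation invariant `basal + sum(topdressing) == total` are refused.
#'
#' @param plans named list of `topdressing_plan` objects (names become the
#'   treatment column).
#' @param path output CSV path.
#' @return the path, invisibly.  An empty list writes a header-only file.
#' @export
write_recommendations <- function(plans, path) {
  if (length(plans) == 0) {
    utils::write.csv(data.frame(treatment = character(), basal = numeric(),
                                total = numeric(), rmse = numeric()),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  stages <- names(plans[[1]]$topdressing)
  rows <- lapply(seq_along(plans), function(i) {
    p <- plans[[i]]
    if (!inherits(p, "topdressing_plan"))
      stop("element ", i, " is not a topdressing_plan")
    if (abs(p$basal + sum(p$topdressing) - p$total) > 1e-9)
      stop("plan ", i, " violates conservation: basal + topdressing != total")
    row <- data.frame(treatment = if (!is.null(names(plans))) names(plans)[i]
                      else as.character(i),
                      basal = p$basal, stringsAsFactors = FALSE)
    for (s in stages) row[[s]] <- p$topdressing[[s]]
    row$total <- p$total
    row$rmse <- if (is.null(p$rmse)) NA_real_ else p$rmse
    row
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 2)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
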