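# Unique-sequence-ratio diversity statistic, per-taxon log-log regression
# with a 95% confidence band, and above/below-line classification.

#' Unique-sequence ratio of a taxon
#'
#' The diversity statistic: unique protein count divided by total observed
#' protein count. Full precision is returned; display rounds to two decimals
#' (the convention used for reporting, e.g. 0.50, 0.31, 0.27).
#'
#' @param n_unique,n_total positive counts with `n_unique <= n_total`.
#' @return The ratio in `(0, 1]`.
#' @export
unique_ratio <- function(n_unique, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_unique <= 0)) stop("n_unique must be positive")
  if (any(n_unique > n_total)) stop("n_unique cannot exceed n_total")
  n_unique / n_total
}

#' Per-taxon diversity table
#'
#' @param taxon character vector of taxon names (phyla or superkingdoms).
#' @param n_total,n_unique observation and unique-sequence counts.
#' @return A data frame of class `flg_taxon_diversity` with `taxon`,
#'   `n_total`, `n_unique`, `ratio`, `log_total`, `log_unique` (base-10
#'   logs). `residual` and `classification` are filled by
#'   [classify_diversity()].
#' @export
taxon_diversity <- function(taxon, n_total, n_unique) {
  ratio <- unique_ratio(n_unique, n_total)
  df <- data.frame(taxon = as.character(taxon),
                   n_total = n_total, n_unique = n_unique,
                   ratio = ratio,
                   log_total = log10(n_total),
                   log_unique = log10(n_unique),
                   stringsAsFactors = FALSE)
  class(df) <- c("flg_taxon_diversity", "data.frame")
  df
}

#' Fit the log-log unique-vs-total regression
#'
#' Ordinary least squares of `log10(n_unique)` on `log10(n_total)` across
#' taxa, with the two-sided t-test p-value for the slope and the pointwise
#' 95% confidence band of the mean response (the gray band around the
#' regression line).
#'
#' @param points an [taxon_diversity()] data frame (>= 3 rows).
#' @param min_total optional filter: taxa with fewer total observations are
#'   dropped before fitting (default 0 = no filter).
#' @return An object of class `flg_regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `model` (the `lm` fit), `data` (the rows used),
#'   and `band(x)` returning the half-width of the confidence band at
#'   abscissa `x` (log10 total).
#' @export
fit_loglog <- function(points, min_total = 0) {
  pts <- points[points$n_total >= min_total, , drop = FALSE]
  if (nrow(pts) < 3) stop("need at least 3 taxa to fit the regression")
  if (length(unique(pts$log_total)) < 2)
    stop("degenerate abscissa: all total counts equal")
  fit <- lm(log_unique ~ log_total, data = pts)
  sm <- summary(fit)
  out <- list(slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              r_squared = sm$r.squared,
              p_value = sm$coefficients["log_total", "Pr(>|t|)"],
              slope_ci = stats::confint(fit)["log_total", ],
              model = fit,
              data = pts,
              band = function(x) {
                pr <- predict(fit, newdata = data.frame(log_total = x),
                              interval = "confidence", level = 0.95)
                unname(pr[, "upr"] - pr[, "fit"])
              })
  class(out) <- "flg_regression_fit"
  out
}

#' @export
print.flg_regression_fit <- function(x, ...) {
  cat(sprintf("log-log fit: slope %.4f, intercept %.4f, R^2 %.4f, p = %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Classify taxa against the regression line
#'
#' A taxon is `above_line` when its log unique count exceeds the predicted
#' mean response by more than the confidence-band half-width at its
#' abscissa, `below_line` when it falls short by more than that, and
#' `on_line` otherwise.
#'
#' @param points an [taxon_diversity()] data frame.
#' @param fit an `flg_regression_fit` from [fit_loglog()].
#' @return `points` with `predicted`, `residual` and `classification`
#'   columns appended.
#' @export
classify_diversity <- function(points, fit) {
  pred <- predict(fit$model,
                  newdata = data.frame(log_total = points$log_total))
  half <- fit$band(points$log_total)
  resid <- points$log_unique - pred
  cls <- ifelse(resid > half, "above_line",
                ifelse(resid < -half, "below_line", "on_line"))
  points$predicted <- unname(pred)
  points$residual <- unname(resid)
  points$classification <- cls
  points
}

#' Read a per-taxon counts table (TSV: taxon, n_total, n_unique)
#'
#' @param path path to the TSV file.
#' @return An [taxon_diversity()] data frame.
#' @export
read_counts_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("taxon", "n_total", "n_unique")
  if (!all(needed %in% names(df)))
    stop("counts table needs columns: ", paste(needed, collapse = ", "))
  taxon_diversity(df$taxon, df$n_total, df$n_unique)
}

#' Per-phylum counts from annotated records
#'
#' Tallies total observations and unique sequences per phylum from a record
#' collection with taxonomy attached: the computation behind the per-phylum
#' diversity chart.
#'
#' @param records a [flg_records] data frame with a `phylum` column.
#' @param rank taxonomy column to tally by (default `"phylum"`).
#' @return An [taxon_diversity()] data frame, one row per phylum.
#' @export
phylum_counts <- function(records, rank = "phylum") {
  if (is.null(records[[rank]]))
    stop("records lack a '", rank, "' column; attach taxonomy first")
  split_res <- split(records$residues, records[[rank]])
  taxon_diversity(names(split_res),
                  n_total = lengths(split_res),
                  n_unique = vapply(split_res,
                                    function(x) length(unique(x)),
                                    integer(1)))
}
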