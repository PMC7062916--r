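#' Precipitation seasonality from a monthly series
#'
#' Standard deviation of the twelve monthly precipitation values expressed as
#' a percentage of their mean (the bioclim BIO15 convention). The population
#' SD (n denominator) is the default, matching BIO15; a sample-SD variant is
#' available.
#'
#' @param values numeric vector of exactly 12 non-negative monthly totals
#'   (mm).
#' @param sd_type `"population"` (default, BIO15) or `"sample"` (n-1).
#' @return Seasonality in percent.
#' @export
precipitation_seasonality <- function(values,
                                      sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(values) != 12L || anyNA(values) || any(values < 0)) {
    stop("precipitation_seasonality(): need 12 non-negative monthly values",
         call. = FALSE)
  }
  m <- mean(values)
  if (m <= 0) {
    stop("precipitation_seasonality(): undefined for zero mean ",
         "precipitation", call. = FALSE)
  }
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt(11 / 12)
  100 * s / m
}

#' Expected rainiest-minus-driest month difference
#'
#' Normal-approximation reading of precipitation seasonality: with monthly
#' precipitation roughly normal around its mean, 95% of months fall within
#' two SDs of the mean, so the difference between the rainiest and driest
#' months is about 4 SDs — i.e. 4 x PS when expressed as a percentage of the
#' mean monthly precipitation. A seasonality of 50% thus corresponds to a
#' spread as large as twice (200%) the monthly mean; 10% to only 40%.
#'
#' @param ps_percent precipitation seasonality (%), non-negative.
#' @param z the per-side coverage multiplier; default 2 (the two-sigma rule),
#'   with `z = 1.96` for the exact normal quantile.
#' @return Expected extreme-month difference as % of mean monthly
#'   precipitation. Vectorised.
#' @export
expected_extreme_range <- function(ps_percent, z = 2) {
  if (any(!is.finite(ps_percent)) || any(ps_percent < 0)) {
    stop("expected_extreme_range(): seasonality must be non-negative",
         call. = FALSE)
  }
  2 * z * ps_percent
}

#' Correlation screen for representative variables
#'
#' Flags variables whose absolute Pearson correlation with a reference
#' variable exceeds a threshold as "represented" by it (the screen used to
#' let one temperature variable stand for the correlated temperature-related
#' bioclim set); the rest are retained. Constant variables have undefined
#' correlation and are flagged rather than silently dropped.
#'
#' @param variable_table data frame of numeric candidate variables
#'   (>= 3 rows).
#' @param reference_var name of the reference column in `variable_table`.
#' @param threshold absolute-correlation cutoff (default 0.8); the screen is
#'   strict (`> threshold`).
#' @return Data frame: `variable`, `r`, `status`
#'   (reference/represented/retained/undefined).
#' @export
correlation_screen <- function(variable_table, reference_var,
                               threshold = 0.8) {
  if (!reference_var %in% names(variable_table)) {
    stop("correlation_screen(): no column '", reference_var, "'",
         call. = FALSE)
  }
  if (nrow(variable_table) < 3L || ncol(variable_table) < 2L) {
    stop("correlation_screen(): need >= 2 variables and >= 3 observations",
         call. = FALSE)
  }
  ref <- variable_table[[reference_var]]
  if (stats::sd(ref) == 0) {
    stop("correlation_screen(): reference variable is constant", call. = FALSE)
  }
  vars <- names(variable_table)
  r <- vapply(vars, function(v) {
    x <- variable_table[[v]]
    if (stats::sd(x) == 0) NA_real_ else stats::cor(ref, x)
  }, numeric(1))
  status <- ifelse(vars == reference_var, "reference",
                   ifelse(is.na(r), "undefined",
                          ifelse(abs(r) > threshold, "represented",
                                 "retained")))
  data.frame(variable = vars, r = unname(r), status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a plot climate table
#'
#' Accepts either a precomputed `precip_seasonality_pct` column or twelve
#' monthly columns `m01`..`m12` (mm) from which seasonality and annual
#' precipitation are computed.
#'
#' @param path CSV with `plot_id`, `annual_mean_temp_c`, and either
#'   `precip_seasonality_pct` or `m01`..`m12`.
#' @param sd_type passed to [precipitation_seasonality()].
#' @return Data frame: `plot_id`, `annual_mean_temp_c`,
#'   `precip_seasonality_pct`, `annual_precip_mm` (NA when only the
#'   precomputed seasonality is available).
#' @export
read_climate <- function(path, sd_type = "population") {
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plot_id", "annual_mean_temp_c")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("read_climate(): '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  months <- sprintf("m%02d", 1:12)
  if (all(months %in% names(x))) {
    mm <- as.matrix(x[, months])
    x$precip_seasonality_pct <- apply(mm, 1, precipitation_seasonality,
                                      sd_type = sd_type)
    x$annual_precip_mm <- rowSums(mm)
  } else if (!"precip_seasonality_pct" %in% names(x)) {
    stop("read_climate(): need either precip_seasonality_pct or monthly ",
         "columns m01..m12", call. = FALSE)
  } else if (!"annual_precip_mm" %in% names(x)) {
    x$annual_precip_mm <- NA_real_
  }
  x[, c("plot_id", "annual_mean_temp_c", "precip_seasonality_pct",
        "annual_precip_mm")]
}
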