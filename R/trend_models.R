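#' Fit a Gamma generalized linear model
#'
#' Thin wrapper around [stats::glm()] with a Gamma error distribution,
#' returning the quantities the trend analysis needs: coefficients with
#' standard errors scaled by the Pearson-chi-square dispersion, null and
#' residual deviance, and the dispersion itself. The canonical inverse link
#' is the default; predictors enter raw (altitude in m, temperature in
#' degrees C, seasonality in %), uncentred.
#'
#' @param formula model formula; the response must be strictly positive.
#' @param data data frame.
#' @param link `"inverse"` (canonical, default) or `"log"`.
#' @param allow_aliased keep aliased (collinear) terms as `NA` rows instead
#'   of erroring; used by [sequential_deviance_table()] to flag duplicate
#'   terms rather than abort.
#' @return An object of class `gamma_glm_fit`: list with `fit` (the glm),
#'   `coefficients` (data frame term/estimate/std_error), `null_deviance`,
#'   `residual_deviance`, `dispersion` (Pearson chi-square / residual df),
#'   `d_squared`, `link`, `n_obs`.
#' @export
fit_gamma_glm <- function(formula, data, link = c("inverse", "log"),
                          allow_aliased = FALSE) {
  link <- match.arg(link)
  y <- stats::model.response(stats::model.frame(formula, data))
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("fit_gamma_glm(): Gamma responses must be strictly positive; ",
         "offset or drop zero-valued stocks", call. = FALSE)
  }
  fit <- stats::glm(formula, data = data, family = stats::Gamma(link = link),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) {
    stop("fit_gamma_glm(): IRLS did not converge in 100 iterations",
         call. = FALSE)
  }
  if (any(is.na(stats::coef(fit))) && !allow_aliased) {
    stop("fit_gamma_glm(): rank-deficient design; collinear term(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  disp <- pearson_dispersion(fit)
  sm <- summary(fit, dispersion = disp)
  structure(list(
    fit = fit,
    coefficients = data.frame(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, "Estimate"],
      std_error = sm$coefficients[, "Std. Error"],
      row.names = NULL, stringsAsFactors = FALSE),
    null_deviance = fit$null.deviance,
    residual_deviance = fit$deviance,
    dispersion = disp,
    d_squared = explained_deviance(fit$null.deviance, fit$deviance),
    link = link,
    n_obs = stats::nobs(fit)
  ), class = "gamma_glm_fit")
}

# Pearson chi-square / residual df, the moment estimator of the Gamma
# dispersion used for analysis-of-deviance tests.
pearson_dispersion <- function(fit) {
  sum(stats::residuals(fit, type = "pearson")^2) / stats::df.residual(fit)
}

#' Explained deviance of a GLM
#'
#' D^2 = (null deviance - residual deviance) / null deviance, the GLM
#' analogue of R^2.
#'
#' @param null_deviance,residual_deviance deviances with
#'   `null >= residual >= 0` and `null > 0`.
#' @return Fraction in [0, 1].
#' @export
explained_deviance <- function(null_deviance, residual_deviance) {
  if (!is.finite(null_deviance) || null_deviance <= 0) {
    stop("explained_deviance(): undefined for null deviance <= 0",
         call. = FALSE)
  }
  if (residual_deviance < 0 || residual_deviance > null_deviance + 1e-8) {
    stop("explained_deviance(): need 0 <= residual <= null deviance",
         call. = FALSE)
  }
  (null_deviance - residual_deviance) / null_deviance
}

#' Sequential (type-I) analysis of deviance for a Gamma GLM
#'
#' Terms are added in the stated order; each row's deviance is the drop in
#' residual deviance when the term enters. Significance uses the chi-squared
#' distribution of (deviance drop / dispersion) with the term's degrees of
#' freedom, the dispersion being the Pearson estimate from the fullest model
#' — the standard analysis-of-deviance convention for Gamma. Per-term
#' estimates and standard errors are taken from the full model. A term that
#' adds no deviance and no df (e.g. a duplicate) is flagged.
#'
#' @param response name of the response column in `data` (strictly
#'   positive).
#' @param terms character vector of model terms in entry order, e.g.
#'   `c("altitude_m", "I(altitude_m^2)")` or `c("t", "ps", "t:ps")`.
#' @param data data frame.
#' @param link passed to [fit_gamma_glm()].
#' @param alpha significance level for the `signif` flag (default 0.05; no
#'   multiplicity correction).
#' @return Data frame of class `deviance_table`: `response`, `term`,
#'   `deviance`, `df`, `p_value`, `d_squared`, `estimate`, `std_error`,
#'   `signif`; attributes `null_deviance`, `residual_deviance`,
#'   `dispersion`.
#' @export
sequential_deviance_table <- function(response, terms, data,
                                      link = c("inverse", "log"),
                                      alpha = 0.05) {
  link <- match.arg(link)
  if (length(terms) == 0L) {
    stop("sequential_deviance_table(): need at least one term", call. = FALSE)
  }
  forms <- lapply(seq_along(terms), function(k) {
    stats::as.formula(paste(response, "~",
                            paste(terms[seq_len(k)], collapse = " + ")))
  })
  full <- fit_gamma_glm(forms[[length(forms)]], data, link = link,
                        allow_aliased = TRUE)
  fits <- c(lapply(forms[-length(forms)], fit_gamma_glm, data = data,
                   link = link, allow_aliased = TRUE),
            list(full))
  resid_dev <- vapply(fits, function(f) f$residual_deviance, numeric(1))
  prev_dev <- c(full$null_deviance, resid_dev[-length(resid_dev)])
  drops <- prev_dev - resid_dev
  dfs <- vapply(fits, function(f) f$n_obs - stats::df.residual(f$fit),
                numeric(1))
  term_df <- diff(c(1, dfs))  # 1 = intercept-only rank

  if (any(term_df < 1)) {
    warning("sequential_deviance_table(): term(s) adding no degrees of ",
            "freedom (duplicate or aliased): ",
            paste(terms[term_df < 1], collapse = ", "), call. = FALSE)
  }
  phi <- full$dispersion
  p <- ifelse(term_df >= 1,
              stats::pchisq(drops / phi, df = pmax(term_df, 1),
                            lower.tail = FALSE),
              NA_real_)
  # full-model coefficients follow the formula's term order, so a
  # single-df term's row index equals the rank of the model it completes
  cf <- full$coefficients
  est_idx <- ifelse(term_df == 1, dfs, NA_integer_)
  out <- data.frame(
    response = response,
    term = terms,
    deviance = drops,
    df = as.integer(pmax(term_df, 0)),
    p_value = p,
    d_squared = drops / full$null_deviance,
    estimate = cf$estimate[est_idx],
    std_error = cf$std_error[est_idx],
    signif = !is.na(p) & p <= alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "null_deviance") <- full$null_deviance
  attr(out, "residual_deviance") <- full$residual_deviance
  attr(out, "dispersion") <- phi
  class(out) <- c("deviance_table", "data.frame")
  out
}

#' Altitude of the extremum of a quadratic trend
#'
#' For a linear predictor eta = a + b * alt + c * alt^2 the extremum of eta
#' sits at -b / (2c). Under the inverse link a minimum of eta is a maximum of
#' the mean response, so a negative linear and positive quadratic
#' coefficient place a peak of the fitted stock at this altitude.
#'
#' @param linear_coef,quadratic_coef coefficients b and c on the link scale;
#'   `quadratic_coef` must be non-zero.
#' @param link link the coefficients come from; with `"inverse"` the
#'   reported `type` is inverted (minimum of eta = maximum of the mean).
#' @return Altitude (m) of the extremum, with attribute `type`
#'   ("maximum"/"minimum" of the mean response).
#' @export
quadratic_peak <- function(linear_coef, quadratic_coef,
                           link = c("inverse", "log")) {
  link <- match.arg(link)
  if (!is.finite(quadratic_coef) || quadratic_coef == 0) {
    stop("quadratic_peak(): no extremum without a quadratic term",
         call. = FALSE)
  }
  x <- -linear_coef / (2 * quadratic_coef)
  eta_min <- quadratic_coef > 0
  type <- if (link == "inverse") {
    if (eta_min) "maximum" else "minimum"
  } else {
    if (eta_min) "minimum" else "maximum"
  }
  structure(x, type = type)
}

.compartments <- c(agc = "agc", bgc = "bgc", soc = "soc", total = "total")

#' Altitudinal trend models per site
#'
#' Fits, separately for each site, Gamma GLMs of each carbon compartment
#' (AGC, BGC, SOC, total) on altitude with linear and quadratic terms, and
#' returns the stacked sequential deviance tables.
#'
#' @param plot_carbon plot-level stocks with `site`, `altitude_m` and the
#'   compartment columns (from [assemble_plot_carbon()]).
#' @param link passed to [fit_gamma_glm()].
#' @param alpha significance level (default 0.05, uncorrected).
#' @return Data frame of stacked deviance-table rows with a `site` column.
#' @export
altitude_models <- function(plot_carbon, link = "inverse", alpha = 0.05) {
  terms <- c("altitude_m", "I(altitude_m^2)")
  out <- list()
  for (s in unique(plot_carbon$site)) {
    d <- plot_carbon[plot_carbon$site == s, , drop = FALSE]
    for (resp in .compartments) {
      tab <- sequential_deviance_table(resp, terms, d, link = link,
                                       alpha = alpha)
      tab <- cbind(site = s, as.data.frame(tab))
      out[[paste(s, resp)]] <- tab
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Climate trend models across sites
#'
#' Pooled-site Gamma GLMs of each compartment on annual mean temperature,
#' precipitation seasonality, and their interaction, entered in that order.
#'
#' @param plot_carbon plot-level stocks (both sites).
#' @param climate climate table with `plot_id`, `annual_mean_temp_c`,
#'   `precip_seasonality_pct` (see [read_climate()]).
#' @param link passed to [fit_gamma_glm()].
#' @param alpha significance level (default 0.05, uncorrected).
#' @return Data frame of stacked deviance-table rows.
#' @export
climate_models <- function(plot_carbon, climate, link = "inverse",
                           alpha = 0.05) {
  d <- merge(plot_carbon, climate, by = "plot_id")
  if (nrow(d) < nrow(plot_carbon)) {
    stop("climate_models(): climate records missing for some plots",
         call. = FALSE)
  }
  names(d)[names(d) == "annual_mean_temp_c"] <- "t_c"
  names(d)[names(d) == "precip_seasonality_pct"] <- "ps_pct"
  terms <- c("t_c", "ps_pct", "t_c:ps_pct")
  out <- lapply(.compartments, function(resp) {
    as.data.frame(sequential_deviance_table(resp, terms, d, link = link,
                                            alpha = alpha))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
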