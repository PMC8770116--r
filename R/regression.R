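# Regression-based migration predictor: a multiple linear regression of
# log10 migration rate on log10-scale chemical/material properties, built
# by forward selection, plus the published three-predictor model shipped as
# the default.

REGRESSION_CANDIDATES <- c("log10_c0", "log10_dp", "log10_kow", "log10_kms", "log10_mw")

REGRESSION_UNITS <- list(
  response = "log10(ug/10cm2/min)",
  log10_c0 = "log10(ug/g)",
  log10_dp = "log10(cm2/s)",
  log10_kow = "log10(-)",
  log10_kms = "log10(-)",
  log10_mw = "log10(g/mol)"
)

#' Construct a migration regression model
#'
#' A linear model on the log10 scale:
#' \eqn{\log_{10} R_{mgr} = \beta_0 + \sum_i \beta_i x_i}. Predictor units
#' are frozen into the object so a model cannot silently be applied to
#' inputs in other units.
#'
#' @param intercept Intercept \eqn{\beta_0}.
#' @param slopes Named numeric vector of slopes; names from
#'   `c("log10_c0", "log10_dp", "log10_kow", "log10_kms", "log10_mw")`.
#' @param p_values Named numeric vector of per-coefficient p-values
#'   (optional, `NA` if unknown).
#' @param fit_r2,fit_se Training-fit statistics on the log10 scale.
#' @param n_obs Number of observations the model was fitted on.
#' @param provenance Free text.
#' @return Object of class `regression_model`.
#' @export
regression_model <- function(intercept, slopes, p_values = NULL,
                             fit_r2 = NA_real_, fit_se = NA_real_,
                             n_obs = NA_integer_, provenance = "user-supplied") {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(slopes), !is.null(names(slopes)))
  unknown <- setdiff(names(slopes), REGRESSION_CANDIDATES)
  if (length(unknown))
    stop_domain("unknown predictor(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(slopes))) stop_domain("all slopes must be finite")
  if (is.null(p_values)) p_values <- setNames(rep(NA_real_, length(slopes)), names(slopes))
  structure(
    list(intercept = intercept, slopes = slopes, included = names(slopes),
         p_values = p_values, fit_r2 = fit_r2, fit_se = fit_se,
         n_obs = n_obs, units = REGRESSION_UNITS, provenance = provenance),
    class = "regression_model"
  )
}

#' The published three-predictor migration regression
#'
#' The default regression predictor:
#' \deqn{\log_{10} R_{mgr} = 3.23 + 0.73 \log_{10} D_p + 0.92 \log_{10} C_0
#'   - 0.06 \log_{10} K_{ow}}
#' (rate in ug/10cm^2/min, D_p in cm^2/s, C_0 in ug/g). Molar mass and
#' K_ms did not enter the published forward selection (p = 0.79 and 0.17).
#'
#' @return A [regression_model()].
#' @export
published_regression_model <- function() {
  regression_model(
    intercept = 3.23,
    slopes = c(log10_dp = 0.73, log10_c0 = 0.92, log10_kow = -0.06),
    fit_r2 = 0.89, fit_se = 0.68, n_obs = 437L,
    provenance = "published forward-selection fit on the harmonized saliva-migration dataset"
  )
}

#' Predict a migration rate from a regression model
#'
#' Evaluates \eqn{\log_{10} R_{mgr} = \beta_0 + \sum_i \beta_i x_i} and
#' returns the rate on the natural scale. Inputs are given on the natural
#' scale and log10-transformed internally; any predictor the model includes
#' must be supplied.
#'
#' @param model A [regression_model()].
#' @param c0 Initial concentration, ug/g.
#' @param dp Diffusion coefficient, cm^2/s.
#' @param log_kow log10 Kow (already a log; passed through).
#' @param kms Material-saliva partition coefficient.
#' @param mw Molar mass, g/mol.
#' @return Predicted migration rate, ug/10cm^2/min (vectorised over inputs).
#' @examples
#' predict_rmgr(published_regression_model(), c0 = 1000, dp = 1e-10, log_kow = 5)
#' @export
predict_rmgr <- function(model, c0 = NULL, dp = NULL, log_kow = NULL,
                         kms = NULL, mw = NULL) {
  stopifnot(inherits(model, "regression_model"))
  vals <- list(
    log10_c0 = if (is.null(c0)) NULL else log10(c0),
    log10_dp = if (is.null(dp)) NULL else log10(dp),
    log10_kow = log_kow,
    log10_kms = if (is.null(kms)) NULL else log10(kms),
    log10_mw = if (is.null(mw)) NULL else log10(mw)
  )
  lr <- model$intercept
  for (p in model$included) {
    if (is.null(vals[[p]]) || anyNA(vals[[p]]))
      stop_domain("model requires predictor '", p, "' but it was not supplied")
    lr <- lr + model$slopes[[p]] * vals[[p]]
  }
  10^lr
}

#' Fit a migration regression by forward selection
#'
#' Classic forward selection on partial-t p-values: starting from the
#' intercept-only model, repeatedly add the candidate predictor whose
#' partial-t p-value (in the model extended by that candidate alone) is
#' smallest, provided it is below `entry_alpha`; stop when no candidate
#' qualifies. Selection is deterministic: ties are broken by candidate
#' order. Response is log10 of the standardized migration rate.
#'
#' @param data Data frame containing the response column and candidate
#'   columns (see [augment_properties()] to derive them from a harmonized
#'   dataset).
#' @param response Name of the response column (log10 rate).
#' @param candidates Candidate predictor columns.
#' @param entry_alpha Entry threshold on the partial-t p-value.
#' @return A [regression_model()] carrying coefficients, p-values of the
#'   included terms, training-fit `fit_r2`/`fit_se` (log10 scale, residuals
#'   about the fitted line, divisor n) and `n_obs`.
#' @export
fit_forward_selection <- function(data, response = "log10_rate",
                                  candidates = REGRESSION_CANDIDATES,
                                  entry_alpha = 0.05) {
  if (!is.data.frame(data) || nrow(data) == 0) stop_domain("empty dataset")
  missing_cols <- setdiff(c(response, candidates), names(data))
  if (length(missing_cols))
    stop_domain("missing column(s): ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[, c(response, candidates), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 10)
    stop_domain("need >= 10 complete observations, got ", nrow(data))

  y <- data[[response]]
  selected <- character(0)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    best_p <- Inf; best <- NA_character_
    for (cand in remaining) {
      rhs <- paste(c(selected, cand), collapse = " + ")
      fit <- stats::lm(stats::reformulate(c(selected, cand), response), data = data)
      coefs <- stats::coef(fit)
      if (anyNA(coefs)) {
        warning("candidate '", cand, "' is collinear with the selected predictors; skipped")
        next
      }
      p <- stats::coef(summary(fit))[cand, "Pr(>|t|)"]
      if (is.finite(p) && p < best_p) { best_p <- p; best <- cand }
    }
    if (is.na(best) || best_p >= entry_alpha) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }

  if (!length(selected)) {
    fit <- stats::lm(y ~ 1)
    m <- regression_model(intercept = unname(stats::coef(fit)[1]),
                          slopes = setNames(numeric(0), character(0)),
                          n_obs = nrow(data),
                          provenance = "forward selection (no predictor entered)")
    m$fit_r2 <- 0
    m$fit_se <- sqrt(mean(stats::resid(fit)^2))
    return(m)
  }

  fit <- stats::lm(stats::reformulate(selected, response), data = data)
  sm <- stats::coef(summary(fit))
  slopes <- stats::coef(fit)[selected]
  pvals <- sm[selected, "Pr(>|t|)"]
  fitted_log <- stats::fitted(fit)
  acc <- log_accuracy(10^fitted_log, 10^y)
  m <- regression_model(
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    slopes = slopes, p_values = setNames(as.numeric(pvals), selected),
    fit_r2 = acc$r2_log, fit_se = acc$se_log, n_obs = nrow(data),
    provenance = sprintf("forward selection (entry p < %g)", entry_alpha)
  )
  attr(m, "lm_fit") <- fit
  m
}

#' Serialize / deserialize a regression model (JSON)
#'
#' @param model A [regression_model()].
#' @param path File path.
#' @export
write_regression_model <- function(model, path) {
  stopifnot(inherits(model, "regression_model"))
  doc <- list(intercept = model$intercept,
              slopes = as.list(model$slopes),
              included = model$included,
              p_values = as.list(model$p_values),
              fit_r2 = model$fit_r2, fit_se = model$fit_se,
              n_obs = model$n_obs, units = model$units,
              provenance = model$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_regression_model
#' @export
read_regression_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  slopes <- unlist(doc$slopes)
  if (is.null(slopes)) slopes <- setNames(numeric(0), character(0))
  m <- regression_model(
    intercept = doc$intercept,
    slopes = slopes,
    p_values = if (length(doc$p_values)) unlist(doc$p_values) else NULL,
    fit_r2 = doc$fit_r2 %||% NA_real_, fit_se = doc$fit_se %||% NA_real_,
    n_obs = doc$n_obs %||% NA_integer_,
    provenance = doc$provenance %||% "deserialized"
  )
  m$included <- unlist(doc$included) %||% m$included
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
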