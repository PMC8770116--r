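# Accuracy statistics on the log10 scale against the 1:1 line, and the
# three cross-validation schemes used to compare the mechanistic and
# regression predictors.

#' Log-scale accuracy against the 1:1 line
#'
#' Residuals are taken about the fixed 1:1 line,
#' \eqn{r_i = \log_{10} pred_i - \log_{10} obs_i}:
#' \deqn{S_e = \sqrt{\sum r_i^2 / n}, \qquad
#'   R^2 = 1 - \frac{\sum r_i^2}{\sum (\log_{10} obs_i - \overline{\log_{10} obs})^2}}
#' The divisor is n by default because the comparison line is fixed, not
#' estimated (no fitted parameter consumes a degree of freedom); an n-1
#' toggle is provided. R^2 is not clamped and can be negative for a
#' predictor worse than the mean of the observations.
#'
#' @param pred,obs Equal-length vectors of positive rates.
#' @param divisor `"n"` (default) or `"n-1"` for the S_e denominator.
#' @return A `fit_metrics` list: `r2_log`, `se_log`, `n`.
#' @export
log_accuracy <- function(pred, obs, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (length(pred) != length(obs)) stop_domain("pred and obs must have equal length")
  n <- length(obs)
  if (n < 2) stop_domain("need at least 2 observations")
  if (any(pred <= 0) || any(obs <= 0))
    stop_domain("pred and obs must be strictly positive (log scale)")
  r <- log10(pred) - log10(obs)
  ss_res <- sum(r^2)
  lobs <- log10(obs)
  ss_tot <- sum((lobs - mean(lobs))^2)
  den <- if (divisor == "n") n else n - 1
  structure(list(r2_log = 1 - ss_res / ss_tot,
                 se_log = sqrt(ss_res / den), n = n),
            class = "fit_metrics")
}

#' Mechanistic predictor for cross-validation
#'
#' Returns a `function(train, test)` evaluating the mechanistic model on
#' the test rows. The training fold is ignored: the mechanistic model fits
#' no parameters, so folds only affect which rows are evaluated.
#'
#' @param materials A `material_table`.
#' @param archetypes An `archetype_table`.
#' @param conservative Force EtOH-eq = 50.
#' @return A predictor function for [cross_validate()].
#' @export
mechanistic_predictor <- function(materials = default_material_table(),
                                  archetypes = default_archetype_table(),
                                  conservative = FALSE) {
  force(materials); force(archetypes); force(conservative)
  function(train, test) {
    vapply(seq_len(nrow(test)), function(i) {
      row <- test[i, ]
      chem <- chemical_record(row$chemical_name, mw = row$mw_g_mol,
                              log_kow = row$log_kow)
      mat <- get_material(materials, row$material)
      med <- medium_spec(in_vivo = row$in_vivo, agitation = row$agitation)
      if (conservative) med$etoh_eq <- 50
      geom <- archetypes[[row$product_archetype]]
      geom$d_p <- row$sample_thickness_cm
      predict_mechanistic_rate(chem, mat, med, c0 = row$c0_ug_g,
                               t_min = row$contact_time_min,
                               geometry = geom)$rate
    }, numeric(1))
  }
}

#' Regression predictor for cross-validation
#'
#' Returns a `function(train, test)` that refits the forward-selection
#' regression on each training fold (augmenting QSPR properties first) and
#' predicts the test rows with the refitted model.
#'
#' @param materials A `material_table`.
#' @param candidates,entry_alpha Passed to [fit_forward_selection()].
#' @return A predictor function for [cross_validate()].
#' @export
regression_predictor <- function(materials = default_material_table(),
                                 candidates = REGRESSION_CANDIDATES,
                                 entry_alpha = 0.05) {
  force(materials); force(candidates); force(entry_alpha)
  function(train, test) {
    tr <- augment_properties(train, materials)
    te <- augment_properties(test, materials)
    model <- fit_forward_selection(as.data.frame(tr), response = "log10_rate",
                                   candidates = candidates,
                                   entry_alpha = entry_alpha)
    lr <- rep(model$intercept, nrow(te))
    for (p in model$included) lr <- lr + model$slopes[[p]] * te[[p]]
    10^lr
  }
}

make_folds <- function(dataset, scheme, seed = NULL, k = 10) {
  df <- as.data.frame(dataset)
  n <- nrow(df)
  fold_of <- switch(
    scheme,
    leave_chemical_group_out = as.integer(factor(df$chemical_group)),
    leave_study_out = as.integer(factor(df$study_id)),
    kfold_random_10 = {
      if (is.null(seed)) stop_domain("kfold_random_10 requires a seed")
      with_seed(seed, {
        f <- integer(n)
        # stratify by material so no fold misses a material entirely
        for (m in unique(df$material)) {
          idx <- sample(which(df$material == m))
          f[idx] <- rep_len(seq_len(k), length(idx))
        }
        f
      })
    },
    stop_domain("unknown cross-validation scheme '", scheme, "'")
  )
  if (length(unique(fold_of)) < 2)
    stop_domain("cannot form folds: a single group/study contains all data")
  fold_of
}

#' Cross-validate a migration predictor
#'
#' Three schemes: `leave_chemical_group_out` (one fold per chemical group;
#' measures error on a chemically new group), `leave_study_out` (one fold
#' per study; controls for experimental bias), and `kfold_random_10`
#' (seeded 10-fold random split stratified by material). For each fold the
#' predictor is given the training rows and evaluated out-of-sample on the
#' test rows; pooled metrics combine all out-of-fold predictions.
#'
#' @param dataset A `migration_dataset` with positive observed rates.
#' @param scheme One of the three scheme names.
#' @param predictor A `function(train, test)` returning positive rate
#'   predictions for the test rows (see [mechanistic_predictor()],
#'   [regression_predictor()]).
#' @param seed Seed for the k-fold split (ignored by the structured schemes).
#' @param divisor Passed to [log_accuracy()].
#' @return A `cv_report`: `scheme`, `seed`, per-fold list (`fold`, `label`,
#'   `metrics`), and pooled `fit_metrics`.
#' @export
cross_validate <- function(dataset,
                           scheme = c("leave_chemical_group_out",
                                      "leave_study_out", "kfold_random_10"),
                           predictor, seed = NULL, divisor = "n") {
  scheme <- match.arg(scheme)
  df <- as.data.frame(dataset)
  fold_of <- make_folds(df, scheme, seed)
  labels <- switch(scheme,
                   leave_chemical_group_out = levels(factor(df$chemical_group)),
                   leave_study_out = levels(factor(df$study_id)),
                   kfold_random_10 = as.character(seq_len(max(fold_of))))
  pooled_pred <- numeric(nrow(df))
  folds <- list()
  for (f in sort(unique(fold_of))) {
    test_idx <- which(fold_of == f)
    train <- df[-test_idx, , drop = FALSE]
    test <- df[test_idx, , drop = FALSE]
    pred <- predictor(train, test)
    pooled_pred[test_idx] <- pred
    folds[[length(folds) + 1L]] <- list(
      fold = f, label = labels[f],
      metrics = log_accuracy(pred, test$rate_ug_per_10cm2_min, divisor = divisor)
    )
  }
  structure(list(scheme = scheme, seed = seed, folds = folds,
                 pooled = log_accuracy(pooled_pred, df$rate_ug_per_10cm2_min,
                                       divisor = divisor)),
            class = "cv_report")
}

#' Serialize a cross-validation report to JSON
#'
#' @param report A `cv_report`.
#' @param path File path.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  doc <- list(
    scheme = report$scheme, seed = report$seed,
    pooled = unclass(report$pooled),
    folds = lapply(report$folds, function(f)
      list(fold = f$fold, label = f$label, metrics = unclass(f$metrics)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation (%s): pooled Se = %.3f, R2 = %.3f over %d folds\n",
              x$scheme, x$pooled$se_log, x$pooled$r2_log, length(x$folds)))
  for (f in x$folds)
    cat(sprintf("  fold %-3s %-40s n=%-4d Se=%.3f\n",
                f$fold, f$label, f$metrics$n, f$metrics$se_log))
  invisible(x)
}
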