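#' Internal regression validation metrics
#'
#' The Golbraikh-Tropsha / Roy metric family over an observed/predicted pair:
#' through-origin slopes `k = sum(y*yhat)/sum(yhat^2)` and
#' `k' = sum(y*yhat)/sum(y^2)`; through-origin determination coefficients
#' `r0^2 = 1 - sum((y - k*yhat)^2)/sum((y - ybar)^2)` and the primed variant
#' with the roles swapped; `r_m^2 = r2 * (1 - sqrt(max(r2 - r0^2, 0)))` (the
#' difference is clipped at zero so the root stays real) and its primed
#' analogue; `delta r_m^2 = |r_m^2 - r_m'^2|`, `rbar_m^2` their mean. The
#' error block holds `chi2 = sum((y - yhat)^2 / |yhat|)`, RMSE, MAE and RSS.
#' `r2` is the squared Pearson correlation between observed and predicted.
#'
#' @param y_obs observed activities (length >= 3).
#' @param y_pred predicted activities.
#' @return object of class `validation_report` (internal block).
#' @export
regression_metrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3,
            all(is.finite(y_obs)), all(is.finite(y_pred)))
  if (stats::sd(y_obs) < 1e-12 || stats::sd(y_pred) < 1e-12) {
    stop("zero variance in observed or predicted values")
  }
  s_p2 <- sum(y_pred^2)
  s_o2 <- sum(y_obs^2)
  if (s_p2 < 1e-24 || s_o2 < 1e-24) stop("through-origin slope undefined")
  k <- sum(y_obs * y_pred) / s_p2
  kp <- sum(y_obs * y_pred) / s_o2
  r2 <- stats::cor(y_obs, y_pred)^2
  r02 <- 1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  r02p <- 1 - sum((y_pred - kp * y_obs)^2) / sum((y_pred - mean(y_pred))^2)
  rm2 <- r2 * (1 - sqrt(max(r2 - r02, 0)))
  rm2p <- r2 * (1 - sqrt(max(r2 - r02p, 0)))
  resid <- y_obs - y_pred
  rep <- list(
    n = length(y_obs),
    r2 = r2, k = k, k_prime = kp, r02 = r02, r02_prime = r02p,
    abs_r02_diff = abs(r02 - r02p),
    rel_r02 = (r2 - r02) / r2,
    rel_r02_prime = (r2 - r02p) / r2,
    rm2 = rm2, rm2_prime = rm2p,
    delta_rm2 = abs(rm2 - rm2p),
    rm2_bar = (rm2 + rm2p) / 2,
    chi2 = sum(resid^2 / abs(y_pred)),
    rmse = sqrt(mean(resid^2)),
    mae = mean(abs(resid)),
    rss = sum(resid^2)
  )
  structure(rep, class = "validation_report")
}

#' External (test-set) predictivity metrics
#'
#' `r_pred^2` (identical to `Q_F1^2`) referencing the training mean,
#' `1 - PRESS/sum((y_test - ybar_train)^2)`; `Q_F2^2` with the test mean in
#' the denominator; `Q_F3^2` comparing mean squared errors,
#' `1 - (PRESS/n_test)/(SS_train/n_train)`; and the concordance correlation
#' coefficient over the test pairs,
#' `Q_ccc = 2*S_xy / (S_xx + S_yy + n*(xbar - ybar)^2)`.
#'
#' @param y_train observed training activities.
#' @param y_test observed test activities (length >= 3).
#' @param y_pred_test predicted test activities.
#' @return object of class `validation_report` (external block).
#' @export
external_metrics <- function(y_train, y_test, y_pred_test) {
  stopifnot(length(y_test) == length(y_pred_test), length(y_test) >= 3,
            all(is.finite(c(y_train, y_test, y_pred_test))))
  ss_train <- sum((y_train - mean(y_train))^2)
  if (ss_train < 1e-24) stop("zero training variance")
  press <- sum((y_test - y_pred_test)^2)
  n_test <- length(y_test)
  qf1 <- 1 - press / sum((y_test - mean(y_train))^2)
  qf2 <- 1 - press / sum((y_test - mean(y_test))^2)
  qf3 <- 1 - (press / n_test) / (ss_train / length(y_train))
  dy <- y_test - mean(y_test)
  dp <- y_pred_test - mean(y_pred_test)
  qccc <- 2 * sum(dy * dp) /
    (sum(dy^2) + sum(dp^2) + n_test * (mean(y_test) - mean(y_pred_test))^2)
  structure(list(n = n_test,
                 r_pred2 = qf1, qf1 = qf1, qf2 = qf2, qf3 = qf3, qccc = qccc),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (nm in setdiff(names(x), "n")) {
    cat(sprintf("  %-14s %8.3f\n", nm, x[[nm]]))
  }
  invisible(x)
}

# published acceptance thresholds for field-based QSAR validation
.thresholds <- list(
  q2 = function(v) v > 0.5,
  r2 = function(v) v > 0.6,
  r_pred2 = function(v) v > 0.6,
  k = function(v) v >= 0.85 && v <= 1.15,
  k_prime = function(v) v >= 0.85 && v <= 1.15,
  abs_r02_diff = function(v) v < 0.3,
  rel_r02 = function(v) v < 0.1,
  rel_r02_prime = function(v) v < 0.1,
  rm2 = function(v) v > 0.5,
  rm2_prime = function(v) v > 0.5,
  rm2_bar = function(v) v > 0.5,
  chi2 = function(v) v < 1.0,
  rmse = function(v) v < 0.5
)

#' Check a validation report against published thresholds
#'
#' Applies the conventional acceptance bounds (q2 > 0.5, r2 > 0.6,
#' r_pred2 > 0.6, 0.85 <= k, k' <= 1.15, |r0^2 - r0'^2| < 0.3,
#' (r2 - r0^2)/r2 < 0.1, r_m^2 family > 0.5, chi2 < 1, RMSE < 0.5) to
#' whichever metrics the report carries. Metrics without a published hard
#' bound, or absent from the report, are marked `not evaluated`.
#'
#' @param report a `validation_report`, optionally augmented with `q2`.
#' @return data.frame with columns `metric`, `value`, `verdict`; attribute
#'   `overall` is TRUE when every evaluated metric passes.
#' @export
threshold_check <- function(report) {
  nm <- names(.thresholds)
  value <- vapply(nm, function(k) {
    v <- report[[k]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  verdict <- vapply(seq_along(nm), function(i) {
    if (is.na(value[i])) "not evaluated"
    else if (.thresholds[[nm[i]]](value[i])) "pass" else "fail"
  }, character(1))
  out <- data.frame(metric = nm, value = value, verdict = verdict,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "overall") <- all(verdict != "fail")
  out
}
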