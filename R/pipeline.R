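#' End-to-end field-QSAR training workflow
#'
#' Runs the full modelling chain on a pre-aligned series: shared grid over
#' all molecules, descriptor matrix built and column-filtered on the training
#' set, optional exhaustive field-combination search by leave-one-out q2,
#' model fit at the cross-validated optimal component count, internal and
#' external validation with threshold verdicts, bootstrap r2, field
#' contributions and the Williams-plot applicability-domain report.
#'
#' @param mols list of `aligned_molecule` (parameterized; activities attached
#'   or supplied via `activities`).
#' @param activities optional `activity_table` to attach by compound id.
#' @param field_kinds kinds to model (canonical names or S/E/H/D/A letters).
#' @param search when TRUE, the best combination of `field_kinds` is selected
#'   by [field_combination_search()] before fitting.
#' @param split list with `train`/`test` id vectors, e.g. from
#'   [split_train_test()]; NULL trains on everything with no external block.
#' @param settings a `field_settings`.
#' @param spacing,margin lattice construction parameters, Angstrom.
#' @param max_components cap for the component scan (<= 6).
#' @param n_boot bootstrap resamples for BS-r2 (default 100).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `qsar_fit`: the `pls_model` (with `q2`, `sep`,
#'   `bs_r2`, `bs_sd` attached), the training `descriptor_matrix`, the
#'   search table when requested, validation reports, threshold verdicts,
#'   field contributions and the AD report.
#' @export
qsar_train <- function(mols, activities = NULL,
                       field_kinds = c("S", "E", "H", "D", "A"),
                       search = FALSE, split = NULL,
                       settings = field_settings(),
                       spacing = 2.0, margin = 4.0,
                       max_components = 6, n_boot = 100, seed = 1) {
  field_kinds <- normalize_field_kinds(field_kinds)
  if (!is.null(activities)) {
    for (i in seq_along(mols)) {
      j <- match(mols[[i]]$id, activities$id)
      if (!is.na(j)) mols[[i]]$pic50 <- activities$pic50[j]
    }
  }
  ids <- vapply(mols, function(m) m$id, character(1))
  grid <- build_grid(mols, spacing = spacing, margin = margin)

  if (is.null(split)) split <- list(train = ids, test = character(0))
  tr <- match(split$train, ids)
  te <- match(split$test, ids)
  if (anyNA(tr) || anyNA(te)) stop("split refers to unknown compound ids")
  if (any(is.na(vapply(mols[tr], function(m) m$pic50, numeric(1))))) {
    stop("training compounds lack activities")
  }

  dm_train <- build_descriptor_matrix(mols[tr], grid, field_kinds, settings)

  search_table <- NULL
  if (isTRUE(search) && length(field_kinds) > 1) {
    search_table <- field_combination_search(dm_train, field_kinds,
                                             max_components = max_components)
    best <- search_table$combination[1]
    chosen <- dm_train$field_kinds[
      sub("comsia_|comfa_", "", dm_train$field_kinds) %in%
        strsplit(best, "+", fixed = TRUE)[[1]]]
    dm_train <- .subset_kinds(dm_train, chosen)
    field_kinds <- chosen
  }

  cv <- loo_q2(dm_train, max_components = max_components)
  model <- fit_pls(dm_train, n_components = cv$onc)
  model$q2 <- cv$q2_onc
  model$sep <- cv$sep_onc
  bs <- bootstrap_r2(dm_train, n_components = cv$onc,
                     n_boot = n_boot, seed = seed)
  model$bs_r2 <- bs$bs_r2
  model$bs_sd <- bs$bs_sd

  val_train <- regression_metrics(model$y, model$fitted)
  val_train$q2 <- cv$q2_onc

  dm_test <- NULL; val_test <- NULL
  if (length(te)) {
    dm_test <- apply_matrix_template(dm_train, mols[te])
    pred_test <- predict(model, dm_test)
    val_test <- regression_metrics(dm_test$y, pred_test)
    ext <- external_metrics(model$y, dm_test$y, pred_test)
    val_test[names(ext)[-1]] <- ext[-1]
  }

  ad <- williams_data(model,
                      X_test = if (length(te)) dm_test else NULL,
                      y_test = if (length(te)) dm_test$y else NULL,
                      ids_train = ids[tr],
                      ids_test = if (length(te)) ids[te] else NULL)

  structure(list(model = model,
                 dm_train = dm_train,
                 grid = grid, settings = settings,
                 field_kinds = field_kinds,
                 search_table = search_table,
                 cv = cv,
                 validation = list(train = val_train, test = val_test),
                 thresholds = list(
                   train = threshold_check(val_train),
                   test = if (!is.null(val_test)) threshold_check(val_test)),
                 contributions = field_contributions(model),
                 ad = ad,
                 split = split, ids = ids, seed = seed),
            class = "qsar_fit")
}

#' @export
print.qsar_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("<qsar_fit> fields: %s | n_train = %d, ONC = %d\n",
              paste(sub("comsia_|comfa_", "", x$field_kinds), collapse = "+"),
              m$n_train, m$n_components))
  cat(sprintf("  q2 = %.3f  SEP = %.3f  r2 = %.3f  SEE = %.3f  F = %.3f\n",
              m$q2, m$sep, m$stats$r2, m$stats$see, m$stats$f))
  cat(sprintf("  BS-r2 = %.3f  BS-SD = %.3f\n", m$bs_r2, m$bs_sd))
  ctr <- x$contributions
  cat("  field contributions (%):",
      paste(sprintf("%s %.1f", sub("comsia_|comfa_", "", names(ctr)), ctr),
            collapse = ", "), "\n")
  if (!is.null(x$validation$test)) {
    v <- x$validation$test
    cat(sprintf("  external: r_pred2 = %.3f  QF2 = %.3f  QF3 = %.3f  Qccc = %.3f\n",
                v$r_pred2, v$qf2, v$qf3, v$qccc))
  }
  invisible(x)
}

#' Predict new compounds with a trained workflow
#'
#' Builds descriptor rows for the new molecules in the training model's
#' descriptor space (training grid, field kinds, column mask and imputation
#' means), predicts activity, and reports leverage plus the
#' applicability-domain verdict. When a `reference` compound id from the
#' training set is given, compounds predicted above that compound's activity
#' (its observed value, or fitted value if no observation) are flagged.
#'
#' @param fit a `qsar_fit`.
#' @param mols list of parameterized `aligned_molecule` in the training frame.
#' @param reference optional training-compound id used as the design
#'   threshold.
#' @return data.frame (`id`, `observed`, `predicted`, `leverage`,
#'   `in_domain`, and `above_reference` when a reference is given).
#' @export
qsar_predict <- function(fit, mols, reference = NULL) {
  stopifnot(inherits(fit, "qsar_fit"))
  dm_new <- apply_matrix_template(fit$dm_train, mols)
  pred <- predict(fit$model, dm_new)
  h <- leverages(fit$model, dm_new)
  h_star <- warning_leverage(fit$model$n_components, fit$model$n_train)
  out <- data.frame(id = dm_new$ids,
                    observed = dm_new$y,
                    predicted = pred,
                    leverage = h,
                    in_domain = h <= h_star,
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    j <- match(reference, fit$ids[match(fit$split$train, fit$ids)])
    if (is.na(j)) stop("reference '", reference, "' is not a training compound")
    thr <- fit$model$y[j]
    if (is.na(thr)) thr <- fit$model$fitted[j]
    out$above_reference <- out$predicted > thr
  }
  out
}
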