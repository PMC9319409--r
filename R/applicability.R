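#' Leverages in latent (score) space
#'
#' `h_i = 1/n_train + t_i' (T'T)^{-1} t_i` where `T` is the training score
#' matrix of the model and `t_i` the row's projection through the model's
#' centering, block scales and weight matrix. Test compounds are projected
#' against the same training `T`, so their leverage measures extrapolation
#' from the training chemical space.
#'
#' @param model a `pls_model`.
#' @param X_rows matrix over the model's active columns (or a
#'   `descriptor_matrix`); omit to score the training set itself.
#' @return numeric leverage vector.
#' @export
leverages <- function(model, X_rows = NULL) {
  Tm <- model$scores
  TtT <- crossprod(Tm)
  if (rcond(TtT) < 1e-14) stop("degenerate score matrix: T'T is singular")
  Ti <- if (is.null(X_rows)) {
    Tm
  } else {
    if (inherits(X_rows, "descriptor_matrix")) X_rows <- X_rows$X
    .project_scores(model, as.matrix(X_rows))
  }
  1 / model$n_train + rowSums(Ti * t(solve(TtT, t(Ti))))
}

#' Warning leverage
#'
#' The Williams-plot convention `h* = 3 (p + 1) / n` with `p` the number of
#' latent components.
#'
#' @param n_components latent dimensionality of the model.
#' @param n_train training-set size.
#' @export
warning_leverage <- function(n_components, n_train) {
  3 * (n_components + 1) / n_train
}

#' Williams-plot applicability-domain report
#'
#' For every compound: leverage, standardized residual
#' `(y - yhat)/s` with `s = sqrt(RSS_train / (n_train - ONC - 1))`, and the
#' in-domain verdict `h <= h*` and `|std residual| <= 3`. Training compounds
#' use the model's fitted values; test compounds are predicted through the
#' model.
#'
#' @param model a `pls_model`.
#' @param X_test optional matrix/`descriptor_matrix` of test rows.
#' @param y_test observed activities for the test rows.
#' @param ids_train,ids_test optional compound identifiers.
#' @return data.frame of class `ad_report` (`id`, `role`, `leverage`,
#'   `std_residual`, `in_domain`) with attributes `h_star` and `s`.
#' @export
williams_data <- function(model, X_test = NULL, y_test = NULL,
                          ids_train = NULL, ids_test = NULL) {
  n <- model$n_train
  a <- model$n_components
  h_star <- warning_leverage(a, n)
  s <- sqrt(model$stats$rss / (n - a - 1))
  h_train <- leverages(model)
  # an (essentially) exact fit has no residual scale; all residuals are zero
  std_res <- function(resid) if (s < 1e-10) rep(0, length(resid)) else resid / s
  res_train <- std_res(model$y - model$fitted)
  if (is.null(ids_train)) ids_train <- sprintf("train_%02d", seq_len(n))
  out <- data.frame(id = ids_train, role = "train",
                    leverage = h_train, std_residual = res_train,
                    stringsAsFactors = FALSE)
  if (!is.null(X_test)) {
    stopifnot(!is.null(y_test))
    if (inherits(X_test, "descriptor_matrix")) {
      if (is.null(ids_test)) ids_test <- X_test$ids
      X_test <- X_test$X
    }
    h_test <- leverages(model, X_test)
    res_test <- std_res(y_test - predict(model, X_test))
    if (is.null(ids_test)) ids_test <- sprintf("test_%02d", seq_along(y_test))
    out <- rbind(out, data.frame(id = ids_test, role = "test",
                                 leverage = h_test, std_residual = res_test,
                                 stringsAsFactors = FALSE))
  }
  out$in_domain <- out$leverage <= h_star & abs(out$std_residual) <= 3
  attr(out, "h_star") <- h_star
  attr(out, "s") <- s
  class(out) <- c("ad_report", "data.frame")
  out
}
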