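# NIPALS PLS1 on a centered (and block-scaled) X and centered y.
# Returns weights W, loadings P, inner coefficients qvec and scores Tm for
# n_components latent directions. Errors out if the residual covariance
# collapses before reaching n_components (effective rank exceeded).
.nipals <- function(Xc, yc, n_components) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0.0, p, n_components)
  P <- matrix(0.0, p, n_components)
  Tm <- matrix(0.0, n, n_components)
  qvec <- numeric(n_components)
  X <- Xc; y <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop("requested ", n_components, " components but the descriptor ",
           "matrix supports only ", a - 1L, " (rank exceeded)")
    }
    w <- w / nw
    t_a <- X %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-24) stop("degenerate score vector at component ", a)
    p_a <- crossprod(X, t_a) / tt
    q_a <- sum(y * t_a) / tt
    X <- X - t_a %*% t(p_a)
    y <- y - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; qvec[a] <- q_a
  }
  list(W = W, P = P, Tm = Tm, qvec = qvec)
}

# regression vector (in the centered/scaled X space) for the first a components
.pls_coef <- function(nip, a) {
  W <- nip$W[, seq_len(a), drop = FALSE]
  P <- nip$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), nip$qvec[seq_len(a)]))
}

# resolve (X, y, col_kinds) from a descriptor_matrix or plain matrix
.resolve_xy <- function(x, y) {
  if (inherits(x, "descriptor_matrix")) {
    if (is.null(y)) y <- x$y
    kinds <- x$col_meta$field_kind[x$mask]
    list(X = x$X, y = y, col_kinds = kinds, dm = x)
  } else {
    X <- as.matrix(x)
    list(X = X, y = y, col_kinds = rep("block", ncol(X)), dm = NULL)
  }
}

# centering and block scaling. Within one field block no autoscaling (CoMFA
# convention); with several blocks each is divided by the pooled standard
# deviation of its centered entries so no single field dominates.
.center_scale <- function(X, col_kinds) {
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  kinds <- unique(col_kinds)
  col_scale <- rep(1.0, ncol(X))
  if (length(kinds) > 1) {
    for (k in kinds) {
      j <- which(col_kinds == k)
      s <- stats::sd(as.vector(Xc[, j, drop = FALSE]))
      if (is.finite(s) && s > 1e-12) col_scale[j] <- s
    }
  }
  list(Xs = sweep(Xc, 2, col_scale, "/"), x_mean = x_mean,
       col_scale = col_scale)
}

#' Fit a partial least squares model
#'
#' NIPALS PLS1 relating a (filtered) field descriptor matrix to activity.
#' X and y are mean-centered; no per-column autoscaling is applied within a
#' field block, and when several field kinds are present each block is
#' divided by its pooled standard deviation (block scaling). Training
#' statistics follow the classical definitions: `r2 = 1 - RSS/SS_tot`,
#' `SEE = sqrt(RSS/(n - A - 1))` and
#' `F = (r2/A) / ((1 - r2)/(n - A - 1))` for `A` latent components.
#'
#' @param x a `descriptor_matrix` or numeric matrix (observations x columns).
#' @param y activity vector; taken from the descriptor matrix when omitted.
#' @param n_components number of latent components.
#' @return object of class `pls_model` with coefficients on both the model
#'   (scaled) and raw descriptor scales, score/loading matrices and the
#'   training statistics.
#' @export
fit_pls <- function(x, y = NULL, n_components) {
  rx <- .resolve_xy(x, y)
  X <- rx$X; y <- rx$y
  n <- nrow(X)
  if (any(is.na(y))) stop("activity vector contains NA")
  if (stats::sd(y) < 1e-12) stop("zero-variance activity vector")
  if (n_components < 1) stop("n_components must be >= 1")
  if (n < n_components + 2) {
    stop("need at least n_components + 2 = ", n_components + 2,
         " training samples, got ", n)
  }
  cs <- .center_scale(X, rx$col_kinds)
  y_mean <- mean(y)
  nip <- .nipals(cs$Xs, y - y_mean, n_components)
  coef_scaled <- .pls_coef(nip, n_components)
  coef_raw <- coef_scaled / cs$col_scale

  fitted <- drop(cs$Xs %*% coef_scaled) + y_mean
  rss <- sum((y - fitted)^2)
  ss_tot <- sum((y - y_mean)^2)
  r2 <- 1 - rss / ss_tot
  dfree <- n - n_components - 1
  see <- sqrt(rss / dfree)
  fval <- (r2 / n_components) / ((1 - r2) / dfree)

  structure(list(
    n_components = n_components,
    x_mean = cs$x_mean, y_mean = y_mean, col_scale = cs$col_scale,
    col_kinds = rx$col_kinds,
    col_sd_scaled = apply(cs$Xs, 2, stats::sd),
    W = nip$W, P = nip$P, qvec = nip$qvec, scores = nip$Tm,
    coef_scaled = coef_scaled, coef_raw = coef_raw,
    n_train = n, fitted = fitted, y = y,
    stats = list(r2 = r2, rss = rss, see = see, f = fval),
    dm_meta = if (!is.null(rx$dm)) {
      rx$dm[c("col_meta", "mask", "grid", "settings", "field_kinds")]
    } else NULL
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, n = %d, r2 = %.3f, SEE = %.3f, F = %.3f\n",
              x$n_components, x$n_train, x$stats$r2, x$stats$see, x$stats$f))
  if (!is.null(x$q2)) cat(sprintf("  LOO q2 = %.3f (ONC = %d)\n", x$q2, x$n_components))
  invisible(x)
}

# new rows (raw active-column space) -> latent scores
.project_scores <- function(model, Xnew) {
  Xs <- sweep(sweep(Xnew, 2, model$x_mean), 2, model$col_scale, "/")
  R <- model$W %*% solve(crossprod(model$P, model$W))
  Xs %*% R
}

#' Predict activities with a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix over the model's active columns, or a
#'   `descriptor_matrix` built with the same field kinds and mask.
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_matrix")) {
    if (!identical(newdata$field_kinds, object$dm_meta$field_kinds)) {
      stop("field-kind mismatch: model uses {",
           paste(object$dm_meta$field_kinds, collapse = ", "),
           "} but the matrix holds {",
           paste(newdata$field_kinds, collapse = ", "), "}")
    }
    newdata <- newdata$X
  }
  Xnew <- as.matrix(newdata)
  if (ncol(Xnew) != length(object$coef_raw)) {
    stop("newdata has ", ncol(Xnew), " columns; model expects ",
         length(object$coef_raw))
  }
  drop(sweep(Xnew, 2, object$x_mean) %*% object$coef_raw) + object$y_mean
}

#' Leave-one-out cross-validation and component selection
#'
#' For every component count `a` up to `max_components`, refits the model n
#' times leaving one observation out and accumulates
#' `PRESS(a) = sum_i (y_i - yhat_(-i),a)^2`; then
#' `q2(a) = 1 - PRESS(a)/SS_tot` and `SEP(a) = sqrt(PRESS(a)/(n - a - 1))`.
#' Column filtering (and the column set) is fixed from the full data set; the
#' centering and block scales are recomputed inside each fold. The optimal
#' number of components (ONC) maximises q2, ties broken toward fewer
#' components; `max_components` is capped at 6, the conventional upper bound.
#'
#' @param x a `descriptor_matrix` or numeric matrix.
#' @param y activity vector; taken from the descriptor matrix when omitted.
#' @param max_components largest component count to scan (capped at 6).
#' @return list with `q2` and `sep` vectors indexed by component count,
#'   `press`, `onc`, `q2_onc` and `sep_onc`.
#' @export
loo_q2 <- function(x, y = NULL, max_components = 6) {
  rx <- .resolve_xy(x, y)
  X <- rx$X; y <- rx$y
  n <- nrow(X)
  if (n < 4) stop("leave-one-out needs at least 4 samples")
  amax <- min(max_components, 6L)
  # a fold can support at most (full rank - 1) latent directions
  r_full <- qr(sweep(X, 2, colMeans(X)))$rank
  amax <- max(1L, min(amax, r_full - 1L))
  if (n - 1 < amax + 2) {
    stop("folds of ", n - 1, " samples cannot support ", amax, " components")
  }
  press <- numeric(amax)
  for (i in seq_len(n)) {
    cs <- .center_scale(X[-i, , drop = FALSE], rx$col_kinds)
    yi <- y[-i]
    nip <- .nipals(cs$Xs, yi - mean(yi), amax)
    xs_new <- (X[i, ] - cs$x_mean) / cs$col_scale
    for (a in seq_len(amax)) {
      pred <- sum(xs_new * .pls_coef(nip, a)) + mean(yi)
      press[a] <- press[a] + (y[i] - pred)^2
    }
  }
  ss_tot <- sum((y - mean(y))^2)
  q2 <- 1 - press / ss_tot
  sep <- sqrt(press / (n - seq_len(amax) - 1))
  onc <- which.max(q2)  # which.max takes the first (fewest components) on ties
  list(q2 = q2, sep = sep, press = press,
       onc = as.integer(onc), q2_onc = q2[onc], sep_onc = sep[onc])
}

#' Bootstrap r2 statistics
#'
#' Resamples training rows with replacement `n_boot` times, refits at the
#' chosen component count and reports the mean (BS-r2) and standard deviation
#' (BS-SD) of the resample r2 values. Resamples with zero activity variance
#' are redrawn; the number of redraws is attached as attribute `redrawn`.
#'
#' @param x a `descriptor_matrix` or numeric matrix.
#' @param y activity vector.
#' @param n_components component count for every refit.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed RNG seed.
#' @return list with `bs_r2`, `bs_sd` and the individual resample `r2`.
#' @export
bootstrap_r2 <- function(x, y = NULL, n_components, n_boot = 100, seed = 1) {
  rx <- .resolve_xy(x, y)
  X <- rx$X; y <- rx$y
  n <- nrow(X)
  set.seed(seed)
  r2s <- numeric(n_boot)
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(y[idx]) > 1e-12) break
      redrawn <- redrawn + 1L
    }
    fit <- fit_pls(X[idx, , drop = FALSE], y[idx], n_components)
    r2s[b] <- fit$stats$r2
  }
  out <- list(bs_r2 = mean(r2s), bs_sd = stats::sd(r2s), r2 = r2s)
  attr(out, "redrawn") <- redrawn
  out
}

# subset a descriptor_matrix to the columns of the given field kinds,
# keeping the original filter mask
.subset_kinds <- function(dm, kinds) {
  kinds <- normalize_field_kinds(kinds)
  keep_raw <- dm$col_meta$field_kind %in% kinds
  if (!any(dm$mask & keep_raw)) return(NULL)
  active_sel <- keep_raw[dm$mask]
  out <- dm
  out$X <- dm$X[, active_sel, drop = FALSE]
  out$col_meta <- dm$col_meta[keep_raw, , drop = FALSE]
  rownames(out$col_meta) <- NULL
  out$mask <- dm$mask[keep_raw]
  out$field_kinds <- kinds[order(match(kinds, dm$field_kinds))]
  if (!"comfa_electrostatic" %in% out$field_kinds) out$elec_impute <- NULL
  out
}

#' Exhaustive field-combination search
#'
#' Evaluates every non-empty combination of the candidate field kinds by
#' leave-one-out cross-validation on a shared, pre-filtered descriptor matrix
#' and ranks the combinations by q2 (ties broken toward fewer fields, then
#' fewer components). This mirrors the permutation-combination protocol used
#' to pick the best CoMSIA descriptor subset.
#'
#' @param dm a `descriptor_matrix` containing all candidate kinds.
#' @param candidate_kinds kinds to combine (canonical names or S/E/H/D/A).
#' @param y activity vector; defaults to the matrix's activities.
#' @param max_components passed to [loo_q2()].
#' @return data.frame (one row per combination) with `combination`,
#'   `n_fields`, `q2`, `onc`, `sep`, ranked best-first.
#' @export
field_combination_search <- function(dm, candidate_kinds = c("S", "E", "H", "D", "A"),
                                     y = NULL, max_components = 6) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  candidate_kinds <- normalize_field_kinds(candidate_kinds)
  missing_kinds <- setdiff(candidate_kinds, dm$field_kinds)
  if (length(missing_kinds)) {
    stop("descriptor matrix lacks candidate kind(s): ",
         paste(missing_kinds, collapse = ", "))
  }
  if (is.null(y)) y <- dm$y
  nk <- length(candidate_kinds)
  rows <- list()
  for (m in seq_len(2^nk - 1)) {
    kinds <- candidate_kinds[bitwAnd(m, 2^(seq_len(nk) - 1)) > 0]
    sub <- .subset_kinds(dm, kinds)
    label <- paste(sub("comsia_|comfa_", "", kinds), collapse = "+")
    if (is.null(sub)) {
      rows[[length(rows) + 1L]] <- data.frame(
        combination = label, n_fields = length(kinds),
        q2 = NA_real_, onc = NA_integer_, sep = NA_real_)
      next
    }
    cv <- loo_q2(sub, y, max_components)
    rows[[length(rows) + 1L]] <- data.frame(
      combination = label, n_fields = length(kinds),
      q2 = cv$q2_onc, onc = cv$onc, sep = cv$sep_onc)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$q2, out$n_fields, out$onc, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Relative field contributions
#'
#' Fraction of the model's explanatory weight carried by each field kind,
#' computed as `sum_j sd_j * |b_j|` over the active columns of the kind (in
#' the model's scaled descriptor space), normalised to percentages — the
#' conventional field-contribution summary of field-based QSAR reports.
#'
#' @param model a `pls_model`.
#' @return named numeric vector of percentages summing to 100.
#' @export
field_contributions <- function(model) {
  w <- model$col_sd_scaled * abs(model$coef_scaled)
  agg <- tapply(w, model$col_kinds, sum)
  100 * agg / sum(agg)
}
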