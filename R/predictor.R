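# Melting-temperature predictor: linear least-squares fit of Tm on the
# four energy features, jack-knife cross-validation, and iterative
# exclusion of the worst-predicted proteins. The fit objective is the
# RMS deviation sigma between predicted and experimental Tm; since the
# model is linear in its parameters, the closed-form least-squares
# solution minimizes it exactly.

rms <- function(x) sqrt(mean(x^2))

per_family_sigma <- function(residuals, families) {
  if (is.null(families)) return(NULL)
  s <- tapply(residuals^2, families, mean)
  stats::setNames(sqrt(as.numeric(s)), names(s))
}

# Rank check: constant feature columns are harmless (absorbed by the
# intercept, coefficient set to 0); genuine collinearity among the
# varying columns is an error naming the offenders.
check_rank <- function(x) {
  varying <- apply(x, 2, function(col) stats::var(col) > 0)
  X <- cbind(intercept = 1, x[, varying, drop = FALSE])
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("fit_tm: rank-deficient design; collinear features: ",
         paste(bad, collapse = ", "))
  }
}

new_tm_fit <- function(mode, coefficients, predictions, tm, ids, families,
                       cv) {
  resid <- predictions - tm
  structure(list(mode = mode, coefficients = coefficients,
                 predictions = stats::setNames(predictions, ids),
                 tm_exp = stats::setNames(tm, ids),
                 residuals = stats::setNames(resid, ids),
                 sigma = rms(resid),
                 sigma_per_family = per_family_sigma(resid, families),
                 r = if (stats::sd(predictions) > 0 && stats::sd(tm) > 0)
                       stats::cor(predictions, tm) else 0,
                 n = length(tm), ids = ids, families = families, cv = cv),
            class = "tm_fit")
}

#' Fit the linear Tm predictor
#'
#' Linear least squares of experimental Tm on the four energy features
#' plus an intercept, minimizing the RMS prediction deviation sigma.
#'
#' @param x numeric matrix (n x 4) of features ([mode_features]).
#' @param tm experimental melting temperatures (degrees C).
#' @param mode label stored in the result (`"deltaDeltaG"` or
#'   `"deltaG_A"`); has no effect on the numerics.
#' @param ids optional protein identifiers (default: rownames of `x`).
#' @param families optional family labels for the per-family sigma
#'   breakdown.
#' @return object of class `tm_fit`: `coefficients` (intercept + 4),
#'   `predictions`, `residuals`, `sigma` (RMS residual, degrees C),
#'   `sigma_per_family`, `r` (Pearson correlation of predicted vs
#'   experimental).
#' @export
fit_tm <- function(x, tm, mode = "deltaDeltaG", ids = rownames(x),
                   families = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < ncol(x) + 2) {
    stop("fit_tm: need at least ", ncol(x) + 2, " proteins")
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  check_rank(x)
  fit <- stats::lm.fit(cbind(intercept = 1, x), tm)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- as.numeric(cbind(1, x) %*% beta)
  new_tm_fit(mode, beta, pred, tm, ids, families, cv = FALSE)
}

#' Jack-knife cross-validated Tm prediction
#'
#' Each protein is predicted by coefficients fitted on all the others
#' (leave-one-out). In strict mode the features themselves are also
#' re-derived without the held-out protein, via a caller-supplied
#' closure (the default re-uses the fixed features, i.e. only the
#' regression parameters are re-identified per fold).
#'
#' @inheritParams fit_tm
#' @param refit_features optional function `(held_out_id)` returning the
#'   full feature matrix recomputed without the held-out protein
#'   (strict mode); `NULL` for coefficients-only jack-knife.
#' @return a `tm_fit` with `cv = TRUE`; `sigma` is the cross-validated
#'   sigma computed from held-out residuals.
#' @export
jackknife_tm <- function(x, tm, mode = "deltaDeltaG", ids = rownames(x),
                         families = NULL, refit_features = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < ncol(x) + 2) stop("jackknife_tm: need at least ",
                            ncol(x) + 2, " proteins")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  check_rank(x)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    xi <- if (is.null(refit_features)) x else {
      m <- refit_features(ids[i])
      as.matrix(m[match(ids, rownames(m)), , drop = FALSE])
    }
    fit <- stats::lm.fit(cbind(1, xi[-i, , drop = FALSE]), tm[-i])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred[i] <- sum(c(1, xi[i, ]) * beta)
  }
  new_tm_fit(mode, NULL, pred, tm, ids, families, cv = TRUE)
}

#' Iterative worst-predicted exclusion
#'
#' Repeats `k` times: compute jack-knife predictions on the current set,
#' remove the protein with the largest absolute residual (ties broken by
#' lexicographic id), and refit. Returns the removal trace and the
#' jack-knife fit on the remaining proteins. `k = 0` reduces to a plain
#' jack-knife.
#'
#' @inheritParams jackknife_tm
#' @param k number of proteins to exclude.
#' @return list with `excluded` (ids in removal order) and `fit`
#'   (the final `tm_fit` on the remainder).
#' @export
worst_k_exclusion <- function(x, tm, mode = "deltaDeltaG", k = 6,
                              ids = rownames(x), families = NULL) {
  x <- as.matrix(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  if (k >= nrow(x) - (ncol(x) + 1)) {
    stop("worst_k_exclusion: k too large for the number of proteins")
  }
  excluded <- character(0)
  keep <- rep(TRUE, nrow(x))
  for (step in seq_len(k)) {
    jk <- jackknife_tm(x[keep, , drop = FALSE], tm[keep], mode,
                       ids = ids[keep],
                       families = if (is.null(families)) NULL
                                  else families[keep])
    res <- abs(jk$residuals)
    worst <- names(res)[order(-res, names(res))[1]]
    excluded <- c(excluded, worst)
    keep[match(worst, ids)] <- FALSE
  }
  fit <- jackknife_tm(x[keep, , drop = FALSE], tm[keep], mode,
                      ids = ids[keep],
                      families = if (is.null(families)) NULL
                                 else families[keep])
  list(excluded = excluded, fit = fit)
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("tm_fit (%s%s): n = %d, sigma = %.2f C, r = %.3f\n",
              x$mode, if (x$cv) ", jack-knife" else "", x$n, x$sigma, x$r))
  if (!is.null(x$sigma_per_family)) {
    for (f in names(x$sigma_per_family)) {
      cat(sprintf("  %-24s sigma = %6.2f C (n = %d)\n", f,
                  x$sigma_per_family[[f]], sum(x$families == f)))
    }
  }
  invisible(x)
}

#' Per-protein prediction report
#'
#' @param fit a `tm_fit`.
#' @return data.frame with id, family, experimental and predicted Tm,
#'   and residual.
#' @export
prediction_report <- function(fit) {
  data.frame(id = fit$ids,
             family = if (is.null(fit$families)) NA_character_
                      else fit$families,
             tm_exp = as.numeric(fit$tm_exp),
             tm_pred = as.numeric(fit$predictions),
             residual = as.numeric(fit$residuals),
             stringsAsFactors = FALSE)
}
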