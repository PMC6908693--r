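#' @title Log-log regression machinery for density dependence
#' @description Helpers around ordinary least squares on log10-transformed
#'   series: outlier exclusion by studentized residual, simple fits,
#'   variance-inflation screening and backward elimination.
#' @name regress
NULL

new_regression_result <- function(fit, n, excluded = character(0)) {
  s <- summary(fit)
  coefs <- stats::coef(fit)
  fstat <- s$fstatistic
  if (is.null(fstat)) {            # intercept-only model
    fvalue <- NA_real_
    df <- c(0, stats::df.residual(fit))
    p <- NA_real_
  } else {
    fvalue <- unname(fstat[1])
    df <- unname(fstat[2:3])
    p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  }
  structure(list(
    coefficients = coefs,
    slope = if (length(coefs) == 2L) unname(coefs[2]) else NULL,
    intercept = unname(coefs[1]),
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    f_statistic = fvalue,
    df = df,
    p_value = unname(p),
    n = n,
    excluded = excluded,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Linear regression (n =", x$n, ")\n")
  print(round(x$coefficients, 4))
  cat(sprintf("adjusted R^2 = %.4f, F = %.2f on %g and %g df, p = %.3g\n",
              x$adj_r_squared, x$f_statistic, x$df[1], x$df[2], x$p_value))
  if (length(x$excluded) > 0) {
    cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Log10 transform with exclusion of non-positive values
#'
#' Quantities entering the log-log fits (densities, concentrations) are
#' strictly positive when detected; zeros or negatives are returned as
#' \code{NA} with a warning rather than offset.
#'
#' @param x Numeric vector.
#' @return log10(x) with \code{NA} where x <= 0.
#' @export
log10_clean <- function(x) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive value(s) excluded from log transform")
    x[bad] <- NA_real_
  }
  log10(x)
}

#' Exclude observations outside the 95 percent residual interval
#'
#' Fits a preliminary simple regression of y on x and drops observations
#' whose studentized residual magnitude exceeds the two-tailed 95 percent
#' normal bound (1.96 by default).
#'
#' @param x,y Paired numeric series (N >= 5 complete pairs).
#' @param bound Residual magnitude threshold.
#' @return List with \code{keep} (indices retained), \code{dropped}
#'   (indices removed), \code{labels_dropped} (names, when x has names)
#'   and \code{residuals} (studentized residuals of the preliminary fit,
#'   \code{NA} for incomplete pairs).
#' @export
exclude_outliers <- function(x, y, bound = 1.96) {
  complete <- which(!is.na(x) & !is.na(y))
  if (length(complete) < 5L) {
    stop("need at least 5 complete observations", call. = FALSE)
  }
  fit <- stats::lm(y[complete] ~ x[complete])
  rs <- stats::rstandard(fit)
  # an (effectively) exact fit has no outliers, only rounding noise
  if (summary(fit)$sigma < 1e-10 * max(stats::sd(y[complete]), 1e-300)) {
    rs[] <- 0
  }
  out <- abs(rs) > bound
  out[is.na(out)] <- FALSE          # zero-residual-variance fits
  res <- rep(NA_real_, length(x))
  res[complete] <- rs
  nm <- names(x)
  list(keep = complete[!out], dropped = complete[out],
       labels_dropped = if (!is.null(nm)) nm[complete[out]] else
         as.character(complete[out]),
       residuals = res)
}

#' Simple linear regression on (log-transformed) series
#'
#' Ordinary least squares of y on x with the usual one-predictor summary:
#' slope, intercept, adjusted R^2 = 1 - (1 - R^2)(N - 1)/(N - 2), F with
#' (1, N - 2) degrees of freedom and its two-tailed p-value. Incomplete
#' pairs are dropped.
#'
#' @param x,y Numeric series (callers pass log10-transformed data for
#'   log-log fits); N >= 3 complete pairs, x non-constant.
#' @param excluded Labels of observations removed beforehand (recorded in
#'   the result).
#' @return A \code{regression_result}.
#' @export
fit_simple <- function(x, y, excluded = character(0)) {
  complete <- !is.na(x) & !is.na(y)
  x <- x[complete]; y <- y[complete]
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  new_regression_result(fit, n = length(x), excluded = excluded)
}

#' Variance inflation factors
#'
#' VIF_k = 1 / (1 - R^2_k) where R^2_k comes from regressing predictor k
#' on all the others. Orthogonal predictors give exactly 1; perfect
#' collinearity gives +Inf.
#'
#' @param predictors Numeric matrix or data frame with >= 2 columns and
#'   more rows than columns.
#' @return Named numeric vector of VIFs.
#' @export
vif_table <- function(predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2L) stop("need at least 2 predictors", call. = FALSE)
  if (nrow(X) <= ncol(X)) {
    stop("need more observations than predictors", call. = FALSE)
  }
  out <- vapply(seq_along(X), function(k) {
    r2 <- summary(stats::lm(X[[k]] ~ ., data = X[-k]))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- names(X)
  out
}

#' Iterative VIF screen
#'
#' While any VIF exceeds \code{limit}, the predictor with the largest VIF
#' (infinite first) is removed and VIFs are recomputed.
#'
#' @param predictors Numeric matrix or data frame.
#' @param limit VIF threshold (default 10).
#' @return List with \code{kept} (data frame of surviving predictors),
#'   \code{dropped} (labels in removal order) and \code{vif} (final VIFs).
#' @export
vif_screen <- function(predictors, limit = 10) {
  X <- as.data.frame(predictors)
  dropped <- character(0)
  repeat {
    if (ncol(X) < 2L) {
      v <- if (ncol(X) == 1L) stats::setNames(1, names(X)) else numeric(0)
      return(list(kept = X, dropped = dropped, vif = v))
    }
    v <- vif_table(X)
    if (max(v) <= limit) return(list(kept = X, dropped = dropped, vif = v))
    worst <- names(v)[order(-v, names(v))][1]
    dropped <- c(dropped, worst)
    X <- X[, setdiff(names(X), worst), drop = FALSE]
  }
}

#' Backward elimination of non-significant predictors
#'
#' Iteratively refits the multiple regression, at each step dropping the
#' single least-significant predictor whose p-value exceeds \code{alpha}
#' (ties broken by larger p, then alphabetical label), until every
#' surviving predictor is significant. If all predictors fall, the
#' intercept-only model is returned with a warning.
#'
#' @param y Response series.
#' @param predictors Numeric matrix or data frame of candidate predictors.
#' @param alpha Significance threshold (default 0.05).
#' @return List with \code{result} (a \code{regression_result} for the
#'   final model) and \code{trace} (data frame: step, dropped predictor,
#'   its p-value at the drop, adjusted R^2 of the refitted model).
#' @export
backward_select <- function(y, predictors, alpha = 0.05) {
  X <- as.data.frame(predictors)
  names(X) <- make.names(names(X), unique = TRUE)
  complete <- stats::complete.cases(X) & !is.na(y)
  X <- X[complete, , drop = FALSE]
  y <- y[complete]
  if (nrow(X) <= ncol(X) + 1L) {
    stop("need N > number of predictors + 1", call. = FALSE)
  }
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_value = numeric(0), adj_r_squared = numeric(0),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (ncol(X) == 0L) {
      warning("all predictors eliminated; returning intercept-only model")
      fit <- stats::lm(y ~ 1)
      break
    }
    fit <- stats::lm(y ~ ., data = X)
    coefs <- summary(fit)$coefficients
    keep_rows <- rownames(coefs) != "(Intercept)"
    pv <- stats::setNames(coefs[keep_rows, "Pr(>|t|)"],
                          rownames(coefs)[keep_rows])
    aliased <- setdiff(names(X), names(pv))
    pv[aliased] <- 1                 # aliased predictors drop first
    pv[is.na(pv)] <- 1
    if (all(pv <= alpha)) break
    worst <- names(pv)[order(-pv, names(pv))][1]
    step <- step + 1L
    X <- X[, setdiff(names(X), worst), drop = FALSE]
    refit <- if (ncol(X) > 0L) stats::lm(y ~ ., data = X) else
      stats::lm(y ~ 1)
    trace <- rbind(trace, data.frame(
      step = step, dropped = worst, p_value = unname(pv[worst]),
      adj_r_squared = summary(refit)$adj.r.squared,
      stringsAsFactors = FALSE))
  }
  list(result = new_regression_result(fit, n = length(y)), trace = trace)
}

#' Multiple regression of a response on environmental covariates
#'
#' Convenience wrapper reproducing the covariate-model workflow: screen
#' the candidate predictors for multicollinearity (VIF > \code{vif_limit}
#' removed), then backward-eliminate non-significant predictors.
#'
#' @param y Response series (log-transformed by the caller).
#' @param predictors Data frame of candidate predictors (environmental
#'   series and density, aligned with y).
#' @param vif_limit VIF threshold for the screen.
#' @param alpha Backward-elimination significance level.
#' @return List with \code{result}, \code{trace}, \code{vif_dropped} and
#'   \code{vif}.
#' @export
fit_environment <- function(y, predictors, vif_limit = 10, alpha = 0.05) {
  screen <- vif_screen(predictors, limit = vif_limit)
  sel <- backward_select(y, screen$kept, alpha = alpha)
  list(result = sel$result, trace = sel$trace,
       vif_dropped = screen$dropped, vif = screen$vif)
}
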