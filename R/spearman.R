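#' @title Spearman rank correlation with an exact permutation test
#' @description Rank correlation between weekly abundance series, with a
#'   p-value either from full enumeration of all n! orderings (feasible
#'   for the short water-mass windows this pipeline works with) or from
#'   the usual t approximation with n - 2 degrees of freedom.
#' @name spearman
NULL

.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  if (n > 9L) stop("full enumeration limited to n <= 9", call. = FALSE)
  recurse <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    cols <- lapply(seq_along(v), function(k) {
      sub <- recurse(v[-k])
      rbind(matrix(v[k], 1, ncol(sub)), sub)
    })
    do.call(cbind, cols)
  }
  out <- recurse(seq_len(n))       # n x n! matrix, one ordering per column
  .perm_cache[[key]] <- out
  out
}

#' Spearman correlation and significance for one pair of series
#'
#' rho is the Pearson correlation of midranks (average ranks on ties).
#' With \code{method = "exact"} (available for n <= 9) the two-tailed
#' p-value is the exact proportion of all n! orderings of one series whose
#' |rho| is at least the observed |rho|; with \code{method = "t"} it comes
#' from t = rho * sqrt((n-2)/(1-rho^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric series (n >= 3).
#' @param method \code{"exact"} or \code{"t"}; \code{"auto"} picks exact
#'   for n <= \code{exact_n_max}.
#' @param exact_n_max Largest n for which \code{"auto"} enumerates.
#' @return List with \code{rho}, \code{p_value}, \code{n} and
#'   \code{method}; \code{rho} is \code{NA} when either series is
#'   constant.
#' @export
spearman_pair <- function(x, y, method = c("auto", "exact", "t"),
                          exact_n_max = 9L) {
  method <- match.arg(method)
  complete <- !is.na(x) & !is.na(y)
  x <- x[complete]; y <- y[complete]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  if (denom == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "none"))
  }
  rho <- sum(rxc * ryc) / denom
  if (method == "auto") method <- if (n <= exact_n_max) "exact" else "t"
  if (method == "exact") {
    perms <- all_permutations(n)
    # rho under every ordering of y against fixed x
    permuted <- matrix(ryc[perms], nrow = n)
    rho_all <- as.vector(crossprod(permuted, rxc)) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, method = method)
}
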