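#' Bray-Curtis dissimilarity between samples
#'
#' Computes pairwise Bray-Curtis dissimilarities between the samples
#' (columns) of an abundance matrix: d(j,k) = sum_i |x_ij - x_ik| /
#' sum_i (x_ij + x_ik). A pair of all-zero samples, where the formula is
#' undefined, is assigned distance 0 (identical emptiness).
#'
#' @param matrix Taxa x samples abundance matrix, non-negative.
#' @return A \code{dist} object with attribute \code{metric = "braycurtis"}.
#' @export
bray_curtis <- function(matrix) {
  check_abundance(matrix)
  # all-zero samples are legal here (distance defined as 0 below), so the
  # empty-row warning vegdist emits for them is spurious
  d <- suppressWarnings(vegan::vegdist(t(matrix), method = "bray"))
  d[is.nan(d)] <- 0
  attr(d, "metric") <- "braycurtis"
  d
}

#' Jaccard dissimilarity between samples
#'
#' With \code{binary = TRUE} (default) abundances are reduced to
#' presence/absence at > 0 and d(j,k) = 1 - |intersection|/|union| of the
#' present taxa. With \code{binary = FALSE} the quantitative Jaccard form
#' 2B/(1+B) (B = Bray-Curtis) is used, which coincides with the set form
#' on 0/1 data and remains defined for fractional entries such as
#' group-mean padding rows.
#'
#' @param matrix Taxa x samples abundance matrix, non-negative.
#' @param binary Reduce to presence/absence first?
#' @return A \code{dist} object with attribute \code{metric = "jaccard"}.
#' @export
jaccard <- function(matrix, binary = TRUE) {
  check_abundance(matrix)
  d <- suppressWarnings(
    vegan::vegdist(t(matrix), method = "jaccard", binary = binary))
  d[is.nan(d)] <- 0
  attr(d, "metric") <- "jaccard"
  d
}

check_abundance <- function(matrix) {
  if (any(matrix < 0, na.rm = TRUE)) {
    stop("abundance matrix contains negative entries", call. = FALSE)
  }
  if (is.null(colnames(matrix))) {
    stop("abundance matrix must have sample (column) names", call. = FALSE)
  }
  if (anyDuplicated(colnames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("taxa and sample labels must be unique", call. = FALSE)
  }
  invisible(matrix)
}

dist_pair_index <- function(n) {
  # row/column indices of the elements of a dist vector, in storage order
  j <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  list(i = i, j = j)
}

anosim_r <- function(ranks, within, n_within, m) {
  sum_w <- sum(ranks[within])
  sum_b <- sum(ranks) - sum_w
  (sum_b / (m - n_within) - sum_w / n_within) / (m / 2)
}

#' One-way analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All off-diagonal dissimilarities
#' are ranked (average ranks on ties) and R = (mean between-group rank -
#' mean within-group rank) / (M/2), M = n(n-1)/2. Significance is assessed
#' by permuting group labels. When the number of distinct label
#' arrangements does not exceed \code{permutations}, the null distribution
#' is enumerated completely and the p-value is the exact proportion of
#' arrangements (including the observed one) with R at least as large;
#' otherwise \code{permutations} random relabellings are drawn and p =
#' (1 + count) / (permutations + 1), so p is never zero.
#'
#' @param dist A \code{dist} of pairwise dissimilarities.
#' @param groups Group labels, one per sample; every group needs >= 2
#'   members and >= 2 groups are required.
#' @param permutations Number of random permutations (and the enumeration
#'   budget for the exact path).
#' @param seed Optional integer seed for the permutation draw.
#' @param pairwise Also run the test on every pair of groups?
#' @return An object of class \code{anosim_result}: list with elements
#'   \code{statistic} (R), \code{p_value}, \code{permutations},
#'   \code{exact} (logical), and when \code{pairwise = TRUE} a data frame
#'   \code{pairwise} of per-pair R and p.
#' @export
anosim_test <- function(dist, groups, permutations = 9999, seed = NULL,
                        pairwise = FALSE) {
  n <- attr(dist, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) {
    stop("groups must have one label per sample", call. = FALSE)
  }
  sizes <- table(droplevels(groups))
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("singleton groups are not allowed: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  if (permutations < 1) stop("permutations must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  res <- anosim_engine(dist, droplevels(groups), permutations)

  if (pairwise) {
    levs <- levels(droplevels(groups))
    combos <- utils::combn(levs, 2)
    rows <- apply(combos, 2, function(pr) {
      keep <- groups %in% pr
      sub <- as.dist(as.matrix(dist)[keep, keep])
      r <- anosim_engine(sub, droplevels(groups[keep]), permutations)
      data.frame(group_1 = pr[1], group_2 = pr[2],
                 R = r$statistic, p_value = r$p_value,
                 exact = r$exact, stringsAsFactors = FALSE)
    })
    res$pairwise <- do.call(rbind, rows)
  }
  class(res) <- "anosim_result"
  res
}

anosim_engine <- function(dist, groups, permutations) {
  n <- attr(dist, "Size")
  dv <- as.vector(dist)
  m <- length(dv)
  if (length(unique(dv)) == 1L) {
    warning("all dissimilarities are equal; R is 0 by construction")
  }
  ranks <- rank(dv)
  idx <- dist_pair_index(n)
  g <- as.integer(groups)
  within_obs <- g[idx$i] == g[idx$j]
  r_obs <- anosim_r(ranks, within_obs, sum(within_obs), m)

  counts <- table(g)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(counts + 1)))
  exact <- is.finite(n_distinct) && n_distinct <= permutations + 0.5

  if (exact) {
    labs <- multiset_permutations(rep(seq_along(counts), counts))
    r_perm <- apply(labs, 2, function(lab) {
      w <- lab[idx$i] == lab[idx$j]
      anosim_r(ranks, w, sum(w), m)
    })
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- ncol(labs)
  } else {
    r_perm <- vapply(seq_len(permutations), function(k) {
      lab <- sample(g)
      w <- lab[idx$i] == lab[idx$j]
      anosim_r(ranks, w, sum(w), m)
    }, numeric(1))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (permutations + 1)
    n_used <- permutations
  }
  list(statistic = r_obs, p_value = p, permutations = n_used, exact = exact)
}

multiset_permutations <- function(x) {
  # all distinct orderings of the multiset x, one per column
  x <- sort(x)
  n <- length(x)
  recurse <- function(remaining) {
    if (length(remaining) == 1L) return(matrix(remaining, 1))
    vals <- unique(remaining)
    cols <- lapply(vals, function(v) {
      rest <- remaining[-match(v, remaining)]
      sub <- recurse(rest)
      rbind(matrix(v, 1, ncol(sub)), sub)
    })
    do.call(cbind, cols)
  }
  recurse(x)
}

#' Pad groups to a balanced design with group-mean pseudo-samples
#'
#' Every group is padded to the size of the largest group by appending
#' synthetic samples equal to the group's taxon-wise mean, following the
#' missing-observation convention for balanced ANOSIM designs. Padding
#' never changes a group's taxon-wise mean. Padded samples are flagged so
#' they can be excluded from SIMPER reporting.
#'
#' @param matrix Taxa x samples abundance matrix.
#' @param groups Group labels, one per sample.
#' @return List with elements \code{matrix} (padded), \code{groups}
#'   (extended labels) and \code{padded} (logical flag per sample).
#' @export
balance_groups <- function(matrix, groups) {
  check_abundance(matrix)
  groups <- as.factor(groups)
  sizes <- table(droplevels(groups))
  if (any(sizes == 0L)) stop("empty group", call. = FALSE)
  target <- max(sizes)
  out <- matrix
  out_groups <- as.character(groups)
  padded <- rep(FALSE, ncol(matrix))
  for (gname in names(sizes)) {
    need <- target - sizes[[gname]]
    if (need == 0L) next
    mean_col <- rowMeans(matrix[, groups == gname, drop = FALSE])
    pad <- matrix(rep(mean_col, need), ncol = need,
                  dimnames = list(rownames(matrix),
                                  sprintf("pad_%s_%d", gname, seq_len(need))))
    out <- cbind(out, pad)
    out_groups <- c(out_groups, rep(gname, need))
    padded <- c(padded, rep(TRUE, need))
  }
  list(matrix = out, groups = factor(out_groups), padded = padded)
}

#' Similarity percentages (SIMPER) decomposition
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-taxon contributions: for each between-group sample pair, taxon i
#' contributes |x_ij - x_ik| / sum_s (x_sj + x_sk); contributions are
#' averaged over all between-group pairs and expressed as percentages of
#' their sum (which equals the average between-group dissimilarity).
#'
#' @param matrix Taxa x samples abundance matrix.
#' @param groups Group labels; with more than two groups every group pair
#'   is analysed.
#' @param exclude Optional logical flag per sample (e.g. the \code{padded}
#'   flag from [balance_groups()]); flagged samples are left out.
#' @return An object of class \code{simper_result}: a named list, one data
#'   frame per group pair, with columns \code{taxon}, \code{average},
#'   \code{percent} and \code{cumulative}, sorted by decreasing
#'   contribution (ties broken alphabetically).
#' @export
simper_analysis <- function(matrix, groups, exclude = NULL) {
  check_abundance(matrix)
  groups <- as.factor(groups)
  if (!is.null(exclude)) {
    matrix <- matrix[, !exclude, drop = FALSE]
    groups <- droplevels(groups[!exclude])
  }
  levs <- levels(droplevels(groups))
  if (length(levs) < 2L) stop("need at least 2 groups", call. = FALSE)
  combos <- utils::combn(levs, 2)
  out <- list()
  for (c_idx in seq_len(ncol(combos))) {
    g1 <- which(groups == combos[1, c_idx])
    g2 <- which(groups == combos[2, c_idx])
    contrib <- matrix(0, nrow(matrix), length(g1) * length(g2))
    p <- 0L
    for (j in g1) {
      for (k in g2) {
        p <- p + 1L
        denom <- sum(matrix[, j] + matrix[, k])
        contrib[, p] <- if (denom > 0) {
          abs(matrix[, j] - matrix[, k]) / denom
        } else {
          0
        }
      }
    }
    avg <- rowMeans(contrib)
    total <- sum(avg)
    percent <- if (total > 0) 100 * avg / total else rep(0, length(avg))
    ord <- order(-avg, rownames(matrix))
    df <- data.frame(taxon = rownames(matrix)[ord], average = avg[ord],
                     percent = percent[ord],
                     cumulative = cumsum(percent[ord]),
                     stringsAsFactors = FALSE)
    out[[paste(combos[, c_idx], collapse = "_vs_")]] <- df
  }
  class(out) <- "simper_result"
  out
}

#' Non-metric multidimensional scaling
#'
#' Kruskal's nMDS: iterative minimization of stress-1 with monotone
#' regression of configuration distances on dissimilarity ranks (via
#' [MASS::isoMDS()]), run from a classical-scaling start plus random
#' restarts; the best configuration over restarts is returned. Zero
#' off-diagonal dissimilarities (duplicate samples) are raised to a tiny
#' positive value so the monotone fit stays defined; such samples end up
#' near-coincident in the ordination.
#'
#' @param dist A \code{dist} of pairwise dissimilarities (>= 3 samples).
#' @param dims Embedding dimension (default 2).
#' @param restarts Number of random restarts in addition to the classical
#'   scaling start.
#' @param seed Optional integer seed.
#' @param maxit Maximum isoMDS iterations per start.
#' @return An object of class \code{nmds_result}: list with \code{points}
#'   (samples x dims), \code{stress} (Kruskal stress-1, on [0,1]),
#'   \code{converged}, and \code{restarts}.
#' @export
nmds <- function(dist, dims = 2, restarts = 20, seed = NULL, maxit = 300) {
  n <- attr(dist, "Size")
  if (n < 3L) stop("nMDS needs at least 3 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- dist
  pos <- d[d > 0]
  eps <- if (length(pos) > 0) min(pos) * 1e-4 else 1e-8
  d[d <= 0] <- eps

  best <- NULL
  starts <- vector("list", restarts + 1L)
  cmd <- stats::cmdscale(d, k = dims)
  if (ncol(cmd) < dims) {
    cmd <- cbind(cmd, matrix(stats::rnorm(n * (dims - ncol(cmd)),
                                          sd = 1e-4), n))
  }
  starts[[1L]] <- cmd
  for (r in seq_len(restarts)) {
    starts[[r + 1L]] <- matrix(stats::rnorm(n * dims), n, dims)
  }
  for (st in starts) {
    fit <- try(suppressWarnings(
      MASS::isoMDS(d, y = st, k = dims, maxit = maxit, trace = FALSE)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("nMDS failed from every start", call. = FALSE)
  rownames(best$points) <- labels(dist)
  structure(list(points = best$points, stress = best$stress / 100,
                 converged = TRUE, restarts = restarts),
            class = "nmds_result")
}
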