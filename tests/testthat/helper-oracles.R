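# Independent brute-force oracles used to verify the package's engines.
# These deliberately re-derive each quantity from first principles with
# base-R tools, sharing no code with the implementation under test.

# all orderings of 1..n, one per row (plain incremental insertion)
oracle_permutations <- function(n) {
  rows <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(rows) * k, k)
    r <- 0L
    for (i in seq_len(nrow(rows))) {
      for (pos in seq_len(k)) {
        r <- r + 1L
        out[r, ] <- append(rows[i, ], k, after = pos - 1L)
      }
    }
    rows <- out
  }
  rows
}

# exact two-sided Spearman permutation p by looping over all orderings
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rho_obs <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  perms <- oracle_permutations(n)
  rho_all <- apply(perms, 1, function(p) {
    suppressWarnings(stats::cor(x, y[p], method = "spearman"))
  })
  list(rho = rho_obs,
       p = mean(abs(rho_all) >= abs(rho_obs) - 1e-12))
}

# ANOSIM R recomputed from its definition
oracle_anosim_r <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  dv <- m[lower.tri(m)]
  ij <- which(lower.tri(m), arr.ind = TRUE)
  rk <- rank(dv)
  within <- labels[ij[, 1]] == labels[ij[, 2]]
  (mean(rk[!within]) - mean(rk[within])) / (length(dv) / 2)
}

# exact ANOSIM p for 2 groups by enumerating all membership subsets
oracle_anosim_exact_p <- function(d, labels) {
  labels <- as.character(labels)
  n <- length(labels)
  levs <- unique(labels)
  stopifnot(length(levs) == 2L)
  n1 <- sum(labels == levs[1])
  r_obs <- oracle_anosim_r(d, labels)
  subsets <- utils::combn(n, n1)
  r_all <- apply(subsets, 2, function(idx) {
    lab <- rep(levs[2], n)
    lab[idx] <- levs[1]
    oracle_anosim_r(d, lab)
  })
  mean(r_all >= r_obs - 1e-12)
}

# all set partitions of 1..n as restricted growth strings (block labels)
oracle_partitions <- function(n) {
  out <- list()
  grow <- function(code, maxblock) {
    k <- length(code)
    if (k == n) {
      out[[length(out) + 1L]] <<- code
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L)) {
      grow(c(code, b), max(maxblock, b))
    }
  }
  grow(1L, 1L)
  out
}

# Newman modularity of a partition, from the definition
oracle_modularity <- function(edges_mat, membership) {
  m <- nrow(edges_mat)
  deg <- table(factor(c(edges_mat[, 1], edges_mat[, 2]),
                      levels = seq_along(membership)))
  same <- membership[edges_mat[, 1]] == membership[edges_mat[, 2]]
  q <- sum(same) / m
  for (b in unique(membership)) {
    db <- sum(deg[membership == b])
    q <- q - (db / (2 * m))^2
  }
  q
}

# maximum modularity over every partition (n <= 8 nodes)
oracle_max_modularity <- function(edges_mat, n) {
  parts <- oracle_partitions(n)
  max(vapply(parts, function(p) oracle_modularity(edges_mat, p),
             numeric(1)))
}

# Kruskal stress-1 of a configuration against given dissimilarities,
# with isotonic regression done by stats::isoreg
oracle_stress1 <- function(coords, diss) {
  d <- as.vector(stats::dist(coords))
  dv <- as.vector(diss)
  ord <- order(dv)
  fit <- stats::isoreg(d[ord])$yf
  sqrt(sum((d[ord] - fit)^2) / sum(d^2))
}

# small helper: a labelled taxa x samples matrix from a plain matrix
as_abund <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

# a tiny edge data frame in the shape spearman_edges() emits
make_edges <- function(pairs, rho = 0.9, p = 0.001, period = "period_1") {
  data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2],
             rho = rho, p_value = p,
             sign = ifelse(rho > 0, "positive", "negative"),
             period = period, n_weeks = 7L, low_support = FALSE,
             stringsAsFactors = FALSE)
}
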