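#' Detect water-mass windows from a weekly salinity series
#'
#' A water-mass window is a run of at least \code{min_len} consecutive
#' sampled weeks whose salinity spread (max - min) does not exceed
#' 2 * \code{tolerance} -- the persistence-of-the-same-water-mass
#' criterion. Candidate runs are taken maximal, then selected greedily
#' longest-first (ties by earlier start) so returned windows never
#' overlap. The default tolerance of 0.15 PSU accepts the widest
#' half-range typically seen in such windows (about 0.12 PSU).
#'
#' @param env Either a data frame with columns \code{week} and
#'   \code{salinity} (and optionally \code{sample}) or a numeric salinity
#'   vector (weeks assumed consecutive). Missing salinity breaks a run.
#' @param tolerance Salinity half-range tolerance in PSU.
#' @param min_len Minimum window length in weeks (default 3).
#' @return List of \code{water_mass_window} objects: each a list with
#'   \code{label}, \code{weeks} (week numbers), \code{samples} (sample
#'   labels), \code{salinity_mean} and \code{salinity_half_range}.
#' @export
detect_water_masses <- function(env, tolerance = 0.15, min_len = 3L) {
  if (is.data.frame(env)) {
    if (!all(c("week", "salinity") %in% names(env))) {
      stop("env must have 'week' and 'salinity' columns", call. = FALSE)
    }
    week <- env$week
    sal <- env$salinity
    sample <- if ("sample" %in% names(env)) env$sample else
      as.character(week)
  } else {
    sal <- as.numeric(env)
    week <- seq_along(sal)
    sample <- as.character(week)
  }
  if (length(sal) == 0L) stop("empty salinity series", call. = FALSE)
  ord <- order(week)
  week <- week[ord]; sal <- sal[ord]; sample <- sample[ord]

  ok <- !is.na(sal)
  candidates <- list()
  for (start in seq_along(sal)) {
    if (!ok[start]) next
    end <- start
    while (end < length(sal) && ok[end + 1L] &&
           week[end + 1L] == week[end] + 1L &&
           diff(range(sal[start:(end + 1L)])) <= 2 * tolerance) {
      end <- end + 1L
    }
    if (end - start + 1L >= min_len) {
      candidates[[length(candidates) + 1L]] <- c(start = start, end = end)
    }
  }
  if (length(candidates) == 0L) return(list())
  cand <- do.call(rbind, candidates)
  cand <- cand[order(-(cand[, "end"] - cand[, "start"]), cand[, "start"]),
               , drop = FALSE]
  taken <- rep(FALSE, length(sal))
  windows <- list()
  for (r in seq_len(nrow(cand))) {
    span <- cand[r, "start"]:cand[r, "end"]
    if (any(taken[span])) next
    taken[span] <- TRUE
    s <- sal[span]
    windows[[length(windows) + 1L]] <- structure(list(
      label = "",
      weeks = week[span],
      samples = sample[span],
      salinity_mean = mean(s),
      salinity_half_range = diff(range(s)) / 2
    ), class = "water_mass_window")
  }
  windows <- windows[order(vapply(windows, function(w) min(w$weeks),
                                  numeric(1)))]
  for (k in seq_along(windows)) {
    windows[[k]]$label <- sprintf("period_%d", k)
  }
  windows
}

#' Infer significant Spearman co-variation edges within a window
#'
#' For every pair of taxa observed in the window (taxa that are all-zero
#' across the window weeks are skipped), computes the Spearman rank
#' correlation of their abundance series and keeps pairs with
#' |rho| >= \code{rho_min} and p < \code{alpha}. Significance defaults to
#' the t approximation because exact enumeration can never reach p < 0.05
#' for the 3-week windows common in this design; edges from windows
#' shorter than 5 weeks are flagged \code{low_support}. Pairs where either
#' series is constant within the window are skipped and counted.
#'
#' @param abundance Taxa x weeks matrix.
#' @param window A \code{water_mass_window} (or a character vector of
#'   sample labels).
#' @param rho_min Absolute correlation threshold (default 0.7).
#' @param alpha Significance threshold (default 0.05).
#' @param p_method \code{"t"} (default), \code{"exact"} or \code{"auto"}
#'   (see [spearman_pair()]).
#' @return Data frame of edges: \code{taxon_a}, \code{taxon_b},
#'   \code{rho}, \code{p_value}, \code{sign}, \code{period},
#'   \code{n_weeks}, \code{low_support}; attributes \code{n_skipped_zero}
#'   and \code{n_skipped_constant}.
#' @export
spearman_edges <- function(abundance, window, rho_min = 0.7, alpha = 0.05,
                           p_method = c("t", "exact", "auto")) {
  p_method <- match.arg(p_method)
  if (inherits(window, "water_mass_window")) {
    samples <- window$samples
    label <- window$label
  } else {
    samples <- as.character(window)
    label <- "period_1"
  }
  samples <- intersect(samples, colnames(abundance))
  if (length(samples) < 3L) {
    stop("window must cover at least 3 sampled weeks", call. = FALSE)
  }
  sub <- abundance[, samples, drop = FALSE]
  nonzero <- rowSums(sub) > 0
  n_skipped_zero <- sum(!nonzero)
  sub <- sub[nonzero, , drop = FALSE]
  taxa <- rownames(sub)
  n <- ncol(sub)

  rows <- list()
  n_skipped_constant <- 0L
  if (length(taxa) >= 2L) {
    for (a in seq_len(length(taxa) - 1L)) {
      for (b in (a + 1L):length(taxa)) {
        sp <- spearman_pair(sub[a, ], sub[b, ], method = p_method)
        if (is.na(sp$rho)) {
          n_skipped_constant <- n_skipped_constant + 1L
          next
        }
        if (abs(sp$rho) >= rho_min - 1e-12 && sp$p_value < alpha) {
          rows[[length(rows) + 1L]] <- data.frame(
            taxon_a = taxa[a], taxon_b = taxa[b],
            rho = sp$rho, p_value = sp$p_value,
            sign = if (sp$rho > 0) "positive" else "negative",
            period = label, n_weeks = n, low_support = n < 5L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(taxon_a = character(0), taxon_b = character(0),
               rho = numeric(0), p_value = numeric(0),
               sign = character(0), period = character(0),
               n_weeks = integer(0), low_support = logical(0),
               stringsAsFactors = FALSE)
  attr(edges, "n_skipped_zero") <- n_skipped_zero
  attr(edges, "n_skipped_constant") <- n_skipped_constant
  attr(edges, "rho_min") <- rho_min
  attr(edges, "alpha") <- alpha
  edges
}

#' Assemble a co-variation network from edge records
#'
#' Nodes are the supplied taxa (integer ids in list order); edges are the
#' significant Spearman co-variations. A pair significant in several
#' periods collapses to a single edge represented by its strongest
#' correlation (largest |rho|, with that period's p-value and sign, so
#' every stored edge keeps satisfying the inference thresholds); the
#' \code{period} field lists all source periods and
#' \code{sign_consistent} records whether the sign agreed across them.
#' Isolated taxa are retained as module-less nodes. Positive and negative
#' degrees are tallied separately.
#'
#' @param edges Edge data frame from [spearman_edges()] (possibly several
#'   windows' results row-bound together).
#' @param taxa Character vector of all node taxa.
#' @return An object of class \code{covariation_network}: list with
#'   \code{nodes} (taxon, id, degree, pos_degree, neg_degree, module),
#'   \code{edges} (merged edge records) and \code{modularity}
#'   (\code{NA} until [find_modules()] is run).
#' @export
build_network <- function(edges, taxa) {
  if (nrow(edges) > 0) {
    bad <- !(edges$taxon_a %in% taxa) | !(edges$taxon_b %in% taxa)
    if (any(bad)) stop("edge taxa missing from taxa list", call. = FALSE)
    if (any(edges$taxon_a == edges$taxon_b)) {
      stop("self-edges are not allowed", call. = FALSE)
    }
    a <- pmin(edges$taxon_a, edges$taxon_b)
    b <- pmax(edges$taxon_a, edges$taxon_b)
    key <- paste(a, b, sep = "\r")
    merged <- lapply(split(seq_len(nrow(edges)), key), function(ii) {
      e <- edges[ii, , drop = FALSE]
      top <- which.max(abs(e$rho))
      data.frame(
        taxon_a = min(e$taxon_a[1], e$taxon_b[1]),
        taxon_b = max(e$taxon_a[1], e$taxon_b[1]),
        rho = e$rho[top],
        p_value = e$p_value[top],
        sign = if (e$rho[top] > 0) "positive" else "negative",
        period = paste(sort(unique(e$period)), collapse = ";"),
        n_periods = length(unique(e$period)),
        sign_consistent = length(unique(e$sign)) == 1L,
        low_support = any(e$low_support),
        stringsAsFactors = FALSE)
    })
    medges <- do.call(rbind, merged)
    rownames(medges) <- NULL
    medges <- medges[order(medges$taxon_a, medges$taxon_b), , drop = FALSE]
  } else {
    medges <- data.frame(taxon_a = character(0), taxon_b = character(0),
                         rho = numeric(0), p_value = numeric(0),
                         sign = character(0), period = character(0),
                         n_periods = integer(0),
                         sign_consistent = logical(0),
                         low_support = logical(0),
                         stringsAsFactors = FALSE)
  }
  pos <- medges$sign == "positive"
  count_deg <- function(sel) {
    tab <- table(factor(c(medges$taxon_a[sel], medges$taxon_b[sel]),
                        levels = taxa))
    as.integer(tab)
  }
  nodes <- data.frame(
    taxon = taxa, id = seq_along(taxa),
    pos_degree = count_deg(pos), neg_degree = count_deg(!pos),
    stringsAsFactors = FALSE)
  nodes$degree <- nodes$pos_degree + nodes$neg_degree
  nodes$module <- NA_integer_
  structure(list(nodes = nodes, edges = medges, modularity = NA_real_),
            class = "covariation_network")
}

#' @export
print.covariation_network <- function(x, ...) {
  n_conn <- sum(x$nodes$degree > 0)
  cat("Co-variation network:", nrow(x$nodes), "nodes (", n_conn,
      "connected ),", nrow(x$edges), "edges (",
      sum(x$edges$sign == "positive"), "positive /",
      sum(x$edges$sign == "negative"), "negative )\n")
  if (!is.na(x$modularity)) {
    cat("modules:", length(unique(stats::na.omit(x$nodes$module))),
        " modularity Q =", round(x$modularity, 4), "\n")
  }
  invisible(x)
}

#' Audit that every stored edge meets the inference thresholds
#'
#' @param network A \code{covariation_network}.
#' @param rho_min,alpha Thresholds the edges must satisfy.
#' @return \code{TRUE} (invisibly) if all edges satisfy
#'   |rho| >= rho_min and p < alpha; otherwise an error.
#' @export
audit_edges <- function(network, rho_min = 0.7, alpha = 0.05) {
  e <- network$edges
  bad <- abs(e$rho) < rho_min - 1e-12 | e$p_value >= alpha
  if (any(bad)) {
    stop(sum(bad), " edge(s) violate the inference thresholds",
         call. = FALSE)
  }
  invisible(TRUE)
}
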