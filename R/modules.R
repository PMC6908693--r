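#' Detect modules by modularity maximization on positive edges
#'
#' Maximizes Newman modularity on the positive-edge subgraph with unit
#' weights; negative edges are kept in the network for degree tallies and
#' annotation but do not enter the modularity objective, which is
#' ill-defined for signed graphs. Graphs with at most
#' \code{exact_max_nodes} connected nodes are solved exactly by
#' enumerating all set partitions (the same guaranteed-exact-at-small-n,
#' heuristic-at-large-n split used for the Spearman permutation test).
#' Larger graphs use greedy multilevel (Louvain) maximization with random
#' restarts, each restart post-refined by single-node moves and
#' community-pair merges, keeping the best Q over restarts. Nodes without
#' positive edges stay module-less (\code{NA}). Module labels are
#' integers starting at 0, ordered by decreasing module size (ties by
#' smallest node id), and are deterministic given the seed.
#'
#' @param network A \code{covariation_network}.
#' @param seed Integer seed for the restart randomization.
#' @param resolution Resolution parameter of the modularity objective
#'   (1 = classic modularity).
#' @param restarts Number of Louvain restarts.
#' @param exact_max_nodes Largest connected-node count solved by exact
#'   partition enumeration (Bell numbers grow quickly; the default 10
#'   keeps enumeration around 1e5 partitions).
#' @return The network with \code{nodes$module} filled in and
#'   \code{modularity} set to the achieved Q.
#' @export
find_modules <- function(network, seed = 1L, resolution = 1,
                         restarts = 20L, exact_max_nodes = 10L) {
  pos <- network$edges[network$edges$sign == "positive", , drop = FALSE]
  nodes <- network$nodes
  if (nrow(pos) == 0L) {
    network$nodes$module <- seq_len(nrow(nodes)) - 1L
    network$modularity <- 0
    return(network)
  }
  g <- igraph::graph_from_data_frame(
    pos[, c("taxon_a", "taxon_b")], directed = FALSE,
    vertices = data.frame(name = nodes$taxon[
      nodes$taxon %in% c(pos$taxon_a, pos$taxon_b)]))

  if (igraph::gorder(g) <= exact_max_nodes) {
    best <- exact_best_partition(g, resolution)
    best_member <- best$membership
    best_q <- best$q
  } else {
    set.seed(seed)
    best_q <- -Inf
    best_member <- NULL
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = resolution)
      memb <- refine_partition(g, igraph::membership(cl), resolution)
      q <- igraph::modularity(g, memb, resolution = resolution)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_member <- memb
      }
    }
  }
  names(best_member) <- igraph::V(g)$name

  # relabel modules 0,1,2,... by decreasing size, ties by smallest node id
  taxa_in <- names(best_member)
  ids <- nodes$id[match(taxa_in, nodes$taxon)]
  sizes <- table(best_member)
  first_id <- tapply(ids, best_member, min)
  ord <- order(-as.integer(sizes[names(first_id)]), first_id)
  relabel <- stats::setNames(seq_along(ord) - 1L, names(first_id)[ord])
  module <- relabel[as.character(best_member)]
  network$nodes$module <- NA_integer_
  network$nodes$module[match(taxa_in, network$nodes$taxon)] <-
    as.integer(module)
  network$modularity <- best_q
  network
}

# exact maximization by enumerating all set partitions (restricted growth
# strings); feasible for graphs with ~10 connected nodes or fewer
exact_best_partition <- function(g, resolution) {
  n <- igraph::gorder(g)
  em <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(em)
  deg <- igraph::degree(g)
  best_q <- -Inf
  best <- rep(1L, n)
  code <- integer(n)
  recurse <- function(k, maxblock) {
    if (k > n) {
      same <- code[em[, 1]] == code[em[, 2]]
      dsum <- tapply(deg, code[seq_len(n)], sum)
      q <- sum(same) / m - resolution * sum((dsum / (2 * m))^2)
      if (q > best_q) {
        best_q <<- q
        best <<- code[seq_len(n)]
      }
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L)) {
      code[k] <<- b
      recurse(k + 1L, max(maxblock, b))
    }
  }
  code[1] <- 1L
  recurse(2L, 1L)
  list(membership = best, q = best_q)
}

# greedy post-refinement: single-node moves between (neighbouring or new)
# communities, then community-pair merges, until neither improves Q; lifts
# Louvain solutions off the occasional aggregation plateau
refine_partition <- function(g, memb, resolution) {
  memb <- as.integer(as.factor(memb))
  q <- igraph::modularity(g, memb, resolution = resolution)
  n <- igraph::gorder(g)
  adj <- igraph::as_adj_list(g)
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      cands <- unique(c(memb[as.integer(adj[[v]])], max(memb) + 1L))
      cands <- setdiff(cands, memb[v])
      for (cc in cands) {
        trial <- memb
        trial[v] <- cc
        tq <- igraph::modularity(g, trial, resolution = resolution)
        if (tq > q + 1e-12) {
          memb <- as.integer(as.factor(trial))
          q <- tq
          improved <- TRUE
          break
        }
      }
    }
    comms <- unique(memb)
    if (length(comms) > 1L) {
      for (a in comms) {
        for (b in comms) {
          if (a >= b) next
          trial <- memb
          trial[trial == b] <- a
          tq <- igraph::modularity(g, trial, resolution = resolution)
          if (tq > q + 1e-12) {
            memb <- as.integer(as.factor(trial))
            q <- tq
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) return(memb)
  }
}
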