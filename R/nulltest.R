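#' Annotate network edges with mean per-cell LOFA production
#'
#' Each edge carries, for each fatty-acid precursor class (HTrA-, EPA-,
#' DHA-derived), the mean fg/cell production over the weeks of the edge's
#' source period (missing weeks skipped). An edge significant in several
#' periods carries the across-period mean of the period means.
#'
#' @param network A \code{covariation_network} (or an edge data frame with
#'   a \code{period} column).
#' @param profile A \code{lofa_profile} with \code{fgcell.<class>} columns
#'   and a \code{sample} column covering the window weeks.
#' @param windows List of \code{water_mass_window} objects covering every
#'   period named by the edges.
#' @param classes Precursor classes to annotate.
#' @return The network (or edge table) with added columns
#'   \code{<class>_fgcell}; edges whose annotation is entirely missing are
#'   flagged in \code{annotation_missing}.
#' @export
annotate_edges <- function(network, profile, windows,
                           classes = c("HTrA", "EPA", "DHA")) {
  is_net <- inherits(network, "covariation_network")
  edges <- if (is_net) network$edges else network
  wl <- stats::setNames(windows,
                        vapply(windows, `[[`, character(1), "label"))
  cols <- paste0("fgcell.", classes)
  missing_cols <- setdiff(cols, names(profile))
  if (length(missing_cols) > 0) {
    stop("profile lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  period_mean <- function(period, col) {
    if (!period %in% names(wl)) {
      stop("edge refers to unknown period '", period, "'", call. = FALSE)
    }
    vals <- profile[[col]][profile$sample %in% wl[[period]]$samples]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  for (k in seq_along(classes)) {
    edges[[paste0(tolower(classes[k]), "_fgcell")]] <-
      vapply(edges$period, function(p) {
        per <- strsplit(p, ";", fixed = TRUE)[[1]]
        m <- vapply(per, period_mean, numeric(1), col = cols[k])
        if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
      }, numeric(1))
  }
  ann_cols <- paste0(tolower(classes), "_fgcell")
  edges$annotation_missing <-
    rowSums(!is.na(edges[, ann_cols, drop = FALSE])) == 0
  if (is_net) {
    network$edges <- edges
    network
  } else {
    edges
  }
}

#' Module-wise null test of LOFA annotation enrichment
#'
#' Tests, per module, whether the mean per-cell production annotating its
#' intra-module edges differs from a null in which annotations are
#' randomly reshuffled among modules. The observed sample is the class
#' annotation of the module's intra-module edges (size n1). The null
#' sample pools, over \code{reshuffles} random permutations of all
#' intra-module edge annotations across modules, the values landing on
#' this module, then subsamples n2 = n1 of them. An F-test for variance
#' equality at the 0.05 level decides between the pooled-variance t-test
#' (df = n1 + n2 - 2) and Welch's t-test. Each reshuffle is a permutation
#' of the pooled annotations, so the annotation multiset is conserved
#' exactly.
#'
#' @param network An annotated \code{covariation_network} with modules
#'   assigned (see [find_modules()] and [annotate_edges()]).
#' @param class_label Precursor class to test (\code{"HTrA"},
#'   \code{"EPA"} or \code{"DHA"}).
#' @param reshuffles Number of reshuffled null networks (default 1000).
#' @param seed Integer seed.
#' @return Data frame with one row per testable module: \code{module},
#'   \code{class}, \code{n1}, \code{n2}, \code{observed_mean},
#'   \code{null_mean}, \code{t}, \code{df}, \code{p_value},
#'   \code{f_test_p}, \code{pooled_variance}, \code{reshuffles},
#'   \code{seed}. Modules with fewer than 2 intra-module edges are
#'   skipped and listed in the \code{skipped_modules} attribute; the
#'   \code{first_reshuffle} attribute records one full reshuffled
#'   assignment for auditing multiset conservation.
#' @export
null_module_test <- function(network, class_label = c("HTrA", "EPA", "DHA"),
                             reshuffles = 1000L, seed = 1L) {
  class_label <- match.arg(class_label)
  col <- paste0(tolower(class_label), "_fgcell")
  edges <- network$edges
  if (!col %in% names(edges)) {
    stop("network edges lack annotation column '", col,
         "'; run annotate_edges first", call. = FALSE)
  }
  nodes <- network$nodes
  mod_of <- stats::setNames(nodes$module, nodes$taxon)
  ma <- mod_of[edges$taxon_a]
  mb <- mod_of[edges$taxon_b]
  intra <- !is.na(ma) & !is.na(mb) & ma == mb & !is.na(edges[[col]])
  if (!any(intra)) stop("no intra-module edges to test", call. = FALSE)
  module <- ma[intra]
  values <- edges[[col]][intra]
  pool_modules <- sort(unique(module))
  sizes <- table(factor(module, levels = pool_modules))
  testable <- names(sizes)[sizes >= 2L]
  skipped <- setdiff(names(sizes), testable)
  if (length(testable) < 2L) {
    stop("need at least 2 modules with >= 2 intra-module edges",
         call. = FALSE)
  }

  set.seed(seed)
  null_by_module <- stats::setNames(
    lapply(testable, function(m) vector("list", reshuffles)), testable)
  first_reshuffle <- NULL
  for (r in seq_len(reshuffles)) {
    shuffled <- sample(values)
    if (r == 1L) first_reshuffle <- shuffled
    for (m in testable) {
      null_by_module[[m]][[r]] <- shuffled[module == as.integer(m)]
    }
  }

  rows <- lapply(testable, function(m) {
    obs <- values[module == as.integer(m)]
    n1 <- length(obs)
    pool_null <- unlist(null_by_module[[m]], use.names = FALSE)
    null_sub <- sample(pool_null, n1)
    n2 <- n1
    v1 <- stats::var(obs); v2 <- stats::var(null_sub)
    if (v1 == 0 && v2 == 0) {
      f_p <- 1
      pooled <- TRUE
      tt <- 0
      df <- n1 + n2 - 2
      p <- if (isTRUE(all.equal(mean(obs), mean(null_sub)))) 1 else 0
    } else {
      f_p <- stats::var.test(obs, null_sub)$p.value
      pooled <- f_p >= 0.05
      ht <- stats::t.test(obs, null_sub, var.equal = pooled)
      tt <- unname(ht$statistic)
      df <- unname(ht$parameter)
      p <- ht$p.value
    }
    data.frame(module = as.integer(m), class = class_label,
               n1 = n1, n2 = n2,
               observed_mean = mean(obs), null_mean = mean(null_sub),
               t = tt, df = df, p_value = p, f_test_p = f_p,
               pooled_variance = pooled,
               reshuffles = reshuffles, seed = seed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped_modules") <- as.integer(skipped)
  attr(out, "first_reshuffle") <- first_reshuffle
  attr(out, "pool") <- values
  out
}

#' Export a co-variation network
#'
#' Writes the network as an edge-list CSV (taxon pair, rho, p, sign,
#' period, per-class annotations when present, endpoint modules), a node
#' table CSV (taxon, node id, module, degrees) and, optionally, GraphML.
#'
#' @param network A \code{covariation_network}.
#' @param edge_csv,node_csv,graphml Output paths (\code{NULL} skips).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, edge_csv = NULL, node_csv = NULL,
                           graphml = NULL) {
  written <- character(0)
  edges <- network$edges
  nodes <- network$nodes
  mod_of <- stats::setNames(nodes$module, nodes$taxon)
  edges$module_a <- unname(mod_of[edges$taxon_a])
  edges$module_b <- unname(mod_of[edges$taxon_b])
  if (!is.null(edge_csv)) {
    utils::write.csv(edges, edge_csv, row.names = FALSE)
    written <- c(written, edge_csv)
  }
  if (!is.null(node_csv)) {
    utils::write.csv(nodes, node_csv, row.names = FALSE)
    written <- c(written, node_csv)
  }
  if (!is.null(graphml)) {
    vert <- nodes[, c("taxon", "id", "module", "degree",
                      "pos_degree", "neg_degree")]
    # GraphML reserves the vertex attribute name "id"
    names(vert)[names(vert) == "id"] <- "node_id"
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = vert)
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  invisible(written)
}
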