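test_that("water-mass detection handles flat, noisy and degenerate series", {
  # constant salinity: one window spanning everything
  w <- detect_water_masses(rep(38, 10), tolerance = 0.15)
  expect_length(w, 1)
  expect_equal(w[[1]]$weeks, 1:10)
  # zero tolerance on a strictly varying series: nothing
  expect_length(detect_water_masses(38 + (1:10) / 10, tolerance = 0), 0)
  expect_error(detect_water_masses(numeric(0)), "empty")
  # a gap in sampling breaks a run
  env <- data.frame(week = c(1:4, 6:9), salinity = 38)
  w2 <- detect_water_masses(env, tolerance = 0.1)
  expect_length(w2, 2)
  expect_equal(w2[[1]]$weeks, 1:4)
  expect_equal(w2[[2]]$weeks, 6:9)
})

test_that("longest-first selection returns non-overlapping maximal windows", {
  sal <- c(38, 38.01, 38.02, 38.5, 38.5, 38.5, 38.51, 36, 39, 36.2)
  w <- detect_water_masses(sal, tolerance = 0.05)
  expect_length(w, 2)
  expect_equal(w[[1]]$weeks, 1:3)
  expect_equal(w[[2]]$weeks, 4:7)
  expect_lte(w[[2]]$salinity_half_range, 0.05)
})

test_that("exact Spearman p equals brute force over all orderings", {
  set.seed(42)
  for (n in 4:7) {
    for (rep in 1:3) {
      x <- rnorm(n)
      y <- 0.5 * x + rnorm(n)
      got <- spearman_pair(x, y, method = "exact")
      want <- oracle_spearman_exact(x, y)
      expect_equal(got$rho, want$rho, tolerance = 1e-12)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
    }
  }
  # tied data as well (midranks)
  x <- c(1, 1, 2, 3, 4, 4, 5)
  y <- c(2, 3, 3, 5, 4, 6, 6)
  got <- spearman_pair(x, y, method = "exact")
  want <- oracle_spearman_exact(x, y)
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
})

test_that("a perfect 3-week correlation cannot reach significance exactly", {
  got <- spearman_pair(c(1, 2, 3), c(10, 20, 30), method = "exact")
  expect_equal(got$rho, 1)
  expect_equal(got$p_value, 1 / 3)   # 2 of the 6 orderings tie |rho| = 1
})

test_that("identical series give rho 1 and constant series are skipped", {
  x <- c(3, 1, 4, 1, 5, 9, 2)
  expect_equal(spearman_pair(x, x * 2 + 1)$rho, 1)
  got <- spearman_pair(x, rep(5, 7))
  expect_true(is.na(got$rho))
})

test_that("edge inference applies thresholds and flags short windows", {
  set.seed(3)
  base <- cumsum(rnorm(7)) + 10
  m <- as_abund(rbind(
    a = base, b = base * 2, c = rev(base) + 0.1,
    d = rnorm(7) * 0.01 + 5, e = rep(0, 7)))
  colnames(m) <- paste0("w", 1:7)
  edges <- spearman_edges(m, colnames(m), rho_min = 0.7, alpha = 0.05)
  # a-b perfectly correlated; a-c / b-c strongly anti-correlated
  key <- paste(edges$taxon_a, edges$taxon_b)
  expect_true("a b" %in% key)
  expect_equal(edges$sign[key == "a b"], "positive")
  expect_true(all(abs(edges$rho) >= 0.7))
  expect_true(all(edges$p_value < 0.05))
  expect_true(all(!edges$low_support))   # 7-week window
  expect_equal(attr(edges, "n_skipped_zero"), 1L)   # taxon e
  # 3-week window: edges flagged low-support under the t default
  m3 <- m[1:3, 1:3]
  e3 <- spearman_edges(as_abund(m3), colnames(m3))
  if (nrow(e3) > 0) expect_true(all(e3$low_support))
})

test_that("network assembly merges duplicate pairs and keeps isolated nodes", {
  taxa <- c("t1", "t2", "t3", "t4")
  e1 <- make_edges(cbind(c("t1", "t2"), c("t2", "t3")), rho = 0.9)
  e2 <- make_edges(cbind("t2", "t1"), rho = 0.8, period = "period_2")
  net <- build_network(rbind(e1, e2), taxa)
  expect_equal(nrow(net$edges), 2)
  merged <- net$edges[net$edges$taxon_a == "t1", ]
  expect_equal(merged$rho, 0.9)          # strongest period wins
  expect_equal(merged$period, "period_1;period_2")
  expect_equal(merged$n_periods, 2L)
  expect_true(merged$sign_consistent)
  # degree bookkeeping: sum of degrees = 2 x edges; t4 isolated
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  expect_equal(net$nodes$degree[net$nodes$taxon == "t4"], 0)
  expect_equal(net$nodes$pos_degree + net$nodes$neg_degree,
               net$nodes$degree)
  expect_error(build_network(make_edges(cbind("t1", "t1")), taxa), "self")
  expect_error(build_network(make_edges(cbind("t1", "zz")), taxa),
               "missing")
})

test_that("a triangle gives degree 2 everywhere", {
  taxa <- c("a", "b", "c")
  net <- build_network(
    make_edges(cbind(c("a", "b", "a"), c("b", "c", "c"))), taxa)
  expect_equal(net$nodes$degree, c(2L, 2L, 2L))
  expect_equal(sum(net$nodes$degree), 6L)
})

test_that("two disjoint cliques split into two modules with closed-form Q", {
  taxa <- paste0("n", 1:10)
  cl1 <- t(utils::combn(taxa[1:5], 2))
  cl2 <- t(utils::combn(taxa[6:10], 2))
  net <- build_network(make_edges(rbind(cl1, cl2)), taxa)
  net <- find_modules(net, seed = 1)
  mods <- net$nodes$module
  expect_equal(length(unique(mods)), 2)
  expect_length(unique(mods[1:5]), 1)
  expect_length(unique(mods[6:10]), 1)
  # two equal disconnected cliques: Q = 2 * (1/2 - 1/4) = 1/2
  expect_equal(net$modularity, 0.5, tolerance = 1e-12)
  # a single clique collapses to one module
  net1 <- find_modules(build_network(make_edges(cl1), taxa[1:5]), seed = 1)
  expect_equal(length(unique(net1$nodes$module)), 1)
})

test_that("module search matches exhaustive modularity maximization on small graphs", {
  set.seed(8)
  n_graphs <- 20
  for (g in seq_len(n_graphs)) {
    n <- sample(4:8, 1)
    p <- runif(1, 0.25, 0.6)
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
    em <- pairs[keep, , drop = FALSE]
    taxa <- paste0("v", seq_len(n))
    net <- build_network(make_edges(cbind(taxa[em[, 1]], taxa[em[, 2]])),
                         taxa)
    net <- find_modules(net, seed = g)
    # brute force over the connected vertices only (isolated nodes do not
    # contribute to Q)
    used <- sort(unique(as.vector(em)))
    em_rel <- matrix(match(em, used), ncol = 2)
    q_best <- oracle_max_modularity(em_rel, length(used))
    expect_equal(net$modularity, q_best, tolerance = 1e-10)
  }
})

test_that("a network with no positive edges puts every node alone at Q = 0", {
  taxa <- c("x", "y", "z")
  net <- build_network(make_edges(cbind("x", "y"), rho = -0.9), taxa)
  net <- find_modules(net, seed = 1)
  expect_equal(net$modularity, 0)
  expect_equal(length(unique(net$nodes$module)), 3)
})

test_that("edge annotation averages class production over source periods", {
  taxa <- c("t1", "t2", "t3")
  edges <- rbind(
    make_edges(cbind("t1", "t2"), period = "period_1"),
    make_edges(cbind("t1", "t2"), period = "period_2"),
    make_edges(cbind("t2", "t3"), period = "period_1"))
  net <- build_network(edges, taxa)
  windows <- list(
    structure(list(label = "period_1", weeks = 1:3,
                   samples = c("w1", "w2", "w3"),
                   salinity_mean = 38, salinity_half_range = 0.05),
              class = "water_mass_window"),
    structure(list(label = "period_2", weeks = 6:8,
                   samples = c("w6", "w7", "w8"),
                   salinity_mean = 37.5, salinity_half_range = 0.05),
              class = "water_mass_window"))
  profile <- data.frame(
    sample = c("w1", "w2", "w3", "w6", "w7", "w8"),
    fgcell.HTrA = c(10, 20, 30, 30, 30, 30),
    fgcell.EPA = c(NA, NA, NA, 5, 5, 5),
    fgcell.DHA = c(1, 2, 3, 4, 5, 6))
  ann <- annotate_edges(net, profile, windows)
  two_period <- ann$edges[ann$edges$taxon_b == "t2", ]
  one_period <- ann$edges[ann$edges$taxon_b == "t3", ]
  expect_equal(one_period$htra_fgcell, 20)        # mean(10, 20, 30)
  expect_equal(two_period$htra_fgcell, 25)        # mean of period means
  expect_true(is.na(one_period$epa_fgcell))       # all missing in period 1
  expect_equal(two_period$epa_fgcell, 5)          # NA period skipped
  expect_false(any(ann$edges$annotation_missing))
  expect_error(annotate_edges(net, profile, windows[1]), "period_2")
})

test_that("reshuffling conserves the annotation multiset", {
  taxa <- paste0("n", 1:10)
  cl1 <- t(utils::combn(taxa[1:5], 2))
  cl2 <- t(utils::combn(taxa[6:10], 2))
  net <- build_network(make_edges(rbind(cl1, cl2)), taxa)
  net <- find_modules(net, seed = 1)
  set.seed(20)
  net$edges$htra_fgcell <- rlnorm(nrow(net$edges))
  res <- null_module_test(net, "HTrA", reshuffles = 50, seed = 2)
  pool <- attr(res, "pool")
  expect_equal(sort(attr(res, "first_reshuffle")), sort(pool))
  expect_equal(nrow(res), 2)
  expect_equal(res$n1, res$n2)
})

test_that("identical annotations everywhere give t = 0 and p = 1", {
  taxa <- paste0("n", 1:10)
  cl1 <- t(utils::combn(taxa[1:5], 2))
  cl2 <- t(utils::combn(taxa[6:10], 2))
  net <- build_network(make_edges(rbind(cl1, cl2)), taxa)
  net <- find_modules(net, seed = 1)
  net$edges$epa_fgcell <- 7
  res <- null_module_test(net, "EPA", reshuffles = 20, seed = 3)
  expect_true(all(res$t == 0))
  expect_true(all(res$p_value == 1))
  expect_true(all(res$df == res$n1 + res$n2 - 2))
})

test_that("planted module enrichment is detected against the null", {
  taxa <- paste0("n", 1:18)
  cl1 <- t(utils::combn(taxa[1:9], 2))
  cl2 <- t(utils::combn(taxa[10:18], 2))
  hits <- 0L
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    net <- build_network(make_edges(rbind(cl1, cl2)), taxa)
    net <- find_modules(net, seed = 1)
    set.seed(5000 + s)
    mod_of <- stats::setNames(net$nodes$module, net$nodes$taxon)
    # the module holding the second clique gets 10x higher HTrA production
    m2 <- mod_of[["n10"]]
    sel <- mod_of[net$edges$taxon_a] == m2 & mod_of[net$edges$taxon_b] == m2
    net$edges$htra_fgcell <- rlnorm(nrow(net$edges), log(2), 0.3)
    net$edges$htra_fgcell[sel] <- rlnorm(sum(sel), log(20), 0.3)
    res <- null_module_test(net, "HTrA", reshuffles = 200, seed = s)
    if (res$p_value[res$module == m2] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_seeds))
})

test_that("stored edges always satisfy the inference thresholds", {
  ab <- generate_community(synth_config(seed = 2))
  env <- generate_environment(synth_config(seed = 2))
  windows <- detect_water_masses(env)
  edges <- do.call(rbind, lapply(windows, function(w)
    spearman_edges(ab, w)))
  net <- build_network(edges, rownames(ab))
  expect_true(audit_edges(net))
  bad <- net
  bad$edges$rho[1] <- 0.3
  expect_error(audit_edges(bad), "violate")
})

test_that("network export writes edge list, node table and GraphML", {
  taxa <- c("a", "b", "c")
  net <- build_network(make_edges(cbind(c("a", "b"), c("b", "c"))), taxa)
  net <- find_modules(net, seed = 1)
  dir <- withr::local_tempdir()
  paths <- export_network(net,
                          edge_csv = file.path(dir, "e.csv"),
                          node_csv = file.path(dir, "n.csv"),
                          graphml = file.path(dir, "g.graphml"))
  e <- read.csv(file.path(dir, "e.csv"))
  expect_true(all(c("taxon_a", "taxon_b", "rho", "p_value", "sign",
                    "period", "module_a", "module_b") %in% names(e)))
  n <- read.csv(file.path(dir, "n.csv"))
  expect_equal(n$id, 1:3)
  g <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
})
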