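test_that("critical correlation inverts the null tail exactly", {
  expect_equal(critical_correlation(0.001, 25), 0.5878, tolerance = 0.0005)
  expect_equal(critical_correlation(0.5 - 1e-12, 10), 0, tolerance = 1e-9)
  for (p in c(0.001, 0.01, 0.05, 0.2)) for (n in c(10, 25, 136)) {
    r <- critical_correlation(p, n)
    expect_equal(null_correlation_tail(r, n), p, tolerance = 1e-9)
  }
  # Monte Carlo check of the tail mass beyond the computed threshold
  set.seed(55)
  nmc <- 2e5
  x <- matrix(rnorm(10 * nmc), 10); y <- matrix(rnorm(10 * nmc), 10)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  rs <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
  r01 <- critical_correlation(0.01, 10)
  phat <- mean(rs > r01)
  expect_lt(abs(phat - 0.01), 3 * sqrt(0.01 * 0.99 / nmc))
  expect_error(critical_correlation(0.7, 25), "p_tail")
})

test_that("top-abundance node selection is deterministic", {
  counts <- matrix(c(10, 30, 20, 40), nrow = 4,
                   dimnames = list(c("d", "b", "c", "a"), "s"))
  expect_equal(top_abundant_nodes(counts, 4), c("a", "b", "c", "d"))
  expect_equal(top_abundant_nodes(counts, 2), c("a", "b"))
  tie <- matrix(c(5, 5, 1), nrow = 3, dimnames = list(c("z", "a", "m"), "s"))
  expect_equal(top_abundant_nodes(tie, 2), c("a", "z"))
  expect_error(top_abundant_nodes(tie, 9), "exceeds")
})

test_that("exceedance counting is seeded, bounded, and flags duplicates", {
  set.seed(3)
  z <- matrix(rnorm(10 * 30), 10, 30,
              dimnames = list(paste0("m", 1:10), paste0("s", 1:30)))
  z["m2", ] <- z["m1", ]                  # perfectly duplicated pair
  meta <- data.frame(sample_id = colnames(z), group = "g")
  thr <- critical_correlation(0.001, 12)
  pc <- subsample_exceedance_counts(z, meta, "g", rownames(z),
                                    subset_size = 12, n_trials = 50,
                                    r_threshold = thr, seed = 4)
  expect_equal(nrow(pc), choose(10, 2))
  expect_true(all(pc$count >= 0 & pc$count <= 50))
  dup_row <- pc[pc$mirna_i == "m1" & pc$mirna_j == "m2", ]
  expect_equal(dup_row$count, 50)
  pc2 <- subsample_exceedance_counts(z, meta, "g", rownames(z),
                                     subset_size = 12, n_trials = 50,
                                     r_threshold = thr, seed = 4)
  expect_identical(pc$count, pc2$count)

  # subset = whole group: every trial identical, counts are 0 or n_trials,
  # and invariant under sample reordering
  full <- subsample_exceedance_counts(z, meta, "g", rownames(z),
                                      subset_size = 30, n_trials = 20,
                                      r_threshold = thr, seed = 1)
  expect_true(all(full$count %in% c(0L, 20L)))
  perm <- sample(colnames(z))
  full2 <- subsample_exceedance_counts(z[, perm], meta, "g", rownames(z),
                                       subset_size = 30, n_trials = 20,
                                       r_threshold = thr, seed = 99)
  expect_identical(full$count, full2$count)
  expect_error(subsample_exceedance_counts(z, meta, "g", rownames(z),
                                           subset_size = 31, n_trials = 5,
                                           r_threshold = thr), "fewer")
})

test_that("edges require strict exceedance beyond edge_min", {
  pc <- data.frame(mirna_i = c("a", "a", "b"),
                   mirna_j = c("b", "c", "c"),
                   count = c(501, 500, 499))
  net <- build_network(pc, edge_min = 500)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$mirna_i, "a")
  expect_equal(net$edges$mirna_j, "b")
  none <- build_network(transform(pc, count = 0), edge_min = 500)
  expect_equal(nrow(none$edges), 0)
  expect_equal(sort(none$nodes), c("a", "b", "c"))
})

test_that("groups with weak latent correlation lose most of their edges", {
  cfg <- cohort_config(seed = 42,
                       correlation_strength = c(unaffected = 0.9,
                                                nonprogressed = 0.9,
                                                progressed = 0))
  co <- generate_cohort(cfg)
  z <- zscore_reference(quotient_normalize(co$counts), co$metadata)
  nodes <- top_abundant_nodes(co$counts, 40)
  thr <- critical_correlation(0.001, 25)
  nets <- lapply(c(unaffected = "unaffected", nonprogressed = "nonprogressed",
                   progressed = "progressed"), function(g) {
    pc <- subsample_exceedance_counts(z, co$metadata, g, nodes,
                                      subset_size = 25, n_trials = 200,
                                      r_threshold = thr, seed = 8)
    build_network(pc, edge_min = 100)
  })
  n_edges <- vapply(nets, function(n) nrow(n$edges), numeric(1))
  expect_gt(n_edges[["unaffected"]], 20)
  expect_gt(n_edges[["nonprogressed"]], 20)
  expect_lte(n_edges[["progressed"]], min(n_edges[c("unaffected",
                                                    "nonprogressed")]) / 5)

  cmp <- compare_networks(nets)
  expect_equal(unname(cmp$edge_counts), unname(n_edges))
  # hub nodes present in the strong groups drop out of the weak group
  present_strong <- cmp$node_presence[, "unaffected"] &
    cmp$node_presence[, "nonprogressed"]
  expect_gt(sum(present_strong & !cmp$node_presence[, "progressed"]), 5)
})

test_that("network comparison reports shared and unique structure", {
  net <- function(edges, nodes = c("a", "b", "c", "d")) {
    structure(list(nodes = nodes,
                   edges = edges, params = list(group = "g")),
              class = "correlation_network")
  }
  e1 <- data.frame(mirna_i = c("a", "b"), mirna_j = c("b", "c"),
                   count = c(600, 700))
  same <- compare_networks(list(x = net(e1), y = net(e1)))
  expect_equal(length(same$shared_edges[["x & y"]]), 2)
  e2 <- data.frame(mirna_i = "c", mirna_j = "d", count = 800)
  disj <- compare_networks(list(x = net(e1), y = net(e2)))
  expect_equal(length(disj$shared_edges[["x & y"]]), 0)
  expect_error(compare_networks(list(net(e1), net(e2, nodes = c("a", "b")))),
               "node universes")
})

test_that("Pajek export matches the dialect byte for byte and round-trips", {
  net <- structure(list(nodes = c("hsa-miR-941", "hsa miR 103a"),
                        edges = data.frame(mirna_i = "hsa-miR-941",
                                           mirna_j = "hsa miR 103a",
                                           count = 812),
                        params = list()), class = "correlation_network")
  f <- withr::local_tempfile()
  export_pajek(net, f)
  expect_identical(readLines(f),
                   c("*Vertices 2",
                     '1 "hsa-miR-941"',
                     '2 "hsa miR 103a"',
                     "*Edges",
                     "1 2 812"))
  back <- read_pajek(f)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges$count, 812)
  f2 <- withr::local_tempfile()
  export_pajek(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # independent reader sees the same graph
  ig <- igraph::read_graph(f, format = "pajek")
  expect_equal(igraph::vcount(ig), 2)
  expect_equal(igraph::ecount(ig), 1)
  expect_equal(unname(igraph::E(ig)$weight), 812)
})

test_that("subset-size robustness: edge sets at 21/23/25 stay similar", {
  cfg <- cohort_config(seed = 77, n_unaffected = 5, n_nonprogressed = 35,
                       n_progressed = 5, n_mirnas = 40, planted = NULL,
                       correlation_strength = c(unaffected = 0,
                                                nonprogressed = 0.9,
                                                progressed = 0))
  co <- generate_cohort(cfg)
  q <- quotient_normalize(co$counts)
  # standardize within the subsampled group itself (no external reference
  # needed for a correlation screen)
  z <- t(scale(t(q)))
  nodes <- rownames(q)
  edge_key <- function(subset_size) {
    thr <- critical_correlation(0.001, subset_size)
    pc <- subsample_exceedance_counts(z, co$metadata, "nonprogressed",
                                      nodes, subset_size = subset_size,
                                      n_trials = 200, r_threshold = thr,
                                      seed = 5)
    e <- build_network(pc, edge_min = 100)$edges
    paste(e$mirna_i, e$mirna_j)
  }
  e25 <- edge_key(25); e23 <- edge_key(23); e21 <- edge_key(21)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gt(jac(e25, e23), 0.5)
  expect_gt(jac(e25, e21), 0.5)
})
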