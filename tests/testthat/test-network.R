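toy_net <- function(edge_df, threshold = 0.5) {
  sc <- tibble::tibble(
    drug = edge_df[[1]], disease = edge_df[[2]],
    similarity = if (ncol(edge_df) > 2) edge_df[[3]] else 1,
    n = 1L, m = 1L
  )
  sc <- dplyr::arrange(sc, dplyr::desc(similarity), drug, disease)
  build_network(sc, threshold)
}

test_that("network thresholding keeps high-similarity edges only", {
  sc <- tibble::tibble(
    drug = rep(sprintf("d%d", 1:5), 2),
    disease = rep(sprintf("s%d", 1:2), each = 5),
    similarity = seq(1, 0.1, length.out = 10),
    n = 1L, m = 1L
  )
  all_net <- build_network(sc, min(sc$similarity))
  expect_equal(nrow(all_net$edges), 10)
  expect_warning(none <- build_network(sc, max(sc$similarity) + 1), "empty")
  expect_equal(nrow(none$edges), 0)
  some <- build_network(sc, sort(sc$similarity, decreasing = TRUE)[4])
  expect_equal(nrow(some$edges), 4)
  expect_setequal(some$nodes$node, unique(c(some$edges$drug,
                                            some$edges$disease)))
  g <- glance(some)
  expect_equal(g$n_edges, 4)
})

test_that("modularity recomputation matches igraph on random bipartite graphs", {
  for (seed in 1:4) {
    ed <- withr::with_seed(seed, {
      tibble::tibble(drug = sample(sprintf("d%d", 1:8), 20, replace = TRUE),
                     disease = sample(sprintf("s%d", 1:8), 20, replace = TRUE))
    })
    ed <- dplyr::distinct(ed)
    net <- toy_net(ed)
    memb <- withr::with_seed(seed, {
      stats::setNames(sample(1:3, nrow(net$nodes), replace = TRUE),
                      net$nodes$node)
    })
    g <- as_igraph(net)
    expect_equal(
      modularity_value(net$edges, memb),
      igraph::modularity(g, memb[igraph::V(g)$name])
    )
  }
})

test_that("community detection recovers planted two-clique structure", {
  # two complete bipartite 2x2 blocks joined by one edge: the optimal
  # partition (verified by exhaustive search over all partitions) is the
  # two blocks
  ed <- tibble::tibble(
    drug = c("d1", "d1", "d2", "d2", "d3", "d3", "d4", "d4", "d1"),
    disease = c("s1", "s2", "s1", "s2", "s3", "s4", "s3", "s4", "s3")
  )
  net <- toy_net(ed)
  cm <- detect_communities(net, seed = 1)
  oracle <- brute_best_partition(as.data.frame(ed))
  expect_equal(cm$modularity, oracle$modularity)
  expect_equal(cm$n_communities, length(unique(oracle$membership)))
  # the blocks stay together
  memb <- stats::setNames(cm$membership$community, cm$membership$node)
  expect_equal(length(unique(memb[c("d1", "d2", "s1", "s2")])), 1)
  expect_equal(length(unique(memb[c("d3", "d4", "s3", "s4")])), 1)

  # reported modularity equals direct recomputation
  expect_equal(cm$modularity, modularity_value(net$edges, cm$membership))
  # deterministic under a fixed seed
  cm2 <- detect_communities(net, seed = 1)
  expect_equal(cm2$membership, cm$membership)
})

test_that("a single edge forms one community; components never merge", {
  one <- toy_net(tibble::tibble(drug = "d1", disease = "s1"))
  cm <- detect_communities(one, seed = 1)
  # closed form: joint community has Q = 0, singletons Q = -1/2
  expect_equal(cm$n_communities, 1)
  expect_equal(cm$modularity, 0)

  # two disconnected blocks: no community spans components
  ed <- tibble::tibble(
    drug = c("d1", "d1", "d2", "d3", "d3", "d4"),
    disease = c("s1", "s2", "s1", "s3", "s4", "s3")
  )
  net <- toy_net(ed)
  cm2 <- detect_communities(net, seed = 2)
  memb <- stats::setNames(cm2$membership$community, cm2$membership$node)
  left <- unique(memb[c("d1", "d2", "s1", "s2")])
  right <- unique(memb[c("d3", "d4", "s3", "s4")])
  expect_equal(length(intersect(left, right)), 0)

  empty_net <- suppressWarnings(
    toy_net(tibble::tibble(drug = character(), disease = character()))
  )
  expect_error(detect_communities(empty_net, seed = 1), "empty")
})

test_that("multi-level optimizer reaches exhaustive-search modularity on tiny graphs", {
  for (seed in 1:4) {
    ed <- withr::with_seed(seed, {
      dplyr::distinct(tibble::tibble(
        drug = sample(sprintf("d%d", 1:4), 10, replace = TRUE),
        disease = sample(sprintf("s%d", 1:4), 10, replace = TRUE)
      ))
    })
    net <- toy_net(ed)
    cm <- detect_communities(net, seed = seed)
    oracle <- brute_best_partition(as.data.frame(ed))
    expect_gte(cm$modularity, oracle$modularity - 0.02)
    expect_gte(cm$modularity, 0)  # at least the all-singleton partition
  }
})

test_that("community class enrichment matches the hypergeometric tail", {
  # community of 10 diseases with 8 of class X; the remaining network has
  # 100 diseases with 10 of class X
  diseases <- sprintf("s%03d", 1:110)
  drugs <- sprintf("d%03d", 1:110)
  ed <- tibble::tibble(drug = drugs, disease = diseases)
  net <- toy_net(ed)
  memb <- tibble::tibble(
    node = net$nodes$node, type = net$nodes$type,
    community = ifelse(net$nodes$node %in% c(diseases[1:10], drugs[1:10]),
                       1L, 2L)
  )
  communities <- structure(
    list(membership = memb, modularity = 0, n_communities = 2L, seed = 1L),
    class = "pheno_communities"
  )
  classes <- tibble::tibble(entity = diseases[c(1:8, 11:20)], class = "X")
  res <- community_class_enrichment(net, communities, classes,
                                    side = "disease", fdr_cutoff = 0.01)
  row <- res[res$community == 1 & res$class == "X", ]
  # independent oracle: upper hypergeometric tail
  p_want <- stats::phyper(8 - 1, 18, 110 - 18, 10, lower.tail = FALSE)
  expect_equal(row$p_value, p_want, tolerance = 1e-12)
  expect_true(row$significant)

  # uniform class: nothing significant
  uni <- tibble::tibble(entity = diseases, class = "U")
  res_u <- community_class_enrichment(net, communities, uni, "disease")
  expect_false(any(res_u$significant[res_u$class == "U" &
                                       res_u$community == 1]))

  # degenerate single community: skipped with a warning
  memb1 <- dplyr::mutate(memb, community = 1L)
  com1 <- structure(list(membership = memb1, modularity = 0,
                         n_communities = 1L, seed = 1L),
                    class = "pheno_communities")
  expect_warning(res1 <- community_class_enrichment(net, com1, classes,
                                                    "disease"),
                 "every classified")
  expect_equal(nrow(res1), 0)
})

test_that("class combination enrichment compares network to universe", {
  # universe of 100 pairs, network of 10; the combination covers 10 pairs
  # overall of which 5 are in the network
  drugs <- sprintf("d%03d", 1:100)
  diseases <- sprintf("s%03d", 1:100)
  sc <- tibble::tibble(drug = drugs, disease = diseases,
                       similarity = seq(1, 0.01, length.out = 100),
                       n = 1L, m = 1L)
  net <- build_network(sc, sc$similarity[10])
  combo_rows <- c(1:5, 51:55)
  dcl <- tibble::tibble(entity = diseases[combo_rows], class = "DX")
  gcl <- tibble::tibble(entity = drugs[combo_rows], class = "MX")
  res <- class_combination_enrichment(net, sc, dcl, gcl, fdr_cutoff = 0.05)
  row <- res[res$disease_class == "DX" & res$drug_class == "MX", ]
  p_want <- stats::phyper(5 - 1, 10, 90, 10, lower.tail = FALSE)
  expect_equal(row$p_value, p_want, tolerance = 1e-12)
  expect_true(row$significant)
  expect_equal(attr(res, "n_covered"), 5)
  expect_equal(attr(res, "fraction_covered"), 0.5)

  # a combination with matching in/out frequency is unremarkable
  dcl2 <- tibble::tibble(entity = diseases, class = "ALL")
  gcl2 <- tibble::tibble(entity = drugs, class = "ALL")
  res2 <- class_combination_enrichment(net, sc, dcl2, gcl2)
  expect_equal(res2$p_value, 1)
})

test_that("enrichment is invariant to community relabeling and permutation-calibrated", {
  w <- simulate_world(sim_config(seed = 31, n_drugs = 60, n_diseases = 90,
                                 ppi_nodes = 150, ppi_edges = 600))
  sc <- score_pairs(w$drug_annotations, w$disease_annotations, w$ontology)
  net <- build_network(sc, stats::quantile(sc$similarity, 0.98))
  cm <- detect_communities(net, seed = 1)
  res <- community_class_enrichment(net, cm, w$disease_classes, "disease")

  # relabeled community ids give the same table modulo the id column
  relab <- cm
  relab$membership$community <- match(relab$membership$community,
                                      rev(sort(unique(relab$membership$community))))
  res2 <- community_class_enrichment(net, relab, w$disease_classes, "disease")
  expect_equal(dplyr::arrange(res[, -1], class, p_value)$p_value,
               dplyr::arrange(res2[, -1], class, p_value)$p_value)

  # permuting class labels rarely yields significance at FDR 0.01
  frac_sig <- vapply(1:20, function(i) {
    perm <- w$disease_classes
    perm$class <- withr::with_seed(1000 + i, sample(perm$class))
    pr <- community_class_enrichment(net, cm, perm, "disease")
    if (nrow(pr) == 0) 0 else mean(pr$significant)
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.05)
})

test_that("planted class-homogeneous communities are recovered as enriched", {
  # communities built from the generator's organ-system classes: entities
  # sharing a focus subtree connect preferentially, so their dominant class
  # should enrich within their community
  w <- simulate_world(sim_config(seed = 13))
  sc <- score_pairs(w$drug_annotations, w$disease_annotations, w$ontology)
  net <- build_network(sc, stats::quantile(sc$similarity, 0.99))
  cm <- detect_communities(net, seed = 1)
  res <- community_class_enrichment(net, cm, w$disease_classes, "disease",
                                    fdr_cutoff = 0.01)
  # most communities of any size carry at least one enriched disease class
  sizes <- table(cm$membership$community[cm$membership$type == "disease"])
  big <- as.integer(names(sizes)[sizes >= 10])
  hit <- vapply(big, function(k) {
    any(res$significant[res$community == k])
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("network export writes edge TSV and GraphML", {
  ed <- tibble::tibble(drug = c("d1", "d2"), disease = c("s1", "s1"))
  net <- toy_net(ed)
  cm <- detect_communities(net, seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, tsv, gml, communities = cm)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 2)
  gg <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(gg), 3)
  expect_true("community" %in% igraph::vertex_attr_names(gg))
})
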