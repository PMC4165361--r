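#' Read an entity-class map TSV
#'
#' Used for MeSH-like disease classes and ATC/MoA-like drug classes. Header
#' required; first column the entity, second the class. Entities may carry
#' several classes.
#'
#' @param path Path to the TSV.
#' @return Tibble `entity`, `class`.
#' @export
read_classes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df)[1:2] <- c("entity", "class")
  dplyr::distinct(df[, c("entity", "class")])
}

#' Build the thresholded phenotypic drug-disease network
#'
#' Keeps the scored pairs with similarity at or above the threshold as edges
#' of a bipartite drug-disease graph; entities not on any retained edge are
#' excluded.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param threshold Similarity threshold (e.g. the [pareto_threshold()]
#'   selection).
#' @return Object of class `pheno_network`: list with `edges` (tibble
#'   `drug`, `disease`, `similarity`), `nodes` (tibble `node`, `type`), and
#'   `threshold`.
#' @export
build_network <- function(scored, threshold) {
  edges <- scored[scored$similarity >= threshold,
                  c("drug", "disease", "similarity")]
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) {
    warning("threshold above the maximum score: empty network", call. = FALSE)
  }
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = unique(edges$drug), type = "drug"),
    tibble::tibble(node = unique(edges$disease), type = "disease")
  )
  structure(list(edges = edges, nodes = nodes, threshold = threshold),
            class = "pheno_network")
}

#' @export
print.pheno_network <- function(x, ...) {
  cat("<pheno_network> threshold ", format(x$threshold, digits = 6), ": ",
      nrow(x$edges), " edges, ",
      sum(x$nodes$type == "disease"), " diseases, ",
      sum(x$nodes$type == "drug"), " drugs\n", sep = "")
  invisible(x)
}

#' @rdname build_network
#' @param x A `pheno_network`.
#' @param ... Unused.
#' @export
glance.pheno_network <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x$edges),
                 n_drugs = sum(x$nodes$type == "drug"),
                 n_diseases = sum(x$nodes$type == "disease"),
                 threshold = x$threshold)
}

#' Convert a phenotypic network to an igraph object
#' @param net A [build_network()] object.
#' @return An undirected igraph with `type` vertex attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "pheno_network"))
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Export the network as edge-list TSV and GraphML
#'
#' @param net A [build_network()] object.
#' @param edges_path Path for the edge-list TSV.
#' @param graphml_path Optional path for a GraphML file with node attributes
#'   (`type`, and `community` if `communities` is given).
#' @param communities Optional [detect_communities()] result.
#' @export
write_network <- function(net, edges_path, graphml_path = NULL,
                          communities = NULL) {
  readr::write_tsv(net$edges, edges_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    g <- as_igraph(net)
    if (!is.null(communities)) {
      mm <- communities$membership
      igraph::V(g)$community <- mm$community[match(igraph::V(g)$name, mm$node)]
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edges_path)
}

#' Modularity of a node partition
#'
#' Recomputes \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)} directly from an edge
#' list and a community assignment, where `e_c` is the number of edges with
#' both ends in community `c`, `d_c` the summed degree of its nodes and `m`
#' the total edge count. Serves as the independent check on the optimizer's
#' reported modularity.
#'
#' @param edges Data frame whose first two columns are the edge endpoints.
#' @param membership Named vector or tibble (`node`, `community`) assigning
#'   every endpoint to a community.
#' @return Modularity value in \[-0.5, 1\].
#' @export
modularity_value <- function(edges, membership) {
  if (is.data.frame(membership)) {
    membership <- stats::setNames(membership$community, membership$node)
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  ca <- membership[a]
  cb <- membership[b]
  if (anyNA(ca) || anyNA(cb)) stop("membership does not cover all endpoints", call. = FALSE)
  m <- length(a)
  comms <- unique(c(ca, cb))
  e_c <- vapply(comms, function(cc) sum(ca == cc & cb == cc), numeric(1))
  deg <- table(c(a, b))
  nodes_comm <- membership[names(deg)]
  d_c <- vapply(comms, function(cc) sum(deg[nodes_comm == cc]), numeric(1))
  sum(e_c / m - (d_c / (2 * m))^2)
}

# One local-moving phase of the multi-level optimizer on a weighted graph
# given as adjacency lists. Returns the community assignment (integers).
louvain_one_level <- function(nb, wt, selfw, order) {
  n <- length(nb)
  k <- vapply(seq_len(n), function(i) sum(wt[[i]]), numeric(1)) + 2 * selfw
  m2 <- sum(k)
  if (m2 == 0) return(seq_len(n))
  comm <- seq_len(n)
  tot <- k
  repeat {
    moved <- FALSE
    for (i in order) {
      ci <- comm[i]
      nbc <- comm[nb[[i]]]
      w_to <- tapply(wt[[i]], nbc, sum)
      tot[ci] <- tot[ci] - k[i]
      cand <- as.integer(names(w_to))
      if (!ci %in% cand) {
        cand <- c(cand, ci)
        w_to <- c(w_to, stats::setNames(0, ci))
      }
      gain <- w_to[as.character(cand)] - tot[cand] * k[i] / m2
      # deterministic ties: keep the current community when it is maximal,
      # otherwise the lowest-id community among the maxima
      best <- cand[which(gain == max(gain))]
      new_c <- if (ci %in% best) ci else min(best)
      tot[new_c] <- tot[new_c] + k[i]
      if (new_c != ci) {
        comm[i] <- new_c
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

# edges: integer matrix (a, b) with weights w; self: per-node self-loop weight
louvain_aggregate <- function(edges, w, self, comm) {
  relab <- match(comm, sort(unique(comm)))
  n_new <- max(relab)
  ca <- relab[edges[, 1]]
  cb <- relab[edges[, 2]]
  internal <- ca == cb
  self_acc <- numeric(n_new)
  grp <- c(ca[internal], relab)
  val <- c(w[internal], self)
  for (g in seq_len(n_new)) self_acc[g] <- sum(val[grp == g])
  ext <- !internal
  if (any(ext)) {
    lo <- pmin(ca[ext], cb[ext])
    hi <- pmax(ca[ext], cb[ext])
    key <- paste(lo, hi)
    agg <- rowsum(w[ext], key)
    parts <- do.call(rbind, strsplit(rownames(agg), " "))
    new_edges <- cbind(as.integer(parts[, 1]), as.integer(parts[, 2]))
    new_w <- as.vector(agg)
  } else {
    new_edges <- matrix(integer(), 0, 2)
    new_w <- numeric()
  }
  list(edges = new_edges, w = new_w, self = self_acc, relab = relab)
}

adjacency_lists <- function(n, edges, w) {
  if (nrow(edges) == 0) {
    return(list(nb = rep(list(integer()), n), wt = rep(list(numeric()), n)))
  }
  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  ww <- c(w, w)
  f <- factor(from, levels = seq_len(n))
  list(nb = split(to, f), wt = split(ww, f))
}

#' Detect communities by multi-level modularity optimization
#'
#' Greedy multi-level (Louvain-style) modularity optimization, implemented in
#' the package so results are reproducible and checkable against exhaustive
#' maximization on small graphs: nodes are repeatedly moved to the
#' neighboring community with the largest modularity gain, the partition is
#' contracted into a weighted super-graph, and the two phases iterate until
#' no move improves modularity. No constraint is placed on the number or
#' size of communities. The greedy search is order-dependent, so it is
#' restarted from several seeded node orders and the partition with the
#' highest modularity is kept; the result is deterministic for a fixed seed.
#'
#' @param net A [build_network()] object with at least one edge.
#' @param seed Integer seed controlling the node visiting orders.
#' @param n_restarts Number of independent greedy runs.
#' @return Object of class `pheno_communities`: list with `membership`
#'   (tibble `node`, `type`, `community`), `modularity`, `n_communities`,
#'   `seed`.
#' @export
detect_communities <- function(net, seed = 1L, n_restarts = 5L) {
  stopifnot(inherits(net, "pheno_network"))
  if (nrow(net$edges) == 0) stop("cannot partition an empty network", call. = FALSE)
  nodes <- net$nodes$node
  n <- length(nodes)
  edges0 <- cbind(match(net$edges$drug, nodes), match(net$edges$disease, nodes))

  best_q <- -Inf
  best_membership <- NULL
  for (r in seq_len(n_restarts)) {
    membership <- louvain_run(n, edges0,
                              withr::with_seed(seed + r - 1L, sample.int(n)))
    q <- modularity_value(net$edges, stats::setNames(membership, nodes))
    if (q > best_q) {
      best_q <- q
      best_membership <- membership
    }
  }
  membership <- match(best_membership, sort(unique(best_membership)))
  mm <- tibble::tibble(node = nodes,
                       type = net$nodes$type,
                       community = membership)
  structure(list(membership = mm, modularity = best_q,
                 n_communities = dplyr::n_distinct(membership), seed = seed),
            class = "pheno_communities")
}

# one full multi-level pass: local moving + aggregation until stable
louvain_run <- function(n, edges0, order0) {
  membership <- seq_len(n)
  edges <- edges0
  w <- rep(1, nrow(edges0))
  self <- numeric(n)
  level_order <- order0
  repeat {
    adj <- adjacency_lists(length(self), edges, w)
    comm <- louvain_one_level(adj$nb, adj$wt, self, level_order)
    if (all(comm == seq_along(comm))) break
    agg <- louvain_aggregate(edges, w, self, comm)
    membership <- agg$relab[membership]
    edges <- agg$edges
    w <- agg$w
    self <- agg$self
    level_order <- seq_along(self)
  }
  membership
}

#' @export
print.pheno_communities <- function(x, ...) {
  cat("<pheno_communities> ", x$n_communities, " communities, modularity ",
      format(x$modularity, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname detect_communities
#' @param x A `pheno_communities` object.
#' @param ... Unused.
#' @export
tidy.pheno_communities <- function(x, ...) x$membership

#' @rdname detect_communities
#' @export
glance.pheno_communities <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$membership),
                 n_communities = x$n_communities,
                 modularity = x$modularity,
                 seed = x$seed)
}

#' Class enrichment within network communities
#'
#' For each community and each disease (or drug) class, tests whether
#' classified nodes of that side inside the community are enriched for the
#' class compared to the rest of the network, with a one-sided Fisher's
#' exact test. P-values are Benjamini-Hochberg-adjusted across all tested
#' (community, class) cells of the chosen side. Entities with several
#' classes count once per class; nodes without any class annotation count
#' as not belonging to the class under test.
#'
#' @param net A [build_network()] object.
#' @param communities A [detect_communities()] result.
#' @param classes Tibble `entity`, `class` (see [read_classes()]).
#' @param side `"disease"` or `"drug"`: which node type the classes apply to.
#' @param fdr_cutoff Significance cutoff on the adjusted p-value.
#' @param alternative Sidedness of the Fisher test; the default tests
#'   over-representation.
#' @return Tibble `community`, `class`, `in_class`, `in_total`, `out_class`,
#'   `out_total`, `odds_ratio`, `p_value`, `fdr`, `significant`.
#' @export
community_class_enrichment <- function(net, communities, classes,
                                       side = c("disease", "drug"),
                                       fdr_cutoff = 0.01,
                                       alternative = c("greater", "two.sided")) {
  side <- match.arg(side)
  alternative <- match.arg(alternative)
  mm <- communities$membership
  mm <- mm[mm$type == side, ]
  cls <- dplyr::inner_join(classes, mm, by = c(entity = "node"))
  if (nrow(cls) == 0) stop("no classified ", side, " nodes in the network", call. = FALSE)
  # the universe is every node of the side in the network; nodes without a
  # class annotation count as not belonging to any class
  n_all <- nrow(mm)
  node_comm <- stats::setNames(mm$community, mm$node)

  comms <- sort(unique(cls$community))
  class_ids <- sort(unique(cls$class))
  out <- purrr::map_dfr(comms, function(k) {
    in_comm <- mm$node[mm$community == k]
    if (length(in_comm) == n_all) {
      warning("community ", k, " holds every classified ", side,
              " node; no rest of network to compare against", call. = FALSE)
      return(NULL)
    }
    purrr::map_dfr(class_ids, function(x) {
      members <- unique(cls$entity[cls$class == x])
      if (length(members) == 0) return(NULL)
      a <- length(intersect(in_comm, members))
      b <- length(in_comm) - a
      cc <- length(members) - a
      d <- n_all - length(in_comm) - cc
      ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                        alternative = alternative)
      tibble::tibble(community = k, class = x,
                     in_class = a, in_total = length(in_comm),
                     out_class = cc, out_total = n_all - length(in_comm),
                     odds_ratio = unname(ft$estimate), p_value = ft$p.value)
    })
  })
  if (nrow(out) == 0) return(out)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr <= fdr_cutoff
  dplyr::arrange(out, .data$fdr, .data$community, .data$class)
}

#' Enrichment of disease-class / drug-class combinations in the network
#'
#' Tests, for every (disease class, drug class) combination, whether pairs of
#' that combination are over-represented among the network edges compared to
#' the full scored pair universe, with one-sided Fisher's exact tests and
#' Benjamini-Hochberg correction. The fraction of network edges covered by
#' at least one significant combination is reported as attributes
#' (`n_covered`, `fraction_covered`).
#'
#' @param net A [build_network()] object.
#' @param scored The full scored pair universe from [score_pairs()].
#' @param disease_classes,drug_classes Tibbles `entity`, `class`.
#' @param fdr_cutoff Significance cutoff on the adjusted p-value.
#' @return Tibble `disease_class`, `drug_class`, `in_network`, `in_universe`,
#'   `odds_ratio`, `p_value`, `fdr`, `significant`, with coverage attributes.
#' @export
class_combination_enrichment <- function(net, scored, disease_classes,
                                         drug_classes, fdr_cutoff = 0.05) {
  if (nrow(disease_classes) == 0 || nrow(drug_classes) == 0) {
    stop("class maps must be non-empty", call. = FALSE)
  }
  uni <- scored[, c("drug", "disease")]
  uni_keys <- pair_key(uni$drug, uni$disease)
  net_keys <- pair_key(net$edges$drug, net$edges$disease)
  n_uni <- nrow(uni)
  n_net <- length(net_keys)

  expand <- dplyr::inner_join(
    dplyr::inner_join(uni, drug_classes, by = c(drug = "entity")),
    disease_classes, by = c(disease = "entity"),
    suffix = c("_drug", "_disease"),
    relationship = "many-to-many"
  )
  names(expand)[names(expand) == "class_drug"] <- "drug_class"
  names(expand)[names(expand) == "class_disease"] <- "disease_class"
  expand <- dplyr::distinct(expand)
  expand$in_net <- pair_key(expand$drug, expand$disease) %in% net_keys

  counts <- dplyr::summarise(
    dplyr::group_by(expand, .data$disease_class, .data$drug_class),
    in_universe = dplyr::n(),
    in_network = sum(.data$in_net),
    .groups = "drop"
  )
  res <- purrr::pmap_dfr(counts, function(disease_class, drug_class,
                                          in_universe, in_network) {
    a <- in_network
    b <- n_net - a
    cc <- in_universe - a
    d <- (n_uni - n_net) - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                      alternative = "greater")
    tibble::tibble(disease_class = disease_class, drug_class = drug_class,
                   in_network = a, in_universe = in_universe,
                   odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr <= fdr_cutoff
  res <- dplyr::arrange(res, .data$fdr, .data$disease_class, .data$drug_class)

  sig <- res[res$significant, c("disease_class", "drug_class")]
  covered <- dplyr::semi_join(expand[expand$in_net, ], sig,
                              by = c("disease_class", "drug_class"))
  n_cov <- dplyr::n_distinct(pair_key(covered$drug, covered$disease))
  structure(res, n_covered = n_cov,
            fraction_covered = if (n_net > 0) n_cov / n_net else NA_real_)
}

#' Fraction of classified entities, as printed coverage percentages
#'
#' Small helper reporting how many of a network's nodes (or any entity
#' vector) carry a class annotation, as count and percentage.
#'
#' @param entities Character vector of entity identifiers.
#' @param classes Tibble `entity`, `class`.
#' @return One-row tibble `n_classified`, `n_total`, `percent` (percent
#'   rounded to two decimals, as customarily printed).
#' @export
class_coverage <- function(entities, classes) {
  entities <- unique(entities)
  n_cl <- sum(entities %in% classes$entity)
  tibble::tibble(n_classified = n_cl, n_total = length(entities),
                 percent = round(100 * n_cl / length(entities), 2))
}
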