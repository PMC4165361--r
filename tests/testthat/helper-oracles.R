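# Independent brute-force oracles used to validate the package's graph and
# statistics code on small instances. All operate on plain edge data frames
# so they share no code with the implementation under test.

# transitive ancestors (incl. self) by naive repeated expansion
brute_ancestors <- function(edges, term) {
  anc <- term
  repeat {
    more <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(more, anc)
    if (length(new) == 0) return(sort(anc))
    anc <- c(anc, new)
  }
}

# distinct descendants by scanning every term's ancestor set
brute_hyponyms <- function(edges) {
  terms <- unique(c(edges$child, edges$parent))
  anc <- lapply(terms, function(t) brute_ancestors(edges, t))
  names(anc) <- terms
  vapply(terms, function(t) {
    sum(vapply(terms, function(u) u != t && t %in% anc[[u]], logical(1)))
  }, integer(1))
}

# MICA IC by exhaustive intersection of ancestor sets
brute_mica_ic <- function(edges, ic_tbl, t1, t2) {
  common <- intersect(brute_ancestors(edges, t1), brute_ancestors(edges, t2))
  max(ic_tbl$ic[ic_tbl$term %in% common])
}

# min shortest-path distance between two node sets by matrix-power BFS
brute_set_distance <- function(edge_df, targets, genes) {
  nodes <- sort(unique(c(edge_df[[1]], edge_df[[2]], targets, genes)))
  if (length(intersect(targets, genes)) > 0) return(0)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  adj[cbind(match(edge_df[[1]], nodes), match(edge_df[[2]], nodes))] <- TRUE
  adj <- adj | t(adj)
  reach <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  diag(reach) <- TRUE
  for (d in seq_len(n)) {
    reach_new <- reach | (reach %*% adj > 0)
    hit <- any(reach_new[targets, genes, drop = FALSE])
    if (hit) return(d)
    if (identical(reach_new, reach)) return(Inf)
    reach <- reach_new
  }
  Inf
}

# exhaustive modularity maximization over all set partitions (tiny n only)
brute_best_partition <- function(edge_df) {
  nodes <- sort(unique(c(edge_df[[1]], edge_df[[2]])))
  n <- length(nodes)
  stopifnot(n <= 9)
  best_q <- -Inf
  best <- NULL
  # enumerate restricted-growth strings
  rgs <- function(prefix, maxv) {
    if (length(prefix) == n) {
      memb <- stats::setNames(prefix, nodes)
      q <- modularity_value(edge_df, memb)
      if (q > best_q) {
        best_q <<- q
        best <<- memb
      }
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1)) {
      rgs(c(prefix, v), max(maxv, v))
    }
  }
  rgs(integer(), 0)
  list(membership = best, modularity = best_q)
}

# random rooted multi-parent DAG for property tests: node i>1 gets 1-2
# parents among nodes with smaller index (node 1 is the root)
random_dag_edges <- function(n, seed) {
  withr::with_seed(seed, {
    child <- character()
    parent <- character()
    ids <- sprintf("N%02d", seq_len(n))
    for (i in seq(2, n)) {
      k <- sample(1:2, 1)
      ps <- sample(seq_len(i - 1), min(k, i - 1))
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ids[ps])
    }
    data.frame(child = child, parent = parent)
  })
}

# small annotation table fixture
tiny_annotations <- function(kind = "disease") {
  annotations(data.frame(
    entity = c("e1", "e1", "e2", "e2", "e3", "e4"),
    term = c("A", "B", "B", "C", "A", "C")
  ), kind = kind)
}
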