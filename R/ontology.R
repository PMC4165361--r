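#' Build a phenotype ontology from a child-parent edge table
#'
#' A phenotype ontology is a rooted directed acyclic graph of terms
#' (MedDRA-like: a single root subsuming organ-system subtrees down to
#' specific preferred terms). Multiple parents are allowed, so cross-hierarchy
#' groupings (SMQ-style bridges) are represented as ordinary extra parent
#' edges; reachability is all that downstream semantic-similarity code needs.
#'
#' @param edges A data frame with columns `child` and `parent`, one row per
#'   parent edge (a term may appear as child in several rows).
#' @return An object of class `pheno_ontology`: a list with elements
#'   `edges` (tibble of child-parent edges), `terms` (character vector),
#'   `root` (the unique term without parents), `n_terms`, and `graph`
#'   (an igraph with edges directed child -> parent).
#' @details The constructor validates the structure: the edge set must be
#'   acyclic and must have exactly one root. Terms mentioned only as parents
#'   or only as children are still part of the term set.
#' @examples
#' onto <- ontology(data.frame(child = c("B", "C"), parent = c("A", "A")))
#' onto$root
#' @export
ontology <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("child", "parent") %in% names(edges))) {
    stop("`edges` must have columns `child` and `parent`", call. = FALSE)
  }
  edges <- dplyr::distinct(edges, .data$child, .data$parent)
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  if (nrow(edges) == 0) stop("ontology has no edges", call. = FALSE)
  if (any(edges$child == edges$parent)) {
    bad <- edges$child[edges$child == edges$parent][1]
    stop("cycle detected: term '", bad, "' is its own parent", call. = FALSE)
  }
  terms <- sort(unique(c(edges$child, edges$parent)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) {
    fas <- igraph::feedback_arc_set(g)
    e1 <- igraph::ends(g, fas[[1]])
    stop("cycle detected involving edge ", e1[1], " -> ", e1[2], call. = FALSE)
  }
  # root(s): terms that never appear as a child (out-degree 0 in child->parent)
  roots <- terms[igraph::degree(g, mode = "out") == 0]
  if (length(roots) != 1) {
    stop("ontology must have exactly one root, found ",
         length(roots), ": ", paste(utils::head(roots, 5), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(edges = edges, terms = terms, root = roots,
         n_terms = length(terms), graph = g),
    class = "pheno_ontology"
  )
}

#' @export
print.pheno_ontology <- function(x, ...) {
  cat("<pheno_ontology> ", x$n_terms, " terms, ",
      nrow(x$edges), " parent edges, root: ", x$root, "\n", sep = "")
  invisible(x)
}

#' Read a phenotype ontology from disk
#'
#' @param path Path to the file.
#' @param format `"edge_tsv"` for a two-column `child<TAB>parent` table
#'   (header optional, detected from a first line reading `child parent`),
#'   or `"obo"` for an OBO-style file whose `is_a` tags become parent edges.
#' @return A [ontology()] object.
#' @export
read_ontology <- function(path, format = c("edge_tsv", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edge_tsv") {
    first <- readLines(path, n = 1L)
    has_header <- identical(tolower(strsplit(first, "\t")[[1]][1:2]),
                            c("child", "parent"))
    edges <- readr::read_tsv(
      path,
      col_names = if (has_header) TRUE else c("child", "parent"),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    names(edges)[1:2] <- c("child", "parent")
    ontology(edges[, c("child", "parent")])
  } else {
    ontology(parse_obo_edges(path))
  }
}

# Minimal OBO reader: [Term] stanzas, `id:` and `is_a:` tags. Obsolete terms
# are skipped. Enough for is_a hierarchies; relationship: tags are ignored.
parse_obo_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  child <- character()
  parent <- character()
  cur <- NA_character_
  in_term <- FALSE
  obsolete <- FALSE
  pend <- character()
  flush <- function() {
    if (!is.na(cur) && !obsolete && length(pend)) {
      child <<- c(child, rep(cur, length(pend)))
      parent <<- c(parent, pend)
    }
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur <- NA_character_; in_term <- TRUE; obsolete <- FALSE
      pend <- character()
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      pend <- c(pend, trimws(sub("^is_a:", "", ln)))
    } else if (in_term && grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  tibble::tibble(child = child, parent = parent)
}

#' Count distinct hyponyms (descendants) of every term
#'
#' A term's hyponyms are all terms below it in the hierarchy, following
#' parent edges transitively. With multiple inheritance a descendant can be
#' reachable along several paths; it is counted once (set semantics), which
#' keeps leaf terms at zero hyponyms and the root at `n_terms - 1`.
#'
#' @param onto A [ontology()] object.
#' @return A tibble with columns `term` and `hypo`.
#' @export
hyponym_counts <- function(onto) {
  stopifnot(inherits(onto, "pheno_ontology"))
  hypo <- vapply(onto$terms, function(t) {
    # vertices that can reach t along child->parent edges, minus t itself
    length(igraph::subcomponent(onto$graph, t, mode = "in")) - 1L
  }, integer(1))
  tibble::tibble(term = onto$terms, hypo = unname(hypo))
}

#' Information content of every ontology term
#'
#' Specificity is measured from the hierarchy itself rather than from corpus
#' annotation frequencies, avoiding annotation bias: a term with fewer
#' hyponyms is more specific. The information content is
#' \deqn{IC(t) = 1 - \frac{\log(hypo(t) + 1)}{\log N}}
#' where `hypo(t)` is the number of distinct descendants of `t` and `N` the
#' total number of terms. Leaves get IC 1, the root gets IC 0, and IC never
#' increases when moving from a term to one of its ancestors. The value is
#' a ratio of logarithms, so the base does not matter.
#'
#' @param onto A [ontology()] object with at least two terms.
#' @return A tibble with columns `term`, `hypo`, `ic`.
#' @export
term_ic <- function(onto) {
  stopifnot(inherits(onto, "pheno_ontology"))
  if (onto$n_terms < 2) {
    stop("information content is undefined for a single-term ontology (log N = 0)",
         call. = FALSE)
  }
  hc <- hyponym_counts(onto)
  hc$ic <- 1 - log(hc$hypo + 1) / log(onto$n_terms)
  hc
}

#' Write a term-IC table to TSV
#'
#' @param ic_tbl A tibble from [term_ic()].
#' @param path Output path; columns `term`, `hypo`, `ic` with IC printed to
#'   six decimals.
#' @export
write_term_ic <- function(ic_tbl, path) {
  out <- ic_tbl
  out$ic <- sprintf("%.6f", out$ic)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Ancestors of a term (including the term itself)
#'
#' @param onto A [ontology()] object.
#' @param term A term identifier.
#' @return Character vector of all terms reachable via parent edges,
#'   including `term` and the root.
#' @export
term_ancestors <- function(onto, term) {
  stopifnot(inherits(onto, "pheno_ontology"))
  if (!term %in% onto$terms) stop("unknown term: ", term, call. = FALSE)
  igraph::subcomponent(onto$graph, term, mode = "out")$name
}

#' Most informative common ancestor (MICA) of two terms
#'
#' The shared ancestor with maximal information content. When several common
#' ancestors tie on IC any one of them may be returned; only the IC value is
#' used by the similarity scores. The MICA of a term with itself is the term.
#'
#' @param onto A [ontology()] object.
#' @param ic A tibble from [term_ic()] (or any data frame with `term`, `ic`).
#' @param t1,t2 Term identifiers.
#' @return A one-row tibble with columns `term` (the MICA) and `ic`.
#' @export
mica <- function(onto, ic, t1, t2) {
  common <- intersect(term_ancestors(onto, t1), term_ancestors(onto, t2))
  icv <- ic$ic[match(common, ic$term)]
  if (anyNA(icv)) stop("IC table does not cover all ancestors", call. = FALSE)
  best <- which.max(icv)
  tibble::tibble(term = common[best], ic = icv[best])
}

# Logical ancestor-indicator matrix: rows = `terms`, columns = all ontology
# terms, TRUE where the column term is an ancestor (incl. self) of the row
# term. Backbone of the vectorized MICA-IC computation.
ancestor_matrix <- function(onto, terms) {
  mat <- matrix(FALSE, nrow = length(terms), ncol = onto$n_terms,
                dimnames = list(terms, onto$terms))
  for (i in seq_along(terms)) {
    mat[i, term_ancestors(onto, terms[i])] <- TRUE
  }
  mat
}

# IC of the MICA for every (row term, column term) combination.
# For each ontology term t (a candidate common ancestor) the outer product of
# the two indicator columns marks the pairs for which t is shared; a running
# pmax over ic(t) yields the maximum IC over shared ancestors.
mica_ic_matrix <- function(onto, ic, terms1, terms2) {
  a1 <- ancestor_matrix(onto, terms1)
  a2 <- ancestor_matrix(onto, terms2)
  icv <- ic$ic[match(onto$terms, ic$term)]
  out <- matrix(0, nrow = length(terms1), ncol = length(terms2),
                dimnames = list(terms1, terms2))
  ord <- order(icv, decreasing = TRUE)
  for (j in ord) {
    if (icv[j] <= 0) break  # remaining ancestors cannot raise the max
    r <- a1[, j]
    c <- a2[, j]
    if (!any(r) || !any(c)) next
    upd <- outer(r, c) & (out < icv[j])
    out[upd] <- icv[j]
  }
  out
}
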