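#' Build an undirected protein-protein interaction network
#'
#' @param edges Data frame with columns `protein_a`, `protein_b` (first two
#'   columns are used whatever their names). Edges are symmetrized and
#'   deduplicated; self-loop rows are dropped with a warning. Confidence
#'   filtering of interactions is assumed done upstream.
#' @return An undirected, simplified igraph of class `ppi_network`.
#' @export
ppi_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 2) stop("PPI edge table needs two columns", call. = FALSE)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop rows dropped", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
  }
  if (length(a) == 0) {
    warning("empty PPI network", call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::simplify(
      igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
    )
  }
  class(g) <- c("ppi_network", class(g))
  g
}

#' Read a PPI edge-list TSV
#'
#' @param path Path to a two-column `protein_a<TAB>protein_b` TSV (header
#'   optional, detected from a first line starting with `protein`).
#' @return A [ppi_network()] igraph.
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0 || !nzchar(first)) {
    return(ppi_network(tibble::tibble(protein_a = character(),
                                      protein_b = character())))
  }
  has_header <- grepl("^protein", tolower(first))
  df <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("protein_a", "protein_b"),
    col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  names(df)[1:2] <- c("protein_a", "protein_b")
  ppi_network(df)
}

#' Read an entity-to-protein map TSV
#'
#' Used for drug -> target and disease -> gene-product maps. Header required,
#' first column the entity identifier, second the protein identifier.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `entity`, `protein`.
#' @export
read_protein_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df)[1:2] <- c("entity", "protein")
  dplyr::distinct(df[, c("entity", "protein")])
}

#' Shortest network distance between a target set and a gene set
#'
#' The molecular distance of a drug-disease pair is the minimum shortest-path
#' length in the PPI network over all (drug target, disease protein)
#' combinations. Sets sharing a protein are at distance 0. Proteins absent
#' from the network are ignored; if an entire set is absent, an error is
#' raised. `Inf` marks pairs with no connecting path.
#'
#' @param ppi A [ppi_network()] igraph.
#' @param targets,genes Character vectors of protein identifiers (non-empty).
#' @return A single numeric distance (0, 1, 2, ... or `Inf`).
#' @export
set_distance <- function(ppi, targets, genes) {
  targets <- unique(targets)
  genes <- unique(genes)
  if (length(targets) == 0 || length(genes) == 0) {
    stop("both protein sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(targets, genes)) > 0) return(0)
  nodes <- igraph::V(ppi)$name
  t_in <- intersect(targets, nodes)
  g_in <- intersect(genes, nodes)
  if (length(t_in) == 0) stop("no target protein found in the network", call. = FALSE)
  if (length(g_in) == 0) stop("no disease protein found in the network", call. = FALSE)
  d <- igraph::distances(ppi, v = t_in, to = g_in)
  min(d)
}

#' Bin molecular distances into the five analysis categories
#'
#' Distances 0-3 keep their value; distances of 4 or more, and pairs with no
#' connecting path, fall into the `">3"` category so that the five categories
#' partition every pair (dropping unreachable pairs would change the lift
#' denominators).
#'
#' @param distance Numeric vector of distances (may contain `Inf`).
#' @return Factor with levels `"0", "1", "2", "3", ">3"`.
#' @export
distance_category <- function(distance) {
  capped <- as.integer(pmin(distance, 4))
  lab <- ifelse(capped <= 3L, as.character(capped), ">3")
  factor(lab, levels = c("0", "1", "2", "3", ">3"))
}

#' Molecular distances for every mapped drug-disease pair
#'
#' Enumerates all combinations of drugs with at least one in-network target
#' and diseases with at least one in-network protein, and computes the
#' set-to-set shortest distance for each. Entities whose proteins are all
#' absent from the network are excluded (with a warning), matching the usual
#' restriction of molecular benchmarks to network-mappable entities.
#'
#' @param ppi A [ppi_network()] igraph.
#' @param target_map Tibble `entity`, `protein` for drugs.
#' @param gene_map Tibble `entity`, `protein` for diseases.
#' @return Tibble `drug`, `disease`, `distance`, `category`.
#' @export
molecular_distances <- function(ppi, target_map, gene_map) {
  nodes <- igraph::V(ppi)$name
  tm <- target_map[target_map$protein %in% nodes, ]
  gm <- gene_map[gene_map$protein %in% nodes, ]
  drop_t <- setdiff(unique(target_map$entity), unique(tm$entity))
  drop_g <- setdiff(unique(gene_map$entity), unique(gm$entity))
  if (length(drop_t) + length(drop_g) > 0) {
    warning(length(drop_t), " drugs and ", length(drop_g),
            " diseases excluded: no protein in the network", call. = FALSE)
  }
  if (nrow(tm) == 0 || nrow(gm) == 0) {
    stop("no mappable entities on one side", call. = FALSE)
  }
  t_prot <- sort(unique(tm$protein))
  g_prot <- sort(unique(gm$protein))
  d <- igraph::distances(ppi, v = t_prot, to = g_prot)

  drugs <- sort(unique(tm$entity))
  diseases <- sort(unique(gm$entity))
  t_idx <- split(match(tm$protein, t_prot), tm$entity)[drugs]
  g_idx <- split(match(gm$protein, g_prot), gm$entity)[diseases]

  n_dr <- length(drugs); n_di <- length(diseases)
  dist <- matrix(Inf, n_dr, n_di)
  for (i in seq_len(n_dr)) {
    di <- d[t_idx[[i]], , drop = FALSE]
    mins <- if (nrow(di) == 1L) di[1, ] else apply(di, 2, min)
    for (j in seq_len(n_di)) dist[i, j] <- min(mins[g_idx[[j]]])
  }
  out <- tibble::tibble(
    drug = rep(drugs, times = n_di),
    disease = rep(diseases, each = n_dr),
    distance = as.vector(dist)
  )
  out$category <- distance_category(out$distance)
  out
}

#' Count drug-disease pairs per molecular distance category
#'
#' @param links Tibble from [molecular_distances()].
#' @return Tibble `category`, `n` with all five categories present.
#' @export
count_categories <- function(links) {
  dplyr::count(links, category = .data$category, .drop = FALSE)
}
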