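#' Configuration for the synthetic world generator
#'
#' Bundles every tunable of the generator with defaults chosen to emulate
#' the structure the analysis assumes: a four-level multi-parent term
#' hierarchy (organ-system subtrees down to specific preferred terms) with
#' one subtree attached only at the root plus a few cross-hierarchy bridge
#' edges; sparse entity-term annotations with heavy-tailed (Zipf) term
#' popularity; a random interaction network with per-entity protein sets;
#' phenotype coupling for molecularly close pairs; and clinical label rates
#' that are elevated at short molecular distance for ADR-disease and
#' contraindication relations but distance-independent for indications and
#' clinical trials.
#'
#' @param seed Integer seed; identical configuration and seed give
#'   identical output.
#' @param depth Number of hierarchy levels below the root.
#' @param n_subtrees Number of level-1 terms (organ-system subtrees).
#' @param branching Integer range (min, max) of children per internal term
#'   below level 1.
#' @param multi_parent_prob Probability that a term below the second level
#'   gains an extra parent from the level above (outside the isolated
#'   subtree).
#' @param cross_links Number of bridge edges giving terms of other subtrees
#'   an extra parent inside the isolated subtree.
#' @param n_drugs,n_diseases Entity counts.
#' @param annot_size Integer range of leaf terms annotated per entity.
#' @param n_focus Integer range of focus subtrees per entity: real phenotype
#'   profiles concentrate in a few organ systems rather than spreading
#'   uniformly, and the focus structure is what the class maps and the
#'   phenotype coupling act on.
#' @param focus_weight Probability that an annotated term is drawn from the
#'   entity's focus subtrees rather than from the whole leaf vocabulary.
#' @param zipf_exponent Exponent of the Zipf term-popularity law (weight
#'   proportional to rank^-exponent); 1 gives the classic heavy tail.
#' @param ppi_nodes,ppi_edges Size of the random interaction network.
#' @param proteins_per_entity Integer range of proteins per drug/disease.
#' @param coupling Probability that a disease at molecular distance <= 1
#'   from some drug has its symptoms re-drawn from that drug's side-effect
#'   subtrees, planting the molecular-phenotypic signal.
#' @param label_rates Named list of `c(base, near)` probabilities per
#'   relation: `near` applies to pairs at molecular distance <= 1, `base`
#'   everywhere else.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       depth = 4L,
                       n_subtrees = 10L,
                       branching = c(2L, 4L),
                       multi_parent_prob = 0.1,
                       cross_links = 5L,
                       n_drugs = 200L,
                       n_diseases = 300L,
                       annot_size = c(5L, 15L),
                       n_focus = c(1L, 2L),
                       focus_weight = 0.8,
                       zipf_exponent = 1,
                       ppi_nodes = 400L,
                       ppi_edges = 1600L,
                       proteins_per_entity = c(1L, 3L),
                       coupling = 0.8,
                       label_rates = list(
                         indication = c(base = 0.010, near = 0.010),
                         clinical_trial = c(base = 0.010, near = 0.010),
                         contraindication = c(base = 0.005, near = 0.080),
                         adr_disease = c(base = 0.010, near = 0.150)
                       )) {
  cfg <- list(seed = as.integer(seed), depth = as.integer(depth),
              n_subtrees = as.integer(n_subtrees),
              branching = as.integer(branching),
              multi_parent_prob = multi_parent_prob,
              cross_links = as.integer(cross_links),
              n_drugs = as.integer(n_drugs), n_diseases = as.integer(n_diseases),
              annot_size = as.integer(annot_size),
              n_focus = as.integer(n_focus), focus_weight = focus_weight,
              zipf_exponent = zipf_exponent,
              ppi_nodes = as.integer(ppi_nodes), ppi_edges = as.integer(ppi_edges),
              proteins_per_entity = as.integer(proteins_per_entity),
              coupling = coupling, label_rates = label_rates)
  stopifnot(cfg$depth >= 1, cfg$n_subtrees >= 2, cfg$branching[1] >= 1,
            cfg$branching[2] >= cfg$branching[1],
            cfg$focus_weight >= 0, cfg$focus_weight <= 1,
            cfg$n_focus[1] >= 1, cfg$n_focus[2] >= cfg$n_focus[1],
            cfg$multi_parent_prob >= 0, cfg$multi_parent_prob <= 1,
            cfg$coupling >= 0, cfg$coupling <= 1,
            cfg$n_drugs >= 1, cfg$n_diseases >= 1,
            all(unlist(cfg$label_rates) >= 0),
            all(unlist(cfg$label_rates) <= 1))
  structure(cfg, class = "sim_config")
}

# uniform draws from an integer range, safe for degenerate ranges
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# unseeded ontology builder; level of each term is tracked for the world
# generator (leaves = deepest level, subtree id = level-1 ancestor)
generate_ontology_impl <- function(cfg) {
  root <- "T0000"
  counter <- 0L
  new_ids <- function(k) {
    ids <- sprintf("T%04d", counter + seq_len(k))
    counter <<- counter + k
    ids
  }
  child <- character(); parent <- character()
  level <- stats::setNames(0L, root)
  subtree <- stats::setNames(NA_character_, root)

  draw_b <- function() sample_range(cfg$branching[1], cfg$branching[2])
  # level 1: subtree roots; the first is the isolated subtree
  n1 <- cfg$n_subtrees
  l1 <- new_ids(n1)
  child <- c(child, l1); parent <- c(parent, rep(root, n1))
  level[l1] <- 1L
  subtree[l1] <- l1
  prev <- l1
  for (lv in seq_len(cfg$depth)[-1]) {
    if (length(prev) == 0) break
    cur <- character()
    for (p in prev) {
      kids <- new_ids(draw_b())
      child <- c(child, kids); parent <- c(parent, rep(p, length(kids)))
      level[kids] <- lv
      subtree[kids] <- subtree[p]
      cur <- c(cur, kids)
    }
    # extra parents within the non-isolated part of the previous level
    open_prev <- prev[subtree[prev] != l1[1]]
    open_cur <- cur[subtree[cur] != l1[1]]
    if (length(open_prev) >= 2 && length(open_cur) > 0) {
      extra <- open_cur[stats::runif(length(open_cur)) < cfg$multi_parent_prob]
      for (ch in extra) {
        cand <- setdiff(open_prev, parent[child == ch])
        if (length(cand)) {
          pp <- cand[sample.int(length(cand), 1)]
          child <- c(child, ch); parent <- c(parent, pp)
        }
      }
    }
    prev <- cur
  }
  # bridge edges: terms of other subtrees gain a parent inside the isolated
  # subtree one level up (acyclic by construction: parents are shallower)
  iso <- names(subtree)[!is.na(subtree) & subtree == l1[1]]
  if (cfg$cross_links > 0 && length(iso) > 0 && cfg$depth >= 2) {
    for (i in seq_len(cfg$cross_links)) {
      lv <- sample_range(2L, cfg$depth)
      cand_child <- names(level)[level == lv & !is.na(subtree) &
                                   subtree != l1[1]]
      cand_par <- iso[level[iso] == lv - 1L]
      if (length(cand_child) && length(cand_par)) {
        ch <- cand_child[sample.int(length(cand_child), 1)]
        pp <- cand_par[sample.int(length(cand_par), 1)]
        if (!any(child == ch & parent == pp)) {
          child <- c(child, ch); parent <- c(parent, pp)
        }
      }
    }
  }
  onto <- ontology(tibble::tibble(child = child, parent = parent))
  attr(onto, "level") <- level[onto$terms]
  attr(onto, "subtree") <- subtree[onto$terms]
  onto
}

#' Generate a synthetic phenotype ontology
#'
#' Builds a rooted multi-parent DAG with `depth` levels below the root: the
#' level-1 terms act as organ-system subtrees, one of which is attached only
#' at the root (emulating a hierarchy branch that shares no terms with the
#' rest) except for a configured number of cross-hierarchy bridge edges.
#'
#' @param cfg A [sim_config()].
#' @return A [ontology()] object with `level` and `subtree` attributes.
#' @export
simulate_ontology <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, generate_ontology_impl(cfg))
}

# Draw one entity profile: `size` distinct leaves, Zipf-weighted, with a
# fraction `focus_weight` of draws restricted to the entity's focus subtrees.
draw_profile <- function(leaves, popularity, size, focus_pool, focus_weight) {
  size <- min(size, length(leaves))
  n_focus_draw <- sum(stats::runif(size) < focus_weight)
  n_focus_draw <- min(n_focus_draw, length(focus_pool))
  from_focus <- if (n_focus_draw > 0) {
    focus_pool[sample.int(length(focus_pool), n_focus_draw,
                          prob = popularity[focus_pool])]
  } else integer()
  rest <- setdiff(seq_along(leaves), from_focus)
  n_bg <- size - n_focus_draw
  from_bg <- if (n_bg > 0) {
    rest[sample.int(length(rest), n_bg, prob = popularity[rest])]
  } else integer()
  leaves[c(from_focus, from_bg)]
}

#' Generate a full synthetic analysis world
#'
#' Produces every input the pipeline consumes, with the planted structure
#' the benchmarks probe for:
#'
#' * annotations: each entity draws leaf terms under a Zipf popularity law,
#'   giving heavy-tailed frequency weights and correlated co-occurrence;
#' * interaction network: a uniform random graph; each drug and disease is
#'   assigned a small protein set;
#' * molecular-phenotypic coupling: a disease at network distance <= 1 from
#'   some drug has, with probability `coupling`, its symptoms re-drawn from
#'   the organ-system subtrees of that drug's side effects, so molecularly
#'   close pairs share phenotypes;
#' * clinical labels: sampled per pair with `near` rates at molecular
#'   distance <= 1 and `base` rates elsewhere — elevated for ADR-disease and
#'   contraindication relations, flat for indications and clinical trials;
#' * classes: each entity's class is the organ-system subtree dominating its
#'   annotation profile (disease classes MeSH-like, drug classes MoA-like).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `pheno_world` with elements `ontology`,
#'   `drug_annotations`, `disease_annotations`, `ppi`, `targets`, `genes`,
#'   `molecular`, `labels`, `disease_classes`, `drug_classes`, `config`.
#' @export
simulate_world <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    onto <- generate_ontology_impl(cfg)
    level <- attr(onto, "level")
    subtree <- attr(onto, "subtree")
    leaves <- onto$terms[level == cfg$depth]
    if (length(leaves) < cfg$annot_size[2]) {
      stop("ontology too small for the requested annotation sizes", call. = FALSE)
    }
    popularity <- sample(seq_along(leaves))^(-cfg$zipf_exponent)
    subtree_ids <- sort(unique(subtree[leaves]))
    leaf_subtree <- subtree[leaves]

    drugs <- sprintf("DR%04d", seq_len(cfg$n_drugs))
    diseases <- sprintf("DI%04d", seq_len(cfg$n_diseases))

    proteins <- sprintf("P%04d", seq_len(cfg$ppi_nodes))
    g <- igraph::sample_gnm(cfg$ppi_nodes, cfg$ppi_edges)
    igraph::V(g)$name <- proteins
    class(g) <- c("ppi_network", class(g))

    # organ-system domains on the interaction network: a few center proteins
    # are seeded per subtree and every protein takes the subtree of its
    # nearest center (BFS Voronoi cells), so interacting proteins tend to
    # share a label, label agreement decays with network distance, and far
    # apart proteins agree only at the 1/n_subtrees baseline
    centers_per_subtree <- 3L
    center_sub <- rep(subtree_ids, centers_per_subtree)
    centers <- sample(proteins, min(length(center_sub), cfg$ppi_nodes))
    center_sub <- center_sub[seq_along(centers)]
    dc <- igraph::distances(g, v = centers)
    # Voronoi cells around the centers, ties broken by uniform jitter; each
    # cell carries the (independently random) subtree of its center. Nearby
    # proteins thus tend to fall in the same cell and share a label, while
    # proteins in different cells agree only at the 1/n_subtrees baseline —
    # agreement decays monotonically with network distance and carries no
    # long-range structure. Disconnected proteins get uniform labels.
    d_jit <- pmin(dc, 30) + matrix(stats::runif(length(dc), 0, 0.5),
                                   nrow = nrow(dc))
    nearest <- apply(d_jit, 2, which.min)
    prot_label <- center_sub[nearest]
    unreachable <- apply(dc, 2, function(x) all(!is.finite(x)))
    if (any(unreachable)) {
      prot_label[unreachable] <- sample(subtree_ids, sum(unreachable),
                                        replace = TRUE)
    }
    names(prot_label) <- proteins

    pick_prot <- function(ids) {
      k <- sample_range(cfg$proteins_per_entity[1], cfg$proteins_per_entity[2],
                        length(ids))
      tibble::tibble(
        entity = rep(ids, k),
        protein = unlist(lapply(k, function(kk) sample(proteins, kk)))
      )
    }
    targets <- pick_prot(drugs)
    genes <- pick_prot(diseases)
    molecular <- molecular_distances(g, targets, genes)

    # drug side effects always reflect the organ systems of the drug's
    # targets; a disease reflects its proteins' organ systems with
    # probability `coupling`, otherwise an unrelated random focus — so a
    # molecularly related pair draws annotations from shared subtrees with
    # probability `coupling`, and the phenotypic signal decays with network
    # distance through the label domains
    # focus-set size is drawn independently of the protein count, so the
    # number of targets does not itself change how concentrated a profile is
    draw_entity <- function(prots, protein_driven) {
      k <- sample_range(cfg$n_focus[1], cfg$n_focus[2])
      focus <- if (protein_driven) {
        labs <- unname(prot_label[prots])
        unique(labs[sample.int(length(labs), min(k, length(labs)))])
      } else {
        subtree_ids[sample.int(length(subtree_ids),
                               min(k, length(subtree_ids)))]
      }
      pool <- which(leaf_subtree %in% focus)
      size <- sample_range(cfg$annot_size[1], cfg$annot_size[2])
      draw_profile(leaves, popularity, size, pool, cfg$focus_weight)
    }
    prot_of_drug <- split(targets$protein, targets$entity)[drugs]
    prot_of_dis <- split(genes$protein, genes$entity)[diseases]
    drug_prof <- stats::setNames(
      lapply(drugs, function(d) draw_entity(prot_of_drug[[d]], TRUE)), drugs)
    dis_prof <- stats::setNames(
      lapply(diseases, function(e) {
        draw_entity(prot_of_dis[[e]], stats::runif(1) < cfg$coupling)
      }), diseases)

    drug_annot <- annotations(
      tibble::tibble(entity = rep(drugs, lengths(drug_prof)),
                     term = unlist(drug_prof, use.names = FALSE)),
      kind = "drug", onto = onto
    )
    disease_annot <- annotations(
      tibble::tibble(entity = rep(diseases, lengths(dis_prof)),
                     term = unlist(dis_prof, use.names = FALSE)),
      kind = "disease", onto = onto
    )

    # labels over the full pair universe, rates depending on distance <= 1
    pairs <- tidyr::expand_grid(drug = drugs, disease = diseases)
    near <- molecular[molecular$distance <= 1, ]
    near_keys <- pair_key(near$drug, near$disease)
    is_near <- pair_key(pairs$drug, pairs$disease) %in% near_keys
    labels <- purrr::imap_dfr(cfg$label_rates, function(rates, rel) {
      p <- ifelse(is_near, rates[["near"]], rates[["base"]])
      hit <- stats::runif(nrow(pairs)) < p
      if (!any(hit)) return(NULL)
      dplyr::mutate(pairs[hit, ], relation = rel)
    })

    dominant_subtree <- function(prof) {
      names(which.max(table(subtree[prof])))
    }
    disease_classes <- tibble::tibble(
      entity = diseases,
      class = paste0("MSH_", vapply(dis_prof, dominant_subtree, character(1)))
    )
    drug_classes <- tibble::tibble(
      entity = drugs,
      class = paste0("MOA_", vapply(drug_prof, dominant_subtree, character(1)))
    )

    structure(list(ontology = onto,
                   drug_annotations = drug_annot,
                   disease_annotations = disease_annot,
                   ppi = g, targets = targets, genes = genes,
                   molecular = molecular, labels = labels,
                   disease_classes = disease_classes,
                   drug_classes = drug_classes,
                   config = cfg),
              class = "pheno_world")
  })
}

#' @export
print.pheno_world <- function(x, ...) {
  cat("<pheno_world> ", x$config$n_drugs, " drugs, ",
      x$config$n_diseases, " diseases, ontology of ",
      x$ontology$n_terms, " terms, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to the TSV dialects the readers consume
#'
#' @param world A [simulate_world()] result.
#' @param dir Output directory (created if missing). Files written:
#'   `ontology.tsv`, `drug_annotations.tsv`, `disease_annotations.tsv`,
#'   `ppi.tsv`, `drug_targets.tsv`, `disease_genes.tsv`, `labels.tsv`,
#'   `disease_classes.tsv`, `drug_classes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "pheno_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(world$ontology$edges, p("ontology.tsv"), progress = FALSE)
  wr_annot <- function(a, f) {
    readr::write_tsv(
      tibble::tibble(entity_id = a$entity, term_id = a$term), p(f),
      progress = FALSE)
  }
  wr_annot(world$drug_annotations, "drug_annotations.tsv")
  wr_annot(world$disease_annotations, "disease_annotations.tsv")
  ed <- igraph::as_data_frame(world$ppi, what = "edges")
  readr::write_tsv(tibble::tibble(protein_a = ed$from, protein_b = ed$to),
                   p("ppi.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(drug_id = world$targets$entity,
                   protein_id = world$targets$protein),
    p("drug_targets.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(disease_id = world$genes$entity,
                   protein_id = world$genes$protein),
    p("disease_genes.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(drug_id = world$labels$drug,
                   disease_id = world$labels$disease,
                   relation = world$labels$relation),
    p("labels.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(entity_id = world$disease_classes$entity,
                   class_id = world$disease_classes$class),
    p("disease_classes.tsv"), progress = FALSE)
  readr::write_tsv(
    tibble::tibble(entity_id = world$drug_classes$entity,
                   class_id = world$drug_classes$class),
    p("drug_classes.tsv"), progress = FALSE)
  invisible(dir)
}
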