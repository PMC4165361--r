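#' Read a clinical relation label TSV
#'
#' @param path TSV `drug_id<TAB>disease_id<TAB>relation` with header.
#'   Relations are typically `indication`, `contraindication`,
#'   `clinical_trial`, `adr_disease`; a pair may carry several relations.
#' @return Tibble `drug`, `disease`, `relation`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df)[1:3] <- c("drug", "disease", "relation")
  dplyr::distinct(df[, c("drug", "disease", "relation")])
}

# canonical pair key used throughout the benchmark code
pair_key <- function(drug, disease) paste(drug, disease, sep = "\r")

# top slice of the ranked list at a given rate, ties at the cutoff included
top_slice_size <- function(similarity, rate) {
  n <- length(similarity)
  k <- ceiling(rate * n)
  cutoff <- similarity[k]
  sum(similarity >= cutoff)
}

#' Lift curve of a positive pair set along the similarity ranking
#'
#' For each rate of positive prediction r, the top `ceiling(r * n)` pairs of
#' the similarity-ranked list are taken as predictions; pairs tied with the
#' score at the cutoff are included as well. The lift is the precision in
#' that slice divided by the prevalence of positives in the whole list, so a
#' random ordering has expected lift 1 at every rate and the curve ends at
#' exactly 1 at rate 1.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param positives Data frame with columns `drug`, `disease` giving the
#'   labeled pairs; must be a subset of the scored universe.
#' @param rates Increasing rates in (0, 1].
#' @return Tibble of class `lift_curve` with columns `rate`, `top_size`,
#'   `tp`, `precision`, `lift`, and attributes `positives_total` and `total`.
#' @export
lift_curve <- function(scored, positives,
                       rates = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  if (nrow(positives) == 0) stop("empty positive set", call. = FALSE)
  if (any(rates <= 0 | rates > 1)) {
    stop("rates must lie in (0, 1]", call. = FALSE)
  }
  rates <- sort(unique(rates))
  keys <- pair_key(scored$drug, scored$disease)
  pos_keys <- unique(pair_key(positives$drug, positives$disease))
  if (!all(pos_keys %in% keys)) {
    stop(sum(!pos_keys %in% keys),
         " positive pairs are not in the scored universe", call. = FALSE)
  }
  is_pos <- keys %in% pos_keys
  n <- length(keys)
  p_total <- sum(is_pos)
  prevalence <- p_total / n
  cum_tp <- cumsum(is_pos)
  out <- purrr::map_dfr(rates, function(r) {
    size <- top_slice_size(scored$similarity, r)
    tp <- cum_tp[size]
    prec <- tp / size
    tibble::tibble(rate = r, top_size = size, tp = tp,
                   precision = prec, lift = prec / prevalence)
  })
  structure(out, class = c("lift_curve", class(out)),
            positives_total = p_total, total = n)
}

#' Lift curves per clinical relation type
#'
#' One curve per relation plus a pooled `"all"` curve over the union of the
#' labeled pair sets. Relations without any labeled pair in the scored
#' universe are skipped with a warning.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param labels Tibble `drug`, `disease`, `relation` (see [read_labels()]).
#' @inheritParams lift_curve
#' @return Tibble with columns `relation`, `rate`, `top_size`, `tp`,
#'   `precision`, `lift`, `n_positives`.
#' @export
lift_by_relation <- function(scored, labels,
                             rates = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  rels <- sort(unique(labels$relation))
  if (length(rels) == 0) stop("no relations in labels", call. = FALSE)
  sets <- c(
    stats::setNames(lapply(rels, function(r) {
      dplyr::distinct(labels[labels$relation == r, c("drug", "disease")])
    }), rels),
    list(all = dplyr::distinct(labels[, c("drug", "disease")]))
  )
  purrr::imap_dfr(sets, function(pp, nm) {
    if (nrow(pp) == 0) {
      warning("relation without pairs skipped: ", nm, call. = FALSE)
      return(NULL)
    }
    lc <- lift_curve(scored, pp, rates)
    dplyr::mutate(tibble::as_tibble(lc), relation = nm,
                  n_positives = attr(lc, "positives_total"),
                  .before = 1)
  })
}

#' Lift curves per relation and molecular distance category
#'
#' Within each relation, the positives are restricted to one molecular
#' distance category at a time, asking whether e.g. contraindicated pairs
#' whose targets and disease proteins coincide are more strongly enriched at
#' the top of the ranking than distant ones. The scored universe is
#' restricted to pairs with molecular information. Categories with no
#' labeled pair are skipped; sparse categories are flagged `low_n`.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param labels Tibble `drug`, `disease`, `relation`.
#' @param molecular Tibble from [molecular_distances()].
#' @inheritParams lift_curve
#' @param low_n Flag categories with fewer labeled pairs than this.
#' @return Tibble with columns `relation`, `category`, `n_positives`,
#'   `low_n`, `rate`, `top_size`, `tp`, `precision`, `lift`.
#' @export
lift_by_distance <- function(scored, labels, molecular,
                             rates = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                             low_n = 5L) {
  mol_scored <- dplyr::semi_join(scored, molecular, by = c("drug", "disease"))
  lab_mol <- dplyr::inner_join(dplyr::distinct(labels),
                               molecular[, c("drug", "disease", "category")],
                               by = c("drug", "disease"))
  combos <- dplyr::distinct(lab_mol[, c("relation", "category")])
  combos <- dplyr::arrange(combos, .data$relation, .data$category)
  purrr::pmap_dfr(combos, function(relation, category) {
    pp <- lab_mol[lab_mol$relation == relation & lab_mol$category == category,
                  c("drug", "disease")]
    pp <- dplyr::distinct(pp)
    if (nrow(pp) == 0) return(NULL)
    lc <- lift_curve(mol_scored, pp, rates)
    dplyr::mutate(tibble::as_tibble(lc),
                  relation = relation, category = category,
                  n_positives = nrow(pp), low_n = nrow(pp) < low_n,
                  .before = 1)
  })
}

# non-dominated front of a two-objective maximization
pareto_front_idx <- function(x, y) {
  idx <- seq_along(x)
  dominated <- vapply(idx, function(i) {
    any(x >= x[i] & y >= y[i] & (x > x[i] | y > y[i]))
  }, logical(1))
  idx[!dominated]
}

#' Select a similarity threshold by Pareto optimization
#'
#' Evaluates, over a grid of candidate thresholds, the enrichment (lift) and
#' precision of molecular distance-0/1 pairs among the pairs scoring at or
#' above each threshold, and returns the non-dominated front together with
#' one selected point. Because lift is precision divided by a constant
#' prevalence, the two stated objectives rank candidates identically and the
#' front can collapse; the retained fraction of distance-0/1 pairs
#' (`recall01`) is therefore also reported, and can be swapped in as second
#' objective to obtain a genuine precision/coverage trade-off.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param molecular Tibble from [molecular_distances()]; only pairs present
#'   here (the molecularly covered universe) are used.
#' @param objectives Two of `"lift01"`, `"precision01"`, `"recall01"`.
#' @param selector `"max_product"` picks the front point maximizing the
#'   product of min-max-normalized objectives; `"knee"` picks the front
#'   point farthest from the segment joining the front extremes.
#' @param max_candidates Grid size; when more distinct scores exist, an
#'   evenly spaced quantile grid of this size is used.
#' @return List of class `pareto_result`: `grid` (all evaluated thresholds
#'   with `threshold`, `n_above`, `lift01`, `precision01`, `recall01`),
#'   `front` (non-dominated subset), `selected` (one row).
#' @export
pareto_threshold <- function(scored, molecular,
                             objectives = c("lift01", "precision01"),
                             selector = c("max_product", "knee"),
                             max_candidates = 100L) {
  selector <- match.arg(selector)
  stopifnot(length(objectives) == 2,
            all(objectives %in% c("lift01", "precision01", "recall01")))
  mol <- dplyr::inner_join(
    scored, molecular[, c("drug", "disease", "category")],
    by = c("drug", "disease")
  )
  if (nrow(mol) == 0) stop("no molecularly covered scored pairs", call. = FALSE)
  close01 <- mol$category %in% c("0", "1")
  prev <- mean(close01)
  if (prev == 0) stop("no distance-0/1 pairs to optimize for", call. = FALSE)

  cand <- sort(unique(mol$similarity))
  if (length(cand) < 2) stop("need at least two candidate thresholds", call. = FALSE)
  if (length(cand) > max_candidates) {
    cand <- unique(quantile(mol$similarity,
                            probs = seq(0, 1, length.out = max_candidates),
                            names = FALSE, type = 1))
  }
  ord <- order(mol$similarity, decreasing = TRUE)
  sim_sorted <- mol$similarity[ord]
  pos_sorted <- close01[ord]
  cum_tp <- cumsum(pos_sorted)
  total01 <- sum(close01)
  grid <- purrr::map_dfr(cand, function(th) {
    n_above <- sum(sim_sorted >= th)
    tp <- if (n_above > 0) cum_tp[n_above] else 0L
    prec <- if (n_above > 0) tp / n_above else 0
    tibble::tibble(threshold = th, n_above = n_above,
                   precision01 = prec, lift01 = prec / prev,
                   recall01 = tp / total01)
  })

  ox <- grid[[objectives[1]]]
  oy <- grid[[objectives[2]]]
  if (length(unique(ox)) == 1 || length(unique(oy)) == 1) {
    warning("degenerate objective (constant on the grid); returning the ",
            "highest candidate threshold", call. = FALSE)
    sel <- which.max(grid$threshold)
    front <- grid[sel, ]
  } else {
    fi <- pareto_front_idx(ox, oy)
    front <- dplyr::arrange(grid[fi, ], .data$threshold)
    norm <- function(v) (v - min(v)) / max(max(v) - min(v), .Machine$double.eps)
    nx <- norm(ox); ny <- norm(oy)
    if (selector == "max_product") {
      sel <- fi[which.max(nx[fi] * ny[fi])]
    } else {
      fx <- nx[fi]; fy <- ny[fi]
      i1 <- which.min(fx); i2 <- which.max(fx)
      dx <- fx[i2] - fx[i1]; dy <- fy[i2] - fy[i1]
      seg <- sqrt(dx^2 + dy^2)
      dist <- abs(dx * (fy[i1] - fy) - (fx[i1] - fx) * dy) / max(seg, .Machine$double.eps)
      sel <- fi[which.max(dist)]
    }
  }
  structure(list(grid = grid, front = front, selected = grid[sel, ],
                 objectives = objectives, selector = selector),
            class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  cat("<pareto_result> objectives:", paste(x$objectives, collapse = " vs "),
      "| selector:", x$selector, "\n")
  cat("selected threshold:", format(x$selected$threshold, digits = 6),
      "(", x$selected$n_above, "pairs above )\n")
  invisible(x)
}

#' @rdname pareto_threshold
#' @param x A `pareto_result`.
#' @param ... Unused.
#' @export
tidy.pareto_result <- function(x, ...) tibble::as_tibble(x$front)

#' @rdname pareto_threshold
#' @export
glance.pareto_result <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$selected),
                n_candidates = nrow(x$grid),
                n_front = nrow(x$front))
}

#' Compare similarity distributions between relation types
#'
#' Two-sided Wilcoxon rank-sum tests on the similarity scores of every pair
#' of relation types, with Benjamini-Hochberg adjustment over all tests.
#' Effect direction is reported as the difference of medians (first minus
#' second relation). Relations with fewer than two labeled pairs are skipped.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param labels Tibble `drug`, `disease`, `relation`.
#' @return Tibble `relation_a`, `relation_b`, `n_a`, `n_b`, `statistic`,
#'   `p_value`, `p_adjusted`, `median_diff`.
#' @export
compare_relation_scores <- function(scored, labels) {
  joined <- dplyr::inner_join(dplyr::distinct(labels), scored,
                              by = c("drug", "disease"))
  groups <- split(joined$similarity, joined$relation)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) < 2) {
    stop("need at least two relations with >= 2 pairs each", call. = FALSE)
  }
  combs <- utils::combn(names(groups), 2)
  out <- purrr::map_dfr(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    wt <- suppressWarnings(wilcox.test(groups[[a]], groups[[b]],
                                       alternative = "two.sided"))
    tibble::tibble(relation_a = a, relation_b = b,
                   n_a = length(groups[[a]]), n_b = length(groups[[b]]),
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   median_diff = median(groups[[a]]) - median(groups[[b]]))
  })
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out[, c("relation_a", "relation_b", "n_a", "n_b", "statistic",
          "p_value", "p_adjusted", "median_diff")]
}

#' Fraction of a relation's pairs that are also ADR-disease pairs, by rate
#'
#' Ranks the pairs of one relation (e.g. contraindications) by phenotypic
#' similarity and reports, within each top-rate slice, the fraction that is
#' also labeled as an ADR-disease pair — i.e. the disease is a reported side
#' effect of the drug. A fraction that rises towards the top of the ranking
#' indicates that highly similar pairs of that relation tend to share a
#' causative mechanism.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param labels Tibble `drug`, `disease`, `relation` containing
#'   `adr_disease` labels.
#' @param relation Which relation's pairs to rank.
#' @inheritParams lift_curve
#' @return Tibble `rate`, `n_pairs`, `n_adr`, `fraction`, plus attribute
#'   `score_cutoffs` (per-rate similarity cutoffs).
#' @export
adr_fraction_curve <- function(scored, labels,
                               relation = c("contraindication", "indication"),
                               rates = c(0.02, 0.05, 0.1, 0.2, 0.5, 1)) {
  relation <- match.arg(relation)
  rates <- sort(unique(rates))
  rel_pairs <- dplyr::distinct(
    labels[labels$relation == relation, c("drug", "disease")]
  )
  adr_keys <- unique(pair_key(labels$drug[labels$relation == "adr_disease"],
                              labels$disease[labels$relation == "adr_disease"]))
  ranked <- dplyr::inner_join(scored, rel_pairs, by = c("drug", "disease"))
  if (nrow(ranked) == 0) stop("no scored pairs for relation ", relation, call. = FALSE)
  is_adr <- pair_key(ranked$drug, ranked$disease) %in% adr_keys
  cum_adr <- cumsum(is_adr)
  cutoffs <- numeric(length(rates))
  out <- purrr::map_dfr(seq_along(rates), function(i) {
    size <- top_slice_size(ranked$similarity, rates[i])
    cutoffs[i] <<- ranked$similarity[size]
    tibble::tibble(rate = rates[i], n_pairs = size, n_adr = cum_adr[size],
                   fraction = cum_adr[size] / size)
  })
  structure(out, class = c("adr_fraction_curve", class(out)),
            score_cutoffs = cutoffs)
}

#' Candidate contraindications from highly similar ADR-disease pairs
#'
#' Pairs in the top fraction of the full similarity ranking whose disease is
#' a reported side effect of the drug (ADR-disease label) but that are not
#' yet labeled as contraindications are proposed as precautions or potential
#' contraindications.
#'
#' @param scored Ranked pair table from [score_pairs()].
#' @param labels Tibble `drug`, `disease`, `relation` with `adr_disease` and
#'   `contraindication` labels.
#' @param top_fraction Fraction of the ranked list considered highly similar
#'   (ties at the cutoff included).
#' @return Tibble `drug`, `disease`, `similarity` of candidates, ranked;
#'   attributes `score_cutoff` and `top_size` record the applied cutoff.
#' @export
candidate_contraindications <- function(scored, labels, top_fraction = 0.02) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  size <- top_slice_size(scored$similarity, top_fraction)
  cutoff <- scored$similarity[size]
  top <- scored[seq_len(size), ]
  keys <- pair_key(top$drug, top$disease)
  adr_keys <- unique(pair_key(labels$drug[labels$relation == "adr_disease"],
                              labels$disease[labels$relation == "adr_disease"]))
  ci_keys <- unique(pair_key(labels$drug[labels$relation == "contraindication"],
                             labels$disease[labels$relation == "contraindication"]))
  cand <- top[keys %in% adr_keys & !keys %in% ci_keys,
              c("drug", "disease", "similarity")]
  structure(tibble::as_tibble(cand), score_cutoff = cutoff, top_size = size)
}
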