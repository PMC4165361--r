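#' Similarity score of one side-effect / symptom term pair
#'
#' The score of a (side effect, symptom) term pair is the information content
#' of their most informative common ancestor, multiplied by the smaller of
#' the two combined term weights:
#' \deqn{s = IC_{MICA} \cdot \min(f_{adr} c_{adr},\; f_{sym} c_{sym})}
#' Taking the minimum emphasizes phenotypes that are specific on both the
#' drug and the disease side; a pair whose only shared ancestor is the root
#' scores 0 regardless of weights.
#'
#' @param adr Side-effect term identifier.
#' @param symptom Symptom term identifier.
#' @param onto A [ontology()] object.
#' @param ic Term-IC tibble from [term_ic()].
#' @param drug_weights,disease_weights Weight tibbles from [term_weights()]
#'   for the drug-side and disease-side annotation tables.
#' @return A one-row tibble with columns `adr`, `symptom`, `s`.
#' @export
term_pair_score <- function(adr, symptom, onto, ic, drug_weights, disease_weights) {
  wa <- drug_weights$w[match(adr, drug_weights$term)]
  ws <- disease_weights$w[match(symptom, disease_weights$term)]
  if (is.na(wa)) stop("no drug-side weight for term: ", adr, call. = FALSE)
  if (is.na(ws)) stop("no disease-side weight for term: ", symptom, call. = FALSE)
  m <- mica(onto, ic, adr, symptom)
  tibble::tibble(adr = adr, symptom = symptom, s = m$ic * min(wa, ws))
}

# Score matrix over two term sets: S[a, s] = IC_MICA(a, s) * min(w_a, w_s).
# Weights are profile-independent, so this matrix is shared across all
# drug-disease pairs and is the workhorse of score_pairs().
term_score_matrix <- function(onto, ic, adr_terms, sym_terms,
                              drug_weights, disease_weights) {
  wa <- drug_weights$w[match(adr_terms, drug_weights$term)]
  ws <- disease_weights$w[match(sym_terms, disease_weights$term)]
  if (anyNA(wa)) {
    stop("no drug-side weight for term: ",
         adr_terms[which(is.na(wa))[1]], call. = FALSE)
  }
  if (anyNA(ws)) {
    stop("no disease-side weight for term: ",
         sym_terms[which(is.na(ws))[1]], call. = FALSE)
  }
  micas <- mica_ic_matrix(onto, ic, adr_terms, sym_terms)
  micas * outer(wa, ws, pmin)
}

#' Best-matching partner scores for two phenotype profiles
#'
#' For each side effect of the drug, the best match is the symptom with the
#' highest term-pair score, and vice versa for each symptom. Ties keep the
#' maximal value; the identity of the partner is irrelevant downstream.
#'
#' @param drug_profile Character vector of side-effect terms (non-empty).
#' @param disease_profile Character vector of symptom terms (non-empty).
#' @inheritParams term_pair_score
#' @return A list with named numeric vectors `best_adr` (one entry per side
#'   effect) and `best_symptom` (one entry per symptom).
#' @export
best_matches <- function(drug_profile, disease_profile, onto, ic,
                         drug_weights, disease_weights) {
  drug_profile <- unique(drug_profile)
  disease_profile <- unique(disease_profile)
  if (length(drug_profile) == 0 || length(disease_profile) == 0) {
    stop("both profiles must be non-empty", call. = FALSE)
  }
  s <- term_score_matrix(onto, ic, drug_profile, disease_profile,
                         drug_weights, disease_weights)
  list(
    best_adr = apply(s, 1, max),
    best_symptom = apply(s, 2, max)
  )
}

#' Phenotypic similarity of one drug-disease pair
#'
#' Sums the best-match scores of all side effects and all symptoms and
#' normalizes by the total number of phenotypic features:
#' \deqn{similarity = \frac{\sum_i best_{adr_i} + \sum_j best_{sym_j}}{n + m}}
#' The normalization removes the bias towards entities with many annotated
#' phenotypes that a plain sum would introduce.
#'
#' @param drug,disease Entity identifiers.
#' @param drug_annot,disease_annot [annotations()] tibbles.
#' @inheritParams term_pair_score
#' @param ic Optional precomputed [term_ic()] table.
#' @param drug_weights,disease_weights Optional precomputed [term_weights()].
#' @return A one-row tibble `drug`, `disease`, `similarity`, `n`, `m`.
#' @export
pair_similarity <- function(drug, disease, drug_annot, disease_annot, onto,
                            ic = NULL, drug_weights = NULL,
                            disease_weights = NULL) {
  ic <- ic %||% term_ic(onto)
  drug_weights <- drug_weights %||% term_weights(drug_annot)
  disease_weights <- disease_weights %||% term_weights(disease_annot)
  dp <- drug_annot$term[drug_annot$entity == drug]
  ep <- disease_annot$term[disease_annot$entity == disease]
  if (length(dp) == 0) stop("drug has no annotations: ", drug, call. = FALSE)
  if (length(ep) == 0) stop("disease has no annotations: ", disease, call. = FALSE)
  bm <- best_matches(dp, ep, onto, ic, drug_weights, disease_weights)
  n <- length(bm$best_adr)
  m <- length(bm$best_symptom)
  tibble::tibble(
    drug = drug, disease = disease,
    similarity = (sum(bm$best_adr) + sum(bm$best_symptom)) / (n + m),
    n = n, m = m
  )
}

#' Score every drug-disease pair by phenotypic similarity
#'
#' Computes the weighted best-match similarity for the full cross product of
#' annotated drugs and diseases and returns the ranked pair table. Term-pair
#' scores depend only on the two terms, not on the entities, so a single
#' term-by-term score matrix is computed once; per-drug column maxima and
#' per-disease row maxima then give all best-match sums as two matrix
#' products, making the all-pairs pass fast and exactly equivalent to
#' calling [pair_similarity()] pair by pair.
#'
#' @param drug_annot,disease_annot [annotations()] tibbles (only annotated
#'   entities enter the table).
#' @param onto A [ontology()] object.
#' @param ic,drug_weights,disease_weights Optional precomputed tables.
#' @return A tibble of class `pheno_scores` with columns `drug`, `disease`,
#'   `similarity`, `n`, `m`, sorted by decreasing similarity with ties broken
#'   by (drug, disease) identifier order.
#' @export
score_pairs <- function(drug_annot, disease_annot, onto, ic = NULL,
                        drug_weights = NULL, disease_weights = NULL) {
  if (nrow(drug_annot) == 0 || nrow(disease_annot) == 0) {
    stop("both annotation tables must be non-empty", call. = FALSE)
  }
  ic <- ic %||% term_ic(onto)
  drug_weights <- drug_weights %||% term_weights(drug_annot)
  disease_weights <- disease_weights %||% term_weights(disease_annot)

  adr_terms <- sort(unique(drug_annot$term))
  sym_terms <- sort(unique(disease_annot$term))
  s <- term_score_matrix(onto, ic, adr_terms, sym_terms,
                         drug_weights, disease_weights)

  drugs <- sort(unique(drug_annot$entity))
  diseases <- sort(unique(disease_annot$entity))
  d_idx <- split(match(drug_annot$term, adr_terms), drug_annot$entity)[drugs]
  e_idx <- split(match(disease_annot$term, sym_terms), disease_annot$entity)[diseases]
  n_d <- lengths(d_idx)
  m_e <- lengths(e_idx)

  # col_max[d, j]: best score of symptom j against drug d's side effects
  cm <- vapply(d_idx, function(ix) {
    if (length(ix) == 1L) s[ix, ] else apply(s[ix, , drop = FALSE], 2, max)
  }, numeric(length(sym_terms)))
  col_max <- if (length(sym_terms) == 1L) matrix(cm, ncol = 1L) else t(cm)
  # row_max[i, e]: best score of side effect i against disease e's symptoms
  rmx <- vapply(e_idx, function(ix) {
    if (length(ix) == 1L) s[, ix] else apply(s[, ix, drop = FALSE], 1, max)
  }, numeric(length(adr_terms)))
  row_max <- if (length(adr_terms) == 1L) matrix(rmx, nrow = 1L) else rmx

  # indicator matrices turn the best-match sums into matrix products
  a_ind <- matrix(0, length(drugs), length(adr_terms))
  for (i in seq_along(d_idx)) a_ind[i, d_idx[[i]]] <- 1
  s_ind <- matrix(0, length(diseases), length(sym_terms))
  for (j in seq_along(e_idx)) s_ind[j, e_idx[[j]]] <- 1

  sum_best_adr <- a_ind %*% row_max              # drugs x diseases
  sum_best_sym <- col_max %*% t(s_ind)           # drugs x diseases
  sim <- (sum_best_adr + sum_best_sym) / outer(n_d, m_e, "+")

  out <- tibble::tibble(
    drug = rep(drugs, times = length(diseases)),
    disease = rep(diseases, each = length(drugs)),
    similarity = as.vector(sim),
    n = rep(unname(n_d), times = length(diseases)),
    m = rep(unname(m_e), each = length(drugs))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$similarity),
                        .data$drug, .data$disease)
  class(out) <- c("pheno_scores", class(out))
  out
}

#' Number of drug-disease pairs in the scored universe
#'
#' The all-pairs table covers the full cross product of annotated drugs and
#' diseases, so its cardinality is simply the product of the two entity
#' counts.
#'
#' @param drug_annot,disease_annot [annotations()] tibbles.
#' @return Integer (as double, to allow large products).
#' @export
pair_universe_size <- function(drug_annot, disease_annot) {
  as.numeric(n_entities(drug_annot)) * as.numeric(n_entities(disease_annot))
}

#' Write a scored pair table to TSV
#' @param scored Tibble from [score_pairs()].
#' @param path Output path; similarity printed to six decimals.
#' @export
write_scores <- function(scored, path) {
  out <- scored
  out$similarity <- sprintf("%.6f", out$similarity)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
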