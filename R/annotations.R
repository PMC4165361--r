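#' Build an annotation table of entities and phenotype terms
#'
#' Holds drug -> side-effect or disease -> symptom annotations as a long
#' tibble of (entity, term) pairs. Duplicated rows are collapsed; rows with
#' missing values are dropped, and entities left without any term are removed
#' with a warning. If an ontology is supplied, every term must exist in it.
#'
#' @param df Data frame with columns `entity` and `term` (the reader accepts
#'   `entity_id`/`term_id` as synonyms).
#' @param kind `"drug"` (terms are side effects) or `"disease"` (symptoms).
#' @param onto Optional [ontology()] used to validate terms.
#' @return A tibble of class `pheno_annotations` with columns `entity`,
#'   `term`, and attributes `kind` and `n_entities`.
#' @export
annotations <- function(df, kind = c("drug", "disease"), onto = NULL) {
  kind <- match.arg(kind)
  df <- tibble::as_tibble(df)
  nm <- names(df)
  nm[nm == "entity_id"] <- "entity"
  nm[nm == "term_id"] <- "term"
  names(df) <- nm
  if (!all(c("entity", "term") %in% names(df))) {
    stop("annotation table needs columns `entity` and `term`", call. = FALSE)
  }
  df <- df[, c("entity", "term")]
  df$entity <- as.character(df$entity)
  df$term <- as.character(df$term)
  before <- unique(df$entity[!is.na(df$entity)])
  df <- df[stats::complete.cases(df) & df$entity != "" & df$term != "", ]
  df <- dplyr::distinct(df)
  if (nrow(df) == 0) stop("no annotations", call. = FALSE)
  if (!is.null(onto)) {
    bad <- !df$term %in% onto$terms
    if (any(bad)) {
      stop("annotation terms absent from the ontology: ",
           paste(utils::head(unique(df$term[bad]), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  dropped <- setdiff(before, df$entity)
  if (length(dropped)) {
    warning(length(dropped), " entities dropped (no valid terms): ",
            paste(utils::head(dropped, 5), collapse = ", "), call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$entity, .data$term)
  structure(df, class = c("pheno_annotations", class(df)),
            kind = kind, n_entities = dplyr::n_distinct(df$entity))
}

#' Read an annotation TSV
#'
#' Expects a header line with columns `entity_id` and `term_id`.
#'
#' @inheritParams annotations
#' @param path Path to the TSV.
#' @return A [annotations()] tibble.
#' @export
read_annotations <- function(path, kind = c("drug", "disease"), onto = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(df) == 0) stop("no annotations in ", path, call. = FALSE)
  annotations(df, kind = kind, onto = onto)
}

#' Number of annotated entities in an annotation table
#' @param annot A [annotations()] tibble.
#' @return Integer count of distinct entities.
#' @export
n_entities <- function(annot) {
  attr(annot, "n_entities") %||% dplyr::n_distinct(annot$entity)
}

#' Jaccard index of two entity sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}. Used on the sets of entities two
#' terms are annotated to, as the basis of the co-occurrence weight.
#'
#' @param a,b Vectors of entity identifiers; their union must be non-empty.
#' @return A value in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard index undefined for two empty sets", call. = FALSE)
  length(intersect(a, b)) / u
}

# term x entity logical incidence matrix
incidence_matrix <- function(annot) {
  terms <- sort(unique(annot$term))
  ents <- sort(unique(annot$entity))
  m <- matrix(FALSE, length(terms), length(ents),
              dimnames = list(terms, ents))
  m[cbind(match(annot$term, terms), match(annot$entity, ents))] <- TRUE
  m
}

#' Frequency weights of annotated terms
#'
#' The frequency weight of a term is the negative natural logarithm of the
#' fraction of entities (of the table's kind) the term is annotated to:
#' \eqn{f = -\ln(n_{term} / M)}. Terms annotated to every entity get weight 0;
#' rare terms get large weights. Weights are computed within kind, i.e. side
#' effects against drugs and symptoms against diseases.
#'
#' @param annot A [annotations()] tibble.
#' @return A tibble with columns `term`, `n_term`, `f`.
#' @export
frequency_weights <- function(annot) {
  m <- n_entities(annot)
  dplyr::summarise(dplyr::group_by(annot, .data$term),
                   n_term = dplyr::n_distinct(.data$entity),
                   .groups = "drop") |>
    dplyr::mutate(f = -log(.data$n_term / m))
}

#' Co-occurrence weights of annotated terms
#'
#' Downweights terms that commonly occur together. For term `t`, the weight is
#' the average of \eqn{-\ln J(A_t, A_u)} over all other terms `u` of the same
#' table whose entity sets overlap (`J > 0`). Zero-Jaccard partners are
#' excluded so the average stays finite; self-pairs (J = 1 by definition) are
#' excluded as uninformative. A term sharing no entity with any other term has
#' no defined average and receives the maximum weight observed among the
#' other terms (`fallback = "max"`), i.e. it is treated as maximally
#' independent; `fallback = "zero"` assigns 0 instead.
#'
#' @param annot A [annotations()] tibble with at least two distinct terms.
#' @param fallback Weight for terms with no overlapping partner.
#' @return A tibble with columns `term`, `n_partners`, `c`.
#' @export
cooccurrence_weights <- function(annot, fallback = c("max", "zero")) {
  fallback <- match.arg(fallback)
  inc <- incidence_matrix(annot)
  if (nrow(inc) < 2) {
    stop("co-occurrence weights need at least two distinct terms", call. = FALSE)
  }
  inter <- tcrossprod(inc * 1)             # |A_t intersect A_u|
  sizes <- rowSums(inc)
  uni <- outer(sizes, sizes, "+") - inter  # |A_t union A_u|
  jac <- inter / uni
  diag(jac) <- 0                           # exclude self-pairs
  pos <- jac > 0
  nl <- ifelse(pos, -log(jac), 0)
  n_partners <- rowSums(pos)
  cvals <- ifelse(n_partners > 0, rowSums(nl) / pmax(n_partners, 1), NA_real_)
  if (anyNA(cvals)) {
    fill <- if (fallback == "max" && any(!is.na(cvals))) {
      max(cvals, na.rm = TRUE)
    } else 0
    cvals[is.na(cvals)] <- fill
  }
  tibble::tibble(term = rownames(inc), n_partners = as.integer(n_partners),
                 c = unname(cvals))
}

#' Combined term weights (frequency x co-occurrence)
#'
#' Convenience wrapper joining [frequency_weights()] and
#' [cooccurrence_weights()]; the combined weight `w = f * c` is the overall
#' weight entering the term-pair similarity score.
#'
#' @inheritParams cooccurrence_weights
#' @return A tibble with columns `term`, `n_term`, `f`, `n_partners`, `c`, `w`.
#' @export
term_weights <- function(annot, fallback = c("max", "zero")) {
  fw <- frequency_weights(annot)
  cw <- cooccurrence_weights(annot, fallback = fallback)
  dplyr::left_join(fw, cw, by = "term") |>
    dplyr::mutate(w = .data$f * .data$c)
}

#' Write a term-weight table to TSV
#' @param weights Tibble from [term_weights()].
#' @param path Output path (`term<TAB>f<TAB>c`).
#' @export
write_term_weights <- function(weights, path) {
  readr::write_tsv(weights[, c("term", "f", "c")], path, progress = FALSE)
  invisible(path)
}
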