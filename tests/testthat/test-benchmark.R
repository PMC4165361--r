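# ranked pair table with controllable positives
toy_scored <- function(n, seed = 1) {
  withr::with_seed(seed, {
    sc <- tibble::tibble(
      drug = sprintf("d%04d", seq_len(n)),
      disease = sprintf("s%04d", seq_len(n)),
      similarity = sort(stats::runif(n), decreasing = TRUE),
      n = 5L, m = 5L
    )
    class(sc) <- c("pheno_scores", class(sc))
    sc
  })
}

test_that("lift is precision over prevalence, with ties included", {
  sc <- toy_scored(1000)
  # 100 positives, 30 of them in the top 100
  pos <- sc[c(1:30, 301:370), c("drug", "disease")]
  lc <- lift_curve(sc, pos, rates = c(0.1, 1))
  expect_equal(lc$lift[lc$rate == 0.1], 0.3 / 0.1)
  expect_equal(lc$lift[lc$rate == 1], 1)

  # all positives ranked first at rate P/total: maximal lift total/P
  pos2 <- sc[1:50, c("drug", "disease")]
  lc2 <- lift_curve(sc, pos2, rates = 50 / 1000)
  expect_equal(lc2$lift, 1000 / 50)

  # ties at the cutoff enlarge the slice
  sct <- sc
  sct$similarity <- rep(1, 1000)
  lct <- lift_curve(sct, pos2, rates = 0.01)
  expect_equal(lct$top_size, 1000)
  expect_equal(lct$lift, 1)

  expect_error(lift_curve(sc, sc[0, c("drug", "disease")]), "empty positive")
  expect_error(lift_curve(sc, pos, rates = 0), "rates")
  expect_error(
    lift_curve(sc, tibble::tibble(drug = "nope", disease = "nope")),
    "not in the scored universe"
  )
})

test_that("per-relation curves include a pooled 'all' set", {
  sc <- toy_scored(200)
  labels <- dplyr::bind_rows(
    dplyr::mutate(sc[1:20, c("drug", "disease")], relation = "indication"),
    dplyr::mutate(sc[30:49, c("drug", "disease")], relation = "contraindication")
  )
  out <- lift_by_relation(sc, labels, rates = c(0.25, 1))
  expect_setequal(unique(out$relation),
                  c("indication", "contraindication", "all"))
  # disjoint sets: pooled positives are the sum
  expect_equal(out$n_positives[out$relation == "all"][1], 40)
  # planted at the top: lift above 1 at the small rate
  expect_gt(out$lift[out$relation == "all" & out$rate == 0.25], 1)

  single <- labels[labels$relation == "indication", ]
  out1 <- lift_by_relation(sc, single, rates = c(0.25, 1))
  expect_equal(out1$lift[out1$relation == "all"],
               out1$lift[out1$relation == "indication"])
})

test_that("within-relation curves split by molecular distance category", {
  sc <- toy_scored(300)
  mol <- tibble::tibble(
    drug = sc$drug, disease = sc$disease,
    distance = rep(c(0, 1, 5), each = 100)
  )
  mol$category <- distance_category(mol$distance)
  labels <- dplyr::bind_rows(
    dplyr::mutate(sc[1:10, c("drug", "disease")], relation = "adr_disease"),
    dplyr::mutate(sc[201:220, c("drug", "disease")], relation = "adr_disease")
  )
  out <- lift_by_distance(sc, labels, mol, rates = c(0.1, 1), low_n = 15)
  expect_setequal(as.character(unique(out$category)), c("0", ">3"))
  top0 <- out[out$category == "0" & out$rate == 0.1, ]
  topf <- out[out$category == ">3" & out$rate == 0.1, ]
  expect_gt(top0$lift, topf$lift)   # planted: close pairs at the top
  expect_true(top0$low_n)           # 10 < 15
  expect_false(topf$low_n)
})

test_that("pareto front keeps only non-dominated points", {
  idx <- phenosim:::pareto_front_idx(c(1, 2, 0.5), c(2, 1, 0.5))
  expect_equal(sort(idx), c(1, 2))
})

test_that("pareto threshold search reports a selected front point", {
  sc <- toy_scored(400, seed = 3)
  # sc is sorted by decreasing similarity; plant distance<=1 at the top
  mol <- tibble::tibble(
    drug = sc$drug, disease = sc$disease,
    distance = c(rep(0, 40), rep(1, 40), rep(2, 160), rep(4, 160))
  )
  mol$category <- distance_category(mol$distance)
  res <- pareto_threshold(sc, mol, max_candidates = 50)
  expect_s3_class(res, "pareto_result")
  expect_true(res$selected$threshold %in% res$grid$threshold)
  expect_true(all(c("lift01", "precision01", "recall01") %in%
                    names(res$grid)))
  # the front is non-dominated in the two requested objectives
  f <- res$front
  for (i in seq_len(nrow(f))) {
    dominated <- any(f$lift01 > f$lift01[i] & f$precision01 > f$precision01[i])
    expect_false(dominated)
  }
  expect_equal(nrow(glance(res)), 1)
  expect_equal(tidy(res), tibble::as_tibble(res$front))

  # precision at the selection is at least the prevalence (lift >= 1)
  expect_gte(res$selected$lift01, 1)

  # a precision/coverage trade-off gives a genuine front
  res2 <- pareto_threshold(sc, mol, objectives = c("precision01", "recall01"),
                           max_candidates = 50)
  expect_gte(nrow(res2$front), 2)
})

test_that("relation score comparisons use rank-sum tests with BH", {
  sc <- toy_scored(300, seed = 9)
  # indication planted at the very top, contraindication at the bottom
  labels <- dplyr::bind_rows(
    dplyr::mutate(sc[1:40, c("drug", "disease")], relation = "indication"),
    dplyr::mutate(sc[261:300, c("drug", "disease")], relation = "contraindication"),
    dplyr::mutate(sc[seq(5, 295, by = 10), c("drug", "disease")],
                  relation = "adr_disease")
  )
  out <- compare_relation_scores(sc, labels)
  expect_equal(nrow(out), 3)   # 3 relations -> 3 pairwise tests
  ic <- out[out$relation_a == "contraindication" &
              out$relation_b == "indication", ]
  expect_lt(ic$p_adjusted, 0.05)
  expect_lt(ic$median_diff, 0)
  expect_true(all(out$p_adjusted >= out$p_value - 1e-15))

  # identical distributions: no signal
  same <- dplyr::bind_rows(
    dplyr::mutate(sc[1:50, c("drug", "disease")], relation = "a"),
    dplyr::mutate(sc[1:50, c("drug", "disease")], relation = "b")
  )
  out2 <- compare_relation_scores(sc, same)
  expect_gt(out2$p_adjusted, 0.9)
  expect_equal(out2$median_diff, 0)

  expect_error(
    compare_relation_scores(sc, dplyr::mutate(sc[1, c("drug", "disease")],
                                              relation = "only")),
    "two relations"
  )
})

test_that("adr fraction curve tracks label overlap along the ranking", {
  sc <- toy_scored(200, seed = 5)
  ci <- dplyr::mutate(sc[seq(1, 100), c("drug", "disease")],
                      relation = "contraindication")
  # overlap concentrated at the top: first 20 contraindications are ADRs
  adr <- dplyr::mutate(sc[1:20, c("drug", "disease")], relation = "adr_disease")
  curve <- adr_fraction_curve(sc, dplyr::bind_rows(ci, adr),
                              relation = "contraindication",
                              rates = c(0.2, 0.5, 1))
  expect_equal(curve$fraction, c(1, 0.4, 0.2))
  expect_true(all(diff(curve$fraction) <= 0))

  # no overlap and full overlap
  none <- adr_fraction_curve(sc, ci, "contraindication", rates = c(0.5, 1))
  expect_equal(none$fraction, c(0, 0))
  full <- adr_fraction_curve(
    sc, dplyr::bind_rows(ci, dplyr::mutate(ci, relation = "adr_disease")),
    "contraindication", rates = c(0.5, 1))
  expect_equal(full$fraction, c(1, 1))
})

test_that("candidate contraindications come from the unlabeled top slice", {
  sc <- toy_scored(100, seed = 2)
  labels <- dplyr::bind_rows(
    dplyr::mutate(sc[c(1, 2, 40, 60, 80), c("drug", "disease")],
                  relation = "adr_disease"),
    dplyr::mutate(sc[2, c("drug", "disease")], relation = "contraindication")
  )
  # top 2% of 100 pairs = 2 rows; ADRs there are rows 1 and 2, row 2 already
  # contraindicated -> exactly one candidate
  cand <- candidate_contraindications(sc, labels, top_fraction = 0.02)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$drug, sc$drug[1])
  expect_equal(attr(cand, "score_cutoff"), sc$similarity[2])

  # row order of the inputs does not matter
  perm <- withr::with_seed(7, sc[sample(nrow(sc)), ])
  class(perm) <- class(sc)
  perm <- dplyr::arrange(perm, dplyr::desc(similarity), drug, disease)
  cand2 <- candidate_contraindications(perm, labels[sample(nrow(labels)), ],
                                       top_fraction = 0.02)
  expect_equal(as.data.frame(cand2), as.data.frame(cand))
})
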