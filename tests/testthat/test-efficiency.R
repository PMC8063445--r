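make_universe_contrasts <- function(genes, vs_dis, vs_wt, treatment = "T1") {
  list(vs_dis = setNames(list(make_contrast_table(genes, vs_dis,
                                                  rep(0.01, length(genes)),
                                                  id = paste0(treatment, "_vs_TG"))),
                         treatment),
       vs_wt = setNames(list(make_contrast_table(genes, vs_wt,
                                                 rep(0.01, length(genes)),
                                                 id = paste0(treatment, "_vs_WT"))),
                        treatment))
}

test_that("category mapping intersects with the universe and drops small sets", {
  sets <- tibble::tibble(set_id = c("S1", "S2"),
                         description = c("d", "d"),
                         genes = list(paste0("g", 1:10), paste0("g", 1:6)))
  universe <- c(paste0("g", 1:4), paste0("g", 5:6))  # g1..g6
  out <- map_categories(sets, universe, min_set_size = 5)
  expect_setequal(out$set_id, c("S1", "S2"))
  expect_identical(sort(out$genes[[match("S1", out$set_id)]]),
                   sort(paste0("g", 1:6)))

  expect_warning(out4 <- map_categories(sets, paste0("g", 1:4), min_set_size = 5),
                 class = "txr_empty_annotation_warning")
  expect_equal(nrow(out4), 0)

  # fully contained set is unchanged
  inside <- map_categories(sets[2, ], paste0("g", 1:6), min_set_size = 5)
  expect_identical(inside$genes[[1]], sets$genes[[2]])

  # random sets vs random universe match brute-force set algebra
  set.seed(41)
  pool <- sprintf("g%03d", 1:100)
  rsets <- tibble::tibble(set_id = paste0("R", 1:20), description = "d",
                          genes = replicate(20, sample(pool, 15), simplify = FALSE))
  uni <- sample(pool, 50)
  mapped <- suppressWarnings(map_categories(rsets, uni, min_set_size = 1))
  for (i in seq_len(nrow(mapped))) {
    brute <- rsets$genes[[match(mapped$set_id[i], rsets$set_id)]]
    brute <- brute[vapply(brute, function(g) g %in% uni, logical(1))]
    expect_setequal(mapped$genes[[i]], brute)
  }
})

test_that("efficiency scores reproduce their closed forms", {
  genes <- paste0("g", 1:3)
  cats <- tibble::tibble(set_id = "C", description = "d", genes = list(genes))

  # restored exactly to WT: displacement from disease 1.0, from WT ~0 (floored)
  cc <- make_universe_contrasts(genes, vs_dis = c(1, 1, 1), vs_wt = c(0, 0, 0))
  tab <- efficiency_scores(cats, cc$vs_dis, cc$vs_wt)
  expect_equal(tab$efficiency_score, 2.0, tolerance = 1e-12)
  expect_false(tab$floored_numerator)
  expect_true(tab$floored_denominator)

  # identical to disease: mirror case
  cc2 <- make_universe_contrasts(genes, vs_dis = c(0, 0, 0), vs_wt = c(1, 1, 1))
  tab2 <- efficiency_scores(cats, cc2$vs_dis, cc2$vs_wt)
  expect_equal(tab2$efficiency_score, -2.0, tolerance = 1e-12)

  # hand-computed ratio: N = 1.0, D = 0.2
  cc3 <- make_universe_contrasts(genes, vs_dis = c(0.5, 1.0, 1.5),
                                 vs_wt = c(0.2, 0.1, 0.3))
  tab3 <- efficiency_scores(cats, cc3$vs_dis, cc3$vs_wt)
  expect_equal(tab3$mean_abs_logfc_vs_disease, 1.0, tolerance = 1e-12)
  expect_equal(tab3$mean_abs_logfc_vs_wt, 0.2, tolerance = 1e-12)
  expect_equal(tab3$efficiency_score, log10(5), tolerance = 1e-12)
  expect_equal(tab3$n_genes_used, 3L)
  expect_error(efficiency_scores(cats, cc3$vs_dis, cc3$vs_wt, epsilon = 0),
               class = "txr_config_error")
})

test_that("scores shift by +1 per tenfold numerator and negate under swap", {
  set.seed(61)
  genes <- sprintf("g%02d", 1:20)
  cats <- tibble::tibble(set_id = paste0("C", 1:4), description = "d",
                         genes = replicate(4, sample(genes, 8), simplify = FALSE))
  vs_dis <- runif(20, 0.1, 2)
  vs_wt <- runif(20, 0.1, 2)
  cc <- make_universe_contrasts(genes, vs_dis, vs_wt)
  base <- efficiency_scores(cats, cc$vs_dis, cc$vs_wt)

  cc10 <- make_universe_contrasts(genes, vs_dis * 10, vs_wt)
  up <- efficiency_scores(cats, cc10$vs_dis, cc10$vs_wt)
  unfloored <- !base$floored_numerator & !base$floored_denominator &
    !up$floored_numerator & !up$floored_denominator
  expect_true(any(unfloored))
  expect_equal(up$efficiency_score[unfloored],
               base$efficiency_score[unfloored] + 1, tolerance = 1e-12)

  swapped <- efficiency_scores(cats, cc$vs_wt, cc$vs_dis)
  expect_equal(swapped$efficiency_score[unfloored],
               -base$efficiency_score[unfloored], tolerance = 1e-12)
})

test_that("the pass filter is consistent and monotone in scores", {
  genes <- paste0("g", 1:10)
  cats <- tibble::tibble(set_id = c("HI", "LO"), description = "d",
                         genes = list(genes[1:5], genes[6:10]))
  vs_dis <- c(rep(2, 5), rep(0.05, 5))
  vs_wt <- c(rep(0.01, 5), rep(2, 5))
  cc <- make_universe_contrasts(genes, vs_dis, vs_wt)
  tab <- efficiency_scores(cats, cc$vs_dis, cc$vs_wt)
  expect_true(all(tab$passes_filter[tab$category == "HI"]))
  expect_false(any(tab$passes_filter[tab$category == "LO"]))
  by_cat <- split(tab$efficiency_score > 1, tab$category)
  expect_equal(unname(vapply(by_cat, any, logical(1))[unique(tab$category)]),
               tab$passes_filter[!duplicated(tab$category)])

  # raising the numerator (hence the score) never un-passes a category
  cc_up <- make_universe_contrasts(genes, vs_dis * 5, vs_wt)
  tab_up <- efficiency_scores(cats, cc_up$vs_dis, cc_up$vs_wt)
  expect_true(all(tab_up$passes_filter[tab$passes_filter]))
})

test_that("category clustering recovers separated archetypes", {
  arch <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  rows <- list()
  for (a in 1:3) {
    for (d in 1:3) {
      v <- arch[a, ] + (d - 1) * 0.01
      rows[[length(rows) + 1]] <- tibble::tibble(
        category = sprintf("C%d_%d", a, d),
        treatment = c("T1", "T2", "T3"),
        efficiency_score = v, passes_filter = TRUE)
    }
  }
  tab <- dplyr::bind_rows(rows)
  cl <- cluster_categories(tab, k = 3)
  truth <- rep(1:3, each = 3)
  got <- cl$assignment$cluster[match(sprintf("C%d_%d", rep(1:3, each = 3),
                                             rep(1:3, 3)),
                                     cl$assignment$item_id)]
  expect_true(same_partition(got, truth))

  singles <- cluster_categories(tab, k = 9)
  expect_length(unique(singles$assignment$cluster), 9)
  expect_error(cluster_categories(tab[tab$category %in% c("C1_1", "C2_1"), ],
                                  k = 3),
               class = "txr_value_error")
})

test_that("category clustering matches the brute-force Ward oracle", {
  set.seed(71)
  for (rep in 1:5) {
    scores <- matrix(rnorm(30), 10)
    tab <- tibble::tibble(
      category = rep(sprintf("C%02d", 1:10), each = 3),
      treatment = rep(c("T1", "T2", "T3"), 10),
      efficiency_score = as.vector(t(scores)),
      passes_filter = TRUE)
    cl <- cluster_categories(tab, k = 3)
    oracle <- brute_ward_partition(scores, 3)
    got <- cl$assignment$cluster[match(sprintf("C%02d", 1:10),
                                       cl$assignment$item_id)]
    expect_true(same_partition(got, oracle))
  }
})
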