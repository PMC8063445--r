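#' Restrict gene-set categories to a gene universe
#'
#' Intersects every category with the analysis universe (typically the
#' extended altered gene set) and drops categories left with fewer than
#' `min_set_size` members — category means over a handful of genes are
#' dominated by single-gene noise.
#'
#' @param sets Gene-set tibble from [read_gmt()] or [simulate_gene_sets()].
#' @param universe A `txr_signature` or character vector of gene ids.
#' @param min_set_size Minimum surviving members (default 5).
#' @return The filtered gene-set tibble with an added `n_in_universe` column.
#'   If nothing survives, an empty tibble is returned with a
#'   `txr_empty_annotation_warning`.
#' @export
map_categories <- function(sets, universe, min_set_size = 5) {
  genes <- if (inherits(universe, "txr_signature")) universe$members
           else as.character(universe)
  if (!length(genes)) abort_value("universe is empty")
  out <- sets
  out$genes <- lapply(sets$genes, intersect, genes)
  out$n_in_universe <- lengths(out$genes)
  out <- out[out$n_in_universe >= min_set_size, , drop = FALSE]
  if (!nrow(out)) {
    txr_warn("txr_empty_annotation_warning",
             "no category retains min_set_size genes inside the universe")
  }
  out
}

#' Treatment-efficiency scores per functional category
#'
#' For category C and treatment T the score is
#' `log10(mean_C |logFC(T vs disease)| / mean_C |logFC(T vs baseline)|)`:
#' the log ratio of the category's mean displacement from the disease state
#' over its mean residual displacement from the healthy state. High scores
#' mean the treatment moved the category's genes far from the disease profile
#' while leaving them close to health — effective restoration without
#' disrupting the healthy state; negative scores mean the category still
#' deviates from health more than it moved away from disease.
#'
#' Absolute values are used in both means so that up- and down-regulated
#' member genes cannot cancel. Both means are floored at `epsilon` before the
#' ratio, keeping scores finite when a treatment coincides exactly with a
#' baseline; flag columns record when the floor fired.
#'
#' @param categories Filtered gene-set tibble from [map_categories()].
#' @param contrasts_vs_disease Named list of `txr_contrast` tables, one per
#'   treatment, each treatment-vs-disease.
#' @param contrasts_vs_wt Named list with the same names, each
#'   treatment-vs-healthy-baseline.
#' @param epsilon Floor for both means (log2 units, > 0; default 0.01).
#' @param score_filter A category "passes" when its score exceeds this value
#'   for at least one treatment (default 1, i.e. a 10-fold ratio).
#' @return A `txr_efficiency` tibble with one row per (category, treatment):
#'   `category`, `treatment`, `n_genes_used`, `mean_abs_logfc_vs_disease`,
#'   `mean_abs_logfc_vs_wt`, `efficiency_score`, `floored_numerator`,
#'   `floored_denominator`, `passes_filter`.
#' @export
efficiency_scores <- function(categories, contrasts_vs_disease, contrasts_vs_wt,
                              epsilon = 0.01, score_filter = 1) {
  if (epsilon <= 0) abort_config("epsilon must be > 0")
  nms <- names(contrasts_vs_disease)
  if (is.null(nms) || any(!nzchar(nms))) {
    abort_value("contrasts_vs_disease must be a named list (one per treatment)")
  }
  if (!identical(sort(nms), sort(names(contrasts_vs_wt) %||% character(0)))) {
    abort_value("contrasts_vs_wt must carry the same treatment names")
  }
  lookup <- function(ct, genes) {
    check_contrast_table(ct)
    idx <- match(genes, ct$gene_id)
    if (anyNA(idx)) return(NULL)
    abs(ct$logFC[idx])
  }
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(categories))) {
    cat_id <- categories$set_id[i]
    genes <- categories$genes[[i]]
    if (!length(genes)) {
      skipped <- c(skipped, cat_id)
      next
    }
    ok <- TRUE
    cat_rows <- lapply(nms, function(tr) {
      num_v <- lookup(contrasts_vs_disease[[tr]], genes)
      den_v <- lookup(contrasts_vs_wt[[tr]], genes)
      if (is.null(num_v) || is.null(den_v)) return(NULL)
      num <- mean(num_v)
      den <- mean(den_v)
      tibble::tibble(category = cat_id, treatment = tr,
                     n_genes_used = length(genes),
                     mean_abs_logfc_vs_disease = num,
                     mean_abs_logfc_vs_wt = den,
                     efficiency_score = log10(max(num, epsilon) / max(den, epsilon)),
                     floored_numerator = num < epsilon,
                     floored_denominator = den < epsilon)
    })
    if (any(vapply(cat_rows, is.null, logical(1)))) {
      skipped <- c(skipped, cat_id)
      next
    }
    rows[[length(rows) + 1]] <- dplyr::bind_rows(cat_rows)
  }
  if (length(skipped)) {
    txr_warn("txr_missing_category_warning", sprintf(
      "%d categor%s skipped (genes absent from the contrast universe): %s",
      length(skipped), if (length(skipped) == 1) "y" else "ies",
      paste(head(skipped, 5), collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(category = character(), treatment = character(),
                          n_genes_used = integer(),
                          mean_abs_logfc_vs_disease = numeric(),
                          mean_abs_logfc_vs_wt = numeric(),
                          efficiency_score = numeric(),
                          floored_numerator = logical(),
                          floored_denominator = logical(),
                          passes_filter = logical())
  } else {
    out <- dplyr::mutate(dplyr::group_by(out, .data$category),
                         passes_filter = max(.data$efficiency_score) > score_filter)
    out <- dplyr::ungroup(out)
  }
  structure(out, class = c("txr_efficiency", class(out)),
            epsilon = epsilon, score_filter = score_filter)
}

#' Cluster categories by their efficiency-score profiles
#'
#' Ward clustering (as in [ward_cluster()]) of the filter-passing categories,
#' using each category's vector of efficiency scores across treatments as its
#' coordinates. Groups categories by which treatment(s) restore them.
#'
#' @param table A `txr_efficiency` from [efficiency_scores()].
#' @param k Number of clusters (default 3).
#' @return A `txr_ward` over the passing categories.
#' @export
cluster_categories <- function(table, k = 3) {
  passing <- dplyr::filter(table, .data$passes_filter)
  wide <- tidyr::pivot_wider(
    passing[, c("category", "treatment", "efficiency_score")],
    names_from = "treatment", values_from = "efficiency_score")
  if (nrow(wide) < k) {
    abort_value(sprintf("only %d categories pass the filter; need >= k = %d",
                        nrow(wide), k))
  }
  ward_cluster(wide, k = k)
}
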