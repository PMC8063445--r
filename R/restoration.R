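#' Assemble a logFC profile matrix for signature genes
#'
#' Builds the genes-by-conditions table clustered downstream: one row per
#' signature gene (in signature order), one column per supplied contrast
#' (in the given order), each cell the gene's logFC in that contrast. With
#' all contrasts taken against the healthy baseline, a row is the gene's
#' displacement-from-healthy profile across disease and treatments.
#'
#' @param contrasts List of `txr_contrast` tables, typically disease-vs-WT
#'   followed by each treatment-vs-WT. Names (or contrast ids) become column
#'   names.
#' @param signature A [select_signature()] result restricting the rows.
#' @return A tibble: `gene_id` plus one numeric logFC column per condition.
#' @export
build_profile <- function(contrasts, signature) {
  if (!inherits(signature, "txr_signature")) {
    abort_value("signature must be a txr_signature")
  }
  if (!length(signature$members)) abort_value("signature is empty")
  if (!length(contrasts)) abort_value("need at least one contrast")
  nms <- names(contrasts) %||% rep("", length(contrasts))
  fallback <- vapply(contrasts, function(ct) contrast_id(ct) %||% "contrast",
                     character(1))
  nms <- ifelse(nzchar(nms), nms, fallback)
  if (anyDuplicated(nms)) abort_duplicate_id("condition names must be unique")
  cols <- purrr::map2(contrasts, nms, function(ct, nm) {
    check_contrast_table(ct)
    idx <- match(signature$members, ct$gene_id)
    if (anyNA(idx)) {
      abort_value(sprintf("contrast '%s' lacks signature gene '%s'",
                          nm, signature$members[which(is.na(idx))[1]]))
    }
    ct$logFC[idx]
  })
  tibble::tibble(gene_id = signature$members, !!!setNames(cols, nms))
}

#' Ward agglomerative clustering of profile rows
#'
#' Hierarchical agglomeration that at each step merges the pair of clusters
#' giving the smallest increase in within-cluster sum of squares (Ward's
#' objective) in Euclidean geometry, using the ward.D2 convention (merge
#' heights are on the scale of Euclidean distance, i.e. the square root of
#' the merged criterion). The tree is cut to exactly `k` clusters and labels
#' are renumbered 1..k by decreasing cluster size, ties broken by the
#' smallest member row index, so the labeling is invariant to input row
#' order.
#'
#' @param profile Data frame whose first column holds item identifiers (e.g.
#'   `gene_id`) and whose remaining numeric columns are the coordinates (logFC
#'   per condition, or efficiency score per treatment).
#' @param k Number of clusters, between 1 and the number of rows.
#' @param standardize If `TRUE`, rows are centered and scaled to unit variance
#'   before clustering (default `FALSE`: raw logFC values are clustered).
#' @return A `txr_ward` object: `assignment` tibble (`item_id`, `cluster`),
#'   `k`, cluster `sizes`, and the underlying [stats::hclust()] tree
#'   (merge history and non-decreasing merge heights).
#' @export
#' @examples
#' pts <- tibble::tibble(id = letters[1:4], x = c(0, 0.1, 10, 10.1))
#' ward_cluster(pts, k = 2)$assignment
ward_cluster <- function(profile, k, standardize = FALSE) {
  if (!is.data.frame(profile) || ncol(profile) < 2) {
    abort_value("profile must be a data frame with an id column plus numeric columns")
  }
  ids <- as.character(profile[[1]])
  x <- as.matrix(profile[-1])
  if (!is.numeric(x)) abort_value("profile columns after the id must be numeric")
  if (any(!is.finite(x))) abort_value("profile contains non-finite values")
  n <- nrow(x)
  if (k < 1 || k > n) abort_value(sprintf("k must be in [1, %d]", n))
  if (standardize) {
    mu <- rowMeans(x)
    s <- apply(x, 1, sd)
    s[s == 0] <- 1
    x <- (x - mu) / s
  }
  if (n == 1) {
    tree <- NULL
    raw <- 1L
  } else {
    tree <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
    raw <- cutree(tree, k = k)
  }
  labels <- canonical_labels(raw, k)
  structure(list(assignment = tibble::tibble(item_id = ids, cluster = labels),
                 k = k,
                 sizes = as.integer(table(labels)),
                 hclust = tree),
            class = "txr_ward")
}

# renumber cluster labels 1..k by decreasing size, ties by smallest member index
canonical_labels <- function(raw, k) {
  sizes <- tabulate(raw, nbins = max(raw))
  first_idx <- vapply(seq_len(max(raw)), function(cl) min(which(raw == cl)),
                      integer(1))
  ord <- order(-sizes, first_idx)
  map <- integer(max(raw))
  map[ord] <- seq_along(ord)
  as.integer(map[raw])
}

#' @export
print.txr_ward <- function(x, ...) {
  cat(sprintf("<ward clustering> %d items in %d clusters (sizes: %s)\n",
              nrow(x$assignment), x$k, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.txr_ward <- function(x, ...) x$assignment

#' @export
glance.txr_ward <- function(x, ...) {
  tibble::tibble(k = x$k, n_items = nrow(x$assignment),
                 min_size = min(x$sizes), max_size = max(x$sizes),
                 max_height = if (is.null(x$hclust)) NA_real_
                              else max(x$hclust$height))
}

#' Mean absolute distance from the healthy baseline per cluster
#'
#' For each condition column of the profile and each gene group ("all"
#' profile genes plus each cluster), the mean over member genes of the
#' absolute logFC against the healthy baseline. Zero means a group of genes
#' is transcriptionally indistinguishable from the healthy state under that
#' condition; smaller is closer to health.
#'
#' @param profile Profile tibble from [build_profile()].
#' @param clusters A `txr_ward` from [ward_cluster()] (or a data frame
#'   `item_id`/`cluster`) covering every profile gene.
#' @return A `txr_distance` tibble: `condition`, `gene_group` (`"all"` or the
#'   cluster label as character), `n_genes`, `mean_abs_logfc`. The "all" cell
#'   equals the size-weighted mean of the cluster cells by construction.
#' @export
distance_report <- function(profile, clusters) {
  assignment <- if (inherits(clusters, "txr_ward")) clusters$assignment
                else tibble::as_tibble(clusters)
  if (!all(c("item_id", "cluster") %in% names(assignment))) {
    abort_value("clusters must provide item_id and cluster")
  }
  idx <- match(profile$gene_id, assignment$item_id)
  if (anyNA(idx)) {
    abort_value(sprintf("cluster assignment lacks gene '%s'",
                        profile$gene_id[which(is.na(idx))[1]]))
  }
  lab <- assignment$cluster[idx]
  long <- tidyr::pivot_longer(profile, -"gene_id",
                              names_to = "condition", values_to = "logFC")
  long$gene_group <- as.character(rep(lab, each = ncol(profile) - 1))
  per_cluster <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$gene_group),
    n_genes = dplyr::n_distinct(.data$gene_id),
    mean_abs_logfc = mean(abs(.data$logFC)), .groups = "drop")
  overall <- dplyr::summarise(
    dplyr::group_by(long, .data$condition),
    gene_group = "all",
    n_genes = dplyr::n_distinct(.data$gene_id),
    mean_abs_logfc = mean(abs(.data$logFC)), .groups = "drop")
  out <- dplyr::bind_rows(overall, per_cluster)
  out <- dplyr::arrange(out,
                        match(.data$condition, names(profile)[-1]),
                        .data$gene_group != "all",
                        suppressWarnings(as.integer(.data$gene_group)))
  out <- out[, c("condition", "gene_group", "n_genes", "mean_abs_logfc")]
  class(out) <- c("txr_distance", class(out))
  out
}
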