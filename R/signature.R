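new_signature <- function(name, members, source_contrasts, logfc_min, adj_p_max) {
  if (!nzchar(name)) abort_value("signature name must be non-empty")
  structure(list(name = name,
                 members = unique(as.character(members)),
                 source_contrasts = as.character(source_contrasts),
                 thresholds = c(logfc_min = logfc_min, adj_p_max = adj_p_max)),
            class = "txr_signature")
}

#' @export
print.txr_signature <- function(x, ...) {
  cat(sprintf("<signature '%s'> %d genes (|logFC| >= %g, adj_p <= %g) from: %s\n",
              x$name, length(x$members), x$thresholds[["logfc_min"]],
              x$thresholds[["adj_p_max"]],
              paste(x$source_contrasts, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.txr_signature <- function(x, ...) {
  tibble::tibble(gene_id = x$members, signature = x$name)
}

#' @export
glance.txr_signature <- function(x, ...) {
  tibble::tibble(signature = x$name, n_genes = length(x$members),
                 logfc_min = x$thresholds[["logfc_min"]],
                 adj_p_max = x$thresholds[["adj_p_max"]],
                 n_source_contrasts = length(x$source_contrasts))
}

#' Select a disease gene signature from one contrast
#'
#' Keeps genes with `|logFC| >= logfc_min` and `adj_p <= adj_p_max`. Both
#' boundaries are inclusive. Applied to the disease-vs-baseline contrast with
#' the defaults this is the conventional disease-associated signature rule
#' (|logFC| >= 1, adjusted p <= 0.05).
#'
#' @param contrast A `txr_contrast` (or any data frame with `gene_id`,
#'   `logFC`, `adj_p`).
#' @param logfc_min Minimum absolute log2 fold change (> 0).
#' @param adj_p_max Maximum adjusted p-value (> 0).
#' @param name Signature name; defaults to the contrast id.
#' @return A `txr_signature`: member gene ids, the source contrast id(s) and
#'   the thresholds used.
#' @export
select_signature <- function(contrast, logfc_min = 1, adj_p_max = 0.05,
                             name = NULL) {
  check_contrast_table(contrast)
  if (logfc_min <= 0 || adj_p_max <= 0) {
    abort_value("thresholds must be positive")
  }
  keep <- abs(contrast$logFC) >= logfc_min & contrast$adj_p <= adj_p_max
  cid <- contrast_id(contrast) %||% "contrast"
  new_signature(name %||% cid, contrast$gene_id[keep], cid,
                logfc_min, adj_p_max)
}

#' Union signature across several contrasts
#'
#' The extended altered gene set: every gene passing the thresholds in at
#' least one of the supplied contrasts (e.g. disease vs baseline plus each
#' treatment vs baseline). All contrasts must share the same gene universe.
#'
#' @param contrasts List of `txr_contrast` tables.
#' @inheritParams select_signature
#' @return A `txr_signature` whose `source_contrasts` records every input.
#' @export
extended_altered_set <- function(contrasts, logfc_min = 1, adj_p_max = 0.05,
                                 name = "extended_altered_set") {
  if (!length(contrasts)) abort_value("need at least one contrast")
  universe <- sort(contrasts[[1]]$gene_id)
  for (ct in contrasts) {
    check_contrast_table(ct)
    if (!identical(sort(ct$gene_id), universe)) {
      abort_value("all contrasts must share the same gene universe")
    }
  }
  parts <- lapply(contrasts, select_signature,
                  logfc_min = logfc_min, adj_p_max = adj_p_max)
  members <- unique(unlist(lapply(parts, `[[`, "members")))
  # keep gene order of the first contrast for determinism
  members <- contrasts[[1]]$gene_id[contrasts[[1]]$gene_id %in% members]
  new_signature(name, members,
                vapply(parts, function(s) s$source_contrasts, character(1)),
                logfc_min, adj_p_max)
}

check_contrast_table <- function(contrast) {
  need <- c("gene_id", "logFC", "adj_p")
  if (!is.data.frame(contrast) || !all(need %in% names(contrast))) {
    abort_value("contrast must be a data frame with columns gene_id, logFC, adj_p")
  }
  invisible(contrast)
}

#' Exclusive overlap counts between signatures (upset-style)
#'
#' For every non-empty combination of the given signatures, counts the genes
#' that belong to exactly that combination; counts over all combinations sum
#' to the size of the union.
#'
#' @param signatures Named list (or list; names default to signature names)
#'   of `txr_signature` objects, length >= 2.
#' @return A tibble with one logical membership column per signature, plus
#'   `degree` (number of signatures in the combination) and `n_genes`. All
#'   `2^k - 1` combinations are listed, including empty cells, sorted by
#'   decreasing degree then by column order.
#' @export
overlap_table <- function(signatures) {
  if (length(signatures) < 2) abort_value("need at least two signatures")
  nms <- names(signatures) %||% rep("", length(signatures))
  fallback <- vapply(signatures, function(s) s$name, character(1))
  nms <- ifelse(nzchar(nms), nms, fallback)
  if (anyDuplicated(nms)) abort_duplicate_id("signature names must be unique")
  member_sets <- lapply(signatures, `[[`, "members")
  universe <- unique(unlist(member_sets))
  memb <- vapply(member_sets, function(m) universe %in% m,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1)
  colnames(memb) <- nms
  combos <- tidyr::expand_grid(!!!setNames(rep(list(c(TRUE, FALSE)), length(nms)), nms))
  combos <- combos[rowSums(as.matrix(combos)) > 0, , drop = FALSE]
  key <- apply(as.matrix(combos), 1, paste, collapse = "|")
  obs <- apply(memb, 1, paste, collapse = "|")
  counts <- table(factor(obs, levels = key))
  out <- tibble::as_tibble(combos)
  out$degree <- rowSums(as.matrix(combos))
  out$n_genes <- as.integer(counts[key])
  dplyr::arrange(out, dplyr::desc(.data$degree))
}
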