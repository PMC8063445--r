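# Small in-code fixtures shared across tests.

# Expression tibble from a named list of per-group replicate matrices
# (genes x replicates), all with the same row count.
make_expr <- function(groups, gene_ids = NULL) {
  n_genes <- nrow(groups[[1]])
  gene_ids <- gene_ids %||% sprintf("g%03d", seq_len(n_genes))
  cols <- list()
  samples <- tibble::tibble(sample_id = character(), group = character())
  for (g in names(groups)) {
    m <- groups[[g]]
    for (r in seq_len(ncol(m))) {
      sid <- paste(g, r, sep = "_")
      cols[[sid]] <- m[, r]
      samples <- dplyr::bind_rows(samples,
                                  tibble::tibble(sample_id = sid, group = g))
    }
  }
  list(expression = tibble::tibble(gene_id = gene_ids, !!!cols),
       samples = samples)
}

# A plain contrast-like table accepted by the signature functions.
make_contrast_table <- function(gene_id, logFC, adj_p, id = "toy") {
  structure(tibble::tibble(gene_id = gene_id, logFC = logFC,
                           t = logFC, df = 4, p = adj_p, adj_p = adj_p),
            class = c("txr_contrast", class(tibble::tibble())),
            contrast_id = id)
}

`%||%` <- rlang::`%||%`
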