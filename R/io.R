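#' Read a normalized log2 expression matrix from TSV
#'
#' The expected layout is a header row of sample identifiers, a first column
#' named `gene_id` holding gene identifiers, and one numeric column per
#' sample. Values must already be log2-normalized intensities; the loader
#' never transforms them. Gene identifiers are opaque strings (no
#' probe-to-symbol mapping is attempted).
#'
#' @param path Path to a tab-separated file.
#' @param dialect File dialect; only `"tsv"` is supported.
#'
#' @return A tibble with a character `gene_id` column followed by one numeric
#'   column per sample, in file order.
#'
#' @details Validation is strict: duplicate gene or sample identifiers,
#'   missing values (`NA`, empty cells) and non-numeric cells are hard,
#'   classed errors (`txr_duplicate_id_error`, `txr_missing_value_error`,
#'   `txr_parse_error`). Missing values are never imputed so that all
#'   downstream statistics are deterministic functions of the file contents.
#'
#' @seealso [write_expression()], [read_design()], [read_gmt()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' sim <- simulate_expression(sim_config(n_genes = 10, seed = 1))
#' write_expression(sim$expression, tf)
#' expr <- read_expression(tf)
#' dim(expr)
read_expression <- function(path, dialect = "tsv") {
  if (!identical(dialect, "tsv")) {
    abort_config(sprintf("unsupported dialect '%s'; only 'tsv' is supported", dialect))
  }
  if (!file.exists(path)) {
    abort_parse(sprintf("expression file not found: %s", path))
  }
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    abort_parse("expression file must have a gene id column plus at least one sample column")
  }
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    abort_duplicate_id(sprintf(
      "duplicate sample id(s) in header: %s",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids)) {
    abort_duplicate_id(sprintf(
      "duplicate gene id(s): %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  vals <- lapply(raw[-1], function(col) {
    missing <- is.na(col) | col == "" | col %in% c("NA", "NaN", "na")
    if (any(missing)) {
      abort_missing_value(sprintf(
        "missing value(s) in expression matrix (first at gene '%s')",
        gene_ids[which(missing)[1]]))
    }
    num <- suppressWarnings(as.numeric(col))
    bad <- is.na(num)
    if (any(bad)) {
      abort_parse(sprintf(
        "non-numeric cell '%s' at gene '%s'",
        col[which(bad)[1]], gene_ids[which(bad)[1]]))
    }
    if (any(!is.finite(num))) {
      abort_parse(sprintf(
        "non-finite value at gene '%s'", gene_ids[which(!is.finite(num))[1]]))
    }
    num
  })
  out <- tibble::tibble(gene_id = gene_ids, !!!vals)
  validate_expression(out)
  out
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; values round-trip exactly.
#'
#' @param expression Tibble as returned by [read_expression()] or
#'   [simulate_expression()].
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_expression <- function(expression, path) {
  validate_expression(expression)
  write_table(expression, path)
  invisible(expression)
}

validate_expression <- function(expression) {
  if (!is.data.frame(expression) || ncol(expression) < 2 ||
      names(expression)[1] != "gene_id") {
    abort_value("expression must be a data frame with first column 'gene_id' plus sample columns")
  }
  if (anyDuplicated(expression$gene_id)) {
    abort_duplicate_id("duplicate gene ids in expression matrix")
  }
  if (anyDuplicated(names(expression))) {
    abort_duplicate_id("duplicate sample ids in expression matrix")
  }
  num_ok <- vapply(expression[-1], is.numeric, logical(1))
  if (!all(num_ok)) {
    abort_parse("all sample columns must be numeric")
  }
  vals <- as.matrix(expression[-1])
  if (anyNA(vals)) abort_missing_value("expression matrix contains missing values")
  if (any(!is.finite(vals))) abort_value("expression matrix contains non-finite values")
  invisible(expression)
}

# genes x samples numeric matrix with gene_id rownames
expr_matrix <- function(expression) {
  m <- as.matrix(expression[-1])
  rownames(m) <- expression$gene_id
  m
}

#' Construct a study design
#'
#' A study design maps each sample to a group and singles out one healthy
#' baseline group (e.g. wild-type littermates) and one disease group; every
#' other group is a treatment arm, kept in the order given.
#'
#' @param samples Data frame with columns `sample_id` and `group`.
#' @param baseline Label of the healthy baseline group.
#' @param disease Label of the disease group.
#' @param treatments Optional character vector fixing the treatment group
#'   order; defaults to all remaining groups in first-appearance order.
#'
#' @return A `study_design` object: the sample tibble with `baseline_group`,
#'   `disease_group` and `treatment_groups` recorded as attributes.
#'
#' @details Requirements enforced (classed `txr_design_error` on violation):
#'   baseline and disease labels differ and are both present, every sample
#'   maps to exactly one group, and every declared group has at least two
#'   samples (group means and variances are undefined otherwise).
#' @export
study_design <- function(samples, baseline, disease, treatments = NULL) {
  if (!is.data.frame(samples) || !all(c("sample_id", "group") %in% names(samples))) {
    abort_design("samples must be a data frame with columns 'sample_id' and 'group'")
  }
  samples <- tibble::as_tibble(samples[c("sample_id", "group")])
  samples$sample_id <- as.character(samples$sample_id)
  samples$group <- as.character(samples$group)
  if (anyDuplicated(samples$sample_id)) {
    abort_design("each sample_id must map to exactly one group (duplicates found)")
  }
  if (identical(baseline, disease)) {
    abort_design("baseline and disease groups must differ")
  }
  groups <- unique(samples$group)
  for (g in c(baseline, disease)) {
    if (!g %in% groups) {
      abort_design(sprintf("group '%s' absent from sample sheet", g))
    }
  }
  if (is.null(treatments)) {
    treatments <- setdiff(groups, c(baseline, disease))
  } else {
    missing <- setdiff(treatments, groups)
    if (length(missing)) {
      abort_design(sprintf("treatment group(s) absent from sample sheet: %s",
                           paste(missing, collapse = ", ")))
    }
    if (any(treatments %in% c(baseline, disease))) {
      abort_design("treatment groups must be disjoint from baseline and disease groups")
    }
  }
  sizes <- table(samples$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    abort_design(sprintf("every group needs >= 2 samples; too small: %s",
                         paste(small, collapse = ", ")))
  }
  structure(samples,
            class = c("study_design", class(samples)),
            baseline_group = baseline,
            disease_group = disease,
            treatment_groups = treatments)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d samples, baseline '%s', disease '%s', treatments: %s\n",
              nrow(x), baseline_group(x), disease_group(x),
              paste(treatment_groups(x), collapse = ", ")))
  NextMethod()
}

#' Accessors for study design groups
#'
#' @param design A `study_design`.
#' @return The baseline group label, disease group label, or character vector
#'   of treatment group labels.
#' @export
baseline_group <- function(design) attr(design, "baseline_group", exact = TRUE)

#' @rdname baseline_group
#' @export
disease_group <- function(design) attr(design, "disease_group", exact = TRUE)

#' @rdname baseline_group
#' @export
treatment_groups <- function(design) attr(design, "treatment_groups", exact = TRUE)

design_samples <- function(design, group) design$sample_id[design$group == group]

#' Read a sample sheet and build a study design
#'
#' The sample sheet is a two-column TSV (`sample_id`, `group`). A header row
#' with exactly those names is accepted and skipped; otherwise every row is a
#' sample.
#'
#' @inheritParams study_design
#' @param path Path to the sample sheet.
#' @return A [study_design()] with all non-baseline, non-disease groups as
#'   treatments in file order.
#' @export
read_design <- function(path, baseline, disease) {
  if (!file.exists(path)) abort_design(sprintf("design file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = c("sample_id", "group"),
                         col_types = "cc", progress = FALSE)
  if (nrow(raw) && identical(unname(unlist(raw[1, ])), c("sample_id", "group"))) {
    raw <- raw[-1, ]
  }
  if (!nrow(raw)) abort_design("design file contains no samples")
  if (anyNA(raw)) abort_design("design file contains missing fields")
  study_design(raw, baseline = baseline, disease = disease)
}

#' Write a study design to TSV
#'
#' @param design A [study_design()].
#' @param path Output path.
#' @return The design, invisibly.
#' @export
write_design <- function(design, path) {
  write_table(tibble::tibble(sample_id = design$sample_id, group = design$group), path)
  invisible(design)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, `description`,
#' then one or more member gene identifiers. Duplicate members within a line
#' are dropped (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `description` and a list-column
#'   `genes` (character vectors); zero rows for an empty file.
#' @details Lines with fewer than three fields (i.e. no members) raise a
#'   `txr_parse_error`; duplicate set ids raise a `txr_duplicate_id_error`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(set_id = character(), description = character(),
                          genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3
  if (any(bad)) {
    abort_parse(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                        which(bad)[1]))
  }
  set_id <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(set_id)) {
    abort_duplicate_id(sprintf("duplicate set id(s) in GMT: %s",
                               paste(unique(set_id[duplicated(set_id)]), collapse = ", ")))
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- vapply(genes, length, integer(1)) < 1
  if (any(empty)) {
    abort_parse(sprintf("GMT line %d has no non-empty members", which(empty)[1]))
  }
  tibble::tibble(set_id = set_id,
                 description = vapply(fields, `[[`, character(1), 2),
                 genes = genes)
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(set_id, description, genes, ...) {
    paste(c(set_id, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(sets)
}

#' Write a results table to TSV
#'
#' All pipeline outputs go through this writer: header row, deterministic
#' column order (as given), and full floating-point precision so that a write
#' / read round trip reproduces values to better than 1e-9.
#'
#' @param records Data frame with at least one column; zero rows produce a
#'   header-only file.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || ncol(records) < 1) {
    abort_value("records must be a data frame with a non-empty schema")
  }
  tryCatch(
    readr::write_tsv(tibble::as_tibble(records), path, progress = FALSE),
    error = function(e) txr_abort("txr_io_error",
                                  sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(records)
}
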