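#' Configuration for the end-to-end restoration pipeline
#'
#' Collects paths and parameters for [run_pipeline()]. Defaults follow the
#' package-wide conventions: signature thresholds |logFC| >= 1 and adjusted
#' p <= 0.05, six gene clusters, three category clusters, efficiency floor
#' 0.01 and score filter 1.
#'
#' @param expression Path to the expression TSV (see [read_expression()]).
#' @param design Path to the sample sheet (see [read_design()]).
#' @param out_dir Output directory (created if absent).
#' @param baseline_group,disease_group Group labels in the sample sheet.
#' @param gmt Optional path to a GMT file; without it the category-efficiency
#'   stage is skipped.
#' @param treatment_groups Optional explicit treatment order; defaults to all
#'   remaining groups in sample-sheet order.
#' @param logfc_min,adj_p_max Signature thresholds.
#' @param k_genes Clusters for signature genes (default 6).
#' @param k_categories Clusters for functional categories (default 3).
#' @param epsilon,min_set_size,score_filter Efficiency-stage parameters, see
#'   [efficiency_scores()] and [map_categories()].
#' @param moderation `"moderated"` or `"ordinary"` t statistic.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, design, out_dir,
                            baseline_group, disease_group,
                            gmt = NULL, treatment_groups = NULL,
                            logfc_min = 1, adj_p_max = 0.05,
                            k_genes = 6, k_categories = 3,
                            epsilon = 0.01, min_set_size = 5,
                            score_filter = 1,
                            moderation = c("moderated", "ordinary")) {
  cfg <- list(expression = expression, design = design, gmt = gmt,
              out_dir = out_dir, baseline_group = baseline_group,
              disease_group = disease_group,
              treatment_groups = treatment_groups,
              logfc_min = logfc_min, adj_p_max = adj_p_max,
              k_genes = k_genes, k_categories = k_categories,
              epsilon = epsilon, min_set_size = min_set_size,
              score_filter = score_filter,
              moderation = match.arg(moderation))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_config(sprintf("unknown config field(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' Run the full transcriptional-restoration analysis
#'
#' Executes, in order: differential expression for every treatment and the
#' disease group against the healthy baseline and for every treatment against
#' the disease group; disease-signature and extended altered-set selection;
#' logFC profile assembly, Ward clustering of signature genes and the
#' per-cluster distance-from-healthy report; category efficiency scores with
#' category clustering (when a GMT is supplied); and signature overlap
#' counts. Every stage writes a TSV into `out_dir` and a `manifest.json`
#' records parameters and the SHA-256 checksum of every output, so two runs
#' with identical inputs and config are verifiably byte-identical (the
#' pipeline itself draws no random numbers).
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly: parameter echo, input/output shapes and
#'   per-file checksums. On any stage failure, files already written are
#'   removed and the error names the stage.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort_config("config must be a pipeline_config or a YAML path")
  }
  for (f in c(config$expression, config$design, config$gmt)) {
    if (!file.exists(f)) abort_config(sprintf("input file not found: %s", f))
  }
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  written <- character(0)
  say <- function(fmt, ...) if (!quiet) rlang::inform(sprintf(fmt, ...))
  emit <- function(records, name) {
    path <- file.path(config$out_dir, name)
    write_table(records, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      txr_abort("txr_stage_error",
                sprintf("pipeline stage '%s' failed: %s", name,
                        conditionMessage(e)),
                parent = e)
    })
  }

  inputs <- stage("load", {
    expr <- read_expression(config$expression)
    design <- read_design(config$design, baseline = config$baseline_group,
                          disease = config$disease_group)
    if (!is.null(config$treatment_groups)) {
      design <- study_design(tibble::as_tibble(design),
                             baseline = config$baseline_group,
                             disease = config$disease_group,
                             treatments = config$treatment_groups)
    }
    missing <- setdiff(design$sample_id, names(expr))
    if (length(missing)) {
      abort_design(sprintf("expression matrix lacks sample(s): %s",
                           paste(missing, collapse = ", ")))
    }
    sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
    list(expr = expr, design = design, sets = sets)
  })
  expr <- inputs$expr; design <- inputs$design
  wt <- baseline_group(design); dis <- disease_group(design)
  treatments <- treatment_groups(design)
  if (!length(treatments)) {
    abort_design("pipeline needs at least one treatment group")
  }
  say("load: %d genes, %d samples, %d treatment group(s)%s",
      nrow(expr), ncol(expr) - 1, length(treatments),
      if (is.null(inputs$sets)) "" else sprintf(", %d gene sets", nrow(inputs$sets)))

  de <- stage("diffexpr", {
    vs_wt <- lapply(setNames(c(dis, treatments), c(dis, treatments)),
                    function(g) compute_contrast(expr, design, g, wt,
                                                 moderation = config$moderation))
    vs_dis <- lapply(setNames(treatments, treatments),
                     function(g) compute_contrast(expr, design, g, dis,
                                                  moderation = config$moderation))
    for (ct in c(vs_wt, vs_dis)) {
      emit(tidy(ct), sprintf("de_%s.tsv", contrast_id(ct)))
    }
    list(vs_wt = vs_wt, vs_dis = vs_dis)
  })
  say("diffexpr: %d contrasts (%s t)", length(de$vs_wt) + length(de$vs_dis),
      config$moderation)

  sigs <- stage("signature", {
    signature <- select_signature(de$vs_wt[[dis]], logfc_min = config$logfc_min,
                                  adj_p_max = config$adj_p_max,
                                  name = "disease_signature")
    if (!length(signature$members)) {
      abort_value("disease signature is empty at the configured thresholds")
    }
    extended <- extended_altered_set(unname(de$vs_wt),
                                     logfc_min = config$logfc_min,
                                     adj_p_max = config$adj_p_max)
    per_contrast <- lapply(de$vs_wt, select_signature,
                           logfc_min = config$logfc_min,
                           adj_p_max = config$adj_p_max)
    flags <- purrr::map(per_contrast, function(s) extended$members %in% s$members)
    names(flags) <- vapply(per_contrast, `[[`, character(1), "name")
    emit(tidy(signature)["gene_id"], "signature.tsv")
    emit(tibble::tibble(gene_id = extended$members, !!!flags), "extended_set.tsv")
    emit(overlap_table(per_contrast), "upset.tsv")
    list(signature = signature, extended = extended)
  })
  say("signature: %d disease genes, %d in extended set",
      length(sigs$signature$members), length(sigs$extended$members))

  rest <- stage("restoration", {
    profile <- build_profile(unname(de$vs_wt), sigs$signature)
    clusters <- ward_cluster(profile, k = min(config$k_genes, nrow(profile)))
    distance <- distance_report(profile, clusters)
    emit(profile, "profile.tsv")
    emit(clusters$assignment, "clusters.tsv")
    emit(tidyr::pivot_wider(distance[, c("gene_group", "condition", "mean_abs_logfc")],
                            names_from = "condition",
                            values_from = "mean_abs_logfc"),
         "distance.tsv")
    list(profile = profile, clusters = clusters, distance = distance)
  })
  say("restoration: %d signature genes in %d clusters",
      nrow(rest$profile), rest$clusters$k)

  eff <- NULL
  if (!is.null(inputs$sets)) {
    eff <- stage("efficiency", {
      categories <- map_categories(inputs$sets, sigs$extended,
                                   min_set_size = config$min_set_size)
      table <- efficiency_scores(categories, de$vs_dis, de$vs_wt[treatments],
                                 epsilon = config$epsilon,
                                 score_filter = config$score_filter)
      n_pass <- length(unique(table$category[table$passes_filter]))
      table$category_cluster <- NA_integer_
      if (n_pass >= config$k_categories && nrow(table)) {
        cc <- cluster_categories(table, k = config$k_categories)
        table$category_cluster <- cc$assignment$cluster[
          match(table$category, cc$assignment$item_id)]
      }
      emit(tibble::as_tibble(table), "efficiency.tsv")
      table
    })
    say("efficiency: %d categories scored, %d pass the filter",
        length(unique(eff$category)), length(unique(eff$category[eff$passes_filter])))
  }

  manifest <- stage("manifest", {
    params <- unclass(config)
    params$treatment_groups <- treatments
    m <- list(
      tool = "txrestore",
      version = as.character(utils::packageVersion("txrestore")),
      parameters = params,
      shapes = list(n_genes = nrow(expr), n_samples = ncol(expr) - 1,
                    n_signature = length(sigs$signature$members),
                    n_extended = length(sigs$extended$members),
                    n_categories_scored = if (is.null(eff)) 0L
                                          else length(unique(eff$category))),
      outputs = lapply(sort(written), function(p) {
        list(file = basename(p),
             sha256 = digest::digest(p, algo = "sha256", file = TRUE))
      }))
    json <- jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             null = "null")
    path <- file.path(config$out_dir, "manifest.json")
    writeLines(json, path)
    m
  })
  say("done: %d output files in %s", length(written) + 1, config$out_dir)
  invisible(manifest)
}
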