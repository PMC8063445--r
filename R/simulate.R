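# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic expression simulator
#'
#' Builds a validated configuration for [simulate_expression()]. The generative
#' model mirrors a small-n microarray study of a disease model versus healthy
#' littermates plus treatment arms: per-gene log2 baselines, a subset of
#' disease-perturbed genes with effect magnitudes of at least one log2 unit,
#' all-or-none per-gene restoration under each treatment, optional off-target
#' perturbations, and Gaussian replicate noise on the log2 scale.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group (default 3, the typical group size
#'   in small in-vivo expression studies).
#' @param n_treatments Number of treatment arms (default 3: two monotherapies
#'   and a combination).
#' @param frac_disease_genes Proportion of genes perturbed in the disease
#'   group.
#' @param effect_size_low,effect_size_high Disease effect magnitudes are drawn
#'   uniformly from this range (log2 units; default 1-3, so every disease gene
#'   clears the conventional |logFC| >= 1 signature threshold in expectation).
#' @param frac_up Probability that a disease gene is perturbed upward.
#' @param restoration_fractions Numeric vector, one entry per treatment, each
#'   in \[0, 1\]: the probability that a disease gene is fully restored to its
#'   healthy baseline under that treatment. Names, if given, become the
#'   treatment group labels.
#' @param off_target_frac Proportion of non-disease genes each treatment
#'   perturbs away from baseline (emulates treatment-specific alterations
#'   outside the disease signature).
#' @param off_target_effect Magnitude (log2 units) of off-target shifts; sign
#'   is random per gene.
#' @param noise_sd Replicate noise standard deviation (log2 units),
#'   homoscedastic across genes by default.
#' @param noise_df If finite, per-gene noise variances are drawn from a scaled
#'   inverse chi-square with this many degrees of freedom (mean variance
#'   `noise_sd^2`), giving heteroscedastic data that exercises variance
#'   moderation. `Inf` (default) keeps one shared variance.
#' @param restored_residual Fraction of the disease effect remaining in a
#'   restored gene (default 0: restoration is all-or-none, giving crisp
#'   cluster-level ground truth).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   intensities.
#' @param baseline_label,disease_label Group labels for the healthy baseline
#'   and the disease group.
#' @param seed Integer seed; one seed drives every draw in a fixed order
#'   (baselines, disease-gene assignment, effects, then per-treatment flags in
#'   treatment order, then noise), so runs are reproducible byte-for-byte.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_per_group = 3,
                       n_treatments = 3,
                       frac_disease_genes = 0.1,
                       effect_size_low = 1,
                       effect_size_high = 3,
                       frac_up = 0.5,
                       restoration_fractions = c(DRUG_A = 0.4, DRUG_B = 0.6,
                                                 COMBO = 0.9),
                       off_target_frac = 0.02,
                       off_target_effect = 1.5,
                       noise_sd = 0.25,
                       noise_df = Inf,
                       restored_residual = 0,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       baseline_label = "WT",
                       disease_label = "TG",
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_per_group = n_per_group,
              n_treatments = n_treatments,
              frac_disease_genes = frac_disease_genes,
              effect_size_low = effect_size_low,
              effect_size_high = effect_size_high,
              frac_up = frac_up,
              restoration_fractions = restoration_fractions,
              off_target_frac = off_target_frac,
              off_target_effect = off_target_effect,
              noise_sd = noise_sd, noise_df = noise_df,
              restored_residual = restored_residual,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              baseline_label = baseline_label, disease_label = disease_label,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0 | x > 1)) {
      abort_config(sprintf("%s must be in [0, 1]", nm))
    }
  }
  if (cfg$n_genes < 1) abort_config("n_genes must be >= 1")
  if (cfg$n_per_group < 2) abort_config("n_per_group must be >= 2")
  if (cfg$n_treatments < 0) abort_config("n_treatments must be >= 0")
  chk_prop(cfg$frac_disease_genes, "frac_disease_genes")
  chk_prop(cfg$frac_up, "frac_up")
  chk_prop(cfg$restoration_fractions, "restoration_fractions")
  chk_prop(cfg$off_target_frac, "off_target_frac")
  chk_prop(cfg$restored_residual, "restored_residual")
  if (length(cfg$restoration_fractions) != cfg$n_treatments) {
    abort_config("restoration_fractions must have length n_treatments")
  }
  if (cfg$noise_sd < 0) abort_config("noise_sd must be >= 0")
  if (!is.infinite(cfg$noise_df) && cfg$noise_df <= 0) {
    abort_config("noise_df must be positive or Inf")
  }
  if (cfg$effect_size_low < 0 || cfg$effect_size_high < cfg$effect_size_low) {
    abort_config("need 0 <= effect_size_low <= effect_size_high")
  }
  if (cfg$baseline_sd < 0) abort_config("baseline_sd must be >= 0")
  if (identical(cfg$baseline_label, cfg$disease_label)) {
    abort_config("baseline_label and disease_label must differ")
  }
  invisible(cfg)
}

sim_treatment_labels <- function(cfg) {
  if (cfg$n_treatments == 0) return(character(0))
  nm <- names(cfg$restoration_fractions)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- sprintf("T%d", seq_len(cfg$n_treatments))
  }
  nm
}

#' Simulate an expression study with known ground truth
#'
#' Generates a normalized log2 expression matrix, a matching study design and
#' a ground-truth table under the generative model described in
#' [sim_config()]: gene baselines `b_g ~ N(baseline_mean, baseline_sd^2)`;
#' disease-group means `b_g + delta_g` with `|delta_g| ~ U(low, high)` for the
#' chosen disease genes and 0 otherwise; treatment means
#' `b_g + (1 - r_g) * delta_g` where `r_g` is 1 for genes restored under that
#' treatment (Bernoulli draw per gene) and 0 otherwise, plus a fixed-magnitude
#' random-sign shift for off-target genes; i.i.d. Gaussian noise on every
#' observation.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (tibble, `gene_id` + one column
#'   per sample), `design` (a [study_design()]), and `truth` (long tibble with
#'   one row per gene x treatment: `gene_id`, `is_disease_gene`,
#'   `disease_effect`, `treatment`, `restored`, `off_target_effect`).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 7))
#' sim$design
#' dplyr::count(sim$truth, treatment, restored)
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) {
    if (is.list(config)) config <- do.call(sim_config, config)
    else abort_config("config must be a sim_config")
  }
  validate_sim_config(config)
  cfg <- config
  treatments <- sim_treatment_labels(cfg)
  gene_id <- sprintf("g%05d", seq_len(cfg$n_genes))

  with_seed(cfg$seed, {
    baseline <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)

    n_dis <- round(cfg$frac_disease_genes * cfg$n_genes)
    dis_idx <- sort(sample.int(cfg$n_genes, n_dis))
    is_disease <- seq_len(cfg$n_genes) %in% dis_idx
    delta <- numeric(cfg$n_genes)
    if (n_dis > 0) {
      mag <- runif(n_dis, cfg$effect_size_low, cfg$effect_size_high)
      sign <- ifelse(runif(n_dis) < cfg$frac_up, 1, -1)
      delta[dis_idx] <- mag * sign
    }

    restored <- matrix(FALSE, cfg$n_genes, cfg$n_treatments)
    off_target <- matrix(0, cfg$n_genes, cfg$n_treatments)
    non_dis <- which(!is_disease)
    for (t in seq_len(cfg$n_treatments)) {
      if (n_dis > 0) {
        restored[dis_idx, t] <-
          rbinom(n_dis, 1, cfg$restoration_fractions[[t]]) == 1
      }
      n_off <- round(cfg$off_target_frac * length(non_dis))
      if (n_off > 0) {
        off_idx <- sort(sample(non_dis, n_off))
        off_sign <- ifelse(runif(n_off) < 0.5, 1, -1)
        off_target[off_idx, t] <- off_sign * cfg$off_target_effect
      }
    }

    gene_sd <- if (is.infinite(cfg$noise_df)) {
      rep(cfg$noise_sd, cfg$n_genes)
    } else {
      cfg$noise_sd * sqrt(cfg$noise_df / rchisq(cfg$n_genes, cfg$noise_df))
    }

    group_means <- cbind(
      baseline,
      baseline + delta,
      vapply(seq_len(cfg$n_treatments), function(t) {
        resid <- ifelse(restored[, t], cfg$restored_residual, 1)
        baseline + resid * delta + off_target[, t]
      }, numeric(cfg$n_genes))
    )
    groups <- c(cfg$baseline_label, cfg$disease_label, treatments)
    colnames(group_means) <- groups

    cols <- list()
    sample_ids <- character(0)
    for (g in groups) {
      for (r in seq_len(cfg$n_per_group)) {
        sid <- paste(g, r, sep = "_")
        noise <- if (cfg$noise_sd > 0) rnorm(cfg$n_genes, 0, gene_sd)
                 else numeric(cfg$n_genes)
        cols[[sid]] <- group_means[, g] + noise
        sample_ids <- c(sample_ids, sid)
      }
    }

    expression <- tibble::tibble(gene_id = gene_id, !!!cols)
    design <- study_design(
      tibble::tibble(sample_id = sample_ids,
                     group = rep(groups, each = cfg$n_per_group)),
      baseline = cfg$baseline_label, disease = cfg$disease_label,
      treatments = treatments)
    truth <- tidyr::expand_grid(gene_idx = seq_len(cfg$n_genes),
                                t_idx = seq_len(cfg$n_treatments))
    truth <- tibble::tibble(
      gene_id = gene_id[truth$gene_idx],
      is_disease_gene = is_disease[truth$gene_idx],
      disease_effect = delta[truth$gene_idx],
      treatment = treatments[truth$t_idx],
      restored = restored[cbind(truth$gene_idx, truth$t_idx)],
      off_target_effect = off_target[cbind(truth$gene_idx, truth$t_idx)])
    if (cfg$n_treatments == 0) {
      truth <- tibble::tibble(gene_id = gene_id, is_disease_gene = is_disease,
                              disease_effect = delta,
                              treatment = NA_character_, restored = FALSE,
                              off_target_effect = 0)
    }
    list(expression = expression, design = design, truth = truth)
  })
}

#' Simulate gene-set annotations over simulated genes
#'
#' Draws gene sets (stand-ins for GO/KEGG/TF-target collections) over the
#' genes of a [simulate_expression()] run, optionally enriched for true
#' disease genes so that category-level treatment-efficiency scoring has
#' signal to find.
#'
#' @param truth Truth tibble from [simulate_expression()].
#' @param n_sets Number of sets to draw.
#' @param set_size_low,set_size_high Set sizes are drawn uniformly from this
#'   integer range (each >= 2).
#' @param disease_enrichment Sampling-weight multiplier for disease genes
#'   (1 = unbiased; larger values concentrate disease genes in every set).
#' @param seed Integer seed.
#' @return A gene-set tibble in the [read_gmt()] layout (`set_id`,
#'   `description`, list-column `genes`).
#' @export
simulate_gene_sets <- function(truth, n_sets, set_size_low = 5,
                               set_size_high = 50, disease_enrichment = 1,
                               seed = 1) {
  genes <- dplyr::distinct(truth, .data$gene_id, .data$is_disease_gene)
  if (!nrow(genes)) abort_config("truth table is empty")
  if (set_size_low < 2 || set_size_high < set_size_low) {
    abort_config("need 2 <= set_size_low <= set_size_high")
  }
  if (set_size_high > nrow(genes)) {
    abort_config("set_size_high exceeds the number of genes")
  }
  if (disease_enrichment <= 0) abort_config("disease_enrichment must be > 0")
  if (n_sets == 0) {
    return(tibble::tibble(set_id = character(), description = character(),
                          genes = list()))
  }
  w <- ifelse(genes$is_disease_gene, disease_enrichment, 1)
  with_seed(seed, {
    sizes <- sample(seq(set_size_low, set_size_high), n_sets, replace = TRUE)
    members <- lapply(sizes, function(sz) {
      sort(sample(genes$gene_id, sz, prob = w))
    })
    tibble::tibble(set_id = sprintf("SET%04d", seq_len(n_sets)),
                   description = sprintf("synthetic gene set %d", seq_len(n_sets)),
                   genes = members)
  })
}
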