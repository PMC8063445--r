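#' Per-gene differential expression for one group-vs-group contrast
#'
#' Computes, for every gene, the log2 fold change `mean(group_a) -
#' mean(group_b)`, a two-sample t statistic (ordinary pooled-variance or
#' empirical-Bayes moderated), the two-sided p-value and the
#' Benjamini-Hochberg adjusted p-value. The second argument of the contrast is
#' the reference, so pipeline contrasts are always "X vs WT" or "X vs
#' disease" with the baseline last.
#'
#' @param expression Expression tibble (`gene_id` + sample columns), as from
#'   [read_expression()] or [simulate_expression()].
#' @param design A [study_design()] covering the two groups.
#' @param group_a,group_b Group labels; `logFC = mean(group_a) - mean(group_b)`.
#' @param moderation `"moderated"` (default) or `"ordinary"`.
#'
#' @return A `txr_contrast` tibble with columns `gene_id`, `logFC`, `t`, `df`,
#'   `p`, `adj_p`, plus attributes `contrast_id` (`"A_vs_B"`), `moderation`,
#'   and for moderated fits the prior degrees of freedom `df_prior` and prior
#'   variance `s2_prior`.
#'
#' @details With only a handful of replicates per group, per-gene variance
#'   estimates are unstable; the moderated t shrinks them toward a common
#'   prior. The prior `(d0, s0^2)` is fitted by matching the first two moments
#'   of `log(s_g^2)` to a scaled F distribution (digamma/trigamma inversion;
#'   no iterative optimizer), then each gene's posterior variance is
#'   `(d0 * s0^2 + d * s_g^2) / (d0 + d)` and the statistic is referred to a t
#'   distribution on `d0 + d` degrees of freedom. Genes with zero sample
#'   variance are excluded from the prior fit but still receive the moderated
#'   variance.
#'
#'   In ordinary mode a gene with zero pooled variance gets `t = 0, p = 1`
#'   when its logFC is 0; otherwise its statistic falls back to the moderated
#'   fit and a `txr_zero_variance_warning` reports how many genes were
#'   affected.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 100, seed = 3))
#' de <- compute_contrast(sim$expression, sim$design, "TG", "WT")
#' head(de)
compute_contrast <- function(expression, design, group_a, group_b,
                             moderation = c("moderated", "ordinary")) {
  moderation <- match.arg(moderation)
  validate_expression(expression)
  for (g in c(group_a, group_b)) {
    if (!g %in% design$group) {
      abort_design(sprintf("unknown group label '%s'", g))
    }
    if (sum(design$group == g) < 2) {
      abort_design(sprintf("group '%s' has fewer than 2 samples", g))
    }
  }
  a_ids <- design_samples(design, group_a)
  b_ids <- design_samples(design, group_b)
  missing <- setdiff(c(a_ids, b_ids), names(expression))
  if (length(missing)) {
    abort_design(sprintf("expression matrix lacks sample(s): %s",
                         paste(missing, collapse = ", ")))
  }
  m <- expr_matrix(expression)
  a <- m[, a_ids, drop = FALSE]
  b <- m[, b_ids, drop = FALSE]
  n_a <- ncol(a)
  n_b <- ncol(b)
  d <- n_a + n_b - 2

  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  logfc <- mean_a - mean_b
  ss <- rowSums((a - mean_a)^2) + rowSums((b - mean_b)^2)
  s2 <- ss / d
  se_factor <- sqrt(1 / n_a + 1 / n_b)

  prior <- NULL
  mod_stats <- function() {
    prior <<- prior %||% fit_variance_prior(s2, d)
    s2_post <- if (is.infinite(prior$df_prior)) {
      rep(prior$s2_prior, length(s2))
    } else {
      (prior$df_prior * prior$s2_prior + d * s2) / (prior$df_prior + d)
    }
    t_mod <- logfc / (sqrt(s2_post) * se_factor)
    df_mod <- d + prior$df_prior
    list(t = t_mod, df = rep(df_mod, length(s2)),
         p = 2 * pt(-abs(t_mod), df_mod))
  }

  if (moderation == "moderated") {
    st <- mod_stats()
    t_stat <- st$t; df_out <- st$df; p <- st$p
  } else {
    t_stat <- ifelse(s2 > 0, logfc / (sqrt(s2) * se_factor), 0)
    df_out <- rep(d, length(s2))
    p <- ifelse(s2 > 0, 2 * pt(-abs(t_stat), d), 1)
    degenerate <- s2 == 0 & logfc != 0
    if (any(degenerate)) {
      st <- mod_stats()
      t_stat[degenerate] <- st$t[degenerate]
      df_out[degenerate] <- st$df[degenerate]
      p[degenerate] <- st$p[degenerate]
      txr_warn("txr_zero_variance_warning", sprintf(
        "%d gene(s) with zero pooled variance but non-zero logFC; moderated fallback used",
        sum(degenerate)))
    }
  }

  out <- tibble::tibble(gene_id = rownames(m), logFC = unname(logfc),
                        t = unname(t_stat), df = unname(df_out),
                        p = unname(pmin(pmax(p, .Machine$double.xmin), 1)),
                        adj_p = NA_real_)
  out$adj_p <- adjust_bh(out$p)
  structure(out,
            class = c("txr_contrast", class(out)),
            contrast_id = paste0(group_a, "_vs_", group_b),
            moderation = moderation,
            n_a = n_a, n_b = n_b,
            df_prior = if (!is.null(prior)) prior$df_prior else NA_real_,
            s2_prior = if (!is.null(prior)) prior$s2_prior else NA_real_)
}

#' @export
print.txr_contrast <- function(x, ...) {
  cat(sprintf("<contrast %s, %s t>\n",
              attr(x, "contrast_id", exact = TRUE) %||% "?",
              attr(x, "moderation", exact = TRUE) %||% "?"))
  NextMethod()
}

contrast_id <- function(contrast) attr(contrast, "contrast_id", exact = TRUE)

#' @export
glance.txr_contrast <- function(x, ...) {
  tibble::tibble(
    contrast_id = contrast_id(x) %||% NA_character_,
    moderation = attr(x, "moderation", exact = TRUE) %||% NA_character_,
    n_genes = nrow(x),
    n_sig_05 = sum(x$adj_p <= 0.05),
    df_prior = attr(x, "df_prior", exact = TRUE) %||% NA_real_,
    s2_prior = attr(x, "s2_prior", exact = TRUE) %||% NA_real_)
}

#' @export
tidy.txr_contrast <- function(x, ...) {
  class(x) <- setdiff(class(x), "txr_contrast")
  tibble::as_tibble(x)
}

# Fit (df_prior, s2_prior) by matching mean/variance of log(s2) to a scaled F
# prior; genes with zero variance are excluded from the fit.
fit_variance_prior <- function(s2, d) {
  pos <- s2[s2 > 0 & is.finite(s2)]
  if (length(pos) < 2) {
    abort_value("cannot fit variance prior: fewer than 2 genes with positive variance")
  }
  e <- log(pos) - digamma(d / 2) + log(d / 2)
  mean_e <- mean(e)
  excess <- var(e) - trigamma(d / 2)
  if (excess <= 0) {
    list(df_prior = Inf, s2_prior = exp(mean_e))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    list(df_prior = d0,
         s2_prior = exp(mean_e + digamma(d0 / 2) - log(d0 / 2)))
  }
}

# Solve trigamma(y) = x for y > 0 (Newton iteration).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with `p_(1) <= ... <= p_(m)` the
#' ascending order statistics, `adj_(i) = min over j >= i of min(1, m *
#' p_(j) / j)`, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values)) abort_value("p_values must be numeric")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort_value("p_values must all lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
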