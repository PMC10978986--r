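# Genomic scaling laws: per-category power-law fits of gene counts versus
# genome size and residual-based enrichment scans.

#' Fit a power law of category gene counts versus total gene counts
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`: the linear-in-log
#' form of the power law `y = c * x^beta` that links the number of genes in
#' a functional category to the total number of genes in a genome. Genomes
#' with zero category or total counts are excluded (log undefined).
#'
#' @param x Total gene counts per genome.
#' @param y Category gene counts per genome.
#' @param category_id Optional label stored in the result.
#' @return An object of class `scaling_fit`: slope (beta), intercept
#'   (log10 c), r_squared, n_genomes, n_excluded, and the `lm` fit.
#' @export
fit_scaling_law <- function(x, y, category_id = NA_character_) {
  ok <- x > 0 & y > 0 & !is.na(x) & !is.na(y)
  stop_if_not(sum(ok) >= 3, "need >= 3 positive (x, y) pairs")
  lx <- log10(x[ok]); ly <- log10(y[ok])
  fit <- stats::lm(ly ~ lx)
  structure(list(category_id = category_id,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 # noise-free fixtures trip summary.lm's perfect-fit warning
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_genomes = sum(ok), n_excluded = sum(!ok),
                 fit = fit, lx = lx, ly = ly, which_ok = which(ok)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s: log10(y) = %.3f + %.3f log10(x), R^2 = %.3f, n = %d (%d excluded)\n",
              x$category_id, x$intercept, x$slope, x$r_squared,
              x$n_genomes, x$n_excluded))
  invisible(x)
}

#' Residuals of a scaling-law fit
#'
#' Observed minus predicted `log10` category counts for each genome;
#' genomes with zero counts have undefined residuals (NA, counted by the
#' fit). The mean residual over the fitting set is 0 by the OLS property.
#'
#' @param object A `scaling_fit`.
#' @param x,y Genome totals and category counts to evaluate (default: the
#'   fitting data).
#' @param ... Unused.
#' @return Numeric vector of residuals (NA where undefined).
#' @export
residuals.scaling_fit <- function(object, x = NULL, y = NULL, ...) {
  if (is.null(x)) return(unname(stats::residuals(object$fit)))
  res <- rep(NA_real_, length(x))
  ok <- x > 0 & y > 0 & !is.na(x) & !is.na(y)
  res[ok] <- log10(y[ok]) -
    (object$intercept + object$slope * log10(x[ok]))
  res
}

#' Scan functional categories for group enrichment/depletion
#'
#' For each category, one pooled power-law fit across both genome groups;
#' categories whose fit has `R^2 < r2_min` are gated out (untested). For
#' tested categories, the residual distributions of the two groups are
#' compared with a two-sided Mann-Whitney U test; p values are corrected
#' across tested categories with both Bonferroni and Benjamini-Hochberg.
#' Direction is the sign of the group-A minus group-B median residual.
#'
#' @param annotations Data frame (genome_id, category_id, count,
#'   total_genes), e.g. from [gen_genome_table()].
#' @param group_a,group_b Disjoint, non-empty genome id vectors.
#' @param r2_min R-squared gate for testing a category.
#' @param per_group_fits If TRUE, fit each group separately and compare
#'   residuals of each group under its own fit (alternative mode); default
#'   is the pooled fit.
#' @return Data frame, one row per category: slope, intercept, r_squared,
#'   tested, u_statistic, p_value, p_bonferroni, p_bh, direction.
#' @export
enrichment_scan <- function(annotations, group_a, group_b, r2_min = 0.3,
                            per_group_fits = FALSE) {
  stop_if_not(length(intersect(group_a, group_b)) == 0,
              "groups must be disjoint")
  stop_if_not(length(group_a) > 0 && length(group_b) > 0,
              "groups must be non-empty")
  cats <- unique(annotations$category_id)
  rows <- list()
  for (cat_id in cats) {
    a <- annotations[annotations$category_id == cat_id, ]
    a <- a[a$genome_id %in% c(group_a, group_b), ]
    in_a <- a$genome_id %in% group_a
    row <- data.frame(category_id = cat_id, slope = NA_real_,
                      intercept = NA_real_, r_squared = NA_real_,
                      tested = FALSE, u_statistic = NA_real_,
                      p_value = NA_real_, p_bonferroni = NA_real_,
                      p_bh = NA_real_, direction = NA_character_,
                      stringsAsFactors = FALSE)
    res_a <- res_b <- NULL
    ok <- a$count > 0 & a$total_genes > 0
    enough <- sum(ok & in_a) >= 3 && sum(ok & !in_a) >= 3
    if (enough) {
      if (per_group_fits) {
        fa <- fit_scaling_law(a$total_genes[in_a], a$count[in_a], cat_id)
        fb <- fit_scaling_law(a$total_genes[!in_a], a$count[!in_a], cat_id)
        row$slope <- fa$slope; row$intercept <- fa$intercept
        row$r_squared <- min(fa$r_squared, fb$r_squared)
        res_a <- residuals(fa); res_b <- residuals(fb)
      } else {
        f <- fit_scaling_law(a$total_genes, a$count, cat_id)
        row$slope <- f$slope; row$intercept <- f$intercept
        row$r_squared <- f$r_squared
        res <- residuals(f, a$total_genes, a$count)
        res_a <- res[in_a & ok]; res_b <- res[!in_a & ok]
      }
      if (row$r_squared >= r2_min) {
        row$tested <- TRUE
        wt <- stats::wilcox.test(res_a, res_b, alternative = "two.sided",
                                 exact = FALSE)
        row$u_statistic <- unname(wt$statistic)
        row$p_value <- wt$p.value
        row$direction <- if (stats::median(res_a) >= stats::median(res_b))
          "enriched" else "depleted"
      }
    }
    rows[[cat_id]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tested <- out$tested
  out$p_bonferroni[tested] <- stats::p.adjust(out$p_value[tested],
                                              "bonferroni")
  out$p_bh[tested] <- stats::p.adjust(out$p_value[tested], "BH")
  out
}
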