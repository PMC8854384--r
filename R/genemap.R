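#' Default receptor gene panel
#'
#' Adrenergic, cholinergic (muscarinic and nicotinic) and dopaminergic receptor
#' gene symbols typically screened against regional imaging differences. Users
#' may supply any list.
#'
#' @export
receptor_gene_panel <- c(
  "ADRA1A", "ADRA1B", "ADRA1D", "ADRA2A", "ADRA2B", "ADRA2C",
  "ADRB1", "ADRB2", "ADRB3",
  "CHRM1", "CHRM2", "CHRM3", "CHRM4", "CHRM5",
  "CHRNA2", "CHRNA3", "CHRNA4", "CHRNA5", "CHRNA6", "CHRNA7",
  "CHRNB2", "CHRNB3", "CHRNB4",
  "DRD1", "DRD2", "DRD3", "DRD4", "DRD5"
)

# align an expression table to a region-difference map by label
align_by_region <- function(expr, diff) {
  if (!"region_id" %in% names(expr) || !"region_id" %in% names(diff))
    abort_fluctnet("both tables need a region_id column")
  missing_in_expr <- setdiff(diff$region_id, expr$region_id)
  missing_in_diff <- setdiff(expr$region_id, diff$region_id)
  if (length(missing_in_expr) || length(missing_in_diff))
    abort_fluctnet(sprintf(
      "region labels do not match; missing from expression: %s; missing from difference map: %s",
      paste(utils::head(missing_in_expr, 5), collapse = ", ") %||% "",
      paste(utils::head(missing_in_diff, 5), collapse = ", ")))
  expr[match(diff$region_id, expr$region_id), , drop = FALSE]
}

#' Correlate regional group differences with gene expression
#'
#' Spearman correlation, across regions, of each gene's mean expression with a
#' per-region group-difference map, with Benjamini-Hochberg FDR control over
#' the gene list. Alignment is by region label, not row order. Genes with
#' constant expression have no defined correlation; they are reported with
#' `NA` and excluded from the FDR family.
#'
#' @param expr tibble: `region_id` plus one numeric column per gene.
#' @param diff tibble: `region_id` and `difference` (per-region group
#'   difference).
#' @param q FDR level over genes (default 0.1).
#' @return tibble of class `gene_map`: `gene`, `rho`, `p`, `q_value`,
#'   `significant`, sorted by p.
#' @export
gene_difference_correlation <- function(expr, diff, q = 0.1) {
  expr <- align_by_region(expr, diff)
  genes <- setdiff(names(expr), "region_id")
  if (!length(genes)) abort_fluctnet("expression table has no gene columns")
  res <- purrr::map_dfr(genes, function(g) {
    v <- expr[[g]]
    if (stats::sd(v) == 0)
      return(tibble::tibble(gene = g, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(v, diff$difference, method = "spearman", exact = FALSE))
    tibble::tibble(gene = g, rho = unname(ct$estimate),
                   p = max(ct$p.value, .Machine$double.xmin))
  })
  ok <- !is.na(res$p)
  fdr <- fdr_bh(res$p[ok], q)
  res$q_value <- NA_real_; res$significant <- FALSE
  res$q_value[ok] <- fdr$q_values
  res$significant[ok] <- fdr$significant
  res <- dplyr::arrange(res, .data$p)
  class(res) <- c("gene_map", class(res))
  res
}

#' Compare gene expression between significant and non-significant regions
#'
#' Independent-samples t test (pooled variance by default, Welch optionally) of
#' each gene's expression in regions flagged as significantly different versus
#' all other regions, with a Shapiro-Wilk normality check (warning on failure)
#' and Benjamini-Hochberg correction across the tested genes.
#'
#' @param expr tibble: `region_id` plus gene columns.
#' @param significant_regions character vector of region labels (or logical
#'   mask over `expr` rows) defining the significant set.
#' @param genes genes to test (default: all gene columns).
#' @param pooled pooled-variance t test (default TRUE); FALSE for Welch.
#' @param q multiple-comparison level across genes (default 0.05).
#' @return tibble: `gene`, `mean_sig`, `mean_nonsig`, `t`, `p`, `q_value`,
#'   `significant`, `normality_p`.
#' @export
regionset_expression_test <- function(expr, significant_regions, genes = NULL,
                                      pooled = TRUE, q = 0.05) {
  if (is.logical(significant_regions)) {
    if (length(significant_regions) != nrow(expr))
      abort_fluctnet("logical mask must match the number of regions")
    mask <- significant_regions
  } else {
    mask <- expr$region_id %in% significant_regions
  }
  if (sum(mask) < 2 || sum(!mask) < 2)
    abort_fluctnet("both region sets need at least 2 regions")
  genes <- genes %||% setdiff(names(expr), "region_id")
  res <- purrr::map_dfr(genes, function(g) {
    a <- expr[[g]][mask]; b <- expr[[g]][!mask]
    if (stats::sd(c(a, b)) == 0) {
      return(tibble::tibble(gene = g, mean_sig = mean(a), mean_nonsig = mean(b),
                            t = 0, p = 1, normality_p = NA_real_))
    }
    tt <- stats::t.test(a, b, var.equal = pooled)
    sw <- tryCatch(stats::shapiro.test(c(a - mean(a), b - mean(b)))$p.value,
                   error = function(e) NA_real_)
    if (!is.na(sw) && sw < 0.05)
      warning(sprintf("gene %s: normality check failed (Shapiro-Wilk p = %.3g)", g, sw))
    tibble::tibble(gene = g, mean_sig = mean(a), mean_nonsig = mean(b),
                   t = unname(tt$statistic), p = tt$p.value, normality_p = sw)
  })
  fdr <- fdr_bh(res$p, q)
  res$q_value <- fdr$q_values
  res$significant <- fdr$significant
  dplyr::arrange(res, .data$p)
}
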