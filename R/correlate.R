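# Gene-body methylation vs expression correlation.

#' Correlate gene-body methylation with gene expression
#'
#' Expression values are log2-transformed with a pseudocount before the
#' correlation.
#'
#' @param meth tibble (`gene_id`, `meth_fraction`)
#' @param expr tibble (`gene_id`, `expression`)
#' @param method `"pearson"` (default) or `"spearman"`
#' @param pseudocount added before the log transform (default 1)
#' @param log_transform log2-transform expression first (default TRUE)
#' @return one-row tibble (`estimate`, `p_value`, `n`, `method`)
#' @export
correlate_meth_expr <- function(meth, expr, method = c("pearson", "spearman"),
                                pseudocount = 1, log_transform = TRUE) {
  method <- match.arg(method)
  d <- inner_join(meth, expr, by = "gene_id") %>%
    filter(!is.na(meth_fraction), !is.na(expression))
  if (nrow(d) < 3) abort(paste0("need >= 3 genes, found ", nrow(d)))
  y <- if (log_transform) log2(d$expression + pseudocount) else d$expression
  ct <- suppressWarnings(cor.test(d$meth_fraction, y, method = method))
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         n = nrow(d), method = method)
}
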