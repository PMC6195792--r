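#' Tissue-specificity summary of an FPKM matrix
#'
#' For each gene profile x over n >= 2 tissues the tau index is
#' `sum(1 - x_i / max(x)) / (n - 1)`: 0 for a uniform nonzero profile, 1 for
#' expression confined to a single tissue. Genes whose maximum FPKM falls
#' below `expressed_threshold` are flagged not-expressed (their tau is `NA`:
#' specificity of a silent gene is undefined).
#'
#' @param fpkm numeric matrix, genes x tissues, non-negative (e.g. from
#'   [read_fpkm()]).
#' @param expressed_threshold minimum max-FPKM to call a gene expressed
#'   (default 1).
#' @return data.frame with columns `gene_id`, `tau`, `top_tissue` (argmax
#'   tissue, `NA` for silent genes), `max_fpkm`, `expressed`.
#' @export
specificity <- function(fpkm, expressed_threshold = 1.0) {
  stopifnot(is.matrix(fpkm))
  if (ncol(fpkm) < 2L) stop("at least 2 tissues required")
  if (any(fpkm < 0)) stop("negative FPKM value(s)")
  n <- ncol(fpkm)
  rows <- lapply(seq_len(nrow(fpkm)), function(i) {
    x <- fpkm[i, ]
    mx <- max(x)
    expressed <- mx >= expressed_threshold
    tau <- if (expressed) sum(1 - x / mx) / (n - 1) else NA_real_
    data.frame(gene_id = rownames(fpkm)[i],
               tau = tau,
               top_tissue = if (expressed) colnames(fpkm)[which.max(x)] else NA_character_,
               max_fpkm = mx, expressed = expressed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
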