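#' Per-replicate log2 translation efficiency
#'
#' Counts are scaled to counts-per-million within each sample; for each
#' (condition, replicate) pair, log2 TE = log2((cpm_RNC + pseudocount) /
#' (cpm_RNA + pseudocount)). The pseudocount (default 0.5, CPM scale)
#' stabilises low-expression ratios; a gene with all-zero counts has
#' log2 TE = 0 exactly. A sample with zero total counts is an error naming
#' the sample.
#'
#' @param te A [TeExperiment-class].
#' @param pseudocount Pseudocount on the CPM scale (default 0.5).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `log2_te` (genes x condition:replicate pairs), colData columns
#'   `condition`, `replicate`, and rowData column `mean_rna_cpm` (used by
#'   the expression filter in [differentialTe()]).
#' @examples
#' sim <- simulateTeCounts(teSimConfig(n_genes = 100, library_depth = 1e5))
#' te <- computeTe(sim$te)
#' @export
computeTe <- function(te, pseudocount = 0.5) {
  stopifnot(is(te, "TeExperiment"))
  cnt <- SummarizedExperiment::assay(te, "counts")
  tot <- colSums(cnt)
  if (any(tot == 0))
    validation_error(paste0("sample(s) with zero total counts: ",
                            paste(colnames(cnt)[tot == 0], collapse = ", ")))
  cpm <- sweep(cnt, 2, tot, "/") * 1e6
  cd <- SummarizedExperiment::colData(te)
  pairs <- unique(data.frame(condition = cd$condition, replicate = cd$replicate,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$condition, pairs$replicate), , drop = FALSE]
  m <- sapply(seq_len(nrow(pairs)), function(i) {
    sel <- cd$condition == pairs$condition[i] & cd$replicate == pairs$replicate[i]
    rnc <- cpm[, which(sel & cd$assay_type == "RNC")]
    rna <- cpm[, which(sel & cd$assay_type == "RNA")]
    log2((rnc + pseudocount) / (rna + pseudocount))
  })
  colnames(m) <- sprintf("%s_rep%s", pairs$condition, pairs$replicate)
  rownames(m) <- rownames(cnt)
  rna_cols <- cd$assay_type == "RNA"
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2_te = m),
    colData = S4Vectors::DataFrame(pairs, row.names = colnames(m)),
    rowData = S4Vectors::DataFrame(
      mean_rna_cpm = rowMeans(cpm[, rna_cols, drop = FALSE])))
}

row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Differential translation efficiency between two conditions
#'
#' Per-gene log2 fold change = mean log2 TE(condition_b) - mean log2
#' TE(condition_a), tested with a moderated two-sample t statistic: the
#' per-gene pooled variance is shrunk toward the mean of all per-gene pooled
#' variances with prior weight `d0` (default 4), and the t statistic gains
#' `d0` degrees of freedom. With `d0 = 0` the test reduces to the ordinary
#' pooled two-sample t. Genes with mean RNA CPM below `min_cpm` are excluded
#' before testing (their ids are attached as attribute `filtered_genes`).
#' Classification follows the |log2FC| > `lfc` and p < `p` gate on raw
#' p-values; a BH-adjusted column is emitted alongside.
#'
#' @param te_table SummarizedExperiment from [computeTe()].
#' @param condition_a,condition_b Condition labels (b - a is reported).
#' @param lfc log2 fold-change threshold (default 1).
#' @param p Raw p-value threshold (default 0.05).
#' @param d0 Prior degrees of freedom of the variance moderation (default 4).
#' @param min_cpm Minimum mean RNA CPM (default 1).
#' @return data.frame with columns `gene`, `log2_te_a`, `log2_te_b`,
#'   `log2fc`, `t`, `p`, `p_adj`, `te_class` (`TE-up` / `TE-down` / `other`),
#'   with the excluded gene ids in `attr(, "filtered_genes")`.
#' @export
differentialTe <- function(te_table, condition_a, condition_b,
                           lfc = 1, p = 0.05, d0 = 4, min_cpm = 1) {
  cd <- SummarizedExperiment::colData(te_table)
  m <- SummarizedExperiment::assay(te_table, "log2_te")
  A <- m[, cd$condition == condition_a, drop = FALSE]
  B <- m[, cd$condition == condition_b, drop = FALSE]
  if (ncol(A) < 2 || ncol(B) < 2)
    validation_error("at least 2 replicates per condition are required")
  keep <- rep(TRUE, nrow(m))
  rd <- SummarizedExperiment::rowData(te_table)
  if ("mean_rna_cpm" %in% colnames(rd)) keep <- rd$mean_rna_cpm >= min_cpm
  filtered <- rownames(m)[!keep]
  if (length(filtered))
    m7g_log("te", sprintf("%d gene(s) below %.3g mean RNA CPM excluded from testing",
                          length(filtered), min_cpm))
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  log2fc <- mean_b - mean_a
  df <- na + nb - 2L
  s2 <- ((na - 1L) * row_vars(A) + (nb - 1L) * row_vars(B)) / df
  s0sq <- mean(s2)
  s2_mod <- (d0 * s0sq + df * s2) / (d0 + df)
  se <- sqrt(s2_mod * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, Inf * sign(log2fc)))
  pval <- 2 * pt(-abs(tstat), df = df + d0)
  cls <- rep("other", nrow(A))
  cls[log2fc > lfc & pval < p] <- "TE-up"
  cls[log2fc < -lfc & pval < p] <- "TE-down"
  out <- data.frame(gene = rownames(A), log2_te_a = mean_a, log2_te_b = mean_b,
                    log2fc = log2fc, t = tstat, p = pval,
                    p_adj = p.adjust(pval, "BH"), te_class = cls,
                    row.names = NULL)
  attr(out, "filtered_genes") <- filtered
  attr(out, "conditions") <- c(a = condition_a, b = condition_b)
  out
}

#' Summarise TE classification counts
#'
#' @param results data.frame from [differentialTe()].
#' @return Named list `n_up`, `n_down`, `n_total_changed`.
#' @export
classifyCounts <- function(results) {
  n_up <- sum(results$te_class == "TE-up")
  n_down <- sum(results$te_class == "TE-down")
  list(n_up = n_up, n_down = n_down, n_total_changed = n_up + n_down)
}

#' Write differential TE results as TSV
#'
#' @param results data.frame from [differentialTe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTeTsv <- function(results, path) write_tsv(results, path)
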