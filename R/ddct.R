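#' Read a qPCR Ct table
#'
#' Tab-separated with header and columns `gene`, `group`, `replicate`,
#' `ct_target`, `ct_reference` (reference = housekeeping gene, e.g. GAPDH).
#' Ct values must lie in (0, 45).
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
readCtTable <- function(path) {
  ct <- read_tsv(path)
  validateCtTable(ct)
}

validateCtTable <- function(ct) {
  req <- c("gene", "group", "replicate", "ct_target", "ct_reference")
  if (!all(req %in% colnames(ct)))
    validation_error(paste("Ct table needs columns", paste(req, collapse = ", ")))
  vals <- c(ct$ct_target, ct$ct_reference)
  if (any(!is.finite(vals)) || any(vals <= 0 | vals >= 45))
    validation_error("Ct values must lie in (0, 45)")
  ct
}

#' Relative quantification by the 2^(-DeltaDeltaCt) method
#'
#' Per replicate, DeltaCt = ct_target - ct_reference; per (gene, group),
#' DeltaCt is averaged over replicates; DeltaDeltaCt = DeltaCt(group) -
#' DeltaCt(control); fold change = 2^(-DeltaDeltaCt). Replicates are
#' aggregated by the arithmetic mean of DeltaCt (equivalently the geometric
#' mean of per-replicate folds); amplification efficiency is assumed 100%.
#' Genes missing from the control group are skipped with a warning.
#'
#' @param ct Ct table (see [readCtTable()]).
#' @param control_group Label of the reference group (e.g. `"NCD"`).
#' @return data.frame with one row per (gene, non-control group):
#'   `gene`, `group`, `delta_ct`, `delta_ct_control`, `delta_delta_ct`,
#'   `fold_change`; per-replicate folds are attached as attribute
#'   `replicate_folds`.
#' @examples
#' ct <- data.frame(gene = "Wdr4", group = rep(c("NCD", "HFD"), each = 2),
#'                  replicate = c(1, 2, 1, 2),
#'                  ct_target = c(24, 24.2, 26, 26.2),
#'                  ct_reference = c(18, 18.1, 18, 18.2))
#' relativeQuantification(ct, "NCD")
#' @export
relativeQuantification <- function(ct, control_group) {
  ct <- validateCtTable(ct)
  if (!control_group %in% ct$group)
    validation_error(sprintf("control group '%s' absent from Ct table",
                             control_group))
  ct$delta_ct <- ct$ct_target - ct$ct_reference
  ctrl <- ct[ct$group == control_group, ]
  ctrl_mean <- tapply(ctrl$delta_ct, ctrl$gene, mean)
  trt <- ct[ct$group != control_group, , drop = FALSE]
  missing <- setdiff(unique(trt$gene), names(ctrl_mean))
  if (length(missing)) {
    warning(paste0("gene(s) missing in control group, skipped: ",
                   paste(missing, collapse = ", ")), call. = FALSE)
    trt <- trt[!trt$gene %in% missing, , drop = FALSE]
  }
  key <- interaction(trt$gene, trt$group, drop = TRUE)
  agg <- do.call(rbind, lapply(split(trt, key), function(d) {
    data.frame(gene = d$gene[1], group = d$group[1],
               delta_ct = mean(d$delta_ct))
  }))
  agg$delta_ct_control <- as.numeric(ctrl_mean[agg$gene])
  agg$delta_delta_ct <- agg$delta_ct - agg$delta_ct_control
  agg$fold_change <- 2^(-agg$delta_delta_ct)
  rownames(agg) <- NULL
  rep_folds <- data.frame(gene = trt$gene, group = trt$group,
                          replicate = trt$replicate,
                          fold_change = 2^(-(trt$delta_ct -
                                               as.numeric(ctrl_mean[trt$gene]))))
  attr(agg, "replicate_folds") <- rep_folds
  agg
}

#' Rank a fold-change screen
#'
#' Sorts genes ascending by fold change, so the strongest downregulation
#' comes first; ties are broken lexicographically by gene.
#'
#' @param folds data.frame from [relativeQuantification()] (one group), or
#'   any data.frame with `gene` and `fold_change`.
#' @return The input rows, reordered, with a `rank` column prepended.
#' @export
rankScreen <- function(folds) {
  if (nrow(folds) < 1) validation_error("at least one gene is required")
  o <- order(folds$fold_change, folds$gene)
  out <- cbind(rank = seq_len(nrow(folds)), folds[o, , drop = FALSE])
  rownames(out) <- NULL
  out
}
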