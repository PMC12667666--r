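#' Construct a TeExperiment from a count matrix and sample sheet
#'
#' @param counts Integer matrix, genes x samples; column names must match
#'   `sample_info$sample`.
#' @param sample_info data.frame with columns `sample`, `assay_type`
#'   (`"RNC"`/`"RNA"`), `condition`, `replicate`.
#' @return A [TeExperiment-class].
#' @export
TeExperiment <- function(counts, sample_info) {
  req <- c("sample", "assay_type", "condition", "replicate")
  if (!all(req %in% colnames(sample_info)))
    validation_error(paste("sample_info needs columns",
                           paste(req, collapse = ", ")))
  m <- match(colnames(counts), sample_info$sample)
  if (any(is.na(m)))
    validation_error("count matrix columns missing from sample sheet")
  cd <- S4Vectors::DataFrame(sample_info[m, , drop = FALSE])
  rownames(cd) <- cd$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = as.matrix(counts)), colData = cd)
  obj <- new("TeExperiment", se)
  validObject(obj)
  obj
}

#' Read a TeExperiment from RNC/RNA count TSVs and a sample sheet
#'
#' Count files are tab-separated with a header row and gene ids in the first
#' column; the sample sheet has columns `sample`, `assay_type`, `condition`,
#' `replicate`.
#'
#' @param rnc_file,rna_file Paths to the RNC-seq and RNA-seq count tables.
#' @param sample_file Path to the sample sheet TSV.
#' @return A [TeExperiment-class].
#' @export
readTeExperiment <- function(rnc_file, rna_file, sample_file) {
  read_counts <- function(path) {
    df <- read_tsv(path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "integer"
    m
  }
  rnc <- read_counts(rnc_file)
  rna <- read_counts(rna_file)
  if (!identical(rownames(rnc), rownames(rna)))
    validation_error("RNC and RNA count tables must list the same genes in the same order")
  TeExperiment(cbind(rnc, rna), read_tsv(sample_file))
}

#' Configuration for the RNC/RNA count simulator
#'
#' Defines a two-condition translation-efficiency experiment with planted
#' per-gene TE shifts and CDS sequences of controlled codon composition.
#' RNA counts are negative binomial around a lognormal per-gene baseline
#' scaled to `library_depth`; RNC counts share the baseline but are
#' multiplied by `2^shift` in the second condition, so the planted shift is
#' the true log2 TE fold change. TE-up genes' CDS are enriched for
#' `codon_set` at the `cds_codon_bias["TE-up"]` target frequency.
#'
#' Defaults: 2000 genes, 2% TE-up at +2, 10% TE-down at -2, 3 replicates,
#' depth 1e6, NB dispersion 0.02 (cell-line-replicate regime), codon set
#' \{AAG, TGC\} at frequency 0.30 in TE-up CDS vs 0.15 elsewhere.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition (>= 2).
#' @param mean_expression Log-scale mean of the per-gene baseline (lognormal,
#'   sdlog 1); rescaled to `library_depth`, so it sets shape not scale.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param frac_te_up,frac_te_down Fractions of genes with shifted TE.
#' @param shift_up,shift_down Planted log2 TE shifts for the two classes.
#' @param te_shift Optional named numeric vector overriding per-gene shifts.
#' @param library_depth Expected reads per sample.
#' @param conditions Length-2 condition labels; the shift applies to the second.
#' @param codon_set Codons whose usage is biased in TE-up CDS.
#' @param cds_codon_bias Named numeric vector of target `codon_set` frequency
#'   per class (`TE-up`, `TE-down`, `other`).
#' @param cds_length_range Min/max CDS length in codons (excluding start/stop).
#' @param rng_seed Integer seed.
#' @return A validated list of class `TeSimConfig`.
#' @export
teSimConfig <- function(n_genes = 2000L,
                        n_replicates = 3L,
                        mean_expression = 5,
                        dispersion = 0.02,
                        frac_te_up = 0.02,
                        frac_te_down = 0.10,
                        shift_up = 2,
                        shift_down = -2,
                        te_shift = NULL,
                        library_depth = 1e6,
                        conditions = c("WT", "WDR4mut"),
                        codon_set = c("AAG", "TGC"),
                        cds_codon_bias = c("TE-up" = 0.30, "TE-down" = 0.15,
                                           "other" = 0.15),
                        cds_length_range = c(100L, 300L),
                        rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
              mean_expression = mean_expression, dispersion = dispersion,
              frac_te_up = frac_te_up, frac_te_down = frac_te_down,
              shift_up = shift_up, shift_down = shift_down, te_shift = te_shift,
              library_depth = library_depth, conditions = as.character(conditions),
              codon_set = toupper(codon_set), cds_codon_bias = cds_codon_bias,
              cds_length_range = as.integer(cds_length_range),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "TeSimConfig"
  validateTeSimConfig(cfg)
  cfg
}

validateTeSimConfig <- function(cfg) {
  if (cfg$n_replicates < 2)
    validation_error("n_replicates must be >= 2 (downstream variance undefined)")
  if (cfg$frac_te_up < 0 || cfg$frac_te_down < 0 ||
      cfg$frac_te_up + cfg$frac_te_down > 1)
    validation_error("class fractions must be non-negative and sum to <= 1")
  if (length(cfg$conditions) != 2)
    validation_error("exactly two conditions are required")
  if (cfg$dispersion <= 0) validation_error("dispersion must be positive")
  if (!all(c("TE-up", "TE-down", "other") %in% names(cfg$cds_codon_bias)))
    validation_error("cds_codon_bias needs entries TE-up, TE-down, other")
  if (any(cfg$cds_codon_bias < 0 | cfg$cds_codon_bias > 1))
    validation_error("cds_codon_bias values must lie in [0, 1]")
  invisible(cfg)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Random CDSs with a target frequency of `codon_set` among internal codons.
simulate_cds <- function(genes, n_codons, target_freq, codon_set) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  background <- setdiff(all_codons, c(STOP_CODONS, codon_set))
  tot <- sum(n_codons)
  in_set <- runif(tot) < rep(target_freq, n_codons)
  draws <- character(tot)
  draws[in_set] <- sample(codon_set, sum(in_set), replace = TRUE)
  draws[!in_set] <- sample(background, sum(!in_set), replace = TRUE)
  stops <- sample(STOP_CODONS, length(genes), replace = TRUE)
  grp <- rep(seq_along(genes), n_codons)
  bodies <- vapply(split(draws, grp), paste, character(1), collapse = "")
  cds <- Biostrings::DNAStringSet(paste0("ATG", bodies, stops))
  names(cds) <- genes
  cds
}

#' Simulate paired RNC-seq / RNA-seq counts with planted TE shifts
#'
#' Produces a [TeExperiment-class] (2 assays x 2 conditions x replicates),
#' an in-frame CDS per gene (starts ATG, ends with a stop, length divisible
#' by 3) with class-dependent codon composition, and a per-gene truth table.
#' Deterministic under `rng_seed`.
#'
#' @param cfg A [teSimConfig()].
#' @param out_dir Optional directory; when given, count matrices, sample
#'   sheet, CDS FASTA and truth table are written there as plain text.
#' @return A list: `te` ([TeExperiment-class]), `cds`
#'   ([Biostrings::DNAStringSet]), `truth` (data.frame with `gene`, `class`,
#'   `true_log2_te_shift`, `target_codon_freq`).
#' @examples
#' sim <- simulateTeCounts(teSimConfig(n_genes = 50, library_depth = 1e4))
#' @export
simulateTeCounts <- function(cfg, out_dir = NULL) {
  validateTeSimConfig(cfg)
  with_seed(derive_seed(cfg$rng_seed, 2L), {
    n <- cfg$n_genes
    genes <- sprintf("gene%05d", seq_len(n))
    n_up <- round(cfg$frac_te_up * n)
    n_down <- round(cfg$frac_te_down * n)
    cls <- rep("other", n)
    cls[sample.int(n, n_up + n_down)] <- rep(c("TE-up", "TE-down"),
                                             c(n_up, n_down))
    shift <- ifelse(cls == "TE-up", cfg$shift_up,
                    ifelse(cls == "TE-down", cfg$shift_down, 0))
    if (!is.null(cfg$te_shift)) {
      m <- match(names(cfg$te_shift), genes)
      if (any(is.na(m))) validation_error("te_shift names must be gene ids")
      shift[m] <- cfg$te_shift
      cls[m] <- ifelse(cfg$te_shift > 0, "TE-up",
                       ifelse(cfg$te_shift < 0, "TE-down", "other"))
    }
    baseline <- rlnorm(n, meanlog = cfg$mean_expression, sdlog = 1)
    p_rna <- baseline / sum(baseline)
    size <- 1 / cfg$dispersion
    cond_b <- cfg$conditions[2]
    cols <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        condition = cfg$conditions, assay_type = c("RNC", "RNA"),
                        stringsAsFactors = FALSE)
    cols$sample <- sprintf("%s_%s_rep%d", cols$assay_type, cols$condition,
                           cols$replicate)
    counts <- matrix(0L, n, nrow(cols), dimnames = list(genes, cols$sample))
    for (j in seq_len(nrow(cols))) {
      mu <- if (cols$assay_type[j] == "RNA") p_rna else {
        w <- baseline * if (cols$condition[j] == cond_b) 2^shift else 1
        w / sum(w)
      }
      counts[, j] <- rnbinom(n, mu = mu * cfg$library_depth, size = size)
    }
    n_codons <- sample_range(cfg$cds_length_range[1], cfg$cds_length_range[2], n)
    cds <- simulate_cds(genes, n_codons,
                        unname(cfg$cds_codon_bias[cls]), cfg$codon_set)
    truth <- data.frame(gene = genes, class = cls, true_log2_te_shift = shift,
                        target_codon_freq = unname(cfg$cds_codon_bias[cls]))
    te <- TeExperiment(counts, cols[, c("sample", "assay_type", "condition",
                                        "replicate")])
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (a in c("RNC", "RNA")) {
        sel <- cols$assay_type == a
        df <- data.frame(gene = genes, counts[, sel, drop = FALSE],
                         check.names = FALSE)
        write_tsv(df, file.path(out_dir, paste0(tolower(a), "_counts.tsv")))
      }
      write_tsv(cols[, c("sample", "assay_type", "condition", "replicate")],
                file.path(out_dir, "samples.tsv"))
      write_tsv(truth, file.path(out_dir, "truth_te.tsv"))
      Biostrings::writeXStringSet(cds, file.path(out_dir, "cds.fa"))
    }
    list(te = te, cds = cds, truth = truth)
  })
}
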