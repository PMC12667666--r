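#' Count codons decoded by a codon set, per CDS
#'
#' Counts frame-0 triplets of each CDS (reading frame fixed at 0; the CDS
#' must start with ATG and have length divisible by 3). The trailing stop
#' codon is excluded from `total_codons`; an internal stop triggers a
#' warning but counting continues. `m7g_decoded_frequency` is the fraction
#' of counted codons that belong to `codon_set` (0 when the set is empty or
#' no codons are counted).
#'
#' @param cds A [Biostrings::DNAStringSet] (or named character vector) of
#'   coding sequences.
#' @param codon_set Character vector of codons (DNA alphabet), e.g. the
#'   codons decoded by the m7G-modified tRNA set.
#' @return data.frame with columns `gene`, `total_codons`,
#'   `m7g_decoded_count`, `m7g_decoded_frequency`; the full 64-codon count
#'   matrix (including the trailing stop) is attached as attribute
#'   `codon_counts` and retrievable with [codonCounts()].
#' @examples
#' res <- countDecodedCodons(c(BMP8B_toy = "ATGAAGTGCAAGTAA"), c("AAG", "TGC"))
#' res$m7g_decoded_frequency  # 0.75
#' @export
countDecodedCodons <- function(cds, codon_set) {
  cds <- Biostrings::DNAStringSet(cds)
  codon_set <- toupper(codon_set)
  if (length(cds) == 0)
    validation_error("no CDS sequences supplied")
  w <- Biostrings::width(cds)
  if (any(w %% 3 != 0))
    validation_error(paste0("CDS length not divisible by 3: ",
                            paste(names(cds)[w %% 3 != 0], collapse = ", ")))
  first <- as.character(Biostrings::subseq(cds, 1, 3))
  if (any(first != "ATG"))
    warning(sprintf("%d CDS(s) do not start with ATG", sum(first != "ATG")),
            call. = FALSE)
  counts <- Biostrings::trinucleotideFrequency(cds, step = 3)
  last <- as.character(Biostrings::subseq(cds, w - 2, w))
  trailing_stop <- last %in% STOP_CODONS
  total <- w / 3L - as.integer(trailing_stop)
  internal_stops <- rowSums(counts[, STOP_CODONS, drop = FALSE]) -
    as.integer(trailing_stop)
  if (any(internal_stops > 0))
    warning(sprintf("internal stop codon(s) in %d CDS(s); counting continues",
                    sum(internal_stops > 0)), call. = FALSE)
  decoded <- if (length(codon_set))
    rowSums(counts[, intersect(codon_set, colnames(counts)), drop = FALSE]) else
      rep(0L, length(cds))
  ## the trailing stop never belongs to a decoded (sense) set, so no adjustment
  out <- data.frame(gene = if (is.null(names(cds)))
    sprintf("seq%d", seq_along(cds)) else names(cds),
    total_codons = as.integer(total),
    m7g_decoded_count = as.integer(decoded),
    m7g_decoded_frequency = ifelse(total > 0, decoded / total, 0),
    row.names = NULL)
  rownames(counts) <- out$gene
  attr(out, "codon_counts") <- counts
  out
}

#' Full per-gene codon count matrix
#'
#' @param usage Result of [countDecodedCodons()].
#' @return Integer matrix genes x 64 codons (includes the trailing stop).
#' @export
codonCounts <- function(usage) attr(usage, "codon_counts")

#' Compare decoded-codon frequencies across TE classes
#'
#' Joins per-gene decoded-codon usage with TE classification, then compares
#' `m7g_decoded_frequency` between TE-up vs other and TE-down vs other with
#' two-sided rank-sum (Mann-Whitney) tests using the normal approximation
#' with tie correction. Genes lacking a CDS are dropped with a logged count.
#' A comparison whose group has fewer than two genes is reported with an NA
#' p-value (not applicable) rather than an error.
#'
#' @param usage data.frame from [countDecodedCodons()].
#' @param te_results data.frame from [differentialTe()].
#' @return A list: `groups` (data.frame with per-class `n`, `median_freq`,
#'   `mean_freq`) and `tests` (data.frame with `comparison`, `p_value`).
#' @export
compareTeGroups <- function(usage, te_results) {
  m <- match(te_results$gene, usage$gene)
  dropped <- sum(is.na(m))
  if (dropped)
    m7g_log("codons", sprintf("%d gene(s) lacking a CDS dropped from group comparison",
                              dropped))
  d <- data.frame(gene = te_results$gene[!is.na(m)],
                  te_class = te_results$te_class[!is.na(m)],
                  freq = usage$m7g_decoded_frequency[m[!is.na(m)]])
  lv <- c("TE-up", "TE-down", "other")
  groups <- do.call(rbind, lapply(lv, function(g) {
    v <- d$freq[d$te_class == g]
    data.frame(group = g, n = length(v),
               median_freq = if (length(v)) median(v) else NA_real_,
               mean_freq = if (length(v)) mean(v) else NA_real_)
  }))
  test_one <- function(g) {
    x <- d$freq[d$te_class == g]; y <- d$freq[d$te_class == "other"]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                correct = TRUE)$p.value
  }
  tests <- data.frame(comparison = c("TE-up vs other", "TE-down vs other"),
                      p_value = c(test_one("TE-up"), test_one("TE-down")))
  list(groups = groups, tests = tests)
}

#' Frame-0 positions of selected codons along a CDS
#'
#' Lists every frame-0 occurrence of the requested codons (e.g. AAG and TGC,
#' the strict partners of the Lys-CTT and Cys-GCA anticodons) with its codon
#' index and 1-based nucleotide start `3 * (codon_index - 1) + 1`.
#' Out-of-frame matches spanning codon boundaries are not reported.
#'
#' @param cds A single CDS (character or [Biostrings::DNAString]), length
#'   divisible by 3.
#' @param codons Character vector of codons to locate.
#' @return data.frame with columns `codon`, `codon_index`, `nt_start`.
#' @examples
#' codonPositionTrack("ATGAAGTGCAAGTAA", c("AAG", "TGC"))
#' @export
codonPositionTrack <- function(cds, codons) {
  s <- toupper(as.character(cds))
  if (nchar(s) %% 3 != 0) validation_error("CDS length not divisible by 3")
  trip <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  hit <- which(trip %in% toupper(codons))
  data.frame(codon = trip[hit], codon_index = hit,
             nt_start = 3L * (hit - 1L) + 1L)
}

#' Write a codon position track as BED
#'
#' 0-based half-open 3-nt intervals `[nt_start - 1, nt_start + 2)` on the
#' gene "chromosome".
#'
#' @param track data.frame from [codonPositionTrack()].
#' @param gene Sequence name for the BED chrom column.
#' @param cds_length CDS length in nt.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeCodonBed <- function(track, gene, cds_length, path) {
  if (nrow(track) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = gene,
    ranges = IRanges::IRanges(start = track$nt_start, width = 3L),
    name = track$codon,
    seqlengths = setNames(as.integer(cds_length), gene))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Codon set decoded by condition-unique m7G tRNAs
#'
#' Collects the tRNAs carrying sites unique to one condition of a
#' [SiteComparison-class], maps their anticodons through a decoding map,
#' and returns the union of decoded codons. The tRNA -> codon provenance is
#' logged; distinct anticodons are collapsed (isodecoders of one
#' isoacceptor contribute once).
#'
#' @param comparison A [SiteComparison-class].
#' @param trnas The [TrnaSet-class] the sites live on.
#' @param map Decoding map from [buildDecodingMap()]; defaults to the strict
#'   map of `trnas`.
#' @param which Which unique set to use, `"b"` (default) or `"a"`.
#' @return Sorted character vector of codons (possibly empty, with warning).
#' @export
m7gCodonSetFromSites <- function(comparison, trnas,
                                 map = buildDecodingMap(trnas),
                                 which = c("b", "a")) {
  which <- match.arg(which)
  u <- uniqueSites(comparison, which)
  if (nrow(u) == 0) {
    warning("no condition-unique sites; empty codon set", call. = FALSE)
    return(character(0))
  }
  ac <- anticodons(trnas)[unique(u$trna_id)]
  for (id in names(ac))
    m7g_log("codons", sprintf("%s (anticodon %s) -> %s", id, ac[[id]],
                              paste(map[[ac[[id]]]], collapse = ",")))
  decodedCodons(map, unique(unname(ac)))
}
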