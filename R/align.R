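#' Read a FASTQ file of TRAC-seq reads
#'
#' Qualities are ignored (no downstream stage consumes them).
#'
#' @param path FASTQ path (4-line records).
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFastqReads <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Trim 3' adapter sequence from reads
#'
#' Removes from each read the longest suffix that exactly matches a prefix of
#' the adapter, requiring at least 6 nt of overlap. Reads shorter than
#' `min_len` after trimming are dropped. Trimmed and dropped counts are
#' logged.
#'
#' @param reads A [Biostrings::DNAStringSet] (or character vector).
#' @param adapter Adapter sequence, length >= 6.
#' @param min_len Minimum read length kept after trimming.
#' @return A [Biostrings::DNAStringSet] of surviving reads.
#' @export
trimAdapter <- function(reads, adapter, min_len = 15L) {
  adapter <- toupper(as.character(adapter))
  if (nchar(adapter) < 6) validation_error("adapter must be >= 6 nt")
  nms <- names(reads)
  s <- as.character(reads)
  trim_at <- rep(NA_integer_, length(s))
  for (k in seq(min(nchar(adapter), max(nchar(s), 0)), 6L)) {
    pre <- substr(adapter, 1L, k)
    hit <- is.na(trim_at) & endsWith(s, pre)
    trim_at[hit] <- k
  }
  n_trim <- sum(!is.na(trim_at))
  has <- !is.na(trim_at)
  s[has] <- substr(s[has], 1L, nchar(s[has]) - trim_at[has])
  keep <- nchar(s) >= min_len
  m7g_log("trim", sprintf("adapter removed from %d/%d reads; %d dropped below %d nt",
                          n_trim, length(s), sum(!keep), min_len))
  out <- Biostrings::DNAStringSet(s[keep])
  names(out) <- nms[keep]
  out
}

## Concatenated-reference index for ungapped alignment. References are
## ordered lexicographically by id so that "first minimal offset" implements
## the documented tie-breaks (smallest id, then smallest start).
build_ref_index <- function(trnas) {
  ids <- sort(trnaIds(trnas))
  seqs <- as.character(trnaSeqs(trnas))[match(ids, trnaIds(trnas))]
  w <- nchar(seqs)
  offset <- c(0L, cumsum(w + 1L))[seq_along(w)]  # 1 'N' spacer between refs
  list(ids = ids, widths = w, offset = offset,
       subject = Biostrings::DNAString(paste(seqs, collapse = "N")))
}

#' Align reads to tRNA references (ungapped, forward strand)
#'
#' Exhaustive ungapped forward-strand search of every read against every
#' reference offset; the best placement is the one with the fewest
#' mismatches. Reads with no placement at `max_mismatches` or fewer are
#' unaligned. Ties between references are resolved to the lexicographically
#' smallest tRNA id (or dropped with `multi = "discard"`); ties between
#' offsets on one reference to the smallest start. Identical read sequences
#' are aligned once and the placement reused, so deeply duplicated small-RNA
#' libraries align quickly. The mismatch scan itself is
#' [Biostrings::neditStartingAt()] over all within-reference offsets.
#'
#' @param reads A [Biostrings::DNAStringSet] (trimmed).
#' @param trnas A [TrnaSet-class].
#' @param max_mismatches Maximum mismatches allowed (default 1).
#' @param multi `"lexicographic"` (default, keep with smallest id) or
#'   `"discard"` for reads whose best score ties across references.
#' @return data.frame with columns `read_id`, `trna_id`, `start`, `end`
#'   (1-based, closed), `mismatches`.
#' @export
alignReads <- function(reads, trnas, max_mismatches = 1L,
                       multi = c("lexicographic", "discard")) {
  multi <- match.arg(multi)
  if (length(trnas) == 0) validation_error("empty tRNA reference")
  if (length(reads) == 0)
    return(data.frame(read_id = character(0), trna_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  idx <- build_ref_index(trnas)
  rs <- as.character(reads)
  uniq <- unique(rs)
  grp <- match(rs, uniq)
  lens <- nchar(uniq)
  ## valid concatenated offsets per read length (reads must fit in one ref)
  offsets_for_len <- function(len) {
    ok <- idx$widths >= len
    unlist(lapply(which(ok), function(i)
      seq.int(idx$offset[i] + 1L, idx$offset[i] + idx$widths[i] - len + 1L)),
      use.names = FALSE)
  }
  u_ref <- rep(NA_integer_, length(uniq))
  u_start <- rep(NA_integer_, length(uniq))
  u_mm <- rep(NA_integer_, length(uniq))
  u_multi <- rep(FALSE, length(uniq))
  for (len in sort(unique(lens))) {
    offs <- offsets_for_len(len)
    if (length(offs) == 0) next
    ref_of <- findInterval(offs, idx$offset + 1L)
    for (u in which(lens == len)) {
      ed <- Biostrings::neditStartingAt(Biostrings::DNAString(uniq[u]),
                                        idx$subject, starting.at = offs,
                                        with.indels = FALSE)
      best <- min(ed)
      if (best > max_mismatches) next
      hits <- which(ed == best)
      u_ref[u] <- ref_of[hits[1]]
      u_start[u] <- offs[hits[1]] - idx$offset[ref_of[hits[1]]]
      u_mm[u] <- best
      u_multi[u] <- length(unique(ref_of[hits])) > 1L
    }
  }
  aligned_u <- !is.na(u_ref)
  n_multi <- sum((u_multi[grp])[aligned_u[grp]])
  if (n_multi > 0)
    m7g_log("align", sprintf(
      "%d reads multi-mapped (best score on >1 reference); %s", n_multi,
      if (multi == "discard") "discarded" else "assigned to smallest trna_id"))
  keep_u <- aligned_u & !(u_multi & multi == "discard")
  keep <- keep_u[grp]
  out <- data.frame(read_id = names(reads)[keep],
                    trna_id = idx$ids[u_ref[grp[keep]]],
                    start = u_start[grp[keep]],
                    end = u_start[grp[keep]] + lens[grp[keep]] - 1L,
                    mismatches = u_mm[grp[keep]])
  m7g_log("align", sprintf("aligned %d/%d reads (%.1f%%)", nrow(out),
                           length(reads), 100 * nrow(out) / length(reads)))
  rownames(out) <- NULL
  out
}

## Sum of reference-consuming CIGAR M lengths; NA if the CIGAR uses
## operations outside the supported M/S subset.
cigar_ref_len <- function(cigar) {
  ops <- gregexpr("\\d+[A-Z=]", cigar)
  vapply(regmatches(cigar, ops), function(parts) {
    op <- substring(parts, nchar(parts))
    n <- as.integer(substring(parts, 1, nchar(parts) - 1))
    if (any(!op %in% c("M", "S"))) return(NA_integer_)
    sum(n[op == "M"])
  }, integer(1))
}

#' Import alignments from a SAM file
#'
#' Reads the minimal SAM subset the pipeline interoperates on: `@SQ` header
#' lines (checked against the reference ids), columns 1-9, CIGAR restricted
#' to M and S. Primary, mapped, forward-strand records are converted;
#' reverse-strand, unmapped, secondary/supplementary and indel-containing
#' (I/D) records are skipped with logged counts. SAM `POS` is already the
#' first aligned base, so soft clips need no start adjustment. Mismatch
#' counts are taken from the `NM` tag when present.
#'
#' @param path SAM file path.
#' @param trnas A [TrnaSet-class]; `@SQ` names must be a subset of its ids.
#' @return data.frame as from [alignReads()].
#' @export
importSam <- function(path, trnas) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- vapply(strsplit(sq, "\t", fixed = TRUE), function(x) {
    f <- grep("^SN:", x, value = TRUE)
    if (length(f)) sub("^SN:", "", f[1]) else NA_character_
  }, character(1))
  if (length(sn) && !all(sn %in% trnaIds(trnas)))
    validation_error(paste0("SAM @SQ reference name(s) not in tRNA set: ",
                            paste(setdiff(sn, trnaIds(trnas)), collapse = ", ")))
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(rec) == 0)
    return(data.frame(read_id = character(0), trna_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  f <- strsplit(rec, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[`, character(1), i)
  flag <- as.integer(getf(2))
  unmapped <- bitwAnd(flag, 4L) > 0L
  reverse <- bitwAnd(flag, 16L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  reflen <- cigar_ref_len(getf(6))
  indel <- is.na(reflen) & !unmapped
  keep <- !unmapped & !reverse & !secondary & !indel
  m7g_log("import_sam", sprintf(
    "%d records: kept %d; skipped %d unmapped, %d reverse-strand, %d secondary/supplementary, %d with unsupported CIGAR",
    length(rec), sum(keep), sum(unmapped), sum(reverse & !unmapped),
    sum(secondary & !reverse & !unmapped), sum(indel)))
  rname <- getf(3)[keep]
  bad <- !rname %in% trnaIds(trnas)
  if (any(bad))
    validation_error(paste0("SAM records reference unknown tRNA(s): ",
                            paste(unique(rname[bad]), collapse = ", ")))
  start <- as.integer(getf(4))[keep]
  nm <- vapply(f[keep], function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, integer(1))
  data.frame(read_id = getf(1)[keep], trna_id = rname, start = start,
             end = start + reflen[keep] - 1L, mismatches = nm)
}

#' Write alignments as SAM
#'
#' Emits a minimal SAM file (`@HD`, `@SQ` header; FLAG 0; CIGAR `<len>M`;
#' `SEQ`/`QUAL` omitted as `*`; `NM` tag) that [importSam()] round-trips to
#' identical pileups.
#'
#' @param alignments data.frame from [alignReads()].
#' @param trnas The [TrnaSet-class] aligned against.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(alignments, trnas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", trnaIds(trnas),
                     Biostrings::width(trnaSeqs(trnas))), con)
  if (nrow(alignments))
    writeLines(sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       alignments$read_id, alignments$trna_id, alignments$start,
                       alignments$end - alignments$start + 1L,
                       alignments$mismatches), con)
  invisible(path)
}
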