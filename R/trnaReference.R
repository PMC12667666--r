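## Parse a GtRNAdb-style header ("tRNA-Cys-GCA-1-1 ...") into amino acid and
## anticodon. Only the first whitespace-delimited token is used.
parse_trna_header <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  parts <- strsplit(id, "-", fixed = TRUE)
  aa <- vapply(parts, function(p) if (length(p) >= 3) p[2] else NA_character_,
               character(1))
  ac <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
               character(1))
  bad <- is.na(ac) | !grepl("^[ACGTacgtUu]{3}$", ac)
  if (any(bad))
    validation_error(paste0(
      "cannot parse anticodon from header(s): ",
      paste(id[bad], collapse = ", "),
      " (expected GtRNAdb-style names like 'tRNA-Cys-GCA-1-1')"))
  list(trna_id = id, amino_acid = aa,
       anticodon = chartr("u", "T", chartr("U", "T", toupper(ac))))
}

## Build a TrnaSet from parallel vectors; shared by the FASTA reader and the
## simulator.
make_trna_set <- function(ids, aa, anticodon, seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  obj <- new("TrnaSet", seqs = ss,
             info = S4Vectors::DataFrame(
               trna_id = ids, amino_acid = aa, anticodon = anticodon,
               length = Biostrings::width(ss)))
  validObject(obj)
  not_cca <- !endsWith(as.character(ss), "CCA")
  if (any(not_cca))
    warning(sprintf("%d tRNA sequence(s) do not end in 'CCA' (expected for mature tRNAs): %s",
                    sum(not_cca), paste(head(ids[not_cca], 5), collapse = ", ")),
            call. = FALSE)
  obj
}

#' Read mature tRNA references from FASTA
#'
#' Parses a FASTA file of mature tRNA sequences with GtRNAdb-style headers
#' (`>tRNA-Cys-GCA-1-1`), extracting the amino acid and anticodon from the
#' header. Lowercase input is uppercased and U is converted to T (DNA
#' alphabet throughout, with a logged note); any other non-ACGT character is
#' an error naming the offending record. Duplicate ids are an error. A
#' sequence not ending in `CCA` triggers a warning (references are assumed
#' mature; no intron or tail processing is performed).
#'
#' @param path Path to a FASTA file.
#' @return A [TrnaSet-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tRNA-Cys-GCA-1-1", paste(rep("ACGT", 19), collapse = "")), fa)
#' suppressWarnings(readTrnaFasta(fa))
#' @export
readTrnaFasta <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) {
    warning("empty tRNA reference FASTA: ", path, call. = FALSE)
    return(new("TrnaSet", seqs = Biostrings::DNAStringSet(),
               info = S4Vectors::DataFrame(trna_id = character(0),
                                           amino_acid = character(0),
                                           anticodon = character(0),
                                           length = integer(0))))
  }
  hdr <- parse_trna_header(names(raw))
  if (anyDuplicated(hdr$trna_id))
    validation_error(paste0("duplicate tRNA id(s): ",
                            paste(unique(hdr$trna_id[duplicated(hdr$trna_id)]),
                                  collapse = ", ")))
  seqs <- toupper(as.character(raw))
  n_u <- sum(vapply(gregexpr("U", seqs, fixed = TRUE),
                    function(m) sum(m > 0), numeric(1)))
  if (n_u > 0) {
    seqs <- chartr("U", "T", seqs)
    m7g_log("trna_reference", sprintf("converted %d 'U' bases to 'T'", n_u))
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    validation_error(paste0("non-ACGTU characters in record(s): ",
                            paste(hdr$trna_id[bad], collapse = ", ")))
  make_trna_set(hdr$trna_id, hdr$amino_acid, hdr$anticodon, seqs)
}

#' Write a TrnaSet to FASTA
#'
#' @param x A [TrnaSet-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeTrnaFasta <- function(x, path) {
  Biostrings::writeXStringSet(trnaSeqs(x), path)
  invisible(path)
}

## Wobble expansion at codon position 3, keyed by anticodon position 34
## (the first base of the 5'->3' anticodon). The strict Watson-Crick codon
## (reverse complement) is always included.
WOBBLE_POS3 <- list(G = c("C", "T"), T = c("A", "G"), A = "T", C = "G")

#' Build an anticodon to codon decoding map
#'
#' Maps each distinct anticodon in a reference set to the codon(s) it decodes,
#' in the DNA alphabet. In `strict` mode each anticodon maps to exactly its
#' reverse complement (Watson-Crick pairing; e.g. anticodon GCA of
#' tRNA-Cys -> codon TGC, CTT of tRNA-Lys -> AAG). In `wobble` mode the strict
#' codon is kept and additional codons differing only at codon position 3 are
#' added according to the pairing of anticodon position 34:
#' G -> \{C, T\}, T -> \{A, G\}, A -> \{T\}, C -> \{G\}.
#'
#' Strict pairing is the default because the decoded-codon analyses this map
#' feeds are defined on exact anticodon partners; wobble is opt-in.
#'
#' @param x A [TrnaSet-class], or a character vector of anticodons.
#' @param mode `"strict"` (default) or `"wobble"`.
#' @return An [IRanges::CharacterList] mapping anticodon -> codons, with the
#'   mode stored in `metadata()`.
#' @examples
#' buildDecodingMap(c("GCA", "CTT"))                   # strict: TGC, AAG
#' buildDecodingMap(c("GCA", "CTT"), mode = "wobble")  # adds TGT, AAA
#' @export
buildDecodingMap <- function(x, mode = c("strict", "wobble")) {
  mode <- match.arg(mode)
  ac <- if (is(x, "TrnaSet")) unname(anticodons(x)) else as.character(x)
  if (length(ac) == 0) validation_error("no anticodons to map")
  if (!all(grepl("^[ACGT]{3}$", ac)))
    validation_error("anticodons must be 3-nt DNA strings over A/C/G/T")
  ac <- sort(unique(ac))
  strict <- revComp(ac)
  codons <- lapply(seq_along(ac), function(i) {
    if (mode == "strict") return(strict[i])
    third <- WOBBLE_POS3[[substr(ac[i], 1, 1)]]
    sort(unique(c(strict[i],
                  paste0(substr(strict[i], 1, 2), third))))
  })
  out <- IRanges::CharacterList(setNames(codons, ac))
  S4Vectors::metadata(out) <- list(mode = mode)
  out
}

#' Codons decoded by a set of anticodons
#'
#' @param map A decoding map from [buildDecodingMap()].
#' @param anticodon Character vector of anticodons to look up; default all.
#' @return Sorted character vector of codons (union).
#' @export
decodedCodons <- function(map, anticodon = names(map)) {
  missing <- setdiff(anticodon, names(map))
  if (length(missing))
    validation_error(paste0("anticodon(s) not in map: ",
                            paste(missing, collapse = ", ")))
  sort(unique(unlist(map[anticodon], use.names = FALSE)))
}
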