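test_that("adapter trimming removes suffix-prefix overlaps of >= 6 nt", {
  adapter <- "AGATCGGAAGAGC"
  reads <- Biostrings::DNAStringSet(c(
    r1 = paste0("ACGTACGTACGTACGTACGT", substr(adapter, 1, 10)),
    r2 = "ACGTACGTACGTACGTACGT",               # no adapter: unchanged
    r3 = paste0("ACGTA", substr(adapter, 1, 13)),  # trimmed below min_len
    r4 = paste0("ACGTACGTACGTACGTACGT", substr(adapter, 1, 5))))  # 5 < 6 nt
  out <- suppressMessages(trimAdapter(reads, adapter, min_len = 8))
  expect_equal(as.character(out[["r1"]]), "ACGTACGTACGTACGTACGT")
  expect_equal(as.character(out[["r2"]]), "ACGTACGTACGTACGTACGT")
  expect_false("r3" %in% names(out))
  expect_equal(nchar(as.character(out[["r4"]])), 25L)  # overlap too short
  expect_error(trimAdapter(reads, "ACGT"), ">= 6")
})

test_that("exact substrings align at the expected coordinates", {
  trnas <- tiny_trnas()
  refs <- as.character(trnaSeqs(trnas))
  read <- substr(refs[[1]], 11, 30)  # 0-based slice ref[10:30]
  aln <- suppressMessages(alignReads(
    Biostrings::DNAStringSet(c(q = read)), trnas))
  expect_equal(aln$trna_id, "tRNA-Cys-GCA-1-1")
  expect_equal(aln$start, 11L)
  expect_equal(aln$end, 30L)
  expect_equal(aln$mismatches, 0L)
})

test_that("one-substitution reads keep their placement (brute-force oracle)", {
  trnas <- tiny_trnas()
  refs <- setNames(as.character(trnaSeqs(trnas)), trnaIds(trnas))
  read <- substr(refs[["tRNA-Cys-GCA-1-1"]], 40, 59)
  substr(read, 8, 8) <- ifelse(substr(read, 8, 8) == "A", "C", "A")
  scan <- brute_scan(read, refs)
  best <- scan[scan$mismatches == min(scan$mismatches), ]
  expect_equal(nrow(best), 1L)  # placement unique at 1 mismatch
  aln <- suppressMessages(alignReads(
    Biostrings::DNAStringSet(c(q = read)), trnas))
  expect_equal(aln$trna_id, best$trna_id)
  expect_equal(aln$start, best$start)
  expect_equal(aln$mismatches, 1L)
})

test_that("unalignable reads are dropped and empty references error", {
  trnas <- tiny_trnas()
  aln <- suppressMessages(alignReads(
    Biostrings::DNAStringSet(c(q = strrep("GC", 10))), trnas))
  expect_equal(nrow(aln), 0L)
  fa <- tempfile(fileext = ".fa"); file.create(fa)
  empty <- suppressWarnings(readTrnaFasta(fa))
  expect_error(alignReads(Biostrings::DNAStringSet("ACGT"), empty), "empty")
})

test_that("SAM import honours flags, CIGAR clips and 1-based POS", {
  trnas <- tiny_trnas()
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:76", trnaIds(trnas)),
    "r1\t0\ttRNA-Cys-GCA-1-1\t47\t255\t20M\t*\t0\t0\t*\t*",
    "r2\t16\ttRNA-Cys-GCA-1-1\t5\t255\t20M\t*\t0\t0\t*\t*",       # reverse
    "r3\t0\ttRNA-Cys-GCA-1-1\t47\t255\t2S18M\t*\t0\t0\t*\t*",     # soft clip
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",                            # unmapped
    "r5\t0\ttRNA-Lys-CTT-1-1\t10\t255\t5M1D15M\t*\t0\t0\t*\t*",   # indel
    "r6\t0\ttRNA-Lys-CTT-1-1\t3\t255\t10M\t*\t0\t0\t*\t*\tNM:i:1"
  ), sam)
  aln <- suppressMessages(importSam(sam, trnas))
  expect_equal(aln$read_id, c("r1", "r3", "r6"))
  expect_equal(aln$start, c(47L, 47L, 3L))
  expect_equal(aln$end, c(66L, 64L, 12L))
  expect_equal(aln$mismatches, c(0L, 0L, 1L))
  # @SQ names not in the reference are an error
  writeLines(c("@SQ\tSN:tRNA-Phe-GAA-1-1\tLN:76"), sam)
  expect_error(importSam(sam, trnas), "tRNA-Phe-GAA-1-1")
})

test_that("pileup matches hand counts on a tiny alignment set", {
  trnas <- tiny_trnas()
  aln <- data.frame(
    read_id = paste0("r", 1:4), trna_id = "tRNA-Cys-GCA-1-1",
    start = c(47L, 47L, 47L, 1L), end = c(66L, 66L, 66L, 76L),
    mismatches = 0L)
  pu <- buildPileup(aln, trnas)
  tr <- pileupTrack(pu, "tRNA-Cys-GCA-1-1")
  expect_equal(tr$starts[47], 3L)
  expect_equal(tr$readthrough[47], 1L)
  expect_equal(tr$stop_fraction[47], 0.75)
  expect_equal(sum(tr$starts), nrow(aln))
  # no alignments -> empty output; all-start-1 -> stop fraction 1 at 1 only
  expect_length(trackNames(buildPileup(aln[0, ], trnas)), 0)
  pu1 <- buildPileup(transform(aln, start = 1L, end = 76L), trnas)
  tr1 <- pileupTrack(pu1, "tRNA-Cys-GCA-1-1")
  expect_equal(tr1$stop_fraction[1], 1)
  expect_true(all(tr1$stop_fraction[-1] == 0))
})

test_that("pileup equals an independent brute-force recount on 200 alignments", {
  trnas <- tiny_trnas()
  set.seed(41)
  n <- 200
  id <- sample(trnaIds(trnas), n, replace = TRUE)
  start <- sample(1:60, n, replace = TRUE)
  end <- pmin(start + sample(14:40, n, replace = TRUE), 76L)
  aln <- data.frame(read_id = paste0("r", 1:n), trna_id = id,
                    start = start, end = end, mismatches = 0L)
  pu <- buildPileup(aln, trnas)
  for (tid in trnaIds(trnas)) {
    oracle <- brute_pileup(aln[aln$trna_id == tid, ], 76L)
    tr <- pileupTrack(pu, tid)
    expect_identical(tr$starts, oracle$starts)
    expect_identical(tr$coverage, oracle$coverage)
    expect_identical(tr$readthrough, oracle$readthrough)
    expect_equal(tr$stop_fraction, oracle$stop_fraction)
  }
})

test_that("SAM round-trip reproduces identical pileup tracks", {
  fx <- small_sim(reads = 1500)
  r <- readFastqReads(fx$sim$libraries$fastq[1])
  aln <- suppressMessages(alignReads(r, fx$trnas))
  pu1 <- buildPileup(aln, fx$trnas)
  sam <- tempfile(fileext = ".sam")
  writeSam(aln, fx$trnas, sam)
  aln2 <- suppressMessages(importSam(sam, fx$trnas))
  pu2 <- buildPileup(aln2, fx$trnas)
  expect_identical(trackNames(pu1), trackNames(pu2))
  for (id in trackNames(pu1))
    expect_equal(pileupTrack(pu1, id), pileupTrack(pu2, id))
})

test_that("alignment output is invariant to read input order", {
  fx <- small_sim(reads = 1000)
  r <- readFastqReads(fx$sim$libraries$fastq[1])
  set.seed(7)
  perm <- sample(length(r))
  a1 <- suppressMessages(alignReads(r, fx$trnas))
  a2 <- suppressMessages(alignReads(r[perm], fx$trnas))
  a1 <- a1[order(a1$read_id), ]; a2 <- a2[order(a2$read_id), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("multi-mapping reads resolve to the smallest id or are discarded", {
  fa <- tempfile(fileext = ".fa")
  common <- strrep("ACGT", 19)
  writeLines(c(">tRNA-Cys-GCA-1-1", common, ">tRNA-Ala-AGC-1-1", common), fa)
  trnas <- suppressWarnings(readTrnaFasta(fa))
  read <- Biostrings::DNAStringSet(c(q = substr(common, 5, 30)))
  a <- suppressMessages(alignReads(read, trnas))
  expect_equal(a$trna_id, "tRNA-Ala-AGC-1-1")  # lexicographically smallest
  a2 <- suppressMessages(alignReads(read, trnas, multi = "discard"))
  expect_equal(nrow(a2), 0L)
})
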