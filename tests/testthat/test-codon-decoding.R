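test_that("the worked decoded-codon example counts as ATG·AAG·TGC·AAG·(TAA)", {
  res <- countDecodedCodons(c(toy = "ATGAAGTGCAAGTAA"), c("AAG", "TGC"))
  expect_equal(res$total_codons, 4L)
  expect_equal(res$m7g_decoded_count, 3L)
  expect_equal(res$m7g_decoded_frequency, 0.75)
  # empty codon set and minimal CDS degenerate cases
  res0 <- countDecodedCodons(c(toy = "ATGAAGTGCAAGTAA"), character(0))
  expect_equal(res0$m7g_decoded_frequency, 0)
  res1 <- countDecodedCodons(c(min = "ATGTAA"), c("AAG"))
  expect_equal(res1$total_codons, 1L)
  expect_equal(res1$m7g_decoded_frequency, 0)
  res2 <- countDecodedCodons(c(min = "ATGTAA"), c("ATG"))
  expect_equal(res2$m7g_decoded_frequency, 1)
})

test_that("counting errors and warnings fire per the CDS contract", {
  expect_error(countDecodedCodons(c(x = "ATGAA"), "AAG"), "divisible")
  expect_warning(countDecodedCodons(c(x = "ATGTAAAAGTGA"), "AAG"), "internal stop")
  expect_warning(countDecodedCodons(c(x = "CCCAAGTAA"), "AAG"), "ATG")
})

test_that("decoded-codon counts equal a brute-force frame-0 oracle", {
  set.seed(55)
  codon_set <- c("AAG", "TGC")
  for (i in 1:200) {
    ncod <- sample(3:40, 1)
    cds <- paste0("ATG", paste(sample(c("AAG", "TGC", "GCT", "TTT", "GGA",
                                        "CAT", "AAA"), ncod, replace = TRUE),
                               collapse = ""), "TAA")
    oracle <- brute_count_codons(cds, codon_set)
    res <- countDecodedCodons(setNames(cds, "g"), codon_set)
    expect_identical(res$total_codons, oracle$total)
    expect_identical(res$m7g_decoded_count, oracle$decoded)
    expect_equal(res$m7g_decoded_frequency, oracle$frequency)
  }
})

test_that("frequency scales exactly under codon-set-free concatenation", {
  cds <- "ATGAAGTGCAAGTAA"                       # 4 codons, 3 decoded
  ext <- paste0("ATGAAGTGCAAG", strrep("GGA", 6), "TAA")  # +6 set-free codons
  f1 <- countDecodedCodons(c(a = cds), c("AAG", "TGC"))$m7g_decoded_frequency
  f2 <- countDecodedCodons(c(b = ext), c("AAG", "TGC"))$m7g_decoded_frequency
  expect_equal(f2, f1 * 4 / 10)
})

test_that("codon position tracks report frame-0 occurrences only", {
  tr <- codonPositionTrack("ATGAAGTGCAAGTAA", c("AAG", "TGC"))
  expect_equal(tr$codon, c("AAG", "TGC", "AAG"))
  expect_equal(tr$codon_index, c(2L, 3L, 4L))
  expect_equal(tr$nt_start, c(4L, 7L, 10L))
  # "AAG" spanning codons 1-2 of ATG|GAA|... is out of frame: not reported
  tr2 <- codonPositionTrack("ATGGAAGGGTAA", "AAG")
  expect_equal(nrow(tr2), 0L)
  expect_equal(nrow(codonPositionTrack("ATGTAA", "CCC")), 0L)
  bed <- tempfile(fileext = ".bed")
  writeCodonBed(tr, "BMP8B", 15L, bed)
  f <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_equal(as.integer(f[2]), 3L)   # nt_start 4 -> 0-based 3
  expect_equal(as.integer(f[3]), 6L)
})

test_that("group comparison reproduces codon enrichment in TE-up genes", {
  set.seed(14)
  n_up <- 100; n_other <- 1000
  mk_cds <- function(n, f) vapply(seq_len(n), function(i) {
    ncod <- 60
    draws <- ifelse(runif(ncod) < f,
                    sample(c("AAG", "TGC"), ncod, replace = TRUE),
                    sample(c("GCT", "GGA", "CAT", "TTT"), ncod, replace = TRUE))
    paste0("ATG", paste(draws, collapse = ""), "TAA")
  }, character(1))
  cds <- c(mk_cds(n_up, 0.30), mk_cds(n_other, 0.15))
  names(cds) <- sprintf("g%04d", seq_along(cds))
  usage <- countDecodedCodons(cds, c("AAG", "TGC"))
  te <- data.frame(gene = names(cds),
                   te_class = rep(c("TE-up", "other"), c(n_up, n_other)))
  g <- compareTeGroups(usage, te)
  med <- setNames(g$groups$median_freq, g$groups$group)
  expect_gt(med[["TE-up"]], med[["other"]])
  expect_lt(g$tests$p_value[g$tests$comparison == "TE-up vs other"], 0.01)
  # identical distributions: p well away from significance across groups
  te_null <- data.frame(gene = names(cds),
                        te_class = sample(rep(c("TE-up", "other"),
                                              c(n_up, n_other))))
  g0 <- compareTeGroups(usage, te_null)
  expect_gt(g0$tests$p_value[1], 0.01)
  # one-gene groups report medians but no p-value
  g1 <- compareTeGroups(usage[1:2, ],
                        data.frame(gene = names(cds)[1:2],
                                   te_class = c("TE-up", "other")))
  expect_true(is.na(g1$tests$p_value[1]))
  expect_false(is.na(g1$groups$median_freq[1]))
})

test_that("condition-unique sites map to the expected codon sets", {
  trnas <- tiny_trnas()  # Cys-GCA and Lys-CTT
  mk <- function(ids) {
    if (length(ids) == 0) return(mk("dummy")[0, , drop = FALSE])
    data.frame(trna_id = ids, position = 46L, stop_fraction = 0.5,
               coverage = 100, score = 0.5, n_replicates_supporting = 2L,
               condition = "x")
  }
  cmp <- compareConditions(mk(character(0)), mk(trnaIds(trnas)),
                           "vector", "WDR4_OE")
  expect_setequal(suppressMessages(m7gCodonSetFromSites(cmp, trnas)),
                  c("TGC", "AAG"))
  wob <- buildDecodingMap(trnas, mode = "wobble")
  expect_setequal(suppressMessages(m7gCodonSetFromSites(cmp, trnas, wob)),
                  c("TGC", "TGT", "AAG"))
  cmp0 <- compareConditions(mk(character(0)), mk(character(0)), "a", "b")
  expect_warning(empty <- m7gCodonSetFromSites(cmp0, trnas), "unique")
  expect_length(empty, 0L)
})
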