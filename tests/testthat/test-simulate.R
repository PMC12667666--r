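test_that("simulated references carry the planted motif context and identity", {
  cfg <- simConfig(n_trnas = 1, trna_length_range = c(76, 76),
                   m7g_positions = c("1" = 46),
                   cleavage_efficiency = data.frame(
                     trna = "1", condition = "WDR4_OE", efficiency = 1),
                   rng_seed = 5)
  trnas <- simulateTrnaReference(cfg)
  s <- as.character(trnaSeqs(trnas)[[1]])
  # centred-window convention: positions 43-49 are TGAACC + any base
  expect_equal(substr(s, 43, 48), "TGAACC")
  expect_true(substr(s, 49, 49) %in% c("A", "C", "G", "T"))
  # anticodon embedded at 34-36 and consistent with the header name
  expect_equal(substr(s, 34, 36), unname(anticodons(trnas)))
  expect_true(endsWith(s, "CCA"))
})

test_that("reference simulation is byte-deterministic under a seed", {
  cfg <- simConfig(n_trnas = 5, rng_seed = 33,
                   m7g_positions = c("1" = 46),
                   cleavage_efficiency = data.frame(
                     trna = "1", condition = "WDR4_OE", efficiency = 0.5))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  simulateTrnaReference(cfg, fasta_out = f1)
  simulateTrnaReference(cfg, fasta_out = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("out-of-bounds m7G positions are a configuration error", {
  # position 100 on a 76-nt tRNA is rejected at configuration time
  expect_error(
    simConfig(n_trnas = 1, trna_length_range = c(76, 76),
              m7g_positions = c("1" = 100),
              cleavage_efficiency = data.frame(
                trna = "1", condition = "WDR4_OE", efficiency = 0.5)),
    "length range")
  # window must fit: a site 2 nt from the end cannot hold a centred 7-mer
  cfg2 <- simConfig(n_trnas = 1, trna_length_range = c(76, 76),
                    m7g_positions = c("1" = 75),
                    cleavage_efficiency = data.frame(
                      trna = "1", condition = "WDR4_OE", efficiency = 0.5))
  expect_error(simulateTrnaReference(cfg2), "window")
  expect_error(simConfig(seq_error_rate = 1.5), "probabilities")
})

test_that("noise-free full-efficiency libraries stop only at 1 and site + 1", {
  cfg <- simConfig(n_trnas = 2, trna_length_range = c(76, 76),
                   m7g_positions = c("1" = 46, "2" = 46),
                   cleavage_efficiency = data.frame(
                     trna = c("1", "2"), condition = "vector", efficiency = 1),
                   background_break_rate = 0, seq_error_rate = 0,
                   reads_per_library = 2000, conditions = "vector",
                   replicates_per_condition = 1, rng_seed = 2)
  trnas <- simulateTrnaReference(cfg)
  sim <- suppressMessages(simulateTracseqReads(cfg, trnas, tempfile()))
  aln <- suppressMessages(alignReads(readFastqReads(sim$libraries$fastq[1]), trnas))
  expect_true(all(aln$start %in% c(1L, 47L)))
  pu <- buildPileup(aln, trnas)
  for (id in trackNames(pu)) {
    tr <- pileupTrack(pu, id)
    expect_setequal(tr$pos[tr$stop_fraction > 0], c(1L, 47L))
  }
})

test_that("empirical stop fraction matches planted efficiency (binomial oracle)", {
  eff <- 0.6
  cfg <- simConfig(n_trnas = 1, trna_length_range = c(76, 76),
                   m7g_positions = c("1" = 46),
                   cleavage_efficiency = data.frame(
                     trna = "1", condition = "vector", efficiency = eff),
                   background_break_rate = 0, seq_error_rate = 0,
                   reads_per_library = 50000, conditions = "vector",
                   replicates_per_condition = 1, rng_seed = 17)
  trnas <- simulateTrnaReference(cfg)
  sim <- suppressMessages(simulateTracseqReads(cfg, trnas, tempfile()))
  aln <- suppressMessages(alignReads(readFastqReads(sim$libraries$fastq[1]), trnas))
  pu <- buildPileup(aln, trnas)
  tr <- pileupTrack(pu, trackNames(pu)[1])
  n <- tr$starts[47] + tr$readthrough[47]
  # 99% binomial interval around the truth-table efficiency
  half <- qnorm(0.995) * sqrt(eff * (1 - eff) / n)
  expect_gt(tr$stop_fraction[47], eff - half)
  expect_lt(tr$stop_fraction[47], eff + half)
  expect_equal(sim$truth$cleavage_efficiency, eff)
})

test_that("zero requested reads yields an empty FASTQ with a warning", {
  cfg <- simConfig(n_trnas = 1, reads_per_library = 0, conditions = "vector",
                   replicates_per_condition = 1,
                   m7g_positions = c("1" = 46),
                   cleavage_efficiency = data.frame(
                     trna = "1", condition = "vector", efficiency = 0.5))
  trnas <- simulateTrnaReference(cfg)
  expect_warning(sim <- simulateTracseqReads(cfg, trnas, tempfile()),
                 "zero reads")
  expect_equal(file.size(sim$libraries$fastq[1]), 0)
})

test_that("null TE simulation centres the estimated log2 TE shift at zero", {
  cfg <- teSimConfig(frac_te_up = 0, frac_te_down = 0, rng_seed = 4)
  sim <- simulateTeCounts(cfg)
  res <- differentialTe(computeTe(sim$te), "WT", "WDR4mut")
  expect_lt(abs(mean(res$log2fc)), 0.05)
  expect_true(all(sim$truth$true_log2_te_shift == 0))
})

test_that("a planted +2 TE shift is recovered near +2", {
  cfg <- teSimConfig(n_genes = 400, rng_seed = 9)
  sim <- simulateTeCounts(cfg)
  res <- differentialTe(computeTe(sim$te), "WT", "WDR4mut")
  up <- sim$truth$gene[sim$truth$class == "TE-up"]
  est <- mean(res$log2fc[match(up, res$gene)], na.rm = TRUE)
  expect_gt(est, 1.5); expect_lt(est, 2.5)
})

test_that("simulated CDS are well-formed and codon-frequency-controlled", {
  cfg <- teSimConfig(n_genes = 300, rng_seed = 21)
  sim <- simulateTeCounts(cfg)
  w <- Biostrings::width(sim$cds)
  expect_true(all(w %% 3 == 0))
  expect_true(all(Biostrings::subseq(sim$cds, 1, 3) == "ATG"))
  last <- as.character(Biostrings::subseq(sim$cds, w - 2, w))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  expect_equal(length(sim$cds), 300L)
  # TE-up CDS are enriched for the designated codon set
  usage <- suppressWarnings(countDecodedCodons(sim$cds, cfg$codon_set))
  f_up <- mean(usage$m7g_decoded_frequency[sim$truth$class == "TE-up"])
  f_ot <- mean(usage$m7g_decoded_frequency[sim$truth$class == "other"])
  expect_gt(f_up, f_ot + 0.05)
})

test_that("TE count simulation rejects single-replicate designs", {
  expect_error(teSimConfig(n_replicates = 1), "replicates")
})

test_that("simulated counts are reproducible and integer-valued", {
  cfg <- teSimConfig(n_genes = 50, rng_seed = 3)
  a <- simulateTeCounts(cfg); b <- simulateTeCounts(cfg)
  ca <- SummarizedExperiment::assay(a$te); cb <- SummarizedExperiment::assay(b$te)
  expect_identical(ca, cb)
  expect_true(all(ca >= 0) && all(ca == round(ca)))
})
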