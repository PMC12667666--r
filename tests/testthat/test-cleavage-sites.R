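# Build a PileupSet from explicit alignments on tiny_trnas().
pileup_from <- function(starts47, readthrough47, trnas = tiny_trnas(),
                        id = "tRNA-Cys-GCA-1-1") {
  aln <- data.frame(
    read_id = sprintf("r%d", seq_len(starts47 + readthrough47)),
    trna_id = id,
    start = c(rep(47L, starts47), rep(1L, readthrough47)),
    end = 76L, mismatches = 0L)
  buildPileup(aln, trnas, library = "lib")
}

test_that("a strong stop site is called with exact binomial arithmetic", {
  pu <- pileup_from(600, 400)
  sites <- callSites(pu)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 46L)  # stop position 47 -> site 46
  expect_equal(sites$score, 0.6)
  expect_equal(sites$coverage, 1000)
  # background here is the floored per-tRNA median (0.001); the reported
  # p-value must equal exact pmf summation to 1e-9
  oracle <- binom_tail_sum(600, 1000, 0.001)
  expect_lt(abs(sites$p_value - oracle), 1e-9)
})

test_that("binomial tails match exact summation across moderate cases", {
  cases <- data.frame(k = c(5L, 30L, 600L, 1L), n = c(1000L, 200L, 1000L, 50L),
                      p = c(0.003, 0.1, 0.01, 0.02))
  for (i in seq_len(nrow(cases))) {
    tail_pkg <- pbinom(cases$k[i] - 1L, cases$n[i], cases$p[i],
                       lower.tail = FALSE)
    expect_lt(abs(tail_pkg - with(cases[i, ], binom_tail_sum(k, n, p))), 1e-9)
  }
})

test_that("coverage and stop-fraction gates suppress calls", {
  # high stop fraction but coverage 10 < min_coverage
  pu <- pileup_from(9, 1)
  expect_equal(nrow(callSites(pu)), 0L)
  # background-only library (no cleavage anywhere): nothing called
  cfg <- simConfig(n_trnas = 3, reads_per_library = 6000,
                   m7g_positions = c("1" = 46),
                   cleavage_efficiency = data.frame(
                     trna = "1", condition = "vector", efficiency = 0),
                   conditions = "vector", replicates_per_condition = 1,
                   rng_seed = 23)
  trnas <- simulateTrnaReference(cfg)
  sim <- suppressMessages(simulateTracseqReads(cfg, trnas, tempfile()))
  aln <- suppressMessages(alignReads(readFastqReads(sim$libraries$fastq[1]),
                                     trnas))
  expect_equal(nrow(callSites(buildPileup(aln, trnas))), 0L)
  expect_error(callSites(pu, min_coverage = 0), "min_coverage")
})

test_that("stop positions 1 and 2 are never callable", {
  trnas <- tiny_trnas()
  aln <- data.frame(read_id = sprintf("r%d", 1:1000),
                    trna_id = "tRNA-Cys-GCA-1-1",
                    start = c(rep(1L, 600), rep(2L, 400)),
                    end = 76L, mismatches = 0L)
  sites <- callSites(buildPileup(aln, trnas))
  expect_false(any(sites$position < 2L))
  expect_equal(nrow(sites), 0L)
})

test_that("raising min_stop_fraction never increases the number of calls", {
  fx <- small_sim(reads = 4000)
  rc <- run_calling(fx)
  pu <- rc$pileups[[3]]  # an OE library
  counts <- vapply(seq(0.02, 0.6, by = 0.04), function(th)
    nrow(callSites(pu, min_stop_fraction = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("site calling is invariant to read input order", {
  fx <- small_sim(reads = 2000)
  r <- readFastqReads(fx$sim$libraries$fastq[3])
  set.seed(5)
  a1 <- suppressMessages(alignReads(r, fx$trnas))
  a2 <- suppressMessages(alignReads(r[sample(length(r))], fx$trnas))
  s1 <- callSites(buildPileup(a1, fx$trnas))
  s2 <- callSites(buildPileup(a2, fx$trnas))
  expect_equal(s1, s2)
})

test_that("replicate merging enforces support and averages scores", {
  s1 <- data.frame(trna_id = c("t1", "t2"), position = c(46L, 46L),
                   stop_fraction = c(0.5, 0.3), coverage = c(100, 80),
                   p_value = 1e-8, p_adj = 1e-7, score = c(0.5, 0.3),
                   library = "rep1")
  s2 <- data.frame(trna_id = "t1", position = 46L, stop_fraction = 0.7,
                   coverage = 120, p_value = 1e-8, p_adj = 1e-7, score = 0.7,
                   library = "rep2")
  m <- mergeReplicates(list(s1, s2), min_support = 2)
  expect_equal(m$trna_id, "t1")
  expect_equal(m$score, 0.6)
  expect_equal(m$n_replicates_supporting, 2L)
  # min_support = 1 is the union of replicate sets
  u <- mergeReplicates(list(s1, s2), min_support = 1)
  expect_setequal(paste(u$trna_id, u$position), c("t1 46", "t2 46"))
})

test_that("condition comparison performs exact set algebra with delta scores", {
  mk <- function(ids, pos, score, cond) data.frame(
    trna_id = ids, position = pos, stop_fraction = score, coverage = 100,
    score = score, n_replicates_supporting = 2L, condition = cond)
  a <- mk("t1", 46L, 0.05, "vector")
  b <- mk(c("t1", "t2"), c(46L, 46L), c(0.60, 0.4), "WDR4_OE")
  cmp <- compareConditions(a, b, "vector", "WDR4_OE")
  expect_equal(nrow(commonSites(cmp)), 1L)
  expect_equal(uniqueSites(cmp, "b")$trna_id, "t2")
  expect_equal(nrow(uniqueSites(cmp, "a")), 0L)
  d <- deltaScores(cmp)
  # hand arithmetic: log2(0.601 / 0.051)
  expect_equal(d$delta_score[d$trna_id == "t1"], log2(0.601 / 0.051),
               tolerance = 1e-6)
  # venn identity |sites(a)| = |common| + |unique_to_a|
  expect_equal(nrow(a), nrow(commonSites(cmp)) + nrow(uniqueSites(cmp, "a")))
  expect_equal(nrow(b), nrow(commonSites(cmp)) + nrow(uniqueSites(cmp, "b")))
  # identical sets -> both unique sets empty
  cmp2 <- compareConditions(b, b, "x", "y")
  expect_equal(nrow(uniqueSites(cmp2, "a")), 0L)
  expect_equal(nrow(uniqueSites(cmp2, "b")), 0L)
})

test_that("modified-tRNA roll-up lists each harbouring tRNA once", {
  mk <- function(ids, score, cond) data.frame(
    trna_id = ids, position = 46L, stop_fraction = score, coverage = 100,
    score = score, n_replicates_supporting = 2L, condition = cond)
  tab <- summarizeModifiedTrnas(list(
    vector = mk(c("t1", "t2"), 0.5, "vector"),
    WDR4_OE = mk(c("t1", "t3"), 0.6, "WDR4_OE")))
  expect_equal(nrow(tab), 3L)
  expect_true(tab$modified_vector[tab$trna_id == "t2"])
  expect_false(tab$modified_WDR4_OE[tab$trna_id == "t2"])
  empty <- summarizeModifiedTrnas(list(vector = mk("t0", 0.1, "vector")[0, ]))
  expect_equal(nrow(empty), 0L)
  expect_true("trna_id" %in% colnames(empty))
})

test_that("site BED export uses 0-based half-open single-base intervals", {
  trnas <- tiny_trnas()
  sites <- data.frame(trna_id = "tRNA-Cys-GCA-1-1", position = 46L,
                      stop_fraction = 0.6)
  bed <- tempfile(fileext = ".bed")
  writeSitesBed(sites, trnas, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(fields[2]), 45L)
  expect_equal(as.integer(fields[3]), 46L)
  expect_equal(as.integer(fields[5]), 600L)
})
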