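# Shared fixtures and independent oracles, built in code at test time.

# A tiny hand-written reference: two 76-nt tRNAs with a TGAACCN context
# planted at positions 43-49 (site 46) and CCA tails.
tiny_trnas <- function() {
  rnd76 <- function(seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE), collapse = "")
  }
  plant <- function(seq, ctx, at) {
    substr(seq, at, at + nchar(ctx) - 1L) <- ctx
    seq
  }
  s1 <- plant(rnd76(101), "TGAACCA", 43)
  s2 <- plant(rnd76(202), "TGAACCG", 43)
  s1 <- paste0(substr(s1, 1, 73), "CCA")
  s2 <- paste0(substr(s2, 1, 73), "CCA")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tRNA-Cys-GCA-1-1", s1, ">tRNA-Lys-CTT-1-1", s2), fa)
  suppressWarnings(suppressMessages(readTrnaFasta(fa)))
}

# Independent O(L * N) pileup recount: per position, loop over alignments.
brute_pileup <- function(alignments, L) {
  starts <- readthrough <- coverage <- integer(L)
  for (i in seq_len(L)) {
    for (r in seq_len(nrow(alignments))) {
      a <- alignments[r, ]
      if (a$start <= i && i <= a$end) coverage[i] <- coverage[i] + 1L
      if (a$start == i) starts[i] <- starts[i] + 1L
      if (a$start < i && i <= a$end) readthrough[i] <- readthrough[i] + 1L
    }
  }
  sf <- ifelse(starts + readthrough > 0, starts / (starts + readthrough), 0)
  list(starts = starts, coverage = coverage, readthrough = readthrough,
       stop_fraction = sf)
}

# Exact upper binomial tail P(X >= k | n, p) by direct pmf summation.
binom_tail_sum <- function(k, n, p) {
  if (k > n) return(0)
  sum(exp(lchoose(n, k:n) + (k:n) * log(p) + (n - (k:n)) * log1p(-p)))
}

# Brute-force ungapped scan of one read against a set of reference strings:
# every (ref, offset) placement with its mismatch count.
brute_scan <- function(read, refs) {
  rl <- nchar(read)
  rchars <- strsplit(read, "")[[1]]
  out <- do.call(rbind, lapply(names(refs), function(id) {
    s <- refs[[id]]
    offs <- seq_len(nchar(s) - rl + 1L)
    mm <- vapply(offs, function(o) {
      sum(strsplit(substr(s, o, o + rl - 1L), "")[[1]] != rchars)
    }, integer(1))
    data.frame(trna_id = id, start = offs, mismatches = mm)
  }))
  out
}

# Frame-0 decoded-codon counting oracle: explicit loop, no vectorised calls.
brute_count_codons <- function(cds, codon_set) {
  n <- nchar(cds)
  total <- 0L; decoded <- 0L
  for (i in seq(1, n, by = 3)) {
    cod <- substr(cds, i, i + 2)
    is_last <- i == n - 2
    if (is_last && cod %in% c("TAA", "TAG", "TGA")) break
    total <- total + 1L
    if (cod %in% codon_set) decoded <- decoded + 1L
  }
  list(total = total, decoded = decoded,
       frequency = if (total > 0) decoded / total else 0)
}

# Small two-condition TRAC-seq simulation reused by several tests.
small_sim <- function(reads = 4000, seed = 11) {
  cfg <- simConfig(n_trnas = 6, reads_per_library = reads,
                   m7g_positions = setNames(rep(46, 4), as.character(1:4)),
                   cleavage_efficiency = data.frame(
                     trna = as.character(c(1:2, 1:4)),
                     condition = rep(c("vector", "WDR4_OE"), c(2, 4)),
                     efficiency = 0.5),
                   rng_seed = seed)
  trnas <- simulateTrnaReference(cfg)
  sim <- suppressMessages(simulateTracseqReads(cfg, trnas, tempfile("sim")))
  list(cfg = cfg, trnas = trnas, sim = sim)
}

# Align + pileup + call every library of a simulation; returns per-condition
# merged site sets and per-library pileups.
run_calling <- function(fx, min_coverage = 50) {
  libs <- fx$sim$libraries
  pus <- list(); sites <- list()
  for (i in seq_len(nrow(libs))) {
    r <- readFastqReads(libs$fastq[i])
    aln <- suppressMessages(alignReads(r, fx$trnas))
    pus[[libs$library[i]]] <- buildPileup(aln, fx$trnas, library = libs$library[i])
    sites[[libs$library[i]]] <- callSites(pus[[libs$library[i]]],
                                          min_coverage = min_coverage)
  }
  by_cond <- lapply(split(seq_len(nrow(libs)), libs$condition), function(ix)
    mergeReplicates(sites[ix], condition = libs$condition[ix[1]]))
  list(pileups = pus, sites = sites, by_cond = by_cond, libs = libs)
}
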