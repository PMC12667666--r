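#' Configuration for the TRAC-seq library simulator
#'
#' Bundles and validates every knob of the synthetic TRAC-seq experiment.
#' The generative model: each sequenced molecule is a full-length mature tRNA;
#' if the tRNA carries a planted m7G site, the backbone is cleaved immediately
#' 3' of the site with the per-(tRNA, condition) cleavage efficiency (the
#' chemical reduction + aniline scission step); independently, every
#' internucleotide bond breaks with `background_break_rate`. All resulting
#' fragments of at least `min_fragment_len` nt enter the library (small-RNA
#' size selection), so a cleaved molecule contributes a downstream fragment
#' whose 5' end sits at site + 1 — the diagnostic signal — plus an upstream
#' fragment starting at position 1. Per-base substitution errors are applied
#' after fragmentation. FASTQ qualities are a constant 'I' (no stage consumes
#' qualities).
#'
#' Defaults describe a two-condition overexpression experiment: 20 tRNAs, m7G
#' at position 46 on tRNAs 1-14; tRNAs 1-9 cleaved at efficiency 0.5 in both
#' conditions and tRNAs 10-14 only in the second (`WDR4_OE`) condition; two
#' replicates of 50,000 reads per library; background breakage 0.002 per
#' bond; sequencing error 0.001 per base; a 7-nt `TGAACCN` context planted
#' centred on every site.
#'
#' @param n_trnas Number of tRNA references to simulate.
#' @param trna_length_range Length-2 integer vector, min/max tRNA length (nt).
#' @param m7g_positions Named integer vector of planted 1-based m7G positions;
#'   names are tRNA indices (`"1"`..`"n"`) or, after simulation, tRNA ids.
#' @param cleavage_efficiency data.frame with columns `trna` (index or id),
#'   `condition`, `efficiency` (probability of scission at the planted site);
#'   tRNA/condition pairs absent from the table have efficiency 0.
#' @param background_break_rate Per-bond background breakage probability.
#' @param seq_error_rate Per-base substitution error probability.
#' @param min_fragment_len Minimum fragment length kept (nt).
#' @param reads_per_library Fragments retained per library.
#' @param conditions Character vector of condition labels.
#' @param replicates_per_condition Libraries per condition.
#' @param motif_context 7-character IUPAC string planted centred on each site.
#' @param anticodons Optional explicit anticodons (5'->3' DNA) for the first
#'   `length(anticodons)` tRNAs; remaining tRNAs draw from the unused pool.
#' @param rng_seed Integer seed; all randomness derives from it.
#' @return A validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(n_trnas = 4, reads_per_library = 1000)
#' @export
simConfig <- function(n_trnas = 20L,
                      trna_length_range = c(70L, 90L),
                      m7g_positions = setNames(rep(46L, 14), as.character(1:14)),
                      cleavage_efficiency = data.frame(
                        trna = as.character(c(1:9, 1:14)),
                        condition = rep(c("vector", "WDR4_OE"), c(9L, 14L)),
                        efficiency = 0.5),
                      background_break_rate = 0.002,
                      seq_error_rate = 0.001,
                      min_fragment_len = 15L,
                      reads_per_library = 50000L,
                      conditions = c("vector", "WDR4_OE"),
                      replicates_per_condition = 2L,
                      motif_context = "TGAACCN",
                      anticodons = NULL,
                      rng_seed = 1L) {
  cfg <- list(n_trnas = as.integer(n_trnas),
              trna_length_range = as.integer(trna_length_range),
              m7g_positions = m7g_positions,
              cleavage_efficiency = cleavage_efficiency,
              background_break_rate = background_break_rate,
              seq_error_rate = seq_error_rate,
              min_fragment_len = as.integer(min_fragment_len),
              reads_per_library = as.integer(reads_per_library),
              conditions = as.character(conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              motif_context = toupper(motif_context),
              anticodons = anticodons,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$n_trnas < 1) validation_error("n_trnas must be >= 1")
  lr <- cfg$trna_length_range
  if (length(lr) != 2 || lr[1] > lr[2] || lr[1] < 60 || lr[2] > 120)
    validation_error("trna_length_range must be an increasing pair within [60, 120]")
  probs <- c(cfg$background_break_rate, cfg$seq_error_rate,
             cfg$cleavage_efficiency$efficiency)
  if (any(probs < 0 | probs > 1))
    validation_error("all probabilities must lie in [0, 1]")
  if (length(cfg$m7g_positions) && is.null(names(cfg$m7g_positions)))
    validation_error("m7g_positions must be named by tRNA index or id")
  if (length(cfg$m7g_positions) &&
      any(cfg$m7g_positions < 1 | cfg$m7g_positions > lr[2]))
    validation_error("m7g positions must lie within the tRNA length range")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", cfg$motif_context))
    validation_error("motif_context must be an IUPAC DNA string")
  if (nchar(cfg$motif_context) %% 2 != 1)
    validation_error("motif_context must have odd width (centred on the site)")
  if (!all(c("trna", "condition", "efficiency") %in%
             colnames(cfg$cleavage_efficiency)))
    validation_error("cleavage_efficiency needs columns trna, condition, efficiency")
  if (!all(cfg$cleavage_efficiency$condition %in% cfg$conditions))
    validation_error("cleavage_efficiency refers to unknown condition(s)")
  if (cfg$replicates_per_condition < 1)
    validation_error("replicates_per_condition must be >= 1")
  invisible(cfg)
}

## Sense-codon pool: anticodon + 3-letter amino-acid code for each of the 61
## coding codons, via the standard genetic code.
anticodon_pool <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  aa1 <- gc[sense]
  aa3 <- Biostrings::AMINO_ACID_CODE[aa1]
  data.frame(anticodon = revComp(sense), amino_acid = unname(aa3),
             codon = sense, stringsAsFactors = FALSE)
}

## Draw one concrete DNA string from an IUPAC pattern.
realize_iupac <- function(pattern) {
  letters <- strsplit(pattern, "")[[1]]
  paste(vapply(letters, function(ch) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

## Resolve m7g_positions names (indices or ids) against a TrnaSet.
resolve_site_ids <- function(keys, trnas) {
  ids <- trnaIds(trnas)
  if (all(keys %in% ids)) return(keys)
  idx <- suppressWarnings(as.integer(keys))
  if (any(is.na(idx)) || any(idx < 1 | idx > length(ids)))
    validation_error(paste0("cannot resolve tRNA key(s): ",
                            paste(keys[is.na(match(keys, ids))], collapse = ", ")))
  ids[idx]
}

#' Simulate a mature tRNA reference set
#'
#' Generates `n_trnas` random mature tRNA sequences with GtRNAdb-style names
#' (`tRNA-Cys-GCA-1-1`), the anticodon embedded at positions 34-36, a CCA
#' 3' tail, and — for every tRNA with a planted m7G position — a realisation
#' of `motif_context` planted centred on the site (for the default 7-mer,
#' window site-3 .. site+3, the same convention [extractWindows()] uses, so
#' motif round-trips are exact). Deterministic for a given `rng_seed`.
#'
#' @param cfg A [simConfig()].
#' @param fasta_out Optional path; when given the reference is also written
#'   as FASTA.
#' @return A [TrnaSet-class]; tRNA order corresponds to config indices.
#' @examples
#' trnas <- simulateTrnaReference(simConfig(n_trnas = 3))
#' @export
simulateTrnaReference <- function(cfg, fasta_out = NULL) {
  validateSimConfig(cfg)
  with_seed(derive_seed(cfg$rng_seed, 1L), {
    pool <- anticodon_pool()
    if (!is.null(cfg$anticodons)) {
      if (length(cfg$anticodons) > cfg$n_trnas)
        validation_error("more anticodons supplied than n_trnas")
      miss <- setdiff(cfg$anticodons, pool$anticodon)
      if (length(miss))
        validation_error(paste0("unknown anticodon(s): ", paste(miss, collapse = ", ")))
      fixed <- match(cfg$anticodons, pool$anticodon)
      rest <- setdiff(seq_len(nrow(pool)), fixed)
      extra <- if (cfg$n_trnas > length(fixed))
        sample(rest, cfg$n_trnas - length(fixed)) else integer(0)
      sel <- c(fixed, extra)
    } else {
      sel <- sample(nrow(pool), cfg$n_trnas,
                    replace = cfg$n_trnas > nrow(pool))
    }
    aa <- pool$amino_acid[sel]
    ac <- pool$anticodon[sel]
    lens <- sample_range(cfg$trna_length_range[1], cfg$trna_length_range[2],
                         cfg$n_trnas)
    w <- nchar(cfg$motif_context)
    half <- (w - 1L) %/% 2L
    seqs <- character(cfg$n_trnas)
    for (i in seq_len(cfg$n_trnas)) {
      s <- sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
      s[34:36] <- strsplit(ac[i], "")[[1]]
      s[(lens[i] - 2):lens[i]] <- c("C", "C", "A")
      seqs[i] <- paste(s, collapse = "")
    }
    ## plant motif contexts (keys are indices at this point)
    keys <- names(cfg$m7g_positions)
    for (k in seq_along(cfg$m7g_positions)) {
      i <- suppressWarnings(as.integer(keys[k]))
      if (is.na(i) || i < 1 || i > cfg$n_trnas)
        validation_error(sprintf("m7g_positions key '%s' is not a valid tRNA index",
                                 keys[k]))
      pos <- cfg$m7g_positions[[k]]
      if (pos > lens[i])
        validation_error(sprintf("m7G position %d exceeds tRNA %d length %d",
                                 pos, i, lens[i]))
      if (pos - half < 1 || pos + half > lens[i])
        validation_error(sprintf(
          "motif window around position %d does not fit inside tRNA %d (length %d)",
          pos, i, lens[i]))
      substr(seqs[i], pos - half, pos + half) <- realize_iupac(cfg$motif_context)
    }
    ## GtRNAdb-style ids; duplicate isoacceptors get incremented gene numbers
    base <- paste0("tRNA-", aa, "-", ac)
    copy <- stats::ave(seq_along(base), base, FUN = seq_along)
    ids <- paste0(base, "-", copy, "-1")
    trnas <- suppressWarnings(make_trna_set(ids, aa, ac, seqs))
    if (!is.null(fasta_out)) writeTrnaFasta(trnas, fasta_out)
    trnas
  })
}

#' Planted-site truth table for a simulated reference
#'
#' Expands the configured m7G positions and per-condition cleavage
#' efficiencies against a simulated reference into one row per
#' (site, condition) — the ground truth all downstream recovery tests compare
#' against. Conditions in which a site has no configured efficiency are
#' listed with efficiency 0.
#'
#' @param cfg A [simConfig()].
#' @param trnas The [TrnaSet-class] produced from `cfg`.
#' @return data.frame with columns `trna_id`, `position`, `condition`,
#'   `cleavage_efficiency`.
#' @export
simTruthTable <- function(cfg, trnas) {
  if (length(cfg$m7g_positions) == 0)
    return(data.frame(trna_id = character(0), position = integer(0),
                      condition = character(0), cleavage_efficiency = numeric(0)))
  site_ids <- resolve_site_ids(names(cfg$m7g_positions), trnas)
  eff <- cfg$cleavage_efficiency
  eff$trna_id <- resolve_site_ids(as.character(eff$trna), trnas)
  out <- expand.grid(i = seq_along(site_ids), condition = cfg$conditions,
                     stringsAsFactors = FALSE)
  out$trna_id <- site_ids[out$i]
  out$position <- as.integer(cfg$m7g_positions[out$i])
  m <- match(paste(out$trna_id, out$condition),
             paste(eff$trna_id, eff$condition))
  out$cleavage_efficiency <- ifelse(is.na(m), 0, eff$efficiency[m])
  out <- out[order(out$trna_id, out$position, out$condition),
             c("trna_id", "position", "condition", "cleavage_efficiency")]
  rownames(out) <- NULL
  out
}

## Simulate one library: returns data.frame(trna_idx, start, end) of fragments.
simulate_fragments <- function(n_reads, lens, site_pos, eff, bg, min_len) {
  frag_t <- integer(0); frag_s <- integer(0); frag_e <- integer(0)
  got <- 0L
  guard <- 0L
  while (got < n_reads) {
    guard <- guard + 1L
    if (guard > 50L) break  # pathological configs (everything filtered)
    nmol <- max(1000L, ceiling((n_reads - got) / 1.2))
    tidx <- sample.int(length(lens), nmol, replace = TRUE)
    L <- lens[tidx]
    s <- site_pos[tidx]                       # NA when unmodified
    cleaved <- !is.na(s) & rbinom(nmol, 1L, ifelse(is.na(s), 0, eff[tidx])) == 1L
    nbg <- rbinom(nmol, L - 1L, bg)
    plain <- nbg == 0L
    ## molecules without background cuts: closed form
    p_unc <- plain & !cleaved
    t1 <- tidx[p_unc]; s1 <- rep(1L, sum(p_unc)); e1 <- L[p_unc]
    p_cl <- plain & cleaved
    k <- sum(p_cl)
    t2 <- rep(tidx[p_cl], each = 2L)
    s2 <- e2 <- integer(2L * k)
    if (k) {  # interleave upstream [1, s] and downstream [s + 1, L] fragments
      s2[c(TRUE, FALSE)] <- 1L;       s2[c(FALSE, TRUE)] <- s[p_cl] + 1L
      e2[c(TRUE, FALSE)] <- s[p_cl];  e2[c(FALSE, TRUE)] <- L[p_cl]
    }
    ## molecules with background cuts: per-molecule fragmentation
    t3 <- integer(0); s3 <- integer(0); e3 <- integer(0); m3 <- integer(0)
    for (m in which(!plain)) {
      cuts <- sort(unique(c(if (cleaved[m]) s[m],
                            sample.int(L[m] - 1L, nbg[m]))))
      b <- c(0L, cuts, L[m])
      t3 <- c(t3, rep(tidx[m], length(b) - 1L))
      s3 <- c(s3, b[-length(b)] + 1L)
      e3 <- c(e3, b[-1])
      m3 <- c(m3, rep(m, length(b) - 1L))
    }
    ts <- c(t1, t2, t3); ss <- c(s1, s2, s3); es <- c(e1, e2, e3)
    ## restore molecule order so truncating to the requested library size
    ## drops whole trailing molecules, not a biased fragment class
    mol <- c(which(p_unc), rep(which(p_cl), each = 2L), m3)
    o <- order(mol)
    ts <- ts[o]; ss <- ss[o]; es <- es[o]
    keep <- (es - ss + 1L) >= min_len
    frag_t <- c(frag_t, ts[keep]); frag_s <- c(frag_s, ss[keep])
    frag_e <- c(frag_e, es[keep])
    got <- length(frag_t)
  }
  n <- min(n_reads, length(frag_t))
  data.frame(trna_idx = frag_t[seq_len(n)], start = frag_s[seq_len(n)],
             end = frag_e[seq_len(n)])
}

## Apply per-base substitution errors to a character vector of reads.
apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  nc <- nchar(seqs)
  tot <- sum(nc)
  nerr <- rbinom(1L, tot, rate)
  if (nerr == 0) return(seqs)
  idx <- sort(sample.int(tot, nerr))
  ends <- cumsum(nc)
  read_i <- findInterval(idx - 1L, ends) + 1L
  pos_i <- idx - c(0L, ends)[read_i]
  for (k in seq_len(nerr)) {
    old <- substr(seqs[read_i[k]], pos_i[k], pos_i[k])
    substr(seqs[read_i[k]], pos_i[k], pos_i[k]) <-
      sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  seqs
}

#' Simulate TRAC-seq libraries
#'
#' Generates one FASTQ per condition x replicate under the cleavage model of
#' [simConfig()], together with the planted-site truth table. Fragments
#' shorter than `min_fragment_len` are discarded; substitution errors are
#' applied after fragmentation; qualities are constant `'I'`. Each library
#' uses a seed derived deterministically from `rng_seed`, so reruns are
#' byte-identical.
#'
#' @param cfg A [simConfig()].
#' @param trnas A [TrnaSet-class] from [simulateTrnaReference()] (same config).
#' @param out_dir Directory for FASTQ and truth-table files (created).
#' @return A list: `libraries` (data.frame with `library`, `condition`,
#'   `replicate`, `fastq`), `truth` (see [simTruthTable()]), `truth_file`.
#' @examples
#' cfg <- simConfig(n_trnas = 2, reads_per_library = 200,
#'                  m7g_positions = c("1" = 46),
#'                  cleavage_efficiency = data.frame(
#'                    trna = "1", condition = "WDR4_OE", efficiency = 0.6))
#' trnas <- simulateTrnaReference(cfg)
#' sim <- simulateTracseqReads(cfg, trnas, tempfile("lib"))
#' @export
simulateTracseqReads <- function(cfg, trnas, out_dir) {
  validateSimConfig(cfg)
  if (length(trnas) == 0) validation_error("empty tRNA reference")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lens <- Biostrings::width(trnaSeqs(trnas))
  refs <- as.character(trnaSeqs(trnas))
  ids <- trnaIds(trnas)

  truth <- simTruthTable(cfg, trnas)
  site_pos <- rep(NA_integer_, length(trnas))
  if (nrow(truth)) {
    st <- unique(truth[, c("trna_id", "position")])
    site_pos[match(st$trna_id, ids)] <- st$position
    bad <- st$position > lens[match(st$trna_id, ids)]
    if (any(bad))
      validation_error("planted m7G position exceeds tRNA length")
  }

  libs <- expand.grid(replicate = seq_len(cfg$replicates_per_condition),
                      condition = cfg$conditions, stringsAsFactors = FALSE)
  libs$library <- sprintf("%s_rep%d", libs$condition, libs$replicate)
  libs$fastq <- file.path(out_dir, paste0(libs$library, ".fastq"))

  for (li in seq_len(nrow(libs))) {
    cond <- libs$condition[li]
    eff <- numeric(length(trnas))
    if (nrow(truth)) {
      tc <- truth[truth$condition == cond, ]
      eff[match(tc$trna_id, ids)] <- tc$cleavage_efficiency
    }
    with_seed(derive_seed(cfg$rng_seed, 100L + li), {
      if (cfg$reads_per_library == 0L) {
        warning(sprintf("library %s: zero reads requested, writing empty FASTQ",
                        libs$library[li]), call. = FALSE)
        file.create(libs$fastq[li])
      } else {
        fr <- simulate_fragments(cfg$reads_per_library, lens, site_pos, eff,
                                 cfg$background_break_rate, cfg$min_fragment_len)
        seqs <- substr(refs[fr$trna_idx], fr$start, fr$end)
        seqs <- apply_seq_errors(seqs, cfg$seq_error_rate)
        dss <- Biostrings::DNAStringSet(seqs)
        names(dss) <- sprintf("%s_read%06d", libs$library[li], seq_len(nrow(fr)))
        Biostrings::writeXStringSet(
          dss, libs$fastq[li], format = "fastq",
          qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(dss))))
        m7g_log("simulate", sprintf("library %s: wrote %d reads",
                                    libs$library[li], nrow(fr)))
      }
    })
  }
  truth_file <- file.path(out_dir, "truth_sites.tsv")
  write_tsv(truth, truth_file)
  list(libraries = libs[, c("library", "condition", "replicate", "fastq")],
       truth = truth, truth_file = truth_file)
}
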