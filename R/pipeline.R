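#' Default pipeline configuration
#'
#' A flat key-value list driving [runPipeline()]. The default is a
#' demonstration-scale fully synthetic experiment: 12 tRNAs of which 5 carry
#' m7G sites in both conditions and 2 (tRNA-Cys-GCA and tRNA-Lys-CTT, so the
#' downstream codon set is \{TGC, AAG\}) only under overexpression; 2
#' replicates of 8,000 reads per library; and a 600-gene TE experiment at
#' depth 2e5. Every value can be overridden via [readConfig()] or by
#' editing the list.
#'
#' @return Named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    ## TRAC-seq simulation (stage: simulate)
    simulate = TRUE,
    n_trnas = 12L,
    n_modified_both = 5L,
    n_modified_oe_only = 2L,
    m7g_position = 46L,
    cleavage_efficiency = 0.5,
    background_break_rate = 0.002,
    seq_error_rate = 0.001,
    reads_per_library = 8000L,
    replicates_per_condition = 2L,
    min_fragment_len = 15L,
    conditions = c("vector", "WDR4_OE"),
    motif_context = "TGAACCN",
    ## external inputs (used when simulate = FALSE)
    trna_fasta = "",
    sample_sheet = "",
    ## trim / align
    adapter = "",
    max_mismatches = 1L,
    discard_multi = FALSE,
    ## site calling
    min_coverage = 50L,
    min_stop_fraction = 0.10,
    alpha = 0.01,
    min_support = "all",
    ## motif
    motif_width = 7L,
    motif_offset = -3L,
    consensus_threshold = 0.8,
    ## translation efficiency
    te_simulate = TRUE,
    te_n_genes = 600L,
    te_n_replicates = 3L,
    te_depth = 2e5,
    te_dispersion = 0.02,
    te_frac_up = 0.05,
    te_frac_down = 0.10,
    te_shift_up = 2,
    te_shift_down = -2,
    rnc_counts = "",
    rna_counts = "",
    te_samples = "",
    cds_fasta = "",
    lfc_threshold = 1,
    p_threshold = 0.05,
    d0 = 4,
    min_cpm = 1,
    ## codon analysis
    decoding_mode = "strict"
  )
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are coerced
#' (numeric where possible, `true`/`false` to logical, comma-separated values
#' to vectors). Unknown keys are an error; missing keys take defaults from
#' [defaultConfig()].
#'
#' @param path Config file path.
#' @return A full configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) validation_error(sprintf("config not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- defaultConfig()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      validation_error(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg))
      validation_error(sprintf("unknown config key: '%s'", key))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    coerced <- suppressWarnings(as.numeric(parts))
    if (!any(is.na(coerced))) {
      cfg[[key]] <- coerced
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      cfg[[key]] <- tolower(parts) == "true"
    } else {
      cfg[[key]] <- parts
    }
  }
  cfg
}

validatePipelineConfig <- function(cfg) {
  miss <- setdiff(names(defaultConfig()), names(cfg))
  if (length(miss))
    validation_error(paste0("config missing key(s): ", paste(miss, collapse = ", ")))
  if (length(cfg$conditions) != 2)
    validation_error("exactly two conditions are required")
  if (!isTRUE(cfg$simulate)) {
    if (!nzchar(cfg$trna_fasta) || !file.exists(cfg$trna_fasta))
      validation_error("simulate = false but trna_fasta is missing")
    if (!nzchar(cfg$sample_sheet) || !file.exists(cfg$sample_sheet))
      validation_error("simulate = false but sample_sheet is missing")
  }
  if (!isTRUE(cfg$te_simulate)) {
    for (k in c("rnc_counts", "rna_counts", "te_samples", "cds_fasta"))
      if (!nzchar(cfg[[k]]) || !file.exists(cfg[[k]]))
        validation_error(sprintf("te_simulate = false but %s is missing", k))
  }
  if (!cfg$decoding_mode %in% c("strict", "wobble"))
    validation_error("decoding_mode must be 'strict' or 'wobble'")
  invisible(cfg)
}

## Expand pipeline config into a full simConfig. OE-only tRNAs come first and
## receive the Cys/Lys anticodons so the demo codon set is {TGC, AAG}.
pipeline_sim_config <- function(cfg) {
  n_oe <- cfg$n_modified_oe_only
  n_both <- cfg$n_modified_both
  if (n_oe + n_both > cfg$n_trnas)
    validation_error("n_modified_both + n_modified_oe_only exceeds n_trnas")
  anticodons <- head(c("GCA", "CTT"), n_oe)
  idx_oe <- seq_len(n_oe)
  idx_both <- seq_len(n_both) + n_oe
  eff <- rbind(
    data.frame(trna = rep(as.character(idx_both), 2L),
               condition = rep(cfg$conditions, each = n_both),
               efficiency = rep(cfg$cleavage_efficiency, 2L * n_both)),
    data.frame(trna = as.character(idx_oe),
               condition = rep(cfg$conditions[2], n_oe),
               efficiency = rep(cfg$cleavage_efficiency, n_oe)))
  simConfig(
    n_trnas = cfg$n_trnas,
    m7g_positions = setNames(rep(cfg$m7g_position, n_oe + n_both),
                             as.character(c(idx_oe, idx_both))),
    cleavage_efficiency = eff,
    background_break_rate = cfg$background_break_rate,
    seq_error_rate = cfg$seq_error_rate,
    min_fragment_len = cfg$min_fragment_len,
    reads_per_library = cfg$reads_per_library,
    conditions = cfg$conditions,
    replicates_per_condition = cfg$replicates_per_condition,
    motif_context = cfg$motif_context,
    anticodons = if (length(anticodons)) anticodons else NULL,
    rng_seed = cfg$seed)
}

#' Run the TRAC-seq analysis pipeline end to end
#'
#' Executes simulate (optional) -> trim -> align -> pileup -> call ->
#' merge -> compare -> motif -> translation efficiency -> codon analysis ->
#' report, writing every intermediate as plain text under `output_dir` and
#' recording a JSON run manifest (config snapshot, package version, derived
#' seeds, input digests, per-stage outputs/row counts and wall-clock).
#' All randomness derives from `config$seed`, so a rerun with the same
#' config reproduces every table byte-identically.
#'
#' @param config Configuration list (see [defaultConfig()], [readConfig()]).
#' @param output_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with `manifest` and `results` (the in-memory
#'   stage outputs: `trnas`, `truth`, `sites_by_condition`, `comparison`,
#'   `modified_trnas`, `motif`, `te_results`, `te_summary`, `codon_set`,
#'   `usage`, `group_comparison`, `report_file`).
#' @export
runPipeline <- function(config = defaultConfig(), output_dir) {
  validatePipelineConfig(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "m7Gtrac",
                   version = as.character(packageVersion("m7Gtrac")),
                   seed = config$seed,
                   config = config[order(names(config))],
                   stages = list())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- c(manifest$stages[[name]],
                                  list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    out
  }
  outfile <- function(...) file.path(output_dir, ...)
  record <- function(stage, path, rows = NA) {
    manifest$stages[[stage]]$outputs <<-
      c(manifest$stages[[stage]]$outputs,
        list(list(path = path, rows = if (is.na(rows)) NULL else rows)))
  }

  ## --- reference + reads -------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim <- t_stage("simulate", {
      scfg <- pipeline_sim_config(config)
      trnas <- simulateTrnaReference(scfg, fasta_out = outfile("trna_ref.fa"))
      reads <- simulateTracseqReads(scfg, trnas, outfile("reads"))
      list(trnas = trnas, libraries = reads$libraries, truth = reads$truth)
    })
    record("simulate", outfile("trna_ref.fa"))
    record("simulate", outfile("reads", "truth_sites.tsv"), nrow(sim$truth))
  } else {
    sim <- t_stage("load_inputs", {
      trnas <- readTrnaFasta(config$trna_fasta)
      libs <- read_tsv(config$sample_sheet)
      if (!all(c("library", "condition", "replicate", "fastq") %in% colnames(libs)))
        validation_error("sample_sheet needs columns library, condition, replicate, fastq")
      list(trnas = trnas, libraries = libs, truth = NULL)
    })
    manifest$input_digests <- as.list(tools::md5sum(
      c(config$trna_fasta, sim$libraries$fastq)))
  }
  results$trnas <- sim$trnas
  results$truth <- sim$truth

  ## --- per-library trim/align/pileup/call --------------------------------
  pileups <- list()
  site_sets <- list()
  for (li in seq_len(nrow(sim$libraries))) {
    lib <- sim$libraries$library[li]
    reads <- t_stage("trim", {
      r <- readFastqReads(sim$libraries$fastq[li])
      if (nzchar(config$adapter))
        r <- trimAdapter(r, config$adapter, config$min_fragment_len)
      r
    })
    aln <- t_stage("align",
                   alignReads(reads, sim$trnas,
                              max_mismatches = config$max_mismatches,
                              multi = if (isTRUE(config$discard_multi))
                                "discard" else "lexicographic"))
    pu <- t_stage("pileup", buildPileup(aln, sim$trnas, library = lib))
    writePileupTsv(pu, outfile(paste0("pileup_", lib, ".tsv")))
    record("pileup", outfile(paste0("pileup_", lib, ".tsv")))
    sites <- t_stage("call",
                     callSites(pu, min_coverage = config$min_coverage,
                               min_stop_fraction = config$min_stop_fraction,
                               alpha = config$alpha))
    writeSitesTsv(sites, outfile(paste0("sites_", lib, ".tsv")))
    record("call", outfile(paste0("sites_", lib, ".tsv")), nrow(sites))
    pileups[[lib]] <- pu
    site_sets[[lib]] <- sites
  }

  ## --- merge replicates, compare conditions ------------------------------
  conds <- config$conditions
  min_support <- if (identical(config$min_support, "all")) NULL else
    as.integer(config$min_support)
  by_cond <- t_stage("merge", {
    out <- list()
    for (cn in conds) {
      reps <- site_sets[sim$libraries$condition == cn]
      ms <- if (is.null(min_support)) length(reps) else min_support
      out[[cn]] <- mergeReplicates(reps, min_support = ms, condition = cn)
      writeSitesTsv(out[[cn]], outfile(paste0("sites_", cn, ".tsv")))
      record("merge", outfile(paste0("sites_", cn, ".tsv")), nrow(out[[cn]]))
    }
    out
  })
  results$sites_by_condition <- by_cond
  comparison <- t_stage("compare", compareConditions(
    by_cond[[conds[1]]], by_cond[[conds[2]]],
    condition_a = conds[1], condition_b = conds[2],
    pileups_a = pileups[sim$libraries$condition == conds[1]],
    pileups_b = pileups[sim$libraries$condition == conds[2]]))
  write_tsv(deltaScores(comparison), outfile("delta_scores.tsv"))
  record("compare", outfile("delta_scores.tsv"), nrow(deltaScores(comparison)))
  results$comparison <- comparison
  results$modified_trnas <- summarizeModifiedTrnas(by_cond)
  write_tsv(results$modified_trnas, outfile("modified_trnas.tsv"))
  record("compare", outfile("modified_trnas.tsv"), nrow(results$modified_trnas))
  writeSitesBed(rbind_sites(by_cond), sim$trnas, outfile("sites.bed"))

  ## --- motif --------------------------------------------------------------
  results$motif <- t_stage("motif", {
    all_sites <- unique(rbind_sites(by_cond)[, c("trna_id", "position")])
    if (nrow(all_sites) >= 5) {
      win <- extractWindows(all_sites, sim$trnas, width = config$motif_width,
                            offset = config$motif_offset)
      Biostrings::writeXStringSet(win, outfile("site_windows.fa"))
      if (length(win) >= 5) {
        mod <- buildMotif(win, consensus_threshold = config$consensus_threshold)
        writeMemeMotif(mod, outfile("motif.meme"))
        writePfmTsv(mod, outfile("motif_pfm.tsv"))
        record("motif", outfile("motif.meme"))
        mod
      } else NULL
    } else NULL
  })

  ## --- translation efficiency ---------------------------------------------
  te_in <- t_stage("te", {
    if (isTRUE(config$te_simulate)) {
      tcfg <- teSimConfig(n_genes = config$te_n_genes,
                          n_replicates = config$te_n_replicates,
                          library_depth = config$te_depth,
                          dispersion = config$te_dispersion,
                          frac_te_up = config$te_frac_up,
                          frac_te_down = config$te_frac_down,
                          shift_up = config$te_shift_up,
                          shift_down = config$te_shift_down,
                          rng_seed = config$seed)
      simulateTeCounts(tcfg, out_dir = outfile("te_input"))
    } else {
      list(te = readTeExperiment(config$rnc_counts, config$rna_counts,
                                 config$te_samples),
           cds = Biostrings::readDNAStringSet(config$cds_fasta),
           truth = NULL)
    }
  })
  te_conds <- unique(SummarizedExperiment::colData(te_in$te)$condition)
  te_res <- t_stage("te", differentialTe(
    computeTe(te_in$te), te_conds[1], te_conds[2],
    lfc = config$lfc_threshold, p = config$p_threshold,
    d0 = config$d0, min_cpm = config$min_cpm))
  writeTeTsv(te_res, outfile("te_results.tsv"))
  record("te", outfile("te_results.tsv"), nrow(te_res))
  results$te_results <- te_res
  results$te_truth <- te_in$truth
  results$te_summary <- classifyCounts(te_res)

  ## --- codon analysis ------------------------------------------------------
  cod <- t_stage("codons", {
    map <- buildDecodingMap(sim$trnas, mode = config$decoding_mode)
    codon_set <- if (nrow(uniqueSites(comparison, "b")) > 0)
      m7gCodonSetFromSites(comparison, sim$trnas, map) else character(0)
    usage <- countDecodedCodons(te_in$cds, codon_set)
    write_tsv(usage, outfile("codon_usage.tsv"))
    record("codons", outfile("codon_usage.tsv"), nrow(usage))
    grp <- compareTeGroups(usage, te_res)
    write_tsv(grp$groups, outfile("codon_groups.tsv"))
    record("codons", outfile("codon_groups.tsv"), nrow(grp$groups))
    list(codon_set = codon_set, usage = usage, group_comparison = grp)
  })
  results <- c(results, cod)

  ## --- report + manifest ---------------------------------------------------
  results$report_file <- outfile("report.txt")
  makeReport(results, results$report_file)
  manifest$outputs_exist <- all(vapply(
    list.files(output_dir, recursive = TRUE, full.names = TRUE),
    file.exists, logical(1)))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results))
}

rbind_sites <- function(by_cond) {
  out <- do.call(rbind, unname(by_cond))
  if (is.null(out)) empty_sites() else out
}

#' Write a plain-text pipeline summary report
#'
#' Covers the modified-tRNA table, common/unique site counts, motif
#' consensus, TE class counts and decoded-codon group medians. Degenerate
#' runs (no sites called) are reported rather than failing.
#'
#' @param results The `results` element returned by [runPipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
makeReport <- function(results, path) {
  ln <- c("m7G TRAC-seq pipeline summary", strrep("=", 31), "")
  cmp <- results$comparison
  if (!is.null(cmp)) {
    n_common <- nrow(commonSites(cmp))
    n_ua <- nrow(uniqueSites(cmp, "a"))
    n_ub <- nrow(uniqueSites(cmp, "b"))
    if (n_common + n_ua + n_ub == 0) {
      ln <- c(ln, "Sites: no sites called in either condition.")
    } else {
      ln <- c(ln, sprintf("Sites (venn): common %d | unique to %s %d | unique to %s %d",
                          n_common, cmp@condition_a, n_ua, cmp@condition_b, n_ub))
      ub <- uniqueSites(cmp, "b")
      ln <- c(ln, sprintf("Unique tRNA isodecoders in %s: %d", cmp@condition_b,
                          length(unique(ub$trna_id))))
    }
  }
  mt <- results$modified_trnas
  if (!is.null(mt))
    ln <- c(ln, sprintf("Modified tRNAs (any condition): %d", nrow(mt)))
  ln <- c(ln, if (!is.null(results$motif))
    sprintf("Motif consensus (%d windows): %s", results$motif@nseq,
            motifConsensus(results$motif))
    else "Motif: not built (fewer than 5 usable windows).")
  s <- results$te_summary
  if (!is.null(s))
    ln <- c(ln, sprintf("Differential TE: %d up, %d down, %d changed of %d tested",
                        s$n_up, s$n_down, s$n_total_changed,
                        nrow(results$te_results)))
  if (!is.null(results$codon_set))
    ln <- c(ln, sprintf("m7G-decoded codon set: %s",
                        if (length(results$codon_set))
                          paste(results$codon_set, collapse = ", ") else "(empty)"))
  g <- results$group_comparison
  if (!is.null(g)) {
    for (i in seq_len(nrow(g$groups)))
      ln <- c(ln, sprintf("  %-8s n=%4d  median decoded-codon freq %.4f",
                          g$groups$group[i], g$groups$n[i],
                          g$groups$median_freq[i]))
    for (i in seq_len(nrow(g$tests)))
      ln <- c(ln, sprintf("  rank-sum %s: p = %.3g", g$tests$comparison[i],
                          g$tests$p_value[i]))
  }
  writeLines(ln, path)
  invisible(path)
}
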