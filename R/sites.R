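#' Call m7G cleavage sites from pileup tracks
#'
#' A stop position j (3 <= j <= L) yields a candidate m7G site at j - 1 when
#' its coverage passes `min_coverage`. For each candidate a one-sided
#' binomial tail P(X >= starts_j | n = starts_j + readthrough_j,
#' p = background) is computed against a per-tRNA background — the median
#' stop fraction over positions 3..L with adequate coverage, floored at
#' 0.001 (or, in mock-normalised mode, the mock library's stop fraction at
#' the same position, floored identically). Benjamini-Hochberg correction is
#' applied across all tested positions of the library; a site is called when
#' additionally `stop_fraction >= min_stop_fraction` and the adjusted
#' p-value is below `alpha`. The per-site score ("m7G score") is the stop
#' fraction itself. Stop positions 1 and 2 are never callable: position-1
#' starts are confounded with intact 5' ends.
#'
#' @param pileup A [PileupSet-class] for one library.
#' @param min_coverage Minimum coverage at the stop position (default 50).
#' @param min_stop_fraction Minimum stop fraction (default 0.10).
#' @param alpha BH-adjusted significance level (default 0.01).
#' @param mock Optional [PileupSet-class] from a no-chemistry control
#'   library; its per-position stop fraction replaces the background.
#' @param background_floor Lower bound on the background rate (default 0.001).
#' @return data.frame of sites sorted by (trna_id, position) with columns
#'   `trna_id`, `position` (inferred m7G position, stop position - 1),
#'   `stop_fraction`, `coverage`, `p_value`, `p_adj`, `score`, `library`.
#' @export
callSites <- function(pileup, min_coverage = 50L, min_stop_fraction = 0.10,
                      alpha = 0.01, mock = NULL, background_floor = 0.001) {
  if (min_coverage < 1) validation_error("min_coverage must be >= 1")
  cand <- list()
  for (id in trackNames(pileup)) {
    tr <- pileupTrack(pileup, id)
    L <- nrow(tr)
    if (L < 3) next
    testable <- seq(3L, L)
    ok <- testable[tr$coverage[testable] >= min_coverage]
    if (length(ok) == 0) next
    if (is.null(mock)) {
      bg <- rep(max(median(tr$stop_fraction[ok]), background_floor), length(ok))
    } else {
      if (!id %in% trackNames(mock)) {
        bg <- rep(background_floor, length(ok))
      } else {
        mt <- pileupTrack(mock, id)
        bg <- pmax(mt$stop_fraction[ok], background_floor)
      }
    }
    n <- tr$starts[ok] + tr$readthrough[ok]
    p <- pbinom(tr$starts[ok] - 1L, n, bg, lower.tail = FALSE)
    cand[[id]] <- data.frame(
      trna_id = id, position = ok - 1L, stop_fraction = tr$stop_fraction[ok],
      coverage = tr$coverage[ok], p_value = p)
  }
  if (length(cand) == 0)
    return(empty_sites(pileup@library))
  all <- do.call(rbind, cand)
  all$p_adj <- p.adjust(all$p_value, method = "BH")
  called <- all[all$stop_fraction >= min_stop_fraction & all$p_adj < alpha, ,
                drop = FALSE]
  called$score <- called$stop_fraction
  called$library <- rep(pileup@library, nrow(called))
  called <- called[order(called$trna_id, called$position), , drop = FALSE]
  rownames(called) <- NULL
  called
}

empty_sites <- function(library = NA_character_) {
  data.frame(trna_id = character(0), position = integer(0),
             stop_fraction = numeric(0), coverage = integer(0),
             p_value = numeric(0), p_adj = numeric(0), score = numeric(0),
             library = character(0))
}

#' Merge per-replicate site calls into a condition-level set
#'
#' A site (keyed by trna_id, position) is kept when called in at least
#' `min_support` replicates (default: all of them). Stop fraction and score
#' are averaged over the supporting replicates.
#'
#' @param site_list List of per-replicate site data.frames from [callSites()].
#' @param min_support Minimum number of supporting replicates.
#' @param condition Optional condition label stored in the result.
#' @return data.frame with columns `trna_id`, `position`, `stop_fraction`,
#'   `coverage`, `score`, `n_replicates_supporting`, `condition`.
#' @export
mergeReplicates <- function(site_list, min_support = length(site_list),
                            condition = NA_character_) {
  if (length(site_list) < 1) validation_error("at least one replicate required")
  all <- do.call(rbind, site_list)
  if (is.null(all) || nrow(all) == 0) {
    out <- data.frame(trna_id = character(0), position = integer(0),
                      stop_fraction = numeric(0), coverage = numeric(0),
                      score = numeric(0), n_replicates_supporting = integer(0))
    out$condition <- character(0)
    return(out)
  }
  key <- paste(all$trna_id, all$position, sep = "@")
  agg <- lapply(split(all, key), function(d) {
    data.frame(trna_id = d$trna_id[1], position = d$position[1],
               stop_fraction = mean(d$stop_fraction),
               coverage = mean(d$coverage), score = mean(d$score),
               n_replicates_supporting = nrow(d))
  })
  out <- do.call(rbind, agg)
  out <- out[out$n_replicates_supporting >= min_support, , drop = FALSE]
  out$condition <- rep(condition, nrow(out))
  out <- out[order(out$trna_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Condition-level stop fraction at (trna_id, position): mean over replicate
## pileups; 0 when the position is uncovered everywhere.
condition_stop_fraction <- function(pileups, trna_id, position) {
  j <- position + 1L  # stop position
  vals <- vapply(pileups, function(p) {
    if (!trna_id %in% trackNames(p)) return(NA_real_)
    tr <- pileupTrack(p, trna_id)
    if (j > nrow(tr)) return(NA_real_)
    tr$stop_fraction[j]
  }, numeric(1))
  if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
}

#' Compare condition-level site sets
#'
#' Exact set algebra on (trna_id, position): sites common to both
#' conditions, unique to each, and a per-site effect
#' `delta_score = log2((s_b + eps)/(s_a + eps))` for every site present in
#' either set. For a site absent from one condition, that condition's score
#' is its stop fraction at the position (mean over replicate pileups when
#' supplied; 0 if uncovered).
#'
#' @param sites_a,sites_b Condition-level data.frames from [mergeReplicates()].
#' @param condition_a,condition_b Condition labels.
#' @param pileups_a,pileups_b Optional lists of replicate [PileupSet-class]
#'   objects used to look up stop fractions for absent sites.
#' @param eps Stabilising offset on the stop-fraction scale (default 0.001).
#' @return A [SiteComparison-class].
#' @export
compareConditions <- function(sites_a, sites_b,
                              condition_a = "a", condition_b = "b",
                              pileups_a = NULL, pileups_b = NULL, eps = 0.001) {
  key_a <- paste(sites_a$trna_id, sites_a$position, sep = "@")
  key_b <- paste(sites_b$trna_id, sites_b$position, sep = "@")
  common <- sites_b[key_b %in% key_a, , drop = FALSE]
  uniq_a <- sites_a[!key_a %in% key_b, , drop = FALSE]
  uniq_b <- sites_b[!key_b %in% key_a, , drop = FALSE]
  u <- unique(rbind(sites_a[, c("trna_id", "position")],
                    sites_b[, c("trna_id", "position")]))
  if (nrow(u)) {
    u <- u[order(u$trna_id, u$position), , drop = FALSE]
    ku <- paste(u$trna_id, u$position, sep = "@")
    sa <- sites_a$score[match(ku, key_a)]
    sb <- sites_b$score[match(ku, key_b)]
    for (i in which(is.na(sa)))
      sa[i] <- if (!is.null(pileups_a))
        condition_stop_fraction(pileups_a, u$trna_id[i], u$position[i]) else 0
    for (i in which(is.na(sb)))
      sb[i] <- if (!is.null(pileups_b))
        condition_stop_fraction(pileups_b, u$trna_id[i], u$position[i]) else 0
    delta <- data.frame(trna_id = u$trna_id, position = u$position,
                        score_a = sa, score_b = sb,
                        delta_score = log2((sb + eps) / (sa + eps)))
  } else {
    delta <- data.frame(trna_id = character(0), position = integer(0),
                        score_a = numeric(0), score_b = numeric(0),
                        delta_score = numeric(0))
  }
  rownames(common) <- rownames(uniq_a) <- rownames(uniq_b) <- rownames(delta) <- NULL
  new("SiteComparison", condition_a = condition_a, condition_b = condition_b,
      common = common, unique_to_a = uniq_a, unique_to_b = uniq_b,
      delta = delta)
}

#' Per-tRNA roll-up of modified tRNAs
#'
#' One row per tRNA harbouring at least one called site in any condition:
#' per-condition any-site indicator and maximum score, total site count, and
#' an overall indicator. Empty site sets yield an empty table with the full
#' header.
#'
#' @param site_sets Named list of condition-level site data.frames
#'   (names = condition labels).
#' @return data.frame sorted by tRNA id.
#' @export
summarizeModifiedTrnas <- function(site_sets) {
  conds <- names(site_sets)
  if (is.null(conds) || any(!nzchar(conds)))
    validation_error("site_sets must be a named list (condition labels)")
  all_ids <- sort(unique(unlist(lapply(site_sets, function(s) s$trna_id))))
  out <- data.frame(trna_id = all_ids, stringsAsFactors = FALSE)
  for (cn in conds) {
    s <- site_sets[[cn]]
    out[[paste0("modified_", cn)]] <-
      all_ids %in% s$trna_id
    out[[paste0("max_score_", cn)]] <- vapply(all_ids, function(id) {
      v <- s$score[s$trna_id == id]
      if (length(v)) max(v) else NA_real_
    }, numeric(1))
  }
  out$n_sites_total <- vapply(all_ids, function(id)
    sum(vapply(site_sets, function(s) sum(s$trna_id == id), numeric(1))),
    numeric(1))
  out$modified_any <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Write called sites as TSV
#'
#' @param sites data.frame from [callSites()] or [mergeReplicates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSitesTsv <- function(sites, path) write_tsv(sites, path)

#' Write called sites as BED
#'
#' 0-based half-open single-base intervals `[position - 1, position)` on the
#' tRNA "chromosome", name = trna_id, score = round(1000 x stop_fraction).
#'
#' @param sites data.frame of sites.
#' @param trnas The [TrnaSet-class] the sites live on (sequence lengths).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
writeSitesBed <- function(sites, trnas, path) {
  if (nrow(sites) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = sites$trna_id,
    ranges = IRanges::IRanges(start = sites$position, width = 1L),
    name = sites$trna_id,
    score = pmin(1000L, as.integer(round(1000 * sites$stop_fraction))),
    seqlengths = setNames(Biostrings::width(trnaSeqs(trnas)), trnaIds(trnas)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
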