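#' Allele frequencies in a query line at given positions
#'
#' Looks up raw read counts for one line at a set of marker positions
#' and reports the alternate-allele frequency, independent of any
#' genotype call (the re-pileup surface: the counts table covers variant
#' and non-variant sites alike). Positions absent from the table, or
#' covered by zero reads, get a missing frequency.
#'
#' @param positions data.frame with `chrom`, `pos` (the markers, e.g.
#'   homozygous SNPs of the mutant pool).
#' @param counts_table allele-count data.frame covering the query line.
#' @param query_line line identifier to extract.
#' @return data.frame with `chrom`, `pos`, `query_line`, `freq`,
#'   `depth`; a `n_missing` attribute counts rows without coverage.
#' @export
allele_frequencies_at <- function(positions, counts_table, query_line) {
  ct <- counts_table[counts_table$line_id == query_line, , drop = FALSE]
  idx <- match(site_key(positions), site_key(ct))
  alt_n <- ct$alt_fwd[idx] + ct$alt_rev[idx]
  ref_n <- ct$ref_fwd[idx] + ct$ref_rev[idx]
  depth <- alt_n + ref_n
  freq <- ifelse(!is.na(depth) & depth > 0, alt_n / depth, NA_real_)
  out <- data.frame(chrom = positions$chrom, pos = positions$pos,
                    query_line = query_line, freq = freq,
                    depth = ifelse(is.na(depth), 0L, depth),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  n_missing <- sum(is.na(freq))
  if (n_missing > 0) {
    warning(n_missing, " marker position(s) lack coverage in line ",
            query_line)
  }
  attr(out, "n_missing") <- n_missing
  out
}

#' Detect the linked interval from wild-type sibling frequencies
#'
#' Scans the markers (sorted by position) for maximal runs of at least
#' `min_interval_markers` consecutive markers whose frequency in the
#' wild-type sibling is at most `wt_max_freq`: the only genomic segment
#' where the wild-type segregant carries reference alleles at positions
#' homozygous in the mutant pool is the segment linked to the causal
#' locus. Markers with missing frequency are uninformative and dropped
#' before run detection. Intervals are ranked by supporting-marker count
#' (descending), then by lower mean frequency, then by coordinate.
#'
#' @param hormigas rows from [allele_frequencies_at()] for the wild-type
#'   sibling at mutant-homozygous markers.
#' @param params a [pipeline_params()].
#' @return data.frame of intervals (`chrom`, `start`, `end`,
#'   `n_supporting_markers`, `mean_wt_freq`), best first; zero rows when
#'   no qualifying run exists.
#' @export
detect_linked_interval <- function(hormigas, params = pipeline_params()) {
  rows <- hormigas[!is.na(hormigas$freq), , drop = FALSE]
  rows <- rows[order(rows$chrom, rows$pos), , drop = FALSE]
  out <- list()
  for (cc in unique(rows$chrom)) {
    r <- rows[rows$chrom == cc, , drop = FALSE]
    low <- r$freq <= params$wt_max_freq
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (j in which(rl$values & rl$lengths >= params$min_interval_markers)) {
      run <- starts[j]:ends[j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = r$pos[starts[j]], end = r$pos[ends[j]],
        n_supporting_markers = length(run),
        mean_wt_freq = mean(r$freq[run]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_supporting_markers = integer(),
                      mean_wt_freq = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$n_supporting_markers, out$mean_wt_freq,
                   out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

role_line <- function(manifest, role) {
  ln <- manifest$line_id[manifest$role == role]
  if (!length(ln)) stop("role ", role, " missing from manifest")
  ln[1]
}

#' Pedigree-consistency filter for causal candidates
#'
#' A causal candidate for a recessive trait mapped in a selfing family
#' must be homozygous alternate in the mutant pool (frequency at least
#' `hom_alt_min_freq`), at intermediate frequency in the heterozygous
#' sibling (inside `het_freq_window`) and absent from the wild-type
#' sibling pool (frequency at most `wt_max_freq`). Each role's evidence
#' is judged only when it rests on at least `min_informative_depth`
#' reads; weaker coverage yields the verdict `insufficient_coverage`
#' rather than exclusion — too few reads cannot rule a candidate out.
#'
#' @param candidates data.frame with `chrom`, `pos` (plus any carried
#'   columns).
#' @param counts_table allele-count table covering all roles.
#' @param manifest pedigree manifest (must name a `mutant_pool`, a
#'   `het_sibling` and a `wt_sibling` line).
#' @param params a [pipeline_params()].
#' @return `candidates` with added columns `mutant_freq`, `het_freq`,
#'   `wt_freq`, their depths, `verdict` (`pass`, `fail`,
#'   `insufficient_coverage`) and `reason`.
#' @export
pedigree_consistency_filter <- function(candidates, counts_table,
                                        manifest,
                                        params = pipeline_params()) {
  mut_ln <- role_line(manifest, "mutant_pool")
  het_ln <- role_line(manifest, "het_sibling")
  wt_ln <- role_line(manifest, "wt_sibling")
  if (!nrow(candidates)) {
    for (cc in c("mutant_freq", "het_freq", "wt_freq", "mutant_depth",
                 "het_depth", "wt_depth")) candidates[[cc]] <- numeric(0)
    candidates$verdict <- character(0)
    candidates$reason <- character(0)
    return(candidates)
  }
  fq <- function(ln) suppressWarnings(
    allele_frequencies_at(candidates, counts_table, ln))
  fm <- fq(mut_ln); fh <- fq(het_ln); fw <- fq(wt_ln)
  ord_key <- site_key(candidates)
  m <- match(ord_key, site_key(fm))
  candidates$mutant_freq <- fm$freq[m]
  candidates$mutant_depth <- fm$depth[m]
  m <- match(ord_key, site_key(fh))
  candidates$het_freq <- fh$freq[m]
  candidates$het_depth <- fh$depth[m]
  m <- match(ord_key, site_key(fw))
  candidates$wt_freq <- fw$freq[m]
  candidates$wt_depth <- fw$depth[m]

  judge <- function(freq, depth, ok) {
    status <- rep("pass", length(freq))
    status[!ok] <- "fail"
    status[is.na(freq) | depth < params$min_informative_depth] <-
      "insufficient"
    status
  }
  s_mut <- judge(candidates$mutant_freq, candidates$mutant_depth,
                 !is.na(candidates$mutant_freq) &
                   candidates$mutant_freq >= params$hom_alt_min_freq)
  s_het <- judge(candidates$het_freq, candidates$het_depth,
                 !is.na(candidates$het_freq) &
                   candidates$het_freq >= params$het_freq_window[1] &
                   candidates$het_freq <= params$het_freq_window[2])
  s_wt <- judge(candidates$wt_freq, candidates$wt_depth,
                !is.na(candidates$wt_freq) &
                  candidates$wt_freq <= params$wt_max_freq)
  any_fail <- s_mut == "fail" | s_het == "fail" | s_wt == "fail"
  any_insuf <- s_mut == "insufficient" | s_het == "insufficient" |
    s_wt == "insufficient"
  candidates$verdict <- ifelse(any_fail, "fail",
                               ifelse(any_insuf,
                                      "insufficient_coverage", "pass"))
  reason <- character(nrow(candidates))
  lab <- function(s, who) ifelse(s == "pass", "",
                                 paste0(who, ":", s))
  reason <- trimws(paste(lab(s_mut, "mutant"), lab(s_het, "het_sib"),
                         lab(s_wt, "wt_sib")))
  reason <- gsub(" +", ";", reason)
  candidates$reason <- ifelse(candidates$verdict == "pass", "",
                              reason)
  candidates
}

#' Rank causal candidates through the sequential mapping ledger
#'
#' Applies, in order: restriction to protein-coding-changing SNPs,
#' the pedigree-consistency filter, and restriction to the top linked
#' interval, recording survivor counts at each step. Candidates judged
#' `insufficient_coverage` are retained (flagged) — weak coverage does
#' not exclude. When no interval was detected, the interval step is
#' skipped and flagged in the ledger.
#'
#' @param candidates data.frame of candidate SNPs (`chrom`, `pos`,
#'   `ref`, `alt`) — the mutant pool's cascade survivors after lineage
#'   subtraction and removal of positions called in sibling lines.
#' @param effects effect annotations for `candidates` (from
#'   [classify_snps()], same row order).
#' @param counts_table allele-count table covering all roles.
#' @param manifest pedigree manifest.
#' @param intervals interval table from [detect_linked_interval()].
#' @param params a [pipeline_params()].
#' @return list with `ledger` (data.frame `step`, `n`, `note`),
#'   `candidates` (annotated, verdicts for the coding subset) and
#'   `final` (the final candidate list).
#' @export
rank_candidates <- function(candidates, effects, counts_table, manifest,
                            intervals, params = pipeline_params()) {
  stopifnot(nrow(candidates) == nrow(effects))
  coding_cats <- c("missense", "nonsense", "stop_loss", "splice_site",
                   "start_loss")
  ann <- cbind(candidates,
               effects[, c("category", "impact", "gene_id",
                           "codon_change", "aa_change")])
  coding <- ann[ann$category %in% coding_cats, , drop = FALSE]
  judged <- pedigree_consistency_filter(coding, counts_table, manifest,
                                        params)
  consistent <- judged[judged$verdict != "fail", , drop = FALSE]
  have_interval <- !is.null(intervals) && nrow(intervals) > 0
  if (have_interval) {
    top <- intervals[1, ]
    in_iv <- consistent$chrom == top$chrom &
      consistent$pos >= top$start & consistent$pos <= top$end
    final <- consistent[in_iv, , drop = FALSE]
    iv_note <- sprintf("top interval %s:%d-%d (%d markers)", top$chrom,
                       top$start, top$end, top$n_supporting_markers)
    iv_n <- nrow(final)
  } else {
    final <- consistent
    iv_note <- "no linked interval detected; step skipped"
    iv_n <- NA_integer_
  }
  ledger <- data.frame(
    step = c("candidate_snps", "coding_changing",
             "pedigree_consistent", "in_mapping_interval"),
    n = c(nrow(candidates), nrow(coding), nrow(consistent), iv_n),
    note = c("", "", sprintf("%d flagged insufficient_coverage",
                             sum(judged$verdict ==
                                   "insufficient_coverage")), iv_note),
    stringsAsFactors = FALSE)
  rownames(final) <- NULL
  list(ledger = ledger, candidates = judged, final = final)
}
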