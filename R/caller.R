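#' Genotype likelihoods under a binomial read model
#'
#' For a site with `alt` alternate reads out of `depth`, computes
#' log-likelihoods of the three diploid genotypes with per-read
#' alternate probabilities `e/3` (homozygous reference: the alternate is
#' seen only by error), `1/2` (heterozygous) and `1 - e` (homozygous
#' alternate).
#'
#' @param alt_count,depth integer read counts.
#' @param e per-base error rate, in (0, 0.5).
#' @return matrix of log-likelihoods with columns `hom_ref`, `het`,
#'   `hom_alt`.
#' @export
genotype_likelihoods <- function(alt_count, depth, e) {
  if (e <= 0 || e >= 0.5) stop("e must lie in (0, 0.5)")
  cbind(hom_ref = stats::dbinom(alt_count, depth, e / 3, log = TRUE),
        het = stats::dbinom(alt_count, depth, 0.5, log = TRUE),
        hom_alt = stats::dbinom(alt_count, depth, 1 - e, log = TRUE))
}

#' Call genotypes from an allele-count table
#'
#' A simplified consensus caller standing in for a full pileup-based
#' likelihood caller: each position is genotyped by maximum likelihood
#' under the binomial read model of [genotype_likelihoods()] with a
#' uniform genotype prior. The reported quality is the Phred-scaled
#' posterior probability that the site is non-variant (homozygous
#' reference), capped at 255. Ties in the likelihood maximum are broken
#' in favour of homozygous reference (fewer false variants). Sites with
#' zero depth are `no_call` with quality 0.
#'
#' `call_all()` processes a whole table (one line), returning calls
#' sorted by (chrom, pos); rows whose genotype is `hom_ref` or `no_call`
#' are retained in the output so allele-frequency queries can reuse it,
#' but carry `is_variant = FALSE`.
#'
#' @param counts allele-count data.frame (see [read_allele_counts()]);
#'   for `call_site()`, a single row.
#' @param e per-base error rate.
#' @return calls data.frame with the columns of
#'   [read_variant_calls()] plus `is_variant`.
#' @export
call_all <- function(counts, e = 0.001) {
  if (!nrow(counts)) {
    out <- empty_calls()
    out$is_variant <- logical(0)
    return(out)
  }
  if (anyDuplicated(counts[, c("line_id", "chrom", "pos")])) {
    dup <- counts[duplicated(counts[, c("line_id", "chrom", "pos")]), ]
    stop("duplicate (line, site) rows in allele-count table, e.g. ",
         dup$line_id[1], " ", dup$chrom[1], ":", dup$pos[1])
  }
  alt_n <- counts$alt_fwd + counts$alt_rev
  ref_n <- counts$ref_fwd + counts$ref_rev
  depth <- alt_n + ref_n
  gt <- rep("no_call", nrow(counts))
  qual <- rep(0, nrow(counts))
  pos_depth <- depth > 0
  if (any(pos_depth)) {
    ll <- genotype_likelihoods(alt_n[pos_depth], depth[pos_depth], e)
    # argmax with ties to hom_ref: column order encodes the preference
    pick <- max.col(ll, ties.method = "first")
    gt[pos_depth] <- colnames(ll)[pick]
    m <- apply(ll, 1, max)
    post_hom_ref <- exp(ll[, "hom_ref"] - m) /
      rowSums(exp(ll - m))
    qual[pos_depth] <- pmin(255, -10 * log10(pmax(post_hom_ref,
                                                  1e-26)))
  }
  out <- data.frame(
    chrom = counts$chrom, pos = counts$pos, ref = counts$ref,
    alt = counts$alt, qual = qual, depth = depth,
    ref_fwd = counts$ref_fwd, ref_rev = counts$ref_rev,
    alt_fwd = counts$alt_fwd, alt_rev = counts$alt_rev,
    rms_mapq = if ("rms_mapq" %in% names(counts)) counts$rms_mapq else
      NA_real_,
    genotype = gt, dist_to_gap = NA_integer_,
    is_variant = gt %in% c("het", "hom_alt"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname call_all
#' @export
call_site <- function(counts, e = 0.001) {
  stopifnot(nrow(counts) == 1)
  call_all(counts, e)
}

#' Variant records only
#'
#' Convenience filter: keeps the `het`/`hom_alt` rows of a call table
#' (the records a variant caller would emit).
#'
#' @param calls calls data.frame from [call_all()].
#' @return subset of `calls`.
#' @export
variant_calls <- function(calls) {
  keep <- calls$genotype %in% c("het", "hom_alt")
  out <- calls[keep, setdiff(names(calls), "is_variant"), drop = FALSE]
  rownames(out) <- NULL
  out
}
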