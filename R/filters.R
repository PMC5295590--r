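#' Sequential SNP quality filters
#'
#' The individual stages of the quality cascade applied to each line's
#' raw variant calls. Every threshold is inclusive on the retained side.
#'
#' * `filter_depth()` keeps calls with
#'   `min_depth <= depth <= max_depth`; the upper bound removes calls of
#'   repetitive origin, the lower bound removes singleton-read calls.
#' * `filter_rms_mapq()` keeps calls whose root-mean-square mapping
#'   quality is at least `min_rms`; records lacking the value pass with
#'   a warning.
#' * `filter_gap_proximity()` removes calls within `window` bases of any
#'   indel/gap position on the same chromosome.
#' * `filter_biallelic()` removes multi-allelic records and any position
#'   represented by records with conflicting alternate alleles.
#' * `filter_hom_qual()` keeps homozygous-alternate calls with quality
#'   at least `min_qual`.
#' * `filter_strand_and_purity()` keeps calls with no reference-base
#'   reads and at least one alternate read on each strand.
#' * `filter_ems_spectrum()` keeps G->A and C->T changes (the EMS
#'   mutation spectrum, read on the reference strand).
#'
#' @param calls calls data.frame (see [read_variant_calls()]).
#' @param min_depth,max_depth,min_rms,window,min_qual thresholds; the
#'   defaults match [pipeline_params()].
#' @param indel_sites data.frame with `chrom`, `pos` of gap evidence.
#' @param params a [pipeline_params()] (for
#'   `filter_strand_and_purity()`'s handling of records without strand
#'   counts).
#' @return the retained subset of `calls`, row order preserved.
#' @name filter_cascade
NULL

#' @rdname filter_cascade
#' @export
filter_depth <- function(calls, min_depth = 2, max_depth = 100) {
  keep <- !is.na(calls$depth) & calls$depth >= min_depth &
    calls$depth <= max_depth
  calls[keep, , drop = FALSE]
}

#' @rdname filter_cascade
#' @export
filter_rms_mapq <- function(calls, min_rms = 10) {
  missing <- is.na(calls$rms_mapq)
  if (any(missing)) {
    warning(sum(missing), " record(s) lack rms_mapq; passing them")
  }
  calls[missing | calls$rms_mapq >= min_rms, , drop = FALSE]
}

#' @rdname filter_cascade
#' @export
filter_gap_proximity <- function(calls, indel_sites, window = 3) {
  if (is.null(indel_sites) || !nrow(indel_sites) || !nrow(calls)) {
    return(calls)
  }
  near <- rep(FALSE, nrow(calls))
  for (cc in unique(indel_sites$chrom)) {
    sel <- calls$chrom == cc
    if (!any(sel)) next
    ip <- sort(indel_sites$pos[indel_sites$chrom == cc])
    # distance to nearest indel position
    idx <- findInterval(calls$pos[sel], ip)
    d_lo <- ifelse(idx >= 1, calls$pos[sel] - ip[pmax(idx, 1)], Inf)
    d_hi <- ifelse(idx < length(ip), ip[pmin(idx + 1, length(ip))] -
                     calls$pos[sel], Inf)
    near[sel] <- pmin(d_lo, d_hi) <= window
  }
  calls[!near, , drop = FALSE]
}

#' @rdname filter_cascade
#' @export
filter_biallelic <- function(calls) {
  multi <- grepl(",", calls$alt, fixed = TRUE)
  key <- paste(calls$chrom, calls$pos)
  conflicted <- vapply(split(calls$alt, key),
                       function(a) length(unique(a)) > 1, logical(1))
  keep <- !multi & !conflicted[key]
  calls[keep, , drop = FALSE]
}

#' @rdname filter_cascade
#' @export
filter_hom_qual <- function(calls, min_qual = 20) {
  keep <- calls$genotype == "hom_alt" & !is.na(calls$qual) &
    calls$qual >= min_qual
  calls[keep, , drop = FALSE]
}

#' @rdname filter_cascade
#' @export
filter_strand_and_purity <- function(calls, params = pipeline_params()) {
  no_strand <- is.na(calls$ref_fwd) | is.na(calls$ref_rev) |
    is.na(calls$alt_fwd) | is.na(calls$alt_rev)
  if (any(no_strand) && !params$strict_strand_missing) {
    warning(sum(no_strand), " record(s) lack strand-resolved counts; ",
            "passing them (strict_strand_missing = FALSE)")
  }
  pure <- !params$require_zero_ref_reads |
    (calls$ref_fwd + calls$ref_rev == 0)
  both <- !params$require_both_strands |
    (calls$alt_fwd >= 1 & calls$alt_rev >= 1)
  ok <- ifelse(no_strand, !params$strict_strand_missing, pure & both)
  calls[ok, , drop = FALSE]
}

#' @rdname filter_cascade
#' @export
filter_ems_spectrum <- function(calls) {
  keep <- (calls$ref == "G" & calls$alt == "A") |
    (calls$ref == "C" & calls$alt == "T")
  calls[keep, , drop = FALSE]
}

#' Run the full quality-filter cascade with survivor accounting
#'
#' Applies, in order: the depth window, the RMS mapping-quality floor
#' and the gap-proximity filter (reported jointly as one stage), then
#' the biallelic restriction, the homozygous/quality filter, the
#' purity-and-strand filter, and finally the EMS-spectrum filter. The
#' report counts survivors at the five canonical accounting stages
#' (`Initial`, `Q10 No Repeat`, `Q20 Homozygous`, `No Reference Calls`,
#' `G/A, C/T`); the biallelic step is applied between the second and
#' third stage and its effect is absorbed into the third count.
#'
#' @param calls one line's variant calls.
#' @param params a [pipeline_params()].
#' @param indel_sites data.frame of gap positions (`chrom`, `pos`), or
#'   `NULL`.
#' @param line_id optional label stored in the report.
#' @return list with `survivors` (calls data.frame) and `report`
#'   (data.frame of `stage`, `survivors`).
#' @export
run_cascade <- function(calls, params = pipeline_params(),
                        indel_sites = NULL, line_id = NA_character_) {
  s0 <- calls
  s1 <- filter_gap_proximity(
    filter_rms_mapq(
      filter_depth(s0, params$min_depth, params$max_depth),
      params$min_rms_mapq),
    indel_sites, params$gap_window)
  s2 <- filter_hom_qual(filter_biallelic(s1), params$min_hom_qual)
  s3 <- filter_strand_and_purity(s2, params)
  s4 <- if (params$ems_spectrum_only) filter_ems_spectrum(s3) else s3
  report <- data.frame(
    stage = c("Initial", "Q10 No Repeat", "Q20 Homozygous",
              "No Reference Calls", "G/A, C/T"),
    survivors = c(nrow(s0), nrow(s1), nrow(s2), nrow(s3), nrow(s4)),
    stringsAsFactors = FALSE)
  report$line_id <- line_id
  list(survivors = s4, report = report)
}

#' Aggregate per-line filter reports into study-wide totals
#'
#' Sums survivor counts across lines per stage and reports each total as
#' a percentage of the initial call count, together with the
#' stage-to-stage drop expressed as a percentage of the initial count
#' (the accounting used in the study-wide narrative: e.g. "discarding
#' low-quality SNPs reduced the total by 59%").
#'
#' @param reports list of report data.frames from [run_cascade()] (or
#'   data.frames with `stage` and `survivors` columns).
#' @return data.frame with `stage`, `total`, `pct_of_initial`,
#'   `pct_drop_of_initial` (integer percentages, rounded half up).
#' @export
cascade_totals <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  stages <- reports[[1]]$stage
  for (r in reports) {
    if (!identical(r$stage, stages)) {
      stop("all reports must share the same stage sequence")
    }
  }
  total <- Reduce(`+`, lapply(reports, `[[`, "survivors"))
  initial <- total[1]
  drop <- c(NA, total[-length(total)] - total[-1])
  data.frame(
    stage = stages, total = total,
    pct_of_initial = round_half_up(100 * total / initial, 0),
    pct_drop_of_initial = round_half_up(100 * drop / initial, 0),
    stringsAsFactors = FALSE)
}

# round half away from zero (printed-table convention, unlike round())
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
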