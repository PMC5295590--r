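site_key <- function(x) paste(x$chrom, x$pos)

#' Positions shared between two SNP sets
#'
#' Matching is by genomic position only (chromosome + coordinate),
#' deliberately allele-agnostic: an error-prone position can surface
#' different alternate alleles in different lines and must still be
#' recognized as shared.
#'
#' @param set_a,set_b data.frames with `chrom` and `pos` columns.
#' @return data.frame of the shared positions (`chrom`, `pos`), sorted.
#' @export
shared_positions <- function(set_a, set_b) {
  ka <- unique(site_key(set_a))
  kb <- unique(site_key(set_b))
  keep <- ka %in% kb
  out <- unique(set_a[match(ka[keep], site_key(set_a)),
                      c("chrom", "pos"), drop = FALSE])
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract SNP positions found in other mutagenesis lineages
#'
#' Removes from the target line's SNP set every position that appears in
#' any line belonging to a different lineage. SNPs shared only within
#' the target's own lineage are retained — those are the cosegregation
#' signal, not error candidates. This is the cross-pedigree
#' false-positive subtraction: positions called in independently
#' mutagenized material cannot be EMS-induced in the target and far more
#' likely mark systematically error-prone positions.
#'
#' @param target_line line identifier present in `manifest`.
#' @param manifest pedigree manifest.
#' @param all_sets named list (by `line_id`) of SNP data.frames.
#' @return the target's lineage-unique subset.
#' @export
subtract_other_lineages <- function(target_line, manifest, all_sets) {
  if (!target_line %in% manifest$line_id) {
    stop("line ", target_line, " absent from manifest")
  }
  lineage <- manifest$lineage_id[manifest$line_id == target_line]
  others <- manifest$line_id[manifest$lineage_id != lineage]
  target <- all_sets[[target_line]]
  if (is.null(target)) stop("no SNP set supplied for ", target_line)
  other_keys <- unique(unlist(lapply(all_sets[intersect(others,
                                                        names(all_sets))],
                                     site_key)))
  out <- target[!site_key(target) %in% other_keys, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-set Venn region counts
#'
#' Counts genomic positions in each of the seven exclusive regions of a
#' three-set Venn diagram (position-level, allele-agnostic).
#'
#' @param sets named list of exactly three SNP data.frames.
#' @return data.frame with `region` and `count`; counts sum to the size
#'   of the position union.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) == 3)
  nm <- names(sets)
  if (is.null(nm)) nm <- c("A", "B", "C")
  keys <- lapply(sets, function(s) unique(site_key(s)))
  u <- unique(unlist(keys))
  inA <- u %in% keys[[1]]; inB <- u %in% keys[[2]]; inC <- u %in% keys[[3]]
  region <- c(paste(nm[1], "only"), paste(nm[2], "only"),
              paste(nm[3], "only"),
              paste(nm[1], "&", nm[2]), paste(nm[1], "&", nm[3]),
              paste(nm[2], "&", nm[3]),
              paste(nm, collapse = " & "))
  count <- c(sum(inA & !inB & !inC), sum(!inA & inB & !inC),
             sum(!inA & !inB & inC), sum(inA & inB & !inC),
             sum(inA & !inB & inC), sum(!inA & inB & inC),
             sum(inA & inB & inC))
  data.frame(region = region, count = count, stringsAsFactors = FALSE)
}

#' Fraction of a SNP set matching the EMS mutation spectrum
#'
#' @param snp_set data.frame with `ref` and `alt` columns.
#' @return fraction of records that are G->A or C->T on the reference
#'   strand, in \[0, 1\]; `NA` for an empty set (0/0 undefined).
#' @export
spectrum_fraction <- function(snp_set) {
  if (!nrow(snp_set)) return(NA_real_)
  mean((snp_set$ref == "G" & snp_set$alt == "A") |
         (snp_set$ref == "C" & snp_set$alt == "T"))
}

#' Percent-unique with printed-table rounding
#'
#' @param unique_n,total_n counts.
#' @return `100 * unique_n / total_n` rounded half-up to one decimal;
#'   `NA` when `total_n` is zero.
#' @export
unique_percent <- function(unique_n, total_n) {
  ifelse(total_n == 0, NA_real_,
         round_half_up(100 * unique_n / total_n, 1))
}

#' Per-line summary of lineage-unique SNPs
#'
#' For each line: the total SNP count, the count unique to its lineage
#' (absent from every other lineage), and the percent unique — computed
#' genome-wide and restricted to coding sequence — plus a `Total` row of
#' column sums. This is the biological-replication accounting that
#' quantifies how many high-quality calls are reproducible
#' false positives.
#'
#' @param manifest pedigree manifest.
#' @param all_sets named list (by `line_id`) of SNP data.frames with
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models list of [gene_model()] used as the coding mask
#'   (CDS exons only); `NULL` skips the coding columns.
#' @return data.frame with columns `line_id`, `total`, `unique`,
#'   `pct_unique` and (with a coding mask) `coding_total`,
#'   `coding_unique`, `coding_pct_unique`.
#' @export
unique_summary <- function(manifest, all_sets, gene_models = NULL) {
  lines <- manifest$line_id[manifest$line_id %in% names(all_sets)]
  rows <- lapply(lines, function(ln) {
    s <- all_sets[[ln]]
    u <- subtract_other_lineages(ln, manifest, all_sets)
    row <- data.frame(line_id = ln, total = nrow(s), unique = nrow(u),
                      stringsAsFactors = FALSE)
    if (!is.null(gene_models)) {
      sc <- s[in_coding(s, gene_models), , drop = FALSE]
      uc <- u[in_coding(u, gene_models), , drop = FALSE]
      row$coding_total <- nrow(sc)
      row$coding_unique <- nrow(uc)
    }
    row
  })
  out <- do.call(rbind, rows)
  totals <- data.frame(line_id = "Total", total = sum(out$total),
                       unique = sum(out$unique),
                       stringsAsFactors = FALSE)
  if (!is.null(gene_models)) {
    totals$coding_total <- sum(out$coding_total)
    totals$coding_unique <- sum(out$coding_unique)
  }
  out <- rbind(out, totals)
  out$pct_unique <- unique_percent(out$unique, out$total)
  if (!is.null(gene_models)) {
    out$coding_pct_unique <- unique_percent(out$coding_unique,
                                            out$coding_total)
    out <- out[, c("line_id", "total", "unique", "pct_unique",
                   "coding_total", "coding_unique",
                   "coding_pct_unique")]
  }
  out
}

#' Which positions fall inside coding sequence
#'
#' @param x data.frame with `chrom`, `pos`.
#' @param gene_models list of [gene_model()].
#' @return logical vector, `TRUE` where the position lies in a CDS exon.
#' @export
in_coding <- function(x, gene_models) {
  if (!nrow(x)) return(logical(0))
  if (!length(gene_models)) return(rep(FALSE, nrow(x)))
  ex <- do.call(rbind, lapply(gene_models, function(gm) {
    data.frame(chrom = gm$chrom, start = gm$cds_exons[, "start"],
               end = gm$cds_exons[, "end"], stringsAsFactors = FALSE)
  }))
  q <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, x$pos))
  s <- GenomicRanges::GRanges(ex$chrom,
                              IRanges::IRanges(ex$start, ex$end))
  IRanges::overlapsAny(q, s)
}
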