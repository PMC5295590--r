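#' The default VCF annotation dialect
#'
#' Names the INFO keys that carry total depth, RMS mapping quality, the
#' 4-integer strand-resolved allelic depths (ref-forward, ref-reverse,
#' alt-forward, alt-reverse) and the distance to the nearest gap. The
#' keys are configurable because upstream callers differ in how they
#' annotate strand-resolved support.
#'
#' @param depth,mapq,strand_counts,gap INFO keys.
#' @param strict if `TRUE`, a record missing a required annotation is an
#'   error; if `FALSE` the field is marked unavailable (`NA`).
#' @return a list describing the dialect.
#' @export
vcf_dialect <- function(depth = "DP", mapq = "MQ", strand_counts = "DP4",
                        gap = "GD", strict = FALSE) {
  list(depth = depth, mapq = mapq, strand_counts = strand_counts,
       gap = gap, strict = strict)
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), depth = integer(),
             ref_fwd = integer(), ref_rev = integer(),
             alt_fwd = integer(), alt_rev = integer(),
             rms_mapq = numeric(), genotype = character(),
             dist_to_gap = integer(), stringsAsFactors = FALSE)
}

GT_CODE <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
             no_call = "./.")

#' Read variant calls from a VCF file
#'
#' Returns one row per record in a calls data.frame with columns `chrom`,
#' `pos` (1-based), `ref`, `alt` (comma-joined when multi-allelic),
#' `qual`, `depth`, `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`,
#' `rms_mapq`, `genotype` (`hom_ref`/`het`/`hom_alt`/`no_call`) and
#' `dist_to_gap` (`NA` = no gap evidence nearby). Strand counts are taken
#' from the dialect's strand-count INFO key when present, otherwise
#' marked unavailable (or an error under a strict dialect).
#'
#' @param path path to a VCF 4.x file.
#' @param dialect a [vcf_dialect()].
#' @return calls data.frame, sorted by (chrom, pos).
#' @export
read_variant_calls <- function(path, dialect = vcf_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#"))
  if (length(body)) {
    nf <- vapply(strsplit(raw[body], "\t", fixed = TRUE), length,
                 integer(1))
    posf <- vapply(strsplit(raw[body], "\t", fixed = TRUE),
                   function(x) if (length(x) >= 2) x[2] else "",
                   character(1))
    bad <- nf < 8 | !grepl("^[0-9]+$", posf)
    if (any(bad)) {
      stop("malformed VCF record at line ", body[bad][1], " of ", path)
    }
  } else {
    return(empty_calls())
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  info1 <- function(key, numeric = TRUE) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) x <- rep(NA_character_, n)
    if (numeric) suppressWarnings(as.numeric(x)) else x
  }
  dp <- info1(dialect$depth)
  mq <- info1(dialect$mapq)
  gd <- info1(dialect$gap)
  dp4 <- info1(dialect$strand_counts, numeric = FALSE)
  if (dialect$strict && (anyNA(dp) || anyNA(mq) || anyNA(dp4))) {
    stop("record missing required annotation (",
         paste(c(dialect$depth, dialect$mapq,
                 dialect$strand_counts)[c(anyNA(dp), anyNA(mq),
                                          anyNA(dp4))],
               collapse = ", "), ") under strict dialect")
  }
  sc <- matrix(NA_integer_, n, 4)
  have <- !is.na(dp4)
  if (any(have)) {
    parts <- strsplit(dp4[have], ",", fixed = TRUE)
    okp <- vapply(parts, length, integer(1)) == 4
    if (!all(okp)) stop("strand-count field must have 4 comma-separated ",
                        "integers")
    sc[have, ] <- t(vapply(parts, function(p) as.integer(p), integer(4)))
  }
  gt_raw <- if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    vcfR::extract.gt(v, element = "GT")[, 1]
  } else rep(NA_character_, n)
  gt <- names(GT_CODE)[match(gt_raw, GT_CODE)]
  gt[is.na(gt)] <- "no_call"
  out <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    depth = as.integer(dp),
    ref_fwd = sc[, 1], ref_rev = sc[, 2],
    alt_fwd = sc[, 3], alt_rev = sc[, 4],
    rms_mapq = mq, genotype = gt, dist_to_gap = as.integer(gd),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write variant calls to a VCF file
#'
#' Inverse of [read_variant_calls()]: emits a VCF 4.2 file carrying
#' depth, RMS mapping quality, strand-resolved allelic depths and gap
#' distance in INFO, and the genotype as a single-sample GT column.
#'
#' @param calls calls data.frame (see [read_variant_calls()]).
#' @param path output path.
#' @param sample_id name for the single genotype column.
#' @param dialect a [vcf_dialect()] naming the INFO keys to write.
#' @export
write_variant_calls <- function(calls, path, sample_id = "sample",
                                dialect = vcf_dialect()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=evilmap",
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Total read depth\">",
            dialect$depth),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"RMS mapping quality\">",
            dialect$mapq),
    sprintf("##INFO=<ID=%s,Number=4,Type=Integer,Description=\"Strand-resolved allelic depths: ref-fwd,ref-rev,alt-fwd,alt-rev\">",
            dialect$strand_counts),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Distance in bases to nearest gap evidence\">",
            dialect$gap),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  ), con)
  if (nrow(calls)) {
    ord <- order(calls$chrom, calls$pos)
    calls <- calls[ord, , drop = FALSE]
    info <- paste0(
      dialect$depth, "=", calls$depth, ";",
      dialect$mapq, "=", format_num(calls$rms_mapq))
    have_sc <- !is.na(calls$ref_fwd)
    info[have_sc] <- paste0(
      info[have_sc], ";", dialect$strand_counts, "=",
      calls$ref_fwd[have_sc], ",", calls$ref_rev[have_sc], ",",
      calls$alt_fwd[have_sc], ",", calls$alt_rev[have_sc])
    have_gap <- !is.na(calls$dist_to_gap)
    info[have_gap] <- paste0(info[have_gap], ";", dialect$gap, "=",
                             calls$dist_to_gap[have_gap])
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s\tGT\t%s",
                       calls$chrom, calls$pos, calls$ref, calls$alt,
                       format_num(calls$qual), info,
                       GT_CODE[calls$genotype]), con)
  }
  invisible(path)
}

# plain decimal formatting (no scientific notation) for VCF fields
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "." else format(round(v, 4), scientific = FALSE,
                                  trim = TRUE)
  }, character(1))
  out
}
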