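#' Construct a gene model
#'
#' A gene model is a stranded CDS structure used for codon-level effect
#' classification: a genomic span plus an ordered list of CDS exons.
#' Exons are stored 5'->3' on the coding strand, so for minus-strand
#' genes the first exon is the one with the highest genomic coordinate.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param cds_exons two-column matrix (`start`, `end`, 1-based inclusive)
#'   in 5'->3' coding order.
#' @param description free-text functional description.
#' @return list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_exons,
                       description = "") {
  stopifnot(is.character(gene_id), nzchar(gene_id),
            strand %in% c("+", "-"))
  cds_exons <- matrix(as.integer(cds_exons), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  if (any(cds_exons[, "end"] < cds_exons[, "start"])) {
    stop("gene ", gene_id, ": exon end < start")
  }
  genomic <- cds_exons[order(cds_exons[, "start"]), , drop = FALSE]
  if (nrow(genomic) > 1 &&
      any(genomic[-1, "start"] <= genomic[-nrow(genomic), "end"])) {
    stop("gene ", gene_id, ": overlapping CDS exons")
  }
  # enforce coding-strand order regardless of input order
  ord <- order(cds_exons[, "start"], decreasing = (strand == "-"))
  cds_exons <- cds_exons[ord, , drop = FALSE]
  len <- sum(cds_exons[, "end"] - cds_exons[, "start"] + 1L)
  translatable <- len %% 3L == 0L
  if (!translatable) {
    warning("gene ", gene_id, ": CDS length ", len,
            " not divisible by 3; flagged untranslatable")
  }
  structure(list(
    gene_id = gene_id, chrom = chrom,
    start = min(cds_exons[, "start"]), end = max(cds_exons[, "end"]),
    strand = strand, cds_exons = cds_exons, cds_length = len,
    translatable = translatable, description = description
  ), class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features and groups CDS exons per gene, ordered
#' 5'->3' on the coding strand. Genes whose total CDS length is not a
#' multiple of three are kept but flagged untranslatable (with a
#' warning); a CDS feature without a resolvable parent is an error.
#'
#' @param path path to a GFF3 file.
#' @return list of [gene_model()] objects, named by `gene_id`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  is_mrna <- type %in% c("mRNA", "transcript")
  is_cds <- type == "CDS"
  mrna_parent <- stats::setNames(parents[is_mrna], ids[is_mrna])
  gene_desc <- if ("description" %in% names(md)) {
    stats::setNames(as.character(md$description)[is_gene], ids[is_gene])
  } else stats::setNames(rep("", sum(is_gene)), ids[is_gene])

  cds_idx <- which(is_cds)
  if (!length(cds_idx)) return(list())
  cds_parent <- parents[cds_idx]
  if (anyNA(cds_parent)) stop("orphan CDS feature (no Parent attribute)")
  # resolve CDS parent: may point at an mRNA or directly at a gene
  gene_of <- ifelse(cds_parent %in% names(mrna_parent),
                    mrna_parent[cds_parent], cds_parent)
  known_genes <- ids[is_gene]
  if (length(known_genes) && !all(gene_of %in% known_genes)) {
    stop("orphan CDS feature: parent ",
         gene_of[!gene_of %in% known_genes][1], " is not a gene")
  }
  out <- lapply(split(cds_idx, gene_of), function(ii) {
    gene_model(
      gene_id = unique(gene_of[match(ii, cds_idx)]),
      chrom = as.character(GenomicRanges::seqnames(gr))[ii[1]],
      strand = as.character(GenomicRanges::strand(gr))[ii[1]],
      cds_exons = cbind(start = GenomicRanges::start(gr)[ii],
                        end = GenomicRanges::end(gr)[ii]),
      description = if (!is.na(gene_desc[unique(gene_of[match(ii, cds_idx)])]))
        gene_desc[[unique(gene_of[match(ii, cds_idx)])]] else ""
    )
  })
  out[order(names(out))]
}

#' Write gene models to GFF3
#'
#' Emits one gene, one mRNA and the CDS features (in genomic order, with
#' phase) per gene model.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in models) {
    gid <- gm$gene_id
    desc <- if (nzchar(gm$description)) {
      paste0(";description=", gm$description)
    } else ""
    writeLines(sprintf("%s\tevilmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       gm$chrom, gm$start, gm$end, gm$strand, gid, desc),
               con)
    mid <- paste0(gid, ".1")
    writeLines(sprintf("%s\tevilmap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       gm$chrom, gm$start, gm$end, gm$strand, mid, gid),
               con)
    ex <- gm$cds_exons  # coding order
    before <- c(0L, cumsum(ex[, "end"] - ex[, "start"] + 1L))
    phase <- (3L - before[seq_len(nrow(ex))] %% 3L) %% 3L
    genomic_ord <- order(ex[, "start"])
    for (i in genomic_ord) {
      writeLines(sprintf(
        "%s\tevilmap\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
        gm$chrom, ex[i, "start"], ex[i, "end"], gm$strand, phase[i],
        mid, mid), con)
    }
  }
  invisible(path)
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates the CDS exons 5'->3' on the coding strand
#' (reverse-complementing minus-strand genes).
#'
#' @param gm a [gene_model()].
#' @param genome named character vector of chromosome sequences.
#' @return the CDS as a single uppercase string.
#' @export
gene_cds_seq <- function(gm, genome) {
  chromseq <- genome[[gm$chrom]]
  ex <- gm$cds_exons[order(gm$cds_exons[, "start"]), , drop = FALSE]
  pieces <- substring(chromseq, ex[, "start"], ex[, "end"])
  s <- paste(pieces, collapse = "")
  if (gm$strand == "-") s <- revcomp(s)
  s
}

#' Reverse-complement a DNA string
#' @param s DNA string (A/C/G/T/N).
#' @return reverse complement, same case.
#' @export
revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}
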