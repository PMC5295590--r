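IMPACT_OF <- c(intergenic = "MODIFIER", intronic = "MODIFIER",
               synonymous = "LOW", missense = "MODERATE",
               nonsense = "HIGH", stop_loss = "HIGH",
               splice_site = "HIGH", start_loss = "HIGH")

aa_label <- function(aa) ifelse(aa == "*", "stop", aa)

#' Classify the coding effect of SNPs
#'
#' Locates each SNP against the CDS exons of the gene models and
#' classifies it as `intergenic`, `intronic`, `splice_site` (within 2
#' intronic bases of an internal exon boundary), `synonymous`,
#' `missense`, `nonsense` (stop gained), `stop_loss` or `start_loss`
#' (initiator ATG destroyed), translating reference and alternate
#' codons with the standard genetic code and complementing alleles for
#' minus-strand genes. Impact follows the conventional mapping:
#' protein-changing substitutions are MODERATE, truncations and
#' start/splice disruptions HIGH, synonymous changes LOW, non-coding
#' MODIFIER.
#'
#' The codon-change string shows the reference and alternate codons on
#' the coding strand with the mutated base uppercase (`Cag/Tag`); the
#' amino-acid change is `<ref><codon number><alt>` with `stop` for a
#' termination codon (`Q225stop`).
#'
#' @param snps data.frame with `chrom`, `pos`, `ref`, `alt` (biallelic).
#' @param gene_models list of [gene_model()].
#' @param genome named character vector of chromosome sequences.
#' @return data.frame with `category`, `impact`, `gene_id`,
#'   `codon_change`, `aa_change`, one row per SNP.
#' @export
classify_snps <- function(snps, gene_models, genome) {
  n <- nrow(snps)
  out <- data.frame(category = rep("intergenic", n),
                    impact = rep("MODIFIER", n),
                    gene_id = rep("none", n),
                    codon_change = rep("", n), aa_change = rep("", n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  ref_obs <- base_at(genome, snps$chrom, snps$pos)
  bad <- ref_obs != snps$ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop("reference mismatch at ", snps$chrom[i], ":", snps$pos[i],
         " (genome has ", ref_obs[i], ", record says ", snps$ref[i],
         ")")
  }
  if (!length(gene_models)) return(out)

  spans <- GenomicRanges::GRanges(
    vapply(gene_models, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(gene_models, `[[`, numeric(1), "start"),
                     vapply(gene_models, `[[`, numeric(1), "end")))
  q <- GenomicRanges::GRanges(snps$chrom,
                              IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(q, spans, select = "first")

  for (i in which(!is.na(hits))) {
    gm <- gene_models[[hits[i]]]
    res <- classify_one(snps$pos[i], snps$alt[i], gm, genome)
    out$category[i] <- res$category
    out$impact[i] <- IMPACT_OF[[res$category]]
    out$gene_id[i] <- if (res$category %in% c("intergenic")) "none" else
      gm$gene_id
    out$codon_change[i] <- res$codon_change
    out$aa_change[i] <- res$aa_change
  }
  out
}

# classify one SNP known to fall inside the span of gene model gm
classify_one <- function(pos, alt, gm, genome) {
  none <- list(category = "intronic", codon_change = "", aa_change = "")
  ex <- gm$cds_exons[order(gm$cds_exons[, "start"]), , drop = FALSE]
  in_exon <- pos >= ex[, "start"] & pos <= ex[, "end"]
  if (!any(in_exon)) {
    # splice site: first 2 intronic bases flanking an internal boundary
    if (nrow(ex) > 1) {
      splice_pos <- c(outer(ex[-nrow(ex), "end"], 1:2, `+`),
                      outer(ex[-1, "start"], 1:2, `-`))
      if (pos %in% splice_pos) {
        return(list(category = "splice_site", codon_change = "",
                    aa_change = ""))
      }
    }
    return(none)
  }
  if (!gm$translatable) {
    warning("gene ", gm$gene_id, " is untranslatable; SNP at ", pos,
            " reported as intronic")
    return(none)
  }
  pos_asc <- unlist(Map(seq.int, ex[, "start"], ex[, "end"]))
  pos_coding <- if (gm$strand == "+") pos_asc else rev(pos_asc)
  cds_idx <- match(pos, pos_coding)
  cds <- gene_cds_seq(gm, genome)
  codon_i <- (cds_idx - 1L) %/% 3L + 1L
  codon_p <- (cds_idx - 1L) %% 3L + 1L
  ref_codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
  alt_coding <- if (gm$strand == "+") alt else chartr("ACGT", "TGCA",
                                                      alt)
  alt_codon <- ref_codon
  substr(alt_codon, codon_p, codon_p) <- alt_coding
  aa_ref <- unname(Biostrings::GENETIC_CODE[ref_codon])
  aa_alt <- unname(Biostrings::GENETIC_CODE[alt_codon])
  cc_ref <- tolower(ref_codon); cc_alt <- tolower(alt_codon)
  substr(cc_ref, codon_p, codon_p) <- substr(ref_codon, codon_p,
                                             codon_p)
  substr(cc_alt, codon_p, codon_p) <- substr(alt_codon, codon_p,
                                             codon_p)
  codon_change <- paste0(cc_ref, "/", cc_alt)
  aa_change <- paste0(aa_label(aa_ref), codon_i, aa_label(aa_alt))
  category <- if (codon_i == 1L && ref_codon == "ATG" &&
                  alt_codon != "ATG") {
    "start_loss"
  } else if (aa_ref != "*" && aa_alt == "*") {
    "nonsense"
  } else if (aa_ref == "*" && aa_alt != "*") {
    "stop_loss"
  } else if (aa_ref == aa_alt) {
    "synonymous"
  } else {
    "missense"
  }
  list(category = category, codon_change = codon_change,
       aa_change = aa_change)
}

#' Tabulate effect classes
#'
#' Counts SNPs per effect category and totals the protein-altering
#' classes (missense, nonsense, stop loss, splice site, start loss).
#'
#' @param effects data.frame from [classify_snps()] (only `category` is
#'   used).
#' @return named list with `counts` (named integer vector over all
#'   categories) and `protein_altering` (integer total).
#' @export
summarize_effects <- function(effects) {
  cats <- names(IMPACT_OF)
  counts <- vapply(cats, function(cc) sum(effects$category == cc),
                   integer(1))
  list(counts = counts,
       protein_altering = protein_altering_total(counts))
}

#' @rdname summarize_effects
#' @param counts named vector of per-category counts (names among the
#'   effect categories).
#' @export
protein_altering_total <- function(counts) {
  keep <- intersect(names(counts), c("missense", "nonsense",
                                     "stop_loss", "splice_site",
                                     "start_loss"))
  as.integer(sum(counts[keep]))
}

#' Expected EMS mutation load in coding sequence
#'
#' The mutational target that matters for phenotype is the genome's
#' protein-coding capacity: with `coding_bp` bases of coding sequence
#' and a per-bp mutation rate, the expected number of genic mutations
#' per line is their product, and the expected number of potentially
#' causative nonsynonymous mutations is that times one minus the
#' synonymous fraction (about one third of EMS alleles are synonymous).
#'
#' @param coding_bp protein-coding genome span in bp.
#' @param per_bp_rate induced mutations per bp.
#' @param synonymous_fraction fraction of coding changes that are
#'   synonymous.
#' @return list with `genic` and `nonsynonymous` expected counts.
#' @export
expected_mutation_load <- function(coding_bp, per_bp_rate,
                                   synonymous_fraction = 1 / 3) {
  stopifnot(coding_bp > 0, per_bp_rate >= 0, per_bp_rate < 1,
            synonymous_fraction >= 0, synonymous_fraction <= 1)
  genic <- coding_bp * per_bp_rate
  list(genic = genic,
       nonsynonymous = genic * (1 - synonymous_fraction))
}
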