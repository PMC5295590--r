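# independent oracle: classify a CDS change by translating the whole
# mutant protein and diffing against the reference protein
translate_oracle <- function(cds_ref, cds_alt) {
  tr <- function(s) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(s))), "")[[1]]
  p_ref <- tr(cds_ref)
  p_alt <- tr(cds_alt)
  d <- which(p_ref != p_alt)
  if (!length(d)) return(list(category = "synonymous", aa = NA))
  i <- d[1]
  cat <- if (i == 1 && p_ref[1] == "M") "start_loss"
  else if (p_alt[i] == "*") "nonsense"
  else if (p_ref[i] == "*") "stop_loss"
  else "missense"
  list(category = cat, aa = paste0(sub("\\*", "stop", p_ref[i]), i,
                                   sub("\\*", "stop", p_alt[i])))
}

snp_at <- function(pos, ref, alt, chrom = "c1") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = alt, stringsAsFactors = FALSE)
}

test_that("published-style codon worked examples classify exactly", {
  cases <- list(
    list(codon = "GCC", idx = 100L, p = 2L, cc = "gCc/gTc",
         aa = "A100V", cat = "missense", impact = "MODERATE"),
    list(codon = "CGG", idx = 138L, p = 2L, cc = "cGg/cAg",
         aa = "R138Q", cat = "missense", impact = "MODERATE"),
    list(codon = "GTG", idx = 13L, p = 1L, cc = "Gtg/Atg",
         aa = "V13M", cat = "missense", impact = "MODERATE"),
    list(codon = "CCG", idx = 28L, p = 1L, cc = "Ccg/Tcg",
         aa = "P28S", cat = "missense", impact = "MODERATE"),
    list(codon = "CGG", idx = 346L, p = 2L, cc = "cGg/cAg",
         aa = "R346Q", cat = "missense", impact = "MODERATE"),
    list(codon = "CAG", idx = 225L, p = 2L, cc = "Cag/Tag",
         aa = "Q225stop", cat = "nonsense", impact = "HIGH"))
  # Cag/Tag mutates the first codon base
  cases[[6]]$p <- 1L
  for (cs in cases) {
    plant <- list()
    plant[[as.character(cs$idx)]] <- cs$codon
    g <- embed_gene(cds_codons(cs$idx + 10L, plant))
    cds_pos <- (cs$idx - 1L) * 3L + cs$p
    gpos <- g$gene$start + cds_pos - 1L
    ref <- substr(cs$codon, cs$p, cs$p)
    alt <- c(G = "A", C = "T")[[ref]]
    got <- classify_snps(snp_at(gpos, ref, alt), list(g$gene),
                         g$genome)
    expect_identical(got$category, cs$cat, label = cs$aa)
    expect_identical(got$impact, cs$impact, label = cs$aa)
    expect_identical(got$aa_change, cs$aa)
    expect_identical(got$codon_change, cs$cc)
    expect_identical(got$gene_id, "g1")
  }
})

test_that("third-position wobble changes are synonymous and LOW", {
  g <- embed_gene(cds_codons(20L, list(`5` = "CTG")))
  gpos <- g$gene$start + 4L * 3L + 2L
  got <- classify_snps(snp_at(gpos, "G", "A"), list(g$gene), g$genome)
  expect_identical(got$category, "synonymous")
  expect_identical(got$impact, "LOW")
  expect_identical(got$aa_change, "L5L")
})

test_that("start loss, stop loss and intergenic SNPs classify correctly", {
  g <- embed_gene(cds_codons(20L))
  # destroy the initiator ATG (third base G->A)
  got <- classify_snps(snp_at(g$gene$start + 2L, "G", "A"),
                       list(g$gene), g$genome)
  expect_identical(got$category, "start_loss")
  expect_identical(got$impact, "HIGH")
  # destroy the terminal stop (TAA -> CAA needs T->C; non-EMS but the
  # classifier is general)
  stop_pos <- g$gene$start + 19L * 3L
  got <- classify_snps(snp_at(stop_pos, "T", "C"), list(g$gene),
                       g$genome)
  expect_identical(got$category, "stop_loss")
  expect_identical(got$impact, "HIGH")
  expect_identical(got$aa_change, "stop20Q")
  # far from any gene
  got <- classify_snps(snp_at(5L, "A", "G"), list(g$gene), g$genome)
  expect_identical(got$category, "intergenic")
  expect_identical(got$gene_id, "none")
})

test_that("intronic SNPs split into splice-site and plain intronic", {
  # two-exon gene: exon1 30 bp, intron 100 bp, exon2 30 bp
  cds <- paste(cds_codons(20L), collapse = "")
  intron <- paste(rep("T", 100L), collapse = "")
  genome <- c(c1 = paste0(strrep("A", 10), substr(cds, 1, 30), intron,
                          substr(cds, 31, 60), strrep("A", 10)))
  gmod <- gene_model("g2", "c1", "+",
                     cbind(start = c(11L, 141L), end = c(40L, 170L)))
  # first intronic base after the donor boundary
  got <- classify_snps(snp_at(41L, "T", "A"), list(gmod), genome)
  expect_identical(got$category, "splice_site")
  expect_identical(got$impact, "HIGH")
  got <- classify_snps(snp_at(140L, "T", "A"), list(gmod), genome)
  expect_identical(got$category, "splice_site")
  got <- classify_snps(snp_at(90L, "T", "A"), list(gmod), genome)
  expect_identical(got$category, "intronic")
  expect_identical(got$impact, "MODIFIER")
})

test_that("a reference mismatch is a named error", {
  g <- embed_gene(cds_codons(10L))
  expect_error(classify_snps(snp_at(g$gene$start, "C", "T"),
                             list(g$gene), g$genome),
               "reference mismatch at c1")
})

test_that("classification equals the whole-protein translation oracle", {
  sim <- small_sim()
  set.seed(44)
  for (gm in sample(sim$genes, 3)) {
    cds <- gene_cds_seq(gm, sim$genome)
    ex <- gm$cds_exons[order(gm$cds_exons[, "start"]), , drop = FALSE]
    pos_asc <- unlist(Map(seq.int, ex[, "start"], ex[, "end"]))
    pos_coding <- if (gm$strand == "+") pos_asc else rev(pos_asc)
    targets <- which(strsplit(cds, "")[[1]] %in% c("G", "C"))
    for (i in sample(targets, min(60, length(targets)))) {
      b <- substr(cds, i, i)
      alt_coding <- c(G = "A", C = "T")[[b]]
      cds_alt <- cds
      substr(cds_alt, i, i) <- alt_coding
      want <- translate_oracle(cds, cds_alt)
      gpos <- pos_coding[i]
      ref <- if (gm$strand == "+") b else chartr("GC", "CG", b)
      alt <- if (gm$strand == "+") alt_coding else
        chartr("AT", "TA", alt_coding)
      got <- classify_snps(
        snp_at(gpos, ref, alt, chrom = gm$chrom), list(gm),
        sim$genome)
      expect_identical(got$category, want$category,
                       label = paste(gm$gene_id, i))
      if (!is.na(want$aa)) {
        expect_identical(got$aa_change, want$aa)
      }
    }
  }
})

test_that("a gene and its reverse-complement mirror classify identically", {
  codons <- cds_codons(30L, list(`12` = "CAG"))
  fwd <- embed_gene(codons, strand = "+")
  revg <- embed_gene(codons, strand = "-")
  cds_pos <- 11L * 3L + 1L            # first base of codon 12
  fwd_pos <- fwd$gene$start + cds_pos - 1L
  rev_pos <- revg$gene$end - cds_pos + 1L
  got_f <- classify_snps(snp_at(fwd_pos, "C", "T"), list(fwd$gene),
                         fwd$genome)
  got_r <- classify_snps(snp_at(rev_pos, "G", "A"), list(revg$gene),
                         revg$genome)
  for (col in c("category", "impact", "codon_change", "aa_change")) {
    expect_identical(got_r[[col]], got_f[[col]], label = col)
  }
  expect_identical(got_f$aa_change, "Q12stop")
})

test_that("effect summaries tally categories and the protein-altering total", {
  empty <- summarize_effects(data.frame(category = character()))
  expect_true(all(empty$counts == 0L))
  expect_equal(empty$protein_altering, 0L)
  set.seed(10)
  cats <- sample(c("intergenic", "intronic", "synonymous", "missense",
                   "nonsense", "stop_loss", "splice_site",
                   "start_loss"), 500, replace = TRUE)
  got <- summarize_effects(data.frame(category = cats))
  expect_equal(unname(got$counts), unname(table(factor(
    cats, levels = names(got$counts)))[names(got$counts)]),
    ignore_attr = TRUE)
  expect_equal(got$protein_altering,
               sum(cats %in% c("missense", "nonsense", "stop_loss",
                               "splice_site", "start_loss")))
})

test_that("the expected mutation load is the coding-target product", {
  load <- expected_mutation_load(30e6, 1 / 125000)
  expect_equal(load$genic, 240)
  expect_equal(load$nonsynonymous, 160)
  zero <- expected_mutation_load(30e6, 0)
  expect_equal(zero$genic, 0)
  expect_equal(zero$nonsynonymous, 0)
})
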