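# fixtures are generated once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

# the default desk-scale study at seed 1 (the demo dataset)
demo_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_ems_study(sim_params(seed = 1))
  }
  .fixtures$sim
}

demo_report <- function() {
  if (is.null(.fixtures$report)) {
    .fixtures$report <- run_end_to_end(sim_params(seed = 1))
  }
  .fixtures$report
}

# a small, fast simulation for structural tests
small_params <- function(seed = 7) {
  sim_params(n_chroms = 1, chrom_length_bp = 4e5, n_genes = 15,
             ems_rate = 1 / 25000, n_error_prone = 10,
             n_background_variants = 10, n_indel_sites = 20,
             n_singleton_sites = 30, seed = seed)
}

small_sim <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_ems_study(small_params())
  }
  .fixtures$small
}

# construct a calls data.frame with sensible defaults, overridable
# per-field (vectors recycle)
make_calls <- function(n = 1, chrom = "chr1", pos = seq_len(n) * 10L,
                       ref = "G", alt = "A", qual = 50, depth = 30L,
                       ref_fwd = 0L, ref_rev = 0L, alt_fwd = 15L,
                       alt_rev = 15L, rms_mapq = 50,
                       genotype = "hom_alt",
                       dist_to_gap = NA_integer_) {
  r <- function(x) rep_len(x, n)
  data.frame(chrom = r(chrom), pos = r(as.integer(pos)), ref = r(ref),
             alt = r(alt), qual = r(qual), depth = r(as.integer(depth)),
             ref_fwd = r(as.integer(ref_fwd)),
             ref_rev = r(as.integer(ref_rev)),
             alt_fwd = r(as.integer(alt_fwd)),
             alt_rev = r(as.integer(alt_rev)), rms_mapq = r(rms_mapq),
             genotype = r(genotype), dist_to_gap = r(dist_to_gap),
             stringsAsFactors = FALSE)
}

# randomized but reproducible call sets for round-trip/oracle tests
random_calls <- function(n, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                character(1), USE.NAMES = FALSE)
  alt_n <- sample(0:40, n, replace = TRUE)
  ref_n <- sample(0:40, n, replace = TRUE)
  af <- rbinom(n, alt_n, 0.5)
  rf <- rbinom(n, ref_n, 0.5)
  make_calls(n, chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             pos = sample(1e6, n), ref = ref, alt = alt,
             qual = round(runif(n, 0, 250), 4),
             depth = alt_n + ref_n + sample(0:3, n, replace = TRUE),
             ref_fwd = rf, ref_rev = ref_n - rf, alt_fwd = af,
             alt_rev = alt_n - af,
             rms_mapq = round(runif(n, 5, 60), 1),
             genotype = sample(c("hom_ref", "het", "hom_alt"), n,
                               replace = TRUE),
             dist_to_gap = ifelse(runif(n) < 0.3, NA_integer_,
                                  sample(0:50, n, replace = TRUE)))
}

# build a genome containing a single plus- or minus-strand gene whose
# CDS is given as codons; returns list(genome, gene)
embed_gene <- function(codons, strand = "+", chrom = "c1",
                       flank = 30L, gene_id = "g1") {
  cds <- paste(codons, collapse = "")
  pad_l <- paste(rep("A", flank), collapse = "")
  pad_r <- paste(rep("A", flank), collapse = "")
  body <- if (strand == "+") cds else revcomp(cds)
  genome <- stats::setNames(paste0(pad_l, body, pad_r), chrom)
  start <- flank + 1L
  end <- flank + nchar(cds)
  gm <- suppressWarnings(
    gene_model(gene_id, chrom, strand,
               cbind(start = start, end = end)))
  list(genome = genome, gene = gm)
}

# codons for a CDS of n_codons total with specific codons planted at
# given indices (1-based); remaining filled with a neutral codon
cds_codons <- function(n_codons, plant = list(), fill = "CTT") {
  codons <- c("ATG", rep(fill, n_codons - 2L), "TAA")
  for (nm in names(plant)) codons[as.integer(nm)] <- plant[[nm]]
  codons
}
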