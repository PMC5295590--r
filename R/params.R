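#' Pipeline filtering and mapping parameters
#'
#' Collects every numeric threshold used by the filter cascade, the
#' cross-lineage subtraction and the cosegregation mapping into one
#' validated list. Defaults follow standard practice for EMS
#' mutant-by-sequencing pipelines: SNPs are kept when sequencing depth is
#' between 2 and 100 (the upper bound doubles as the repetitive-region
#' filter), root-mean-square mapping quality is at least 10, no indel
#' evidence lies within 3 bp, the call is homozygous-alternate with Phred
#' quality >= 20, no reference-base reads remain and the alternate allele
#' is seen on both strands, and the change is a G:C->A:T transition.
#'
#' @param min_depth,max_depth inclusive read-depth bounds for a call.
#' @param min_rms_mapq minimum root-mean-square mapping quality.
#' @param gap_window calls within this many bases of an indel/gap are
#'   discarded.
#' @param min_hom_qual minimum Phred variant quality for a retained
#'   homozygous call.
#' @param require_zero_ref_reads if `TRUE`, a retained call must have no
#'   reference-base reads.
#' @param require_both_strands if `TRUE`, a retained call needs at least
#'   one alternate read on each strand.
#' @param ems_spectrum_only if `TRUE`, only G->A and C->T changes (on the
#'   reference strand) pass the spectrum filter.
#' @param strict_strand_missing records lacking strand-resolved counts
#'   fail the strand/purity filter when `TRUE` (default); set `FALSE` to
#'   let them pass with a warning.
#' @param het_freq_window numeric length-2: inclusive alternate-frequency
#'   window consistent with a heterozygote (used for the segregating
#'   sibling).
#' @param hom_alt_min_freq minimum alternate frequency in the mutant pool
#'   for a causal candidate.
#' @param wt_max_freq maximum alternate frequency in the wild-type
#'   sibling pool for a causal candidate (and for a marker to support a
#'   linked interval).
#' @param min_interval_markers minimum number of consecutive qualifying
#'   markers that define a linked interval.
#' @param min_informative_depth frequencies computed from fewer reads
#'   than this are treated as "insufficient coverage" rather than
#'   evidence for or against a candidate. The default of 10 is the
#'   smallest depth at which a true heterozygote lands inside the default
#'   `het_freq_window` with >= 95% probability.
#'
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_depth = 2, max_depth = 100,
                            min_rms_mapq = 10, gap_window = 3,
                            min_hom_qual = 20,
                            require_zero_ref_reads = TRUE,
                            require_both_strands = TRUE,
                            ems_spectrum_only = TRUE,
                            strict_strand_missing = TRUE,
                            het_freq_window = c(0.2, 0.8),
                            hom_alt_min_freq = 0.9,
                            wt_max_freq = 0.2,
                            min_interval_markers = 3,
                            min_informative_depth = 10) {
  stopifnot(min_depth >= 0, min_depth <= max_depth,
            min_rms_mapq >= 0, gap_window >= 0, min_hom_qual >= 0,
            length(het_freq_window) == 2,
            het_freq_window[1] <= het_freq_window[2])
  freqs <- c(het_freq_window, hom_alt_min_freq, wt_max_freq)
  if (any(freqs < 0 | freqs > 1)) {
    stop("frequency bounds must lie in [0, 1]")
  }
  if (min_interval_markers < 1) stop("min_interval_markers must be >= 1")
  structure(list(
    min_depth = min_depth, max_depth = max_depth,
    min_rms_mapq = min_rms_mapq, gap_window = gap_window,
    min_hom_qual = min_hom_qual,
    require_zero_ref_reads = require_zero_ref_reads,
    require_both_strands = require_both_strands,
    ems_spectrum_only = ems_spectrum_only,
    strict_strand_missing = strict_strand_missing,
    het_freq_window = het_freq_window,
    hom_alt_min_freq = hom_alt_min_freq,
    wt_max_freq = wt_max_freq,
    min_interval_markers = min_interval_markers,
    min_informative_depth = min_informative_depth
  ), class = "pipeline_params")
}

#' Simulation parameters for a desk-scale EMS pedigree study
#'
#' Defines the synthetic study design: three independently mutagenized
#' lineages, one of which segregates a recessive causal mutation, selfed
#' for three generations and sequenced as pools at unequal depths. The
#' defaults reproduce a five-line dwarf-mapping study design at desk
#' scale: a 5 Mb genome (2 chromosomes of 2.5 Mb) with 100
#' genes, an EMS rate of one mutation per 125,000 bp, pools of 17
#' wild-type siblings, 1 heterozygous sibling and 13 mutants, and
#' sequencing depths of 45/7/30 for the focal lineage and 3/43 for the
#' two unrelated lineages.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bases.
#' @param n_genes number of non-overlapping protein-coding genes placed
#'   on the genome.
#' @param mean_cds_len mean coding-sequence length in bp (including the
#'   stop codon).
#' @param ems_rate expected EMS mutations per bp of genome (G:C->A:T
#'   transitions, heterozygous in the treated founder).
#' @param generations_selfed selfing generations between the mutagenized
#'   founder and the sequenced family (3 = M1 -> M4).
#' @param crossovers_per_meiosis Poisson mean crossover count per
#'   chromosome per meiosis.
#' @param pool_sizes named integer vector: individuals pooled per role
#'   (`mutant_pool`, `wt_sibling`, `het_sibling`, `unrelated`).
#' @param depths named numeric vector of target sequencing depths per
#'   line (`10-2`, `10-3`, `10-d`, `12-2`, `dhr2-1`).
#' @param seq_error_rate per-base sequencing error probability.
#' @param n_error_prone number of planted error-prone positions that emit
#'   spurious alternate reads in every line.
#' @param error_prone_alt_prob per-read probability of the spurious
#'   alternate base at an error-prone position. The default of 1 models
#'   paralogy/misassembly artifacts, whose reads are consistently
#'   non-reference (a lower value would let reference reads through and
#'   the sites would be removed by the purity filter instead of reaching
#'   the cross-lineage subtraction stage they are planted to exercise).
#' @param n_background_variants homozygous non-EMS-spectrum differences
#'   from the reference shared by all lineages (sub-line drift).
#' @param n_indel_sites random indel positions emitted to the truth set
#'   (exercise the gap-proximity filter).
#' @param n_singleton_sites per-line count of spiked low-depth
#'   sequencing-error-only positions (stand-in for genome-wide error
#'   singletons, which are not enumerated at scale).
#' @param seed integer seed; fixed seed makes every output byte-identical.
#'
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_chroms = 2,
                       chrom_length_bp = 2.5e6,
                       n_genes = 100,
                       mean_cds_len = 1200,
                       ems_rate = 1 / 125000,
                       generations_selfed = 3,
                       crossovers_per_meiosis = 1,
                       pool_sizes = c(mutant_pool = 13, wt_sibling = 17,
                                      het_sibling = 1, unrelated = 1),
                       depths = c(`10-2` = 45, `10-3` = 7, `10-d` = 30,
                                  `12-2` = 3, `dhr2-1` = 43),
                       seq_error_rate = 0.001,
                       n_error_prone = 50,
                       error_prone_alt_prob = 1.0,
                       n_background_variants = 50,
                       n_indel_sites = 100,
                       n_singleton_sites = 200,
                       seed = 1) {
  rates <- c(ems_rate, seq_error_rate, error_prone_alt_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  stopifnot(n_chroms >= 1, chrom_length_bp >= 1000, n_genes >= 0,
            generations_selfed >= 1, crossovers_per_meiosis >= 0,
            all(depths > 0), all(pool_sizes >= 1))
  if (ems_rate * n_chroms * chrom_length_bp < 1) {
    stop("ems_rate times genome length must be >= 1 expected mutation")
  }
  structure(list(
    n_chroms = as.integer(n_chroms),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_genes = as.integer(n_genes),
    mean_cds_len = as.integer(mean_cds_len),
    ems_rate = ems_rate,
    generations_selfed = as.integer(generations_selfed),
    crossovers_per_meiosis = crossovers_per_meiosis,
    pool_sizes = pool_sizes,
    depths = depths,
    seq_error_rate = seq_error_rate,
    n_error_prone = as.integer(n_error_prone),
    error_prone_alt_prob = error_prone_alt_prob,
    n_background_variants = as.integer(n_background_variants),
    n_indel_sites = as.integer(n_indel_sites),
    n_singleton_sites = as.integer(n_singleton_sites),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Default pedigree manifest of the simulated study
#'
#' Five lines from three independent mutagenesis events: the focal
#' lineage contributes a wild-type sibling pool, a heterozygous sibling
#' and the mutant pool; the other two lineages each contribute one
#' phenotypically normal line used only for false-positive subtraction.
#'
#' @param params a [sim_params()] object supplying pool sizes and depths.
#' @return a data.frame with columns `line_id`, `lineage_id`, `role`,
#'   `pool_size`, `target_depth`.
#' @export
default_manifest <- function(params = sim_params()) {
  ps <- params$pool_sizes
  data.frame(
    line_id = c("10-2", "10-3", "10-d", "12-2", "dhr2-1"),
    lineage_id = c("L10", "L10", "L10", "L12", "Ldhr2"),
    role = c("wt_sibling", "het_sibling", "mutant_pool",
             "unrelated", "unrelated"),
    pool_size = as.integer(c(ps[["wt_sibling"]], ps[["het_sibling"]],
                             ps[["mutant_pool"]], ps[["unrelated"]],
                             ps[["unrelated"]])),
    target_depth = as.numeric(params$depths[
      c("10-2", "10-3", "10-d", "12-2", "dhr2-1")]),
    stringsAsFactors = FALSE
  )
}

validate_manifest <- function(manifest) {
  need <- c("line_id", "lineage_id", "role", "pool_size", "target_depth")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  ok_roles <- c("mutant_pool", "het_sibling", "wt_sibling", "unrelated")
  if (!all(manifest$role %in% ok_roles)) {
    stop("unknown role(s): ",
         paste(setdiff(manifest$role, ok_roles), collapse = ", "))
  }
  if (sum(manifest$role == "mutant_pool") != 1) {
    stop("manifest must contain exactly one mutant_pool line")
  }
  if (anyDuplicated(manifest$line_id)) stop("duplicate line_id in manifest")
  invisible(manifest)
}
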