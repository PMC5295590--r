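BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")
# EMS transition on the reference strand
EMS_ALT <- c(G = "A", C = "T")

all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

#' Simulate a reference genome with annotated genes
#'
#' Generates a random uniform-composition genome and places
#' non-overlapping protein-coding genes on it, roughly half per strand,
#' each with 1-4 CDS exons. Every CDS starts with ATG, contains no
#' internal stop codon, ends with a stop codon and has length divisible
#' by three; the coding sequence is written into the genome so that
#' extraction and translation round-trip exactly.
#'
#' @param params a [sim_params()]. Draws from the current RNG state;
#'   call `set.seed()` first (or use [simulate_ems_study()], which seeds
#'   from `params$seed`).
#' @return list with `genome` (named character vector of chromosome
#'   sequences) and `genes` (list of [gene_model()]).
#' @export
simulate_reference <- function(params) {
  L <- params$chrom_length_bp
  chroms <- paste0("chr", seq_len(params$n_chroms))
  chars <- lapply(chroms, function(cc) sample(BASES, L, replace = TRUE))
  names(chars) <- chroms
  genes <- vector("list", params$n_genes)
  placed <- stats::setNames(
    rep(list(matrix(numeric(0), ncol = 2)), length(chroms)), chroms)
  nonstop <- setdiff(all_codons(), STOP_CODONS)
  margin <- 50L
  attempts <- 0L
  max_attempts <- 200L * max(1L, params$n_genes)
  i <- 1L
  while (i <= params$n_genes) {
    n_codons <- max(60L, round(stats::rnorm(1, params$mean_cds_len / 3,
                                            params$mean_cds_len / 9)))
    cds_len <- 3L * as.integer(n_codons)
    n_exons <- sample(1:4, 1)
    exon_lens <- if (n_exons == 1) cds_len else {
      cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
      diff(c(0L, cuts, cds_len))
    }
    intron_lens <- if (n_exons > 1) sample(80:400, n_exons - 1,
                                           replace = TRUE) else integer(0)
    span <- cds_len + sum(intron_lens)
    chrom <- sample(chroms, 1)
    start <- sample(seq(margin, L - span - margin), 1)
    ivs <- placed[[chrom]]
    overlaps <- nrow(ivs) > 0 &&
      any(start <= ivs[, 2] + 10 & (start + span - 1) >= ivs[, 1] - 10)
    attempts <- attempts + 1L
    if (overlaps) {
      if (attempts > max_attempts) {
        stop("could not place ", params$n_genes, " genes without ",
             "overlap; increase chrom_length_bp or reduce n_genes")
      }
      next
    }
    placed[[chrom]] <- rbind(ivs, c(start, start + span - 1))
    strand <- sample(c("+", "-"), 1)
    codons <- c("ATG",
                sample(nonstop, n_codons - 2L, replace = TRUE),
                sample(STOP_CODONS, 1))
    cds_chars <- strsplit(paste(codons, collapse = ""), "")[[1]]
    # genomic exon intervals, ascending
    ex_starts <- start + c(0L, cumsum(exon_lens[-n_exons] +
                                        intron_lens))
    ex_ends <- ex_starts + exon_lens - 1L
    pos_asc <- unlist(Map(seq.int, ex_starts, ex_ends))
    if (strand == "+") {
      chars[[chrom]][pos_asc] <- cds_chars
    } else {
      # first codon sits at the highest coordinate, complemented
      chars[[chrom]][rev(pos_asc)] <-
        chartr("ACGT", "TGCA", cds_chars)
    }
    genes[[i]] <- gene_model(
      gene_id = sprintf("gene%03d", i), chrom = chrom, strand = strand,
      cds_exons = cbind(start = ex_starts, end = ex_ends),
      description = sprintf("simulated gene %d", i))
    i <- i + 1L
  }
  genome <- vapply(chars, paste, character(1), collapse = "")
  genes <- genes[!vapply(genes, is.null, logical(1))]
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  list(genome = genome, genes = genes)
}

#' Plant heterozygous EMS mutations on a founder genome
#'
#' Each G or C position is mutated independently such that the expected
#' genome-wide mutation count equals `rate` times the genome length;
#' only G->A and C->T transitions are produced and each mutation is
#' assigned to one founder haplotype at random.
#'
#' @param genome named character vector of chromosome sequences.
#' @param rate expected mutations per bp of genome.
#' @param exclude optional data.frame with `chrom`/`pos` of positions to
#'   leave untouched.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `hap`.
#' @export
induce_ems_mutations <- function(genome, rate, exclude = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (rate == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      hap = integer(), stringsAsFactors = FALSE))
  }
  per_chrom <- lapply(names(genome), function(cc) {
    ch <- strsplit(genome[[cc]], "")[[1]]
    idx <- which(ch == "G" | ch == "C")
    if (!is.null(exclude)) {
      idx <- setdiff(idx, exclude$pos[exclude$chrom == cc])
    }
    list(chrom = cc, idx = idx, ref = ch)
  })
  n_gc <- sum(vapply(per_chrom, function(x) length(x$idx), integer(1)))
  total_len <- sum(nchar(genome))
  if (n_gc == 0) return(induce_ems_mutations(genome, 0))
  p_site <- min(1, rate * total_len / n_gc)
  out <- lapply(per_chrom, function(x) {
    hit <- x$idx[stats::rbinom(length(x$idx), 1, p_site) == 1]
    if (!length(hit)) return(NULL)
    ref <- x$ref[hit]
    data.frame(chrom = x$chrom, pos = as.integer(hit), ref = ref,
               alt = unname(EMS_ALT[ref]),
               hap = sample(1:2, length(hit), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(induce_ems_mutations(genome, 0))
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# choose a codon position where a single G:C->A:T change creates a
# premature stop; returns the causal mutation with its codon-level truth
plant_causal_mutation <- function(genome, genes) {
  for (gm in sample(genes)) {
    if (!gm$translatable) next
    cds <- gene_cds_seq(gm, genome)
    n_cod <- nchar(cds) / 3
    # coding-order genomic positions of every CDS base
    ex <- gm$cds_exons[order(gm$cds_exons[, "start"]), , drop = FALSE]
    pos_asc <- unlist(Map(seq.int, ex[, "start"], ex[, "end"]))
    pos_coding <- if (gm$strand == "+") pos_asc else rev(pos_asc)
    cands <- list()
    for (ci in 2:(n_cod - 1)) {
      codon <- substr(cds, 3 * ci - 2, 3 * ci)
      for (p in 1:3) {
        b <- substr(codon, p, p)
        if (!b %in% c("G", "C")) next
        mut <- codon
        substr(mut, p, p) <- EMS_ALT[[b]]
        if (mut %in% STOP_CODONS) {
          cands[[length(cands) + 1L]] <- list(ci = ci, p = p, b = b,
                                              codon = codon, mut = mut)
        }
      }
    }
    if (!length(cands)) next
    pick <- cands[[sample(length(cands), 1)]]
    gpos <- pos_coding[3L * (pick$ci - 1L) + pick$p]
    ref <- if (gm$strand == "+") pick$b else
      chartr("ACGT", "TGCA", pick$b)
    cc_ref <- chartr(toupper(pick$b), tolower(pick$b),
                     tolower(pick$codon))
    substr(cc_ref, pick$p, pick$p) <- toupper(pick$b)
    cc_alt <- tolower(pick$mut)
    substr(cc_alt, pick$p, pick$p) <- toupper(substr(pick$mut, pick$p,
                                                     pick$p))
    aa_ref <- unname(Biostrings::GENETIC_CODE[pick$codon])
    return(list(chrom = gm$chrom, pos = as.integer(gpos), ref = ref,
                alt = unname(EMS_ALT[ref]), gene_id = gm$gene_id,
                codon_index = pick$ci,
                codon_change = paste0(cc_ref, "/", cc_alt),
                aa_change = paste0(aa_ref, pick$ci, "stop")))
  }
  stop("no gene offers a G:C->A:T premature-stop site; ",
       "increase n_genes or mean_cds_len")
}

# --- pedigree machinery -------------------------------------------------

#' Low-level pedigree operations
#'
#' An individual is represented as a list over chromosomes, each
#' chromosome holding two haplotypes as sorted integer vectors of
#' carried mutation positions. `founder_individual()` builds the
#' heterozygous mutagenized founder from a mutation table;
#' `make_gamete()` draws one meiotic product per chromosome (Poisson
#' crossovers, no interference, uniform breakpoints);
#' `self_individual()` combines two gametes of the same parent;
#' `genotype_at()` returns the alternate-allele dosage (0/1/2) at one
#' site.
#'
#' @param muts mutation data.frame (`chrom`, `pos`, `hap`).
#' @param chroms chromosome names the individual should carry.
#' @param ind an individual.
#' @param L chromosome length in bp.
#' @param xo_mean Poisson mean crossovers per chromosome per meiosis.
#' @param xo_log optional environment collecting breakpoint vectors.
#' @param chrom,pos genomic site.
#' @name pedigree_ops
NULL

#' @rdname pedigree_ops
#' @export
founder_individual <- function(muts, chroms) {
  ind <- lapply(chroms, function(cc) {
    m <- muts[muts$chrom == cc, , drop = FALSE]
    list(h1 = sort(m$pos[m$hap == 1]), h2 = sort(m$pos[m$hap == 2]))
  })
  names(ind) <- chroms
  ind
}

# one meiotic product for one chromosome
gamete_chrom <- function(hap, L, xo_mean) {
  n_xo <- stats::rpois(1, xo_mean)
  start <- sample(1:2, 1)
  if (n_xo == 0) {
    sites <- if (start == 1) hap$h1 else hap$h2
    return(list(sites = sites, breakpoints = numeric(0)))
  }
  bp <- sort(stats::runif(n_xo, 0, L))
  seg1 <- findInterval(hap$h1, bp)
  seg2 <- findInterval(hap$h2, bp)
  want1 <- if (start == 1) 0 else 1
  sites <- sort(c(hap$h1[seg1 %% 2 == want1],
                  hap$h2[seg2 %% 2 != want1]))
  list(sites = sites, breakpoints = bp)
}

#' @rdname pedigree_ops
#' @export
make_gamete <- function(ind, L, xo_mean, xo_log = NULL) {
  out <- lapply(ind, gamete_chrom, L = L, xo_mean = xo_mean)
  if (!is.null(xo_log)) {
    xo_log$breakpoints <- c(xo_log$breakpoints,
                            lapply(out, `[[`, "breakpoints"))
  }
  lapply(out, `[[`, "sites")
}

#' @rdname pedigree_ops
#' @export
self_individual <- function(ind, L, xo_mean, xo_log = NULL) {
  g1 <- make_gamete(ind, L, xo_mean, xo_log)
  g2 <- make_gamete(ind, L, xo_mean, xo_log)
  out <- Map(function(a, b) list(h1 = a, h2 = b), g1, g2)
  names(out) <- names(ind)
  out
}

#' @rdname pedigree_ops
#' @export
genotype_at <- function(ind, chrom, pos) {
  hap <- ind[[chrom]]
  as.integer(pos %in% hap$h1) + as.integer(pos %in% hap$h2)
}

# alt-allele dosage count (0/1/2) for each row of sites, one individual
genotypes_at_sites <- function(ind, sites) {
  out <- integer(nrow(sites))
  for (cc in unique(sites$chrom)) {
    sel <- sites$chrom == cc
    hap <- ind[[cc]]
    if (is.null(hap)) next
    out[sel] <- as.integer(sites$pos[sel] %in% hap$h1) +
      as.integer(sites$pos[sel] %in% hap$h2)
  }
  out
}

#' Propagate the mutagenized pedigree by selfing with recombination
#'
#' Each lineage founder (heterozygous for its induced mutations) is
#' selfed `generations_selfed` times with Poisson crossovers per
#' chromosome per meiosis. From the final segregating family of the
#' focal lineage, individuals are selected by genotype at the causal
#' site: a mutant pool (homozygous alternate), one heterozygous sibling,
#' and a homozygous-reference ancestor that is selfed once more to form
#' the wild-type sibling pool. Unrelated lineages are propagated
#' identically with no selection.
#'
#' @param lineage_muts named list (by lineage) of mutation data.frames
#'   from [induce_ems_mutations()].
#' @param causal list with at least `chrom` and `pos` of the causal
#'   mutation (must be present in the focal lineage's mutations).
#' @param params a [sim_params()].
#' @param manifest pedigree manifest (see [default_manifest()]).
#' @param max_family_draws cap on offspring draws before giving up on a
#'   required genotype class.
#' @return list with `individuals` (named by `line_id`, each a list of
#'   individuals), `crossover_breakpoints` (list of numeric vectors, one
#'   per meiosis per chromosome) and `segregation_counts`.
#' @export
propagate_pedigree <- function(lineage_muts, causal, params,
                               manifest = default_manifest(params),
                               max_family_draws = 4000L) {
  validate_manifest(manifest)
  L <- params$chrom_length_bp
  xo <- params$crossovers_per_meiosis
  chroms <- paste0("chr", seq_len(params$n_chroms))
  xo_log <- new.env()
  xo_log$breakpoints <- list()

  focal_lineage <- manifest$lineage_id[manifest$role == "mutant_pool"]
  fm <- lineage_muts[[focal_lineage]]
  if (!any(fm$chrom == causal$chrom & fm$pos == causal$pos)) {
    stop("causal site absent from focal lineage mutations")
  }

  # selfing chain keeping the causal site heterozygous (the sequenced
  # family must still segregate)
  parent <- founder_individual(fm, chroms)
  for (g in seq_len(params$generations_selfed - 1L)) {
    for (try in seq_len(200L)) {
      off <- self_individual(parent, L, xo, xo_log)
      if (genotype_at(off, causal$chrom, causal$pos) == 1L) break
      if (try == 200L) stop("selfing chain never produced a causal ",
                            "heterozygote (generation ", g, ")")
    }
    parent <- off
  }

  roles <- stats::setNames(manifest$role, manifest$line_id)
  sizes <- stats::setNames(manifest$pool_size, manifest$line_id)
  mutant_line <- manifest$line_id[manifest$role == "mutant_pool"]
  het_line <- manifest$line_id[manifest$role == "het_sibling" &
                                 manifest$lineage_id == focal_lineage]
  wt_line <- manifest$line_id[manifest$role == "wt_sibling" &
                                manifest$lineage_id == focal_lineage]

  need_mut <- sizes[[mutant_line]]
  need_het <- if (length(het_line)) sizes[[het_line]] else 0L
  need_wt_anc <- if (length(wt_line)) 1L else 0L
  pool_mut <- list(); pool_het <- list(); wt_anc <- NULL
  seg <- c(hom_ref = 0L, het = 0L, hom_alt = 0L)
  draws <- 0L
  while ((length(pool_mut) < need_mut || length(pool_het) < need_het ||
          (need_wt_anc && is.null(wt_anc))) && draws < max_family_draws) {
    off <- self_individual(parent, L, xo, xo_log)
    gt <- genotype_at(off, causal$chrom, causal$pos)
    seg[gt + 1L] <- seg[gt + 1L] + 1L
    draws <- draws + 1L
    if (gt == 2L && length(pool_mut) < need_mut) {
      pool_mut[[length(pool_mut) + 1L]] <- off
    } else if (gt == 1L && length(pool_het) < need_het) {
      pool_het[[length(pool_het) + 1L]] <- off
    } else if (gt == 0L && need_wt_anc && is.null(wt_anc)) {
      wt_anc <- off
    }
  }
  if (length(pool_mut) < need_mut || length(pool_het) < need_het ||
      (need_wt_anc && is.null(wt_anc))) {
    stop("required genotype class absent after ", draws,
         " family draws (segregation hom_ref/het/hom_alt = ",
         paste(seg, collapse = "/"), ")")
  }

  individuals <- list()
  individuals[[mutant_line]] <- pool_mut
  if (length(het_line)) individuals[[het_line]] <- pool_het
  if (length(wt_line)) {
    individuals[[wt_line]] <- replicate(
      sizes[[wt_line]], self_individual(wt_anc, L, xo, xo_log),
      simplify = FALSE)
  }

  other_lines <- manifest$line_id[manifest$lineage_id != focal_lineage]
  for (ln in other_lines) {
    lm <- lineage_muts[[manifest$lineage_id[manifest$line_id == ln]]]
    if (is.null(lm)) stop("no mutations supplied for lineage of line ",
                          ln)
    ind <- founder_individual(lm, chroms)
    for (g in seq_len(params$generations_selfed)) {
      ind <- self_individual(ind, L, xo, xo_log)
    }
    individuals[[ln]] <- replicate(sizes[[ln]], ind, simplify = FALSE)
    if (sizes[[ln]] > 1L) {
      # independent pool members: extra selfings of the same parent
      individuals[[ln]] <- c(list(ind), replicate(
        sizes[[ln]] - 1L, self_individual(ind, L, xo, xo_log),
        simplify = FALSE))[seq_len(sizes[[ln]])]
    }
  }

  list(individuals = individuals,
       crossover_breakpoints = xo_log$breakpoints,
       segregation_counts = seg)
}

#' Pooled alternate-allele dosage per line at a set of sites
#'
#' @param individuals named list of individual lists (from
#'   [propagate_pedigree()]).
#' @param sites data.frame with `chrom`, `pos`.
#' @return matrix of dosage fractions in \[0, 1\], rows = sites, columns
#'   = lines.
#' @export
pool_dosage <- function(individuals, sites) {
  out <- vapply(individuals, function(pool) {
    g <- vapply(pool, genotypes_at_sites, integer(nrow(sites)),
                sites = sites)
    if (nrow(sites) == 1L) g <- matrix(g, nrow = 1)
    rowMeans(g) / 2
  }, numeric(nrow(sites)))
  if (nrow(sites) == 1L) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL,
                                                       names(individuals)))
  out
}

#' Sample pooled sequencing read counts for one line
#'
#' At each site, depth is Poisson(target depth) and the alternate read
#' count is Binomial(depth, p) with
#' `p = dosage * (1 - e) + (1 - dosage) * e / 3` for per-base error rate
#' `e`; counts are split between strands Binomial(n, 1/2). At
#' error-prone sites a spurious alternate base (fixed per site, shared
#' by every line) replaces each read with probability
#' `error_prone_alt_prob`, regardless of genotype.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` and logical
#'   `error_prone`.
#' @param dosage numeric vector of pooled alternate dosages in \[0, 1\].
#' @param line_id line identifier stamped on each row.
#' @param target_depth mean sequencing depth.
#' @param e per-base sequencing error rate.
#' @param error_prone_alt_prob per-read spurious-alternate probability
#'   at error-prone sites.
#' @return allele-count data.frame (see [read_allele_counts()]).
#' @export
sample_read_counts <- function(sites, dosage, line_id, target_depth,
                               e, error_prone_alt_prob = 1.0) {
  stopifnot(target_depth > 0, length(dosage) == nrow(sites))
  n <- nrow(sites)
  depth <- stats::rpois(n, target_depth)
  p <- dosage * (1 - e) + (1 - dosage) * e / 3
  alt_n <- stats::rbinom(n, depth, p)
  ep <- which(isTRUE_vec(sites$error_prone))
  if (length(ep)) {
    alt_n[ep] <- stats::rbinom(length(ep), depth[ep],
                               error_prone_alt_prob)
  }
  ref_n <- depth - alt_n
  alt_fwd <- stats::rbinom(n, alt_n, 0.5)
  ref_fwd <- stats::rbinom(n, ref_n, 0.5)
  data.frame(
    line_id = line_id, chrom = sites$chrom, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    ref_fwd = ref_fwd, ref_rev = ref_n - ref_fwd,
    alt_fwd = alt_fwd, alt_rev = alt_n - alt_fwd,
    rms_mapq = pmax(0, round(stats::rnorm(n, 48, 3), 1)),
    stringsAsFactors = FALSE
  )
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else
  !is.na(x) & x

sample_positions <- function(genome, n, exclude_key = character(0)) {
  chroms <- names(genome)
  lens <- nchar(genome)
  out <- data.frame(chrom = character(0), pos = integer(0))
  guard <- 0L
  while (nrow(out) < n && guard < 50L) {
    k <- n - nrow(out)
    cc <- sample(chroms, k, replace = TRUE, prob = lens)
    pp <- vapply(cc, function(x) sample.int(nchar(genome[[x]]), 1),
                 integer(1))
    cand <- data.frame(chrom = cc, pos = pp, stringsAsFactors = FALSE)
    key <- paste(cand$chrom, cand$pos)
    keep <- !key %in% exclude_key & !duplicated(key)
    out <- rbind(out, cand[keep, ])
    exclude_key <- c(exclude_key, key[keep])
    guard <- guard + 1L
  }
  rownames(out) <- NULL
  out
}

base_at <- function(genome, chrom, pos) {
  substring(genome[chrom], pos, pos)
}

#' Run the complete desk-scale EMS pedigree simulation
#'
#' Builds a reference genome with genes, induces heterozygous EMS
#' mutations in three independent lineage founders, plants one causal
#' premature-stop mutation in the focal lineage, propagates the pedigree
#' by selfing with recombination, selects the sequenced pools by
#' genotype at the causal site, and samples pooled read counts per line
#' including planted error-prone positions, shared background variants,
#' indel positions and low-depth error singletons. The returned object
#' carries the complete ground truth.
#'
#' @param params a [sim_params()]; `params$seed` fully determines the
#'   output.
#' @param manifest pedigree manifest (defaults to the five-line,
#'   three-lineage design).
#' @return list of class `ems_simulation` with components `params`,
#'   `manifest`, `genome`, `genes`, `counts` (all lines, one
#'   data.frame), `calls` (named list of per-line call data.frames) and
#'   `truth`.
#' @export
simulate_ems_study <- function(params = sim_params(),
                               manifest = default_manifest(params)) {
  validate_manifest(manifest)
  set.seed(params$seed)
  ref <- simulate_reference(params)
  genome <- ref$genome

  lineages <- unique(manifest$lineage_id)
  focal <- manifest$lineage_id[manifest$role == "mutant_pool"]
  lineage_muts <- list()
  used <- character(0)
  for (lg in lineages) {
    m <- induce_ems_mutations(genome, params$ems_rate)
    m <- m[!paste(m$chrom, m$pos) %in% used, , drop = FALSE]
    used <- c(used, paste(m$chrom, m$pos))
    lineage_muts[[lg]] <- m
  }

  causal <- plant_causal_mutation(genome, ref$genes)
  ck <- paste(causal$chrom, causal$pos)
  if (ck %in% used) {
    # vanishingly rare; drop the colliding background mutation
    for (lg in lineages) {
      m <- lineage_muts[[lg]]
      lineage_muts[[lg]] <- m[paste(m$chrom, m$pos) != ck, ,
                              drop = FALSE]
    }
  }
  lineage_muts[[focal]] <- rbind(
    lineage_muts[[focal]],
    data.frame(chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
               alt = causal$alt, hap = sample(1:2, 1),
               stringsAsFactors = FALSE))
  lineage_muts[[focal]] <- lineage_muts[[focal]][
    order(lineage_muts[[focal]]$chrom, lineage_muts[[focal]]$pos), ,
    drop = FALSE]
  used <- c(used, ck)

  ep <- sample_positions(genome, params$n_error_prone, used)
  ep$ref <- base_at(genome, ep$chrom, ep$pos)
  ep$alt <- vapply(ep$ref, function(r) sample(setdiff(BASES, r), 1),
                   character(1), USE.NAMES = FALSE)
  used <- c(used, paste(ep$chrom, ep$pos))

  bg <- sample_positions(genome, params$n_background_variants, used)
  bg$ref <- base_at(genome, bg$chrom, bg$pos)
  # sub-line drift: any change except the EMS transition
  bg$alt <- vapply(bg$ref, function(r) {
    sample(setdiff(setdiff(BASES, r), EMS_ALT[r]), 1)
  }, character(1), USE.NAMES = FALSE)
  used <- c(used, paste(bg$chrom, bg$pos))

  indels <- sample_positions(genome, params$n_indel_sites, used)

  ped <- propagate_pedigree(lineage_muts, causal, params, manifest)

  induced <- do.call(rbind, lapply(lineages, function(lg) {
    m <- lineage_muts[[lg]]
    if (!nrow(m)) return(NULL)
    cbind(data.frame(lineage = lg, stringsAsFactors = FALSE), m)
  }))
  induced$is_causal <- induced$chrom == causal$chrom &
    induced$pos == causal$pos

  sites <- rbind(
    data.frame(chrom = induced$chrom, pos = induced$pos,
               ref = induced$ref, alt = induced$alt,
               category = "induced", lineage = induced$lineage,
               error_prone = FALSE, stringsAsFactors = FALSE),
    data.frame(chrom = ep$chrom, pos = ep$pos, ref = ep$ref,
               alt = ep$alt, category = "error_prone",
               lineage = NA_character_, error_prone = TRUE,
               stringsAsFactors = FALSE),
    data.frame(chrom = bg$chrom, pos = bg$pos, ref = bg$ref,
               alt = bg$alt, category = "background",
               lineage = NA_character_, error_prone = FALSE,
               stringsAsFactors = FALSE))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  dosages <- pool_dosage(ped$individuals, sites)
  dosages[sites$category == "background", ] <- 1

  counts_list <- list()
  for (i in seq_len(nrow(manifest))) {
    ln <- manifest$line_id[i]
    cl <- sample_read_counts(sites, dosages[, ln], ln,
                             manifest$target_depth[i],
                             params$seq_error_rate,
                             params$error_prone_alt_prob)
    if (params$n_singleton_sites > 0) {
      sg <- sample_positions(genome, params$n_singleton_sites,
                             c(used, paste(cl$chrom, cl$pos)))
      sg$ref <- base_at(genome, sg$chrom, sg$pos)
      sg$alt <- vapply(sg$ref, function(r) sample(setdiff(BASES, r), 1),
                       character(1), USE.NAMES = FALSE)
      d <- pmax(1L, stats::rpois(nrow(sg), manifest$target_depth[i]))
      af <- stats::rbinom(nrow(sg), 1, 0.5)
      rf <- stats::rbinom(nrow(sg), d - 1L, 0.5)
      cl <- rbind(cl, data.frame(
        line_id = ln, chrom = sg$chrom, pos = sg$pos, ref = sg$ref,
        alt = sg$alt, ref_fwd = rf, ref_rev = d - 1L - rf,
        alt_fwd = af, alt_rev = 1L - af,
        rms_mapq = pmax(0, round(stats::rnorm(nrow(sg), 48, 3), 1)),
        stringsAsFactors = FALSE))
    }
    cl <- cl[order(cl$chrom, cl$pos), , drop = FALSE]
    rownames(cl) <- NULL
    counts_list[[ln]] <- cl
  }
  counts <- do.call(rbind, counts_list)
  rownames(counts) <- NULL

  calls <- lapply(counts_list, call_all, e = params$seq_error_rate)

  genotypes <- lapply(ped$individuals, function(pool) {
    g <- vapply(pool, genotypes_at_sites, integer(nrow(sites)),
                sites = sites)
    if (nrow(sites) == 1L) g <- matrix(g, nrow = 1)
    g
  })

  truth <- list(
    induced_mutations = induced,
    causal_site = causal,
    error_prone_sites = ep,
    background_variants = bg,
    indel_sites = indels,
    crossover_breakpoints = ped$crossover_breakpoints,
    segregation_counts = as.list(ped$segregation_counts),
    site_key = paste(sites$chrom, sites$pos),
    pool_dosages = dosages,
    genotype_matrix = genotypes
  )

  structure(list(params = params, manifest = manifest, genome = genome,
                 genes = ref$genes, counts = counts,
                 counts_by_line = counts_list, calls = calls,
                 truth = truth),
            class = "ems_simulation")
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.gff3`, one `<line>.vcf` and
#' `<line>.counts.tsv` per line, `pedigree.yaml` and `truth.json`. With
#' a fixed seed the file set is byte-identical across runs.
#'
#' @param sim an `ems_simulation` from [simulate_ems_study()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
emit_dataset <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create directory: ",
                                         outdir)
  }
  if (file.access(outdir, 2) != 0) stop("directory not writable: ",
                                        outdir)
  paths <- c(
    genome = file.path(outdir, "genome.fa"),
    genes = file.path(outdir, "genes.gff3"),
    manifest = file.path(outdir, "pedigree.yaml"),
    truth = file.path(outdir, "truth.json"))
  write_fasta(sim$genome, paths[["genome"]])
  write_gene_models(sim$genes, paths[["genes"]])
  write_manifest(sim$manifest, paths[["manifest"]])
  truth <- sim$truth
  truth$pool_dosages <- NULL       # large derived matrices stay in R
  truth$genotype_matrix <- NULL
  write_truth(truth, paths[["truth"]])
  for (ln in sim$manifest$line_id) {
    vp <- file.path(outdir, paste0(ln, ".vcf"))
    cp <- file.path(outdir, paste0(ln, ".counts.tsv"))
    write_variant_calls(variant_calls(sim$calls[[ln]]), vp,
                        sample_id = ln)
    write_allele_counts(sim$counts_by_line[[ln]], cp)
    paths <- c(paths, vp, cp)
  }
  invisible(paths)
}
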