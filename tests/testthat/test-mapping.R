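counts_for <- function(line, pos, alt_n, ref_n, chrom = "chr1") {
  af <- alt_n %/% 2L
  rf <- ref_n %/% 2L
  data.frame(line_id = line, chrom = chrom, pos = as.integer(pos),
             ref = "G", alt = "A", ref_fwd = rf, ref_rev = ref_n - rf,
             alt_fwd = af, alt_rev = alt_n - af, rms_mapq = 50,
             stringsAsFactors = FALSE)
}

test_that("allele frequencies come straight from raw counts", {
  ct <- rbind(counts_for("q", 10, 0L, 10L), counts_for("q", 20, 10L, 0L),
              counts_for("q", 30, 5L, 15L))
  pos <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L))
  f <- allele_frequencies_at(pos, ct, "q")
  expect_equal(f$freq, c(0, 1, 0.25))
  expect_equal(f$depth, c(10L, 10L, 20L))
})

test_that("uncovered marker positions are reported missing with a warning", {
  ct <- counts_for("q", 10, 3L, 3L)
  pos <- data.frame(chrom = "chr1", pos = c(10L, 99L))
  expect_warning(f <- allele_frequencies_at(pos, ct, "q"),
                 "lack coverage")
  expect_true(is.na(f$freq[f$pos == 99L]))
  expect_equal(attr(f, "n_missing"), 1L)
})

test_that("het-sibling frequencies concentrate around one half", {
  sim <- demo_sim()
  idx <- which(sim$truth$genotype_matrix[["10-3"]][, 1] == 1L)
  keys <- sim$truth$site_key[idx]
  parts <- strsplit(keys, " ", fixed = TRUE)
  pos <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                    pos = as.integer(vapply(parts, `[[`, "", 2)))
  f <- suppressWarnings(
    allele_frequencies_at(pos, sim$counts, "10-3"))
  f <- f[!is.na(f$freq), ]
  total_reads <- sum(f$depth)
  se <- sqrt(0.25 / total_reads)
  expect_lt(abs(weighted.mean(f$freq, f$depth) - 0.5), 3 * se + 0.02)
})

test_that("interval detection finds exactly the planted low-frequency run", {
  pos <- seq(1000L, 20000L, by = 1000L)
  freq <- rep(1, length(pos))
  freq[8:12] <- 0.05
  rows <- data.frame(chrom = "chr1", pos = pos, query_line = "wt",
                     freq = freq, depth = 40L)
  params <- pipeline_params(min_interval_markers = 3)
  iv <- detect_linked_interval(rows, params)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, pos[8])
  expect_equal(iv$end, pos[12])
  expect_equal(iv$n_supporting_markers, 5L)
  # all-high frequencies: nothing qualifies
  none <- detect_linked_interval(
    transform(rows, freq = 1), params)
  expect_equal(nrow(none), 0L)
  # runs shorter than the marker minimum do not qualify
  short <- transform(rows, freq = replace(rep(1, length(pos)), 3:4,
                                          0))
  expect_equal(nrow(detect_linked_interval(short, params)), 0L)
})

test_that("intervals rank by marker count, then mean frequency", {
  pos <- seq(1000L, 30000L, by = 1000L)
  freq <- rep(1, length(pos))
  freq[2:6] <- 0.1      # five markers
  freq[20:23] <- 0.0    # four markers, cleaner
  rows <- data.frame(chrom = "chr1", pos = pos, query_line = "wt",
                     freq = freq, depth = 40L)
  iv <- detect_linked_interval(rows, pipeline_params())
  expect_equal(iv$n_supporting_markers, c(5L, 4L))
  expect_equal(iv$start[1], pos[2])
})

role_counts <- function(pos, mut, het, wt, depth = 30L) {
  rbind(counts_for("10-d", pos, as.integer(round(mut * depth)),
                   depth - as.integer(round(mut * depth))),
        counts_for("10-3", pos, as.integer(round(het * depth)),
                   depth - as.integer(round(het * depth))),
        counts_for("10-2", pos, as.integer(round(wt * depth)),
                   depth - as.integer(round(wt * depth))))
}

man5 <- data.frame(
  line_id = c("10-2", "10-3", "10-d"),
  lineage_id = "L10",
  role = c("wt_sibling", "het_sibling", "mutant_pool"),
  pool_size = 1L, target_depth = 30, stringsAsFactors = FALSE)

test_that("pedigree consistency verdicts follow the role thresholds", {
  cand <- data.frame(chrom = "chr1", pos = 10L, ref = "G", alt = "A",
                     stringsAsFactors = FALSE)
  pass <- pedigree_consistency_filter(cand, role_counts(10, 1, 0.5, 0),
                                      man5)
  expect_identical(pass$verdict, "pass")
  shared <- pedigree_consistency_filter(cand, role_counts(10, 1, 1, 1),
                                        man5)
  expect_identical(shared$verdict, "fail")
  wt_bad <- pedigree_consistency_filter(cand,
                                        role_counts(10, 1, 0.5, 0.9),
                                        man5)
  expect_identical(wt_bad$verdict, "fail")
})

test_that("thin coverage yields insufficient_coverage, not exclusion", {
  cand <- data.frame(chrom = "chr1", pos = 10L, ref = "G", alt = "A",
                     stringsAsFactors = FALSE)
  thin_het <- rbind(counts_for("10-d", 10, 30L, 0L),
                    counts_for("10-3", 10, 2L, 2L),
                    counts_for("10-2", 10, 0L, 30L))
  got <- pedigree_consistency_filter(cand, thin_het, man5)
  expect_identical(got$verdict, "insufficient_coverage")
  expect_match(got$reason, "het_sib:insufficient")
  # a role absent from the manifest is an error
  expect_error(
    pedigree_consistency_filter(cand, thin_het,
                                man5[man5$role != "het_sibling", ]),
    "het_sibling")
})

test_that("candidate ranking is a nested non-increasing chain", {
  rep <- demo_report()
  led <- rep$ledger
  n <- led$n[!is.na(led$n)]
  expect_true(all(diff(n) <= 0))
  expect_true(all(c("cascade_survivors", "lineage_unique",
                    "coding_changing", "pedigree_consistent") %in%
                    led$step))
  # finals are a subset of the judged coding candidates
  expect_true(all(paste(rep$final$chrom, rep$final$pos) %in%
                    paste(rep$candidates$chrom, rep$candidates$pos)))
})

test_that("a missing interval skips the interval step with a flag", {
  cand <- data.frame(chrom = "chr1", pos = 10L, ref = "G", alt = "A",
                     stringsAsFactors = FALSE)
  eff <- data.frame(category = "missense", impact = "MODERATE",
                    gene_id = "g1", codon_change = "gCc/gTc",
                    aa_change = "A2V", stringsAsFactors = FALSE)
  no_iv <- detect_linked_interval(
    data.frame(chrom = character(), pos = integer(),
               query_line = character(), freq = numeric(),
               depth = integer()), pipeline_params())
  rk <- rank_candidates(cand, eff, role_counts(10, 1, 0.5, 0), man5,
                        no_iv)
  expect_true(is.na(rk$ledger$n[rk$ledger$step ==
                                  "in_mapping_interval"]))
  expect_match(rk$ledger$note[rk$ledger$step == "in_mapping_interval"],
               "skipped")
  expect_equal(nrow(rk$final), 1L)
})

test_that("lingering artifact markers show impossible frequencies", {
  # an error-prone position that slipped through in one line presents
  # an intermediate frequency no single selfed individual can have
  sim <- demo_sim()
  ep <- sim$truth$error_prone_sites
  f <- suppressWarnings(allele_frequencies_at(
    data.frame(chrom = ep$chrom, pos = ep$pos), sim$counts, "10-2"))
  f <- f[!is.na(f$freq) & f$depth >= 20, ]
  # spurious reads drive these sites toward fixed high frequency in
  # every line regardless of genotype
  expect_gt(mean(f$freq > 0.9), 0.9)
})
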