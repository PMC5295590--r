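#' Run the full mapping pipeline end to end
#'
#' Orchestrates every stage on either a fresh simulation (demo mode) or
#' a dataset directory written by [emit_dataset()]: genotype calling
#' from allele counts, the per-line quality-filter cascade,
#' cross-lineage false-positive subtraction, effect annotation,
#' allele-frequency cosegregation mapping and candidate ranking. All
#' intermediates are returned and, when `outdir` is given, persisted as
#' TSV/VCF so every number in the final report is recomputable from
#' disk.
#'
#' @param sim_params a [sim_params()] for demo mode (ignored when
#'   `input_dir` is given).
#' @param params a [pipeline_params()].
#' @param input_dir directory holding `genome.fa`, `genes.gff3`,
#'   `pedigree.yaml`, `<line>.counts.tsv` and (optionally) `truth.json`,
#'   as written by [emit_dataset()].
#' @param outdir optional output directory for artifacts.
#' @return list of class `mapping_report`: `ledger`, `final`
#'   (candidates), `candidates` (all judged coding candidates),
#'   `intervals`, `hormigas`, `unique_summary`, `cascade_reports`,
#'   `survivor_sets`, `venn`, `manifest`, `truth` (when available) and
#'   `params`.
#' @export
run_end_to_end <- function(sim_params = NULL,
                           params = pipeline_params(),
                           input_dir = NULL, outdir = NULL) {
  if (is.null(input_dir)) {
    if (is.null(sim_params)) sim_params <- evilmap::sim_params()
    sim <- simulate_ems_study(sim_params)
    genome <- sim$genome; genes <- sim$genes
    manifest <- sim$manifest; counts_by_line <- sim$counts_by_line
    calls <- sim$calls; truth <- sim$truth
    err <- sim_params$seq_error_rate
  } else {
    genome <- read_fasta(file.path(input_dir, "genome.fa"))
    genes <- read_gene_models(file.path(input_dir, "genes.gff3"))
    manifest <- read_manifest(file.path(input_dir, "pedigree.yaml"))
    counts_by_line <- lapply(manifest$line_id, function(ln) {
      read_allele_counts(file.path(input_dir,
                                   paste0(ln, ".counts.tsv")))
    })
    names(counts_by_line) <- manifest$line_id
    truth_path <- file.path(input_dir, "truth.json")
    truth <- if (file.exists(truth_path)) read_truth(truth_path) else
      NULL
    err <- if (!is.null(sim_params)) sim_params$seq_error_rate else
      0.001
    calls <- lapply(counts_by_line, call_all, e = err)
  }
  counts <- do.call(rbind, counts_by_line)
  rownames(counts) <- NULL
  indels <- if (!is.null(truth)) truth$indel_sites else NULL

  cascades <- lapply(manifest$line_id, function(ln) {
    run_cascade(variant_calls(calls[[ln]]), params, indels,
                line_id = ln)
  })
  names(cascades) <- manifest$line_id
  sets <- lapply(cascades, function(x)
    x$survivors[, c("chrom", "pos", "ref", "alt"), drop = FALSE])
  reports <- lapply(cascades, `[[`, "report")

  tab_unique <- unique_summary(manifest, sets, genes)

  mut_ln <- role_line(manifest, "mutant_pool")
  het_ln <- role_line(manifest, "het_sibling")
  wt_ln <- role_line(manifest, "wt_sibling")
  mut_unique <- subtract_other_lineages(mut_ln, manifest, sets)

  other_lineages <- setdiff(unique(manifest$lineage_id),
                            manifest$lineage_id[manifest$line_id ==
                                                  mut_ln])
  venn <- NULL
  if (length(other_lineages) == 2) {
    ol <- vapply(other_lineages, function(lg)
      manifest$line_id[manifest$lineage_id == lg][1], character(1))
    venn <- venn_counts(stats::setNames(
      list(sets[[mut_ln]], sets[[ol[1]]], sets[[ol[2]]]),
      c(mut_ln, ol)))
  }

  markers <- mut_unique[, c("chrom", "pos"), drop = FALSE]
  horm_wt <- suppressWarnings(
    allele_frequencies_at(markers, counts, wt_ln))
  horm_het <- suppressWarnings(
    allele_frequencies_at(markers, counts, het_ln))
  hormigas <- rbind(horm_wt, horm_het)
  intervals <- detect_linked_interval(horm_wt, params)

  sib_keys <- unique(c(site_key(sets[[wt_ln]]),
                       site_key(sets[[het_ln]])))
  candidates <- mut_unique[!site_key(mut_unique) %in% sib_keys, ,
                           drop = FALSE]
  effects <- classify_snps(candidates, genes, genome)
  ranked <- rank_candidates(candidates, effects, counts, manifest,
                            intervals, params)
  ledger <- rbind(
    data.frame(step = c("cascade_survivors", "lineage_unique",
                        "not_in_siblings"),
               n = c(nrow(sets[[mut_ln]]), nrow(mut_unique),
                     nrow(candidates)),
               note = c(mut_ln, "", ""), stringsAsFactors = FALSE),
    ranked$ledger[-1, ])
  rownames(ledger) <- NULL

  report <- structure(list(
    ledger = ledger, final = ranked$final,
    candidates = ranked$candidates, intervals = intervals,
    hormigas = hormigas, unique_summary = tab_unique,
    cascade_reports = reports, survivor_sets = sets, venn = venn,
    manifest = manifest, truth = truth, params = params
  ), class = "mapping_report")

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    for (ln in manifest$line_id) {
      write_variant_calls(cascades[[ln]]$survivors,
                          file.path(outdir,
                                    paste0(ln, ".filtered.vcf")),
                          sample_id = ln)
      write_tsv_report(sets[[ln]],
                       file.path(outdir, paste0(ln, ".unique.tsv")))
    }
    write_tsv_report(do.call(rbind, reports),
                     file.path(outdir, "filter_report.tsv"))
    write_tsv_report(tab_unique, file.path(outdir,
                                           "unique_summary.tsv"))
    write_tsv_report(hormigas, file.path(outdir, "hormigas.tsv"))
    write_tsv_report(intervals, file.path(outdir, "intervals.tsv"))
    write_tsv_report(ranked$candidates,
                     file.path(outdir, "candidates.tsv"))
    write_tsv_report(ledger, file.path(outdir, "ledger.tsv"))
    if (!is.null(venn)) {
      write_tsv_report(venn, file.path(outdir, "venn.tsv"))
    }
  }
  report
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("EMS mapping report\n")
  cat("------------------\n")
  ledger <- x$ledger
  for (i in seq_len(nrow(ledger))) {
    cat(sprintf("%-22s %6s  %s\n", ledger$step[i],
                ifelse(is.na(ledger$n[i]), "-", ledger$n[i]),
                ledger$note[i]))
  }
  if (nrow(x$final)) {
    cat("\nFinal candidate(s):\n")
    cols <- intersect(c("chrom", "pos", "ref", "alt", "gene_id",
                        "codon_change", "aa_change", "verdict"),
                      names(x$final))
    print(x$final[, cols], row.names = FALSE)
  } else {
    cat("\nNo candidate satisfied all filters.\n")
  }
  invisible(x)
}
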