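#' Read and write per-position allele-count tables
#'
#' The allele-count table is the re-pileup surface used for
#' allele-frequency mapping: one row per (line, genomic position) with
#' reference and alternate read counts split by strand, covering variant
#' and non-variant sites alike. Columns: `line_id`, `chrom`, `pos`,
#' `ref`, `alt`, `ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`, `rms_mapq`.
#'
#' @param counts data.frame as described above.
#' @param path file path.
#' @return `read_allele_counts()` returns the counts data.frame.
#' @export
write_allele_counts <- function(counts, path) {
  write_tsv_report(counts, path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  x <- read_tsv_report(path)
  need <- c("line_id", "chrom", "pos", "ref", "alt",
            "ref_fwd", "ref_rev", "alt_fwd", "alt_rev")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("allele-count table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  x$pos <- as.integer(x$pos)
  for (cc in c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")) {
    x[[cc]] <- as.integer(x[[cc]])
  }
  x
}

#' Read and write the pedigree manifest
#'
#' The manifest lists each sequenced line, the mutagenesis lineage it
#' descends from, its role in the mapping design (`mutant_pool`,
#' `het_sibling`, `wt_sibling` or `unrelated`), the number of pooled
#' individuals and the target sequencing depth.
#'
#' @param manifest manifest data.frame (see [default_manifest()]).
#' @param path YAML file path.
#' @return `read_manifest()` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  entries <- lapply(seq_len(nrow(manifest)), function(i) {
    list(line_id = manifest$line_id[i],
         lineage_id = manifest$lineage_id[i],
         role = manifest$role[i],
         pool_size = manifest$pool_size[i],
         target_depth = manifest$target_depth[i])
  })
  yaml::write_yaml(list(lines = entries), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$lines)) stop("manifest YAML must have a 'lines' list")
  df <- do.call(rbind, lapply(y$lines, function(e) {
    data.frame(line_id = e$line_id, lineage_id = e$lineage_id,
               role = e$role, pool_size = as.integer(e$pool_size),
               target_depth = as.numeric(e$target_depth),
               stringsAsFactors = FALSE)
  }))
  validate_manifest(df)
  df
}

#' Read and write the simulation truth set
#'
#' The truth set records everything the simulator planted — induced
#' mutations per lineage, the causal site, error-prone positions,
#' background variants, indel positions and crossover breakpoints — and
#' is the oracle for recovery tests. Stored as JSON.
#'
#' @param truth truth list (component `truth` of [simulate_ems_study()]).
#' @param path JSON file path.
#' @return `read_truth()` returns the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("induced_mutations", "error_prone_sites",
               "background_variants", "indel_sites")) {
    if (!is.null(out[[nm]])) out[[nm]] <- as.data.frame(out[[nm]])
  }
  out
}
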