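# On-disk layout of a cohort directory:
#   gene_model.tsv            exon spans (exon_id, cdna_start, cdna_end)
#   reference.fasta           single-record coding reference
#   samples.tsv               manifest: sample_id, group, file
#   <sample_id>.fasta         one multi-FASTA per sample, record ids
#                             "<sample_id>|<exon_id>"
#   catalogue.tsv             planted events (simulated cohorts only)

#' Write a gene model to a TSV plus reference FASTA
#'
#' @param model A [gene_model()].
#' @param path Output path for the exon-span TSV.
#' @param reference_fasta Output path for the reference FASTA.
#' @return Invisibly, the two paths.
#' @export
write_gene_model <- function(model, path, reference_fasta) {
  stopifnot(inherits(model, "gene_model"))
  utils::write.table(model$exons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ref <- Biostrings::DNAStringSet(model$reference_cdna)
  names(ref) <- model$gene_name
  Biostrings::writeXStringSet(ref, reference_fasta)
  invisible(c(path, reference_fasta))
}

#' Write a cohort to a directory of per-sample FASTA files
#'
#' Each sample becomes one multi-FASTA with record ids
#' \code{"<sample_id>|<exon_id>"}; a \code{samples.tsv} manifest records the
#' group of each sample, and the gene model is written alongside so the
#' directory is self-contained.
#'
#' @param cohort A list with \code{model}, \code{samples} and optionally
#'   \code{catalogue}, as returned by [build_fixture_cohort()] or
#'   [random_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort), !is.null(cohort$model), !is.null(cohort$samples))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  write_gene_model(cohort$model, file.path(dir, "gene_model.tsv"),
                   file.path(dir, "reference.fasta"))
  manifest <- data.frame(
    sample_id = vapply(cohort$samples, `[[`, character(1), "sample_id"),
    group = vapply(cohort$samples, `[[`, character(1), "group"))
  manifest$file <- paste0(manifest$sample_id, ".fasta")
  utils::write.table(manifest, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (rec in cohort$samples) {
    seqs <- Biostrings::DNAStringSet(unlist(rec$exon_seqs))
    names(seqs) <- paste0(rec$sample_id, "|", names(rec$exon_seqs))
    Biostrings::writeXStringSet(seqs,
                                file.path(dir, paste0(rec$sample_id, ".fasta")))
  }
  if (!is.null(cohort$catalogue))
    utils::write.table(cohort$catalogue, file.path(dir, "catalogue.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A list with \code{model}, \code{samples} and \code{catalogue}
#'   (NULL when no catalogue file is present).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  manifest_path <- file.path(dir, "samples.tsv")
  if (!file.exists(manifest_path))
    stop("no samples.tsv manifest in ", dir)
  model <- load_gene_model(file.path(dir, "gene_model.tsv"),
                           file.path(dir, "reference.fasta"))
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    fa <- Biostrings::readDNAStringSet(file.path(dir, manifest$file[i]))
    ids <- sub("^.*\\|", "", names(fa))
    seqs <- stats::setNames(as.list(as.character(fa)), ids)
    sample_record(manifest$sample_id[i], manifest$group[i], seqs)
  })
  cat_path <- file.path(dir, "catalogue.tsv")
  catalogue <- if (file.exists(cat_path))
    utils::read.delim(cat_path, stringsAsFactors = FALSE) else NULL
  list(model = model, samples = samples, catalogue = catalogue)
}

# header lines echoing the run configuration, prepended to every output TSV
config_header <- function(summary, extra = character(0)) {
  s <- summary$scheme
  c(sprintf("# gene=%s", summary$model$gene_name),
    sprintf("# group=%s n_samples=%d", summary$group, summary$n_samples),
    sprintf("# scheme: match=%g mismatch=%g gap_open=%g gap_extend=%g",
            s$match, s$mismatch, s$gap_open, s$gap_extend),
    extra)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write cohort-summary artifacts to a directory
#'
#' Emits \code{summary.tsv} (sample tallies), \code{variants.tsv} (flat call
#' list), \code{histogram.tsv} (per-exon counts) and \code{hotspots.tsv},
#' each prefixed with a commented header echoing the configuration so a run
#' is reproducible from its outputs.
#'
#' @param summary A [compare_cohort()] result.
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix, e.g. the group name.
#' @param hotspot_width,hotspot_min Parameters for [hotspot_windows()].
#' @return Invisibly, the paths written.
#' @export
write_cohort_summary <- function(summary, dir, prefix = summary$group,
                                 hotspot_width = 50L, hotspot_min = 4L) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- config_header(summary)
  paths <- file.path(dir, paste0(prefix, "_", c("summary", "variants",
                                                "histogram", "hotspots"),
                                 ".tsv"))
  tallies <- data.frame(metric = c("n_samples", "n_altered", "n_unaltered",
                                   "n_events"),
                        value = c(summary$n_samples, summary$n_altered,
                                  summary$n_unaltered, nrow(summary$variants)))
  write_tsv_with_header(tallies, paths[1], hdr)
  write_tsv_with_header(
    summary$variants[, c("sample_id", "exon_id", "name", "kind",
                         "cdna_start", "cdna_end", "ref", "alt")],
    paths[2], hdr)
  write_tsv_with_header(exon_histogram(summary), paths[3], hdr)
  hs <- hotspot_windows(summary, hotspot_width, hotspot_min)
  write_tsv_with_header(
    hs, paths[4],
    config_header(summary, sprintf("# hotspot: width=%d min_events=%d",
                                   hotspot_width, hotspot_min)))
  invisible(paths)
}
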