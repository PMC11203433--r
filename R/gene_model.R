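#' Build a gene model
#'
#' A gene model ties together a coding (cDNA) reference sequence and the exon
#' structure laid over it. All coordinates in the package are 1-based inclusive
#' cDNA (c.) positions, with c.1 the first base of \code{reference_cdna}. Exon
#' spans must start at 1, be contiguous (each exon starts one base after the
#' previous one ends) and jointly cover the reference exactly; introns are not
#' modeled because samples are supplied and compared exon by exon.
#'
#' @param gene_name Character scalar naming the gene.
#' @param reference_cdna Coding reference sequence, a character scalar over
#'   \code{A,C,G,T}.
#' @param exons A \code{data.frame} with columns \code{exon_id} (integer
#'   labels), \code{cdna_start} and \code{cdna_end} (1-based inclusive).
#' @return An object of class \code{"gene_model"}: a list with elements
#'   \code{gene_name}, \code{reference_cdna} and \code{exons}.
#' @seealso [load_gene_model()], [exon_of()], [exon_local_to_cdna()]
#' @examples
#' m <- gene_model("demo", "ACGTACGTACGT",
#'                 data.frame(exon_id = 1L, cdna_start = 1L, cdna_end = 12L))
#' exon_of(m, 5)
#' @export
gene_model <- function(gene_name, reference_cdna, exons) {
  stopifnot(is.character(gene_name), length(gene_name) == 1L,
            is.character(reference_cdna), length(reference_cdna) == 1L,
            is.data.frame(exons))
  req <- c("exon_id", "cdna_start", "cdna_end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols))
    stop("gene model table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  exons <- data.frame(exon_id = as.integer(exons$exon_id),
                      cdna_start = as.integer(exons$cdna_start),
                      cdna_end = as.integer(exons$cdna_end))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  if (anyNA(exons)) stop("gene model table contains missing values")

  reference_cdna <- toupper(reference_cdna)
  bad <- which(!strsplit(reference_cdna, "", fixed = TRUE)[[1]] %in%
                 c("A", "C", "G", "T"))
  if (length(bad))
    stop("reference sequence contains non-ACGT character(s) at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))

  exons <- exons[order(exons$cdna_start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$cdna_start > exons$cdna_end)) {
    off <- exons$exon_id[which(exons$cdna_start > exons$cdna_end)[1]]
    stop("exon ", off, " has cdna_start > cdna_end")
  }
  if (anyDuplicated(exons$exon_id))
    stop("duplicated exon_id: ",
         exons$exon_id[anyDuplicated(exons$exon_id)])
  if (exons$cdna_start[1] != 1L)
    stop("exon ", exons$exon_id[1], " must start at cDNA position 1, not ",
         exons$cdna_start[1])
  if (nrow(exons) > 1L) {
    gap <- which(exons$cdna_start[-1] != exons$cdna_end[-nrow(exons)] + 1L)
    if (length(gap)) {
      off <- exons$exon_id[gap[1] + 1L]
      prev <- exons$exon_id[gap[1]]
      if (exons$cdna_start[gap[1] + 1L] <= exons$cdna_end[gap[1]])
        stop("exon ", off, " overlaps exon ", prev)
      stop("exon ", off, " is not contiguous with exon ", prev)
    }
  }
  if (exons$cdna_end[nrow(exons)] != nchar(reference_cdna))
    stop("exon spans cover 1..", exons$cdna_end[nrow(exons)],
         " but the reference has ", nchar(reference_cdna), " bases")

  structure(list(gene_name = gene_name,
                 reference_cdna = reference_cdna,
                 exons = exons),
            class = "gene_model")
}

#' Load a gene model from a TSV file plus a reference FASTA
#'
#' The TSV needs a header line with columns \code{exon_id}, \code{cdna_start}
#' and \code{cdna_end}; the companion FASTA must hold a single record carrying
#' the full coding reference. Validation errors name the offending exon or
#' reference position.
#'
#' @param path Path to the exon-span TSV.
#' @param reference_fasta Path to the single-record reference FASTA.
#' @param gene_name Optional gene name; defaults to the FASTA record id.
#' @return A validated [gene_model()].
#' @examples
#' tsv <- system.file("extdata", "demo_gene_model.tsv", package = "exonmut")
#' fa  <- system.file("extdata", "demo_reference.fasta", package = "exonmut")
#' load_gene_model(tsv, fa)
#' @export
load_gene_model <- function(path, reference_fasta, gene_name = NULL) {
  if (!file.exists(path)) stop("gene-model file not found: ", path)
  if (!file.exists(reference_fasta))
    stop("reference FASTA not found: ", reference_fasta)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  fa <- Biostrings::readDNAStringSet(reference_fasta)
  if (length(fa) != 1L)
    stop("reference FASTA must contain exactly one record, found ", length(fa))
  if (is.null(gene_name))
    gene_name <- sub("\\s.*$", "", names(fa)[1])
  gene_model(gene_name, as.character(fa[[1]]), tab)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", x$gene_name, "\n")
  cat("  reference cDNA:", nchar(x$reference_cdna), "nt\n")
  cat("  exons:", nrow(x$exons),
      sprintf("(%s)", paste0(x$exons$exon_id, ":", x$exons$cdna_start, "-",
                             x$exons$cdna_end, collapse = " ")), "\n")
  invisible(x)
}

#' Map a cDNA position to its exon
#'
#' @param model A [gene_model()].
#' @param cdna_pos 1-based cDNA position(s).
#' @return Integer exon id(s); vectorized over \code{cdna_pos}.
#' @examples
#' m <- tp53_gene_model()
#' exon_of(m, c(404, 994))  # exon 5 and exon 10
#' @export
exon_of <- function(model, cdna_pos) {
  stopifnot(inherits(model, "gene_model"))
  cdna_pos <- as.integer(cdna_pos)
  n <- nchar(model$reference_cdna)
  if (any(is.na(cdna_pos)) || any(cdna_pos < 1L) || any(cdna_pos > n))
    stop("cDNA position out of range 1..", n, ": ",
         paste(cdna_pos[is.na(cdna_pos) | cdna_pos < 1L | cdna_pos > n],
               collapse = ", "))
  idx <- findInterval(cdna_pos, model$exons$cdna_start)
  model$exons$exon_id[idx]
}

# internal: row of the exon table for one exon id
exon_row <- function(model, exon_id) {
  i <- match(as.integer(exon_id), model$exons$exon_id)
  if (is.na(i)) stop("unknown exon_id: ", exon_id)
  model$exons[i, , drop = FALSE]
}

#' Convert between exon-local and cDNA coordinates
#'
#' Samples enter the pipeline one exon at a time, so variant positions are
#' first observed relative to an exon and must be lifted to cDNA coordinates
#' (and back). \code{exon_local_to_cdna(model, e, 1)} is exon \code{e}'s
#' \code{cdna_start}; the two functions are inverses.
#'
#' @param model A [gene_model()].
#' @param exon_id Exon label present in the model.
#' @param local_pos 1-based offset within the exon.
#' @return \code{exon_local_to_cdna}: integer cDNA position(s).
#'   \code{cdna_to_exon_local}: a list with \code{exon_id} and \code{local_pos}.
#' @examples
#' m <- tp53_gene_model()
#' exon_local_to_cdna(m, 5, 1)     # 376
#' cdna_to_exon_local(m, 376)      # exon 5, local 1
#' @export
exon_local_to_cdna <- function(model, exon_id, local_pos) {
  row <- exon_row(model, exon_id)
  local_pos <- as.integer(local_pos)
  len <- row$cdna_end - row$cdna_start + 1L
  if (any(is.na(local_pos)) || any(local_pos < 1L) || any(local_pos > len))
    stop("local position out of range 1..", len, " for exon ", row$exon_id)
  row$cdna_start + local_pos - 1L
}

#' @rdname exon_local_to_cdna
#' @param cdna_pos 1-based cDNA position.
#' @export
cdna_to_exon_local <- function(model, cdna_pos) {
  e <- exon_of(model, cdna_pos)
  starts <- model$exons$cdna_start[match(e, model$exons$exon_id)]
  list(exon_id = e, local_pos = as.integer(cdna_pos) - starts + 1L)
}

#' Extract the reference sequence of one exon
#'
#' @param model A [gene_model()].
#' @param exon_id Exon label present in the model.
#' @return Character scalar, the exon's slice of the reference cDNA.
#' @export
exon_sequence <- function(model, exon_id) {
  row <- exon_row(model, exon_id)
  substr(model$reference_cdna, row$cdna_start, row$cdna_end)
}

# Exon spans of the default TP53-like coding model (coding exons 2..11).
# Chosen to be consistent with the cDNA positions the package's bundled
# variant catalogue assigns to each exon; frozen as package data.
tp53_exon_table <- function() {
  data.frame(
    exon_id    = 2:11,
    cdna_start = c(1L, 75L, 97L, 376L, 561L, 673L, 783L, 920L, 994L, 1101L),
    cdna_end   = c(74L, 96L, 375L, 560L, 672L, 782L, 919L, 993L, 1100L, 1182L)
  )
}
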