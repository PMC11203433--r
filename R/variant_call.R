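# Variants travel as plain data.frames with one row per event and columns
#   kind        substitution | deletion | insertion
#   cdna_start  1-based cDNA position (insertions: 5' anchor base)
#   cdna_end    = cdna_start for substitutions and 1-base deletions;
#                 deletion: last deleted base; insertion: cdna_start + 1
#   ref         deleted/substituted reference bases ("" for insertions)
#   alt         substituted/inserted bases ("" for deletions)
#   exon_id     exon containing the event
#   name        formatted c.-notation string

empty_variants <- function() {
  data.frame(kind = character(0), cdna_start = integer(0),
             cdna_end = integer(0), ref = character(0), alt = character(0),
             exon_id = integer(0), name = character(0))
}

new_variants <- function(kind, cdna_start, cdna_end, ref, alt) {
  data.frame(kind = as.character(kind), cdna_start = as.integer(cdna_start),
             cdna_end = as.integer(cdna_end), ref = as.character(ref),
             alt = as.character(alt), exon_id = NA_integer_,
             name = NA_character_)
}

# fill exon_id and name, sort by position; shared by caller and simulator
annotate_variants <- function(v, model, dialect = "paper", sort = TRUE) {
  if (nrow(v) == 0L) return(empty_variants())
  v$exon_id <- exon_of(model, pmax(v$cdna_start, 1L))
  v$name <- format_variant(v, dialect = dialect)
  if (sort)
    v <- v[order(v$cdna_start, v$cdna_end, v$kind), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Call variants from an exon alignment
#'
#' Walks the alignment columns and converts them into variant events in cDNA
#' coordinates: mismatch columns become single-nucleotide substitutions,
#' maximal runs of gap columns in the sample row become one (possibly
#' multi-base) deletion, and maximal runs of gap columns in the reference row
#' become one insertion anchored between its flanking reference bases.
#' Indels are then shifted to their 3'-most equivalent position
#' ([normalize_3prime()]) before naming. Columns where the sample base is N
#' are skipped with a warning. Identical sequences yield a zero-row table.
#'
#' @param aln A [global_align()] result whose degapped reference row equals
#'   the model's sequence for \code{exon_id}.
#' @param model A [gene_model()].
#' @param exon_id Exon the alignment belongs to.
#' @param dialect Naming dialect passed to [format_variant()].
#' @return A variant \code{data.frame} (see package overview), sorted by
#'   \code{cdna_start}.
#' @examples
#' m <- tp53_gene_model()
#' ref <- exon_sequence(m, 5)
#' mut <- apply_variant(ref, parse_variant("c.404G>T", m), m)
#' call_variants(global_align(ref, mut), m, 5)$name  # "c.404G>T"
#' @export
call_variants <- function(aln, model, exon_id, dialect = "paper") {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(model, "gene_model"))
  cols <- alignment_columns(aln)
  ref_seq <- paste(cols$ref[cols$ref != "-"], collapse = "")
  if (!identical(ref_seq, exon_sequence(model, exon_id)))
    stop("degapped reference row does not match the model's sequence for exon ",
         exon_id)
  row <- exon_row(model, exon_id)
  n_skipped <- sum(cols$sample == "N" & cols$ref != "-")
  if (n_skipped > 0L)
    warning(n_skipped, " column(s) with ambiguous base N skipped in exon ",
            exon_id)

  # cDNA position of the reference base in each column (0 before the first)
  refpos <- cumsum(cols$ref != "-") + row$cdna_start - 1L
  state <- ifelse(cols$sample == "-", "D", ifelse(cols$ref == "-", "I", "M"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  out <- list()
  for (k in seq_along(runs$values)) {
    a <- starts[k]; b <- ends[k]
    if (runs$values[k] == "D") {
      out[[length(out) + 1L]] <- new_variants(
        "deletion", refpos[a], refpos[b],
        paste(cols$ref[a:b], collapse = ""), "")
    } else if (runs$values[k] == "I") {
      anchor <- if (a == 1L) row$cdna_start - 1L else refpos[a - 1L]
      out[[length(out) + 1L]] <- new_variants(
        "insertion", anchor, anchor + 1L, "",
        paste(cols$sample[a:b], collapse = ""))
    } else {
      sub <- a:b
      sub <- sub[cols$ref[sub] != cols$sample[sub] & cols$sample[sub] != "N"]
      if (length(sub))
        out[[length(out) + 1L]] <- new_variants(
          "substitution", refpos[sub], refpos[sub],
          cols$ref[sub], cols$sample[sub])
    }
  }
  if (!length(out)) return(empty_variants())
  v <- do.call(rbind, out)
  v <- normalize_3prime(v, model)
  annotate_variants(v, model, dialect = dialect)
}

#' Shift indels to their 3'-most equivalent position
#'
#' Within a run of repeated sequence, a deletion or insertion has several
#' equivalent representations; the HGVS convention places the event at the
#' highest cDNA coordinate that leaves the mutated sequence unchanged. The
#' shift is bounded by the end of the exon containing the event (per-exon
#' comparison never produces cross-exon indels). Substitutions are returned
#' unchanged; the operation is idempotent.
#'
#' @param v A variant \code{data.frame} (one or more rows).
#' @param model A [gene_model()].
#' @return The normalized variant \code{data.frame}.
#' @export
normalize_3prime <- function(v, model) {
  stopifnot(is.data.frame(v), inherits(model, "gene_model"))
  if (nrow(v) == 0L) return(v)
  refchars <- strsplit(model$reference_cdna, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(v))) {
    kind <- v$kind[i]
    if (kind == "substitution") {
      if (refchars[v$cdna_start[i]] != v$ref[i])
        stop("reference allele mismatch at c.", v$cdna_start[i], ": model has ",
             refchars[v$cdna_start[i]], ", variant claims ", v$ref[i])
      next
    }
    if (kind == "deletion") {
      s <- v$cdna_start[i]; e <- v$cdna_end[i]
      claimed <- paste(refchars[s:e], collapse = "")
      if (claimed != v$ref[i])
        stop("reference allele mismatch for deletion at c.", s, "_", e,
             ": model has ", claimed, ", variant claims ", v$ref[i])
      exon_end <- exon_row(model, exon_of(model, e))$cdna_end
      while (e + 1L <= exon_end && refchars[e + 1L] == refchars[s]) {
        s <- s + 1L; e <- e + 1L
      }
      v$cdna_start[i] <- s; v$cdna_end[i] <- e
      v$ref[i] <- paste(refchars[s:e], collapse = "")
    } else if (kind == "insertion") {
      p <- v$cdna_start[i]
      alt <- strsplit(v$alt[i], "", fixed = TRUE)[[1]]
      exon_end <- exon_row(model,
                           exon_of(model, max(p, 1L)))$cdna_end
      while (p + 1L <= exon_end && refchars[p + 1L] == alt[1]) {
        alt <- c(alt[-1], alt[1])
        p <- p + 1L
      }
      v$cdna_start[i] <- p; v$cdna_end[i] <- p + 1L
      v$alt[i] <- paste(alt, collapse = "")
    } else {
      stop("unknown variant kind: ", kind)
    }
  }
  v
}

#' Format variants in c.-notation
#'
#' The \code{"paper"} dialect writes single-base deletions with the deleted
#' base (\code{c.80delC}) and multi-base deletions with a length suffix
#' (\code{c.450_478del29}); \code{"hgvs"} drops both suffixes
#' (\code{c.80del}, \code{c.450_478del}). Substitutions
#' (\code{c.404G>T}) and insertions (\code{c.622_623insGATA}) are written
#' identically in both dialects.
#'
#' @param v A variant \code{data.frame}.
#' @param dialect \code{"paper"} (default) or \code{"hgvs"}.
#' @return Character vector of names, one per row.
#' @export
format_variant <- function(v, dialect = c("paper", "hgvs")) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(v))
  vapply(seq_len(nrow(v)), function(i) {
    kind <- v$kind[i]; s <- v$cdna_start[i]; e <- v$cdna_end[i]
    if (kind == "substitution") {
      sprintf("c.%d%s>%s", s, v$ref[i], v$alt[i])
    } else if (kind == "deletion") {
      len <- e - s + 1L
      if (len == 1L) {
        if (dialect == "paper") sprintf("c.%ddel%s", s, v$ref[i])
        else sprintf("c.%ddel", s)
      } else {
        if (dialect == "paper") sprintf("c.%d_%ddel%d", s, e, len)
        else sprintf("c.%d_%ddel", s, e)
      }
    } else if (kind == "insertion") {
      sprintf("c.%d_%dins%s", s, e, v$alt[i])
    } else stop("unknown variant kind: ", kind)
  }, character(1))
}

#' Parse a c.-notation variant name
#'
#' Accepts both naming dialects produced by [format_variant()]. When a
#' \code{model} is supplied, reference alleles omitted by the name (multi-base
#' and bare \code{del} forms) are filled in from the reference sequence, the
#' stated deleted base is checked against it, and \code{exon_id} is assigned.
#'
#' @param name Character vector of variant names.
#' @param model Optional [gene_model()] used to fill and validate alleles.
#' @return A variant \code{data.frame} with one row per name.
#' @examples
#' parse_variant(c("c.404G>T", "c.450_478del29", "c.622_623insGATA"))
#' @export
parse_variant <- function(name, model = NULL) {
  stopifnot(is.character(name))
  rows <- lapply(name, function(x) {
    if (grepl("^c\\.(\\d+)([ACGT])>([ACGT])$", x)) {
      m <- regmatches(x, regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", x))[[1]]
      pos <- as.integer(m[2])
      if (m[3] == m[4])
        stop("malformed variant name '", x, "': ref and alt alleles are equal")
      return(new_variants("substitution", pos, pos, m[3], m[4]))
    }
    if (grepl("^c\\.(\\d+)del([ACGT]?)$", x)) {
      m <- regmatches(x, regexec("^c\\.(\\d+)del([ACGT]?)$", x))[[1]]
      pos <- as.integer(m[2])
      return(new_variants("deletion", pos, pos, m[3], ""))
    }
    if (grepl("^c\\.(\\d+)_(\\d+)del(\\d*)$", x)) {
      m <- regmatches(x, regexec("^c\\.(\\d+)_(\\d+)del(\\d*)$", x))[[1]]
      s <- as.integer(m[2]); e <- as.integer(m[3])
      if (s > e) stop("malformed variant name '", x, "': start exceeds end")
      if (nzchar(m[4]) && as.integer(m[4]) != e - s + 1L)
        stop("malformed variant name '", x, "': length suffix ", m[4],
             " does not match span ", e - s + 1L)
      return(new_variants("deletion", s, e, "", ""))
    }
    if (grepl("^c\\.(\\d+)_(\\d+)ins([ACGT]+)$", x)) {
      m <- regmatches(x, regexec("^c\\.(\\d+)_(\\d+)ins([ACGT]+)$", x))[[1]]
      s <- as.integer(m[2]); e <- as.integer(m[3])
      if (e != s + 1L)
        stop("malformed variant name '", x,
             "': insertion anchors must be adjacent")
      return(new_variants("insertion", s, e, "", m[4]))
    }
    stop("cannot parse variant name '", x, "'")
  })
  v <- do.call(rbind, rows)
  if (!is.null(model)) {
    refchars <- strsplit(model$reference_cdna, "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(v))) {
      if (v$kind[i] == "deletion") {
        span <- paste(refchars[v$cdna_start[i]:v$cdna_end[i]], collapse = "")
        if (nzchar(v$ref[i]) && v$ref[i] != span)
          stop("deleted base in '", name[i], "' does not match the reference (",
               span, ")")
        v$ref[i] <- span
      } else if (v$kind[i] == "substitution") {
        if (refchars[v$cdna_start[i]] != v$ref[i])
          stop("reference allele in '", name[i],
               "' does not match the reference (",
               refchars[v$cdna_start[i]], ")")
      }
    }
    v <- annotate_variants(v, model, sort = FALSE)
  } else {
    v$name <- format_variant(v)
  }
  rownames(v) <- NULL
  v
}
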