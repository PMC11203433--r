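#' Create a sample record
#'
#' One study subject: an identifier, a group label and one nucleotide
#' sequence per exon of the gene model. Exons may be missing (NULL or empty
#' string); they are logged and excluded from comparison.
#'
#' @param sample_id Character scalar.
#' @param group Group label, conventionally \code{"tumor"} or \code{"healthy"}.
#' @param exon_seqs Named list (or named character vector) of exon sequences,
#'   names are exon ids.
#' @return An object of class \code{"sample_record"}.
#' @export
sample_record <- function(sample_id, group, exon_seqs) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(group), length(group) == 1L)
  exon_seqs <- as.list(exon_seqs)
  if (is.null(names(exon_seqs)) || any(!nzchar(names(exon_seqs))))
    stop("exon_seqs must be named by exon id")
  structure(list(sample_id = sample_id, group = group,
                 exon_seqs = exon_seqs),
            class = "sample_record")
}

#' Compare a cohort against the reference, exon by exon
#'
#' For every sample and every exon of the model: globally align the sample
#' exon against the reference exon, call and 3'-normalize variants, and pool
#' the calls into a cohort summary — per-exon mutation counts, a per-position
#' recurrence table, and the altered/unaltered sample split. Samples from
#' different groups are summarized separately by design (synonymous carriers
#' in a healthy arm must never be pooled with tumor counts), so the input
#' must be a single group; subset first if you hold a mixed list.
#'
#' @param samples List of [sample_record()]s from one group.
#' @param model A [gene_model()].
#' @param scheme A [scoring_scheme()].
#' @param dialect Variant naming dialect, see [format_variant()].
#' @return An object of class \code{"cohort_summary"}: list with
#'   \code{group}, \code{n_samples}, \code{n_altered}, \code{n_unaltered},
#'   \code{exon_counts} (named integer, one entry per exon, zeros kept),
#'   \code{position_counts} (named integer over mutated cDNA positions),
#'   \code{variants} (flat data.frame with \code{sample_id} column),
#'   \code{missing} (data.frame of skipped sample/exon pairs), plus the
#'   \code{model} and \code{scheme} used.
#' @examples
#' fx <- build_fixture_cohort(seed = 1)
#' s <- compare_cohort(fx$samples[1:50], fx$model)
#' s$n_altered              # 42
#' recurrent_positions(s)   # 818 x4, then 108/404/844/994 x2
#' @export
compare_cohort <- function(samples, model, scheme = scoring_scheme(),
                           dialect = "paper") {
  stopifnot(inherits(model, "gene_model"), inherits(scheme, "scoring_scheme"))
  if (!length(samples)) stop("cohort must contain at least one sample")
  if (!all(vapply(samples, inherits, logical(1), "sample_record")))
    stop("samples must be a list of sample_record objects")
  groups <- unique(vapply(samples, `[[`, character(1), "group"))
  if (length(groups) > 1L)
    stop("cohort mixes groups (", paste(groups, collapse = ", "),
         "); summarize each group separately")

  calls <- list()
  missing <- list()
  for (rec in samples) {
    for (e in model$exons$exon_id) {
      seq <- rec$exon_seqs[[as.character(e)]]
      if (is.null(seq) || !nzchar(seq)) {
        message("sample ", rec$sample_id, ": exon ", e,
                " missing, excluded from counts")
        missing[[length(missing) + 1L]] <-
          data.frame(sample_id = rec$sample_id, exon_id = e)
        next
      }
      aln <- global_align(exon_sequence(model, e), seq, scheme)
      v <- call_variants(aln, model, e, dialect = dialect)
      if (nrow(v)) {
        v$sample_id <- rec$sample_id
        calls[[length(calls) + 1L]] <- v
      }
    }
  }
  variants <- if (length(calls)) do.call(rbind, calls) else
    cbind(empty_variants(), sample_id = character(0))
  sample_ids <- vapply(samples, `[[`, character(1), "sample_id")
  out <- new_cohort_summary(variants, model, scheme, sample_ids, groups)
  out$missing <- if (length(missing)) do.call(rbind, missing) else
    data.frame(sample_id = character(0), exon_id = integer(0))
  out
}

# assemble a cohort_summary from a flat variant table; the summary
# invariants (altered + unaltered = n, sum of exon counts = sum of position
# counts = number of events) hold by construction
new_cohort_summary <- function(variants, model, scheme, sample_ids, group) {
  variants <- variants[order(variants$sample_id, variants$cdna_start), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  exon_ids <- model$exons$exon_id
  exon_counts <- stats::setNames(
    vapply(exon_ids, function(e) sum(variants$exon_id == e), integer(1)),
    exon_ids)
  pos_tab <- table(variants$cdna_start)
  position_counts <- stats::setNames(as.integer(pos_tab), names(pos_tab))
  altered <- unique(variants$sample_id)
  structure(list(group = group,
                 n_samples = length(sample_ids),
                 n_altered = length(altered),
                 n_unaltered = length(sample_ids) - length(altered),
                 exon_counts = exon_counts,
                 position_counts = position_counts,
                 variants = variants,
                 missing = data.frame(sample_id = character(0),
                                      exon_id = integer(0)),
                 sample_ids = sample_ids,
                 model = model,
                 scheme = scheme),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (%s): %d samples, %d altered, %d unaltered\n",
              x$group, x$n_samples, x$n_altered, x$n_unaltered))
  cat(sprintf("  %d variant events across %d exon(s)\n",
              nrow(x$variants), sum(x$exon_counts > 0)))
  cat("  events per exon:",
      paste0(names(x$exon_counts), ":", x$exon_counts, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.cohort_summary <- function(object, ...) {
  print(object)
  rec <- recurrent_positions(object)
  if (nrow(rec)) {
    cat("  recurrent positions (>=2 events):",
        paste0("c.", rec$position, " x", rec$count, collapse = ", "), "\n")
  }
  hs <- hotspot_windows(object)
  if (nrow(hs)) {
    cat("  hotspot intervals:",
        paste0("c.", hs$cdna_start, "-", hs$cdna_end, " (exon ", hs$exon_id,
               ", ", hs$event_count, " events)", collapse = "; "), "\n")
  }
  invisible(object)
}

#' Plot the per-exon mutation histogram
#'
#' @param x A [compare_cohort()] summary.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.cohort_summary <- function(x, ...) {
  h <- exon_histogram(x)
  graphics::barplot(h$count, names.arg = h$exon_id,
                    xlab = "exon", ylab = "mutation events",
                    main = sprintf("%s mutations by exon (%s cohort)",
                                   x$model$gene_name, x$group), ...)
  invisible(h)
}

#' Per-exon mutation histogram table
#'
#' One row per exon in model order, including zero-count exons, with the
#' number of variant events assigned to each.
#'
#' @param summary A [compare_cohort()] result.
#' @return \code{data.frame} with columns \code{exon_id} and \code{count};
#'   counts sum to the total number of events.
#' @export
exon_histogram <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  data.frame(exon_id = as.integer(names(summary$exon_counts)),
             count = as.integer(summary$exon_counts))
}

#' Recurrently mutated cDNA positions
#'
#' @param summary A [compare_cohort()] result.
#' @param min_count Minimum number of events at a position, \code{>= 1}.
#' @return \code{data.frame} with columns \code{position} and \code{count},
#'   sorted by count (descending) then position (ascending).
#' @export
recurrent_positions <- function(summary, min_count = 2L) {
  stopifnot(inherits(summary, "cohort_summary"))
  if (min_count < 1L) stop("min_count must be at least 1")
  pc <- summary$position_counts
  keep <- pc >= min_count
  out <- data.frame(position = as.integer(names(pc)[keep]),
                    count = as.integer(pc[keep]))
  out <- out[order(-out$count, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect mutation hotspots by sliding window
#'
#' Slides a \code{width}-nt window in 1-nt steps across the cDNA, flags
#' windows holding at least \code{min_events} variant events (an event counts
#' at its \code{cdna_start}), merges overlapping flagged windows into maximal
#' intervals, and reports each interval trimmed to the span of the events it
#' contains. The default calibration (50 nt, 4 events) is a package choice;
#' both knobs are exposed here and on the command line.
#'
#' @param summary A [compare_cohort()] result.
#' @param width Window width in nucleotides, \code{>= 1}.
#' @param min_events Events required for a window to qualify, \code{>= 1}.
#' @return \code{data.frame} with columns \code{cdna_start}, \code{cdna_end}
#'   (the trimmed event span), \code{exon_id} (exon of the interval's most
#'   recurrent position), \code{event_count} and \code{recurrent_positions}
#'   (comma-separated positions with >= 2 events inside the interval).
#' @export
hotspot_windows <- function(summary, width = 50L, min_events = 4L) {
  stopifnot(inherits(summary, "cohort_summary"))
  width <- as.integer(width); min_events <- as.integer(min_events)
  if (is.na(width) || width < 1L) stop("width must be a positive integer")
  if (is.na(min_events) || min_events < 1L)
    stop("min_events must be a positive integer")
  n <- nchar(summary$model$reference_cdna)
  counts <- integer(n)
  pc <- summary$position_counts
  counts[as.integer(names(pc))] <- as.integer(pc)
  empty <- data.frame(cdna_start = integer(0), cdna_end = integer(0),
                      exon_id = integer(0), event_count = integer(0),
                      recurrent_positions = character(0))
  if (!sum(counts)) return(empty)

  # events inside [s, s+width-1] for every start s, via cumulative sums
  cs <- c(0L, cumsum(counts))
  starts <- seq_len(max(n - width + 1L, 1L))
  ends <- pmin(starts + width - 1L, n)
  win_events <- cs[ends + 1L] - cs[starts]
  ok <- which(win_events >= min_events)
  if (!length(ok)) return(empty)

  # merge overlapping qualifying windows (step 1: runs of consecutive starts,
  # then runs closer than width apart still overlap)
  gap <- which(diff(ok) > width)
  run_start <- ok[c(1L, gap + 1L)]
  run_end <- ok[c(gap, length(ok))]
  out <- lapply(seq_along(run_start), function(i) {
    lo <- run_start[i]; hi <- min(run_end[i] + width - 1L, n)
    inside <- which(counts > 0L)
    inside <- inside[inside >= lo & inside <= hi]
    rec <- inside[counts[inside] >= 2L]
    peak <- inside[which.max(counts[inside])]
    data.frame(cdna_start = min(inside), cdna_end = max(inside),
               exon_id = exon_of(summary$model, peak),
               event_count = sum(counts[inside]),
               recurrent_positions = paste(rec, collapse = ","))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
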