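# Independent oracles, deliberately naive: they share no code with the
# package internals they check.

# best global alignment score by exhaustive enumeration of every alignment
# (each column is a residue pair or a single-sided gap; affine gap runs are
# charged open once plus extend per column)
enum_align_score <- function(a, b, scheme = scoring_scheme()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > na && j > nb) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, "M",
          acc + if (A[i] == B[j]) scheme$match else scheme$mismatch)
    if (i <= na)
      rec(i + 1L, j, "D",
          acc + scheme$gap_extend + if (prev == "D") 0 else scheme$gap_open)
    if (j <= nb)
      rec(i, j + 1L, "I",
          acc + scheme$gap_extend + if (prev == "I") 0 else scheme$gap_open)
  }
  rec(1L, 1L, "S", 0)
  best
}

# identity by direct column recount, via raw bytes rather than split strings
recount_identity <- function(aln) {
  r <- charToRaw(aln$ref_row)
  s <- charToRaw(aln$sample_row)
  gap <- charToRaw("-")
  sum(r == s & r != gap) / length(r)
}

# per-position event tally straight off the flat variant list
tally_positions <- function(summary) {
  pos <- summary$variants$cdna_start
  out <- integer(0)
  for (p in pos) {
    key <- as.character(p)
    out[key] <- if (is.na(out[key])) 1L else out[key] + 1L
  }
  out[order(as.integer(names(out)))]
}

# naive hotspot finder: loop every window start, count events by scanning the
# event list, merge qualifying windows, trim to the covered events
naive_hotspots <- function(summary, width, min_events) {
  pos <- summary$variants$cdna_start
  n <- nchar(summary$model$reference_cdna)
  flagged <- integer(0)
  for (s in seq_len(max(n - width + 1L, 1L))) {
    cnt <- 0L
    for (p in pos) if (p >= s && p <= s + width - 1L) cnt <- cnt + 1L
    if (cnt >= min_events) flagged <- c(flagged, s)
  }
  if (!length(flagged)) {
    return(data.frame(cdna_start = integer(0), cdna_end = integer(0)))
  }
  # merge windows that overlap
  groups <- cumsum(c(1L, diff(flagged) > width))
  do.call(rbind, lapply(split(flagged, groups), function(ss) {
    lo <- min(ss); hi <- min(max(ss) + width - 1L, n)
    covered <- pos[pos >= lo & pos <= hi]
    data.frame(cdna_start = min(covered), cdna_end = max(covered))
  }))
}
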