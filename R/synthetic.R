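# Synthetic references and cohorts with planted (spiked-in) variants.
#
# The bundled fixture reconstructs a two-arm study: 50 tumor samples carrying
# a fixed catalogue of 48 coding variants across exons 2-11 (42 samples
# altered, 8 identical to reference, six samples carrying events in two
# different exons) and 50 "healthy" samples of which 30 carry a single
# synonymous substitution (at least three carriers per exon). The catalogue's
# positions, kinds and clinically recorded alleles are fixed; the reference
# is random at all other sites, so the seed changes filler alleles and
# background sequence but never the catalogue's positions or event types.

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

transition <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[[base]]
}

# Reference bases pinned so that every recorded allele in the fixture
# catalogue matches the reference, single-base deletions sit at the 3' end of
# their homopolymer run (c.453-455 is CCC with a non-C at 452 and 456), the
# 29-base deletion at c.450_478 cannot shift right (c.479 differs from c.450)
# and the GATA insertion at c.622_623 cannot shift (c.623 is not G).
fixture_base_constraints <- function() {
  c("80" = "C", "81" = "A", "254" = "C", "255" = "G",
    "404" = "G", "447" = "C", "450" = "A", "452" = "A", "453" = "C",
    "454" = "C", "455" = "C", "456" = "G", "465" = "C", "475" = "G",
    "479" = "G", "483" = "C", "487" = "T", "524" = "G", "623" = "T",
    "637" = "C", "742" = "C", "818" = "G", "822" = "T", "844" = "C",
    "1024" = "C")
}

#' Synthetic TP53-like gene model
#'
#' Builds the package's default gene model: ten coding exons labeled 2 to 11
#' spanning a 1182-nt coding sequence. The reference is a seeded random ACGT
#' sequence except at a small set of pinned sites whose bases are dictated by
#' the bundled variant catalogue (recorded alleles, homopolymer context of
#' the single-base deletions, non-shiftable indel anchors); it is a synthetic
#' stand-in, not the real TP53 transcript.
#'
#' @param seed Integer seed controlling the unpinned reference bases.
#' @return A [gene_model()] named \code{"TP53"}.
#' @export
tp53_gene_model <- function(seed = 1L) {
  tab <- tp53_exon_table()
  n <- tab$cdna_end[nrow(tab)]
  bases <- with_seed(seed, sample(c("A", "C", "G", "T"), n, replace = TRUE))
  cons <- fixture_base_constraints()
  bases[as.integer(names(cons))] <- cons
  gene_model("TP53", paste(bases, collapse = ""), tab)
}

#' Apply a variant to an exon sequence
#'
#' The inverse of [call_variants()]: mutates the exon sequence that contains
#' the variant. The reference allele stated by \code{spec} is checked against
#' the sequence, which guards against drift between a catalogue and the
#' reference it was built for.
#'
#' @param seq The exon's current sequence (character scalar).
#' @param spec One-row variant \code{data.frame} in cDNA coordinates.
#' @param model The [gene_model()] supplying the exon frame.
#' @return The mutated exon sequence.
#' @export
apply_variant <- function(seq, spec, model) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1L, inherits(model, "gene_model"))
  exon <- exon_row(model, exon_of(model, max(spec$cdna_start, 1L)))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  loc_s <- spec$cdna_start - exon$cdna_start + 1L
  loc_e <- spec$cdna_end - exon$cdna_start + 1L
  if (spec$kind == "substitution") {
    if (loc_s < 1L || loc_s > length(chars) || chars[loc_s] != spec$ref)
      stop("reference mismatch applying ", spec$name, ": expected ", spec$ref,
           " at exon-local position ", loc_s)
    chars[loc_s] <- spec$alt
  } else if (spec$kind == "deletion") {
    if (loc_s < 1L || loc_e > length(chars) ||
        paste(chars[loc_s:loc_e], collapse = "") != spec$ref)
      stop("reference mismatch applying deletion ", spec$name)
    chars <- chars[-(loc_s:loc_e)]
  } else if (spec$kind == "insertion") {
    if (loc_s < 0L || loc_s > length(chars))
      stop("insertion anchor outside exon for ", spec$name)
    chars <- append(chars, strsplit(spec$alt, "", fixed = TRUE)[[1]],
                    after = loc_s)
  } else stop("unknown variant kind: ", spec$kind)
  paste(chars, collapse = "")
}

# --- fixture catalogue ----------------------------------------------------
# One row per planted event: sample, kind, span, and the recorded alternate
# allele (NA means "transition of whatever the reference base is", so the
# allele follows the seed while position and type stay fixed).

fixture_tumor_plan <- function() {
  p <- function(sample, kind, start, end = start, alt = NA_character_)
    data.frame(sample_id = sample, kind = kind, cdna_start = start,
               cdna_end = end, alt = alt)
  rbind(
    p("T01", "substitution", 69),
    p("T02", "deletion", 80),
    p("T03", "substitution", 96),
    p("T04", "substitution", 108),
    p("T05", "substitution", 108),
    p("T06", "deletion", 254),
    p("T07", "substitution", 260),
    p("T08", "substitution", 270),
    p("T09", "substitution", 285),
    p("T10", "substitution", 404, alt = "T"),
    p("T11", "substitution", 404, alt = "T"),
    p("T12", "substitution", 412),
    p("T13", "substitution", 423),
    p("T14", "substitution", 434),
    p("T15", "substitution", 441),
    p("T16", "deletion", 450, 478),
    p("T17", "deletion", 455),
    p("T18", "substitution", 468),
    p("T19", "substitution", 475, alt = "A"),
    p("T20", "substitution", 487, alt = "A"),
    p("T21", "substitution", 524, alt = "A"),
    p("T22", "insertion", 622, 623, alt = "GATA"),
    p("T23", "substitution", 637, alt = "T"),
    p("T24", "substitution", 639),
    p("T25", "substitution", 575),
    p("T26", "substitution", 590),
    p("T27", "substitution", 605),
    p("T28", "substitution", 742, alt = "T"),
    p("T29", "substitution", 680),
    p("T30", "substitution", 700),
    p("T31", "substitution", 720),
    p("T32", "substitution", 818, alt = "A"),
    p("T33", "substitution", 818, alt = "A"),
    p("T34", "substitution", 818, alt = "C"),
    p("T35", "substitution", 818, alt = "C"),
    p("T36", "substitution", 844, alt = "T"),
    p("T37", "substitution", 844, alt = "T"),
    p("T38", "substitution", 816),
    p("T39", "substitution", 825),
    p("T40", "substitution", 831),
    p("T41", "substitution", 837),
    p("T42", "substitution", 850),
    p("T01", "substitution", 857),
    p("T02", "substitution", 994),
    p("T03", "substitution", 994),
    p("T04", "substitution", 1000),
    p("T05", "substitution", 1024, alt = "T"),
    p("T06", "substitution", 1169)
  )
}

fixture_healthy_plan <- function() {
  p <- function(sample, start, alt = NA_character_)
    data.frame(sample_id = sample, kind = "substitution", cdna_start = start,
               cdna_end = start, alt = alt)
  rbind(
    p("H01", 30), p("H02", 45), p("H03", 60),          # exon 2
    p("H04", 78), p("H05", 85), p("H06", 92),          # exon 3
    p("H07", 120), p("H08", 200), p("H09", 300),       # exon 4
    p("H10", 447, "G"), p("H11", 465, "G"), p("H12", 483, "G"),  # exon 5
    p("H13", 580), p("H14", 600), p("H15", 650),       # exon 6
    p("H16", 690), p("H17", 710), p("H18", 730),       # exon 7
    p("H19", 822, "A"), p("H20", 800), p("H21", 860),  # exon 8
    p("H22", 940), p("H23", 960), p("H24", 980),       # exon 9
    p("H25", 1010), p("H26", 1050), p("H27", 1080),    # exon 10
    p("H28", 1120), p("H29", 1140), p("H30", 1160)     # exon 11
  )
}

# resolve a plan against a concrete reference: fill ref alleles, default
# substitution alts to the transition of the reference base, name and place
plan_to_catalogue <- function(plan, model, group) {
  refchars <- strsplit(model$reference_cdna, "", fixed = TRUE)[[1]]
  ref <- character(nrow(plan))
  alt <- plan$alt
  for (i in seq_len(nrow(plan))) {
    if (plan$kind[i] == "insertion") {
      ref[i] <- ""
    } else {
      ref[i] <- paste(refchars[plan$cdna_start[i]:plan$cdna_end[i]],
                      collapse = "")
    }
    if (plan$kind[i] == "substitution" && is.na(alt[i]))
      alt[i] <- transition(ref[i])
    if (plan$kind[i] == "deletion") alt[i] <- ""
  }
  v <- new_variants(plan$kind, plan$cdna_start, plan$cdna_end, ref, alt)
  v <- annotate_variants(v, model, sort = FALSE)
  v$sample_id <- plan$sample_id
  v$group <- group
  v[, c("sample_id", "group", "exon_id", "name", "kind", "cdna_start",
        "cdna_end", "ref", "alt")]
}

# materialize sample records from a catalogue: reference exons + planted events
catalogue_to_samples <- function(catalogue, model, sample_ids, group) {
  ref_exons <- vapply(model$exons$exon_id, function(e) exon_sequence(model, e),
                      character(1))
  names(ref_exons) <- as.character(model$exons$exon_id)
  lapply(sample_ids, function(sid) {
    seqs <- ref_exons
    rows <- catalogue[catalogue$sample_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      e <- as.character(rows$exon_id[i])
      seqs[[e]] <- apply_variant(seqs[[e]], rows[i, , drop = FALSE], model)
    }
    sample_record(sid, group, as.list(seqs))
  })
}

#' Build the bundled fixture cohort
#'
#' Generates the canonical synthetic study: a [tp53_gene_model()] reference,
#' 50 tumor samples (42 carrying at least one of 48 catalogued coding
#' variants, 8 identical to the reference) and 50 healthy samples (30 carrying
#' one synonymous substitution each, at least three per exon). Per-exon tumor
#' event totals are 1, 2, 6, 12, 6, 4, 12, 0, 4 and 1 for exons 2 through 11;
#' recurrent cDNA positions are 818 (4 events) and 108, 404, 844 and 994
#' (2 events each). The seed changes only the reference background and the
#' alleles of events whose alternate base is not pinned; positions, kinds and
#' sample assignments are identical for every seed.
#'
#' @param seed Integer seed.
#' @return A list with elements \code{model} (the gene model),
#'   \code{samples} (list of 100 [sample_record()]s, tumor then healthy) and
#'   \code{catalogue} (data.frame of all planted events with sample_id,
#'   group, exon_id, name, kind, coordinates and alleles).
#' @examples
#' fx <- build_fixture_cohort(seed = 1)
#' summary_t <- compare_cohort(fx$samples[1:50], fx$model)
#' exon_histogram(summary_t)
#' @export
build_fixture_cohort <- function(seed = 1L) {
  model <- tp53_gene_model(seed)
  tumor_ids <- sprintf("T%02d", 1:50)
  healthy_ids <- sprintf("H%02d", 1:50)
  cat_t <- plan_to_catalogue(fixture_tumor_plan(), model, "tumor")
  cat_h <- plan_to_catalogue(fixture_healthy_plan(), model, "healthy")
  catalogue <- rbind(cat_t, cat_h)
  samples <- c(catalogue_to_samples(cat_t, model, tumor_ids, "tumor"),
               catalogue_to_samples(cat_h, model, healthy_ids, "healthy"))
  list(model = model, samples = samples, catalogue = catalogue)
}

#' Random cohort with planted variants
#'
#' Property-test input generator: every sample/exon pair carries one planted
#' variant with probability \code{mutation_rate} (at most one per exon per
#' sample, so calls can be matched back to the catalogue unambiguously).
#' Planted events are uniform over exon-interior positions; a fraction
#' \code{indel_fraction} are indels (deletions of 1-3 bases or insertions of
#' 1-4 random bases, split evenly), the rest substitutions. The returned
#' catalogue is 3'-normalized, so it equals the variant set an exact caller
#' recovers.
#'
#' @param n_samples Number of samples.
#' @param mutation_rate Per-exon probability of planting a variant, in [0,1].
#' @param indel_fraction Fraction of planted events that are indels, in [0,1].
#' @param seed Integer seed.
#' @param model Optional [gene_model()]; defaults to \code{tp53_gene_model(seed)}.
#' @param group Group label for the generated samples.
#' @return A list with \code{model}, \code{samples} and \code{catalogue}, as
#'   in [build_fixture_cohort()].
#' @export
random_cohort <- function(n_samples, mutation_rate = 0.05,
                          indel_fraction = 0.1, seed = 1L, model = NULL,
                          group = "tumor") {
  stopifnot(n_samples >= 0L)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  if (indel_fraction < 0 || indel_fraction > 1)
    stop("indel_fraction must be in [0, 1]")
  if (is.null(model)) model <- tp53_gene_model(seed)
  ids <- if (n_samples > 0L) sprintf("S%03d", seq_len(n_samples)) else character(0)
  refchars <- strsplit(model$reference_cdna, "", fixed = TRUE)[[1]]
  specs <- with_seed(seed + 1L, {
    out <- list()
    for (sid in ids) {
      for (j in seq_len(nrow(model$exons))) {
        if (stats::runif(1) >= mutation_rate) next
        es <- model$exons$cdna_start[j]; ee <- model$exons$cdna_end[j]
        is_indel <- stats::runif(1) < indel_fraction
        if (!is_indel) {
          pos <- sample(es:ee, 1L)
          ref <- refchars[pos]
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
          v <- new_variants("substitution", pos, pos, ref, alt)
        } else if (stats::runif(1) < 0.5) {
          len <- sample(1:3, 1L)
          pos <- sample(es:(ee - len), 1L)
          v <- new_variants("deletion", pos, pos + len - 1L,
                            paste(refchars[pos:(pos + len - 1L)],
                                  collapse = ""), "")
        } else {
          len <- sample(1:4, 1L)
          anchor <- sample(es:(ee - 1L), 1L)
          ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
          v <- new_variants("insertion", anchor, anchor + 1L, "", ins)
        }
        v$sample_id <- sid
        out[[length(out) + 1L]] <- v
      }
    }
    out
  })
  if (length(specs)) {
    v <- do.call(rbind, specs)
    sample_col <- v$sample_id
    v <- normalize_3prime(v[, setdiff(names(v), "sample_id")], model)
    v <- annotate_variants(v, model, sort = FALSE)
    v$sample_id <- sample_col
    v$group <- group
    catalogue <- v[, c("sample_id", "group", "exon_id", "name", "kind",
                       "cdna_start", "cdna_end", "ref", "alt")]
  } else {
    catalogue <- cbind(sample_id = character(0), group = character(0),
                       empty_variants()[, c("exon_id", "name", "kind",
                                            "cdna_start", "cdna_end",
                                            "ref", "alt")])
  }
  samples <- catalogue_to_samples(catalogue, model, ids, group)
  list(model = model, samples = samples, catalogue = catalogue)
}
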