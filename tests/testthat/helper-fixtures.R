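# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_fixture_cohort(seed = seed)
  .fixture_cache[[key]]
}

cached_tumor_summary <- function(seed = 1L) {
  key <- paste0("tumor", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture(seed)
    .fixture_cache[[key]] <- compare_cohort(fx$samples[1:50], fx$model)
  }
  .fixture_cache[[key]]
}

cached_healthy_summary <- function(seed = 1L) {
  key <- paste0("healthy", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture(seed)
    .fixture_cache[[key]] <- compare_cohort(fx$samples[51:100], fx$model)
  }
  .fixture_cache[[key]]
}

# a small gene model for unit tests
toy_model <- function(ref = "ACGTACGTACGTGGCCAATTGGCC",
                      spans = data.frame(exon_id = 1:2,
                                         cdna_start = c(1L, 13L),
                                         cdna_end = c(12L, 24L))) {
  gene_model("TOY", ref, spans)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# the named variants of the bundled catalogue: tumor coding events plus the
# healthy-arm synonymous substitutions
catalogue_variant_names <- function() {
  c("c.80delC", "c.254delC", "c.404G>T", "c.450_478del29", "c.455delC",
    "c.475G>A", "c.487T>A", "c.524G>A", "c.622_623insGATA", "c.637C>T",
    "c.742C>T", "c.818G>A", "c.818G>C", "c.844C>T", "c.1024C>T",
    "c.447C>G", "c.465C>G", "c.483C>G", "c.822T>A")
}

# expected per-exon tumor event totals of the bundled catalogue
fixture_exon_totals <- function() {
  stats::setNames(c(1L, 2L, 6L, 12L, 6L, 4L, 12L, 0L, 4L, 1L), 2:11)
}

make_spec <- function(kind, start, end, ref, alt) {
  data.frame(kind = kind, cdna_start = as.integer(start),
             cdna_end = as.integer(end), ref = ref, alt = alt,
             exon_id = NA_integer_, name = NA_character_)
}
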