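test_that("substitutions, deletions and insertions are called and named", {
  fx <- cached_fixture()
  m <- fx$model
  ref5 <- exon_sequence(m, 5)

  sub <- make_spec("substitution", 404, 404, "G", "T")
  aln <- global_align(ref5, apply_variant(ref5, sub, m))
  v <- call_variants(aln, m, 5)
  expect_equal(nrow(v), 1L)
  expect_equal(v$name, "c.404G>T")
  expect_equal(v$exon_id, 5L)

  del29 <- make_spec("deletion", 450, 478,
                     substr(m$reference_cdna, 450, 478), "")
  aln <- global_align(ref5, apply_variant(ref5, del29, m))
  v <- call_variants(aln, m, 5)
  expect_equal(v$name, "c.450_478del29")
  expect_equal(v$kind, "deletion")

  ref6 <- exon_sequence(m, 6)
  ins <- make_spec("insertion", 622, 623, "", "GATA")
  aln <- global_align(ref6, apply_variant(ref6, ins, m))
  v <- call_variants(aln, m, 6)
  expect_equal(v$name, "c.622_623insGATA")

  # identical sequences give an empty call set
  expect_equal(nrow(call_variants(global_align(ref5, ref5), m, 5)), 0L)
})

test_that("single-base deletions normalize to the 3' end of their run", {
  fx <- cached_fixture()
  m <- fx$model
  # reference holds CCC at 453-455; deleting any copy names c.455delC
  expect_equal(substr(m$reference_cdna, 453, 455), "CCC")
  ref5 <- exon_sequence(m, 5)
  for (pos in 453:455) {
    del <- make_spec("deletion", pos, pos, "C", "")
    aln <- global_align(ref5, apply_variant(ref5, del, m))
    v <- call_variants(aln, m, 5)
    expect_equal(v$name, "c.455delC", info = paste("deleted at", pos))
  }
})

test_that("3' normalization is idempotent and checks the reference allele", {
  m <- toy_model("AAACCCGGGTTTAAACCCGGGTTT")
  v <- make_spec("deletion", 4, 4, "C", "")
  n1 <- normalize_3prime(v, m)
  expect_equal(n1$cdna_start, 6L)        # CCC run ends at 6
  expect_equal(normalize_3prime(n1, m), n1)

  ins <- make_spec("insertion", 3, 4, "", "C")  # C before CCC run
  n2 <- normalize_3prime(ins, m)
  expect_equal(n2$cdna_start, 6L)
  expect_equal(normalize_3prime(n2, m), n2)

  sub <- make_spec("substitution", 4, 4, "C", "T")
  expect_equal(normalize_3prime(sub, m), sub)

  bad <- make_spec("deletion", 4, 4, "G", "")
  expect_error(normalize_3prime(bad, m), "mismatch")
})

test_that("normalization stops at the exon boundary", {
  # run of A spans the junction 11-14; a deletion in exon 1 must not slide
  # into exon 2
  m <- gene_model("J", "ACGTACGTACAAAACGTACGTACG",
                  data.frame(exon_id = 1:2, cdna_start = c(1, 13),
                             cdna_end = c(12, 24)))
  v <- make_spec("deletion", 11, 11, "A", "")
  n <- normalize_3prime(v, m)
  expect_equal(n$cdna_start, 12L)
})

test_that("N columns are skipped with a warning", {
  m <- toy_model()
  ref1 <- exon_sequence(m, 1)
  smp <- sub("^(.{3}).", "\\1N", ref1)
  aln <- global_align(ref1, smp)
  expect_warning(v <- call_variants(aln, m, 1), "N skipped")
  expect_equal(nrow(v), 0L)
})

test_that("a reference row that disagrees with the model is rejected", {
  m <- toy_model()
  aln <- global_align(exon_sequence(m, 1), exon_sequence(m, 1))
  expect_error(call_variants(aln, m, 2), "does not match")
})

test_that("variants called from an alignment reconstruct the sample", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(10:30, 1)
    ref <- random_seq(n)
    m <- gene_model("R", ref, data.frame(exon_id = 1, cdna_start = 1,
                                         cdna_end = n))
    # mutate the reference a little
    smp <- ref
    spec_kind <- sample(c("substitution", "deletion", "insertion"), 1)
    pos <- sample(2:(n - 2), 1)
    spec <- switch(spec_kind,
      substitution = {
        refb <- substr(ref, pos, pos)
        make_spec("substitution", pos, pos, refb,
                  sample(setdiff(c("A", "C", "G", "T"), refb), 1))
      },
      deletion = make_spec("deletion", pos, pos + 1,
                           substr(ref, pos, pos + 1), ""),
      insertion = make_spec("insertion", pos, pos + 1, "", random_seq(2)))
    smp <- apply_variant(ref, spec, m)
    v <- call_variants(global_align(ref, smp), m, 1)
    # re-apply every called variant (right to left so coordinates stay valid)
    rebuilt <- ref
    if (nrow(v)) {
      v <- v[order(-v$cdna_start), , drop = FALSE]
      for (k in seq_len(nrow(v)))
        rebuilt <- apply_variant(rebuilt, v[k, , drop = FALSE], m)
    }
    expect_equal(rebuilt, smp, info = paste("case", i, spec_kind))
  }
})
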