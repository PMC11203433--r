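test_that("apply_variant mutates sequences and guards the reference allele", {
  m <- toy_model("AAACCCGGGTTTAAACCCGGGTTT")
  ref1 <- exon_sequence(m, 1)
  sub <- make_spec("substitution", 4, 4, "C", "T")
  expect_equal(apply_variant(ref1, sub, m), "AAATCCGGGTTT")
  del <- make_spec("deletion", 4, 6, "CCC", "")
  expect_equal(apply_variant(ref1, del, m), "AAAGGGTTT")
  ins <- make_spec("insertion", 3, 4, "", "GG")
  expect_equal(apply_variant(ref1, ins, m), "AAAGGCCCGGGTTT")
  # length bookkeeping: output = input - del + ins
  expect_equal(nchar(apply_variant(ref1, del, m)), 12 - 3)
  expect_equal(nchar(apply_variant(ref1, ins, m)), 12 + 2)
  bad <- make_spec("substitution", 4, 4, "G", "T")
  expect_error(apply_variant(ref1, bad, m), "reference mismatch")
})

test_that("the fixture cohort is deterministic for a given seed", {
  a <- build_fixture_cohort(seed = 5)
  b <- build_fixture_cohort(seed = 5)
  expect_identical(a$model$reference_cdna, b$model$reference_cdna)
  expect_identical(a$catalogue, b$catalogue)
  for (i in seq_along(a$samples))
    expect_identical(a$samples[[i]]$exon_seqs, b$samples[[i]]$exon_seqs)
  # and the written file tree is byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("the seed moves filler alleles but never positions or types", {
  a <- cached_fixture(1)
  b <- build_fixture_cohort(seed = 2)
  cols <- c("sample_id", "group", "exon_id", "kind", "cdna_start", "cdna_end")
  expect_identical(a$catalogue[, cols], b$catalogue[, cols])
  expect_false(identical(a$catalogue$alt, b$catalogue$alt))
  # recorded alleles stay pinned regardless of seed
  named <- intersect(catalogue_variant_names(), a$catalogue$name)
  expect_identical(sort(named),
                   sort(intersect(catalogue_variant_names(),
                                  b$catalogue$name)))
})

test_that("fixture structure matches the study design", {
  fx <- cached_fixture()
  expect_length(fx$samples, 100L)
  tum <- fx$catalogue[fx$catalogue$group == "tumor", ]
  expect_equal(nrow(tum), 48L)
  expect_equal(length(unique(tum$sample_id)), 42L)
  # six samples carry events in two different exons
  two <- table(tum$sample_id)
  expect_equal(sum(two == 2), 6L)
  dup <- names(two)[two == 2]
  for (sid in dup)
    expect_equal(anyDuplicated(tum$exon_id[tum$sample_id == sid]), 0L)
  # healthy arm: 30 single-variant carriers, at least 3 per exon
  hea <- fx$catalogue[fx$catalogue$group == "healthy", ]
  expect_equal(nrow(hea), 30L)
  expect_true(all(table(hea$exon_id) >= 3))
  expect_true(all(hea$kind == "substitution"))
  # per-exon planted totals
  planted <- table(factor(tum$exon_id, levels = 2:11))
  expect_equal(as.integer(planted), unname(fixture_exon_totals()))
})

test_that("the caller recovers exactly the planted catalogue", {
  for (seed in c(4, 23)) {
    rc <- random_cohort(n_samples = 15, mutation_rate = 0.15,
                        indel_fraction = 0.3, seed = seed)
    s <- compare_cohort(rc$samples, rc$model)
    got <- s$variants[order(s$variants$sample_id, s$variants$cdna_start),
                      c("sample_id", "name")]
    want <- rc$catalogue[order(rc$catalogue$sample_id,
                               rc$catalogue$cdna_start),
                         c("sample_id", "name")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("random cohort extremes behave", {
  rc0 <- random_cohort(0, seed = 1)
  expect_length(rc0$samples, 0L)
  expect_equal(nrow(rc0$catalogue), 0L)
  subs <- random_cohort(8, mutation_rate = 0.3, indel_fraction = 0,
                        seed = 2)
  expect_true(all(subs$catalogue$kind == "substitution"))
  expect_error(random_cohort(3, mutation_rate = 1.5), "mutation_rate")
  expect_error(random_cohort(3, indel_fraction = -0.1), "indel_fraction")
})

test_that("cohorts round-trip through the on-disk FASTA layout", {
  rc <- random_cohort(4, mutation_rate = 0.2, seed = 6)
  dir <- withr::local_tempdir()
  write_cohort(rc, dir)
  back <- read_cohort(dir)
  expect_equal(back$model$reference_cdna, rc$model$reference_cdna)
  expect_length(back$samples, 4L)
  for (i in seq_along(rc$samples)) {
    expect_equal(back$samples[[i]]$sample_id, rc$samples[[i]]$sample_id)
    expect_equal(unlist(back$samples[[i]]$exon_seqs),
                 unlist(rc$samples[[i]]$exon_seqs))
  }
  expect_equal(back$catalogue$name, rc$catalogue$name)
})
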