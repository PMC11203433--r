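test_that("a cohort identical to the reference yields an all-zero summary", {
  m <- toy_model()
  refs <- setNames(lapply(m$exons$exon_id,
                          function(e) exon_sequence(m, e)),
                   m$exons$exon_id)
  samples <- lapply(1:3, function(i)
    sample_record(sprintf("S%d", i), "tumor", refs))
  s <- compare_cohort(samples, m)
  expect_equal(s$n_altered, 0L)
  expect_equal(s$n_unaltered, 3L)
  expect_true(all(s$exon_counts == 0L))
  expect_equal(nrow(recurrent_positions(s)), 0L)
  h <- exon_histogram(s)
  expect_equal(h$count, c(0L, 0L))
})

test_that("summary counts are conserved and match independent tallies", {
  s <- cached_tumor_summary()
  expect_equal(sum(s$exon_counts), nrow(s$variants))
  expect_equal(sum(s$position_counts), nrow(s$variants))
  expect_equal(s$n_altered + s$n_unaltered, s$n_samples)
  # independent per-position recount
  expect_equal(s$position_counts, tally_positions(s))
  # recurrence off the flat list
  rec <- recurrent_positions(s, 2)
  tal <- tally_positions(s)
  expect_setequal(rec$position, as.integer(names(tal)[tal >= 2]))
  expect_true(all(diff(rec$count) <= 0))
  expect_error(recurrent_positions(s, 0), "at least 1")
})

test_that("groups are never pooled and empty cohorts are rejected", {
  fx <- cached_fixture()
  expect_error(compare_cohort(fx$samples[49:52], fx$model), "mixes groups")
  expect_error(compare_cohort(list(), fx$model), "at least one")
})

test_that("missing exons are logged and excluded from counts", {
  m <- toy_model()
  seqs <- setNames(lapply(m$exons$exon_id, function(e) exon_sequence(m, e)),
                   m$exons$exon_id)
  seqs[["2"]] <- ""
  expect_message(
    s <- compare_cohort(list(sample_record("S1", "tumor", seqs)), m),
    "exon 2 missing")
  expect_equal(nrow(s$missing), 1L)
  expect_equal(s$missing$exon_id, 2L)
  expect_equal(nrow(s$variants), 0L)
})

test_that("hotspot windows agree with a naive recount over random cohorts", {
  for (seed in c(3, 17)) {
    rc <- random_cohort(n_samples = 12, mutation_rate = 0.2,
                        indel_fraction = 0.2, seed = seed)
    s <- compare_cohort(rc$samples, rc$model)
    for (width in c(25L, 50L)) {
      got <- hotspot_windows(s, width = width, min_events = 3L)
      want <- naive_hotspots(s, width = width, min_events = 3L)
      expect_equal(got$cdna_start, want$cdna_start,
                   info = paste("seed", seed, "width", width))
      expect_equal(got$cdna_end, want$cdna_end)
    }
  }
})

test_that("hotspot edge cases and parameter validation behave", {
  m <- toy_model()
  refs <- setNames(lapply(m$exons$exon_id, function(e) exon_sequence(m, e)),
                   m$exons$exon_id)
  mut <- refs
  mut[["1"]] <- paste0("T", substr(refs[["1"]], 2, nchar(refs[["1"]])))
  s <- compare_cohort(list(sample_record("S1", "tumor", mut)), m)
  expect_equal(nrow(hotspot_windows(s, width = 10, min_events = 2)), 0L)
  expect_equal(nrow(hotspot_windows(s, width = 10, min_events = 1)), 1L)
  expect_error(hotspot_windows(s, width = 0), "width")
  expect_error(hotspot_windows(s, min_events = 0), "min_events")
})

test_that("summary TSV output is byte-identical across reruns", {
  s <- cached_tumor_summary()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_summary(s, d1)
  write_cohort_summary(s, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("plot and print methods run", {
  s <- cached_tumor_summary()
  expect_output(print(s), "42 altered")
  expect_output(summary(s), "recurrent positions")
  pdf(NULL)
  on.exit(dev.off())
  h <- plot(s)
  expect_equal(sum(h$count), 48L)
})
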