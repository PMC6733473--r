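# Synthetic references and survivor cohorts with planted ground truth.

test_that("make_reference is deterministic, GC-calibrated and repeat-free", {
  r1 <- make_reference(length_bp = 20000, gc_fraction = 0.36, seed = 8)
  r2 <- make_reference(length_bp = 20000, gc_fraction = 0.36, seed = 8)
  expect_identical(r1$sequence, r2$sequence)
  r3 <- make_reference(length_bp = 20000, gc_fraction = 0.36, seed = 9)
  expect_false(identical(r1$sequence, r3$sequence))
  gc <- mean(strsplit(r1$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.36), 0.01)
  # screened free of the core telomere unit
  expect_false(grepl("GTTAC", r1$sequence, fixed = TRUE))
  expect_error(make_reference(length_bp = 500), "length_bp")
})

test_that("default geometry places the cassette at coordinate 5442736", {
  r <- make_reference(seed = 1)
  expect_equal(r$cassette_coord, 5442736L)
  expect_equal(nchar(r$sequence), 16800L)
  expect_equal(r$genome_offset + nchar(r$sequence) - 1L, 5442736L)
})

test_that("make_survivor plants recoverable deletions and translocations", {
  ref <- make_reference(length_bp = 4000, genome_offset = 1L, seed = 10)
  partner <- make_reference(length_bp = 4000, genome_offset = 90001L,
                            seed = 11, name = "donor_arm")
  # deletion: tail of exactly the requested units, round-trips
  bp <- 2000
  while (substr(ref$sequence, bp + 1, bp + 1) == "G") bp <- bp + 1
  sp <- survivor_spec("deletion_telomere_addition", bp, telomere_units = 3,
                      seed = 2)
  del <- make_survivor(ref, spec = sp)
  n_units <- detect_telomere_addition(del$truth$telomere_tail,
                                      telomere_motif())$n_repeat_units
  expect_equal(n_units, 3L)
  rec <- classify_junction(del$read, ref, list(partner))
  expect_equal(rec$gcr_type, "deletion_telomere_addition")
  expect_equal(rec$breakpoint_coord, del$truth$breakpoint_coord)
  # translocation with zero microhomology measures zero
  sp0 <- survivor_spec("translocation", 1800, microhomology_len = 0,
                       partner_pos = 2500, seed = 3)
  tr0 <- make_survivor(ref, partner, sp0)
  rec0 <- classify_junction(tr0$read, ref, list(tr0$partner))
  expect_equal(rec0$microhomology_length, 0L)
  # acceptor edits are recorded
  sp7 <- survivor_spec("translocation", 1800, microhomology_len = 7,
                       partner_pos = 2500, seed = 4)
  tr7 <- make_survivor(ref, partner, sp7)
  expect_true(is.data.frame(tr7$edits))
  expect_equal(classify_junction(tr7$read, ref,
                                 list(tr7$partner))$microhomology_length, 7L)
})

test_that("make_cohort apportions types deterministically and reproducibly", {
  coh <- make_cohort(15, seed = 6)
  counts <- table(coh$truth$gcr_type)
  expect_equal(unname(counts["deletion_telomere_addition"]), 12L,
               ignore_attr = TRUE)
  expect_equal(unname(counts["translocation"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(counts["indeterminate"]), 1L, ignore_attr = TRUE)
  coh2 <- make_cohort(15, seed = 6)
  expect_identical(coh$reads, coh2$reads)
  expect_identical(coh$truth, coh2$truth)
  # empty cohort: schema-complete empty outputs
  coh0 <- make_cohort(0, seed = 1)
  expect_equal(length(coh0$reads), 0L)
  expect_equal(nrow(coh0$truth), 0L)
  expect_error(make_cohort(10, type_proportions = c(
    deletion_telomere_addition = 0.5, translocation = 0.5,
    indeterminate = 0.5)), "sum to 1")
})

test_that("a mixed cohort is reclassified with full truth recovery", {
  coh <- make_cohort(60, seed = 13,
                     type_proportions = c(deletion_telomere_addition = 0.5,
                                          translocation = 0.4,
                                          indeterminate = 0.1))
  res <- classify_cohort(coh$reads, coh$reference, list(coh$partner))
  expect_equal(res$gcr_type, coh$truth$gcr_type)
  expect_equal(res$breakpoint_coord, coh$truth$breakpoint_coord)
  tr <- res$gcr_type == "translocation"
  expect_equal(res$microhomology_length[tr],
               coh$truth$microhomology_length[tr])
  expect_equal(res$partner_coord[tr], coh$truth$partner_coord[tr])
  dl <- res$gcr_type == "deletion_telomere_addition"
  expect_equal(res$telomere_tail[dl], coh$truth$telomere_tail[dl])
})

test_that("cohort FASTA and truth TSV round-trip through files", {
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  coh <- make_cohort(10, seed = 20, fasta = fa, truth_tsv = tsv)
  reads <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(reads), 10L)
  expect_equal(as.character(reads[["survivor_001"]]),
               unname(coh$reads["survivor_001"]))
  truth <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(truth$gcr_type, coh$truth$gcr_type)
  res <- classify_cohort(fa, coh$reference, list(coh$partner))
  expect_equal(res$gcr_type, coh$truth$gcr_type)
})
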