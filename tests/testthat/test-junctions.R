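# Breakpoint anchoring, telomere detection, microhomology and
# classification.

ref <- make_reference(length_bp = 5000, genome_offset = 10001L, seed = 42)

test_that("anchor_breakpoint finds the longest exact prefix match", {
  # read fully explained by the reference
  read <- substr(ref$sequence, 1000, 1100)
  anc <- anchor_breakpoint(read, ref)
  expect_equal(anc$breakpoint_coord, 10001L + 1100L - 1L)
  expect_equal(anc$tail, "")
  expect_equal(anc$matched_length, 101L)
  # read with a G-rich non-reference tail
  tail <- "GGTTACGGTTACGGTTACGG"
  read2 <- paste0(substr(ref$sequence, 1000, 1050), tail)
  anc2 <- anchor_breakpoint(read2, ref)
  expect_equal(anc2$breakpoint_coord, 10001L + 1050L - 1L)
  expect_equal(anc2$tail, tail)
  # unanchorable reads raise a typed condition
  expect_error(anchor_breakpoint(random_dna(60), ref),
               class = "gcr_unanchored")
  expect_error(anchor_breakpoint("ACGT", ref), "seed")
})

test_that("anchoring recovers random planted breakpoints exactly", {
  set.seed(12)
  for (i in 1:200) {
    bp <- sample(100:4900, 1)
    if (substr(ref$sequence, bp + 1, bp + 1) == "G") next
    tail <- random_dna(30)
    if (substr(tail, 1, 1) == substr(ref$sequence, bp + 1, bp + 1)) next
    read <- paste0(substr(ref$sequence, max(1, bp - 199), bp), tail)
    anc <- anchor_breakpoint(read, ref)
    expect_equal(anc$breakpoint_coord, 10001L + bp - 1L)
  }
})

test_that("detect_telomere_addition tiles degenerate repeats", {
  motif <- telomere_motif()
  pure <- detect_telomere_addition("GGTTACGGTTACGGTTAC", motif)
  expect_true(pure$is_telomeric)
  expect_equal(pure$covered_fraction, 1.0)
  expect_equal(pure$n_repeat_units, 3L)
  # variable G-runs and short spacers still count as covered
  deg <- detect_telomere_addition("GGGGTTACAGTTACACGGGGGTTAC", motif)
  expect_true(deg$is_telomeric)
  # non-repeat sequence is rejected
  expect_false(detect_telomere_addition("ACGTACGTACGTACGT", motif)$is_telomeric)
  expect_false(detect_telomere_addition("", motif)$is_telomeric)
  # below the minimum tail length, even pure repeat is not called
  expect_false(detect_telomere_addition("GGTTAC", motif)$is_telomeric)
})

test_that("random tails are almost never called telomeric", {
  set.seed(77)
  motif <- telomere_motif()
  calls <- vapply(1:10000, function(i)
    detect_telomere_addition(random_dna(18), motif)$is_telomeric, logical(1))
  expect_lt(mean(calls), 0.01)
})

test_that("microhomology_length matches worked examples", {
  expect_equal(microhomology_length("GCATTCAA", "TTCAAGGC", "GCATTCAAGGC"), 5L)
  expect_equal(microhomology_length("AAAA", "CCCC", "AAAACCCC"), 0L)
  expect_error(microhomology_length("AAAA", "CCCC", "GGGGTTTT"),
               "inconsistent")
})

test_that("microhomology_length agrees with exhaustive brute force on short strings", {
  set.seed(21)
  for (i in 1:300) {
    k <- sample(0:8, 1)
    hom <- random_dna(k)
    donor <- paste0(random_dna(sample(3:12, 1)), hom)
    acceptor <- paste0(hom, random_dna(sample(3:12, 1)))
    fused <- paste0(donor, substring(acceptor, k + 1))
    if (nchar(fused) > 30) next
    oracle <- mh_brute_force_oracle(donor, acceptor, fused)
    expect_identical(microhomology_length(donor, acceptor, fused), oracle)
  }
})

test_that("classify_junction distinguishes the three junction types", {
  partner <- make_reference(length_bp = 3000, genome_offset = 500001L,
                            seed = 43, name = "partner_arm")
  # deletion survivor
  sdel <- survivor_spec("deletion_telomere_addition", breakpoint_pos = 2000,
                        telomere_units = 3, seed = 5)
  del <- make_survivor(ref, spec = sdel)
  rec <- classify_junction(del$read, ref, list(partner))
  expect_equal(rec$gcr_type, "deletion_telomere_addition")
  expect_equal(rec$breakpoint_coord, del$truth$breakpoint_coord)
  expect_equal(rec$telomere_tail, del$truth$telomere_tail)
  # translocation survivor with 7-nt planted microhomology
  str <- survivor_spec("translocation", breakpoint_pos = 1500,
                       microhomology_len = 7, partner_pos = 1200, seed = 6)
  trl <- make_survivor(ref, partner, str)
  rec2 <- classify_junction(trl$read, ref, list(trl$partner))
  expect_equal(rec2$gcr_type, "translocation")
  expect_equal(rec2$microhomology_length, 7L)
  expect_equal(rec2$breakpoint_coord, trl$truth$breakpoint_coord)
  expect_equal(rec2$partner_coord, trl$truth$partner_coord)
  # short non-telomeric, non-alignable tail falls through to indeterminate
  read3 <- paste0(substr(ref$sequence, 1200, 1500), "ACGTACGT")
  rec3 <- classify_junction(read3, ref, list(partner))
  expect_equal(rec3$gcr_type, "indeterminate")
})

test_that("translocation tails anchor on the reverse strand too", {
  partner <- make_reference(length_bp = 3000, genome_offset = 1L,
                            seed = 44, name = "partner_arm")
  rcseq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(partner$sequence)))
  read <- paste0(substr(ref$sequence, 1000, 1300), substr(rcseq, 500, 620))
  rec <- classify_junction(read, ref, list(partner))
  expect_equal(rec$gcr_type, "translocation")
  expect_equal(rec$partner_strand, "-")
})

test_that("breakpoints centromeric of the essential-gene boundary are flagged", {
  # small region whose cassette sits at the telomeric end; boundary
  # 2 kb centromeric of it
  r2 <- make_reference(length_bp = 5000, genome_offset = 1L, seed = 45)
  r2$cassette_coord <- 5000L
  r2$boundary_kb <- 2
  read <- paste0(substr(r2$sequence, 500, 800), "ACGTACGTAC")
  rec <- classify_junction(read, r2, survivor_id = "s1")
  expect_true(rec$beyond_boundary)   # 800 < 5000 - 2000
  read2 <- paste0(substr(r2$sequence, 3500, 4000), "ACGTACGTAC")
  expect_false(classify_junction(read2, r2)$beyond_boundary)
})

test_that("virtual marker mapping brackets truncation breakpoints", {
  # truncation inside the region: interval of width <= 2 * tile
  p <- 2345
  survivor <- substr(ref$sequence, 1, p)
  vm <- virtual_marker_mapping(survivor, ref, tile_bp = 400)
  expect_equal(vm$signal, "breakpoint")
  lo <- vm$interval["low"] - ref$genome_offset + 1
  hi <- vm$interval["high"] - ref$genome_offset + 1
  expect_true(lo <= p && p <= hi)
  expect_lte(hi - lo, 800)
  # full reference: no-breakpoint signal
  vm2 <- virtual_marker_mapping(ref$sequence, ref, tile_bp = 400)
  expect_equal(vm2$signal, "no_breakpoint")
  expect_null(vm2$interval)
  expect_error(virtual_marker_mapping(survivor, ref, tile_bp = 10), "tile_bp")
})

test_that("marker-mapping intervals contain the base-resolution breakpoint", {
  coh <- make_cohort(10, ref = ref, seed = 3, flank = Inf,
                     type_proportions = c(deletion_telomere_addition = 1,
                                          translocation = 0,
                                          indeterminate = 0))
  for (i in seq_along(coh$reads)) {
    anc <- anchor_breakpoint(coh$reads[[i]], ref)
    vm <- virtual_marker_mapping(coh$reads[[i]], ref, tile_bp = 400)
    if (vm$signal == "no_breakpoint") next  # breakpoint beyond the last tile
    expect_true(vm$interval["low"] <= anc$breakpoint_coord &&
                  anc$breakpoint_coord <= vm$interval["high"])
  }
})
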