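# Breakpoint-junction analysis for GCR survivors.
#
# Survivor reads are oriented centromere -> telomere and begin inside
# the reference breakpoint region. The longest exact prefix match
# anchors the read and defines the breakpoint (last retained reference
# base); the unmatched suffix ("tail") is then tested for de novo
# telomere repeats or anchored in a partner locus to call a
# translocation. Coordinates are handled 0/1-based internally as
# needed but always reported 1-based inclusive, matching the genome
# database convention.

#' Reference breakpoint region
#'
#' Container for the sequence of the assayed breakpoint region, its
#' genomic anchor and the geometry of the assay: the marker-cassette
#' insertion coordinate and the distance to the nearest centromeric
#' essential gene, which bounds the detectable deletions.
#'
#' @param sequence DNA string (A/C/G/T/N) or a `Biostrings` XString.
#' @param name Region name (used as the chromosome field in BED
#'   output).
#' @param genome_offset 1-based genomic coordinate of the first base of
#'   `sequence`.
#' @param cassette_coord 1-based genomic coordinate of the marker
#'   cassette insertion; default 5442736, the chromosome I insertion
#'   point of the assay, when it falls inside the region, otherwise the
#'   telomeric end of the region.
#' @param boundary_kb Distance in kb from the cassette to the most
#'   distal centromeric essential gene; default 16.8. Breakpoints
#'   centromeric of this boundary are flagged, not rejected.
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(sequence, name = "region", genome_offset = 1L,
                             cassette_coord = NULL, boundary_kb = 16.8) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1 || nchar(sequence) == 0)
    stop("'sequence' must be a single non-empty DNA string")
  if (grepl("[^ACGTN]", sequence))
    stop("'sequence' contains characters other than A/C/G/T/N")
  if (boundary_kb <= 0) stop("'boundary_kb' must be > 0")
  len <- nchar(sequence)
  if (is.null(cassette_coord)) {
    cassette_coord <- if (5442736 >= genome_offset &&
                          5442736 < genome_offset + len)
      5442736 else genome_offset + len - 1
  }
  if (cassette_coord < genome_offset || cassette_coord >= genome_offset + len)
    stop("'cassette_coord' must fall within the region")
  structure(list(name = name, sequence = sequence,
                 genome_offset = genome_offset,
                 cassette_coord = cassette_coord,
                 boundary_kb = boundary_kb),
            class = "reference_region")
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf(
    "reference_region '%s': %d bp at %d..%d, cassette at %d, boundary %.1f kb\n",
    x$name, nchar(x$sequence), x$genome_offset,
    x$genome_offset + nchar(x$sequence) - 1, x$cassette_coord, x$boundary_kb))
  invisible(x)
}

#' Degenerate telomere-repeat motif
#'
#' Fission-yeast telomere repeats are heterogeneous: a G-rich core unit
#' (consensus `GGTTAC`, with the leading G-run varying from 1 to 8) with
#' occasional short non-repeat spacers between units. The motif is a
#' documented, configurable choice rather than a fixed string.
#'
#' @param core Core repeat unit; the leading run of G's is replaced by
#'   the variable-length run.
#' @param g_run_max Maximum G-run length (default 8).
#' @param spacer_max Maximum spacer length (nt) between consecutive
#'   units still counted as telomeric coverage.
#' @param min_tail_length Minimum tail length (nt) for a telomere call;
#'   default 12, about two core units.
#' @param min_match_fraction Minimum fraction of the tail covered by
#'   repeat units (plus internal spacers); default 0.8.
#' @return An object of class `telomere_motif` with the compiled unit
#'   regular expression in `$unit_regex`.
#' @export
telomere_motif <- function(core = "GGTTAC", g_run_max = 8L, spacer_max = 3L,
                           min_tail_length = 12L, min_match_fraction = 0.8) {
  rest <- sub("^G+", "", toupper(core))
  if (nchar(rest) == 0) stop("'core' must contain non-G bases")
  if (min_match_fraction <= 0 || min_match_fraction > 1)
    stop("'min_match_fraction' must be in (0, 1]")
  unit_min <- 1 + nchar(rest)
  if (min_tail_length < unit_min)
    stop("'min_tail_length' must be at least one repeat unit")
  structure(list(core = toupper(core), g_run_max = as.integer(g_run_max),
                 spacer_max = as.integer(spacer_max),
                 min_tail_length = as.integer(min_tail_length),
                 min_match_fraction = min_match_fraction,
                 unit_regex = sprintf("G{1,%d}%s", g_run_max, rest)),
            class = "telomere_motif")
}

# longest common prefix length of two strings
.common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  x <- utf8ToInt(substr(a, 1, n))
  y <- utf8ToInt(substr(b, 1, n))
  d <- which(x != y)
  if (length(d) == 0) n else d[1] - 1L
}

#' Anchor a survivor read in the reference region
#'
#' Finds the longest exact prefix of the read that matches a substring
#' of the reference. The breakpoint is the genomic coordinate of the
#' last matched base and the unmatched suffix is returned as the tail.
#' Ties are broken by longest match, then leftmost genomic position.
#' Requires a seed match of at least `seed_length` nt; reads whose
#' prefix cannot be seeded raise a condition of class `gcr_unanchored`.
#'
#' @param read DNA string, 5' end originating in the reference
#'   (centromere -> telomere orientation); length >= `seed_length`.
#' @param ref A [reference_region()].
#' @param seed_length Seed length for the initial exact match
#'   (default 20).
#' @return A list with `breakpoint_coord` (1-based genomic coordinate of
#'   the last retained reference base), `matched_length`, `tail`
#'   (unmatched suffix, possibly empty) and `ref_start` (1-based local
#'   start of the match in the region sequence).
#' @export
anchor_breakpoint <- function(read, ref, seed_length = 20L) {
  stopifnot(inherits(ref, "reference_region"))
  read <- toupper(as.character(read))
  if (nchar(read) < seed_length)
    stop(sprintf("read shorter than the %d-nt anchoring seed", seed_length))
  seed <- substr(read, 1, seed_length)
  hits <- gregexpr(seed, ref$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1)
    stop(errorCondition(
      sprintf("read prefix has no %d-nt seed match in '%s'",
              seed_length, ref$name),
      class = c("gcr_unanchored", "error")))
  starts <- as.integer(hits)
  lens <- vapply(starts, function(s)
    .common_prefix_len(read, substring(ref$sequence, s)), integer(1))
  best <- which(lens == max(lens))[1]  # leftmost among longest
  s <- starts[best]
  len <- lens[best]
  list(breakpoint_coord = ref$genome_offset + s + len - 2L,
       matched_length = len,
       tail = substring(read, len + 1),
       ref_start = s)
}

#' Detect de novo telomere-repeat addition in a junction tail
#'
#' Greedily tiles the tail 5' to 3' with maximal repeat-unit matches
#' (the motif's G-run quantifier is greedy, so each unit consumes the
#' longest available G-run). Gaps of at most `spacer_max` nt between
#' consecutive units count as covered spacer sequence. The tail is
#' called telomeric when it reaches `min_tail_length` and the covered
#' fraction reaches `min_match_fraction`.
#'
#' @param tail DNA string (possibly empty).
#' @param motif A [telomere_motif()].
#' @return A list with `is_telomeric`, `covered_fraction` and
#'   `n_repeat_units`.
#' @examples
#' detect_telomere_addition("GGTTACGGTTACGGTTAC", telomere_motif())
#' @export
detect_telomere_addition <- function(tail, motif = telomere_motif()) {
  stopifnot(inherits(motif, "telomere_motif"))
  tail <- toupper(as.character(tail))
  if (nchar(tail) == 0)
    return(list(is_telomeric = FALSE, covered_fraction = 0,
                n_repeat_units = 0L))
  m <- gregexpr(motif$unit_regex, tail, perl = TRUE)[[1]]
  if (m[1] == -1) {
    covered <- 0L; n_units <- 0L
  } else {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    covered <- sum(lens)
    n_units <- length(starts)
    if (n_units > 1) {
      gaps <- starts[-1] - (starts[-n_units] + lens[-n_units])
      covered <- covered + sum(gaps[gaps > 0 & gaps <= motif$spacer_max])
    }
  }
  frac <- covered / nchar(tail)
  list(is_telomeric = nchar(tail) >= motif$min_tail_length &&
         frac >= motif$min_match_fraction,
       covered_fraction = frac,
       n_repeat_units = n_units)
}

#' Microhomology length at a rearrangement junction
#'
#' A junction's microhomology is the stretch of bases assignable to both
#' fusion partners: the maximal window at the fusion point that matches
#' the donor 3' end and the acceptor 5' start simultaneously, maximized
#' over all valid placements of the junction. Equivalently, with `d` the
#' longest prefix of the fused sequence explained by the donor (a suffix
#' of `donor_end`) and `a` the longest suffix explained by the acceptor
#' (a prefix of `acceptor_start`), the microhomology is
#' `d + a - nchar(fused)`.
#'
#' @param donor_end Donor parental sequence ending at the donor's
#'   maximal attributable base.
#' @param acceptor_start Acceptor parental sequence starting at the
#'   acceptor's minimal attributable base.
#' @param fused Junction-spanning sequence composed of a donor prefix
#'   and an acceptor suffix.
#' @return Integer microhomology length (>= 0). Errors when `fused`
#'   cannot be composed from the two parents.
#' @examples
#' microhomology_length("GCATTCAA", "TTCAAGGC", "GCATTCAAGGC")  # 5
#' @export
microhomology_length <- function(donor_end, acceptor_start, fused) {
  donor_end <- toupper(as.character(donor_end))
  acceptor_start <- toupper(as.character(acceptor_start))
  fused <- toupper(as.character(fused))
  lf <- nchar(fused)
  ld <- nchar(donor_end)
  la <- nchar(acceptor_start)
  d <- 0L
  for (i in rev(seq_len(min(lf, ld)))) {
    if (substr(fused, 1, i) == substring(donor_end, ld - i + 1)) {
      d <- i; break
    }
  }
  a_len <- 0L
  for (j in rev(seq_len(min(lf, la)))) {
    if (substring(fused, lf - j + 1) == substr(acceptor_start, 1, j)) {
      a_len <- j; break
    }
  }
  if (d + a_len < lf)
    stop("fused sequence is inconsistent with the two parental sequences")
  as.integer(d + a_len - lf)
}

# longest-prefix anchoring of 'tail' in a partner region, both strands;
# returns NULL when no match of >= seed_length
.anchor_in_partner <- function(tail, partner, seed_length) {
  best <- NULL
  fwd <- partner$sequence
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(partner$sequence)))
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") fwd else rev
    if (nchar(tail) < seed_length) next
    seed <- substr(tail, 1, seed_length)
    hits <- gregexpr(seed, seqs, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    starts <- as.integer(hits)
    lens <- vapply(starts, function(s)
      .common_prefix_len(tail, substring(seqs, s)), integer(1))
    b <- which(lens == max(lens))[1]
    if (is.null(best) || lens[b] > best$matched_length) {
      q <- starts[b]
      lp <- nchar(fwd)
      coord <- if (strand == "+") partner$genome_offset + q - 1L
               else partner$genome_offset + (lp - q + 1L) - 1L
      best <- list(partner = partner, strand = strand, q = q,
                   strand_seq = seqs, matched_length = lens[b],
                   partner_coord = coord)
    }
  }
  best
}

#' Classify a survivor junction read
#'
#' Anchors the read in the primary reference, then classifies the
#' unmatched tail: a telomeric tail calls a terminal deletion healed by
#' de novo telomere addition; otherwise a tail that anchors in a partner
#' reference (either strand) calls a translocation, with the junction
#' microhomology measured by walking the junction back across both
#' parents; anything else is indeterminate. Breakpoints centromeric of
#' the essential-gene boundary are flagged in the record, not rejected.
#'
#' @param read DNA string; must anchor in `primary_ref`.
#' @param primary_ref A [reference_region()] for the breakpoint region.
#' @param partner_refs List of candidate partner [reference_region()]s
#'   (may be empty).
#' @param motif A [telomere_motif()].
#' @param seed_length Anchoring seed length (default 20).
#' @param survivor_id Identifier copied into the record.
#' @return An object of class `junction_record`: a list with
#'   `survivor_id`, `gcr_type` (`"deletion_telomere_addition"`,
#'   `"translocation"` or `"indeterminate"`), `breakpoint_coord`,
#'   `telomere_tail`, `microhomology_length`, `partner_ref`,
#'   `partner_coord`, `partner_strand`, `matched_length`,
#'   `beyond_boundary` and `note`.
#' @export
classify_junction <- function(read, primary_ref, partner_refs = list(),
                              motif = telomere_motif(), seed_length = 20L,
                              survivor_id = "survivor") {
  if (inherits(partner_refs, "reference_region"))
    partner_refs <- list(partner_refs)
  anc <- anchor_breakpoint(read, primary_ref, seed_length)
  tail <- anc$tail
  boundary_coord <- primary_ref$cassette_coord -
    round(primary_ref$boundary_kb * 1000)
  rec <- list(survivor_id = survivor_id,
              gcr_type = "indeterminate",
              breakpoint_coord = anc$breakpoint_coord,
              telomere_tail = "",
              microhomology_length = NA_integer_,
              partner_ref = "",
              partner_coord = NA_integer_,
              partner_strand = NA_character_,
              matched_length = anc$matched_length,
              beyond_boundary = anc$breakpoint_coord < boundary_coord,
              note = "")
  if (nchar(tail) == 0) {
    rec$note <- "read fully matches reference; no junction"
    return(structure(rec, class = "junction_record"))
  }
  tel <- detect_telomere_addition(tail, motif)
  if (tel$is_telomeric) {
    rec$gcr_type <- "deletion_telomere_addition"
    rec$telomere_tail <- tail
    rec$note <- sprintf("%d repeat units, %.2f covered",
                        tel$n_repeat_units, tel$covered_fraction)
    return(structure(rec, class = "junction_record"))
  }
  best <- NULL
  for (p in partner_refs) {
    hit <- .anchor_in_partner(tail, p, seed_length)
    if (!is.null(hit) &&
        (is.null(best) || hit$matched_length > best$matched_length))
      best <- hit
  }
  if (!is.null(best)) {
    # walk the junction backwards: bases immediately 5' of the partner
    # match that also match the donor end are attributable to both
    refseq <- primary_ref$sequence
    bp_local <- anc$ref_start + anc$matched_length - 1L
    S <- best$strand_seq
    q <- best$q
    h <- 0L
    while (q - h - 1L >= 1L && bp_local - h >= 1L &&
           substr(S, q - h - 1L, q - h - 1L) ==
           substr(refseq, bp_local - h, bp_local - h))
      h <- h + 1L
    rec$gcr_type <- "translocation"
    rec$microhomology_length <- h
    rec$partner_ref <- best$partner$name
    rec$partner_coord <- best$partner_coord
    rec$partner_strand <- best$strand
    return(structure(rec, class = "junction_record"))
  }
  rec$note <- "tail neither telomeric nor anchorable in any partner"
  structure(rec, class = "junction_record")
}

#' @export
print.junction_record <- function(x, ...) {
  cat(sprintf("junction_record %s: %s at %d", x$survivor_id, x$gcr_type,
              x$breakpoint_coord))
  if (x$gcr_type == "translocation")
    cat(sprintf(" -> %s:%d (%s), microhomology %d nt",
                x$partner_ref, x$partner_coord, x$partner_strand,
                x$microhomology_length))
  if (x$beyond_boundary) cat(" [beyond essential-gene boundary]")
  cat("\n")
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.junction_record <- function(x, ...) {
  data.frame(survivor_id = x$survivor_id, gcr_type = x$gcr_type,
             breakpoint_coord = x$breakpoint_coord,
             telomere_tail = x$telomere_tail,
             microhomology_length = x$microhomology_length,
             partner_ref = x$partner_ref, partner_coord = x$partner_coord,
             partner_strand = x$partner_strand,
             matched_length = x$matched_length,
             beyond_boundary = x$beyond_boundary,
             note = x$note, stringsAsFactors = FALSE)
}

#' Classify a cohort of survivor reads
#'
#' @param reads Named character vector of reads, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param primary_ref,partner_refs,motif,seed_length As in
#'   [classify_junction()].
#' @return A data frame with one row per read (columns as in
#'   [classify_junction()] records, plus `ref_name`).
#' @export
classify_cohort <- function(reads, primary_ref, partner_refs = list(),
                            motif = telomere_motif(), seed_length = 20L) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads)
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (length(reads) == 0) {
    out <- as.data.frame(structure(list(
      survivor_id = character(0), gcr_type = character(0),
      breakpoint_coord = integer(0), telomere_tail = character(0),
      microhomology_length = integer(0), partner_ref = character(0),
      partner_coord = integer(0), partner_strand = character(0),
      matched_length = integer(0), beyond_boundary = logical(0),
      note = character(0)), class = "data.frame"))
    out$ref_name <- character(0)
    return(out)
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("survivor_%03d", seq_along(reads))
  recs <- lapply(seq_along(reads), function(i)
    as.data.frame(classify_junction(reads[[i]], primary_ref, partner_refs,
                                    motif, seed_length,
                                    survivor_id = ids[i])))
  out <- do.call(rbind, recs)
  out$ref_name <- primary_ref$name
  rownames(out) <- NULL
  out
}

#' Virtual sequential-PCR mapping of a breakpoint
#'
#' Emulates mapping a breakpoint to ~400 bp resolution by sequential
#' PCR: the reference is tiled with consecutive `tile_bp` amplicons
#' (a trailing partial tile is ignored) and an amplicon "amplifies" iff
#' its full sequence occurs in the survivor sequence. The breakpoint is
#' bracketed between the end of the last present amplicon and the end of
#' the first absent one, an interval of width at most `2 * tile_bp`.
#'
#' @param survivor_seq Full survivor sequence (DNA string).
#' @param ref A [reference_region()].
#' @param tile_bp Amplicon length in bp (>= 50; default 400).
#' @return An object of class `marker_mapping`: a list with `signal`
#'   (`"breakpoint"` or `"no_breakpoint"`), `interval` (1-based
#'   inclusive genomic coordinates, or `NULL`) and `tiles_present`
#'   (logical vector).
#' @export
virtual_marker_mapping <- function(survivor_seq, ref, tile_bp = 400L) {
  stopifnot(inherits(ref, "reference_region"))
  if (tile_bp < 50) stop("'tile_bp' must be >= 50")
  survivor_seq <- toupper(as.character(survivor_seq))
  L <- nchar(ref$sequence)
  n_tiles <- L %/% tile_bp
  if (n_tiles < 1) stop("reference shorter than one tile")
  present <- vapply(seq_len(n_tiles), function(i) {
    tile <- substr(ref$sequence, (i - 1) * tile_bp + 1, i * tile_bp)
    grepl(tile, survivor_seq, fixed = TRUE)
  }, logical(1))
  if (all(present))
    return(structure(list(signal = "no_breakpoint", interval = NULL,
                          tiles_present = present),
                     class = "marker_mapping"))
  first_absent <- which(!present)[1]
  low_local <- if (first_absent == 1) 1L else (first_absent - 1L) * tile_bp
  high_local <- first_absent * tile_bp
  structure(list(
    signal = "breakpoint",
    interval = c(low = ref$genome_offset + low_local - 1L,
                 high = ref$genome_offset + high_local - 1L),
    tiles_present = present), class = "marker_mapping")
}

#' @export
print.marker_mapping <- function(x, ...) {
  if (x$signal == "no_breakpoint") {
    cat("virtual marker mapping: all amplicons present (no breakpoint)\n")
  } else {
    cat(sprintf("virtual marker mapping: breakpoint in [%d, %d] (%d bp)\n",
                x$interval["low"], x$interval["high"],
                x$interval["high"] - x$interval["low"] + 1))
  }
  invisible(x)
}
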