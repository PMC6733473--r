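# Synthetic reference regions and survivor reads with planted ground
# truth, so the junction classifier is fully testable without any
# genome download. Reference sequences are screened free of the
# telomere repeat unit, deletion tails are sampled from the degenerate
# motif (not a fixed string) to exercise the tiling matcher, and
# translocation junctions are engineered to share exactly the requested
# number of microhomologous bases, with mismatch guards on both sides
# so the planted breakpoint and microhomology are unambiguous.

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n, gc_fraction) {
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# redraw bases until the sequence is free of the minimal telomere unit
.screen_unit <- function(seq, gc_fraction, unit = "GTTAC") {
  for (iter in 1:100) {
    hits <- gregexpr(unit, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(seq)
    for (s in as.integer(hits)) {
      repl <- .random_dna(nchar(unit), gc_fraction)
      substr(seq, s, s + nchar(unit) - 1) <- repl
    }
  }
  stop("failed to screen telomere units from the synthetic sequence")
}

#' Generate a synthetic reference breakpoint region
#'
#' Reproducible pseudo-random sequence at a configurable GC content,
#' screened free of the core telomere repeat unit (`GTTAC`) so that no
#' spurious telomere calls or tail anchors can arise outside planted
#' tails. Defaults mirror the assayed chromosome I geometry: a 16.8-kb
#' region whose telomeric end carries the marker cassette at coordinate
#' 5442736, and a genome-wide GC fraction of 0.36.
#'
#' @param length_bp Region length (>= 1000); default 16800.
#' @param gc_fraction GC content in (0, 1); default 0.36.
#' @param genome_offset 1-based genomic coordinate of the region start;
#'   default places the region end at coordinate 5442736.
#' @param seed Integer seed.
#' @param name Region name.
#' @return A [reference_region()].
#' @examples
#' ref <- make_reference(length_bp = 2000, seed = 1)
#' @export
make_reference <- function(length_bp = 16800L, gc_fraction = 0.36,
                           genome_offset = 5442736L - 16800L + 1L,
                           seed = 1L, name = "chrI_breakpoint_region") {
  if (length_bp < 1000) stop("'length_bp' must be >= 1000")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("'gc_fraction' must be in (0, 1)")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  seq <- .screen_unit(.random_dna(length_bp, gc_fraction), gc_fraction)
  reference_region(seq, name = name, genome_offset = as.integer(genome_offset),
                   cassette_coord = as.integer(genome_offset) + length_bp - 1L)
}

#' Specification of one synthetic survivor
#'
#' @param gcr_type `"deletion_telomere_addition"`, `"translocation"` or
#'   `"indeterminate"`.
#' @param breakpoint_pos 1-based local position in the reference of the
#'   last retained base.
#' @param telomere_units Number of telomere repeat units appended
#'   (deletions; >= 2).
#' @param microhomology_len Planted microhomology length in nt
#'   (translocations; >= 0).
#' @param partner_name,partner_pos Partner region name and 1-based local
#'   start of the acceptor suffix (translocations).
#' @param seed Integer seed for the survivor's degenerate choices.
#' @return An object of class `survivor_spec`.
#' @export
survivor_spec <- function(gcr_type, breakpoint_pos, telomere_units = 3L,
                          microhomology_len = 0L, partner_name = NULL,
                          partner_pos = NULL, seed = 1L) {
  gcr_type <- match.arg(gcr_type, c("deletion_telomere_addition",
                                    "translocation", "indeterminate"))
  if (breakpoint_pos < 20)
    stop("'breakpoint_pos' must be >= 20 so the read can be anchored")
  if (gcr_type == "deletion_telomere_addition" && telomere_units < 2)
    stop("'telomere_units' must be >= 2")
  if (gcr_type == "translocation") {
    if (is.null(partner_pos)) stop("translocations require 'partner_pos'")
    if (microhomology_len < 0) stop("'microhomology_len' must be >= 0")
  }
  structure(list(gcr_type = gcr_type,
                 breakpoint_pos = as.integer(breakpoint_pos),
                 telomere_units = as.integer(telomere_units),
                 microhomology_len = as.integer(microhomology_len),
                 partner_name = partner_name,
                 partner_pos = if (is.null(partner_pos)) NULL
                               else as.integer(partner_pos),
                 seed = as.integer(seed)),
            class = "survivor_spec")
}

# one degenerate telomere tail: 'units' repeat units with random G-run
# lengths, separated by short non-G spacers, ending on a full unit;
# redrawn until it reaches the motif's minimum callable tail length
.sample_telomere_tail <- function(units, motif) {
  rest <- sub("^G+", "", motif$core)
  repeat {
    parts <- character(0)
    for (u in seq_len(units)) {
      k <- sample(seq_len(motif$g_run_max), 1)
      parts <- c(parts, paste0(strrep("G", k), rest))
      if (u < units && motif$spacer_max > 0) {
        slen <- sample(0:motif$spacer_max, 1)
        if (slen > 0)
          parts <- c(parts, paste(sample(c("A", "C", "T"), slen,
                                         replace = TRUE), collapse = ""))
      }
    }
    tail <- paste(parts, collapse = "")
    if (nchar(tail) >= motif$min_tail_length) return(tail)
  }
}

.char_at <- function(seq, i) substr(seq, i, i)

.other_base <- function(avoid) setdiff(.BASES, avoid)[1]

# engineer the acceptor side of a translocation junction inside the
# partner sequence: plant exactly k microhomologous bases before the
# acceptor start p, with mismatch guards at p - k - 1 (stops backward
# extension) and p (stops forward extension of the primary anchor)
.plan_translocation_edits <- function(refseq, partnerseq, bp, p, k) {
  lp <- nchar(partnerseq)
  if (p - k - 1 < 1) stop("'partner_pos' too close to the partner start")
  if (p + 20 > lp) stop("'partner_pos' too close to the partner end")
  edits <- list()
  note <- function(pos, from, to)
    data.frame(pos = pos, from = from, to = to, stringsAsFactors = FALSE)
  if (k > 0) for (j in seq_len(k)) {
    want <- .char_at(refseq, bp - j + 1)
    have <- .char_at(partnerseq, p - j)
    if (have != want) {
      edits[[length(edits) + 1]] <- note(p - j, have, want)
      substr(partnerseq, p - j, p - j) <- want
    }
  }
  g1 <- p - k - 1
  if (.char_at(partnerseq, g1) == .char_at(refseq, bp - k)) {
    to <- .other_base(c(.char_at(refseq, bp - k), "G"))
    edits[[length(edits) + 1]] <- note(g1, .char_at(partnerseq, g1), to)
    substr(partnerseq, g1, g1) <- to
  }
  if (.char_at(partnerseq, p) == .char_at(refseq, bp + 1)) {
    to <- .other_base(c(.char_at(refseq, bp + 1), "G"))
    edits[[length(edits) + 1]] <- note(p, .char_at(partnerseq, p), to)
    substr(partnerseq, p, p) <- to
  }
  list(partnerseq = partnerseq,
       edits = if (length(edits)) do.call(rbind, edits)
               else note(integer(0), character(0), character(0)))
}

#' Build one synthetic survivor read with its ground truth
#'
#' Deletion survivors append a degenerate telomere tail of
#' `spec$telomere_units` units to the retained reference prefix.
#' Translocation survivors fuse the reference prefix to a partner
#' suffix engineered to share exactly `spec$microhomology_len` bases at
#' the junction (the acceptor is locally edited where needed; edits are
#' recorded and the edited partner returned, to be used as the partner
#' reference downstream). Indeterminate survivors carry a random tail
#' that is neither telomeric nor anchorable.
#'
#' @param ref Primary [reference_region()].
#' @param partner Partner [reference_region()] (translocations only).
#' @param spec A [survivor_spec()].
#' @param flank Number of retained reference bases included in the read
#'   5' of the breakpoint (default 300); `Inf` for the full prefix.
#' @param tail_len Partner bases included 3' of the junction
#'   (translocations; default 150).
#' @return A list with `read`, `truth` (a `junction_record`), `partner`
#'   (the possibly edited partner region, or `NULL`) and `edits` (data
#'   frame of recorded acceptor edits).
#' @export
make_survivor <- function(ref, partner = NULL, spec, flank = 300L,
                          tail_len = 150L) {
  stopifnot(inherits(ref, "reference_region"), inherits(spec, "survivor_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  refseq <- ref$sequence
  bp <- spec$breakpoint_pos
  if (bp >= nchar(refseq)) stop("'breakpoint_pos' beyond the reference end")
  start <- if (is.finite(flank)) max(1L, bp - as.integer(flank) + 1L) else 1L
  prefix <- substr(refseq, start, bp)
  motif <- telomere_motif()
  truth <- list(survivor_id = "synthetic", gcr_type = spec$gcr_type,
                breakpoint_coord = ref$genome_offset + bp - 1L,
                telomere_tail = "", microhomology_length = NA_integer_,
                partner_ref = "", partner_coord = NA_integer_,
                partner_strand = NA_character_)
  edits <- NULL
  partner_out <- partner

  if (spec$gcr_type == "deletion_telomere_addition") {
    if (.char_at(refseq, bp + 1) == "G")
      stop("reference continues with G after the breakpoint; ",
           "the telomere-tail start would be ambiguous - pick another position")
    tail <- .sample_telomere_tail(spec$telomere_units, motif)
    truth$telomere_tail <- tail
    read <- paste0(prefix, tail)
  } else if (spec$gcr_type == "translocation") {
    if (is.null(partner)) stop("translocations require a partner region")
    plan <- .plan_translocation_edits(refseq, partner$sequence, bp,
                                      spec$partner_pos,
                                      spec$microhomology_len)
    partner_out <- partner
    partner_out$sequence <- plan$partnerseq
    edits <- plan$edits
    p <- spec$partner_pos
    tl <- min(as.integer(tail_len), nchar(plan$partnerseq) - p + 1L)
    read <- paste0(prefix, substr(plan$partnerseq, p, p + tl - 1L))
    truth$microhomology_length <- spec$microhomology_len
    truth$partner_ref <- partner$name
    truth$partner_coord <- partner$genome_offset + p - 1L
    truth$partner_strand <- "+"
  } else {
    repeat {
      tail <- .random_dna(40, 0.5)
      if (!grepl("GTTAC", tail, fixed = TRUE) &&
          .char_at(tail, 1) != .char_at(refseq, bp + 1)) break
    }
    read <- paste0(prefix, tail)
  }
  list(read = read, truth = structure(truth, class = "junction_record"),
       partner = partner_out, edits = edits)
}

# deterministic largest-remainder apportionment of n among proportions
.apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a cohort of synthetic survivors with a truth table
#'
#' Draws `n` survivors with types apportioned deterministically to the
#' requested proportions (largest-remainder rule, so `n = 15` at the
#' default proportions yields exactly 12 deletions, 2 translocations
#' and 1 indeterminate — the wild-type survivor breakdown used as a
#' scenario template). Translocation junctions are placed in disjoint
#' windows of the partner so that all engineered junctions coexist in a
#' single edited partner reference, which is returned and must be used
#' for classification.
#'
#' @param n Number of survivors (>= 0).
#' @param ref Primary region; auto-generated with [make_reference()]
#'   when `NULL`.
#' @param partner Partner region; auto-generated (and auto-sized to fit
#'   the required number of disjoint junction windows) when `NULL`.
#' @param type_proportions Named weights over the three types; must sum
#'   to 1.
#' @param microhomology_range Integer vector sampled uniformly for
#'   planted microhomology lengths.
#' @param telomere_unit_range Integer vector sampled uniformly for
#'   planted telomere unit counts.
#' @param seed Integer seed; the cohort is fully reproducible.
#' @param flank,tail_len As in [make_survivor()].
#' @param fasta,truth_tsv Optional output paths; when given, reads are
#'   written as FASTA and the truth table as TSV.
#' @return An object of class `gcr_cohort`: a list with `reads` (named
#'   character vector), `truth` (data frame), `reference` and `partner`
#'   (the final, edited partner region).
#' @examples
#' coh <- make_cohort(15, seed = 1)
#' table(coh$truth$gcr_type)
#' @export
make_cohort <- function(n, ref = NULL, partner = NULL,
                        type_proportions = c(deletion_telomere_addition = 12 / 15,
                                             translocation = 2 / 15,
                                             indeterminate = 1 / 15),
                        microhomology_range = 0:10,
                        telomere_unit_range = 2:8,
                        seed = 1L, flank = 300L, tail_len = 150L,
                        fasta = NULL, truth_tsv = NULL) {
  types <- c("deletion_telomere_addition", "translocation", "indeterminate")
  if (is.null(names(type_proportions)) ||
      !setequal(names(type_proportions), types))
    stop("'type_proportions' must be named with the three junction types")
  type_proportions <- type_proportions[types]
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("'type_proportions' must sum to 1")
  if (n < 0) stop("'n' must be >= 0")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  counts <- .apportion(n, type_proportions)
  names(counts) <- types
  n_tr <- counts["translocation"]

  if (is.null(ref)) ref <- make_reference(seed = seed + 1000L)
  if (is.null(partner) && n_tr > 0) {
    need <- max(20000L, as.integer(n_tr) * (as.integer(tail_len) + 40L) + 2000L)
    partner <- make_reference(length_bp = need, genome_offset = 1L,
                              seed = seed + 2000L, name = "chrI_left_arm")
  }

  truth_cols <- c("survivor_id", "gcr_type", "breakpoint_pos",
                  "breakpoint_coord", "telomere_units", "telomere_tail",
                  "microhomology_length", "partner_name", "partner_pos",
                  "partner_coord")
  if (n == 0) {
    truth <- as.data.frame(setNames(
      list(character(0), character(0), integer(0), integer(0), integer(0),
           character(0), integer(0), character(0), integer(0), integer(0)),
      truth_cols))
    coh <- structure(list(reads = setNames(character(0), character(0)),
                          truth = truth, reference = ref, partner = partner),
                     class = "gcr_cohort")
    if (!is.null(fasta)) .write_cohort_fasta(coh, fasta)
    if (!is.null(truth_tsv))
      utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    return(coh)
  }

  type_vec <- sample(rep(types, times = counts))
  refseq <- ref$sequence
  L <- nchar(refseq)
  bp_lo <- max(100L, as.integer(min(flank, 300L)))
  bp_hi <- L - 60L

  # disjoint acceptor windows in the partner for all translocations
  kmax <- max(microhomology_range)
  if (n_tr > 0) {
    slot_w <- as.integer(tail_len) + kmax + 20L
    slots <- seq(kmax + 10L, nchar(partner$sequence) - tail_len - 25L,
                 by = slot_w)
    if (length(slots) < n_tr)
      stop("partner region too short for ", n_tr,
           " disjoint translocation junctions; enlarge it")
    tr_pos <- slots[sample.int(length(slots), n_tr)]
  }

  # pass 1: assign breakpoints and, for translocations, engineer all
  # acceptor junctions into a single shared partner sequence
  bp_vec <- integer(n); mh_vec <- rep(NA_integer_, n)
  tu_vec <- rep(NA_integer_, n); pp_vec <- rep(NA_integer_, n)
  partnerseq <- if (!is.null(partner)) partner$sequence else NULL
  i_tr <- 0L
  for (i in seq_len(n)) {
    t <- type_vec[i]
    if (t == "deletion_telomere_addition") {
      repeat {
        bp <- sample(bp_lo:bp_hi, 1)
        if (.char_at(refseq, bp + 1) != "G") break
      }
      bp_vec[i] <- bp
      tu_vec[i] <- sample(telomere_unit_range, 1)
    } else if (t == "translocation") {
      i_tr <- i_tr + 1L
      bp_vec[i] <- sample(bp_lo:bp_hi, 1)
      mh_vec[i] <- sample(microhomology_range, 1)
      pp_vec[i] <- tr_pos[i_tr]
      plan <- .plan_translocation_edits(refseq, partnerseq, bp_vec[i],
                                        pp_vec[i], mh_vec[i])
      partnerseq <- plan$partnerseq
    } else {
      bp_vec[i] <- sample(bp_lo:bp_hi, 1)
    }
  }
  partner_final <- partner
  if (!is.null(partner)) partner_final$sequence <- partnerseq

  # pass 2: build reads against the final (fully edited) partner
  ids <- sprintf("survivor_%03d", seq_len(n))
  reads <- character(n)
  tails <- character(n)
  for (i in seq_len(n)) {
    t <- type_vec[i]
    bp <- bp_vec[i]
    start <- if (is.finite(flank)) max(1L, bp - as.integer(flank) + 1L) else 1L
    prefix <- substr(refseq, start, bp)
    if (t == "deletion_telomere_addition") {
      tails[i] <- .sample_telomere_tail(tu_vec[i], telomere_motif())
      reads[i] <- paste0(prefix, tails[i])
    } else if (t == "translocation") {
      p <- pp_vec[i]
      tl <- min(as.integer(tail_len), nchar(partnerseq) - p + 1L)
      reads[i] <- paste0(prefix, substr(partnerseq, p, p + tl - 1L))
    } else {
      repeat {
        tl <- .random_dna(40, 0.5)
        if (!grepl("GTTAC", tl, fixed = TRUE) &&
            .char_at(tl, 1) != .char_at(refseq, bp + 1)) break
      }
      reads[i] <- paste0(prefix, tl)
    }
  }
  names(reads) <- ids

  truth <- data.frame(
    survivor_id = ids, gcr_type = type_vec, breakpoint_pos = bp_vec,
    breakpoint_coord = ref$genome_offset + bp_vec - 1L,
    telomere_units = tu_vec, telomere_tail = tails,
    microhomology_length = mh_vec,
    partner_name = ifelse(type_vec == "translocation",
                          if (!is.null(partner)) partner$name else "", ""),
    partner_pos = pp_vec,
    partner_coord = ifelse(is.na(pp_vec), NA_integer_,
                           if (!is.null(partner))
                             partner$genome_offset + pp_vec - 1L
                           else NA_integer_),
    stringsAsFactors = FALSE)

  coh <- structure(list(reads = reads, truth = truth, reference = ref,
                        partner = partner_final), class = "gcr_cohort")
  if (!is.null(fasta)) .write_cohort_fasta(coh, fasta)
  if (!is.null(truth_tsv))
    utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  coh
}

.write_cohort_fasta <- function(coh, path) {
  x <- Biostrings::DNAStringSet(coh$reads)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @export
print.gcr_cohort <- function(x, ...) {
  cat(sprintf("gcr_cohort: %d survivors\n", length(x$reads)))
  if (nrow(x$truth) > 0) print(table(x$truth$gcr_type))
  invisible(x)
}
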