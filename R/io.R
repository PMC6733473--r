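# Tabular and structured I/O: culture tables (TSV/CSV), result files
# (JSON + TSV + BED). TSV is the primary tabular format; decimal points
# are locale-independent and scientific notation is accepted on input.

.required_culture_cols <- c("r", "z", "nonselective_count", "dilution_factor",
                            "plated_volume_ml", "culture_volume_ml")

# field-level validation with row/column-citing error messages
validate_culture_table <- function(df, file = NULL) {
  where <- if (is.null(file)) "" else sprintf(" in '%s'", file)
  if (!is.data.frame(df)) stop("culture table must be a data frame")
  missing_cols <- setdiff(.required_culture_cols, names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("missing column(s)%s: %s", where,
                 paste(missing_cols, collapse = ", ")))
  for (col in .required_culture_cols) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0)
        stop(sprintf("non-numeric value in column '%s', row %d%s",
                     col, bad[1], where))
      df[[col]] <- vn
      v <- vn
    }
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("missing or non-finite value in column '%s', row %d%s",
                   col, bad[1], where))
  }
  checks <- list(
    list("r", function(v) v >= 0, "must be >= 0"),
    list("z", function(v) v > 0 & v <= 1, "must be in (0, 1]"),
    list("nonselective_count", function(v) v >= 0, "must be >= 0"),
    list("dilution_factor", function(v) v >= 1, "must be >= 1"),
    list("plated_volume_ml", function(v) v > 0, "must be > 0"),
    list("culture_volume_ml", function(v) v > 0, "must be > 0"))
  for (chk in checks) {
    bad <- which(!chk[[2]](df[[chk[[1]]]]))
    if (length(bad) > 0)
      stop(sprintf("column '%s', row %d%s: value %s %s",
                   chk[[1]], bad[1], where,
                   format(df[[chk[[1]]]][bad[1]]), chk[[3]]))
  }
  df
}

#' Read a fluctuation-culture table
#'
#' Reads a TSV or CSV culture table with header columns `strain`, `r`,
#' `z`, `nonselective_count`, `dilution_factor`, `plated_volume_ml`,
#' `culture_volume_ml` (`strain` optional) and validates every field,
#' citing the offending row and column on failure.
#'
#' @param path File path; `.csv` is read comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param sep Optional field separator.
#' @return A validated data frame, one row per culture.
#' @export
read_culture_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  validate_culture_table(df, file = path)
}

#' Write a fluctuation-culture table
#'
#' @param df Culture table data frame.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return The path, invisibly.
#' @export
write_culture_table <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# small deterministic hash for provenance stamping (no external digest
# dependency; not cryptographic)
.provenance_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 268435399
  sprintf("%07x", h)
}

.rate_row <- function(e) {
  data.frame(strain = e$strain, rate = e$rate,
             is_upper_bound = e$is_upper_bound,
             ci_low = e$ci_low, ci_high = e$ci_high,
             ci_coverage = e$ci_coverage, n_cultures = e$n_cultures,
             stringsAsFactors = FALSE)
}

#' Write assay results as JSON, TSV and BED
#'
#' Serializes rate estimates, comparisons and junction records into a
#' machine-readable JSON file (schema-versioned, full numeric
#' precision, provenance-stamped with package version, seed and a
#' config hash), a human-readable TSV of rates, and a BED file of
#' breakpoint coordinates (0-based half-open, one record per junction).
#' Empty inputs produce valid, schema-complete outputs.
#'
#' @param estimates A `gcr_rate` object or list thereof (may be empty).
#' @param comparisons Optional list of `gcr_rate_comparison` objects.
#' @param junctions Optional junction data frame from
#'   [classify_cohort()].
#' @param path_prefix Output prefix; files `<prefix>.json`,
#'   `<prefix>_rates.tsv` and `<prefix>_breakpoints.bed` are written.
#' @param seed Optional seed to record in the provenance block.
#' @param config Optional configuration list; hashed into the
#'   provenance block.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_gcr_results <- function(estimates = list(), comparisons = list(),
                              junctions = NULL, path_prefix,
                              seed = NULL, config = NULL) {
  if (inherits(estimates, "gcr_rate")) estimates <- list(estimates)
  if (inherits(comparisons, "gcr_rate_comparison"))
    comparisons <- list(comparisons)
  paths <- c(json = paste0(path_prefix, ".json"),
             rates = paste0(path_prefix, "_rates.tsv"),
             bed = paste0(path_prefix, "_breakpoints.bed"))

  rates_df <- if (length(estimates) > 0)
    do.call(rbind, lapply(estimates, .rate_row))
  else data.frame(strain = character(0), rate = numeric(0),
                  is_upper_bound = logical(0), ci_low = numeric(0),
                  ci_high = numeric(0), ci_coverage = numeric(0),
                  n_cultures = integer(0))
  utils::write.table(rates_df, paths["rates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bed <- if (!is.null(junctions) && nrow(junctions) > 0)
    data.frame(chrom = junctions$ref_name,
               start = junctions$breakpoint_coord - 1L,
               end = junctions$breakpoint_coord,
               name = junctions$survivor_id,
               score = 0L,
               strand = ifelse(is.na(junctions$partner_strand), ".",
                               junctions$partner_strand))
  else data.frame(chrom = character(0), start = integer(0), end = integer(0),
                  name = character(0), score = integer(0),
                  strand = character(0))
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  payload <- list(
    schema = "gcrassay/1",
    provenance = list(
      package_version = as.character(utils::packageVersion("gcrassay")),
      seed = seed,
      config_hash = .provenance_hash(config)),
    estimates = lapply(estimates, function(e)
      list(strain = e$strain, rate = e$rate,
           is_upper_bound = e$is_upper_bound,
           ci_low = e$ci_low, ci_high = e$ci_high,
           ci_coverage = e$ci_coverage, n_cultures = e$n_cultures,
           per_culture_rate = e$per_culture_rate)),
    comparisons = lapply(comparisons, function(cp)
      list(strain_a = cp$strain_a, strain_b = cp$strain_b,
           p_value = cp$p_value, method = cp$method,
           fold_change = cp$fold_change)),
    junctions = if (is.null(junctions)) list() else junctions)
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}

#' Read back a results JSON file
#'
#' @param path Path to a JSON file written by [write_gcr_results()].
#' @return The parsed list.
#' @export
read_gcr_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
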