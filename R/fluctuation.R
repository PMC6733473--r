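# Fluctuation-assay estimation of GCR rates per cell division.
#
# A fluctuation experiment grows many independent cultures from small
# inocula, plates a fraction z of each saturated culture on selective
# media, and counts resistant colonies r. The number of de novo GCR
# events per culture, m, is recovered from r with the Lea-Coulson
# median estimator; dividing by the total cell number N of the culture
# gives a per-culture rate, and the median across cultures is reported
# as the GCR rate of the strain.

#' Lea-Coulson median estimate of mutational events per culture
#'
#' Converts a selective-plate colony count into the expected number of
#' de novo GCR (or mutation) events in the whole culture, using the
#' closed-form median estimator
#' \deqn{m = (r/z - 0.693) / \ln(r/z + 0.367)}
#' where `r` is the colony count on selective media and `z` the fraction
#' of the culture that was plated. The formula is undefined or negative
#' for small counts, so `m` is defined as 0 whenever `r/z <= 1`: an
#' event count cannot be negative and the estimator is only meaningful
#' once the rescaled count exceeds one colony equivalent.
#'
#' @param r Integer vector of selective-plate colony counts (>= 0).
#' @param z Fraction of each culture plated on selective media, in
#'   (0, 1]. Recycled against `r`.
#' @return Numeric vector of estimated event counts `m >= 0`.
#' @examples
#' lea_coulson_m(10, 1)       # ~3.98 events
#' lea_coulson_m(0:3, 1)      # clamped to 0 for r/z <= 1
#' @seealso [estimate_rate()] for the full per-strain pipeline.
#' @export
lea_coulson_m <- function(r, z = 1) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("'r' must be a non-negative finite colony count")
  if (any(!is.finite(z)) || any(z <= 0) || any(z > 1))
    stop("'z' must lie in (0, 1]")
  x <- r / z
  m <- ifelse(x > 1, (x - 0.693) / log(x + 0.367), 0)
  pmax(m, 0)
}

#' Total cell number of a culture from the non-selective plating
#'
#' Counts back the total number of cells in a saturated culture from the
#' colony count on a diluted non-selective plate:
#' `N = count * dilution_factor * culture_volume / plated_volume`.
#'
#' @param nonselective_count Colony count on the non-selective plate
#'   (> 0; a zero count leaves the population size unmeasurable).
#' @param dilution_factor Fold dilution of the suspension before
#'   plating (>= 1), e.g. `1e5`.
#' @param plated_volume_ml Volume of the dilution plated, in ml.
#' @param culture_volume_ml Total culture volume, in ml.
#' @return Numeric vector of total cell numbers.
#' @examples
#' total_cells(100, 1e5, 0.1, 10)  # 1e9 cells
#' @export
total_cells <- function(nonselective_count, dilution_factor,
                        plated_volume_ml, culture_volume_ml) {
  if (any(nonselective_count <= 0))
    stop("'nonselective_count' must be > 0: total population unmeasurable")
  if (any(dilution_factor < 1)) stop("'dilution_factor' must be >= 1")
  if (any(plated_volume_ml <= 0) || any(culture_volume_ml <= 0))
    stop("volumes must be > 0")
  if (any(plated_volume_ml > culture_volume_ml * dilution_factor))
    stop("'plated_volume_ml' exceeds the diluted culture volume")
  nonselective_count * dilution_factor * culture_volume_ml / plated_volume_ml
}

#' Order-statistic confidence interval for the population median
#'
#' Returns the tightest symmetric interval of order statistics
#' `(x_(k), x_(n-k+1))` whose exact binomial coverage of the population
#' median is at least `coverage`. Coverage of the k-th symmetric
#' interval is `1 - 2 * pbinom(k - 1, n, 0.5)` for samples from a
#' continuous distribution. When even the widest interval (sample
#' minimum to maximum) cannot attain the requested coverage (n <= 5 for
#' 95%), that interval is returned with a warning and the attainable
#' coverage recorded.
#'
#' @param values Numeric vector, length >= 2.
#' @param coverage Target coverage in (0, 1); default 0.95 matches the
#'   ">95% confidence interval" convention of fluctuation assays.
#' @return Named numeric vector `c(low, high)` with attributes `k` (the
#'   order-statistic depth used), `coverage` (exact attained coverage)
#'   and `attained` (logical, `FALSE` when the target was unattainable).
#' @examples
#' median_ci(1:7)  # (1, 7); exact coverage 1 - 2/128 = 0.984
#' @export
median_ci <- function(values, coverage = 0.95) {
  if (!is.numeric(values) || length(values) < 2)
    stop("'values' must be a numeric vector of length >= 2")
  if (!is.numeric(coverage) || length(coverage) != 1 ||
      coverage <= 0 || coverage >= 1)
    stop("'coverage' must be a single number in (0, 1)")
  n <- length(values)
  s <- sort(values)
  ks <- seq_len(floor((n + 1) / 2))
  cov_k <- 1 - 2 * stats::pbinom(ks - 1, n, 0.5)
  ok <- cov_k >= coverage
  if (!any(ok)) {
    warning(sprintf(
      "coverage %.3f unattainable with n = %d (max %.3f); returning sample range",
      coverage, n, cov_k[1]))
    k <- 1L
    attained <- FALSE
  } else {
    k <- max(ks[ok])
    attained <- TRUE
  }
  out <- c(low = s[k], high = s[n - k + 1])
  attr(out, "k") <- k
  attr(out, "coverage") <- cov_k[k]
  attr(out, "attained") <- attained
  out
}

#' Estimate a strain's GCR rate from a fluctuation-culture table
#'
#' Runs the full median-rate pipeline on a culture table: each culture's
#' event count `m_i = lea_coulson_m(r_i, z_i)` is divided by its total
#' cell number `N_i` (from the non-selective plating), and the median of
#' the per-culture rates `m_i / N_i` is reported as the GCR rate per
#' cell division. When the median is zero (no informative cultures), a
#' tentative rate is computed by assuming one event in every culture
#' (`m = 1`), reported as an upper bound with `is_upper_bound = TRUE`
#' and no confidence interval. Otherwise an exact order-statistic
#' confidence interval for the median rate is attached.
#'
#' @param cultures A data frame with one row per culture and columns
#'   `r`, `z`, `nonselective_count`, `dilution_factor`,
#'   `plated_volume_ml`, `culture_volume_ml` and optionally `strain`
#'   (see [read_culture_table()]).
#' @param coverage Confidence-interval coverage; default 0.95.
#' @param strain Optional strain label; defaults to the `strain` column
#'   when present.
#' @return An object of class `gcr_rate`: a list with elements `strain`,
#'   `per_culture_m`, `per_culture_N`, `per_culture_rate`, `rate`,
#'   `is_upper_bound`, `ci_low`, `ci_high`, `ci_coverage`, `n_cultures`.
#' @examples
#' tab <- data.frame(r = c(0, 0, 0, 2, 5, 20, 400), z = 1,
#'                   nonselective_count = 100, dilution_factor = 1e5,
#'                   plated_volume_ml = 0.1, culture_volume_ml = 10)
#' estimate_rate(tab)
#' @export
estimate_rate <- function(cultures, coverage = 0.95, strain = NULL) {
  cultures <- validate_culture_table(cultures)
  n <- nrow(cultures)
  if (n < 1) stop("'cultures' must contain at least one culture")
  if (n < 7)
    warning(sprintf(
      "only %d cultures; fluctuation assays conventionally use at least 7", n))
  if (is.null(strain)) {
    strain <- if ("strain" %in% names(cultures))
      paste(unique(cultures$strain), collapse = "+") else "unknown"
  }
  m <- lea_coulson_m(cultures$r, cultures$z)
  N <- total_cells(cultures$nonselective_count, cultures$dilution_factor,
                   cultures$plated_volume_ml, cultures$culture_volume_ml)
  rate_i <- m / N
  med <- stats::median(rate_i)
  if (med == 0) {
    # zero-median rule: assume m = 1 in every culture; the result is an
    # upper bound on the rate and carries no confidence interval
    rate <- stats::median(1 / N)
    ub <- TRUE
    ci <- c(low = NA_real_, high = NA_real_)
    cov_attained <- NA_real_
  } else {
    rate <- med
    ub <- FALSE
    ci <- median_ci(rate_i, coverage)
    cov_attained <- attr(ci, "coverage")
  }
  structure(list(
    strain = strain,
    per_culture_m = m,
    per_culture_N = N,
    per_culture_rate = rate_i,
    rate = rate,
    is_upper_bound = ub,
    ci_low = unname(ci["low"]),
    ci_high = unname(ci["high"]),
    ci_coverage = unname(cov_attained),
    n_cultures = n
  ), class = "gcr_rate")
}

#' @export
print.gcr_rate <- function(x, ...) {
  cat("GCR rate estimate (fluctuation assay)\n")
  cat(sprintf("  strain:       %s\n", x$strain))
  cat(sprintf("  cultures:     %d\n", x$n_cultures))
  cat(sprintf("  rate:         %.3g per cell division%s\n", x$rate,
              if (x$is_upper_bound) " (upper bound, zero-median rule)" else ""))
  if (!x$is_upper_bound)
    cat(sprintf("  %.1f%% CI:     [%.3g, %.3g]\n", 100 * x$ci_coverage,
                x$ci_low, x$ci_high))
  invisible(x)
}

#' Compare two strains' GCR rates with a two-tailed Mann-Whitney test
#'
#' Tests the per-culture rates (`m_i / N_i`) of two strains against each
#' other. With both sample sizes at most 8 and no ties the exact null
#' distribution of the U statistic is used (equivalent to enumerating
#' all labelings); otherwise a tie-corrected normal approximation with
#' continuity correction is applied. The fold change between the two
#' reported (median) rates is attached.
#'
#' @param a,b Objects of class `gcr_rate` (see [estimate_rate()]), or
#'   plain numeric vectors of per-culture rates.
#' @return An object of class `gcr_rate_comparison`: a list with
#'   `strain_a`, `strain_b`, `statistic` (U for sample a), `p_value`,
#'   `method` ("exact" or "approximate") and `fold_change`
#'   (rate a / rate b).
#' @examples
#' a <- c(1, 2, 3, 4, 5, 6, 7); b <- c(8, 9, 10, 11, 12, 13, 14)
#' compare_rates(a, b)$p_value  # 2/3432
#' @export
compare_rates <- function(a, b) {
  lab_a <- "a"; lab_b <- "b"
  fc <- NA_real_
  if (inherits(a, "gcr_rate")) {
    lab_a <- a$strain
    if (inherits(b, "gcr_rate") && b$rate > 0) fc <- a$rate / b$rate
    a <- a$per_culture_rate
  }
  if (inherits(b, "gcr_rate")) { lab_b <- b$strain; b <- b$per_culture_rate }
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (n1 <= 8 && n2 <= 8 && !ties) {
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    dev <- u - mu
    cc <- sign(dev) * 0.5  # continuity correction toward the null
    z <- if (sigma2 > 0) (dev - cc) / sqrt(sigma2) else 0
    if (dev == 0) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "approximate"
  }
  if (is.na(fc) && is.numeric(a) && is.numeric(b)) {
    mb <- stats::median(b)
    if (mb > 0) fc <- stats::median(a) / mb
  }
  structure(list(strain_a = lab_a, strain_b = lab_b,
                 statistic = u, p_value = p, method = method,
                 fold_change = fc),
            class = "gcr_rate_comparison")
}

#' @export
print.gcr_rate_comparison <- function(x, ...) {
  cat("Two-tailed Mann-Whitney comparison of per-culture GCR rates\n")
  cat(sprintf("  %s vs %s: U = %g, p = %.3g (%s)\n",
              x$strain_a, x$strain_b, x$statistic, x$p_value, x$method))
  if (!is.na(x$fold_change))
    cat(sprintf("  fold change: %.3g\n", x$fold_change))
  invisible(x)
}

#' Fold change between two rates
#'
#' Ratio of a strain's rate to a reference rate. Figures conventionally
#' report the integer fold change, rounded half away from zero and
#' computed from the unrounded rates.
#'
#' @param rate,reference_rate Per-cell-division rates;
#'   `reference_rate > 0`.
#' @param as_integer Report the conventional integer fold change instead
#'   of the raw ratio.
#' @return Numeric ratio, or its integer report.
#' @examples
#' fold_change(1.1e-7, 2.6e-9, as_integer = TRUE)  # 42
#' @export
fold_change <- function(rate, reference_rate, as_integer = FALSE) {
  if (any(reference_rate <= 0)) stop("'reference_rate' must be > 0")
  ratio <- rate / reference_rate
  if (as_integer) sign(ratio) * floor(abs(ratio) + 0.5) else ratio
}

#' Length-normalized GCR rate
#'
#' Divides a per-cell-division rate by the length of the breakpoint
#' region in kb, for comparison between assay systems with different
#' target sizes. Reported values are conventionally given to two
#' significant figures.
#'
#' @param rate Per-cell-division rate.
#' @param region_length_kb Length of the breakpoint region in kb (> 0).
#' @param digits Optional number of significant digits for reporting.
#' @return Rate per cell division per kb.
#' @examples
#' normalize_per_kb(2.6e-9, 16.8, digits = 2)  # 1.5e-10
#' @export
normalize_per_kb <- function(rate, region_length_kb, digits = NULL) {
  if (any(region_length_kb <= 0)) stop("'region_length_kb' must be > 0")
  out <- rate / region_length_kb
  if (!is.null(digits)) out <- signif(out, digits)
  out
}
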