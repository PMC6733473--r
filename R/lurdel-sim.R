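# Luria-Delbruck culture simulator.
#
# Discrete synchronous generations under the Lea-Coulson model: the
# wild-type population doubles each generation, new mutants arise at
# division with per-division probability mu, and each mutant clone
# founded at generation g doubles deterministically to final size
# 2^(G - g). No back mutation, fitness cost or death. Populations are
# tracked as counts, never as individual cells, so saturated cultures
# of 1e8-1e9 cells simulate in milliseconds.

#' Simulator settings for fluctuation cultures
#'
#' @param mu Per-cell-division GCR/mutation probability in `[0, 1]`.
#' @param n0 Founder population (>= 1). Default 100 cells, a small
#'   inoculum excised from a colony.
#' @param n_final Saturated population. Growth proceeds in whole
#'   doublings, so the realized population is `n0 * 2^G` with
#'   `G = ceiling(log2(n_final / n0))`. Default `2e8`: a 2 ml culture
#'   at a typical fission-yeast saturation density of 1e8 cells/ml.
#' @param z Fraction of the saturated culture plated on selective
#'   media, in (0, 1].
#' @param n_cultures Number of independent cultures per experiment;
#'   default 7, the conventional minimum.
#' @param dilution_factor,plated_volume_ml,culture_volume_ml
#'   Non-selective plating scheme used to count back the total cell
#'   number; defaults (1e5-fold dilution, 0.1 ml plated, 2 ml culture)
#'   give an expected non-selective count of ~100 colonies.
#' @param pre_expansion Optional whole-colony pre-expansion factor
#'   (>= 1): when > 1 the founder population is itself first grown from
#'   `n0 / pre_expansion` cells under the same mutation process,
#'   modelling mutations arising while the picked colony grew. Default
#'   1 (off), matching the estimator's assumptions.
#' @param seed Integer seed; all draws are reproducible given
#'   `(seed, culture_index)`.
#' @param strain Strain label written into the culture table.
#' @return An object of class `ld_sim_params`.
#' @examples
#' ld_sim_params(mu = 2.6e-9)
#' @export
ld_sim_params <- function(mu, n0 = 100, n_final = 2e8, z = 1,
                          n_cultures = 7L, dilution_factor = 1e5,
                          plated_volume_ml = 0.1, culture_volume_ml = 2,
                          pre_expansion = 1, seed = 1L, strain = "sim") {
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0, mu <= 1,
            n0 >= 1, n_final >= n0, z > 0, z <= 1, n_cultures >= 1,
            dilution_factor >= 1, plated_volume_ml > 0,
            culture_volume_ml > 0, pre_expansion >= 1)
  if (!is.finite(mu * n_final)) stop("mu * n_final must be finite")
  structure(list(mu = mu, n0 = n0, n_final = n_final, z = z,
                 n_cultures = as.integer(n_cultures),
                 dilution_factor = dilution_factor,
                 plated_volume_ml = plated_volume_ml,
                 culture_volume_ml = culture_volume_ml,
                 pre_expansion = pre_expansion,
                 seed = as.integer(seed), strain = strain),
            class = "ld_sim_params")
}

#' @export
print.ld_sim_params <- function(x, ...) {
  cat(sprintf(
    "Luria-Delbruck simulator: mu = %.3g, n0 = %g, n_final = %g, z = %g, %d cultures, seed %d\n",
    x$mu, x$n0, x$n_final, x$z, x$n_cultures, x$seed))
  invisible(x)
}

# deterministic 32-bit substream seed from (seed, index)
.substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6 * 7919 + index * 104729) %% 2147483629)
}

# new mutants among 'divisions' cell divisions: Poisson approximation for
# small mu, exact binomial when mu is large enough for it to matter
.draw_mutations <- function(divisions, mu) {
  if (mu == 0 || divisions == 0) return(0)
  if (mu > 0.05 && divisions < 2^31) {
    stats::rbinom(1, round(divisions), mu)
  } else {
    k <- stats::rpois(1, mu * divisions)
    if (k > divisions)
      stop("mutation load exceeds population; mu * n_final too large")
    k
  }
}

# grow from 'start' cells through G doublings; returns final wild-type
# count, the number of mutation events, and the mutant count at
# saturation (clones double deterministically after founding)
.grow <- function(start, G, mu, carried_mutants = 0) {
  wt <- start
  events <- 0
  mutants <- carried_mutants * 2^G
  if (G > 0) for (g in seq_len(G)) {
    new_m <- .draw_mutations(wt, mu)
    events <- events + new_m
    mutants <- mutants + new_m * 2^(G - g)
    wt <- 2 * wt - new_m
  }
  list(wt = wt, events = events, mutants = mutants)
}

#' Simulate one fluctuation culture
#'
#' Grows a single culture under the discrete-generation Lea-Coulson
#' model, thins the saturated mutant population by binomial plating at
#' fraction `z`, and back-computes a non-selective colony count from the
#' realized population with Poisson plating noise. Deterministic given
#' `(params$seed, culture_index)`.
#'
#' @param params An [ld_sim_params()] object.
#' @param culture_index Positive integer identifying the culture; each
#'   index selects an independent RNG substream.
#' @return A one-row data frame in the standard culture-table layout
#'   (`strain`, `r`, `z`, `nonselective_count`, `dilution_factor`,
#'   `plated_volume_ml`, `culture_volume_ml`), with attributes
#'   `true_mutants` (mutant cells at saturation), `true_events` (de novo
#'   mutation events) and `true_N` (realized population size).
#' @examples
#' simulate_culture(ld_sim_params(mu = 1e-7, seed = 1), 1)
#' @export
simulate_culture <- function(params, culture_index) {
  stopifnot(inherits(params, "ld_sim_params"), culture_index >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(.substream_seed(params$seed, culture_index))

  carried <- 0
  start <- params$n0
  events_pre <- 0
  if (params$pre_expansion > 1) {
    Gpre <- ceiling(log2(params$pre_expansion))
    pre_start <- max(1, round(params$n0 / 2^Gpre))
    pre <- .grow(pre_start, Gpre, params$mu)
    carried <- pre$mutants / 2^0  # mutants present in the inoculum
    events_pre <- pre$events
    start <- pre$wt + pre$mutants
  }
  G <- if (params$n_final > start) ceiling(log2(params$n_final / start)) else 0L
  res <- .grow(start - carried, G, params$mu, carried_mutants = carried)
  N_true <- start * 2^G
  if (res$mutants > N_true)
    stop("mutation load exceeds population; mu * n_final too large")

  r <- stats::rbinom(1, res$mutants, params$z)
  lambda <- N_true * params$plated_volume_ml /
    (params$culture_volume_ml * params$dilution_factor)
  ns <- stats::rpois(1, lambda)

  out <- data.frame(strain = params$strain, r = r, z = params$z,
                    nonselective_count = ns,
                    dilution_factor = params$dilution_factor,
                    plated_volume_ml = params$plated_volume_ml,
                    culture_volume_ml = params$culture_volume_ml,
                    stringsAsFactors = FALSE)
  attr(out, "true_mutants") <- res$mutants
  attr(out, "true_events") <- res$events + events_pre
  attr(out, "true_N") <- N_true
  out
}

#' Simulate a complete fluctuation experiment
#'
#' Draws `params$n_cultures` independent cultures, one RNG substream per
#' culture, and returns them as a standard culture table suitable for
#' [estimate_rate()]. Bit-for-bit reproducible for a fixed seed.
#'
#' @param params An [ld_sim_params()] object.
#' @return A data frame with one row per culture; the attribute `truth`
#'   holds a per-culture data frame of the simulator's own bookkeeping
#'   (`mutants`, `events`, `N_true`).
#' @examples
#' tab <- simulate_experiment(ld_sim_params(mu = 1e-7, seed = 42))
#' estimate_rate(tab)
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "ld_sim_params"))
  rows <- lapply(seq_len(params$n_cultures), function(i)
    simulate_culture(params, i))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(
    culture = seq_len(params$n_cultures),
    mutants = vapply(rows, attr, numeric(1), which = "true_mutants"),
    events = vapply(rows, attr, numeric(1), which = "true_events"),
    N_true = vapply(rows, attr, numeric(1), which = "true_N"))
  out
}
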