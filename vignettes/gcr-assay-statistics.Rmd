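---
title: "Estimating and dissecting gross chromosomal rearrangement rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and dissecting gross chromosomal rearrangement rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcrassay)
```

## The assay and its statistics

Gross chromosomal rearrangements (GCRs) — terminal deletions,
translocations and related large-scale events — are rare: on the order
of one event per 10^9 cell divisions in wild-type yeast. The GCR assay
measures their rate by placing two counter-selectable markers in a
non-essential subtelomeric region (in the fission-yeast version, a
*ura4*–*TK* cassette ~150 kb from the right telomere of chromosome I)
and selecting for simultaneous loss of both. Because the nearest
centromeric essential gene (*sec16*) lies ~16.8 kb from the cassette,
any rearrangement whose breakpoint falls in this "breakpoint region" is
recoverable; simultaneous point mutation of both markers is negligible
(~10^-14 per division, see `double_mutation_rates()`).

Rates cannot be read off a single plating: by the time a culture
saturates, an early ("jackpot") event has grown into a large resistant
clone, so resistant counts across replicate cultures follow the
heavy-tailed Luria–Delbrück distribution, not a Poisson. The classical
fluctuation-analysis remedy is to grow many independent cultures from
small inocula and convert the colony count of each into the expected
number of *de novo* events per culture with the Lea–Coulson median
estimator,

$$ m = \frac{r/z - 0.693}{\ln(r/z + 0.367)}, $$

where $r$ is the selective colony count and $z$ the fraction of the
culture plated. Dividing by the culture's total cell number $N$
(counted back from a diluted non-selective plating,
$N = \text{count} \times \text{dilution} \times V_\text{culture} /
V_\text{plated}$) gives a per-culture rate, and the **median** across
at least 7 cultures is reported as the strain's GCR rate per cell
division (`estimate_rate()`).

### Numerical choices

* **Clamp at small counts.** The printed formula is undefined at
  $r/z = 0$ and negative just above it; `lea_coulson_m()` returns 0
  whenever $r/z \le 1$. An event count cannot be negative, and the
  estimator is never evaluated in that region in practice.
* **Zero-median upper bound.** When the median per-culture rate is
  zero the data only bound the rate from above; following assay
  convention the rate is recomputed assuming $m = 1$ in every culture
  (i.e. $\mathrm{median}(1/N_i)$), flagged `is_upper_bound`, and no
  confidence interval is attached.
* **Confidence intervals.** The assay literature cites a prior method
  without restating it; this package uses the exact nonparametric
  order-statistic interval for the median: the tightest symmetric pair
  of order statistics $(x_{(k)}, x_{(n-k+1)})$ whose binomial coverage
  $1 - 2\,P(\mathrm{Bin}(n, 1/2) \le k-1)$ reaches the target. For
  $n = 7$ at 95% this is the sample range, with exact coverage 98.4% —
  consistent with the ">95% confidence interval" phrasing used in this
  field. Coverage 95% is unattainable for $n \le 5$; `median_ci()`
  then returns the range with a warning rather than failing.
* **Comparisons.** Genotypes are compared by a two-tailed Mann–Whitney
  test on the per-culture rates $m_i/N_i$ (the quantities whose median
  is reported). The exact U null distribution is used for both samples
  $\le 8$ without ties; otherwise a tie-corrected normal approximation
  with continuity correction. No multiple-testing adjustment is
  applied, matching the raw-p-value convention. Fold changes are
  computed from unrounded rates and only rounded (half away from zero)
  at report time.

## The culture simulator as a stated world

`simulate_experiment()` implements the model under which the estimator
is derived — discrete synchronous generations, new mutants arising at
division as Poisson($\mu \times$ wild-type population) (exact binomial
draws when $\mu > 0.05$), each clone doubling deterministically
thereafter, binomial plating at fraction $z$, and Poisson noise on the
non-selective count-back plate. There is no death, fitness cost or
back mutation. Growth proceeds in whole doublings, so the realized
population is $n_0 2^G$ with $G = \lceil \log_2(n_\text{final}/n_0)
\rceil$.

Defaults state a realistic assay where the protocol is silent: a 2 ml
culture saturating at $10^8$ cells/ml ($n_\text{final} = 2\times10^8$),
founded by $n_0 = 100$ cells, with 0.1 ml of a $10^5$-fold dilution on
the non-selective plate (expected count ~100). The colony-growth phase
before liquid culture is not simulated by default (the estimator
ignores it too); a `pre_expansion` factor is available. These defaults
were chosen once, from the protocol's stated volumes and standard
saturation densities, and are not tuned to test outcomes.

What a green simulation test establishes: the estimator's median-scale
recovery of a known $\mu$, the jackpot overdispersion
($\mathrm{var}/\mathrm{mean} \gg 1$), and the plating-thinning identity
$E[r] = z\,E[\text{mutants}]$. What it does not: real cultures deviate
from synchronous doubling and may carry death, differential fitness or
pre-culture jackpots — none of which the estimator models either.

### A known limitation: the low-count regime

At the wild-type operating point ($\mu \approx 2.6\times10^{-9}$,
$N \approx 2\times10^8$) a culture expects only $\mu N \approx 0.5$
events, so roughly three quarters of cultures yield an estimated rate
of zero and ~93% of 7-culture experiments have a zero median. The
reported value is then the $1/N$ upper bound ($\approx 5\times10^{-9}$),
which overstates the true rate by a factor of ~1.9. This saturation is
a property of the published procedure itself, not of this
implementation: with the same estimator at $\mu N \approx 10$ the
median recovery is well within a factor of 1.5. Measuring rates near
$1/N$ reliably requires larger cultures (or more of them), and the
acceptance suite records this regime honestly rather than masking it.

## Junction classification

Survivor junctions are classified from sequence alone
(`classify_junction()`), refining the traditional ~400 bp sequential
PCR mapping (emulated by `virtual_marker_mapping()`) to base
resolution:

1. **Anchoring.** The longest exact prefix of the read (oriented
   centromere → telomere) matching the reference defines the
   breakpoint, the genomic coordinate of the last retained base; ties
   go to the longest match, then the leftmost position. Matching is
   exact by default — survivors are Sanger-grade sequences — with the
   seed length configurable. Coordinates are reported 1-based
   inclusive.
2. **Telomere calls.** The unmatched tail is greedily tiled with
   degenerate repeat units `G{1,8}TTAC` (the consensus G-rich unit of
   fission-yeast telomeres; the exact degenerate pattern is not
   standardized, so the motif, the ≤3 nt inter-unit spacers, the 12 nt
   minimum tail and the 0.8 minimum covered fraction are all
   configurable via `telomere_motif()`). Random 18-mers are called
   telomeric at well under 1%.
3. **Translocations.** A non-telomeric tail is anchored in candidate
   partner references on both strands. The junction microhomology — the
   bases attributable to both parents — is measured by walking the
   junction backwards across donor and acceptor; placement ambiguity
   within the homology tract is resolved by maximizing, which is the
   definition of microhomology. `microhomology_length()` exposes the
   same quantity for explicit donor/acceptor/fused triples.
4. **Fall-through.** Tails that are neither telomeric nor anchorable
   are `indeterminate`. Breakpoints centromeric of the essential-gene
   boundary are flagged (`beyond_boundary`), not rejected, since the
   assay's geometry makes them suspect but not impossible to observe.

## The synthetic-genome generator

`make_reference()` draws reproducible sequence at GC 0.36 (the
fission-yeast genome average) and screens it free of the core telomere
unit, so planted tails are the only telomeric sequence and round-trip
tests are exact. `make_survivor()`/`make_cohort()` plant ground truth
with two guards that make truth recovery well-defined: deletion
breakpoints are never placed where the reference continues with `G`
(the tail's leading G-run would make the coordinate ambiguous), and
translocation acceptors are locally edited — edits recorded, the edited
partner returned — so the junction shares *exactly* the requested
number of homologous bases, with mismatches planted on both flanks to
stop chance extension. Cohorts apportion types by largest remainder
(so 15 survivors at the 12:2:1 wild-type-like proportions give exactly
12 deletions, 2 translocations, 1 indeterminate) and place all
translocation junctions in disjoint windows of one shared partner.

The generator does not simulate sequencing error, whole-genome context
or chromosome circularization; a 100% round trip therefore validates
the classifier's logic, not its robustness to noisy reads.

## Assay calculators

`double_mutation_rates()` chains the published arithmetic: from a total
5-FOA-resistance mutation rate of $1.3\times10^{-7}$ and a ura5/ura4
ratio of 1.85, the *ura4* rate is $1.3\times10^{-7}/2.85 =
4.6\times10^{-8}$; scaling by ORF length (1100/800) gives
$6.3\times10^{-8}$ for *TK*; the product, $\sim 3\times10^{-15}$, is an
order-of-magnitude bound showing double point mutants cannot confound
the assay. `gcr_frequency()` is the plain plating ratio with an
optional viability correction (used after G1-arrest experiments where
rates per division are not defined). `cut_efficiency()` implements
$\Delta\Delta C_t$ relative quantification with configurable
amplification efficiency (the control amplicon is any uncut reference
locus). `survival_rate()` is the percentage of colony-forming cells
relative to an untreated control.

## Worked example

```{r example}
set.seed(1)
mut_tab <- simulate_experiment(ld_sim_params(mu = 1e-7, seed = 7,
                                             strain = "mutant_like"))
wt_tab  <- simulate_experiment(ld_sim_params(mu = 2.6e-9, seed = 8,
                                             strain = "wt_like"))
mut <- estimate_rate(mut_tab)
wt  <- suppressWarnings(estimate_rate(wt_tab))
mut
compare_rates(mut, wt)

coh <- make_cohort(15, seed = 2)
res <- classify_cohort(coh$reads, coh$reference, list(coh$partner))
table(res$gcr_type)
```
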