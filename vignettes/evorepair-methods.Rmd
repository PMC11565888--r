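---
title: "Models and methods behind evorepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evorepair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorepair)
```

evorepair analyses serial-transfer evolution experiments in budding yeast,
with a focus on compensatory ("evolutionary repair") adaptation: populations
carrying a costly perturbation — the motivating case is loss of the
replisome component Ctf4, which causes chronic DNA replication stress —
recover fitness over hundreds of generations, and the package quantifies
how fast they adapt, which genes they converge on, and what the adapted
cells look like physiologically. This vignette explains each model, its
assumptions and tunable parameters, what the synthetic-data generators do
and do not emulate, and the numerical choices made where the design was
genuinely open.

## The experimental regime and its bookkeeping

All analyses assume daily serial dilution. A culture diluted by a factor
$F$ regrows $F$-fold by the next passage, so each cycle contains
$n = \log_2 F$ generations; the standard 1:1000 dilution gives
$n = \log_2 1000 \approx 9.97$, i.e. about 10 generations per passage.
The effective population size of such a regime is approximated by
$N_e \sim N_0 \times n$, where $N_0$ is the bottleneck census size.
`design_passage()` implements exactly this arithmetic; rounding of $n$ to
whole generations is presentation only, internal computation keeps full
precision.

## Relative fitness from two-colour competitions

In the competition assay a non-fluorescent test strain is co-cultured with
a fluorescent reference. At each sampling the flow cytometer reports
fluorescent events, non-fluorescent events and total events. The package
computes

* the strain ratio $r = \mathrm{NonFluorescent}/\mathrm{Fluorescent}$
  (`compute_ratio()`),
* generations between two samples of one cycle from total-event growth,
  $g = \log_2(\mathrm{events}_{t24}/\mathrm{events}_{t0})$
  (`compute_generations()`), and
* relative fitness as the ordinary-least-squares slope of $\ln r$ on
  cumulative generations (`estimate_fitness()`).

Under constant selection $\ln r(g) = \ln r(0) + s\,g$, so the slope
estimates the per-generation selection coefficient $s$ of the test strain
against the reference. Design choices:

* **Cumulative generations start at zero at the day-0 sample** (the
  initial sample taken shortly after inoculation); generations during that
  pre-growth are not counted.
* **Natural log** is used for the ratio, so slopes are per-generation
  log-fitness differences and are additive: normalisation across
  conditions, and "delta fitness" against a deletion ancestor, are slope
  differences (`normalize_fitness()`), and the expected fitness of a
  multi-mutant under additivity is the ancestor's fitness plus the sum of
  per-mutation effects (`computed_fitness()`, which refuses duplicated
  gene entries).
* The regression is unweighted by default; `weighted = TRUE` weights
  points by their channel-event totals. Replicate slopes are aggregated as
  mean ± SD (`aggregate_fitness()`), and strain comparisons use one-way
  ANOVA with Tukey HSD (`compare_fitness()`).

The totals-versus-channels distinction matters: $g$ uses `total_events`
only, $r$ uses the two channel counts only, and the tests enforce that
scaling one does not leak into the other.

## Power-law adaptation dynamics

Fitness trajectories $\bar w(t)$ of evolving populations are fitted with
the diminishing-returns power law

$$\bar w(t) = (b\,t)^a + w_0,$$

where $w_0$ is the measured ancestral fitness (held fixed, not
estimated), $b$ is the adaptation rate and $a$ the curvature exponent.
`fit_power_law()` uses bounded Levenberg–Marquardt least squares
($b \in [0,1]$, $a \in (0, 1.5]$) restarted from $a_0 \in \{0.3, 0.5,
0.8\}$, keeping the best converged start. A straight line is fitted
alongside and both $R^2$ values reported, since nearly linear
trajectories make the exponent weakly identified. Optimiser failure is a
*reported state* (`converged = FALSE`), not an exception — real
trajectories do occasionally defeat the fit, and downstream comparisons
must be able to exclude those populations explicitly. With `fix_a = 1`
the model degenerates to the straight line through $(0, w_0)$, a useful
internal consistency check. Adaptation rates between conditions are
compared pairwise by exact Mann–Whitney tests with Bonferroni correction
(`compare_adaptation_rates()`).

## Convergent evolution: the Poisson recurrence test

The central inference is which genes are mutated across independent
populations more often than chance. With mutations scattered uniformly at
per-base rate $\lambda$, the number hitting a gene of effective length
$N$ is Poisson with mean $\mu = \lambda N$. The package:

1. classifies variants (`classify_variants()`): non-synonymous (decided
   codon-wise via the genetic code when CDS sequence is available; indels
   in CDS count as coding hits regardless of frame), synonymous,
   regulatory (within 500 bp of the gene span) or intergenic;
2. estimates $\lambda$ as counted mutations divided by the summed
   effective length $N = \mathrm{CDS} + 1000$ bp, the extra 1000 bp per
   ORF covering the same regulatory flanks the classifier admits
   (`compute_lambda()`); numerator and denominator use the same class set
   so the rate is internally consistent;
3. computes the upper tail $P(X \ge n)$ through the regularised
   incomplete-gamma identity $P(X \ge n) = P(\Gamma(n,1) \le \mu)$
   (`poisson_tail()`), which the tests verify against brute-force term
   summation to $10^{-10}$;
4. applies Benjamini–Hochberg correction at $\alpha = 0.05$ across all
   tested units (`bh_correct()`, delegated to `stats::p.adjust`).

`detect_convergence()` pools hits across populations per unit — genes, or
GO terms with hits and effective lengths summed over member genes — and
returns the ranked table. Genes significant in a wild-type background can
be removed from a focal result with `filter_background()`, separating
generic media adaptation from perturbation-specific repair.
`clonality_stats()` summarises read-fraction (clonality) profiles with
the field's conventional non-parametric tests, and
`compare_units_between_conditions()` applies Fisher's exact test to
per-unit hit counts between conditions.

Open choices resolved here: every mutation counts (no per-population
collapsing; the Poisson model counts mutations, not populations — a
collapsed mode exists for sensitivity analysis); synonymous variants are
excluded from $\lambda$'s numerator by default; variants falling in two
genes' overlapping extended spans go to the nearer CDS boundary, with
exact ties duplicated and flagged. $\lambda$ is a *pooled* rate (all
populations of a background together), so recovery tests on the
generator, whose rate is per population, expect
$\hat\lambda \approx n_\mathrm{pop}\,\lambda_\mathrm{true}$.

## CNV detection from windowed read depths

Per-100-bp read depths are (1) normalised to the genome-wide median to
control for sequencing depth, (2) reduced by the ancestor's normalised
profile, which cancels repetitive-region mapping artefacts shared between
samples, and (3) smoothed with a centred 5-window moving average whose
value sits at the centre coordinate; at contig edges the window shrinks
symmetrically so the grid stays aligned across samples. Segments are
maximal runs of $\ge$ 10 windows with $|\Delta| \ge 0.5$ copies; runs of
the same direction separated by at most 5 sub-threshold windows are
bridged first, because a single noisy window would otherwise split a long
amplification in two (set `merge_gap = 0` for strict runs). One caveat
the tests encode: when a sizeable fraction of the genome is amplified the
genome-wide median itself shifts slightly, so the copy-number readout of
a segment is best taken relative to the background median.

Recurrence of amplification at a locus across populations is tested with
an exact binomial tail (`test_recurrence()`): under the null that event
locations are uniform, each of the $n$ observed amplifications hits the
locus with probability $p_0 = \mathrm{locus}/\mathrm{genome}$, and the
p-value is $P(\mathrm{Bin}(n, p_0) \ge k)$. The uniform-location null is
the simplest defensible choice; $p_0$ is an explicit argument so
alternative nulls can be substituted.

## Growth and cell-cycle phenotypes

`fit_growth_curve()` estimates the maximum specific growth rate as the
largest slope of $\ln \mathrm{OD}$ over a sliding window of consecutive
timepoints (default 8 points, ~80 min at 10-min sampling — long enough to
damp read noise, short enough to sit inside the exponential phase);
doubling time is $\ln 2 / r$ and the maximum OD comes from a 3-point
running median. The rate is invariant to uniform OD scaling and to
blank-subtraction round trips.

`gate_dna_content()` decomposes a DNA-content histogram into G1/S/G2
fractions with a constrained mixture: Gaussian 1C peak, Gaussian 2C peak
whose mean is fixed at exactly twice the 1C mean, a shared coefficient of
variation, and a uniform S-phase bridge between the peak positions.
Weights are fitted by maximising the multinomial likelihood of the binned
counts (Nelder–Mead on softmax-parameterised weights and log-scale
$\mu_{1C}$, CV); non-convergence raises an error carrying the optimiser
diagnostics, and an effectively absent 2C component yields a warning with
$f_{G2} \approx 0$. A threshold mode (cuts at 1.25× and 1.75× the 1C
mode) is provided as a coarse fallback. `phase_durations()` multiplies
fractions by the doubling time; this linear mapping ignores the age
structure of exponentially growing populations (young cells are
over-represented), a deliberate simplification that the conventional
analysis shares — durations always sum to the supplied doubling time.

## The synthetic-data generators

Every input the pipeline reads can be generated with known truth, so all
stages are testable end to end without sequencing data.

* **`simulate_serial_transfer()`** is a Wright–Fisher serial-transfer
  model: multinomial sampling of $N_0$ cells at each bottleneck,
  Poisson injection of new mutant lineages at rate
  (cell$^{-1}$ generation$^{-1}$, counted on the bottleneck census — the
  mutants that survive dilution), and deterministic regrowth with lineage
  weights $e^{s n}$ per cycle. Beneficial effects default to an
  exponential distribution of fitness effects with mean 0.05; defaults
  mirror the experiment (12 populations, 100 passages of ~10 generations,
  $N_0 \approx 10^5$, $N_e \approx 10^6$). Frequencies are renormalised
  each step and conserve unity to $10^{-9}$; a mutation's final read
  fraction is the summed frequency of the subtree of lineages carrying
  it.
* **`simulate_competition_counts()`** draws channel counts binomially
  from the true ratio $\ln r(g) = \ln r_0 + s g$ at a fixed number of
  events per sample, while total events grow by the dilution factor
  within each cycle. Noiseless mode emits exact expectations, so the
  $(g, \ln r)$ points lie exactly on a line with slope $s$.
* **`simulate_depth_profile()`** draws window depths from a negative
  binomial (size = `dispersion`, default 100 — moderate overdispersion
  typical of uniform short-read libraries; larger values approach
  Poisson) around `mean_depth` × planted copy number.
* **`simulate_od_curve()`** is the closed-form logistic with lag plus
  Gaussian read noise; **`simulate_dna_histogram()`** mirrors the gating
  mixture exactly (two Gaussians at 1C/2C plus a uniform bridge) and
  conserves the event count.
* **`simulate_mutation_dataset()`** draws per-gene, per-population hit
  counts $\mathrm{Poisson}(\lambda N_g \cdot e_g)$ with optional planted
  enrichment factors $e_g$, uniform positions within the extended span
  and uniform read fractions on (0, 100] percent — the exact null (and
  spiked alternative) of the convergence test.
  **`make_gene_models()`** lays out a yeast-scale annotation (16
  chromosomes, log-normal CDS lengths with median ~1.35 kb, gaps wide
  enough that extended spans stay disjoint).

What the generators deliberately do **not** emulate: read-level sequences
(no FASTQ), base-level mutational signatures, diploidy, clonal
interference structure beyond what the lineage model produces, GC or
mappability bias in coverage, asymmetric or skewed cytometry peaks, and
correlated plate-reader drift. Passing recovery tests therefore
demonstrate correctness of the estimators *under the stated models*, not
robustness to every artefact of real instruments.

All generators are bit-reproducible from a single integer seed;
independent streams are derived with `derive_seed()` (a documented
multiplicative string hash modulo $2^{31}-1$), so one run seed determines
every stage without stream collisions.

## Pipeline, problem sizes and reproducibility

`validate_config()` reads a YAML (or list) configuration, fills defaults
(α = 0.05, ±500 bp regulatory flanks, +1000 bp per ORF, 100-bp windows,
smoothing span 5), rejects unknown keys outright and range-checks the
rest before anything runs. `run_pipeline()` executes the stages in
dependency order, writes per-stage TSV outputs plus a planted-truth
JSON, and returns a report whose provenance block (config hash, seed,
package version) suffices to re-execute the run; a failed stage is
recorded and its dependents skipped. Identical config and seed reproduce
all outputs byte for byte.

The package's own validation simulations use these problem sizes: 6000
genes × 48 populations with 200 null replicates and 100 power replicates
for the convergence test; 200 simulated competitions spanning
$s \in [-0.2, 0.1]$ at $10^5$ events per sample; 20 noisy power-law
trajectories; 50 planted depth profiles of 2000 windows; 10 DNA-content
mixtures of $10^5$ events. These sizes give Monte-Carlo standard errors
comfortably below the tolerances being checked while keeping a full run
in well under a minute each.

## Known limitations

* The Poisson null treats sites as independent and the rate as uniform
  across the genome; mutational hotspots or context effects would inflate
  apparent convergence.
* Effective gene length uses a fixed +1000 bp per ORF; genes with
  unusually long regulatory regions are under-covered.
* The fraction→duration mapping and the uniform S-phase bridge are
  first-order conveniences, adequate for comparing conditions rather than
  for absolute phase timing.
* Segment calling reports window-resolution boundaries (100 bp) and makes
  no attempt at breakpoint resolution, GC correction or ploidy inference.
* The serial-transfer simulator grows deterministically between
  bottlenecks; drift during growth and mutation during the final cycle
  are absorbed into the bottleneck approximation.
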