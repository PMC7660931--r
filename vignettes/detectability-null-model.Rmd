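---
title: "A null model of homology detection failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A null model of homology detection failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homfail)
```

## The problem

Lineage-specific genes — genes whose homologs are detectable only inside one
monophyletic group — are routinely interpreted as evolutionary novelties:
de novo births from non-coding sequence, or duplicates diverged beyond
recognition after neofunctionalisation. But there is a mundane alternative.
Similarity-search programs such as BLASTP declare homology only when an
alignment's bitscore clears a significance threshold, and bitscores decay as
sequences diverge. A short, fast-evolving gene can have perfectly ordinary
homologs in outgroup species that fall below the threshold. That is homology
detection *failure*, not homolog absence.

`homfail` makes this alternative a quantitative null hypothesis. For each
gene it asks: if the gene existed in the common ancestor and evolved at a
constant, novelty-free rate, what is the probability that a similarity search
would still find its ortholog at the evolutionary distance of the nearest
outgroup? Genes for which this probability is low need no special
explanation. Genes for which it is high — the search *should* have found a
homolog and did not — are the interesting candidates for genuine novelty.

## The model

Assume the bitscore between two homologs is proportional to the fraction of
identical aligned positions, and that each position substitutes at the same
protein-specific rate, constant in time and across lineages. If each
position is intact with probability $e^{-bt}$ at divergence $t$
(substitutions/site), the number of intact positions is binomial, so

$$S(t) = a\,e^{-bt}, \qquad
  \sigma^2(t) = a\,(1 - e^{-bt})\,e^{-bt},$$

where $a$ is the score of the gene against itself (it tracks protein
length: roughly 2 bits per residue under BLOSUM-like scoring) and $b$ is
the score decay rate. The variance is exactly the binomial variance
expressed in score units: zero at $t = 0$, zero again at saturation, and
maximal at $a/4$ where $e^{-bt} = 1/2$. Site-to-site rate variation and
indels perturb the exponential form only mildly; because $a$ and $b$ are
fit per gene empirically, they absorb those effects rather than requiring a
parameter-rich evolutionary model.

A search of a query of $m$ residues against a database of $n$ residues
expects $E = mn\,2^{-S}$ chance hits at bitscore $S$, so the detectability
threshold at significance $E^*$ is $S_{\min} = \log_2(mn/E^*)$. The test
statistic is then the upper tail mass of the predicted score distribution,

$$P(\mathrm{detected} \mid \mathrm{null}, t)
  = 1 - \Phi\!\left(\frac{S_{\min} - a e^{-bt}}{\sigma_{\mathrm{tot}}(t)}\right),$$

evaluated at the outgroup distance.

```{r example}
# three observed orthologs inside a young lineage
pr <- score_profile(species = c("focal", "near", "far"),
                    t = c(0, 0.02, 0.09),
                    score = c(140, 115, 95), gene_id = "demo")
fit <- fit_decay(pr)
summary(fit)
# would an ortholog still be seen at the nearest outgroup (t = 0.28)?
p_detected(fit, t = 0.28, threshold = bitscore_threshold(0.001, 70, 3e6))
```

## Fitting choices

The fit is nonlinear least squares in raw score space
(Levenberg–Marquardt via `minpack.lm`, with a derivative-free fallback),
not a log-linear regression: the log transform biases estimates exactly
where it matters, near the threshold. The log-linear regression is still
used twice, deliberately — to initialise $b$ (as minus the slope of
$\ln S$ on $t$) and as the `r2_log` goodness-of-fit diagnostic. The focal
self-comparison enters as an ordinary observation at $t = 0$; species with
no assigned ortholog contribute nothing. The fit is unweighted by default
(no weighting is implied by the model's provenance); `weighted = TRUE`
reweights once by the inverse model variance for users who want it.

Eligibility and pathologies are explicit statuses, not silent drops:

* fewer than 3 observations, or fewer than 2 distinct positive distances —
  `insufficient_data` (the minimum-3-homologs rule);
* zero response variance — `degenerate` ($b = 0$, $a$ = the common score);
* a least-squares optimum with $b \le 0$ — `model_violation`; such a gene's
  score is not decaying, so the conservative report is
  $P(\mathrm{detected}) = 1$ with a flag: its lineage specificity is *not*
  explained by detection failure.

The parameter covariance comes from the fit's local curvature. Prediction
intervals combine the model variance with that parameter uncertainty by the
delta method (gradient $(e^{-bt}, -ate^{-bt})$); this is the conservative
default, and `param_uncertainty = FALSE` gives the model-variance-only
interval for exact-reproduction experiments. Intervals use normal
quantiles, symmetric about the mean, with the lower bound clamped at zero.
The detection probability uses a normal, not a zero-truncated, score
distribution, with clamping to $[0, 1]$; truncation changes results
negligibly when the cutoff is well above zero, which is the regime in which
the test is informative. When the total variance is zero the distribution
collapses and the tail mass is a step function. Predictions at distances
beyond the largest fitted one carry an `extrapolation_beyond_data` flag —
that extrapolation is the method's central move, so it is flagged, not
forbidden.

The threshold formula applies no effective-length (edge) correction; BLAST's
internal adjustment depends on the search engine's exact accounting, and
published cutoffs are approximate. Every downstream function therefore also
accepts an explicit bitscore cutoff.

## Evolutionary distances

Distances $t$ are precomputed once per species set from concatenated
single-copy marker alignments (e.g. BUSCO genes), not per gene: only
*relative* distances matter, because each gene's $b$ rescales them. The
pairwise estimator maximises the two-sequence likelihood
$\sum_{xy} N_{xy}\log(\pi_x P_{xy}(d))$ under an empirical replacement
matrix (JTT by default, the classic protdist choice; WAG, LG, Dayhoff and
a uniform 20-state model are selectable because the original protdist-era
defaults are not fully pinned down). The rate matrix is normalised to one
expected substitution per site per unit $d$, and the optimum is found by a
coarse scan plus refinement over $d \in [10^{-6}, 20]$. Columns with a gap
or `X` in either sequence are excluded per pair (complete-pair deletion),
which maximises usable sites and matches pairwise-distance practice. The
Poisson correction $-\ln(1-p)$ is provided as a fast fallback, with
saturation capped at 20 substitutions/site. Alignment construction itself
is out of scope: alignments are consumed, not built.

## Orthology and lineage calls

Orthologs are reciprocal best hits between proteomes: each gene is the
other's lowest-E-value hit, with ties broken by higher bitscore and then
lexicographic subject id so runs are reproducible. A query–subject pair
with several HSP lines contributes its single best-scoring line, matching
the single-score input of the decay model. Lineage specificity is stricter
than orthology on purpose: a gene is lineage-specific only if *no* hit
below the E-value threshold exists in *any* outgroup proteome — any hit,
not only reciprocal best ones. The default threshold everywhere is the
permissive $E < 0.001$.

## What the simulators emulate — and what they do not

`simulate_scores()` draws scores directly from the model's normal
distribution (left-censored at zero, which matters only at saturation), at
a fixed 12-taxon distance ladder whose near end (0.02, 0.09) and far end
(0.92) match a yeast-like species panel, with the remaining rungs spread
between. `simulate_sequences()` works at the sequence level: a random
ancestor, star-topology descent, Poisson substitution events per site, the
replacement residue drawn from the background frequencies (so it may
coincide with the original — giving the closed-form identity probability
$e^{-rt} + (1-e^{-rt})\sum_i f_i^2$ used as an independent oracle), and
optional gamma-distributed per-site rate multipliers. Scoring identities at
$\lambda = 2$ bits each (the order of the BLOSUM62 diagonal average)
connects the two levels; only the relative scale of $\lambda$ matters.

The simulators deliberately realise the null model's own assumptions. They
do not emulate indels, alignment truncation, annotation errors, paralog
interference in ortholog assignment, or lineage-restricted rate shifts.
Consequently simulated data are *cleaner* than real data: log-scale $r^2$
values near 0.99 and essentially all Z-scores within 3 SD, where real
proteome-wide data show medians near 0.9 and a left skew from indels
disrupting local alignments. Passing tests on simulated data therefore
validate the statistical machinery — fitting, extrapolation, calibration —
not the adequacy of the null model for any particular real proteome; that
adequacy is exactly what the $r^2$ and Z diagnostics are for when the
package is run on real score tables.

In the packaged synthetic study (`scripts/acceptance.R`), the conserved
genome draws $a \sim \mathrm{LogNormal}(\log 900, 0.5)$ (a typical ~450
residue protein) and $b \sim \mathrm{LogNormal}(\log 1, 0.4)$, matching the
long-tailed, roughly log-normal parameter distributions seen genome-wide;
lineage-restricted genes draw $a \sim \mathrm{LogNormal}(\log 140, 0.6)$
and $b \sim \mathrm{LogNormal}(\log 6, 0.6)$ — short and fast-evolving, the
regime that produces detection failure. The search space uses a
3-million-residue database (a ~6,000-protein fungal proteome), which puts
the threshold near 37 bits for $E^* = 0.001$. These values were fixed once
as realistic study conditions.

## Numerical details worth knowing

* Initialisation: $a_0$ = maximum observed score; $b_0$ from the log-linear
  slope; zero scores are excluded from log-space computations with a
  warning.
* The covariance of an exact (zero-residual) fit is exactly zero; the
  analytic identities in the tests exploit this.
* `r2_log` on degenerate input (zero variance in either variable) is `NA`,
  never 0/0.
* Result tables serialise at 6 significant digits, making reruns
  byte-identical and round-trips exact to printed precision.
* Test problem sizes — 12-taxon profiles, 500-gene recovery panels,
  200-replicate coverage checks, $10^6$-draw tail samplers, 10,000-site
  recovery alignments — were chosen as the smallest sizes at which the
  Monte-Carlo tolerances (3 standard errors) are meaningfully tight.

## Limitations

The method needs at least two non-focal orthologs, so single-species
orphans are out of reach. It tests a *sufficiency* question: a low
$P(\mathrm{detected})$ means detection failure explains the data, not that
the gene is old; a truly novel but short, fast-evolving gene can also fail
to reject the null. Horizontal transfer or clade-restricted rate shifts
violate the constant-rate assumption and surface as model violations or
high-$P$ outliers rather than being modelled. And the bitscore threshold
here ignores BLAST's effective-length correction — supply an explicit
cutoff when exact parity with a specific search is required.
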