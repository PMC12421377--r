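---
title: "Models and design choices in pasbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in pasbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasbind)
```

pasbind quantifies how the mammalian polyadenylation specificity factor
(mPSF) recognises polyadenylation-signal (PAS) hexamers, from two sides:
binding affinity measured by fluorescence-anisotropy titration, and usage
frequency counted from genome annotation. This vignette explains the
models, the tunable parameters, and the choices made where the design was
genuinely open.

## Binding models

### Direct titration

A fluorescently labeled probe oligo (FAM-labeled AAUAAA 12-mer, total
concentration $L_t$, here 3 nM) is titrated with receptor (mPSF, total
$R_t$). Because probe and dissociation constant are of comparable
magnitude (nanomolar), the no-depletion hyperbola $R_t/(R_t+K_d)$ is not
adequate; `fraction_bound_direct()` uses the depletion-aware quadratic

$$FB = \frac{(R_t+L_t+K_d) - \sqrt{(R_t+L_t+K_d)^2 - 4R_tL_t}}{2L_t},$$

evaluated in the conjugate form $2R_t/(S+\sqrt{S^2-4R_tL_t})$,
$S=R_t+L_t+K_d$, which avoids catastrophic cancellation when $L_t \to 0$.
Nothing is lost by this choice: the hyperbola is its small-$L_t$ limit.

### Competition titration

Unlabeled competitor oligo (total $I_t$) displaces the probe. With
dissociation constants $K_1$ (probe) and $K_2$ (competitor), free receptor
$R$ satisfies the cubic mass balance

$$R^3 + aR^2 + bR + c = 0,\quad
a = K_1+K_2+L_t+I_t-R_t,\;
b = K_2(L_t-R_t)+K_1(I_t-R_t)+K_1K_2,\;
c = -K_1K_2R_t.$$

`solve_competitive()` evaluates the trigonometric (three-real-root) form
$R = -a/3 + \tfrac{2}{3}\sqrt{a^2-3b}\,\cos(\theta/3)$ and selects the
physical root by membership in $[0, R_t]$. The trigonometric expression
can lose several significant digits to cancellation when the roots are
widely separated, so the selected root is polished with three Newton steps
on the monotone mass-balance form
$g(R) = R\,(1+L_t/(K_1+R)+I_t/(K_2+R)) - R_t$; because $g$ is increasing
and concave on $[0,R_t]$, these steps converge monotonically and restore
machine precision. Numerical guards: the arccos argument is clamped to
$[-1,1]$ when within $10^{-12}$ of the boundary; a discriminant
$a^2-3b \le 0$, an argument beyond tolerance, or a root outside the
bracket delegates to `numeric_equilibrium()`, an independent bisection
solver on $g$ that terminates at $|g| < 10^{-12}\max(1,R_t)$ and doubles
as the test oracle. Across $10^4$ log-uniform random systems
(concentrations $10^{-3}$–$10^{6}$ nM, $K_d$s $10^{-2}$–$10^{5}$ nM) the
two routes agree to $10^{-9}$ relative on the bound-probe fraction; the
bisection fallback handles only a small fraction of that deliberately
extreme range (bounded at 5% in the validation suite) and none of the
realistic assay conditions.

### Signal model and fitting

Observed anisotropy is the intensity-weighted two-state mixture
$r = (Q\,FB\,r_b + (1-FB)\,r_f)/(Q\,FB + 1-FB)$ with free/bound endpoints
$r_f, r_b$ and bound/free intensity ratio $Q$. $Q$ is fixed at 1 by
default (binding is assumed not to change the probe's quantum yield) but
exposed for instruments where it does.

`fit_direct()` and `fit_competition()` estimate
$(\log_{10}K_d,\,r_f,\,r_b)$ by Levenberg–Marquardt least squares
(`minpack.lm`). Choices that matter:

* **Log-scale $K_d$.** The measured affinities span roughly 40 to
  13,000 nM; fitting $\log_{10}K_d$ enforces positivity and makes the
  optimisation equally well-conditioned across that range.
* **Multi-start.** Three starts with $K_d$ log-spaced across the titrant
  range; the lowest residual sum of squares wins, ties go to the smaller
  $K_d$. Convergence tolerance $10^{-10}$ on the relative rss change.
* **Per-curve endpoints.** $r_f$ and $r_b$ are fitted per curve rather
  than shared across oligos — the conservative choice in the absence of
  evidence that plates share endpoints.
* **Pooled replicates.** Triplicate points enter the fit individually
  (not averaged first), preserving the error structure for the residual
  bootstrap in `estimate_uncertainty()`.
* **Failure is flagged, not hidden.** A constant signal, inverted
  endpoints ($r_b \le r_f$), or optimizer non-convergence marks the
  result `converged = FALSE`. A competition curve whose fitted signal
  never falls below 90% of its fitted upper plateau across the measured
  competitor range cannot bound $K_d$ from above and is flagged
  `lower_bound_only` — the failure mode that historically produced
  "$K_d > 500$ nM" estimates when competitor stocks topped out too low.
  The 90% rule was checked against both regimes before freezing: at the
  full design a 13,000 nM competitor depresses the fitted floor to ~56%
  of plateau (no flag), while a series truncated at 5 µM leaves it at
  ~92% (flag).

## The synthetic assay generator

`simulate_direct_curve()` / `simulate_competition_curve()` reproduce the
study designs: probe 3 nM; direct receptor series from 300 nM down (the
printed floor is 0.04 nM), competition with receptor 30 nM and competitor
from 100 µM down to 0.5 nM; triplicates. The printed spans fit no integer
power of a single step cleanly, so the dilution factor defaults to the
plate-standard 2-fold with the point count chosen to cover the span (13
points for the direct design, 18 for competition); endpoints and factor
are configurable. Noise is additive i.i.d. Gaussian on anisotropy with
default $\sigma = 0.005$ — a typical plate-reader repeatability scale,
chosen here as a realistic default rather than taken from any instrument
record. What the generator deliberately does not emulate: pipetting error
correlated along the dilution series, intensity artefacts at high oligo
concentration, and plate-position effects. Parameter-recovery results on
these simulations therefore demonstrate estimator correctness under the
stated noise model, not robustness to every real-plate pathology.

Under that model, the package's validation (run in the test suite) shows:
noiseless curves return the generating parameters to $10^{-6}$ relative;
with $\sigma = 0.005$ the median recovered $K_d$ over 50 seeds is within
15% of truth at 40 nM and within 25% at 13,000 nM; and medians over 20
seeds rank-order a 16-oligo panel spanning 40–13,000 nM perfectly
(Spearman $\rho = 1$).

## The synthetic annotation corpus and the census

`generate_corpus()` plants hexamers drawn i.i.d. from a specified
distribution into uniform-ACGT background, one transcript per contig,
with per-transcript signal counts drawn from a configurable distribution
(default 1:60%, 2:25%, 3:15% — a stand-in for the empirical prevalence of
single- versus multi-signal transcripts, not a measured quantity), a
configurable minus-strand fraction (default 0.5), and signals at least
10 nt from sequence ends. The same corpus is written as GFF3 + FASTA and
as a GenBank flat file, with a ground-truth table; the census must
reproduce the truth exactly, and the two dialects must census
identically. Background composition is immaterial by construction — the
census reads features by coordinate — which is exactly why it is left
uniform. The corpus does not model transcript architecture (exons, UTRs),
cleavage sites, or downstream elements.

`parse_annotation()` recognises the annotation dialects in circulation:
GFF3 types `polyA_signal_sequence` and legacy `polyA_signal`, and
`regulatory_region`/`region`/`regulatory` features carrying
`regulatory_class=polyA_signal_sequence`. Transcript association uses
`Parent`/`transcript_id` when present, then coordinate containment within
an mRNA on the same contig and strand; unresolvable features are kept on
synthetic singleton transcripts and reported, and malformed features
(span ≠ 6 nt, non-ACGU sequence) are excluded and counted in
`skip_report()`. Counting is per feature–transcript association by
default because the position strata are transcript-centric; genomic
deduplication (`dedupe_genomic = TRUE`) is available where an
isoform-shared signal should count once.

`census()` stratifies by each signal's ordinal among its transcript's
signals in 5′→3′ order: `single`, `first`, `intermediate` (interior
signals of ≥3-signal transcripts), `last`, plus `all`. By construction
the `first` and `last` totals both equal the number of multi-signal
transcripts.

## Hexamer taxonomy, ratios, and the frequency–affinity correlation

`classify_variant()` groups hexamers by which recognition element a
single-nucleotide change touches: positions 1–2 (`A1A2`, read by CPSF30
ZF2), 4–5 (`A4A5`, CPSF30 ZF3), or 3 and 6 (`U3A6`, the Hoogsteen pair
packed against WDR33); AUUAAA's own single-nucleotide variants form
`AUUAAA_derived`, and anything else (in practice the double variant
AACAAG) is `other`. Of the 18 annotated human PAS hexamers, 14 are at
Hamming distance 1 from AAUAAA and 2 are AUUAAA-derived.

`ratio_table()` reports fold changes $K_d/K_d(\mathrm{AAUAAA})$ both raw
and in display form. The display rounding — half-to-even, to an integer
at ratios ≥ 1 and one decimal below 1 — is the unique simple rule
consistent with every published fold-change value we reproduce (e.g.
14.5→14 but 19.5→20, 67.5→68, 287.5→288); raw ratios are always retained
so no downstream computation depends on presentation rounding.

`loglog_correlation()` regresses $\log_{10}$ frequency on
$\log_{10}K_d$ and reports the Pearson correlation of the transformed
pairs together with the Spearman rank correlation of the raw pairs. The
Spearman coefficient is the headline statistic: the inverse relationship
is approximately linear on log–log axes but no distributional claim is
made, and rank correlation is insensitive to the handful of
low-frequency hexamers that sit off the trend. Those are flagged
descriptively as records with |standardised log–log residual| > 2 — a
conventional cut chosen for description, not inference; no p-values are
attached by design. The FAM-labeled probe measurement is excluded from
correlation input by the caller, since the label itself enhances binding
and the labeled row duplicates AAUAAA's frequency.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and is a pure function of
(parameters, seed); the bundled validation uses 2,000–10,000 random
equilibrium systems, 50-seed recovery studies, and a 10,000-transcript
corpus — sizes at which the multinomial and Monte-Carlo tolerances quoted
above are meaningful while the full suite stays fast. Concentrations are
nanomolar throughout; µM inputs are converted at the I/O boundary.

## Known limitations

* Single-site, single-competitor equilibrium only: no cooperativity,
  no kinetics, at most one unlabeled species competing with the probe.
* No global multi-curve fitting; each oligo's curve is fitted alone.
* The census counts annotated signals only — it is a usage census of the
  annotation, not de-novo PAS discovery — and annotation-version drift
  changes the frequencies.
* Absolute $K_d$ values depend on the receptor construct and the label;
  the FAM-labeled probe binds about two-fold tighter than the same
  unlabeled oligo. Ratios to the common AAUAAA reference are the robust
  cross-oligo quantity, which is why the report centres on them.
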