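# pasbind

Binding affinity and genomic frequency of polyadenylation signal (PAS)
hexamers.

Cleavage and polyadenylation of pre-mRNA 3′ ends is directed by a
hexanucleotide signal — canonically AAUAAA, with AUUAAA and sixteen rarer
variants — recognised by the mammalian polyadenylation specificity factor
(mPSF). pasbind is for researchers quantifying that recognition: it turns
replicated fluorescence-anisotropy titrations into dissociation constants
(including the competition format needed to measure unlabeled oligos
free of label artefacts), counts how often each hexamer is annotated as a
poly(A) signal in a genome, and links the two through the inverse
frequency–affinity relationship.

## The models

**Direct titration.** Labeled probe (total $L_t$) titrated with receptor
(total $R_t$); because $L_t$ and $K_d$ are both nanomolar, the bound
fraction uses the depletion-aware quadratic

$$FB = \frac{(R_t+L_t+K_d) - \sqrt{(R_t+L_t+K_d)^2 - 4R_tL_t}}{2L_t}.$$

**Competition titration.** Unlabeled competitor (total $I_t$, constant
$K_2$) displaces the probe (constant $K_1$). Free receptor $R$ is the
physical root of the cubic mass balance

$$R^3 + aR^2 + bR + c = 0,\qquad
a = K_1{+}K_2{+}L_t{+}I_t{-}R_t,\quad
b = K_2(L_t{-}R_t)+K_1(I_t{-}R_t)+K_1K_2,\quad
c = -K_1K_2R_t,$$

solved exactly in trigonometric form (with a bisection solver as
independent cross-check), and the bound-probe fraction $R/(K_1+R)$ feeds
the anisotropy observation model
$r = r_f + (r_b - r_f)\,FB$ (optionally intensity-weighted). $K_d$ is
estimated by multi-start Levenberg–Marquardt least squares on
$\log_{10}K_d$.

**Census.** Annotated `polyA_signal_sequence` / legacy `polyA_signal`
features are read from GFF3 + FASTA or GenBank flat files, each signal's
hexamer extracted (reverse-complemented on the minus strand), and usage
tabulated per stratum of the signal's position among its transcript's
signals (single / first / intermediate / last).

## Worked example

Simulate a competition assay at the study design (3 nM probe, 30 nM
receptor, probe $K_1$ = 19 nM, competitor 2-fold diluted from 100 µM to
0.76 nM, triplicates, noise σ = 0.005) for a competitor with true
$K_d$ = 2,200 nM, and refit it:

```r
library(pasbind)
design <- assay_design("competition", noise_sd = 0.005, seed = 42)
curve  <- simulate_competition_curve(design, kd_probe = 19,
                                     kd_competitor_true = 2200)
fit    <- fit_competition(curve)
fit    <- estimate_uncertainty(curve, fit, n_boot = 100, seed = 42)
fit
#> Kd = 2503 nM (r_free 0.0458, r_bound 0.2033; rss 0.00164, n 54)
```

The estimate (2,503 nM) lands within one bootstrap standard error
(0.045 on log10 Kd, i.e. about ×1.11) of the generating value. Joining
the packaged affinity/frequency reference table into the full report:

```r
tab <- pas_reference_table()
unl <- tab[!tab$labeled & is.finite(tab$kd_nM), ]   # 16 unlabeled oligos
rep <- pas_report(setNames(unl$kd_nM, unl$hexamer),
                  setNames(unl$frequency_percent, unl$hexamer))
rep$correlation
#> log-log correlation (n = 16): Pearson r = -0.833, slope = -0.671; Spearman rho = -0.694
#> outliers (|z| > threshold): AAUAAA
```

Frequency and affinity are strongly inversely correlated (rarer hexamers
bind mPSF more weakly); the canonical AAUAAA is flagged as sitting above
the log–log trend — it is even more frequent than its affinity alone
predicts. Each record also carries the variant taxonomy and fold change
versus AAUAAA:

```r
head(rep$records[order(-rep$records$frequency_percent),
     c("hexamer", "group", "frequency_percent", "kd_nM", "ratio_display")])
#>   hexamer     group frequency_percent kd_nM ratio_display
#> 1  AAUAAA canonical             60.76    40             1
#> 2  AUUAAA      A1A2             16.76    79             2
#> 3  AGUAAA      A1A2              3.29   194             5
#> 4  UAUAAA      A1A2              2.92   520            13
#> 5  AAUAUA      A4A5              2.85  2500            62
#> 6  AAUACA      A4A5              2.18  2200            55
```

A thin command-line front end over the same functions (subcommands
`simulate-assay`, `simulate-corpus`, `fit`, `census`, `report`) is
installed at `inst/scripts/pasbind.R`.

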