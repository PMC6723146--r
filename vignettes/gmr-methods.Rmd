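---
title: "Ranking gene master regulators: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking gene master regulators: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmrank)
```

## The model

A *gene master regulator* (GMR) is the gene whose expression a cell
phenotype protects most tightly while coordinating the expression of many
other genes: small excursions of the GMR are amplified by in-phase
(synergistic) or antiphase (antagonistic) responses across the
transcriptome, so forcing its expression should have outsized
consequences.  `gmrank` quantifies both halves of that definition from
\(\lambda \ge 4\) biological replicas of one condition (quarters of a
homogeneous tumor region, or parallel culture dishes) and combines them
into a single ranking score.

**Stability.**  For gene \(i\) probed redundantly by \(R_i\) spots, each
spot's coefficient of variation across replicas is pooled and corrected
by the chi-square mid-interval estimator with \(r_i = \lambda R_i - 1\)
degrees of freedom:

\[
REV_i \;=\; \frac12\!\left(\sqrt{\frac{r_i}{\chi^2(r_i;\,1-\varepsilon/2)}} +
\sqrt{\frac{r_i}{\chi^2(r_i;\,\varepsilon/2)}}\right)
\sqrt{\frac{1}{R_i}\sum_{k=1}^{R_i}\left(\frac{s_{ik}}{\mu_{ik}}\right)^2}.
\]

The correction exceeds 1 and falls towards 1 as \(r\) grows
(`chi2_midinterval_coefficient(3)` = 2.1475, `...(111)` = 1.06), so
sparsely probed transcripts are penalised for their poorly determined
CVs.  Stability is then expressed relative to the median gene,
\(RES_i = \ln(\langle REV\rangle / REV_i)\): the median gene scores 0 and
tightly controlled genes score positive.  Genes with literally zero
sample variance get a floored REV (half the smallest positive REV,
flagged in the output) so downstream logarithms stay finite while the
"most stable" rank is preserved.

A note on the correction's range: an average of the two interval ends
\(\sqrt{r/\chi^2}\) is always above 1 by the AM–GM inequality, for every
\(r\) and \(\varepsilon\) on the supported grid.  Claims that the
coefficient can fall below 1 for highly redundant probes cannot be
reproduced under any quantile convention; this package treats the
closed form above as normative.

**Coordination.**  All-pairs Pearson correlations \(\rho_{ij}\) are
computed on log2 gene-level expression (probes averaged within each
replicate) across the \(\lambda\) replicas, and each gene is summarised
by its coordination power \(CP_i = \overline{\rho_{ij}^2}, j \ne i\).
With \(\lambda = 4\) a single pair reaches two-sided significance only
at \(|\rho| \ge 0.950\) (`correlation_critical(4)`), which is why the
method aggregates squared correlations instead of testing pairs; the
null expectation of a squared sample correlation at \(\lambda = 4\) is
\(1/(\lambda - 1) = 1/3\), a number worth keeping in mind when reading
CP values.  The computation streams over gene blocks
(`block_size`, default 512) so the full \(N \times N\) matrix is never
held in memory, and is exactly equal to the dense computation.

**The ranking score.**  The Gene Commanding Height combines the two:

\[
GCH_i \;=\; \frac{\langle REV\rangle}{REV_i}\, e^{4\,CP_i}
\qquad\text{(form \texttt{approx4}, the default)},
\]

with the alternative `exact_ratio` form
\(\exp(RES_i + CP_i/\langle CP\rangle)\) that normalises coordination by
its grand mean.  The two coincide only when \(\langle CP\rangle = 1/4\),
which at \(\lambda = 4\) is generally false; `approx4` is the default
because its scale matches GCH magnitudes reported for real phenotypes
(top genes of order 40–170) and because within one condition the two
forms rank genes almost identically (`approx4` ranking equals ranking by
\(RES + 4\,CP\) exactly).  The GMR is the rank-1 gene; it is flagged
*actionable* when its GCH exceeds the runner-up's by the `gap_threshold`
ratio (default 1.5 — a deliberate operationalisation of "clearly
dominant", since no formal test accompanies the notion).

**Regulation between conditions.**  Instead of a uniform fold-change
cut-off, each gene's threshold grows with its own measured noise,
\(CUT_i = 1 + \sqrt{2(REV_{i,c}^2 + REV_{i,n}^2)}\), compared against
the signed expression ratio (\(x = \mu_c/\mu_n\) up, \(-\mu_n/\mu_c\)
down, \(+1\) when exactly equal — the convention makes \(|x|\ge 1\)
always).  The call is by \(|x| > CUT\) alone; the Welch p-value (computed
on replicate-level gene means, the biological unit of inference) is
reported but only weights the *Weighted Pathway Regulation*:

\[
WPR = \left\langle \mu_i^{(normal)}\,(|x_i| - 1)\,(1 - p_i)\right\rangle
\]

averaged over a pathway's quantified members.  The magnitude term
\((|x| - 1)\) is zero at no change in either direction; the
`literal_eq4 = TRUE` variant (\(|x-1|\)) and the `weight = "gch"`
variant are retained for comparison with other formulations but are not
defaults, because the former scores an unchanged down-regulated gene as
2 under the signed-ratio convention.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 4 | biological replicas per condition (design minimum) |
| `epsilon` | 0.05 | chi-square interval probability for the CV correction; supported grid 0.010–0.100, smaller values drown in technical noise |
| `form` | `approx4` | GCH algebraic form |
| `gap_threshold` | 1.5 | top-to-second GCH ratio for an actionable GMR |
| `top_k` | 3 | genes per condition in cross-condition tables |
| `block_size` | 512 | correlation block rows; memory is `block_size` × N doubles |
| `rho_ind` | 0.05 | below this \|ρ\| a pair is called independently expressed (no published numeric threshold exists; this is the package's choice) |

## QC and normalisation

Spot exclusion removes control spots, spots with corrupted or saturated
pixels in any replicate, and spots whose foreground is less than twice
the background in any replicate (a strict inequality: the boundary
`fg == 2*bg` is kept).  Net signal is `fg - bg`, strictly positive for
survivors.  Each replicate is then divided by its median gene-level
expression, so all means are in "median units" (the median quantified
transcript sits at 1).  Filtering is per condition; cross-condition
statistics first restrict both datasets to their common gene symbols,
which are matched verbatim and case-sensitively (no alias resolution).
Dye-bias and quantile normalisation are out of scope; input is assumed
to be post-feature-extraction intensities, one net intensity per probe
per replicate.

## The synthetic harness

`generate_dataset()` emulates the relevant features of a replicated
two-colour array experiment: probe redundancy \(R \in 1..28\)
(geometric-like law, mean ≈ 1.8 probes per gene), log-normal abundance
(log2 SD 1.5), per-gene replicate noise \(\sigma_i \in [0.2, 0.6]\) log2
units (replicate CVs of roughly 15–40%, the range seen across
biological replicas of tissue samples), probe-specific affinity offsets
(SD 0.25 log2, constant across replicates — they cancel from every CV),
small per-measurement probe noise (SD 0.01 log2), and a shared
per-replicate latent factor.  A loaded gene devotes a signed fraction
\(w_i\) of its noise SD to the factor, so coexpressed partners fluctuate
in phase or antiphase with population correlation \(w_i w_j\) while each
gene's total variability remains \(\sigma_i\) regardless of loading.
One root seed is split into per-gene streams, so enlarging a
transcriptome never reshuffles existing genes.

The planted master regulator gets a ×20 baseline, \(\sigma = 0.02\),
loading 0.8 and probe redundancy 12: simultaneously the most stable and
most coordinated gene, estimated with many degrees of freedom.

Three design points deserve emphasis:

* **Normalisation at desk scale.**  The synthetic studies run a few
  hundred genes, where the per-replicate median itself carries ~2%
  sampling jitter; dividing by it injects that jitter into every gene's
  replicate CV and would bury a planted regulator whose true CV is 2%.
  Real arrays quantify >10,000 transcripts, where the same jitter is an
  order of magnitude smaller and irrelevant.  Because the generator
  emits all replicates on one common scale, the synthetic validation
  studies therefore run the pipeline with `normalize = FALSE`
  (`gch_pipeline()` exposes the switch; the default for real data
  remains `TRUE`).  This is a property of small simulated panels, not of
  the method.
* **Perturbation propagation.**  `simulate_perturbation()` shifts the
  target by \(\delta\) log2 units and every other gene by
  \(\rho_{tj}\,\delta\,(s_j/s_t)\) — the regression slope of gene \(j\)
  on the target.  This rule is the package's own minimal model chosen
  to make the "higher GCH ⇒ larger consequences" claim testable in
  software; the original claim was established by transfection
  experiments, and nothing here simulates their biology.  Propagated
  shifts are clamped at ±30 log2 units for numerical sanity.
* **What passing does not show.**  The generator has no dye bias,
  spatial artifacts, cell-type mixtures or alias ambiguity, and its
  coexpression is a single latent factor rather than pathway-structured
  networks.  Recovery of the planted regulator demonstrates the
  estimator chain's correctness and power under known conditions — not
  performance on real tumours.

## Study sizes and numerical choices

The bundled studies are sized to run in seconds to a couple of minutes
on one core: planted-regulator recovery uses 200 generator seeds at 500
genes (measured recovery ≈ 95–97%, with a 4-point power curve over the
planted gene's noise SD that collapses from ≈0.96 to ≈0 as \(\sigma_p\)
grows to 0.5); the crossed two-line perturbation experiment uses 50
seeds at 300 genes and recovers sign-concordance 1.0 at \(\delta = 2\);
null calibration uses 50 paired null datasets (false-positive rate
≈ 1.7%) and a 2,000-gene independent panel (mean CP within 0.02 of
1/3).  Ties in rankings break alphabetically by gene symbol; all
Monte-Carlo assertions use fixed seed streams and tolerate two standard
errors where a trend (not an exact value) is asserted.

One calibration result is worth stating plainly: under the null with
the default noise model, the mean pathway WPR is ≈ 0.23 in median
units, not near zero — \(|x| - 1\) is strictly positive, and at
\(\lambda = 4\) the Welch p rarely approaches 1, so WPR has a
substantial positive floor that scales with replicate noise.  WPR is
therefore meaningful as a *comparison* between conditions or
perturbations, not as an absolute "no change" score.

## Known limitations

* Gene symbols are trusted verbatim; probes mapping to the same symbol
  are pooled, everything else is distinct.
* With \(\lambda = 4\), per-pair correlation classifications are weak by
  construction (critical \(|\rho| = 0.95\)); only aggregated CP is
  stable.
* The `exact_ratio` and `approx4` GCH forms diverge in scale; published
  GCH magnitudes can only be reproduced with the original arrays and
  normalisation protocol, so this package guarantees table *shape* and
  within-condition ranking, not those numbers.
* GEO series-matrix conversion is sketched in
  `inst/scripts/geo_example.R` but is explicitly non-validated.
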