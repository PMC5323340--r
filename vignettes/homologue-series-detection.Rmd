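---
title: "Detecting homologue series in LC-HRMS peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homologue series in LC-HRMS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homolseries)
```

## The problem

Homologous compounds — sets of chemicals differing by integer repeats of a
chemical unit such as CH2 or C2H4O — dominate many environmental sample
matrices, surfactants in sewage effluent being the classic case. In
LC-HRMS data they appear as *series* of picked peaks with near-constant m/z
spacing and systematically drifting retention times. `homolseries`
extracts all such peak series from a picked peak list without prior
knowledge of the units involved, in two stages: a k-d-tree-driven
enumeration of feasible peak *triplets*, followed by a recursive
recombination of triplets into longer series tuples.

## The series definition

A series of length $n \ge n_{min}$ is an m/z-ordered tuple of peaks
$(p_1, \dots, p_n)$, $p = \{m/z, RT, intensity\}$, in which every adjacent
pair and every pair of consecutive pairs satisfies:

* **m/z spacing.** $\Delta m/z \in [\Delta m/z_{min}, \Delta m/z_{max}]$,
  the a-priori mass range of the chemical units at the charges considered.
  Consecutive spacings may differ by at most $4\varepsilon$, where
  $\varepsilon$ is the maximum $\pm$ m/z measurement error (absolute or
  ppm; evaluated at the middle peak for this check).
* **Mass defect.** The defect $\Delta m$ of an ion is its deviation from
  the nearest integer m/z. For a monoisotopic unit composed of a given
  element set, the defect change per Th of spacing is bounded by the
  extreme defect/mass ratios of the lightest isotopes of those elements
  ($\gamma_{min}, \gamma_{max}$). With C, H, N, O, S, Cl, Br these are
  $-0.0010$ (from $^{79}$Br) and $0.0078$ (from $^{1}$H). The adjacent
  defect change must lie in
  $[\gamma_{min}\,\Delta m/z - 2\varepsilon,\;
    \gamma_{max}\,\Delta m/z + 2\varepsilon]$.
  Since stored defects live in $[-0.5, 0.5)$, a true change can appear
  shifted by $\pm 1$ u (the *wrap*); shifts are tried where they can apply.
* **Retention time.** Adjacent RT differences lie in
  $[\Delta RT_{min}, \Delta RT_{max}]$ (negative minima admit
  early-eluting cross-meshed series), consecutive RT differences change by
  at most $\Delta\Delta RT$, and for tuples of length $\ge 4$ a cubic
  smoothing spline of RT against m/z must reach a coefficient of
  determination $R^2 \ge R^2_{min}$ at smoothing penalty $\lambda$.

## Stage 1: triplets from k-d tree range queries

Each peak is embedded as
$a_x = (m/z_x,\; \Delta m_x - \gamma_{min} m/z_x,\;
        \Delta m_x - \gamma_{max} m/z_x,\; RT_x)$;
the two middle coordinates turn the sloped defect constraints into
one-sided, axis-aligned bounds. A balanced 4-d k-d tree (splitting
dimension cycling $a_1 \to a_2 \to a_3 \to a_4$ from the root, median
element per split, ties to the lower peak id) supports closed-box range
queries. Centered at every peak, a successor box H and a predecessor box L
are queried; every (predecessor, center, successor) combination passing
the exact predicates becomes a triplet. The boxes are deliberately
*supersets* of the feasible set — padded by $10^{-9}$ on every bound and
duplicated with $\pm 1$ u shifts on the defect dimensions where the wrap
can apply — and all candidates are re-validated in exact unwrapped
arithmetic, so box/predicate floating-point disagreement cannot lose or
invent triplets. The test suite checks stage 1 against an exhaustive
predicate enumeration on dozens of random instances.

## Stage 2: recombination

Two $n$-tuples merge into an $(n{+}1)$-tuple when the first $n-1$ peaks of
one equal the last $n-1$ peaks of the other (id equality, not coordinate
equality) and the merged tuple passes the full series definition including
the spline check. Merging repeats until no merge succeeds; tuples that
extended are dropped from their set, the rest are retained. A peak can
appear in many tuples but never twice in one. At each recursion,
*regular-omission* sub-tuples — tuples equal to every $k$-th peak
($k \ge 2$, any offset) of a longer tuple of length $\ge 5$ — are
filtered; irregular subsets are kept, since series bridging a genuine gap
with doubled spacing are no strict index-regular subsequence of any
retained tuple and carry real information. Filtering the retained pool
against each freshly formed set suffices: a sub-tuple of length $m$
retires from its live set no later than the recursion at which any parent
(length $\ge 2m-1$) forms, so every parent is seen while its subs are
still in the pool.

## Numerical choices

* `smooth.spline(lambda = , all.knots = TRUE)` supplies the cubic
  smoothing spline. Its `lambda` is the roughness-penalty weight on the
  internally rescaled abscissa; larger values are smoother, and the
  package treats `lambda = 0` as the interpolation limit ($R^2 = 1$ for
  distinct m/z values — `smooth.spline` itself rejects zero). Because the
  penalty parameterization is package-specific, only this monotonicity
  and the zero limit are portable; thresholds tuned in other tools need
  re-tuning here.
* An all-equal-RT tuple has zero total sum of squares; it passes the
  spline check by convention ($R^2$ reported as 1), since a flat RT trend
  is perfectly smooth.
* Spline checking starts at $n = 4$; on three points a cubic smoothing
  spline is degenerate and the $\Delta\Delta RT$ bound already constrains
  triplets.
* $\varepsilon$ in the pairwise defect bound is evaluated at the pair's
  lower-m/z peak; the query boxes use the center peak's $\varepsilon$,
  which in ppm mode is never smaller for the predecessor side, keeping
  the boxes supersets.
* `acos` arguments are clamped to $[-1, 1]$ in the intersection angle;
  half-integer masses round away from zero in the defect (a tie rule that
  only matters for defects of exactly $\pm 0.5$).
* Ties everywhere (k-d medians, modal isotopologue ranks, pair ordering)
  resolve deterministically, so identical inputs give identical outputs.

## Post-processing and pairing

`blank_flag()` votes a series to blank origin when at least half its
peaks have a picked blank peak within a $\pm$m/z, $\pm$RT window exceeding
0.1 times the sample peak intensity. It screens *picked* blank peaks; the
raw-profile blank check of upstream pipelines is out of scope, so verdicts
here are a peak-list-native approximation. The window half-widths have no
published default and must be chosen to match the instrument (the CLI
defaults, 0.005 Th and 30 RT units, suit a high-resolution QE-type setup
with RT in seconds). `monoisotopic_flag()` consumes externally supplied
isotopologue annotations and votes a series monoisotopic when the modal
m/z rank of its annotated peaks is 1; a tie involving rank 1 resolves,
permissively, to monoisotopic and is flagged as a tie. Isotopologue
grouping itself is a separate published method and is not reimplemented.

Peak-sharing series pairs get an intersection angle $\theta$ from the
range-scaled vectors of mean RT and m/z differences; $\theta = 0$ means
fully superjacent series (typically isobaric-peak combinatorics — $n$
isobaric pairs along a series yield exactly $2^n$ same-spacing series —
or gapped series with multiple spacings). The default superjacency
threshold $0.08\pi$ is the histogram-derived value from the reference
evaluation. `pair_vectors()` exports uncertainty-scaled 4-vectors for
external SOM clustering; SOM training is deliberately not part of the
package. `delta_mz_prevalence()` counts, per observed series mean
spacing, the samples containing a series within $\pm 5$ mu (read as
$\pm 0.005$ Th) — the moving-window cross-site comparison.

## The synthetic generator, and what green tests mean

`simulate_peaklist()` plants series with configurable unit, charge,
length, RT trend (constant, geometrically decaying, or smoothly tapering
steps), Gaussian m/z / RT noise, gaps and isobaric twins, over a uniform
(m/z, RT) background with log-uniform intensities. Defaults mirror the
reference use case: CH2-type units, lengths within the observed 5–30
range, RT in seconds with tens-of-seconds steps. The generator emulates
the *geometry* of homologue signals, not raw spectra: no isotope
envelopes, adducts, chromatographic peak shapes, intensity-dependent mass
error, or correlated noise. A green recovery test therefore establishes
that the two-stage search is algorithmically sound on in-bounds series —
not that any particular real-world sample will be free of false or
ambiguous series, which the reference evaluation addresses by
randomization: `estimate_false_series_rate()` permutes RT against
(m/z, defect) across peaks, preserving both marginals while destroying
the joint structure, and reports the fraction of peaks still assigned to
series. The exact randomization design behind the published
$0.02 \pm 0.01$ figure is not reproducible from the text, so that number
is data-dependent and not asserted by the tests; the machinery is instead
validated by null self-consistency (on pure background the permuted rate
scatters around the observed one) and by collapse on structured input.

## Known limitations

* No gap-tolerant search: a missing member splits a series into fragments
  that must each reach $n_{min}$, possibly bridged by a double-spacing
  series when $2\,\overline{\Delta m/z} \le \Delta m/z_{max}$.
* Intensity information is unused in detection.
* $\varepsilon$ depends on m/z only; the intensity dependence the
  measurement model allows is unspecified and omitted.
* Runtime grows with triplet density; very homologue-rich matrices (oil
  extracts) need narrowed $\Delta m/z$ windows, as the reference
  implementation also advises.
```{r example}
sim <- simulate_peaklist(list(planted_series(length = 8)),
                         n_background = 300, seed = 1)
res <- detect_series(sim$peaks, detection_params(n_min = 5))
series_summary(res)
```
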