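---
title: "Methods: profiling oxidative-stress hepatotoxicity from qHTS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling oxidative-stress hepatotoxicity from qHTS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions
behind `toxprofiler`. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## 1. The problem and the model

Long-term oxidative stress is a recognised route to liver damage. The
antioxidant response element (ARE) pathway — Keap1/Nrf2-regulated
transcription of antioxidative enzymes — is perturbed by electrophilic
compounds, and a beta-lactamase reporter assay (ARE-*bla*) run in qHTS
mode (15 concentrations, triplicate) measures that perturbation at
library scale. The package implements a three-stage analysis that links
such in vitro readouts to binary in vivo liver-damage labels:
assay-profile mining, consensus QSAR gap-filling, and fragment-level
in vitro–in vivo correlation (IVIVC).

### Curve processing

Raw responses are range-scaled with plate controls,
`100 * (x - low) / (high - low)`; out-of-range values are *not* clipped so
the noise filter sees them. The filter is fully specified (the original
processing points to external code without printing formulas):

1. responses below the noise threshold (default **10 response units**,
   aligned with the `< 10` bound of the inactive category) are set to 0;
   negative responses never survive, since the reporter signal is
   activation-only;
2. a monotone non-decreasing envelope is enforced by flattening the
   minimal number of violating points. Kept points form a maximum-length
   non-decreasing subsequence; each discarded point takes the value of
   the nearest kept point to its left (0 before the first). Among
   maximum-length kept sets the one minimising the repaired sum is chosen,
   which flattens an isolated spike rather than propagating it forward.
   The implementation is validated against an exhaustive-enumeration
   oracle on short vectors.

**CurveP** is the sum of the filtered vector; CurveP = 0 means no
significant signal. Classification uses CurveP, the maximum response and
the number of responses ≥ 20, as a four-row cascade with scores
1 / 0.75 / 0.25 / 0 (active / potential active / inconclusive /
inactive); "inconclusive" is the catch-all for inconsistent signals
(e.g. CurveP > 0 with max < 20). Replicate scores are averaged and
mapped to the nearest category score; exact midpoints resolve toward the
*less* active category (conservative labelling for downstream modeling).

**Design decision — which maximum?** The source material is ambiguous:
the category table describes an inconclusive row with CurveP = 0 and a
maximum in [10, 20), which the filter can never emit if the maximum is
taken on the filtered vector, yet a pre-filter maximum makes an isolated
10–15-unit noise excursion (probability ≈ 0.29 per 15-point replicate at
noise sd 5) demote a truly inactive replicate to inconclusive, capping
compound-level inactive recovery near 79%. We compute `max_response` on
the **filtered** vector: the classification cascade stays total and the
inconclusive row remains reachable for fingerprints supplied directly
(weak signals recorded by other processing paths), while noise-only
curves classify as inactive with high probability. The row header "number
of responses > 20" conflicts with the accompanying text "≥ 20"; the ≥
reading is implemented.

### Profile statistics

For one assay against one endpoint, only definite calls contribute:
inconclusive and untested cells are excluded. From TP/TN/FP/FN:

- sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
  CCR = (sensitivity + specificity)/2 — stored as fractions, formatted as
  percent for display (the source mixes both scales);
- **L = sensitivity × (FP + TP)/(FP + 1)** — large when an assay's active
  calls are both sensitive and precise; chance level is below 1 for any
  low-prevalence endpoint;
- Pearson χ² on the 2×2, **without** Yates correction (plain Pearson is
  the default reading of "chi-squared test"; a `correct` toggle is
  exposed). Degenerate tables (a zero margin) raise an error rather than
  returning a number.

Assay selection requires, in *both* profile groups: presence, more than
10 matching active responses (implemented as TP > 10 — "matched the
inputted data" is read as agreement with input actives), CCR > 0.5 and
L ≥ 1, plus the in vitro metadata flag. Output order is deterministic
(descending mean CCR, then assay id).

**RA (rate of actives)** for a compound over the selected assays is
A/(A+I) over definite responses only; adding untested or inconclusive
responses never changes RA — that invariance is the parameter's purpose
(missing data are endemic in repository-scale profiles). RA > 0.25
(strict) is called toxic. With no definite response the result is
`no_data`, never 0.

### Consensus QSAR

Descriptors are range-scaled to [0, 1] with parameters fit on the
modeling set only; constant descriptors are dropped and recorded;
external values are clipped to [0, 1] after scaling so distances stay
bounded. Two open descriptor families replace the commercial generators:
`const` (18 constitutional/topological scalars) and `circ` (64 hashed
circular-fragment counts, radius ≤ 2). Their sizes intentionally differ
from the commercial counts, which are declared non-reproducible.

Class imbalance (≈ 15% actives) is handled by similarity-guided
down-sampling: all actives are kept and each active draws its most
similar remaining inactive (2-D fingerprint Tanimoto, or negative
Euclidean distance when only descriptor matrices exist) in round-robin
until the active:inactive ratio reaches 750:800.

Six models — {const, circ} × {random forest, linear SVM, k-NN} — produce
scores on a common [0, 1] scale: tree-vote fraction for the forest,
distance-weighted neighbour fraction for k-NN, and a logistic link on the
margin for the SVM (a monotone map; consensus averaging needs
comparability, not calibration). The consensus score is their arithmetic
mean. Hyperparameters are fixed and recorded (100 trees, mtry = √p,
depth ≤ 12, min node 5; k = 5; Pegasos λ = 1e-3, 30 epochs); the source
gives none. The random forest is compiled (Rcpp) because no forest
implementation ships with the target R environment; the SVM is trained by
Pegasos subgradient descent for the same reason.

Classification thresholds follow the printed inequalities exactly:
CPT-1 ≥ 0.5 active; CPT-2 ≥ 0.8 active, ≤ 0.3 inactive, the open band
(0.3, 0.8) inconclusive.

**Applicability domain.** The source names no algorithm; we use the
field-standard k-NN convention: a query is in-AD iff its mean Euclidean
distance to its k = 5 nearest modeling compounds (concatenated scaled
descriptor space) is at most D̄ + z·s with z = 0.5, where D̄ and s
summarise the same self-excluded quantity over the modeling set. Coverage
is the in-AD fraction; both k and z are configurable.

External validation is stratified 5-fold (80/20); the scaler, the
down-sampler and all six models are re-fit inside each training fold —
the held-out fold is never touched by any fitted component.

### Toxicophore evaluation

Candidate fragments are matched by subgraph isomorphism; a matched
subset's IVIVC is the 2×2 of in vitro call (experimental, or consensus
prediction where no experiment exists — experimental always wins) against
the in vivo label, plus the χ² test. Predictions outside the AD are used
but flagged low-confidence, mirroring the source workflow's own use of
out-of-AD predictions and the false positives it reported as a
limitation.

Fragment *discovery* replaces two commercial programs with a transparent
ranking of enumerated circular fragments (radius ≤ 2), labelled
*simplified* in all outputs: each fragment is scored by the
Haldane-corrected odds ratio of occurrence in dual-active compounds
(in vitro active ∧ in vivo toxic) versus all others, and ranked by the
**lower bound of the Wald 95% CI of the log odds ratio**. The CI bound,
not the raw OR, is ranked because rare fragments near the support
threshold otherwise dominate with noisy extreme estimates; minimum
support defaults to max(10, 2.5% of the library).

## 2. The synthetic world

The generator states the world the analysis assumes; its defaults are
frozen and tests never tune them.

- **Structures**: four scaffolds (benzene, pyridine, cyclohexane, hexane)
  with four substitution slots, decorated with fragments at configured
  prevalences. Three fragments (a sulfonamide, an
  N-methylformamide-like amide echoing the described amide toxicophore,
  and an allylic chain echoing the allylic-hydrogen electrophile) multiply
  the odds of both ARE activity and liver toxicity (odds 6, 6, 4 at
  prevalences 0.10, 0.10, 0.12); five decoys carry no effect. Every
  generated string parses, and fragment carriage is verifiable by
  independent substructure matching because each planted feature is
  chemically exclusive to its fragment within the vocabulary.
- **Latent labels**: logistic in carried fragments; intercepts are solved
  exactly (enumeration over the carriage distribution) so the marginal
  ARE-active rate is 15% (the class imbalance the down-sampler must
  handle, mirroring the real screen) and the liver-toxic rate 50%
  (mirroring the roughly balanced in vivo reference set).
- **Curves**: 15 concentrations log-spaced over four decades (1 nM–10 µM;
  the count is stated by the source, the range is ours), triplicate.
  Actives get a Hill curve with observed top in [25, 100] response units
  attained exactly at the highest concentration, midpoint log-uniform
  between concentrations 4 and 11 (so at least two upper points clear the
  20-unit criterion even at top = 25), slope in [1, 3]; inactives are
  pure noise. Noise is homoscedastic Gaussian (default sd 5), the
  simplest model consistent with a threshold-based filter.
- **Assay matrix**: planted assays multiply a compound's active-call odds
  by `association_odds` (default 8) when it is liver-toxic; background
  active rate 15%; cells are independently inconclusive (5%) and masked
  untested (30%).
- **Descriptor simulator** (for exercising the QSAR engine in isolation):
  three latent archetypes along eight informative descriptors — baseline,
  clear responders (shift 2.5 SD, labelled active with probability 0.90)
  and a small borderline cluster at half shift whose labels are close to
  a coin flip (0.55). The borderline cluster is what a two-Gaussian world
  lacks: it makes the consensus place label-noisy compounds at mid-range
  scores, so the CPT-2 band absorbs exactly the unreliable labels. That
  is the regime the original consensus model reported (a large
  specificity gain at nearly constant sensitivity when tightening the
  threshold), and it is also chemically sensible: weak, irreproducible
  responders are a fixture of real qHTS data.

**What a green test does and does not establish.** The synthetic world has
no medicinal-chemistry diversity, no correlated assay panel, no
pharmacokinetics, no plate artefacts, and its curves are exactly Hill
plus white noise. Recovery results certify the statistical machinery —
that the selection criteria, RA, consensus thresholds and enrichment
ranking find structure of the stated kind at the stated strength — not
performance on real screening data. Absolute performance numbers from the
original study are out of reach by design (they require the original
screening data and commercial descriptors) and only their *direction* is
asserted.

**Two profile groups.** The recovery harness builds its two profile
groups by splitting the probe compounds in half, each half scored against
the in vivo endpoint (analogous to two screening phases probing one
outcome). Scoring one group against the ARE endpoint instead would make
the selection criterion L ≥ 1 unattainable for a liver-associated assay
at 15% ARE prevalence — L ≥ 1 requires precision ≥ 1 − sensitivity, which
a marginally informative assay cannot reach against a rare endpoint —
so appearance-in-both is exercised as two independent profile passes.

## 3. Numerical conventions

- Category/score bijection is exact; score comparisons use exact
  equality on the four values {0, 0.25, 0.75, 1}.
- Aggregation midpoint ties resolve toward the lower score.
- χ² requires strictly positive margins; callers treat degenerate tables
  as "no test", never as p = 1.
- The monotone repair tie-break (minimum repaired sum among
  maximum-length kept sets) makes `curvep` non-increasing in the noise
  threshold; this is property-tested, not assumed.
- All generators take explicit seeds and restore the caller's RNG state;
  identical configs are byte-identical across calls.
- Canonical line notation: Morgan-style invariant refinement with
  promotion tie-breaking (lexicographically smallest emitted string);
  stereochemistry and isotopes are dropped at parse time, so
  stereoisomers share one identity key by construction. Round-tripping
  is tested; the dev-time reference implementation agreed with an
  external toolkit on the supported dialect.
- Charged-species handling in curation: proton-transfer neutralization
  only (O⁻/N⁻/S⁻ gain a proton, N⁺/P⁺ with a proton lose one);
  quaternary cations stay charged; counter-ions drop out via the
  largest-component rule, with one log line per mixture replacing the
  original manual mixture review. Metalorganic means a carbon–metal bond
  (metal = outside {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I}); simple
  metal salts are desalted, not rejected.
- Duplicate labels resolve by majority, ties to inconclusive (the
  original's rule for conflicting duplicates is unstated).

## 4. Known limitations

- The SMILES layer supports the dialect the package generates and
  curates (organic subset, brackets, rings, aromatics); it is not a
  general-purpose toolkit (no tautomers, no aromaticity *perception* —
  aromatic input stays aromatic, Kekulé input stays Kekulé; mixed-form
  duplicates of the same ring system would not be merged).
- Fragment discovery is deliberately simplified; it ranks circular
  environments, not maximum common substructures, and the mined alerts
  are scaffold-specialised refinements of the underlying feature.
- The QSAR engine fixes hyperparameters; there is no tuning loop.
- AC50/Hill-fit estimation, plate-effect correction and live repository
  retrieval are out of scope.
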