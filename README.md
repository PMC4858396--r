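# toxprofiler

`toxprofiler` is an R package for profiling the mechanisms of
hepatotoxicity driven by oxidative stress from quantitative
high-throughput screening (qHTS) data. It is aimed at computational
toxicologists who want to connect in vitro pathway readouts — in
particular activation of the antioxidant response element reporter assay
(ARE-*bla*) — to in vivo liver-damage outcomes, at the scale of public
bioassay repositories, without commercial cheminformatics software.

The workflow has three stages:

1. **Automated biological response profiling.** Every assay in a
   compound × assay response matrix is scored against a binary in vivo
   endpoint via its confusion counts: sensitivity, specificity, the
   correct classification rate CCR = (sensitivity + specificity) / 2, and
   a likelihood parameter **L = sensitivity × (FP + TP) / (FP + 1)** that
   measures how strongly an assay's *active* calls track the endpoint.
   Assays that appear in both profile groups, have > 10 matching active
   responses, beat chance (CCR > 0.5, L ≥ 1) and are in vitro are
   selected. Each compound is then summarized by its **rate of actives
   RA = A / (A + I)** over the selected assays (untested and inconclusive
   responses are excluded from both counts, so missing data do not bias
   the rate), with RA > 0.25 called toxic. The association between the
   combined calls and the in vivo labels is tested by a Pearson χ² on the
   2×2 table.

2. **Consensus QSAR modeling of ARE activation.** qHTS
   concentration–response curves are range-scaled to [0, 100],
   noise-filtered into monotone curve fingerprints whose sum is the
   **CurveP** scalar (CurveP = 0 ⇔ no significant signal), and classified
   into four categories with scores {1, 0.75, 0.25, 0}; replicate scores
   are averaged to a per-compound call. Definite calls train a consensus
   of six models (two descriptor families × {random forest, linear SVM,
   k-NN}) on a class-balanced modeling set obtained by similarity-guided
   down-sampling of the inactives. Consensus scores in [0, 1] are
   classified under **CPT-1** (≥ 0.5 active) and **CPT-2** (≥ 0.8 active,
   ≤ 0.3 inactive, inconclusive in between), gated by a k-NN
   applicability domain (in-AD iff mean distance to the 5 nearest
   modeling compounds ≤ D̄ + 0.5·s). The model fills the data gap for
   compounds never tested in the ARE assay.

3. **Chemical IVIVC evaluation.** Candidate toxicophores — substructures
   whose carriers show a significant in vitro–in vivo correlation — are
   matched against the library; each matched subset gets a TP/TN/FP/FN
   table and χ² test, using experimental calls where available and QSAR
   predictions elsewhere. A transparent circular-fragment enrichment
   ranking (odds ratio of occurrence in dual-active compounds, ranked by
   the lower 95% confidence bound of the log odds ratio) stands in for
   commercial fragment-mining tools and is labeled *simplified*.

Because the real data sources (PubChem bioassays, a proprietary FDA
liver-damage set) cannot ship with a package, a first-class
**synthetic-data module** generates everything the pipeline consumes with
known ground truth: compound structures built from a fixed scaffold
vocabulary carrying planted fragments, Hill-shaped triplicate qHTS curves,
sparse assay matrices with planted label-associated assays, and binary in
vivo labels. All recovery tests compare analysis output against this
latent truth. The package also carries a small self-contained molecular
graph layer (SMILES parsing, canonicalization, substructure matching,
descriptors) because no open cheminformatics toolkit is available in the
target R environment.

## Worked example

```r
library(toxprofiler)

cfg <- sim_config(n_compounds = 300, seed = 42)
lib <- generate_library(cfg)
head(lib[, c("compound_id", "smiles", "is_are_active", "is_liver_toxic")], 3)
#>   compound_id                 smiles is_are_active is_liver_toxic
#> 1   CMPD00001 c1c(OC)cc(C(F)(F)F)cn1          TRUE           TRUE
#> 2   CMPD00002     C1CCC(C(F)(F)F)CC1         FALSE           TRUE
#> 3   CMPD00003  c1c(N(C)C=O)cc(OC)cc1         FALSE          FALSE

calls <- process_curves(generate_curves(lib, cfg))
table(calls$category)
#>   active inactive
#>       41      259

am <- generate_assay_matrix(lib, cfg)
labels <- setNames(as.integer(lib$is_liver_toxic), lib$compound_id)
half <- seq_len(nrow(lib)) %% 2 == 1
bp <- build_profile(am, labels[lib$compound_id[half]],
                    labels[lib$compound_id[!half]], ra_labels = labels)
bp$selected          # the four planted assays are recovered
#> [1] "AID0002" "AID0001" "AID0003" "AID0004"
head(assay_stats_table(bp$stats_a, bp$selected)[,
     c("assay_id", "TP", "FP", "ccr_pct", "L", "selected")], 5)
#>   assay_id TP FP  ccr_pct         L selected
#> 1  AID0001 30  7 75.72464 3.0833333     TRUE
#> 2  AID0002 29  7 76.35077 2.9659091     TRUE
#> 3  AID0003 26  8 69.58656 2.1827160     TRUE
#> 4  AID0004 34  8 69.70559 2.6010929     TRUE
#> 5  AID0005  5 10 45.19231 0.1311189    FALSE
unlist(bp$ivivc)     # RA-combined calls vs in vivo labels
#>    statistic            p           df
#> 1.301548e+02 3.790257e-30 1.000000e+00

r <- rate_of_actives(c(1, 0, 0, NA))   # 1 active, 2 inactive, 1 untested
sprintf("RA = %.2f, call = %s", r$ra, r$call)
#> "RA = 0.33, call = toxic"
```

Individually weak assays (CCR ≈ 0.70–0.76 above) combine through RA into a
strongly significant association with the in vivo label — the central
observation the workflow is built around.

The full pipeline runs from one config:

```r
run_pipeline(default_run_config(out_dir = "run1", seed = 7))
```

or from the command line (installed under `exec/`):

```sh
toxprofiler run-all --config inst/extdata/example_config.json --out run1 --seed 7
```

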