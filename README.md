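# sclcTaxonomy

Molecular subtyping and microenvironment deconvolution of small cell lung
cancer (SCLC) transcriptomes.

SCLC is usually treated as a single disease, yet bulk transcriptomes
resolve it into molecular subtypes driven by lineage transcription factors
(ASCL1, NEUROD1, POU2F3), by YAP1/TAZ-driven mesenchymal programs, by
immune infiltration, and by hypoxia. Distinguishing a *mesenchymal*
(SCLC-M) tumor — elevated epithelial-to-mesenchymal transition (EMT)
activity but little antitumor immunity — from an *inflamed* (SCLC-I)
tumor matters clinically: the two look similar in stromal content but
differ in immune contexture and outcome. This package implements the
complete analysis chain a study of this question needs, as reusable,
tested R functions:

* **Subtype discovery** — consensus non-negative matrix factorization
  (NMF, generalized Kullback–Leibler multiplicative updates) over gene
  subsamples; clustering stability per rank K measured by the cophenetic
  correlation of the consensus matrix, calibrated against a permutation
  null band; the rank K\* is the largest K that is stable above the null
  and shows a substantial stability drop at K+1.
* **Characterization** — single-sample gene-set enrichment (ssGSEA,
  rank-weighted running sum with exponent α = 0.25), marker-mean
  abundance scores, ESTIMATE-like immune/stromal scores, and a
  mutual-information regulon network (equal-frequency-bin MI, permutation
  threshold, data-processing-inequality pruning) with subtype–regulon
  Fisher enrichment.
* **Classification** — a nearest-shrunken-centroid (PAM-style) classifier
  with cross-validated shrinkage for carrying subtype labels to new
  cohorts and cell-line panels.
* **Deconvolution** — non-negative least squares of bulk TPM on a
  four-cell-type signature matrix (epithelial, fibroblast, endothelial,
  immune), group-mode purified profiles, a per-sample epithelial
  approximation, Welch-t differential expression between purified groups,
  and tumor-intrinsic M/I scores (mean expression of 100 classifier
  genes, 50 per direction; `diff = M − I`).
* **Trajectories** — principal-curve pseudotime on PCA coordinates with
  neuroendocrine (NE) score orientation
  (`NE score = (r_NE − r_nonNE)/2`), subtype occurrence along
  pseudotime, and a human × mouse expression-concordance matrix over an
  explicit ortholog map.
* **Clinical arm** — Kaplan–Meier curves, k-group log-rank tests,
  immunohistochemistry H-score (proportion × intensity, 0–300), CD8+
  tumor-infiltrating-lymphocyte score (mean of five fields), Mann–Whitney
  U (exact by enumeration at small n), and the IHC-based subtype call:
  vimentin-positive/CD8-low → SCLC-M, vimentin-positive/CD8-high →
  SCLC-I, vimentin-negative → other.
* **Synthetic cohorts** — `generateCohort()` plants six subtype programs,
  four-cell-type mixing, an NE→non-NE continuum shared with a mouse-like
  single-cell time course, subtype-dependent survival and coupled IHC
  records, with full ground truth for recovery testing.

## Worked example

```r
library(sclcTaxonomy)

co  <- generateCohort(cohortConfig(nSamples = 72L, nGenes = 600L, seed = 7L))
lg  <- countsToLogTPM(co$counts, co$geneLengths)
res <- consensusNMF(lg, kRange = 2:8, nSubsamples = 25L, nPerm = 0L, seed = 1L)
res
#> ConsensusResult: K scanned 2..8; selected K* = 5
#>   cophenetic: 2:0.850 3:0.919 4:0.931 5:0.968 6:0.962 7:0.957 8:0.941

table(clusterLabels(res), co$truth$labels)
#>      M  I  A  P  N  H
#>   1  0  1  0 10  0  0
#>   2  0  0  0  0 12  0
#>   3  0  0 13  0  0  0
#>   4  9  0  0  0  0  0
#>   5  0 24  0  0  0  3

tpm <- countsToTPM(co$counts, co$geneLengths)
fr  <- estimateFractionsMatrix(tpm, co$truth$signatureMatrix)
round(head(fr, 3), 3)
#>      epithelial fibroblast endothelial immune
#> S001      0.432      0.164       0.297  0.106
#> S002      0.833      0.089       0.025  0.052
#> S003      0.578      0.138       0.018  0.267
mean(abs(fr - co$truth$fractions))
#> [1] 0.0586
```

The cophenetic trace rises while the planted structure resolves and
decays beyond it. At this reduced scale (72 tumors, 25 subsamples per
rank) the stability peak sits at K\* = 5: the mesenchymal, ASCL1-like,
POU2F3-like and NEUROD1-like programs each claim a near-pure cluster,
while the two microenvironment-defined subtypes (inflamed and hypoxic)
merge — the acceptance-scale conditions (120 tumors, 50 subsamples,
permutation band) resolve all six. The fraction matrix rows are
simplex-valued cell-type proportions per tumor (inflamed tumors carry
the larger immune fraction); against the planted truth the mean
absolute error is ~0.06 at default sequencing noise. Cluster ids match
planted labels up to permutation.

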