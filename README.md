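# amvml

Adaptive multi-view multi-label learning for miRNA-disease association
prediction.

Experimentally confirmed miRNA-disease associations form a sparse binary
matrix *Y* (diseases × miRNAs).  Given several similarity matrices
("views") per entity space — MeSH-DAG semantic similarity and Gaussian
interaction-profile (GIP) kernels for diseases; sequence, functional and
GIP similarities for miRNAs — the package ranks the unobserved pairs by
jointly solving

> min Σᵥ w_D⁽ᵛ⁾‖SD − AD⁽ᵛ⁾‖²_F + 2α Tr(Fᵀ L_SD F)
>    + Σᵤ w_M⁽ᵘ⁾‖SM − AM⁽ᵘ⁾‖²_F + 2β Tr(F L_SM Fᵀ) + ‖F − Y‖²_F

over row-stochastic consensus affinity graphs *SD*, *SM* and a score
matrix *F*, with view weights w = 1/(2‖S − A‖_F) re-estimated from the
data (self-conducted weight learning).  The alternating solver uses exact
simplex projections for the graph rows and a symmetric-eigenbasis
Sylvester solve for *F*, so the objective decreases monotonically within
every inner loop.  The package also ships the standard similarity
constructors, four cross-validation protocols with leakage-safe rebuilding
of label-derived views, a seeded synthetic block-model benchmark, and a
command-line interface.

Who it is for: computational biologists prioritising candidate
disease-miRNA pairs for experimental follow-up, and method developers who
need a reproducible multi-view graph-learning baseline with honest
validation protocols.

## Worked example

```r
library(amvml)

# seeded synthetic benchmark: block-structured ground truth, one faithful
# (noise 0.2) and one pure-noise (noise 1.0) similarity view per space
inst <- make_block_instance(q = 30, p = 40, seed = 3)
inst
#> <synthetic_instance> 30 x 40, 202 positives, views at lambda = 0.2/1, seed 3

fit <- amvml(inst$Y, inst$views_d, inst$views_m)
fit
#> <amvml_fit> 30 diseases x 40 miRNAs; 5 outer round(s), converged
#>   disease view weights: lambda0.20=0.1667, lambda1.00=0.03294
#>   miRNA view weights:   lambda0.20=0.1251, lambda1.00=0.02458
#>   final objective: 21.3132
```

The self-conducted weights recover the view quality: the faithful view
gets roughly five times the weight of the pure-noise view in both spaces.
Candidate miRNAs for one disease (known associations excluded; the scores
are propagation mass, only their ranking matters):

```r
predict(fit, "disease001", top = 5)
#> # A tibble: 5 × 3
#>    rank mirna          score
#>   <int> <chr>          <dbl>
#> 1     1 hsa-mir-033 0.000187
#> 2     2 hsa-mir-037 0.000152
#> 3     3 hsa-mir-010 0.000145
#> 4     4 hsa-mir-009 0.000133
#> 5     5 hsa-mir-001 0.000122
```

Cross-validated ranking quality, with the label-derived GIP views rebuilt
from each masked training matrix (never from the full matrix):

```r
cv <- kfold_cv(inst$Y, inst$views_d, inst$views_m, k = 5, repeats = 2,
               seed = 1, view_builder = gip_view_builder())
cv
#> <amvml_cv> scheme = kfold
#>   AUC: 0.7933 +/- 0.0339 (sd over 10 fold-ROCs)
```

At the default benchmark scale (60 × 80) this protocol reaches a mean AUC
of about 0.83 — close to the 0.84 ceiling attained by the generating
propensities themselves — versus about 0.58 for a label-free
mean-similarity baseline.  `tidy()`, `glance()` and `autoplot()` methods
are provided for fits and CV reports; `global_loocv()`, `lodocv()` and
`topn_validation()` implement the other validation schemes.

Real data enter through `read_association()` (edge list or dense CSV),
`read_similarity()`, `read_dag_edges()` + `semantic_similarity_matrix()`,
`read_mature_fasta()` + `sequence_similarity_matrix()`, and
`gip_kernel()`; `align_axes()` reconciles identifiers across sources.

## Command line

A thin launcher wraps the same functions:

```sh
AMVML=$(Rscript -e 'cat(system.file("cli/amvml.R", package = "amvml"))')
Rscript $AMVML simulate --preset block --q 60 --p 80 --seed 7 --out-dir sim/
Rscript $AMVML fit --assoc sim/Y.csv \
  --disease-view sim/disease_view_lambda0.20.csv \
  --mirna-view sim/mirna_view_lambda0.20.csv \
  --alpha 1e-4 --beta 1e-4 --out F.csv --trace trace.tsv
Rscript $AMVML evaluate --scheme kfold --assoc sim/Y.csv --gip \
  --k 5 --repeats 10 --seed 42 --out report.json
```

`build-sim` constructs similarity views from raw inputs (DAG edge list,
mature-sequence FASTA, associations), and `predict` prints a ranked
candidate table for one disease.

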