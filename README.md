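# edgesnp

Elastic data-driven genotype encoding (EDGE) and SNP-SNP interaction
testing, with a biallelic penetrance-model simulator and a power /
type-I-error study framework.

## The problem

Association and epistasis regressions must map SNP genotypes
(0/1/2 copies of the minor allele) to numeric design values.  The
traditional encodings fix the heterozygous value in advance — additive
(0, 0.5, 1), dominant (0, 1, 1), recessive (0, 0, 1), codominant (two
dummy columns) — and a mismatched choice both loses power and inflates
the interaction term of a SNP-SNP model, because main-effect signal the
encoding cannot represent leaks into the product term.

EDGE instead estimates the heterozygous value per SNP from the data,
before any interaction testing.  From the codominant dummy regression

    Y ~ b0 + bHet * I(g == 1) + bHA * I(g == 2) [+ covariates]

(homozygous referent class as baseline) it computes

    alpha = bHet / bHA,

the heterozygous effect as a fraction of the homozygous-alternate
effect, and encodes the SNP as {0, alpha, 1}.  Alpha is not clamped:
values below 0 (under-recessive) or above 1 (over-dominant) pass through
unchanged.  Interactions are then tested with a likelihood ratio test
between the full model `Y ~ SNP1 + SNP2 + SNP1:SNP2` and the reduced
model `Y ~ SNP1 + SNP2` (1 df for single-column encodings, 4 df for
codominant).

The package is intended for statistical geneticists who want to run
encoding-aware epistasis scans (TSV / VCF / PLINK bed input, top-K
main-effect filtering, Bonferroni/BH adjustment) or to study encoding
behavior by simulation (29-model interaction catalogue, main-effect and
null models, retrospective case-control sampler in exact
Hardy-Weinberg proportions).

## Worked example

Simulate a pure SUB x DOM interaction (log-odds product effect 1.25,
baseline risk 0.1, both MAFs 0.30, n = 2,000 balanced), then run the
EDGE pipeline on it:

```r
library(edgesnp)

pen <- penetrance_interaction("SUB", "DOM", baseline = 0.1, effect = 1.25)
d <- sample_dataset(pen, sim_config(n_samples = 2000, maf = 0.3, seed = 42))

estimate_alpha(d$SNP1, d$status)
#> EDGE alpha estimate (logistic family)
#>   alpha     0.3056
#>   beta_het    0.2535 (SE 0.0951)
#>   beta_ha     0.8295 (SE 0.1566)
#>   n = 2000, converged: TRUE

edge_interaction_pipeline(d$SNP1, d$SNP2, d$status)
#> SNP-SNP interaction LRT (edge encoding, logistic family)
#>   LRT statistic 10.9808 on 1 df, p = 0.0009206
#>   pseudo-r2 increment 0.00396; n = 2000; converged: TRUE
```

SNP1 was simulated sub-additive: its estimated alpha (0.31) sits near
the simulated heterozygous risk fraction 0.25, and the 1-df EDGE LRT
detects the interaction (p = 9.2e-4).  The same pair under the
recessive encoding gives p = 0.026 — a mismatched fixed encoding pays
an order of magnitude in evidence on this draw.

Study runners reproduce the simulation experiments, e.g.

```r
run_type1_study(seed = 1)   # FPR per main-effect/null model x encoding
run_power_study(seed = 1)   # 29-model x 5-encoding power grid
run_alpha_recovery_study(seed = 1)   # alpha-distribution modes
```

A thin command-line interface wraps the same pipelines:

```sh
exec/edgesnp simulate --model XOR --maf 0.3 --n 2000 --seed 7 --out sim.tsv
exec/edgesnp interact --geno geno.tsv --pheno pheno.tsv --top-k 50 --out-prefix scan
exec/edgesnp study --kind power --fast --out study.tsv
```

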