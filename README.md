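# fflsurv

Network-motif analysis of somatic mutations on cancer survival networks,
with survival-outcome validation.

## The problem

Somatic mutations in tumors are heterogeneous: even within one cancer
subtype, few mutated genes are shared between patients, which makes it hard
to link genome sequencing to clinical outcome. A recurrent driver such as
*PIK3CA* in luminal A breast cancer (mutated in roughly 46.6% of samples)
often shows **no** survival difference on its own. `fflsurv` implements a
network-level approach to this problem:

1. **Survival network.** Genome-wide RNAi screening of subtype cell lines,
   copy-number (GISTIC) scores and expression nominate genes supporting
   tumor cell survival — *cancer-essential* (screen *P* < 0.05, not
   housekeeping, top 75% expressed), *proliferation-influencing*
   (0.05 < *P* < 0.1, top 75% expressed) and *driver regulators*
   (GISTIC > 0.3, top 50% expressed, *P* < 0.4). Genes selected in at least
   one cell line are mapped onto a curated signed signaling network and the
   induced subgraph is the subtype-specific **survival network**.
2. **Network profiles.** For each tumor, its missense-mutated genes are
   seeds `Y` for insulated heat diffusion over the survival network:
   `F = α W'F + (1 − α)Y`, with `W' = D^(−1/2) A D^(−1/2)` and α = 0.7.
   Converged heat scores are multiplied by 100,000, then median-centered
   and scaled per gene across samples.
3. **Feed-forward loops (FFLs).** All ordered triples (master, secondary,
   target) with edges master→secondary, master→target, secondary→target
   are enumerated; loops whose three genes are all differentially
   expressed between driver-mutated and non-mutated tumors (Welch t-test,
   BH FDR < 0.05) are kept; a *positive* loop (all three edges activating)
   is called **active** in a sample when its normalized heat exceeds the
   cohort mean on all three genes, and **enriched** when active in more
   than 70% of driver-mutated tumors.
4. **Outcome.** Driver-mutated patients with and without the enriched loop
   are compared by Kaplan–Meier curves and the log-rank test, and by a
   proliferation index — the mean expression of the 11-gene PAM50
   proliferation subset (MKI67, CDC20, BIRC5, CCNB1, CDCA1, CEP55, KNTC2,
   PTTG1, UBE2C, RRM2, TYMS) — compared by Welch t-test.

A synthetic-data module generates the complete input bundle (network with
planted positive loops, screening evidence, mutation catalogs, expression,
survival) with known ground truth, so the whole pipeline is testable
without any external download.

## Worked example

```r
library(fflsurv)

spec <- cohort_spec(seed = 42)               # 348 samples, 46.6% driver-mutated
b    <- simulate_cohort(spec, dir = file.path(tempdir(), "demo"))
cfg  <- pipeline_config(
  network = b$paths[["network"]],     evidence   = b$paths[["evidence"]],
  mutations = b$paths[["mutations"]], expression = b$paths[["expression"]],
  clinical = b$paths[["clinical"]],   outdir = file.path(tempdir(), "demo_out"))
res <- run_pipeline(cfg)

res$survival_network
#> <survival_network> 50 nodes, 154 edges (69 activate, 47 inhibit, 38 neutral)
head(as.data.frame(res$enrichment), 3)
#>   master secondary target sign_class n_active cohort_size  fraction passes
#> 1  SG001     SG002  SG003   positive      123         159 0.7735849   TRUE
```

The top-ranked loop is the planted triad `SG001 → SG002 → SG003`: it is
active in 123 of 159 driver-mutated samples (77.4% > 70%, so it passes the
enrichment rule). Splitting the driver-mutated cohort on loop activity:

```r
res$survival$ffl_pos_vs_neg
#> chi2 = 17.97, p = 2.24e-05 (n = 123 vs 36)   # loop+ patients survive longer
res$proliferation$comparison
#> t = -8.85, p = 3.46e-12                      # loop+ tumors proliferate slower
```

while the driver mutation alone does not stratify survival
(`res$survival$mutated_vs_nonmutated`), reproducing the qualitative
pattern the method is designed to expose. Every stage also writes a TSV or
JSON artifact plus a manifest under `outdir`.

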