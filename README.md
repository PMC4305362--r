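# twowaytables

Publication-ready statistical tables for two-factor experiments.

Biomedical and agricultural papers summarise two-factor experiments in a
standard table: one row per response variable, `mean ± SEM` per
treatment, superscript letters encoding which treatments differ, and
three p-value columns for the two main effects and their interaction.
Producing these tables by hand — running the ANOVA, running a post-hoc
test, translating the pairwise decisions into letters, and typesetting
the result — is tedious and error-prone. `twowaytables` automates the
whole pipeline: it reads long-format Excel workbooks (or CSV), fits the
two-way ANOVA, runs all-pairwise comparisons under the cell-means model,
builds compact letter displays, and writes the finished tables (with
auto-generated captions) to an RTF document that opens directly in a
word processor. Interaction plots can be written to PDF.

## The statistics

For a response with observations $y_{ijk} \sim N(\mu_{ij}, \sigma^2)$
in cell $(i, j)$ of an $a \times b$ layout, the package reports the
sequential (Type I) decomposition SS(A), SS(B | A), SS(A×B | A, B) with
F tests against the residual mean square (MSE). All post-hoc work uses
the cell-means model — the $ab$ treatments analysed as one factor with
the pooled MSE. Available all-pairwise procedures:

| test | statistic | FWER control |
|---|---|---|
| `lsd` | $t = \Delta / \sqrt{MSE(1/n_i + 1/n_j)}$, optional Bonferroni/Holm | weak (strong with Holm/Bonferroni) |
| `tukey` | studentized range $q$ with $k = ab$ groups (Tukey–Kramer) | strong |
| `snk`, `duncan` | step-down multiple range tests on the ordered means | weak |
| `westfall` | free step-down max-\|t\| resampling adjustment | strong |

Pairwise decisions become superscript letters (insert-and-absorb with a
minimal-cover reduction): treatments sharing a letter do **not** differ
at the chosen level; when nothing differs, no letters are printed. The
pooled-SEM table format reports one
$PSEM = \sqrt{MSE \cdot 2/n}$ column instead of per-group SEMs
(unbalanced designs report the maximum per-pair value).

## Worked example

A packaged fixture carries the summary statistics (means, SEMs, n = 9
per treatment) of a rat plasma amino-acid study with factors diet
(HF/LF) and weight class (Lean/Overweight). `dataset_from_summary()`
rebuilds raw-data stand-ins with exactly those moments, and
`analyze_dataset()` produces the finished table:

```r
library(twowaytables)

s  <- read.csv(system.file("extdata", "plasma_table1.csv",
                           package = "twowaytables"))
ds <- dataset_from_summary(s[s$response %in% c("Asp", "Ser", "Cit"), ],
                           n = 9, factor_names = c("Diet", "Weight"),
                           source_sheet = "Plasma")
analyze_dataset(ds, table_options())
```

```
Summary table 'Plasma' (3 responses x 7 columns)
 Variable       HF-Lean HF-Overweight       LF-Lean  LF-Overweight  Diet Weight
      Asp   45.3 ± 2.39   47.6 ± 2.97   46.2 ± 2.96    45.3 ± 3.45 0.815  0.815
      Ser  359 ± 10.3^a  294 ± 4.39^b  353 ± 7.43^a   292 ± 3.76^b  0.57 <0.001
      Cit 79.9 ± 2.66^a 53.8 ± 1.63^c 69.6 ± 3.37^b 73.9 ± 1.84^ab 0.056 <0.001
  D × W
  0.593
  0.776
 <0.001
Values are means ± SEM, n = 9 per treatment group. a-cMeans in a row
without a common superscript letter differ (P < 0.05) as analyzed by
two-way ANOVA and the TUKEY test. D × W = Diet × Weight interaction effect.
```

Reading: aspartate shows no effect anywhere (no letters); serine
separates lean from overweight rats under both diets (`a` vs `b`, weight
p < 0.001); citrulline shows a diet-by-weight interaction (p < 0.001)
with all four treatments partially separated. The caption is generated,
not typed. Writing the same analysis to an editable RTF document — one
table per workbook sheet — is one call:

```r
run_twoway("plasma.xlsx", out = "tables.rtf", plots = "plots.pdf")
```

or from a shell:

```sh
Rscript inst/scripts/twoway_tables.R --input plasma.xlsx \
  --out tables.rtf --test tukey --alpha 0.05 --format per-group
```

Post-hoc analysis from a *published* table (no raw data needed):

```r
fit <- cell_means_fit_from_summary(
  means = c(359, 294, 353, 292),
  sems  = c(10.3, 4.39, 7.43, 3.76), n = 9,
  treatments = c("HF-Lean", "HF-Overweight", "LF-Lean", "LF-Overweight"))
pooled_sem(fit)            # 9.87
tukey_kramer(fit)          # all six pairwise q statistics and p-values
```

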