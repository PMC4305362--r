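---
title: "Methods: two-way ANOVA tables with post-hoc letter displays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-way ANOVA tables with post-hoc letter displays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twowaytables)
```

## The model

`twowaytables` turns long-format two-factor experimental data — two
nominal factors A (with $a$ levels) and B (with $b$ levels) plus one or
more numeric responses — into publication-ready statistical tables. The
underlying model is the standard two-way ANOVA with interaction:
observations in treatment cell $(i, j)$ are independent draws from
$N(\mu_{ij}, \sigma^2)$, with a common variance across all $ab$
treatments. Three hypotheses are tested per response: the main effect of
A, the main effect of B, and their interaction. Normality and
homoscedasticity are assumed, not tested; the package should be applied
only when these assumptions are plausible, and it deliberately ships no
diagnostic tests.

### Sums of squares

The ANOVA decomposition is *sequential* (Type I): SS(A), SS(B | A),
SS(A×B | A, B), residual. In balanced designs this decomposition is
orthogonal and the factor order is irrelevant; in unbalanced designs the
order matters, which is why `fit_two_way()` takes the order as an
explicit argument and `run_twoway(both_orders = TRUE)` emits a second
table with the factors reversed for unbalanced sheets — presenting both
orders is the usual recommendation when a single canonical decomposition
does not exist. Type II/III sums of squares are out of scope. F ratios
use the residual mean square; p-values come from the F survival function
with no finite-sample corrections.

### The cell-means model

All post-hoc work collapses the two factors into a single factor with
$ab$ levels (one per treatment) and proceeds as a one-way analysis. The
pooled within-cell variance of this fit equals the two-way residual mean
square (MSE) on the same data — an identity the test suite checks to
machine precision. A design with exactly one observation per treatment
leaves no within-cell variability: two-way ANOVA with interaction cannot
be conducted, and the pipeline reports an alert for such a sheet instead
of producing a table.

`cell_means_fit_from_summary()` rebuilds the same fit from published
summary statistics (per-treatment means, SEMs, n): since
$\mathrm{sem}_i = s_i / \sqrt{n_i}$, the pooled MSE is
$\sum_i (n_i - 1)\, n_i\, \mathrm{sem}_i^2 / \sum_i (n_i - 1)$, which
reduces to $n \cdot \overline{\mathrm{sem}^2}$ when balanced. This makes
every post-hoc quantity reproducible from a printed table alone.

## Pairwise comparison procedures

All procedures compare every pair of the $ab$ treatment means using the
pooled MSE with $N - ab$ error degrees of freedom.

* **LSD** — per pair,
  $t = (\bar y_i - \bar y_j) / \sqrt{MSE (1/n_i + 1/n_j)}$, two-sided p
  from the t distribution. Optionally Bonferroni or Holm adjusted (via
  `stats::p.adjust`); plain LSD is the unadjusted default.
* **Tukey–Kramer** —
  $q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}$ referred
  to the studentized range distribution with $k = ab$ groups. In
  balanced designs this is Tukey's HSD; the Kramer standard error keeps
  the unbalanced per-pair statistic exact. Controls the familywise error
  rate (FWER) in the strong sense.
* **SNK and Duncan** — multiple range tests on the ordered means. A pair
  spanning $p$ positions is tested at level $\gamma_p = \alpha$ (SNK) or
  $\gamma_p = 1 - (1-\alpha)^{p-1}$ (Duncan) against
  $q(\gamma_p; p, df)$. Step-down protection applies: once a range is
  declared non-significant, every sub-range inside it is declared
  non-significant without testing. Because the protected decisions do
  not factor into one number per pair, range tests return decisions with
  `NA` p-values, and the letter display consumes the decision matrix
  directly. For unbalanced data the per-pair Kramer standard error is
  used; harmonic-mean variants were rejected so that each pairwise SE
  stays exact. These tests control the FWER only in the weak sense.
* **Westfall-style max-t** — a free step-down max-|t| resampling
  adjustment: treatment means are simulated under the complete null
  (normal with variance $MSE/n_i$, error variance rescaled by a
  $\chi^2_{df}/df$ draw), and the h-th largest observed |t| is compared
  against the resampled maximum over the h-th and smaller statistics,
  with monotonicity enforced and the adjusted p floored at the raw p.
  This accounts for the correlation between pairs but not for the
  logical constraints among pairwise hypotheses, so it is conservative
  relative to truncated closed testing; it remains at least as powerful
  as Holm up to Monte-Carlo error (a property the tests check at
  100 000 draws). Resampling is deterministic given the configured seed;
  the default is 10 000 draws.

Ties in the mean ordering are broken by treatment order, so every
procedure is deterministic. On any shared fit the significant-pair sets
nest: Tukey ⊆ SNK ⊆ Duncan, and Bonferroni-LSD ⊆ Holm-LSD ⊆ raw LSD —
checked over hundreds of random fits in the test suite.

## Compact letter displays

The significance pattern is encoded by insert-and-absorb: start with one
column containing every treatment; for each significant pair sharing a
column, duplicate that column and delete one member from each copy; then
absorb columns contained in others. Significant pairs are processed in a
deterministic order (by the position of the larger-mean member, then the
smaller). The resulting columns are cliques of the non-significance
graph, and two treatments share a letter **iff** their pair is
non-significant — both directions are verified for every instance.

Insert-and-absorb alone terminates with the *maximal* cliques of the
non-significance graph, which can be far from a minimum letter set: with
three disjoint significant pairs among six treatments it yields eight
letters where four suffice. A final reduction step therefore keeps the
smallest sub-collection of the produced columns that still covers every
treatment and every non-significant pair — an exact search when the
column set is small (the practical case for two-factor tables), a greedy
redundancy elimination otherwise. The test suite compares the letter
count against an exhaustive minimum-clique-cover oracle on up to six
treatments and allows at most one excess letter.

Letters are anchored to the means: `a` attaches to the column with the
largest mean, ties broken by treatment order (the ordering convention
for tied means is our choice; conventions differ between
implementations). When no pair is significant, no letters are shown at
all — the conventional signal that all treatments are equivalent for
that response. More than 26 required letters is an error; it cannot
occur for factorial tables of realistic size.

## Summaries, pooled SEM, and formatting

Two table formats are supported. *Per-group SEM* prints
`mean ± SEM` per treatment. *Pooled SEM* prints means only plus one
pooled-SEM column per response:
$PSEM = \sqrt{MSE \cdot 2/n}$ when balanced — the common standard error
of every pairwise difference — and, when unbalanced, the maximum of
$\sqrt{MSE (1/n_i + 1/n_j)}$ over all pairs, a conservative single
number for a format best reserved for balanced designs. Each response
uses its own MSE.

Means and SEMs are rendered with a fixed number of significant digits
(default 3) under the usual counting rules (nonzero digits count, zeros
between them count, trailing fractional zeros count); table cells then
trim trailing fractional zeros, matching the mixed precision customary
in journal tables ("197 ± 6.4" rather than "6.40"). `format_sigfigs()`
exposes both behaviours. p-values are rounded to a fixed number of
decimals (default 3); values below the display resolution print as a
bound (`<0.001`), so a positive p never renders as zero.

Captions are generated automatically: the summary type, the
per-treatment n (a single value when uniform, a range otherwise), a
letter sentence stating the range of letters actually used, the
significance level and the test name (only when letters appear), and the
interaction-abbreviation footnote ("D × W = Diet × Weight interaction
effect", abbreviations taken from the factor names' initials).

## Input handling

Factors are detected by parsing: a column in which at least one value
fails numeric parsing is a factor; columns of numbers are responses even
when integer-coded. Exactly two factor columns are required — a factor
coded 0/1 is therefore reported as "unable to find two factors", with
the fix being letter-coded levels. Factor order follows column order;
level order is lexicographic by code point, so prefixing levels with
digits ("1Overweight", "2Lean") overrides the default ordering with no
special casing. Names are sanitized, never abbreviated: spaces become
underscores, Greek letters are transliterated (they render poorly in RTF
readers), other invalid characters become dots, and invalid leading
patterns get an "X" prefix (".2Ala" → "X.2Ala"); every rename is
reported. Missing response values are allowed and dropped per
(response, record) pair, with per-cell n recomputed per response — the
caption then reports an n range; missing factor labels are an error. A
column mixing numbers and text is treated as a factor (any unparsable
value makes the column categorical); this is our convention and other
tools may coerce instead.

## RTF output

Tables are serialized in a minimal RTF 1.x dialect — plain row/cell
control words, horizontally merged header cells for the nested
factor-A-over-factor-B header, `\super` for letter superscripts, fixed
column widths proportional to header text length — chosen for maximal
reader compatibility and post-hoc editability rather than pixel
fidelity. The stream is pure 7-bit ASCII; "±" and "×" are emitted as
`\uN` control words with an ASCII fallback. Output is byte-deterministic
(a golden-file test pins the dialect), and identical input produces
byte-identical documents end to end.

## The synthetic generator

`generate_dataset()` draws each cell of a two-factor layout
independently from $N(\mu_{ij}, \sigma^2)$ with a single shared
$\sigma$ — exactly the sampling model the analysis assumes — with
optional completely-at-random masking of response values. It emulates
the analysis assumptions, **not** real data: no heteroscedasticity, no
non-normal errors, no correlation between responses, no informative
missingness. Tests passing on generated data therefore validate the
computations under the model, and say nothing about robustness to
violations. `dataset_from_summary()` complements it by reconstructing
raw-data stand-ins whose cell means and SEMs equal published summary
statistics exactly (each cell is the mean plus the implied SD times a
standardized sequence); such reconstructions reproduce every quantity
that depends only on first and second moments, while quantities
sensitive to the printed rounding (near-null p-values especially) can
shift visibly — reconstructions from 3-significant-digit summaries move
third decimals, and for tiny effects the shift can reach a few
hundredths.

## Test problem sizes and numerical choices

The property-style checks use: 500 random balanced fits (k = 4, n = 9)
for the procedure-nesting invariant; 1000 null replicates for the Tukey
FWER simulation (the observed rate must sit within three Monte-Carlo
standard errors of 0.05); 1000 random significance patterns on up to six
treatments against the exhaustive letter-count oracle; and 15–25
replicate checks for the design-matrix ANOVA oracle and equivariance
properties. These sizes give stable verdicts while keeping the default
test run quick. Internal tolerances: the sequential decomposition must
sum to the total SS within 1e-9 relative; the two MSE computations must
agree within 1e-12 relative; all comparisons of analytic p-values to the
oracle use 1e-8 or tighter.

## Known limitations

* Two factors only; no covariates, random effects, or higher-way
  layouts.
* No confidence intervals for pairwise differences — tables report
  significance letters, which is what the target table format uses.
* The max-t procedure is the free step-down variant, not the
  logically-constrained truncated closure.
* No Dunnett-style comparisons against a control.
* The RTF dialect is intentionally spartan (no style sheets, borders or
  fonts beyond one default).
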