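---
title: "Scoring genetic interactions in combinatorial double-knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in combinatorial double-knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gipairs)
library(dplyr)
```

## The measurement and the model

A pooled combinatorial knockout screen transduces cells with a lentiviral
library in which every construct expresses two CRISPR guides — position 1 and
position 2 of one cassette — and lets the pool grow for several weeks.
Sequencing the guide-pair cassette at harvest timepoints and in the plasmid
library before transduction turns growth into counts: a construct whose double
knockout slows growth is depleted, one that accelerates growth is enriched.

For construct $c$ in sample $s$, after scaling each sample to counts per
million, the observed effect is

$$\mathrm{LFC}_{obs}(c,s) = \log_2\frac{\mathrm{cpm}(c,s) + p}{\mathrm{cpm}(c,\mathrm{input}) + p},$$

with pseudocount $p$ (default 1 cpm) keeping dropouts finite. Constructs
pairing two olfactory-receptor (OR) guides carry no knockout: their median
defines zero, and every sample is centered on it.

Each guide's *single*-knockout effect at a position is the mean
$\mathrm{LFC}_{obs}$ of its pairings with OR guides at the other position, kept
separate per orientation because cassette position affects expression. Under
the additive null model the expected double-knockout effect is the sum of the
two single-KO effects,

$$\mathrm{LFC}_{exp} = \overline{\mathrm{LFC}}_{g_1@pos1} + \overline{\mathrm{LFC}}_{g_2@pos2},
\qquad
d\mathrm{LFC} = \mathrm{LFC}_{obs} - \mathrm{LFC}_{exp}.$$

A negative $d\mathrm{LFC}$ means the double knockout is worse than additivity
predicts (synthetic lethality); positive means better (synthetic viability).
Per sample, $d\mathrm{LFC}$ is re-centered so that the median over constructs
carrying at least one OR guide — a built-in null set, since a guide's own
single-KO estimate enters its expectation — is zero.

One numerical point matters here. The centering is implemented as a per-sample
calibration *of the expectation* (`lfc_exp` absorbs the offset), so the
identity $d\mathrm{LFC} = \mathrm{LFC}_{obs} - \mathrm{LFC}_{exp}$ holds for
exactly the columns the significance test consumes. Centering the
$d\mathrm{LFC}$ column alone looks equivalent but is not: a chance shift of
the OR$\times$OR anchor median then leaks into the paired test of every gene
pair simultaneously, in all replicates, and inflates the false-call rate by
an order of magnitude. Our null simulations caught precisely this.

## From constructs to gene-pair calls

All guide pairs targeting the same unordered gene pair (with 3 guides per gene
and both orientations: 18 constructs) are compared by a two-tailed paired
Student t-test of $\mathrm{LFC}_{obs}$ against $\mathrm{LFC}_{exp}$; the pair
$d\mathrm{LFC}$ is the mean per-construct difference, identical to
$\overline{\mathrm{LFC}}_{obs} - \overline{\mathrm{LFC}}_{exp}$ over the same
set. P-values are adjusted per replicate with the two-stage linear step-up
procedure of Benjamini, Krieger and Yekutieli (BKY): a first Benjamini-
Hochberg pass at $q' = q/(1+q)$ estimates the number of true nulls $m_0$,
a second pass rescales by $m_0/m$. Our adjusted values are scaled so that
thresholding at $q$ reproduces the two-stage rejection set; they are valid
for the given $q$ only and, unlike plain BH, may fall below the raw p-value.
No installed adjustment routine provides this procedure, so it is implemented
here and verified against a brute-force two-stage oracle over thousands of
random p-vectors.

Calling is deliberately conservative. In `per_replicate` mode (default
$\alpha = 0.1$, threshold $|d\mathrm{LFC}| > 0.3$, week 3) a pair is called
only when *every* replicate is independently significant and beyond the
threshold with a common sign. The published criterion ("all three replicates
significant and $|d\mathrm{LFC}| > 0.3$") does not say which dLFC the
threshold hits; we apply it per replicate because that is the only reading
under which the unanimity call set is a subset of each single replicate's
call set — the property that makes "all replicates agree" a guarantee rather
than a slogan. `merged` mode concatenates constructs across replicates and
tests once at a stricter $\alpha = 0.005$, the variant used for two-replicate
screens.

Degenerate variance is handled by convention, not accident: identically zero
differences give $p = 1$ (no evidence), constant nonzero differences give
$p = 0$ with a flag. Pairs with fewer than `min_constructs` (default 2)
testable constructs are recorded as untestable (`NA`), never silently dropped.

## Post-hoc filters

Three filters act on annotated fields only, so they are order-independent
pure predicates, each leaving a provenance flag; the flagged table is a
superset view of the final network.

**Saturation filter.** When both partners are strongly deleterious, cells are
dying or arrested and cannot express the summed effect; the double knockout
then looks spuriously "viable". A viable call is removed when
$\mathrm{LFC}_{exp} < -0.3$ *and* the observed double-KO effect lies strictly
below both single-KO effects. We read "lower than each of the single gene KO
LFC values" as strictly-below-both; an observed effect that rises above even
one single KO is a genuine rescue and is kept. The filter never touches
lethal calls.

**Time-course filter.** An interaction whose replicate-averaged
$d\mathrm{LFC}$ changed by less than 0.1 log2 units between week 1 and the
scoring week is removed: a construct-abundance offset already present at
week 1 and constant thereafter is indistinguishable from variable
transduction efficiency. "0.1-fold" is interpreted as 0.1 log2 units. The
literal absolute-change rule is the default; a directional variant (the
change must move in the called direction) is available but off.

**Essential-gene flag.** Genes with a gene-level single-KO LFC below −2 in
*all* provided screens saturate the growth readout; calls touching them are
flagged (annotation-only by default, exclusion by configuration).

## The simulator

`sim_config()` / `generate_design()` / `simulate_counts()` generate screens
with known truth so every stage above is testable without external data. Per
guide, an editing outcome is drawn once at transduction with probability equal
to its efficiency (outcomes are fixed thereafter, as in a selected pool). A
lineage's fitness in log2 per week is

$$f = \max(s_1 e_1^* + s_2 e_2^* + \varepsilon\, e_1^* e_2^* + \delta_{cond},\ \mathrm{floor}),$$

where $e^*$ are the 0/1 outcomes, $\varepsilon$ a planted interaction, and
the floor (default −3 log2/week) models death/arrest saturation — clamping
fitness, not truncating counts. Expected construct abundance at week $t$
mixes the four outcome classes, $\sum_k P_k\, 2^{f_k t}$, times a log-normal
plasmid abundance (sdlog 0.5); observed counts are multinomial at the sample's
depth (default 500 reads per construct) after multiplicative gamma
overdispersion (default squared-CV 0.04, i.e. CV 0.2). Because the outcome
mixture factorizes exactly when $\varepsilon = 0$, observed and expected
effects agree for non-interacting pairs at any efficiency — the additive null
is faithful, not approximate, in the generator. In the analytic mode
(`noise = FALSE`, efficiencies 1, pseudocount 0) the pipeline recovers
$\mathrm{LFC} = s\,t$ and $d\mathrm{LFC} = \varepsilon\, t$ to machine
precision, which pins the scale conventions end to end. With partial editing
the measured interaction is attenuated roughly by $e_1 e_2$ and by the
log-of-mixture: at efficiency 0.8, a planted $\varepsilon = -1$ yields a pair
dLFC near $-1.1$ at week 3 rather than $-3$ — the simulator's account of why
screens under-call with inefficient guides.

Defaults emulate the benchmark metal-transporter screen: gene fitness a
mixture of 85% near-neutral, 10% mildly deleterious (−0.5 ± 0.2) and 5%
essential (−2.5 ± 0.3) log2/week; guide efficiencies Beta(8, 2) (mean 0.8);
3 replicates; harvests at weeks 1, 2, 3 and 5. Where the study does not state
a value (abundance skew, overdispersion, the efficiency distribution) the
defaults are plausible for pooled lentiviral screens, chosen once, and not
fitted. What the generator does *not* emulate: multiple infection and
cassette recombination, copy-number effects, ongoing editing, guide-specific
off-target toxicity, and batchy library amplification. Passing simulation
tests therefore demonstrates internal consistency of the scoring scheme under
its own assumptions, not performance on any particular real screen.

Two structural features of real screens that the simulator *does* carry turned
out to be load-bearing:

* **One plasmid input per screen.** Counting noise in the shared input enters
  every replicate's LFC identically, so input-driven errors are correlated
  across replicates and replicate unanimity does not dilute them. Deeply
  sequencing the input (or per-replicate inputs, which the reader supports)
  is the remedy.
* **The number of OR anchors.** With only 3 OR pairings per guide and
  orientation, single-KO estimates are noisy enough that null screens exceed
  a 1% false-call rate; with the benchmark library's 9 anchors per guide and
  orientation the rate in our simulations drops to zero at the same depth.
  Anchor count is a design requirement for error control, not a nicety.

## Simulation scales used by the checks

The test suite and the acceptance script run, at desk scale: 50 seeded null
screens and 9 planted-interaction screens of the metal-library geometry
(21 genes, 5184 constructs, 3 replicates, weeks 1 and 3, depth 500 reads per
construct), plus analytic-mode micro-screens for the exact identities.
Power/recovery screens plant ten disjoint interactions on a neutral fitness
background so that recall isolates interaction detectability; the null
screens keep the full fitness mixture, essentials included, because that is
where saturation artifacts live.

## Multi-screen integration

`fuse_screens()` unions call tables into one edge per unordered gene pair per
condition, keeping per-screen provenance; discordant-sign edges (lethal in one
system, viable in the other — as observed for functionally obligate partners
with clone-dependent single-KO directions) are retained and flagged rather
than dropped, since the direction of a real interaction can legitimately
differ between cell clones. `condition_compare()` defines "rewired in a
condition" as a call-state change against the reference condition
(NONE/lethal/viable); a dLFC-magnitude variant exists because "changed" is
not otherwise pinned down. `concordance()` reports Pearson correlation and
$R^2$ over shared pairs; `orientation_concordance()` splits an all-by-all
design by cassette orientation. Networks export as edge-list TSV, GraphML
(via igraph) or SIF.

## Known limitations

* The multiplicity family defaults to all pairs tested in the same screen /
  condition / replicate / timepoint; sublibrary-wise adjustment, where a
  screen was built from sublibraries, is the caller's responsibility via
  `screen_id`.
* Single-KO effects are estimated per orientation from OR pairings only;
  guides lacking OR anchors propagate `NA` (never an implicit zero), and the
  pairs relying on them become untestable.
* The paired t-test assumes approximately normal construct-level differences;
  no moderated-variance or permutation alternative is provided.
* Alternative expectation models (multiplicative, minimum) are out of scope;
  the additive model on the log2 scale is the one the screens' anchoring
  supports.
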