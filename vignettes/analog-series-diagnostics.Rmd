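---
title: "Analog-series diagnostics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analog-series diagnostics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it
implements: the scoring model and its assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the choices made where the method leaves room.

## The neighborhood scoring model

An analog series (AS) is a core scaffold with labeled substitution
sites plus existing analogs (EAs), each a core decoration with a pIC50
potency. Virtual analogs (VAs) are computationally designed series
members used as probes: EAs and a VA sample are embedded in a chemical
reference space, and each EA defines a chemical neighborhood (NBH) —
the closed ball of radius $r$ around its descriptor vector.

With $m(v)$ the number of NBHs containing VA $v$, and $V$ the VA
sample:

$$C = \frac{|\{v : m(v) \ge 1\}|}{|V|}, \qquad
  D = 1 - \frac{1}{\bar d}, \qquad
  S = \frac{2CD}{C+D},$$

where $\bar d$ is the mean multiplicity $m(v)$ over covered VAs. For
SAR progression, each VA $i$ lying in $m_i > 1$ neighborhoods
contributes the mean absolute pairwise potency difference
$\bar\Delta_i$ of its $m_i$ EAs, and

$$P = \frac{\sum_i w_i \bar\Delta_i}{\sum_i w_i}, \qquad
  w_i = \begin{cases} 1/m_i & m_i > 1 \\ 0 & m_i = 1.\end{cases}$$

**Reading of the density term.** A literal ratio of "overlapping
neighborhoods to total VAs in neighborhoods" can fall below one and
drive $D$ negative. We therefore define $\bar d$ as the mean
NBH-membership multiplicity per covered VA, which guarantees
$\bar d \ge 1$ and $D \in [0, 1)$: $D = 0$ means every covered VA sits
in exactly one neighborhood, and $D \to 1$ means unbounded overlap.
This is the only reading under which density behaves as a bounded
overlap score.

**Degenerate cases.** No covered VA means no overlap information:
$D = 0$ by definition. No VA with $m_i > 1$ likewise gives $P = 0$.
Both are semantic floors, not errors. Membership uses the closed ball
($\le r$), so boundary behavior is deterministic and documented.

**Exclusion of reproduced EAs.** VAs whose canonical SMILES equals an
EA are removed from the scoring pool before sampling (generative
sampling reproduces training analogs); they would trivially inflate
coverage.

## The chemical reference space

Seven physicochemical descriptors form the default space: molecular
weight, computed logP, H-bond donors, H-bond acceptors, topological
polar surface area, rotatable bonds, and aromatic ring count. These are
standard lead-optimization-relevant properties; the set is an
implementation choice and fully configurable through a descriptor
registry. Aromatic rings are counted as unique 5- and 6-membered
aromatic ring SMARTS matches, the sizes that occur in this chemistry.

Descriptors are z-scored. Whether and on which population the
original method standardized is unstated, so the package makes its own
documented choice: the standardizer is fitted on the union of the EAs
and the full VA pool of the scoring run, so both populations live in
one coordinate system and the radius means the same thing for every
resample. Population (not sample) standard deviation is used; constant
dimensions get scale 1 with a warning — they carry no distance
information and are not discarded.

**The NBH radius** is the one hyper-parameter the scores cannot fix
internally, and no universally correct value exists: it must mirror
typical EA-VA distances for the population at hand. The package offers
a distance-quantile calibration (`calibrate_radius`, default quantile
0.05 of all EA-VA standardized distances) and always echoes the radius
in the score report so runs are comparable. Score standard deviations
are sample standard deviations over the resamples.

## Series representation and fragmentation

Compounds are decomposed into core + substituents by cutting acyclic
single bonds matched by a configurable rule set of common
retrosynthetic disconnections (amide, ester, sulfonamide, amine, ether,
ring-to-chain). Exotic published rule collections are deliberately not
reproduced; the rule set is data, not code. A decomposition is valid
when one fragment (the core) touches every cut and each substituent
touches exactly one, when no substituent exceeds 13 heavy atoms, and
when the core is at least as heavy as its heaviest substituent (the
core is the dominant part; without this convention a carbonyl fragment
can "win" a series). Reassembly of any decomposition reproduces the
input canonical SMILES exactly, which is tested property-style.

Attachment sites are identified canonically by a probe signature: the
core SMILES with one site marked by a xenon atom (an element absent
from the fragment library). Sites are ordered by sorting these
signatures, making per-site substituent tables comparable across
compounds. Topologically equivalent sites produce identical signatures;
assignments are then deterministic but arbitrary, a documented
limitation. During series extraction, each compound joins the core
matched by the most compounds (ties: heavier core, then lexicographic
SMILES); analogs carrying H at a site are absorbed afterwards by
explicit core matching, and the minimum series size is applied after
absorption. Substituent "H" is an explicit placeholder at unused sites.

## Virtual analog design

Diverse and close-in enumeration differ only in the pool: series
substituents (close-in) or an external fragment library (diverse). Each
VA sets every site independently to H — with a per-site probability
that defaults to the fraction of EAs carrying H there, the only series
statistic directly interpretable as a substitution probability — or to
a uniformly drawn pool fragment (with replacement; the method does not
state the drawing scheme, and independent draws are the simplest
reproducible choice). VAs outside the EA heavy-atom size range are
rejected and redrawn; rejection sampling is bounded at 100 × `n_target`
draws so small combinatorial spaces terminate with a documented
shortfall instead of hanging.

Free-Wilson analysis is positional: matched molecular pairs are
analogs differing at exactly one site, which within a series is
equivalent to, and far less ambiguous than, generic single-cut
fragmentation. Quartets are closed double-exchange cycles on two sites
with fixed context; a compound's "Free-Wilson neighborhood" membership
is operationalized as appearing in at least one quartet in any role
(the counts of participating EAs are reported with this definition).
Multiple quartets sharing a target are aggregated by unweighted mean —
no weighting scheme is described, and the additive model gives no
reason to prefer one quartet over another.

## Global potency models

Compounds are encoded as 2048-bit folded extended-connectivity
fingerprints of bond diameter 4 (the backend produces 4096 bits; OR
folding preserves the Tanimoto ordering closely). Epsilon-SVR uses the
Tanimoto kernel; ridge regression uses the raw bit vector. Since no
hyper-parameter grids are published, conventional grids are exposed in
the configuration: C in {0.1, 1, 10, 100}, epsilon in
{0.01, 0.1, 0.5}, ridge lambda in {0.01, 0.1, 1, 10, 100}. Selection
runs on an inner 3-fold CV, generalization is estimated on an outer
3-fold CV, and the final model refits on all data with the modal
hyper-parameters. $R^2$ is the coefficient of determination (not
squared Pearson correlation), which is the stricter and more common
reading. The 50/50 series split for external validation stratifies by
potency quartile so neither half has a degenerate potency range.

## The generative module

The sampled-VA strategy fine-tunes a pre-trained SMILES language model
on the EAs of one series. The architecture is an LSTM language model
over tokenized SMILES (multi-character atom symbols, bracket atoms and
two-digit ring closures are single tokens; detokenization is the
identity). The full-size configuration (embedding 512, three LSTM
layers of 512, sequence length 256, 50 epochs × 1024 samples) is
selectable, but the default is desk-scale: embedding 64, two layers of
128, sequence length 128, 15 fine-tuning epochs with 256 samples per
epoch, Adam at 0.005 with exponential decay (factor 0.9) after 3
stalled epochs on a 10% held-out split. Held-out cross-entropy is the
convergence monitor; divergence-based sampling metrics from the
literature are not reimplemented. The model is implemented directly in
matrix algebra with full backpropagation through time and
length-bucketed minibatches; at these sizes a dedicated deep-learning
framework adds nothing but a dependency.

Data augmentation randomizes SMILES by permuting atom order before
writing, a standard trick that multiplies the effective training set of
a small series. Core containment of a sampled molecule is tested by
substructure match of the series core with attachment sites
unconstrained, so H-substituted sites count as containing the core.

**Validity of sampled strings** is deliberately stricter than "the
parser returns a molecule": the Open Babel parser repairs unclosed
branches and broken aromatic systems instead of rejecting them. A
sampled string counts as valid when (1) its SMILES grammar is
well-formed (balanced branches and ring bonds, no dangling bond
symbols), (2) it parses, and (3) its canonical form stays within the
vocabulary's token universe — a canonical form sprouting new bracket
atoms means the parser invented radicals or explicit valences to
rescue a chemically broken string.

## The synthetic-data generator

The generator is first-class, tested code and defines the conditions
under which the package validates itself. Series are real,
valence-correct molecules assembled from a shipped library of benzamide
cores (2-4 substitution sites) and ~30 substituent fragments; per-site
alphabets are drawn so every attachment is cleavable by the default
rule set, making fragmentation recovery exact by construction. Recorded
potency is

$$\mathrm{pot} = \mathrm{base} + \sum_s \beta_{s,R_s}
  + \sum_{s<t} \gamma_{s,t,R_s,R_t} + \varepsilon,$$

with additive effects $\beta \sim N(0, 0.5^2)$ per (site, substituent),
optional pairwise interactions $\gamma \sim N(0, \sigma_\mathrm{int}^2)$
(the non-additivity dial), and noise
$\varepsilon \sim N(0, \sigma_\mathrm{noise}^2)$. All components are
stored as ground truth, so Free-Wilson predictions, MMP and quartet
counts, and series extraction can be checked exactly. All randomness
flows from a single spec seed.

What the generator does *not* emulate: assay artifacts and censored
measurements, activity cliffs caused by binding-mode switches (its
non-additivity is smooth and Gaussian), selectivity or ADMET
dimensions, tautomers/stereochemistry, and the scale and structural
heterogeneity of public bioactivity databases. Passing tests therefore
demonstrate internal correctness of the statistics and algorithms
under a controlled SAR model — not that any particular real series
will score the same way.

Background corpora for generative pretraining are assembled from
scaffolds disjoint from the series cores, so a fresh prior samples
essentially no core-containing molecules and the fine-tuning focusing
effect is measurable from a near-zero baseline.

## Validation quantities and problem sizes

The test-suite problem sizes are the package's own validation
conditions, chosen so every check runs comfortably on a laptop: series
of 10-100 analogs on 2-3 sites, VA pools up to ~3200 (scores compared
between resample sizes 1000 and 3000, drift below 0.05), brute-force
oracle comparisons on 60 × 1500 point sets, a 500-molecule pretraining
corpus with 55 epochs for the prior, and 15 fine-tuning epochs with 256
samples per epoch. The Free-Wilson noise band is pre-registered from a
20-seed Monte-Carlo reference run at noise 0.2 (aggregated MAE
0.094-0.152, band [0.05, 0.25]); the single-quartet error has the
closed form $\sigma\sqrt{3}\sqrt{2/\pi} \approx 0.276$ at
$\sigma = 0.2$ and is tested separately, since per-series means scatter
around it with correlated quartet errors.

## Stage classification

The scores support only relative staging, so the stage labels are a
pragmatic formalization with configurable thresholds that are always
printed: saturation below 0.15 is `early` regardless of progression;
moderate saturation is `early_mid` under strong progression
(P ≥ 0.8) and `mid` otherwise; high saturation (S ≥ 0.5) is `mid`
under strong progression and `late` otherwise. The label is monotone
in S by construction. Strategy recommendations map stages to design
strategies (late → Free-Wilson/close-in first; early → diverse/sampled
first) through a configuration table.

## Known limitations

- Open Babel is the single chemistry backend: canonicalization,
  aromaticity perception, logP and TPSA values follow its models and
  may differ numerically from other toolkits. Descriptor values are
  only meaningful relative to one another inside one run.
- Fragmentation recovery is rule-bound: substituents attached through
  bonds no rule cleaves (e.g. direct ring-ring couplings) cannot be
  decomposed back, and such compounds are excluded from series with a
  warning rather than guessed at.
- Potency aggregation across repeated measurements is out of scope:
  the caller supplies one pIC50 per compound.
- The desk-scale generative model is a real language model but a small
  one; its validity and uniqueness fractions are far below what a
  full-size prior trained on millions of compounds achieves, and the
  module is exercised on synthetic chemistry only.
- Symmetric substitution sites receive deterministic but arbitrary
  labels; per-site statistics across compounds are only meaningful for
  topologically distinguishable sites.
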