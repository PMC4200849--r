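---
title: "Neighbor preferences and context-dependent substitutions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbor preferences and context-dependent substitutions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Amino acids are not placed independently along proteins: an alanine is more
likely than chance to sit next to another alanine, glycine recurs with period
three inside collagen-like domains, and helical residues pair with partners
three or four positions away on the same helix face.  The same is suspected of
amino-acid *substitutions*: whether an S at some site is replaced by a P over
evolutionary time may depend on what flanks that site.  `aacontext` quantifies
both effects with one statistic, the relative entropy of flanking-site residue
distributions, and one significance device, a positional shuffle null.

## The statistic

Fix a focal residue type (say A), and an offset $i \in \{-W,\dots,-1,
+1,\dots,+W\}$ relative to its occurrences (negative = N-terminal side).
Collect the residues observed at offset $i$ over all qualifying occurrences;
call their frequencies $P(a)$.  Against a background $Q(a)$, the per-residue
contribution is

$$ d(a) = P(a)\,\log_2 \frac{P(a)}{Q(a)}, $$

and the relative entropy (Kullback–Leibler divergence) of the site is

$$ D_i = \sum_{a=1}^{20} d(a) \ge 0, $$

zero exactly when $P = Q$.  A large $D_i$ means the residue mix at offset $i$
deviates from expectation; the individual $d(a)$ say which residues drive the
deviation.  Residues whose $d(a)$ falls outside the Tukey whiskers of the 20
components (above $Q_3 + 1.5\,\mathrm{IQR}$ or below $Q_1 - 1.5\,
\mathrm{IQR}$) are flagged as preferred / avoided neighbors.

The logarithm base is 2 (bits).  No published convention exists for this
analysis; since shuffle thresholds are computed in the same base, significance
calls are base-invariant, and only the absolute scale of profiles changes.

## Windows, completeness, unknowns

* Whole-sequence analyses use $W = 20$; structure-stratified analyses use
  $W = 6$, because helix/strand/coil segments are short (mean helix length in
  globular proteins is near 10 residues) and larger windows would leave almost
  no qualifying occurrence.
* An occurrence contributes its N-side flank iff $\ge W$ residues precede it,
  and its C-side flank iff $\ge W$ residues follow it.  The sides are
  *independent*: a residue 10 positions from the C-terminus still contributes
  its N-side flank at $W = 20$.  This is why the two sides have different
  context counts, and consequently different thresholds.
* In structure-stratified runs the occurrence *and its whole flank* must lie
  inside a single segment of the requested class.  The alternative — letting
  windows cross segment boundaries — would mix classes at the outer offsets;
  confinement is the reading under which the short average segment length
  actually limits the usable window, and it is what
  `extract_contexts_in_structure()` implements.
* Non-canonical residues (X, U, B, Z, O, \*, …) are collapsed to one unknown
  symbol `?` on input.  The symbol occupies its position — windows remain
  "complete", coordinates and structure tracks stay aligned — but it is
  excluded from every count and every frequency denominator, so $P$ and $Q$
  always sum to 1 over exactly 20 residues.  A strictness flag
  (`drop_unknown_contexts`) discards whole flanks containing `?` instead.

## Backgrounds

Two backgrounds are used, and the difference between them is the heart of the
substitution analysis:

* **Neighbor preferences** use the *global* background: the observed residue
  frequencies over the scoped dataset (all sequences, one secondary-structure
  class, or one group label).  $D_i$ then measures how the flanks of the focal
  residue differ from the dataset at large.
* **Substitution profiles** for a type X→Y use the *per-offset* background:
  $Q_i(a)$ is the observed distribution at offset $i$ of *all occurrences of
  X* in the reference dataset.  Without this correction, every substitution
  profile would simply inherit X's own neighbor preferences; with it, $D_i$
  measures whether the substituted occurrences of X have *different* flanks
  than X generally does — genuine context dependence of the substitution.

Zero background frequencies make $d(a)$ undefined when $P(a) > 0$; the package
raises an error by default.  An optional pseudocount (+0.5 to every background
count before normalizing) is available behind a flag rather than applied
silently, because pseudocounts change every component value.

## Significance: the shuffle null

Positional preference should vanish when positions are destroyed but
composition is kept.  Each shuffle round permutes the $W$ positions of every
stored flanking string independently (each flank keeps its own residue
multiset), recomputes all $W$ per-offset totals against the same background,
and pools them.  With 500 rounds and $W = 20$ the pool holds 10,000 simulated
totals and the threshold is the 10th-highest value — the empirical 0.001
quantile; with $W = 6$ it is the 3rd-highest of 3,000.  In general the rank is
$k = \max(1, \mathrm{round}(\alpha\,|\mathrm{pool}|))$.  N- and C-side pools
are built and thresholded separately, since their context sets differ.

Two design points deserve note:

* *Shuffle granularity.*  Permuting each string independently (the default)
  preserves per-context composition, which is the natural null for positional
  preference.  Applying one shared permutation per round is also implemented
  (`shuffle_mode = "global"`) for sensitivity analysis; with one shared
  permutation the pooled totals are merely relabelings of the observed ones,
  which makes the null far more conservative for strongly positional signals.
* *What the null absorbs.*  Shuffling equalizes offsets but keeps the
  window-averaged composition of the contexts.  If that average differs from
  the background — as it does when a strong signal sits at some offsets — the
  null totals are elevated, and the threshold rises accordingly.  This is the
  mechanism by which, e.g., the mild glycine depletion at non-3n offsets of a
  collagen mixture stays below threshold while the 3n offsets stand far above
  it.

Bootstrap error bars resample the stored flanks per side with replacement at
the original count, 100 times by default, and report the standard deviation
(denominator $n-1$) of each offset's total.

One master seed drives everything; shuffle and bootstrap consume independent
sub-streams derived from it, so enabling or disabling the bootstrap does not
change thresholds.

## Substitution events

Events are inferred from aligned ancestor/descendant pairs by pairwise
column comparison: a column yields one event iff both rows hold canonical
residues and they differ.  Gap and unknown columns yield nothing.  Contexts
are read from the *ungapped ancestral* sequence: the background correction is
keyed to the pre-substituted residue, so ancestral context is the only
consistent pairing (reading descendant context against an ancestral
background would confound the correction).  Columns adjacent to other
substitutions are kept in contexts by default — there is no published rule to
follow — and a strictness flag (`drop_overlapping`) removes events with
another substitution inside their window.

Of the 380 ordered substitution types, those with fewer than
`min_events_per_side` (default 100) contexts on their better side are
excluded; below that, per-offset frequencies are too noisy for a 20-category
divergence to be meaningful.  A type is *called* context dependent when at
least one offset exceeds its threshold; because a reasonable analyst might
require more, the per-type count of significant offsets is always reported
alongside the call.

## The synthetic generators

The generators produce data whose planted structure is known exactly, so
recovery can be scored without circularity:

* `gen_iid()` — residues i.i.d. from a configurable composition; the
  calibration null.  Defaults: uniform composition, lengths
  uniform-integer in [150, 400] so full 20-site windows exist.
* `gen_collagen_mix()` — a fraction of records carries one (G-X-Y)$_n$ block
  (X, Y drawn from the composition excluding G) embedded in i.i.d. flanks.
  Default 30 triplets, a modest triple-helical domain that fits desk-scale
  sequence lengths.
* `gen_self_clustering()` — Poisson-placed homopolymer runs, the slippage-like
  self-preference signal.
* `gen_helix_pairing()` — sequences built left to right where the residue $d$
  upstream being X multiplies Y's probability by a chosen enrichment;
  all-H tracks make each record a single helix segment.
* `gen_context_substitutions()` — per-site independent substitutions:
  X→Y at `base_rate` (times a multiplier when a neighbor condition holds),
  every other residue to a uniformly random different residue at `base_rate`;
  gapless alignments plus the exact event list.

What these emulate — and what they do not: real proteomes have highly
non-uniform composition, length distributions with heavy tails, domain
structure, homology between sequences, and substitution processes coupled at
the codon level (the CpG effect behind much context dependence at the DNA
level).  The generators reproduce only the statistical features the analysis
consumes: flanking-site composition, segment structure, and
neighbor-conditioned event rates.  Passing recovery tests therefore
demonstrates the *method* (extraction, correction, thresholds) recovers
planted signals of realistic effect size, not that any particular biological
dataset will show them.

## Numerical and degenerate-input choices

* $0 \log 0 = 0$ throughout; $P(a) > 0$ with $Q(a) = 0$ is an error unless a
  pseudocount background is used.
* Offsets whose side has no qualifying context are absent from profiles, not
  reported as zero.
* All-zero count vectors (e.g. an offset populated only by unknowns) are an
  error, not a zero.
* Quartiles for the outlier rule use linear interpolation between order
  statistics (R's default type 7); the convention is exposed
  (`quartile_type`) because boxplot implementations differ and the flagged
  set can change for borderline components.
* Ties in the shuffle pool count separately: the k-th highest is taken from
  the sorted multiset.
* Bootstrap SDs for sides with fewer than two contexts are reported missing
  (`NA`), not zero.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so each
experiment completes in minutes while leaving clear margins between planted
effects and thresholds: calibration on 2,000 i.i.d. sequences of length 200
(about 16,000 contexts per side per residue type); collagen and helix
recovery on 1,500 sequences; substitution experiments on 3,000 ancestors
(roughly 1,000 events for the planted S→P rule at its published-scale rate,
and above 5,000 events for the negative control).  The shuffle and bootstrap
inner loops are implemented in C++ (via Rcpp), which keeps a full 20-residue,
500-round calibration under a few minutes.

## Known limitations

* The per-side completeness rule discards sequence ends; for very short
  sequences and $W = 20$ this can exclude most occurrences.
* The shuffle null conditions on per-flank composition but not on
  higher-order structure within flanks (e.g. runs), so signals that survive
  within-flank permutation — pure compositional enrichment spread evenly over
  all offsets — are invisible to it by design.
* Substitution inference trusts the supplied ancestor/descendant pairs;
  reconstruction error in the ancestral sequences propagates directly into
  event contexts.
* With hundreds of substitution types tested at $\alpha = 0.001$ per offset,
  a handful of false context-dependence calls across all types is expected;
  no cross-type multiplicity correction is applied, matching the analysis
  this package operationalizes.
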