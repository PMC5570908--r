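---
title: "Methods: naive Bayes integration of heterogeneous evidence for E3-substrate prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: naive Bayes integration of heterogeneous evidence for E3-substrate prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

An E3-substrate interaction (ESI) is a *directional* pair: the E3 ubiquitin
ligase recognizes the substrate. `esibayes` scores a candidate pair by
naive Bayes integration of five evidence types, each calibrated as a
likelihood ratio (LR) against a gold standard of `T` positive (GSP) and `F`
negative (GSN) pairs:

    LR(f) = P(f | positive) / P(f | negative) = (TP_f / T) / (FP_f / F)

Within one evidence type, several features may fire (several matching
domain pairs, several motifs of the E3); the maximum LR of the type is
retained. Across types, conditional independence is assumed as-is — no
correlation correction — so the composite ratio is the product
`LR_comp = prod_i LR(f_i)`. Missing evidence contributes nothing to the
product (equivalently LR = 1): absence is treated as uninformative, since
the calibration data cannot distinguish "measured and absent" from
"unmeasurable". Posterior odds are `O_post = O_prior * LR_comp` with
`O_prior = T/F` estimated from the gold standard; ranking uses `LR_comp`
itself (equivalently the score below), not `O_post`.

The confidence score is a logistic normalization of the *base-10* logarithm,

    score = 1 / (1 + exp(-log10(LR_comp)))

which maps LR 1 to 0.5 and LR 195.79 to 0.908. The base matters: with a
natural logarithm the expression collapses to `LR/(1+LR)`, which would give
0.995 for LR 195.79 and could not reproduce the published worked value, so
base 10 is the package's definition.

### Evidence types

* **Ortholog transfer** (boolean). A pair is supported when a mouse ESI maps
  onto it through the ortholog map on both components. One-to-many maps are
  expanded. Support is monotone in the map: adding ortholog links never
  removes support.
* **Domain-pair enrichment (DER)** and **GO-pair enrichment (GER)**. For an
  ordered label pair, `ratio = Pr(l_e3:l_sub|GSP) / (Pr(l_e3|GSP) *
  Pr(l_sub|GSP))`, all three probabilities being fractions *of GSP pairs*
  (not of proteins): `Pr(l_e3|GSP)` is the fraction of positive pairs whose
  E3 carries the label. The statistic is therefore invariant to duplicating
  the gold standard, and 1 is the independence point. Label pairs are
  directional — recognition is asymmetric. GO uses all three aspects; the
  three root terms are dropped at load time (they hold for nearly every
  protein, so their ratios are ~1 and they only bloat the tables).
* **Network loops.** The candidate edge is added to the interaction
  network; `n3` counts common neighbors (triangles), `n4` counts
  quadrilaterals `e3 - x - y - substrate` with `x != y`; chords are allowed
  (standard cycle counting — a 4-cycle does not stop counting because one
  of its diagonals exists). Endpoints absent from the network give zero
  counts; the evidence type fires only when both endpoints are network
  nodes, so proteins wholly outside the network contribute no (pseudo-)
  negative loop evidence.
* **Recognition motifs.** Per E3, ungapped linear motifs of widths 3-5 are
  discovered in the sequences of its gold-standard substrates (foreground)
  against the sequences of its other network interactors (background) —
  interactors share the physical-contact context but not the recognition
  signal, which makes them the natural null. Discovery and scoring are
  described below. At prediction time, a motif fires when the candidate
  substrate's sequence contains a matching window; the feature value is the
  motif's score.

### Calibration

LR tables are binned. Defaults (configuration, not data): DER/GER on
log-spaced edges {0, 1, 2, 4, 8, 16, Inf}; `n3` in {0, 1, 2, 3, 4+}; `n4`
in {0, 1-2, 3-5, 6+}; motif score in {<2, 2-5, 5-10, >10}; homology boolean.
Bins are half-open `[lo, hi)`, cover the non-negative axis, and lookup is
total. Counts are smoothed with a pseudocount `s = 1`:
`LR = ((TP_f+s)/(T+s)) / ((FP_f+s)/(F+s))`; empty bins (no positives, no
negatives) are neutral at LR 1; ratios are capped to `[1e-3, 1e3]` so
log-odds stay finite. `T` and `F` always count the *whole* gold standard,
including pairs for which the evidence type never fired — the firing rate
itself is informative and enters through the denominators.

Enrichment evidence is calibrated by a repeated-split protocol: three
rounds, each using two thirds of the GSP to build the enrichment table and
the held-out third (feature: maximum matching ratio, 0 if none) plus the
whole GSN to accumulate TP/FP counts; counts are pooled across rounds
before the LR table is estimated, and the final enrichment table is rebuilt
on the full GSP. This prevents the table-building pairs from certifying
themselves. The network, homology, and motif types are calibrated directly
on the training gold standard; for motifs this is mildly optimistic within
a training set, but every evaluation in the package retrains from scratch
per fold, so reported performance is unaffected.

## Motif discovery: definition and rationale

The package's motif procedure is its own definition (the upstream
"modified motif-x" is not recoverable in detail); downstream code depends
only on the motif contract (pattern, width, score, counts).

A sequence *contains* a pattern when some window of the pattern's width
satisfies every fixed position. For each width `w` in {3, 4, 5}:

1. every exact `w`-mer present in at least `min_fg = 3` foreground
   sequences is a candidate seed, together with every variant of such a
   window with one *interior* position wildcarded (leading/trailing
   wildcards are equivalent to shorter motifs and are skipped) — the
   wildcard variants make degenerate motifs such as `PPxY` reachable;
2. each candidate is scored by the enrichment of presence-in-sequence
   counts (below); the top scorer wins, ties resolving to the
   lexicographically smallest pattern;
3. the winner is greedily relaxed: each position in turn is replaced by a
   wildcard if that increases the score;
4. if the final score exceeds the retention threshold (2), the motif is
   emitted and the foreground sequences it matches are removed before the
   search repeats.

A note on search structure: fixing one position at a time starting from the
all-wildcard pattern — the textbook greedy — cannot work on unaligned
full-length sequences, because any pattern with a single fixed residue
matches essentially every 300-residue sequence; the presence-count score is
flat at zero and a hill-climber never leaves the start. Seeding with fully
fixed windows (all positions at once) is the working limit of the same
greedy, and the relaxation pass restores the degenerate patterns.

**Score.** With `fg_hits` of `fg_total` foreground and `bg_hits` of
`bg_total` background sequences containing the pattern, the background
presence rate is add-one smoothed, `p = max((bg_hits+1)/(bg_total+1),
p_floor)` (default floor `1/(bg_total+1)`, so a zero background never
divides by zero), and

    motif_score = -log10( min(1, 20^w * P(X >= fg_hits | n = fg_total, p)) )

computed in log space. The `20^w` factor is a Bonferroni adjustment for the
candidate-pattern space of the width searched (the one-wildcard variants
add at most a further 15%, which is under 0.1 log10 units and is ignored).
The adjustment is what makes the fixed retention threshold of 2 meaningful
under selection: without it, a foreground *drawn from the background
distribution* reaches maximum scores of 3-6 merely by trying thousands of
candidates, and the threshold would pass noise constantly. With it,
measured null emission is 0-2.5% of runs across foreground/background size
regimes (the package's tests assert <= 5%).

**Sensitivity bound.** The adjustment costs sensitivity at small sample
sizes: with a ~25-sequence background, a width-3 motif needs roughly 8 of
11 foreground sequences to carry it; at a planting rate of 0.8 per
substrate, about one planted motif in six sits below the threshold in the
default synthetic world (measured 50/60 recovered over ten seeds). The
discoverability property is therefore asserted at full insertion — the
"sufficiently strong" regime — while the default world keeps the more
realistic partial insertion.

## The synthetic world

`generate_world()` builds a complete, seeded input set: gold-standard
positives and negatives, domain and GO annotations, an interaction network,
mouse ESIs with an ortholog map, and protein sequences — serializable to
exactly the file dialects the loaders read (`world_to_files()` /
`load_world_files()`).

What it emulates, and the defaults:

* **Scale** (`n_e3 = 30`, `n_proteins = 400`, `n_gsp = 200`,
  `n_gsn = 600`): small enough that a full fivefold CV with per-fold
  retraining runs in a few seconds, large enough for stable LR bins; the
  3:1 negative:positive ratio mirrors the curated-data situation.
* **E3 substrate counts** are Zipf-skewed (`e3_skew = 1`): real E3
  interactomes are hub-dominated. The skew is itself weakly predictive
  (hub E3s are enriched among positives but not among edge-sampled
  negatives), which is a property of the sampling design, not an artifact.
* **Enrichment signal**: each E3 carries one preferred planted
  (domain-on-E3, domain-on-substrate) pair — recognition specificity is the
  E3's own — and each substrate one preferred planted GO pair — functional
  context is the substrate's own. A positive pair receives its components'
  planted labels with probability `min(0.9, 0.15*(enrichment_strength-1))`,
  so `enrichment_strength = 1` is an exact null. Splitting the two
  namespaces this way gives both components of a pair an identity-linked
  signal, which is what the pair-input C1/C2/C3 partition probes.
* **Network signal** (`loop_boost = 0.4`): a boosted positive gains 1-2
  planted common neighbors. Negatives are sampled from E3-incident network
  edges — like a curated negative set, they are real physical interactions.
* **Motif signal**: the 6 E3s with the most substrates each get a planted
  width-3 motif, inserted into 80% of their substrates' sequences and into
  2% of all other sequences. Sequences are uniform over the 20-letter
  alphabet (length ~ N(300, 50), min 60): the binomial motif test needs a
  consistent background, not a realistic composition.
* **Ortholog coverage** (`ortholog_coverage = 0.3`): ~30% of positives are
  mirrored as mouse pairs under a bijective synthetic map (`m_` prefix),
  matching the ~30% ortholog support reported for curated human ESIs.

`null_world_config()` switches every planted channel off *and* sets
`e3_skew = 0`: the null world is the fully exchangeable design. Measured
cross-validated AUROC on null worlds is 0.48-0.53 (mean ~0.505 over ten
seeds).

What the generator does **not** emulate: scale-free network topology,
realistic sequence composition or homology between paralogs, annotation
incompleteness bias, database release quirks. A green test on a synthetic
world therefore establishes that the pipeline recovers the *kinds* of
signal it models, with correct null calibration — it does not establish the
published performance numbers, which depend on 2010-2014 releases of the
original databases and are out of scope.

## Evaluation protocol

* **Fivefold CV** stratifies positives and negatives independently (each
  fold preserves `T:F`); per fold, the *entire* model — enrichment tables,
  motifs, all LR tables — is refit on the other four folds; the held-out
  fold is scored; TP/FP counts are pooled across folds. A structural
  no-leakage audit (training fingerprints exclude every test pair) is part
  of the test suite.
* **TP/FP curve**: calls use `>=`-cutoff semantics (ties at the cutoff are
  calls, fixed for determinism); `tp/fp` is `Inf` when `fp = 0, tp > 0`
  and flagged `NaN` when both are zero. The default cutoff grid is all
  unique observed `LR_comp` values.
* **ROC/AUROC**: the AUROC is the Mann-Whitney rank statistic with ties at
  1/2; the 95% CI uses the Hanley-McNeil normal approximation (the original
  analysis delegated the CI to a statistics package without naming the
  method; Hanley-McNeil is the documented substitute here).
  No curve smoothing is applied anywhere.
* **Pair-input partition**: C1/C2/C3 by membership of the test pair's E3
  and substrate in the training pairs. In the package's own evaluations,
  membership is judged against the training *positives*: the negative set
  is constructed from E3-incident edges, so counting it would put every E3
  in every training fold and make C2/C3 vacuous.
* **Hold-out protocol** (`evaluate_holdout()`): train once on the full gold
  standard, score an independent later positive set against matched
  negatives — the analogue of testing on interactions curated after the
  training cutoff.
* **Fisher test**: one-tailed hypergeometric tail in the direction of the
  observed deviation, with degenerate rows/columns rejected.

## Numerical and design choices

* Identifiers are opaque, case-sensitive strings; no accession mapping is
  bundled. Self-pairs (autoubiquitination) are dropped at load with a
  message unless explicitly re-admitted (`allow_self = TRUE`).
* Date filtering is strict at the cutoff (`date < cutoff`; `after = TRUE`
  gives `date >= cutoff`).
* All stochastic steps (splits, folds, sampling, world generation) consume
  explicit integer seeds; per-fold training seeds are derived as
  `(seed*97 + fold) mod 2^31-1`. Identical seeds give byte-identical
  serialized worlds and model archives.
* The model archive is a directory of TSVs plus a JSON schema snapshot;
  doubles are written with 17 significant digits, so reload-and-rescore is
  bit-identical.
* Greedy/tie situations (motif seeds, scan output ordering) resolve
  lexicographically.

## Known limitations

* The motif search is presence/absence per sequence; it does not model
  positional preference relative to modification sites, multiple
  occurrences, or residue similarity groups beyond single wildcards.
* Conditional independence across evidence types is assumed, not tested;
  correlated evidence (e.g. domain and GO pairs derived from the same
  curation) inflates composite ratios.
* The Hanley-McNeil CI underestimates uncertainty for heavily tied scores;
  a DeLong implementation would be the next step if CI coverage mattered
  downstream.
* `proteome_scan()` streams per E3 and holds only one E3's candidate rows
  in memory, but the emitted result is collected in full; for
  genuinely proteome-scale output, write per-chunk via the CLI.
* Published reference values tied to specific 2010-2014 database releases
  (per-pair LRs, headline AUROCs, the 3856/10480 feature counts) are not
  reproducible from scratch and are treated as regression context, not
  targets.
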