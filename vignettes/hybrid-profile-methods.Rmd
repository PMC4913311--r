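---
title: "Hybrid sequence-structure profiles for fold recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid sequence-structure profiles for fold recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridfold)
```

## The model

A **hybrid profile** represents a protein of length $L$ as $L$ probability
columns over three alphabets:

* **AA track** — 20 amino-acid probabilities plus a separate gap probability
  $g_i$, estimated from a multiple sequence alignment of the protein's
  homologs;
* **PB track** — 16 probabilities over the Protein Blocks structural
  alphabet, a set of pentapeptide backbone conformations whose letters encode
  local structure far more finely than 3-state secondary structure (letter
  *m* is the repetitive helix core, *d* the strand core, the other fourteen
  are caps and transitions);
* **SA track** — 10 probabilities over solvent-accessibility classes,
  equal-width 10% bins of relative accessibility from fully buried (class 1)
  to fully exposed (class 10).

Template profiles take the structural tracks directly from coordinates (PB by
minimal angular distance to the 16 reference dihedral windows, SA by
Shrake–Rupley surface computation); query structural tracks are pluggable —
anything from an external predictor to the uniform distribution, which scores
neutrally (0 bits against any column under the track's own background).

Two columns are compared by the weighted, floored co-emission log-odds
$$S(i,j) \;=\; \sum_{c \in \{AA,PB,SA\}} w_c\,
\max\!\Big(S_{\min},\ \log_2 \sum_a \frac{q_c(i,a)\,t_c(j,a)}{f_c(a)}\Big),$$
and the alignment maximizes the summed column scores minus affine gap costs,
with a clustered-conservation bonus $S_{corr}=\sum_l S_l \sum_{j\le d} S_{l+j}$
added afterwards with weight $w_{corr}$. Gap columns contribute $S_l = 0$ to
the bonus.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| $w_{AA}, w_{PB}, w_{SA}$ | 1, 1, 0.5 | — | track weights; SA is the coarsest signal, hence down-weighted |
| $S_{\min}$ | −10 | bits | floor per track; a single zero co-emission must not veto a column |
| $\gamma_{open}, \gamma_{ext}$ | 3.0, 0.3 | bits | base affine gap costs, scaled per position by $(1-g_i)$ |
| $d$ | 4 | columns | correlation window |
| $w_{corr}$ | 0.1 | — | weight of $S_{corr}$ in the reported total |
| mode | gloloc | — | end-gap policy (see below) |
| $\beta$ | 10 | pseudo-observations | BLOSUM62 pseudocount admixture in AA columns |
| $\varepsilon$ | 0.05 | — | uniform smoothing of PB/SA frequency columns |
| probe, points | 1.4 Å, 960 | — | SASA probe radius and quadrature density |
| break | 2.5 Å | — | C–N distance beyond which the chain is split |

The three alignment modes differ only in end-gap policy: **global** consumes
both profiles entirely; **local** clamps at zero with free ends on both
sides; **gloloc** — the default, intended for domain databanks — consumes
every template column while the query's flanks are skipped free of charge.
We read that mode literally: unmatched template ends are paid for as gaps,
unmatched query ends are not, which makes a domain-sized template findable
inside a multi-domain query without rewarding template truncation.

## Profile construction choices

*Master-column convention.* Profiles live in the coordinates of a designated
master sequence: alignment columns where the master is gapped are dropped.
Search and rendering then work in query/template residue numbering directly.

*Sequence weighting and pseudocounts.* Observed AA frequencies use Henikoff
position-based weights (gap characters count as a symbol type in mixed
columns; all-gap columns are skipped). Columns are mixed with BLOSUM62
conditional-probability pseudocounts,
$p' = (N_{eff} f_{obs} + \beta f_{pc})/(N_{eff}+\beta)$ with
$N_{eff} = 1/\sum_i w_i^2$; the conditionals are reconstructed from the
half-bit BLOSUM62 scores via $P(a\mid b) \propto f(a)\,2^{S(a,b)/2}$. The gap
probability is stored beside the AA simplex, not inside it, and feeds only
the gap penalties, not the match score.

*Structural tracks.* PB/SA columns are smoothed member frequencies,
$(1-\varepsilon)f + \varepsilon/k$; columns with no defined evidence (e.g.
the two all-`Z` positions at each chain end) fall back to the uniform
distribution. Ten SA classes are equal-width bins — the simplest monotone
choice consistent with "from buried to exposed"; a quantile scheme would need
a reference composition that a toy-scale package cannot estimate credibly.
Relative accessibility is normalized by the Hubbard–Thornton (NACCESS)
per-residue maxima by default, with the Tien 2013 theoretical table as an
alternative (`max_asa_table()`).

## Numerical and degenerate-input conventions

* **PB assignment**: pentapeptide window of 8 dihedrals
  $(\psi_{i-2},\phi_{i-1},\psi_{i-1},\phi_i,\psi_i,\phi_{i+1},\psi_{i+1},\phi_{i+2})$;
  the first/last two residues and any window touching a missing atom or a
  chain break are `Z`. Equal RMSDA breaks to the alphabetically first
  letter. Assignment uses internal coordinates only and is therefore exactly
  rigid-body invariant.
* **SASA**: deterministic golden-section sphere lattice, so results are
  reproducible to the bit for a fixed point count; because the lattice is
  fixed in the laboratory frame, rotating a molecule changes results only at
  quadrature level (~0.1% at 960 points). Bondi van der Waals radii;
  hydrogens are ignored.
* **DP traceback**: ties prefer match over delete over insert, making
  alignments deterministic. Insert and delete runs may abut (each opens its
  own run), which is required for the optimum to range over *all* gapped
  alignments.
* **Empty alignments** report identity 0, coverage 0 and zero bounds rather
  than NA, so hit tables stay rectangular.
* **Quality bands**: z-score boundaries at −1, −2, −4 are assigned to the
  better (lower-energy) class; smoothing is a truncated centred mean (window
  15), i.e. no padding is invented at chain ends. The decoy generator
  permutes the residue labels; rescoring the permuted sequence is the
  caller's responsibility, since the scoring function (e.g. a statistical
  potential) is external to this package.
* **ROC**: tied scores collapse into one threshold step; pair weights
  multiply the query and template fold weights ($1/\text{fold size}$ each).
* **Randomness**: every generator takes an explicit integer seed, seeds a
  local RNG and restores the caller's state, so fixtures are pure functions
  of their seeds.

## What the synthetic generator does and does not emulate

`make_toy_databank()` builds folds as random Protein-Blocks segment plans
(segments of 3–7 residues), kept pairwise Hamming-separated by ≥30% of their
length, realizes them as ideal-geometry backbones (standard bond lengths and
angles, ω = 180°, side chains truncated at Cβ), and populates each fold with
members whose sequences diverge by a configurable mutation rate (default
30%, matching the held-out query divergence used in the tests).
`make_toy_query()` simulates a new fold member: mutated sequence on the fold
backbone, an MSA of further 30%-mutated rows (with 5% deletion openings),
and structural tracks taken from the held-out structure itself — i.e. an
idealized, error-free structural predictor.

This emulates the *geometry* of the fold-recognition problem — distinct local
structure between folds, conserved structure with divergent sequence within a
fold — but not its hard parts: real MSAs have phylogenetic correlation and
alignment errors; real PB/SA predictions from sequence are noisy; real folds
share sub-structures, and real databanks are five orders of magnitude larger.
Passing tests therefore demonstrate correctness of the machinery and the
expected qualitative behaviour (structure tracks dominate when sequences
diverge), not benchmark-level sensitivity on natural proteins.

Problem sizes throughout the tests and the acceptance script — 40-residue
toys, 5 folds × 2 members, 50 recovery trials, 200 oracle pairs of length
≤ 5 — were chosen as the smallest sizes at which every contract (full
pentapeptide windows, >30% fold separation, stable recovery statistics) is
exercised meaningfully.

## Known limitations

* The scoring function's absolute values are uncalibrated: no E-values or
  significance estimates are attached to hits, mirroring the raw-score
  design of the method this package implements.
* Query PB/SA tracks must come from outside (predictor or structure); the
  package deliberately does not ship a sequence-based structural predictor.
* The DP is quadratic time and memory in pure R; it is comfortable at domain
  scale (≤ 1000 positions, the supported query range) but not tuned for
  proteome-scale screening.
* mmCIF input, NMR multi-model ensembles and redundancy filtering of
  template sets are out of scope.
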