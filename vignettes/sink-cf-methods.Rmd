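---
title: "Sink-CF: model, design decisions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sink-CF: model, design decisions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinkcf)
```

## The inference problem

A death certificate carries a cause-of-death chain: the direct cause *A*
and up to three antecedents *B*, *C*, *D*, each an ICD-10 category code,
optionally with the duration the condition was present; a contributing
cause *E* may be recorded off the chain. The target of inference is the
*underlying* cause — the condition that initiated the progression. It is
usually the earliest antecedent, but not always: chains contain
"causality gaps" where the true initiating condition is a mid-chain
cause or even *E* (an aspiration event during a cancer illness, an
adverse drug reaction during an infection). Those records are exactly
where a purely statistical ranking errs, and they motivate the hybrid
design.

## The CDCP model

For cause $i$, the conditional death-cause proportion is
$\mathrm{cdcp}_i = P(S_i \mid T_i)$, where $S_i$ is the event that $i$ is
the underlying cause and $T_i$ that $i$ appears on the chain. It is
estimated per age-group $\times$ gender stratum from labeled records as

$$\widehat{\mathrm{cdcp}}_i \;=\; \log_2\!\Big(
  \frac{\text{death\_count}_i + s}{\text{occur\_count}_i + s}
  \times 10 \Big).$$

Choices embedded here:

* **Placement of the $\times 10$ factor.** The factor sits *inside* the
  logarithm, so a count ratio of $0.1$ scores $0$ and a ratio of $1$
  scores $\log_2 10 \approx 3.32$. Moving it outside would be a monotone
  rescaling: it cannot change which cause ranks first, only the geometry
  of the confidence threshold. We fix the inside reading and treat it as
  part of the score's definition.
* **Smoothing.** The additive pseudo-count $s$ (default 1) is applied to
  both numerator and denominator. It exists to make the estimator total:
  a (cause, stratum) cell with no observations has smoothed ratio 1 and
  scores $\log_2 10$ — deliberately *uninformative-high* rather than
  undefined. With both counts positive, $s \to 0$ recovers the raw
  ratio (a tested property).
* **Stratification.** Age groups are $[0,18)$, $[18,55)$, $[55,\infty)$.
  The group boundaries are half-open so every age maps to exactly one
  group; ages 18 and 55 go to the older group.
* **Occurrence weighting.** The sink and CF strategies use
  $\max(\widehat{\mathrm{cdcp}}_i, 0) \cdot w_i$ with the damped
  normalized frequency $w_i = \log(1 + n_i)/\log(1 + \max_j n_j)$, where
  $n_i$ is the cause's total occurrence count over all strata. The damping
  reflects how well-attested a cause is without annihilating rare causes
  the way raw relative frequency would; raw relative frequency
  (`"relative"`) and no weighting (`"none"`) remain selectable and are
  recorded in the model. Negative CDCP scores (ratio below $0.1$) are
  floored at zero before weighting so the weights act as non-negative
  importances, as the similarity formula requires.

The regional death-cause proportion $n_{ij}/N_j$ is carried as a
descriptive statistic (`rdcp()`); it plays no role in prediction.

## The sink strategy and its confidence gate

Each chain cause (including *E*) is scored with the weighted CDCP in the
record's own stratum; the top-scoring cause is the sink answer. The gate
is

$$C_{\mathrm{sink}} = \mathrm{round}\big(\sin(\tfrac{\pi}{2} n)\big)
  \in \{-1, 0, 1\},$$

with $n$ the number of chain causes *strictly* above the chain-mean
weighted CDCP. The trigonometric form is read as $\sin(\pi n / 2)$ — the
alternative reading $\sin(\pi / (2n))$ can never produce $-1$ and would
make the documented low-confidence outcomes unreachable, so it is ruled
out. Consequences of the strict comparison: an all-equal chain has
$n = 0$, confidence $0$, and is sent to CF — the desired behaviour when
the scores carry no signal. For $n = 1..5$ the gate yields
$1, 0, -1, 0, 1$; the values at $n = 4, 5$ follow the formula literally
(a documented quirk — we do not special-case them, and chains cap at five
causes including *E*).

Ties at the top of the ranking are broken toward the earliest antecedent
(role *D* over *C* over *B* over *A*, *E* last), consistent with the
underlying-cause concept of the condition that initiated the chain.

## The CF strategy

Similarity between two certificates is a weighted Jaccard index computed
after *dimension transposition*: positions carrying equal codes are
matched one-to-one across the two chains (a maximum multiset matching),
so the same disease at different chain positions still counts as shared.
Each matched pair contributes the arithmetic mean of the two records'
own-stratum weighted CDCP values to the intersection term; each unmatched
cause contributes its own-record weight to the union term. The mean is
the symmetric combination — the weight matrix lists one value per record
per dimension without prescribing their combination, and symmetry of the
similarity forces a symmetric choice. When every weight is zero the
unweighted Jaccard index is used so structural similarity still
discriminates.

Retrieval takes the top $k = 10$ cases with similarity $\ge 0.2$
(both configurable; the defaults are conventional neighborhood sizes for
sparse categorical case bases). Candidate generation goes through an
inverted code index — an accelerator only, since a case sharing no code
has similarity 0 and can never pass the threshold. The vote is
similarity-weighted over neighbor labels, restricted to labels present on
the query chain (the underlying cause must come from *A*–*E* in the usual
case); if no neighbor label is on the chain the vote is unrestricted.
Vote ties break by best single-neighbor similarity, then
lexicographically. We deliberately introduce no second numeric confidence
for CF: it abstains only when it has no neighbors, and the pipeline then
falls back to the sink answer, so an inference is always produced.

During evaluation a query present in the case library is excluded from
retrieval by id — standard cross-validation hygiene against
self-matching.

## The synthetic registry generator

Real multi-cause mortality registries are access-restricted, so the
package ships a generator that emulates the structure the method assumes:

* demographics: 5% / 30% / 65% of deaths in the three age groups, 52%
  male, three regions — a plausible age profile for an urban death
  registry;
* an underlying cause $U$ drawn per stratum (infections dominating child
  deaths, chronic disease old age, with a mild male tilt toward cancer
  and ischaemic deaths);
* a forward path $U \to \dots \to A$ through an *acyclic* 12-cause
  transition graph (chronic seeds progressing to terminal events), drawn
  chain length 1–4 (probabilities 0.10/0.30/0.35/0.25), truncated at
  terminal causes;
* with probability `p_E = 0.3`, a contributing cause drawn uniformly off
  the chain;
* with probability `p_offchain = 0.2`, the adjudicated label moved from
  $U$ uniformly to another chain cause or *E* — the causality-gap regime.
  One in five is our reading of "usually, but not always, the earliest
  antecedent"; the accuracy-lift property holds for any rate
  $\ge 0.15$;
* durations decaying geometrically from the earliest antecedent (years)
  to the direct cause (hours), with lognormal jitter; durations are
  parsed and preserved by the I/O layer but unused by inference.

The acyclic graph is a design decision with a payoff: every generable
(path, *E*) outcome can be enumerated exactly, so the ground-truth
conditional proportion $P(\text{label} = i \mid i \text{ on chain})$ is
available analytically (`true_cdcp_ratio()`), with an independent Monte
Carlo mode as a cross-check. Parameter-recovery tests compare fitted
count ratios against this oracle rather than against other sampled data.

What the generator does **not** emulate: ICD coding error and miscoded
chains, correlation between durations and cause identity, secular trends,
regional differences in cause structure (region only affects the RDCP
statistic), and multi-morbidity beyond a single linear path. Passing
tests therefore demonstrate correctness of the machinery and internal
consistency under the stated generative assumptions — not clinical
performance on real registries.

A labeled record whose underlying cause is absent from its own chain is
accepted and flagged rather than rejected (*E* or an unlisted cause can
legitimately be underlying). When counting, such a label is treated as
occurring for its own record — the adjudicated cause was operative even
if the certifier omitted it — which preserves the defining inequality
$\text{death\_count} \le \text{occur\_count}$ cellwise.

## Evaluation conventions

Cross-validation uses 17 folds (seeded shuffle, sizes within one), runs
all 17 rounds, and pools held-out predictions before computing metrics
(micro pooling); per-cause F1 comes from the pooled confusion counts.
Headline precision/recall are macro averages over causes that occur as
true labels, with precision 0 for a cause never predicted; micro values
are reported as diagnostics (in this single-label setting micro
precision, recall and accuracy coincide). The F1 distribution summaries
use strict thresholds — the fraction of causes with F1 $> 0.95$ and with
F1 $< 0.7$. The share of records answered directly by the sink route is
reported alongside; it equals the fraction of confidence-1 gates by
construction.

## Problem sizes

The statistical checks run at fixed sizes chosen to make sampling error
small relative to the assertions: parameter recovery on a 50,000-record
registry (cells with $\ge 200$ occurrences, absolute tolerance 0.05 —
roughly three binomial standard errors at the smallest admitted cell);
the end-to-end accuracy comparison on 20,000 records under 17-fold
cross-validation; similarity axioms on 1,000 random record pairs;
alignment verified exhaustively against a brute-force matcher for all
chain pairs of length $\le 3$ over a 5-code alphabet. All seeds are
fixed in the tests.

## Known limitations

* The CDCP estimator ranks causes marginally; it cannot express
  interactions between co-occurring causes on one chain.
* An unseen (cause, stratum) cell scores the maximal $\log_2 10$ by
  smoothing; in very small training sets this can promote rare chain
  members. The occurrence weight counteracts this (weight 0 for globally
  unseen causes) except under the `"none"` scheme.
* The gate's behaviour at $n = 4, 5$ (confidence 0, 1) is formula-faithful
  but arguably unintuitive; such chains are rare because $n$ counts
  strictly-above-mean scores among at most five.
* ICD-10 codes are validated syntactically (category pattern), not
  against the official tabular list.
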