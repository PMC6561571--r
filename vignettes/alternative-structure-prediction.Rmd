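---
title: "Predicting alternative RNA conformations from conditional base-pair probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting alternative RNA conformations from conditional base-pair probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaswitch)
```

## The problem

An RNA switch — a riboswitch being the canonical example — regulates gene
expression by toggling between two secondary-structure conformations.
One of them is usually well captured by ordinary free-energy minimisation;
the other, *alternative* conformation is metastable: it sits higher in the
computed energy landscape, often separated from the minimum-free-energy
(MFE) structure by many kilocalories, and plain folding never reports it.
`rnaswitch` implements two routes to that alternative structure:

* a **conditional-probability (CP)** pipeline that removes the
  neighbourhood of the MFE structure from the Boltzmann ensemble and folds
  an alternative structure around whatever stable stem remains, and
* a **sampling–clustering (SC)** baseline that samples the Boltzmann
  ensemble at several temperatures, splits the samples into two clusters
  under base-pair Hamming distance, and reports the lowest-energy member
  of the cluster that does not contain the MFE structure.

## The conditional-probability pipeline

Write $[i\cdot j]$ for a base pair between positions $i<j$. Two distances
drive the method: the base-pair distance
$\delta_{bb}([i\cdot j],[i'\cdot j']) = \max\{|i-i'|,\,|j-j'|\}$ and the
base-pair-to-structure distance
$\delta_{bs}([i\cdot j], S) = \min_{[i'\cdot j']\in S}\,\delta_{bb}$,
with the convention $\delta_{bs}(\cdot,\varnothing)=\infty$ so that the
neighbourhood of an open chain is empty.

Given a sequence, the pipeline (`predict_alternative()`):

1. computes the MFE structure $S_1^*$ at 37&nbsp;°C;
2. builds the exclusion set
   $E(\tau) = \{[i\cdot j] : \delta_{bs}([i\cdot j], S_1^*) \le \tau\}$
   (default $\tau = 5$); $E(0)$ is exactly the pair set of $S_1^*$, and
   $E(\tau)$ grows monotonically with $\tau$;
3. computes conditional base-pair probabilities
   $P^{\sim E}_{i,j} = \Pr\{[i\cdot j]\in S \mid [i'\cdot j']\notin S\;
   \forall [i'\cdot j']\in E\}$
   with a McCaskill-style inside–outside pass over the partition function
   restricted to structures avoiding $E$;
4. selects a **seed** $L^*$: by default, a longest bulge-tolerant stem in
   which every pair individually has conditional probability strictly
   above 0.5;
5. folds the alternative structure $S_2^*$ as the lowest-energy structure
   containing every seed pair (`constrained_mfe()` with forced pairs).

$E$ constrains only the probability computation, never the final fold, so
$S_2^*$ may incidentally contain excluded pairs; because excluded pairs
have conditional probability zero, the seed always avoids $E$ and
therefore $S_2^* \neq S_1^*$ whenever the seed is non-empty. An empty seed
is a reported outcome, not an error: it simply says that nothing in the
remaining landscape is individually probable, which is itself evidence
against a second stable state.

The seed length in base pairs, divided by $\log_{10}$ of the sequence
length, is the **normalised seed length**, the CP switch-classification
score; a 100-nt sequence with an 8-bp seed scores 4.0.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | 5 | radius (in positions) of the excluded neighbourhood |
| `temperature` | 37 °C | temperature of the conditional-probability computation; $S_1^*$ is always folded at 37 °C |
| `seed_kind` | `"stem"` | `"stem"`, `"single-bp"` (argmax pair), or `"all-above-threshold"` |
| `threshold` | 0.5 | strict (`>`) conditional-probability cutoff for seed pairs |
| `iteration` | 2 | at iteration $i>2$, $E$ is the union of the $\tau$-neighbourhoods of all previously predicted structures |

Design choices where the procedure is under-determined:

* **Stem steps.** Consecutive seed pairs must step by $(1,1)$ (stack),
  $(2,1)$ (5' bulge) or $(1,2)$ (3' bulge). $1{\times}1$ internal loops
  are *not* stem steps — a bulge means a single unpaired base on one side
  only. Ties in chain length are resolved by the larger sum of
  conditional probabilities, then by the smallest 5' start, so seed
  selection is deterministic.
* **Iteration semantics.** "Exclude previous predictions" is read as the
  union of the full $E(\tau)$ neighbourhoods of every structure predicted
  so far, not just their bare pair sets; with $\tau = 0$ the two readings
  coincide.
* **Exclusion membership is positional.** $E(\tau)$ is defined on index
  pairs regardless of sequence content; excluding a non-canonical index
  pair only suppresses a pair that could never form anyway.
* **Temperature.** The reference energy model has no enthalpy/entropy
  split, so temperature acts only through $RT$ in Boltzmann weights;
  structure energies, and hence constrained MFE folds, are
  temperature-independent, while probabilities and samples are not.

## The ensemble engine

The reference thermodynamic model (`energy_model()`) is additive: each
canonical pair contributes by class (GC/CG −3.0, AU/UA −2.0, GU/UG −1.0
kcal/mol), each stacked adjacent pair contributes −1.0 kcal/mol, hairpin
loops must enclose at least 3 unpaired bases, and loop-size, dangle and
multiloop terms are deliberately absent. The model preserves the
GC > AU > GU stability ordering and stacking cooperativity while keeping
the energy function exactly additive, so the $O(n^3)$ dynamic programme
and the exhaustive enumeration oracle (`enumerate_all_structures()`,
guarded to 22 nt) provably share one energy function; the test suite
checks the partition function, every base-pair probability, and the
constrained MFE against direct enumeration to $10^{-9}$ on hundreds of
random sequences, under empty, excluded, and forced constraint sets.
All parameters are user-settable (`--params`, `load_energy_params()`), and
any function mapping (sequence, structure) to an energy could be swapped
in behind the same interface — at the cost of re-deriving the recursions
it implies; nearest-neighbour parameter sets with loop entropies are out
of scope here.

Numerical choices: inside tables are rescaled per base by
$\sigma = \exp(-E_{\mathrm{MFE}}/(RT\,n))$, the standard guard against
partition-function overflow (log-partition values remain finite for any
length the package will realistically see); MFE traceback breaks energy
ties (tolerance $10^{-9}$) by preferring pairing over not pairing, then
the smallest 5' index, then the largest 3' index; stochastic traceback
(`sample_structures()`) draws from the same tables and takes a mandatory
integer seed, restoring the caller's RNG state afterwards.

The operational **melting temperature** (`estimate_melting_temperature()`)
is the smallest temperature in a 1-degree scan over [37, 100] °C at which
the ensemble's expected base-pair count drops to half of its 37 °C value,
100 °C if it never does, and 37 °C for sequences with no canonical pair.
This is an ensemble-probability notion, not a thermodynamic melting curve
— with temperature entering only through $RT$, nothing else is available,
and the SC temperature ladder only needs a plausible upper anchor.

## The sampling–clustering baseline

`run_sc_pipeline()` draws 300 structures at 37 °C and 150 at each of six
decile steps from 37 °C towards the melting temperature (1200 samples
total), represents each sample as a binary indicator vector over the
observed pairs — squared Euclidean distance between such vectors *is*
base-pair Hamming distance — and runs 2-means with ten seeded restarts.
The MFE structure's cluster is found by assigning its own indicator
vector to the nearest centroid ($S_1^*$ is not injected into the sample
set); the alternative prediction $\hat S_2^*$ is the lowest-energy member
of the other cluster, ties broken by first occurrence. The mean
silhouette under Hamming distance (singletons scoring zero) is the SC
classification score. A sample set with fewer than two distinct
structures is flagged degenerate rather than clustered.

## The synthetic test bed

`generate_bistable()` emits `a·l1·b·l2·c`: a core `b` over {G, U}, arms
`a` and `c` both equal to its reverse complement (hence over {A, C}), and
adenosine linkers. Helix A pairs `a` with `b`, helix B pairs `b` with
`c`; they share the core, so they are mutually exclusive, and their
pair-set distance from each other grows with core and linker length
(≥ 12 positions at the defaults), safely outside the default exclusion
radius.

The alphabet is the load-bearing choice. Arms over {A, C} have no
self-complementarity, so intra-arm and arm–arm pairs are impossible; a
G/C-only design does not have this property, and its MFE splits the core
between *both* arms, closed by stray arm–arm pairs — neither designed
helix then exists in the landscape. Similarly, the bias that orders the
two states cannot be a G·U wobble: a wobble in the alternative helix is
sliced out of the restricted ensemble by a register slide that trades the
wobble for a stronger pair and a linker partner. The bias therefore
knocks out one terminal helix-B pair outright, mutating its arm-`c` base
to A — a letter with no accessible partner — and only at an end whose
core base is a G with a U inward neighbour, so the freed core base cannot
re-pair and no iso-energetic shifted register survives. The stored
helix-B ground truth is the remaining contiguous helix of
`core_len − 1` pairs. As a final guard the generator redraws the core
until the designed stable state is *exactly* the MFE under the reference
model — the usual inverse-folding discipline of verifying a design
against the model it is meant for. `generate_monostable()` emits a single
G/C hairpin with no self-complementary run of 3 or more bases, the
negative class for classification.

What the generator deliberately does **not** emulate: real aptamer
architecture, ligand-binding energetics, multiloop junctions,
nearest-neighbour loop entropies, or the sequence heterogeneity of
genomic RNA. Passing the synthetic recovery tests therefore shows that
the pipeline implements its definitions correctly and recovers designed
two-state landscapes under the reference model; it does not certify
accuracy on natural riboswitches, which depends on the energy model.
One concrete transfer caveat the test bed itself exposes: on these
designs the SC silhouette score *anti*-discriminates (monostable hairpins
melt into two extremely clean clusters — folded and open — while genuine
two-state designs spread over three families), so the silhouette AUC on
synthetic cohorts is near 0 while the normalised-seed-length AUC is near
1. On natural sequences the silhouette ordering is an empirical claim
about real landscapes that synthetic data cannot arbitrate.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: oracle comparisons on 200 random sequences of 5–18 nt (the
enumeration oracle is exact there), sampling checks with 10,000 draws on
an 11-nt two-state sequence, and end-to-end cohorts of 50 bistable plus
20 + 20 classification designs of 32 and 20 nt. The engine itself is
$O(n^3)$ time / $O(n^2)$ space and is comfortable at a few hundred
nucleotides; the SC baseline at its default 1200 samples is the slow
path, which is exactly the asymmetry the CP method exists to exploit.

## Known limitations

* The reference energy model is intentionally minimal; absolute energies
  and melting temperatures are not comparable to nearest-neighbour
  implementations, only the machinery around them is.
* Pseudoknots are rejected in prediction and greedily resolved (5'-most
  pair kept, with a warning) when reading external CT references.
* `tau` is not auto-tuned; the default is a fixed convention exposed to
  the caller.
* Iterated prediction ($i > 2$) stops early, with the reason recorded,
  as soon as any round yields an empty seed.
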