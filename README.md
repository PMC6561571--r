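# rnaswitch

Prediction of the *alternative* (metastable) secondary structure of RNA
switches — riboswitch-like sequences that toggle between two
conformations — from conditional base-pair probabilities, together with a
sampling–clustering baseline, evaluation metrics, a synthetic
bistable-sequence generator with known ground truth, and an exhaustive
enumeration oracle that keeps the whole engine honest.

## The method

For a sequence with MFE structure S1\*, ordinary folding never reports the
second functional conformation of a switch. The conditional-probability
(CP) pipeline:

1. folds S1\* at 37 °C;
2. builds the exclusion set `E(τ) = {[i·j] : δ_bs([i·j], S1*) ≤ τ}`,
   where `δ_bs([i·j], S) = min over [i'·j'] in S of max(|i−i'|, |j−j'|)`
   (default τ = 5; `E(0)` is exactly the pair set of S1\*);
3. computes conditional base-pair probabilities
   `P~E_ij = Pr{[i·j] ∈ S | no pair of E in S}` by a McCaskill-style
   inside–outside pass over the constrained partition function
   `Z = Σ exp(−E(S)/RT)`;
4. selects a seed L\*: a longest bulge-tolerant stem whose every pair has
   `P~E > 0.5`;
5. reports S2\*, the lowest-energy structure containing L\*.

`#L* / log10(sequence length)` — the normalised seed length — doubles as
a switch-classification score. The sampling–clustering (SC) baseline
draws 1200 Boltzmann samples over a temperature ladder, 2-means-clusters
them under base-pair Hamming distance, and reports the lowest-energy
member of the non-MFE cluster plus the mean silhouette as its score.

All thermodynamics run on a minimal additive reference model (pair-class
plus stacking energies, exactly additive, fully user-configurable), which
lets an exhaustive enumeration oracle verify the partition function,
every probability, and every constrained fold to 1e−9 in the test suite.

## Worked example

```r
library(rnaswitch)

d <- generate_bistable(seed = 11)   # designed two-state sequence
d
#> Designed bistable sequence (32 nt, core 8 nt, linkers 4 nt, biased)
#> CCCCCCACAAAAGUGGGGGGAAAACCCCCCAA
#> helix A: ((((((((....))))))))............
#> helix B: .............(((((((....))))))).

predict_alternative(d$sequence)
#> Conditional-probability alternative-structure prediction (32 nt, tau = 5,
#>   T = 37 degC, stem seed, iteration 2)
#> S1* (-30 kcal/mol): ((((((((....))))))))............
#> S2* (-29 kcal/mol): (...........)(((((((....))))))).
#> Seed: 7 bp; normalized seed length 4.651
```

The MFE structure is the designed stable helix A (−30 kcal/mol). After
excluding its τ = 5 neighbourhood, the seven pairs of the designed
alternative helix B all exceed conditional probability 0.5, become the
stem seed, and the constrained fold around them recovers helix B at
−29 kcal/mol (plus one incidental exterior pair — the exclusion set
constrains only the probability computation, never the final fold). The
normalised seed length 7 / log10(32) = 4.65 is the classification score.

The SC baseline on the same sequence:

```r
run_sc_pipeline(d$sequence, seed = 42)
#> Sampling-clustering prediction (32 nt, 1200 samples)
#> S1* (-30 kcal/mol): ((((((((....))))))))............
#> S^2* (-29 kcal/mol): .(..........)(((((((....))))))).
#> Mean silhouette: 0.3169
```

## Command line

A thin front end over the same functions ships in
`inst/cli/rnaswitch.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rnaswitch.R",package="rnaswitch"))')" \
  predict --fasta switches.fa --out results/ --tau 5
# subcommands: predict | sc | classify | synth | oracle
```

Exit codes: 0 success, 1 usage error, 2 compute error; logs go to
stderr, results to files (JSON + dot-bracket + TSV).

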