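# decoyrank

Estimation of protein model accuracy (EMA) by **template injection**: a
candidate ("decoy") 3D structure for a target sequence is encoded as a
*sequence-free structural template* — a gap-token amino-acid row, the
Cβ–Cβ distance matrix, backbone torsions and atom masks — and handed to a
structure predictor together with the target sequence. Because the
template hides the decoy's amino-acid identity (side chains are stripped
to Cβ, glycines get a virtual Cβ, the one-hot sequence is all gap
tokens), the predictor's confidence in its output reflects how plausible
the *geometry* is for that sequence. Decoys are ranked by the composite
confidence score

```
composite = (mean pLDDT / 100) × pTM × TM(decoy, output)
```

where pLDDT and pTM are the predictor's per-residue and global confidence
estimates and the last factor corrects for the output structure drifting
away from the injected decoy.

The package is aimed at people studying decoy ranking and black-box uses
of structure predictors. It provides:

* **structure I/O** — a minimal single-chain PDB reader/writer for the
  backbone + Cβ data model, plus FASTA input;
* **metrics** — native TM-score, GDT_TS and (CA) lDDT implementations,
  Kabsch superposition, sequence recovery, Spearman correlation;
* **template featurization** — virtual Cβ construction (1.522 Å,
  110.4°, L-chirality), gap-token one-hot encoding, φ/ψ/ω torsions with
  terminus masking, serializable feature containers;
* **a predictor contract with mock implementations** — a geometry
  plausibility mock and a hidden-native oracle mock, so the whole
  protocol runs and is testable without network weights (a real
  AlphaFold-style adapter plugs in behind the same interface);
* **ranking statistics** — per-target Spearman, top-1 TM, top-1 GDT_TS
  loss, across-method Z-scores with the best-GDT > 0.4 target filter,
  percentile-bootstrap CIs;
* **two application protocols** — structure prediction by a
  generator–discriminator search, and fixed-backbone sequence design
  minimizing a distogram cross-entropy surrogate loss;
* **a synthetic decoy generator** — toy natives (helix, helix-hairpin,
  random compact) and graded noise ladders with known true quality.

## Worked example

```r
library(decoyrank)

# a toy native and a ladder of 15 decoys at three noise levels
spec   <- decoy_ladder_spec(native_length = 24, topology = "helix_hairpin",
                            sigmas = c(0.25, 1, 3), n_per_sigma = 5, seed = 9)
ladder <- make_decoy_ladder(spec)

# score every decoy with the hidden-native oracle predictor
om  <- oracle_mock(ladder$native)
rec <- score_decoy_set(om, ladder$native$sequence, ladder$decoys,
                       native = ladder$native)
head(rec[, c("decoy_id", "composite", "plddt_mean", "ptm", "true_tm")], 3)
#>   decoy_id composite plddt_mean       ptm   true_tm
#> 1  s01_001 0.8882182   99.46030 0.8930379 0.8930379
#> 2  s01_002 0.8186587   98.17036 0.8339164 0.8339164
#> 3  s01_003 0.7937248   94.98249 0.8356538 0.8356538

evaluate_target(rec, "toy")
#>   target_id spearman_composite_vs_tm top1_decoy_id top1_true_tm top1_gdt_loss
#> 1       toy                0.9642857       s01_001    0.8930379             0
#>   n_decoys
#> 1       15
```

The composite tracks the true TM-score closely (Spearman 0.964 here) and
the top-ranked decoy is also the best one by GDT_TS (top-1 loss 0). With the geometry mock instead of the oracle, ranking relies only on
local backbone plausibility and is noisier but still strongly ordered by
noise level.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/decoyrank.R make-decoys --out work --length 24 \
        --sigmas 0.25,1,3 --n-per-sigma 5 --seed 9
Rscript inst/cli/decoyrank.R score --target work/target.fasta \
        --decoys work/decoys --native work/native.pdb \
        --predictor oracle-mock --out work/scores.tsv
Rscript inst/cli/decoyrank.R evaluate --scores work/scores.tsv \
        --out work/report.json
```

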