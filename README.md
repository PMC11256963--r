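# fcadti

Fragment-based drug–target interaction (DTI) prediction in pure R.

Screening which small molecules bind which proteins is a bottleneck of
early drug discovery; sequence-based DTI models predict the interaction
directly from the drug's SMILES string and the protein's amino-acid
sequence, with no structures or docking.  `fcadti` implements a
fragment-oriented classifier for this task, aimed at computational
chemists and method developers who want an auditable, dependency-light
reference implementation:

* **Branch-chain mining** splits a SMILES string into branch chains
  (outermost parenthesised spans), common substructures (benzene, oxygen
  chain `COC`, carboxyl `C(=O)O`; user-editable pattern table) and short
  synthetic fragments, conserving every atom token exactly once.
* **Category-fragment mining** maps amino acids onto eight
  physicochemical categories `A`–`H` and partitions the category string
  into k-grams (default k = 3).
* Both fragment sequences are embedded and passed through parallel
  1-D CNN blocks (conv → batch-norm → ELU, three layers each), fused by a
  **shared-weight multihead cross-attention** module
  (Q<sub>D</sub> = D<sub>CNN</sub>W<sub>Q</sub>,
  K<sub>D</sub>,V<sub>D</sub> from P<sub>CNN</sub>, and the mirrored
  protein direction re-using the *same* W<sub>Q</sub>, W<sub>K</sub>,
  W<sub>V</sub>), mixed residually
  (D<sub>f</sub> = ½M<sub>D</sub> + ½D<sub>CNN</sub>), max-pooled,
  concatenated and classified by a small FCN trained with binary
  cross-entropy.
* The network, its backpropagation and AdamW are hand-implemented in base
  R matrix algebra — no deep-learning runtime; gradients are
  finite-difference-verified in the test suite.
* A synthetic generator plants a learnable motif rule with a closed-form
  Bayes-optimal AUC, so the whole pipeline is testable offline.

## Worked example

Fragment a drug and a protein:

```r
library(fcadti)
fragment_drug("CC(=O)Oc1ccccc1")          # aspirin
#> <fragment_sequence> (unnamed): 3 fragments
#>       text               ftype
#> 1 c1ccccc1 common_substructure
#> 2      CCO           synthetic
#> 3       =O        branch_chain
fragment_protein("GAVRKD")$fragments$text
#> [1] "AAA" "EEF"
```

The benzene ring was lifted out of the main chain, the acetyl `=O` came
from the parenthesised branch, and the residual main-chain atoms `CCO`
form one synthetic fragment; the protein was mapped to categories
(`G,A,V → A`, `R,K → E`, `D → F`) and split into 3-grams.

Train and evaluate on the synthetic planted-rule benchmark (about two
minutes on one CPU):

```r
data  <- generate_dataset(400, planted_rule(), seed = 1)
pairs <- data[, c("smiles", "sequence", "label")]
sp    <- split_dataset(pairs, ratio = 0.8, seed = 1)    # stratified 8:2
model <- fit_dti(sp$train, small_model_config(), small_train_config(seed = 1))
evaluate_dti(model, sp$test)
#> AUC 0.9371  AUPR 0.9602  accuracy 0.7375  precision 1.0000  recall 0.5116
bayes_auc()                                              # rule ceiling
#> [1] 0.95
```

The held-out AUC of 0.937 is 99.9% of what the motif-presence oracle
itself scores on this 80-pair test split (0.938): the model has recovered
the planted rule essentially optimally; the remaining gap to the nominal
0.95 ceiling is the sampling noise of an 80-pair test set.  Accuracy and
recall are lower because the 0.5 threshold is not calibrated to the
label-noise rates — ranking metrics are the primary endpoint here.

Cross-validation, ablations and a CLI are available:

```r
cross_validate_dti(pairs, folds = 5)                    # 5-fold CV
fit_dti(sp$train, small_model_config(ablation = "no_cross_attention"), ...)
```

```sh
Rscript inst/cli/fcadti fragment --drug "CC(=O)Oc1ccccc1"
Rscript inst/cli/fcadti synth --n 400 --seed 11 --out data.tsv
Rscript inst/cli/fcadti train --data data.tsv --out run/
Rscript inst/cli/fcadti predict --checkpoint run/checkpoint.json \
    --drug "CC(=O)O" --protein MKTAYIAK
```

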