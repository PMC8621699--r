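# lpipred

Sequence-based prediction of lncRNA–protein interactions in R.

Long noncoding RNAs (lncRNAs, ≥ 200 nt) act largely through physical
interactions with proteins, and testing candidate pairs experimentally is
slow and expensive. `lpipred` is for computational biologists who want a
self-contained, tested implementation of a multi-representation
interaction classifier: it takes lncRNA and protein FASTA files plus a
pair table, builds reliable negatives, and scores pairs with a four-branch
convolutional model.

## What is inside

A pair `(r, p)` is described four ways, and each description feeds one
branch of the classifier:

* **GloCNN** — fixed-length one-hot matrices. RNA uses rows A/C/G/U;
  proteins are first reduced to the 7 conjoint-triad groups
  (R1={A,G,V}, R2={I,L,F,P}, R3={Y,M,T,S}, R4={H,N,Q,W}, R5={R,K},
  R6={D,E}, R7={C}). Unknown/padding columns are uniform (1/4 or 1/7).
* **LocCNN** — overlapping windows of the sequence, each window a channel.
* **FC** — hand-designed vectors `a1 = [RED, DNC, 3mer]` (118-dim) and
  `a2 = [AAC, 3mer, 4mer]` (2764-dim), where RED is a coding-potential
  descriptor block (ORF statistics, Fickett score, hexamer usage, pI,
  GRAVY, instability index, nucleotide CTD).
* **SS** — structure tracks (RNA dot-bracket from a built-in Nussinov
  folder plus contact propensities; five protein physicochemical scales),
  each compressed to its first 10 cosine-series terms
  `X'_k = (2/L) Σ_n X_n cos[(π/L)(n+½)(k+½)]`, giving fixed 30- and
  50-dim vectors for any sequence length.

Negatives are built by similarity-ranked sampling: candidates are ranked
by global-alignment similarity to an lncRNA's known partners, one half of
the lncRNAs draws from the most-dissimilar 20%, the other from the
remaining 80%, one negative per positive pair.

The neural engine (conv/batch-norm/max-pool/dense/Adam) and the random
forest behind the feature-ranking harness are implemented in the package
(R + compiled kernels) — no external deep-learning framework is required.
A seeded synthetic-data generator plants a recoverable motif/composition
signal so the whole pipeline is testable offline.

## Worked example

```r
library(lpipred)

toy <- worked_toy()                      # 4 lncRNAs, 5 proteins, 6 positives
sim <- protein_similarity_matrix(toy$prot)
neg <- build_negatives(toy$positives, sim,
                       negative_sampling_config(0.20, seed = 42))
neg
#>   lnc_id prot_id label
#> 1  lncT1  protTB     0
#> 2  lncT2  protTD     0
#> 3  lncT2  protTE     0
#> 4  lncT3  protTE     0
#> 5  lncT3  protTB     0
#> 6  lncT4  protTB     0

ds <- assemble_dataset(toy$positives, neg, toy$registry, "toy")
ds
#> <interaction_dataset> toy: 12 pairs (6 +, 6 -), 9 sequences

fold_rna("GGGAAACCC")                    # built-in base-pair maximizer
#> [1] "(((...)))"

hv <- assemble_handcrafted(toy$lnc[[1]]$seq, toy$prot[[1]]$seq)
c(length(hv$a1), length(hv$a2))
#> [1]  118 2764
sv <- assemble_structure(toy$lnc[[1]]$seq, toy$prot[[1]]$seq)
c(length(sv$b1), length(sv$b2))
#> [1] 30 50
```

Each negative pairs an lncRNA with a protein drawn from the dissimilar
(bottom-20%) or moderately-similar (80%) part of its candidate ranking;
`a1`/`a2` and `b1`/`b2` are the fixed-width branch inputs.

End to end on synthetic data with a planted signal (`effect = 0.9` means
90% of labels are determined by the signal, the rest are coin flips):

```r
spec <- synthetic_spec(n_lnc = 60, n_prot = 30, rna_len_range = c(200, 400),
                       prot_len_range = c(50, 150), n_pairs = 600,
                       effect = 0.9, seed = 1)
g <- generate(spec)
res <- run_pipeline(g$dataset,
                    model_config(epochs = 10, patience = 3, seed = 1),
                    seed = 1)
res$report
#> <metrics_report> acc=0.8889  mcc=0.7904  f1=0.8980  sn=0.9778  sp=0.8000
#>                  ppv=0.8302  auroc=0.9427  auprc=0.9439
```

The report is the test-split evaluation: accuracy, Matthews correlation,
F1, sensitivity, specificity, precision, and the areas under the ROC and
precision–recall curves. With 90% label fidelity the achievable AUROC is
about 0.95; 0.94 means the planted signal is essentially fully recovered.

## Command line

```sh
Rscript inst/cli/lpipred.R fixtures --n-lnc 60 --n-prot 30 --n-pairs 600 \
        --rna-len 200,400 --prot-len 50,150 --seed 1 --out fx/
Rscript inst/cli/lpipred.R make-negatives --pos fx/pairs.tsv \
        --prot fx/prot.fa --low-frac 0.2 --seed 42 --out neg.tsv
Rscript inst/cli/lpipred.R train --lnc fx/lnc.fa --prot fx/prot.fa \
        --pairs fx/pairs.tsv --seed 1 --out model.rds
Rscript inst/cli/lpipred.R predict --model model.rds --lnc fx/lnc.fa \
        --prot fx/prot.fa --pairs fx/pairs.tsv --out scores.tsv
Rscript inst/cli/lpipred.R evaluate --scores scores.tsv \
        --labels fx/pairs.tsv --out report.json
```

Pair tables are TSV `lnc_id<TAB>prot_id<TAB>label`; propensity scales are
TSV `symbol<TAB>value` with a `#source:` header.

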