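# ddimamba

Cross-modal classification of drug-drug interaction (DDI) sentences into
the five DDIExtraction2013 relation types — `Advice`, `Mechanism`,
`Effect`, `Int`, `Negative` — from multimodal drug-pair input: the mention
sentence, each drug's description text, its SMILES string and its
molecular graph.

The package is aimed at biomedical NLP / cheminformatics researchers who
want a fully inspectable, CPU-trainable implementation of a selective
state-space (Mamba) fusion classifier, together with the evaluation
protocol of the task (macro precision/recall/F1, rank AUC, stratified
5-fold cross-validation) and a seeded synthetic-corpus generator that
makes every stage testable without the benchmark corpus.

## Model

For a sentence s with drugs A and B, per-drug channel embeddings are
concatenated position-wise,

    E_dA = [E_w ; E_qA ; E_gA ; E_sA],    E_dB = [E_w ; E_qB ; E_gB ; E_sB]

(word table E_w, mean-pooled description vector E_q, Weisfeiler-Lehman
graph fingerprint E_g, character-convolution SMILES encoding E_s), reduced
by PCA, and encoded per drug by a Mamba block — a selective SSM with
zero-order-hold discretization

    Abar = exp(delta A),   Bbar = (exp(delta A) - 1)/A * B,
    x_t = Abar_t x_{t-1} + Bbar_t u_t,   y_t = C_t x_t + D u_t,

whose step size delta_t and matrices B_t, C_t are functions of the input
(the "selective" part). The two drugs' sequences are fused by **partial
cross-attention**: the first channel halves attend across the pair,

    Z_A = softmax( (Dr_A^1 W_Q)(Dr_B^1 W_K)^T / sqrt(d_k) ) Dr_B^1 W_V,

while the second halves pass through unchanged; a second Mamba block plus
a residual gives Er' = Mamba([Z, Dr^2]) + Dr. A width-3 convolution, ReLU
and a second partial cross-attention refine the fused sequences; max
pooling over positions and concatenation give the pair vector, and
one-vs-rest sigmoid heads with class-weighted binary cross-entropy produce
the per-type probabilities. Training handles the task's severe class
imbalance with SMOTE oversampling of the rarest positive class (to the
second-rarest count, interpolated in PCA feature space) and
inverse-frequency class weights. All gradients are hand-written and
verified against finite differences; the scan kernel is compiled (Rcpp)
and bound by tests to a sequential reference implementation.

## Worked example

Generate a seeded synthetic corpus with a planted class signal, train at a
reduced diagnostic scale, and evaluate on held-out samples:

```r
library(ddimamba)

corpus <- gen_pair_dataset(
  synth_config(n_samples = 400, seed = 42, signal_strength = 0.9))
table(vapply(corpus, `[[`, character(1), "label"))
#>    Advice    Effect       Int Mechanism  Negative
#>        27        56        11        39       267

train <- corpus[1:320]; test <- corpus[321:400]
cfg <- model_config(d_w = 64, d_q = 32, d_g = 32, d_s = 64, d_model = 32,
                    pca_dim = 64, iterations = 400, dropout_block = 0,
                    dropout_head = 0, seed = 7)
model <- train_model(train, cfg)
evaluate_model(model, test)
#> Metrics over 80 samples
#>       class precision recall    f1
#> 1    Advice     100.0  100.0 100.0
#> 2 Mechanism     100.0   83.3  90.9
#> 3    Effect      85.7   85.7  85.7
#> 4       Int     100.0   50.0  66.7
#> 5  Negative      94.5   98.1  96.3
#> macro P 96.1%  macro R 83.4%  F1 89.3%  macro-F1 87.9%  AUC 98.3%
```

The class distribution mirrors the benchmark's imbalance (two thirds
`Negative`, `Int` rare), and the numbers show exactly what a
signal-recovery run measures: the model has learned the planted motifs
(high precision everywhere, AUC 98.3%), while the rare `Int` class — 11
samples total, of which ~10% carry no motif by construction — loses recall
first. Larger corpora and more steps close that gap; the package's
acceptance run (n = 2000, 800 steps) reaches held-out macro-F1 above 0.90.

Drug-pair corpora are read and written as JSONL
(`read_pair_samples()` / `write_pair_samples()`), one object per line:

```json
{"id": "s00001", "sentence": "...", "drug_a": {"id": "...", "smiles":
"CCO", "description": "..."}, "drug_b": {...}, "label": "Effect"}
```

A thin command-line front end over the same functions is installed at
`inst/cli/ddimamba` (subcommands `synth`, `train`, `predict`, `eval`,
`cv`).

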