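# gofunnet

Adaptive dual-graph convolutional networks for Gene Ontology (GO) protein
function prediction, in pure R.

## What it is for

Assigning GO terms to proteins is a multi-label classification problem
over a structured label space: terms form a rooted DAG (`is_a` /
`part_of` edges, true-path rule), and proteins are related through
sequence similarity. gofunnet frames the task as

    Y = M(X, G_F, G_P)

where `X` are per-residue sequence embeddings, `G_F` is a *function
graph* (the GO hierarchy restricted to annotation-frequency-selected
terms, adjacency `A_F` with child rows), and `G_P` is a *protein graph*
(a sequence-similarity network: `A_P[j,j'] = 1` iff the best BLAST
E-value between j and j' is below a threshold, default `1e-10`).

The model is *adaptive*: inside each graph block a learned sparse top-k
attention matrix (per row, the `k = max(1, floor(N/4))` largest bilinear
correlation scores, softmax-normalized) is diffused alongside the fixed
prior over `N = 2` steps,

    Z_F = sum_n A_F^n X W_n1 + Ftilde^n X W_n2            (function side)
    Z_P = sum_n R_f^n X U_n1 + R_b^n X U_n2 + Ptilde^n X U_n3   (protein side)

with `R_f`, `R_b` the row-normalized forward/backward transition matrices
of the SSN (self-loops included). The priors are never modified by
training — they are checksummed at assembly and verified afterwards.
Sequences are encoded by a pluggable frozen embedder (a protein language
model in production, a deterministic stub in tests) refined by 4 stacked
dilated causal convolutions (kernel width 3, dilations 1/2/4/8, receptive
fields 3/7/15/31 residues) with gated multi-scale and global/local
fusion. Training minimizes BCE-with-logits under Adam; evaluation is
protein-centric CAFA style (Fmax over a 0.01-step threshold sweep,
rank-based AUC).

Because the R stack here has no neural-network framework, the package
ships a small reverse-mode autodiff engine (`R/autodiff.R`); analytic
gradients are verified against finite differences in the test suite.

## Worked example

Twenty synthetic proteins, a 10-term toy ontology, seed 42:

```r
library(gofunnet)
cfg   <- fixture_config(n_terms = 10, n_proteins = 20, seed = 42)
paths <- cmd_fixtures(file.path(tempdir(), "demo"), cfg)

ontology <- parse_obo(paths$obo)
proteome <- read_fasta(paths$fasta)
ontology
#> ontology_graph: 10 terms, 10 edges ( 9 is_a / 1 part_of )

evalues <- read_blast_tabular(paths$blast, names(proteome))
a_p <- build_ssn(evalues, threshold = 1e-10, names(proteome))  # 48 edges
a_f <- build_function_adjacency(ontology, ontology$terms)      # 10 edges

labels  <- generate_labels(ontology, cfg$n_proteins, cfg)
config  <- model_config(channels = 8, embed_dim = 16, batch_size = 8,
                        lr = 0.01, seed = 42)
dataset <- build_dataset(proteome, labels, make_stub_embedder(16))
model   <- assemble_model(config, a_f, diffusion_matrices(a_p))
model
#> gofunnet_model: 10 terms x 20 proteins; 4346 parameters; 2 layer(s), N = 2 diffusion steps

model  <- train_model(model, dataset)
round(model$history[c(1, 50)], 4)
#> [1] 1.3896 0.0919

scores <- predict_scores(model, dataset)
report <- evaluate_predictions(scores, labels)
sprintf("training Fmax = %.3f at h = %.2f, AUC = %.3f",
        report$fmax, report$threshold, report$auc)
#> "training Fmax = 1.000 at h = 0.34, AUC = 1.000"

identical(prior_checksums(model), model$prior_checksums)
#> TRUE
```

The loss falls from 1.39 to 0.09 over 50 epochs and the model memorizes
the toy fixture perfectly (training Fmax 1.0) — a capacity check, not a
biological claim; the fixture's labels carry no real sequence signal.
The last line is the package's structural-preservation guarantee: the
graph priors are bit-identical after training.

A command-line entry point wraps the same pipeline
(`inst/cli/gofunnet.R`): `fixtures`, `build-graphs`, `train`, `predict`,
`evaluate`, with exit codes 0 / 2 (config) / 3 (data) / 4 (runtime) and a
JSON run manifest per stage.

## Layout

- `R/` — autodiff core, fixtures, ontology, protein graph, sequence
  block, attention, graph convolution, model/training, metrics, CLI
- `tests/testthat/` — unit + property tests, independent brute-force
  oracles (`helper-oracles.R`), acceptance criteria
  (`test-acceptance.R`)
- `vignettes/adaptive-dual-graph-function-prediction.Rmd` — the methods
  vignette: model assumptions, every open design decision and why, what
  the synthetic fixtures do and do not establish
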