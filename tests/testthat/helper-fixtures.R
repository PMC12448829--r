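# Shared toy objects, built once per test run.

toy_protein_ids_for_test <- function(n) sprintf("P%05d", seq_len(n))

.toy_cache <- new.env(parent = emptyenv())

# the deterministic reference fixture: 20 proteins, 10 terms, seed 42
toy_world <- function() {
  if (!is.null(.toy_cache$world)) return(.toy_cache$world)
  cfg <- fixture_config(n_terms = 10, n_proteins = 20, seed = 42)
  ont <- generate_toy_ontology(cfg)
  prot <- generate_toy_proteome(cfg)
  ev <- generate_evalue_table(cfg)
  lab <- generate_labels(ont, cfg$n_proteins, cfg)
  a_f <- build_function_adjacency(ont, ont$terms)
  a_p <- build_ssn(ev, 1e-10, names(prot))
  diff <- diffusion_matrices(a_p)
  .toy_cache$world <- list(cfg = cfg, ont = ont, prot = prot, ev = ev,
                           lab = lab, a_f = a_f, a_p = a_p, diff = diff)
  .toy_cache$world
}

# embeddings + dataset at stub width 16
toy_dataset <- function() {
  if (!is.null(.toy_cache$dataset)) return(.toy_cache$dataset)
  w <- toy_world()
  .toy_cache$dataset <- build_dataset(w$prot, w$lab, make_stub_embedder(16))
  .toy_cache$dataset
}

toy_overfit_config <- function(epochs = 50L) {
  # capacity preset for the 20-protein fixture: lr raised to 0.01 because
  # 50 epochs of batch-8 steps give only ~150 optimizer updates
  model_config(channels = 8L, embed_dim = 16L, epochs = epochs,
               batch_size = 8L, lr = 0.01, seed = 42L)
}

# 50-epoch overfit run, trained once and reused by the acceptance tests
toy_trained <- function() {
  if (!is.null(.toy_cache$trained)) return(.toy_cache$trained)
  w <- toy_world()
  model <- assemble_model(toy_overfit_config(), w$a_f, w$diff)
  .toy_cache$trained <- train_model(model, toy_dataset())
  .toy_cache$trained
}

# a micro model for gradient checks: 5 proteins, 4 terms
micro_setup <- function(seed = 7L) {
  cfg <- fixture_config(n_terms = 4, n_proteins = 5,
                        seq_len_range = c(8L, 12L), edge_density = 0.6,
                        seed = seed)
  ont <- generate_toy_ontology(cfg)
  prot <- generate_toy_proteome(cfg)
  lab <- generate_labels(ont, 5, cfg)
  a_f <- build_function_adjacency(ont, ont$terms)
  diff <- diffusion_matrices(build_ssn(generate_evalue_table(cfg), 1e-5,
                                       names(prot)))
  mc <- model_config(channels = 3L, embed_dim = 6L, steps = 2L,
                     layers = 1L, dropout = 0, epochs = 2L,
                     batch_size = 5L, seed = seed)
  ds <- build_dataset(prot, lab, make_stub_embedder(6))
  list(model = assemble_model(mc, a_f, diff), dataset = ds, labels = lab)
}

random_hidden_state <- function(nf, np, C) {
  array(stats::rnorm(nf * np * C), c(nf, np, C))
}
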