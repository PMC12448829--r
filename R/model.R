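#' Model assembly, training and prediction
#'
#' The full network composes the sequence-processing block with L stacked
#' adaptive graph-convolution layers.  Per-protein pooled sequence features
#' are tiled along the function axis and a learned per-function embedding
#' is added, giving the initial hidden tensor X0 (N_F x N_P x C).  Each
#' layer recomputes the sparse protein and function attention from the
#' current tensor, applies the bidirectional protein diffusion block and
#' then the unidirectional function diffusion block (ReLU + dropout in
#' between), and a linear head maps channels to one logit per
#' (protein, term).  Training minimizes binary cross-entropy with logits
#' under Adam; the prior adjacencies are never touched by training.
#'
#' @name model_training
NULL

stop_runtime <- function(...) {
  stop(structure(class = c("gofunnet_runtime_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Model configuration
#'
#' Defaults follow the reference training setup: 2 diffusion steps,
#' 50 epochs, batch size 128, learning rate 0.001, dropout 0.2, seed 42,
#' kernel width 3 with dilations 1, 2, 4, 8, sparsity ratio 1/4 and an
#' SSN E-value threshold of 1e-10.  `embed_dim` is the embedder output
#' width (1280 for the production language model; tests use a narrower
#' stub), `channels` the internal width all blocks work at.
#'
#' @param channels working channel width C
#' @param embed_dim embedder output width K
#' @param steps diffusion steps N
#' @param layers number of stacked attention + convolution layers L
#' @param dropout feature dropout rate in \[0, 1)
#' @param lr learning rate
#' @param batch_size proteins whose loss terms are accumulated per
#'   optimizer step (the graph itself is always global)
#' @param epochs training epochs
#' @param seed integer seed for initialization, shuffling and dropout
#' @param sparsity_mode `"fixed"` (k from `sparsity_ratio`) or
#'   `"learnable"` (a bounded scalar lambda, updated only through retained
#'   entries)
#' @param sparsity_ratio top-k retention ratio
#' @param evalue_threshold SSN E-value cutoff E
#' @param kernel_width DCC taps per kernel
#' @param dilations DCC dilation schedule (one per stacked DCC layer)
#' @param block_order order of the two graph blocks within a layer
#' @param pooling residue-to-protein pooling, `"mean"` or `"max"`
#' @param normalize_prior row-normalize the function adjacency before
#'   taking diffusion powers
#' @param residual wrap each graph block in a residual connection
#'   (`x + relu(block(x))`); all diffusion operators are row-stochastic
#'   smoothers, so without the identity path stacked blocks over-smooth
#'   and node-specific signal is lost
#' @param standardize z-score the pooled per-protein features across
#'   proteins before they enter the graph layers (mean-pooled embeddings
#'   have small between-protein variance)
#' @return a `model_config` list
#' @export
model_config <- function(channels = 16L, embed_dim = 32L, steps = 2L,
                         layers = 2L, dropout = 0.2, lr = 0.001,
                         batch_size = 128L, epochs = 50L, seed = 42L,
                         sparsity_mode = c("fixed", "learnable"),
                         sparsity_ratio = 0.25, evalue_threshold = 1e-10,
                         kernel_width = 3L, dilations = c(1L, 2L, 4L, 8L),
                         block_order = c("protein", "function"),
                         pooling = c("mean", "max"),
                         normalize_prior = TRUE, residual = TRUE,
                         standardize = TRUE) {
  sparsity_mode <- match.arg(sparsity_mode)
  pooling <- match.arg(pooling)
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  if (steps < 1) stop_config("steps must be >= 1")
  if (layers < 1) stop_config("layers must be >= 1")
  if (lr <= 0 || batch_size < 1 || epochs < 1)
    stop_config("lr, batch_size, epochs must be positive")
  if (sparsity_ratio <= 0 || sparsity_ratio > 1)
    stop_config("sparsity_ratio must be in (0, 1]")
  if (!all(block_order %in% c("protein", "function")))
    stop_config("block_order entries must be 'protein' or 'function'")
  structure(list(channels = as.integer(channels),
                 embed_dim = as.integer(embed_dim),
                 steps = as.integer(steps), layers = as.integer(layers),
                 dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 sparsity_mode = sparsity_mode,
                 sparsity_ratio = sparsity_ratio,
                 evalue_threshold = evalue_threshold,
                 kernel_width = as.integer(kernel_width),
                 dilations = as.integer(dilations),
                 block_order = block_order, pooling = pooling,
                 normalize_prior = normalize_prior, residual = residual,
                 standardize = standardize),
            class = "model_config")
}

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Assemble the model
#'
#' Initializes all learnable parameters (seeded) and freezes the graph
#' priors: the row-normalized function adjacency and the forward/backward
#' protein diffusion matrices are stored read-only and checksummed.
#'
#' @param config a [model_config()]
#' @param a_f binary function adjacency (terms x terms, with dimnames)
#' @param diffusion list(forward, backward) from [diffusion_matrices()]
#' @return a `gofunnet_model` list: `params` (named list of matrices),
#'   `priors`, `config`, `term_ids`, `protein_ids`
#' @export
assemble_model <- function(config, a_f, diffusion) {
  stopifnot(inherits(config, "model_config"))
  nf <- nrow(a_f); np <- nrow(diffusion$forward)
  if (nrow(diffusion$backward) != np || ncol(a_f) != nf)
    stop_config("inconsistent graph dimensions")
  C <- config$channels; K <- config$embed_dim
  Q <- length(config$dilations); S <- config$kernel_width
  p <- list()
  withr_seed(config$seed, {
    p$proj <- init_mat(K, C, 1 / sqrt(K))
    for (q in seq_len(Q)) {
      for (s in seq_len(S))
        p[[sprintf("dcc%d_k%d", q, s)]] <- init_mat(C, C, 1 / sqrt(C * S))
      p[[sprintf("dcc%d_b", q)]] <- matrix(0, 1, C)
      p[[sprintf("gate%d_w", q)]] <- init_mat(Q * C, C, 1 / sqrt(Q * C))
      p[[sprintf("gate%d_b", q)]] <- matrix(0, 1, C)
    }
    p$fuse_w <- init_mat(2 * C, C, 1 / sqrt(2 * C))
    p$fuse_b <- matrix(0, 1, C)
    p$fn_emb <- init_mat(nf, C, 0.1)
    for (l in seq_len(config$layers)) {
      for (side in c("attf", "attp")) {
        p[[sprintf("l%d_%s_u1", l, side)]] <- init_mat(C, C, 1 / sqrt(C))
        p[[sprintf("l%d_%s_u2", l, side)]] <- init_mat(C, C, 1 / sqrt(C))
        p[[sprintf("l%d_%s_u3", l, side)]] <- init_mat(C, C, 1 / sqrt(C))
        p[[sprintf("l%d_%s_v", l, side)]] <- matrix(1, 1, 1)
        p[[sprintf("l%d_%s_b", l, side)]] <- matrix(0, 1, 1)
      }
      for (n in seq_len(config$steps)) {
        sdw <- 1 / sqrt(C * config$steps)
        p[[sprintf("l%d_convf_w1_%d", l, n)]] <- init_mat(C, C, sdw)
        p[[sprintf("l%d_convf_w2_%d", l, n)]] <- init_mat(C, C, sdw)
        p[[sprintf("l%d_convp_u1_%d", l, n)]] <- init_mat(C, C, sdw)
        p[[sprintf("l%d_convp_u2_%d", l, n)]] <- init_mat(C, C, sdw)
        p[[sprintf("l%d_convp_u3_%d", l, n)]] <- init_mat(C, C, sdw)
      }
    }
    p$head_w <- init_mat(C, nf, 1 / sqrt(C))   # per-term channel readout
    p$head_b <- matrix(0, 1, nf)
    if (config$sparsity_mode == "learnable") {
      p$lambda_f <- matrix(0, 1, 1)   # sigmoid(0) = 0.5 start
      p$lambda_p <- matrix(0, 1, 1)
    }
  })
  priors <- list(a_f = a_f,
                 a_f_norm = if (config$normalize_prior)
                   normalize_prior(a_f) else a_f,
                 r_f = diffusion$forward, r_b = diffusion$backward)
  model <- list(params = p, priors = priors, config = config,
                term_ids = rownames(a_f),
                protein_ids = rownames(diffusion$forward))
  model$prior_checksums <- prior_checksums(model)
  class(model) <- "gofunnet_model"
  model
}

#' Total number of learnable scalars
#' @param model a `gofunnet_model`
#' @export
n_model_params <- function(model) sum(vapply(model$params, length, 1L))

#' MD5 checksums of the frozen graph priors
#' @param model a `gofunnet_model`
#' @return named character vector over a_f, r_f, r_b
#' @export
prior_checksums <- function(model) {
  vapply(model$priors[c("a_f", "r_f", "r_b")], function(m) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(unname(m), f, compress = FALSE)
    unname(tools::md5sum(f))
  }, "")
}

#' @export
print.gofunnet_model <- function(x, ...) {
  cat("gofunnet_model:", length(x$term_ids), "terms x",
      length(x$protein_ids), "proteins;", n_model_params(x),
      "parameters;", x$config$layers, "layer(s), N =", x$config$steps,
      "diffusion steps\n")
  invisible(x)
}

# retained-k for one axis under the configured sparsity mode
model_k <- function(model, n, which = c("f", "p")) {
  which <- match.arg(which)
  cfg <- model$config
  if (cfg$sparsity_mode == "learnable") {
    lam <- 1 / (1 + exp(-model$params[[paste0("lambda_", which)]][1, 1]))
    max(1L, as.integer(floor(lam * n)))
  } else resolve_k(n, cfg$sparsity_ratio)
}

# Build the full forward graph.  embs: list of L x K matrices (one per
# protein, frozen embedder output).  Returns logits node (np x nf) and the
# named list of parameter nodes.  Dropout masks are drawn from the current
# RNG stream when train = TRUE.
model_forward_nodes <- function(model, embs, train = FALSE) {
  cfg <- model$config
  nf <- length(model$term_ids); np <- length(embs)
  C <- cfg$channels
  pn <- lapply(model$params, ad_param)
  Q <- length(cfg$dilations)
  spb <- list(proj = pn$proj,
              dcc = lapply(seq_len(Q), function(q) list(
                kernels = lapply(seq_len(cfg$kernel_width), function(s)
                  pn[[sprintf("dcc%d_k%d", q, s)]]),
                bias = pn[[sprintf("dcc%d_b", q)]],
                dilation = cfg$dilations[q])),
              gate_w = lapply(seq_len(Q), function(q)
                pn[[sprintf("gate%d_w", q)]]),
              gate_b = lapply(seq_len(Q), function(q)
                pn[[sprintf("gate%d_b", q)]]),
              fuse_w = pn$fuse_w, fuse_b = pn$fuse_b)
  pooled <- lapply(embs, function(e)
    .spb_forward_ad(ad_const(e), spb, cfg$pooling)$pooled)
  h <- ad_rbind(pooled)                        # np x C
  if (cfg$standardize) h <- ad_standardize_cols(h)
  x <- ad_add(ad_index_rows(h, rep(seq_len(np), each = nf)),
              ad_index_rows(pn$fn_emb, rep(seq_len(nf), times = np)))
  k_f <- model_k(model, nf, "f"); k_p <- model_k(model, np, "p")
  drop_node <- function(z) {
    if (!train || cfg$dropout == 0) return(z)
    keep <- matrix(stats::runif(length(z$value)) >= cfg$dropout,
                   nrow(z$value), ncol(z$value))
    ad_mul(z, ad_const(keep / (1 - cfg$dropout)))
  }
  for (l in seq_len(cfg$layers)) {
    for (block in cfg$block_order) {
      x_in <- x
      if (block == "protein") {
        att <- .correlation_ad(x, list(
          u1 = pn[[sprintf("l%d_attp_u1", l)]],
          u2 = pn[[sprintf("l%d_attp_u2", l)]],
          u3 = pn[[sprintf("l%d_attp_u3", l)]],
          v = pn[[sprintf("l%d_attp_v", l)]],
          b = pn[[sprintf("l%d_attp_b", l)]]), nf, np, "protein")
        p_att <- ad_topk_softmax(att, k_p)
        w <- lapply(1:3, function(i) lapply(seq_len(cfg$steps), function(n)
          pn[[sprintf("l%d_convp_u%d_%d", l, i, n)]]))
        x <- .diffusion_sum_ad(x, list(model$priors$r_f, model$priors$r_b,
                                       p_att), w, cfg$steps, nf, np,
                               "protein")
      } else {
        att <- .correlation_ad(x, list(
          u1 = pn[[sprintf("l%d_attf_u1", l)]],
          u2 = pn[[sprintf("l%d_attf_u2", l)]],
          u3 = pn[[sprintf("l%d_attf_u3", l)]],
          v = pn[[sprintf("l%d_attf_v", l)]],
          b = pn[[sprintf("l%d_attf_b", l)]]), nf, np, "function")
        f_att <- ad_topk_softmax(att, k_f)
        w <- lapply(1:2, function(i) lapply(seq_len(cfg$steps), function(n)
          pn[[sprintf("l%d_convf_w%d_%d", l, i, n)]]))
        x <- .diffusion_sum_ad(x, list(model$priors$a_f_norm, f_att), w,
                               cfg$steps, nf, np, "function")
      }
      x <- drop_node(ad_relu(x))
      if (cfg$residual) x <- ad_add(x, x_in)
    }
  }
  # per-term readout: logit[p, f] = x[(f,p), ] . head_w[, f] + head_b[f]
  tmp <- ad_matmul(x, pn$head_w)                            # (nf*np) x nf
  mask <- matrix(0, nf * np, nf)
  mask[cbind(seq_len(nf * np), rep(seq_len(nf), np))] <- 1
  lg_flat <- ad_matmul(ad_mul(tmp, ad_const(mask)), ad_const(matrix(1, nf, 1)))
  lg <- ad_t(ad_reshape(lg_flat, nf, np))                   # np x nf
  lg <- ad_add_rowvec(lg, pn$head_b)
  list(logits = lg, params = pn)
}

#' Forward pass returning the logit matrix
#'
#' @param model a `gofunnet_model`
#' @param embs list of per-protein L x K embedding matrices
#' @return N_P x N_F numeric logit matrix
#' @export
model_forward <- function(model, embs) {
  out <- model_forward_nodes(model, embs, train = FALSE)
  lg <- out$logits$value
  dimnames(lg) <- list(names(embs), model$term_ids)
  lg
}

#' Numerically stable binary cross-entropy with logits
#'
#' Mean over all entries of `max(x, 0) - x*y + log(1 + exp(-|x|))`, finite
#' for arbitrarily large logits.
#'
#' @param logits real matrix
#' @param labels binary matrix of the same shape
#' @export
bce_with_logits_loss <- function(logits, labels) {
  logits <- as.matrix(logits); labels <- as.matrix(labels)
  if (!all(dim(logits) == dim(labels)))
    stop_data("logits and labels shapes differ")
  if (!all(labels %in% c(0, 1))) stop_data("labels must be binary")
  mean(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

#' Literal printed-form BCE variant (fidelity flag)
#'
#' The published loss formula contains an apparent typo, `log(1 +
#' exp(1 - |x|))` instead of `log(1 + exp(-|x|))`; this helper evaluates
#' that literal form for comparison.  Training always uses
#' [bce_with_logits_loss()].
#'
#' @inheritParams bce_with_logits_loss
#' @export
bce_printed_variant <- function(logits, labels) {
  logits <- as.matrix(logits); labels <- as.matrix(labels)
  mean(pmax(logits, 0) - logits * labels + log1p(exp(1 - abs(logits))))
}

#' Build a training dataset from sequences and labels
#'
#' Preprocesses (truncates) each sequence and runs the frozen embedder
#' once; embeddings are cached in the returned object.
#'
#' @param proteome named character vector of sequences
#' @param labels binary protein x term matrix (rownames matching the
#'   proteome)
#' @param embedder embedder adapter, e.g. [make_stub_embedder()]
#' @return list(embeddings, labels, protein_ids)
#' @export
build_dataset <- function(proteome, labels, embedder) {
  ids <- names(proteome)
  if (!all(ids %in% rownames(labels)))
    stop_data("labels missing proteins: ",
              paste(setdiff(ids, rownames(labels)), collapse = ", "))
  embs <- lapply(ids, function(id)
    embed_sequence(preprocess_sequence(proteome[[id]]), embedder, id = id))
  names(embs) <- ids
  list(embeddings = embs, labels = labels[ids, , drop = FALSE],
       protein_ids = ids)
}

#' Split proteins 8:2 into train and test
#'
#' Random split by protein, then repaired so that every term keeps at
#' least one training positive (a protein carrying the orphaned term is
#' swapped into the training set), which keeps per-term metrics defined.
#'
#' @param labels binary protein x term matrix
#' @param ratio training fraction
#' @param seed integer seed
#' @return list(train, test) of row indices
#' @export
split_dataset <- function(labels, ratio = 0.8, seed = 42L) {
  np <- nrow(labels)
  withr_seed(seed, {
    train <- sort(sample.int(np, max(1L, round(ratio * np))))
    test <- setdiff(seq_len(np), train)
    for (term in seq_len(ncol(labels))) {
      pos <- which(labels[, term] == 1)
      if (length(pos) && !any(pos %in% train)) {
        move <- pos[1]
        train <- sort(c(train, move))
        test <- setdiff(test, move)
      }
    }
    list(train = train, test = test)
  })
}

#' Train the model
#'
#' Full-graph forward passes with mini-batched loss accumulation (the
#' batch picks which proteins' loss entries drive each Adam step).  All
#' randomness (shuffling, dropout) derives from `config$seed`, so a rerun
#' reproduces the loss history bit for bit.  Aborts on NaN loss.  The
#' frozen priors are verified by checksum after training.
#'
#' @param model a `gofunnet_model`
#' @param dataset from [build_dataset()]
#' @param train_idx protein indices to train on (default all)
#' @param verbose print per-epoch loss
#' @return model with trained `params`, `history` (per-epoch mean loss)
#'   and `best` (epoch + params of the lowest-loss epoch)
#' @export
train_model <- function(model, dataset, train_idx = NULL, verbose = FALSE) {
  cfg <- model$config
  embs <- dataset$embeddings
  labels <- as.matrix(dataset$labels)
  if (is.null(train_idx)) train_idx <- seq_along(embs)
  adam_m <- lapply(model$params, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  history <- numeric(cfg$epochs)
  best <- list(loss = Inf, epoch = NA_integer_, params = model$params)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    order_idx <- sample(train_idx)
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / cfg$batch_size))
    ep_loss <- 0
    for (batch in batches) {
      fw <- model_forward_nodes(model, embs, train = cfg$dropout > 0)
      lg_batch <- ad_index_rows(fw$logits, batch)
      loss <- ad_bce_logits(lg_batch, labels[batch, , drop = FALSE])
      if (!is.finite(loss$value[1, 1]))
        stop_runtime("NaN/Inf loss at epoch ", epoch,
                     "; lower the learning rate")
      ad_backward(loss)
      t <- t + 1
      for (nm in names(model$params)) {
        g <- fw$params[[nm]]$grad
        if (is.null(g)) next
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        mhat <- adam_m[[nm]] / (1 - beta1^t)
        vhat <- adam_v[[nm]] / (1 - beta2^t)
        model$params[[nm]] <- model$params[[nm]] -
          cfg$lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + loss$value[1, 1] * length(batch)
    }
    history[epoch] <- ep_loss / length(order_idx)
    if (history[epoch] < best$loss)
      best <- list(loss = history[epoch], epoch = epoch,
                   params = model$params)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f", epoch, history[epoch]))
  }
  if (!identical(unname(prior_checksums(model)),
                 unname(model$prior_checksums)))
    stop_runtime("graph priors were modified during training")
  model$history <- history
  model$best <- best
  model
}

#' Predict GO-term scores
#'
#' @param model a trained `gofunnet_model`
#' @param dataset a dataset from [build_dataset()] (all proteins are
#'   scored; subset with `idx`)
#' @param idx optional protein indices
#' @param use_best use the best-epoch checkpoint if present
#' @return N x N_F score matrix in \[0, 1\]
#' @export
predict_scores <- function(model, dataset, idx = NULL, use_best = FALSE) {
  if (use_best && !is.null(model$best)) model$params <- model$best$params
  embs <- dataset$embeddings
  lg <- model_forward(model, embs)
  scores <- 1 / (1 + exp(-lg))
  if (!is.null(idx)) scores <- scores[idx, , drop = FALSE]
  scores
}

#' Write predictions as a CAFA-style submission TSV
#'
#' @param scores protein x term score matrix with dimnames
#' @param path output TSV (protein_id, go_id, score)
#' @param min_score drop entries below this score (default keep all)
#' @export
write_predictions <- function(scores, path, min_score = 0) {
  idx <- which(scores >= min_score, arr.ind = TRUE)
  df <- data.frame(protein_id = rownames(scores)[idx[, 1]],
                   go_id = colnames(scores)[idx[, 2]],
                   score = round(scores[idx], 6))
  df <- df[order(df$protein_id, -df$score, df$go_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a prediction TSV back into a score matrix
#'
#' @param path TSV (protein_id, go_id, score)
#' @param protein_ids,term_ids matrix frame (defaults to IDs in the file)
#' @export
read_predictions <- function(path, protein_ids = NULL, term_ids = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein_id", "go_id", "score"),
                          stringsAsFactors = FALSE)
  if (is.null(protein_ids)) protein_ids <- sort(unique(df$protein_id))
  if (is.null(term_ids)) term_ids <- sort(unique(df$go_id))
  m <- matrix(0, length(protein_ids), length(term_ids),
              dimnames = list(protein_ids, term_ids))
  m[cbind(df$protein_id, df$go_id)] <- df$score
  m
}
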