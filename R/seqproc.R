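#' Sequence processing: embedder interface, dilated causal convolutions,
#' gated multi-scale aggregation and global/local fusion
#'
#' A frozen per-residue embedder (a protein language model in production, a
#' deterministic stub in tests) supplies the global representation F_ESM.
#' A linear projection maps it to the working channel width, after which a
#' stack of dilated causal convolution (DCC) layers extracts local motifs
#' at exponentially growing receptive fields.  Per-layer outputs are
#' combined by sigmoid gates, and the global and local branches are fused
#' by a learned elementwise gate: X_h = sigma(W_g [F_ESM; F_DCC]) *
#' (F_ESM + F_DCC).
#'
#' @name seqproc
NULL

#' Truncate over-length sequences
#'
#' Sequences longer than 1024 residues are cut to their first 1000
#' residues (the embedder input constraint); everything else passes
#' through unchanged.
#'
#' @param seq non-empty amino-acid string
#' @return the (possibly truncated) sequence
#' @export
preprocess_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop_data("preprocess_sequence: empty sequence")
  if (nchar(seq) > 1024) substr(seq, 1, 1000) else seq
}

#' Embed a sequence through a frozen embedder adapter
#'
#' @param seq preprocessed amino-acid string
#' @param embedder a callable `function(sequence) -> L x K matrix`
#' @param id optional sequence ID used in error messages
#' @return L x K numeric matrix
#' @export
embed_sequence <- function(seq, embedder, id = NULL) {
  out <- tryCatch(embedder(seq), error = function(e)
    stop_data("embedding failed", if (!is.null(id)) paste0(" for ", id),
              ": ", conditionMessage(e)))
  if (!is.matrix(out) || nrow(out) != nchar(seq))
    stop_data("embedder returned wrong shape",
              if (!is.null(id)) paste0(" for ", id))
  out
}

# --- ad-level building blocks (shared by the numeric API and the model) ---

# one dilated causal convolution layer; kernels: list of S (C_in x C_out)
# node matrices, bias: 1 x C_out node; left zero-padding keeps length
.dcc_layer_ad <- function(x, kernels, bias, dilation) {
  acc <- NULL
  for (s in seq_along(kernels)) {
    term <- ad_matmul(ad_shift_rows(x, dilation * (s - 1L)), kernels[[s]])
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  if (!is.null(bias)) acc <- ad_add_rowvec(acc, bias) else acc
}

# gated multi-scale aggregation: alpha_q = sigma([F1;...;FQ] Wq + bq),
# F_DCC = sum_q alpha_q * Fq
.gated_fusion_ad <- function(features, gate_w, gate_b) {
  cc <- ad_cbind(features)
  acc <- NULL
  for (q in seq_along(features)) {
    gate <- ad_matmul(cc, gate_w[[q]])
    if (!is.null(gate_b)) gate <- ad_add_rowvec(gate, gate_b[[q]])
    term <- ad_mul(ad_sigmoid(gate), features[[q]])
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  acc
}

# global/local fusion gate: X_h = sigma([F_ESM; F_DCC] W_g + b_g) *
# (F_ESM + F_DCC)
.fuse_global_local_ad <- function(f_esm, f_dcc, w_g, b_g) {
  gate <- ad_matmul(ad_cbind(list(f_esm, f_dcc)), w_g)
  if (!is.null(b_g)) gate <- ad_add_rowvec(gate, b_g)
  ad_mul(ad_sigmoid(gate), ad_add(f_esm, f_dcc))
}

# full sequence-processing block for one protein.
# p: list(proj, dcc = list of Q list(kernels, bias, dilation),
#         gate_w, gate_b, fuse_w, fuse_b) of ad nodes
.spb_forward_ad <- function(emb_node, p, pooling = "mean") {
  h <- ad_matmul(emb_node, p$proj)             # project K -> C
  feats <- vector("list", length(p$dcc))
  cur <- h
  for (q in seq_along(p$dcc)) {
    cur <- .dcc_layer_ad(cur, p$dcc[[q]]$kernels, p$dcc[[q]]$bias,
                         p$dcc[[q]]$dilation)
    feats[[q]] <- cur
  }
  f_dcc <- .gated_fusion_ad(feats, p$gate_w, p$gate_b)
  xh <- .fuse_global_local_ad(h, f_dcc, p$fuse_w, p$fuse_b)
  pooled <- if (pooling == "mean") ad_colmeans(xh) else
    ad_node(matrix(apply(xh$value, 2, max), nrow = 1), list(xh),
            function(g, node) {
              xv <- node$parents[[1]]$value
              gi <- matrix(0, nrow(xv), ncol(xv))
              gi[cbind(max.col(t(xv)), seq_len(ncol(xv)))] <- as.numeric(g)
              list(gi)
            })
  list(residue = xh, pooled = pooled)
}

# --- numeric API -----------------------------------------------------------

# accept a numeric vector (single-channel taps) or a list of matrices
as_kernel_list <- function(kernel) {
  if (is.list(kernel)) lapply(kernel, as.matrix)
  else lapply(as.numeric(kernel), function(v) matrix(v, 1, 1))
}

#' Apply one dilated causal convolution layer
#'
#' `out[t, ] = sum_s in[t - dilation*s, ] %*% kernel[[s+1]] + bias`, with
#' zero input outside the sequence (left padding), so the output has the
#' input length and position `t` depends only on positions `<= t`.
#'
#' @param x L x C input matrix (a numeric vector is taken as L x 1)
#' @param kernel list of S matrices (C_in x C_out), tap s = 0 first; a
#'   plain numeric vector is treated as single-channel taps
#' @param bias length-C_out bias (default 0)
#' @param dilation positive integer dilation factor
#' @return L x C_out matrix
#' @export
dcc_layer <- function(x, kernel, bias = NULL, dilation = 1L) {
  x <- as.matrix(x)
  kernels <- lapply(as_kernel_list(kernel), ad_const)
  b <- if (is.null(bias)) NULL else ad_const(matrix(bias, nrow = 1))
  ad_value(.dcc_layer_ad(ad_const(x), kernels, b, as.integer(dilation)))
}

#' Receptive field of a stacked dilated convolution (closed form)
#'
#' `1 + (kernel_width - 1) * sum(dilations[1:Q])`.  With kernel width 3 and
#' dilations 1, 2, 4, 8 the per-layer receptive fields are 3, 7, 15, 31
#' residues.
#'
#' @param q number of stacked layers counted
#' @param kernel_width taps per kernel
#' @param dilations dilation factor per layer (length >= q)
#' @export
receptive_field <- function(q, kernel_width = 3L, dilations = c(1L, 2L, 4L, 8L)) {
  if (q < 1 || length(dilations) < q) stop_config("need dilations for q layers")
  1L + (as.integer(kernel_width) - 1L) * sum(as.integer(dilations[seq_len(q)]))
}

#' Measure the receptive field empirically by impulse response
#'
#' Builds a single-channel stack with all-ones kernels (no cancellation),
#' feeds a unit impulse and measures the span of each layer's nonzero
#' response — the window of input positions able to influence one output.
#' (The span, not the nonzero count: dilated kernels without a unit-
#' dilation first layer leave holes inside the window.)
#'
#' @inheritParams receptive_field
#' @param len sequence length used for the probe (must exceed the field)
#' @return integer vector of per-layer receptive fields, length `q`
#' @export
measure_receptive_field <- function(q, kernel_width = 3L,
                                    dilations = c(1L, 2L, 4L, 8L),
                                    len = 64L) {
  x <- matrix(0, len, 1); x[1, 1] <- 1
  out <- integer(q)
  for (layer in seq_len(q)) {
    x <- dcc_layer(x, rep(1, kernel_width), dilation = dilations[layer])
    nz <- which(abs(x) > 1e-12)
    out[layer] <- max(nz) - min(nz) + 1L
  }
  out
}

#' Gated multi-scale aggregation of per-layer DCC features
#'
#' @param features list of Q matrices, all L x C
#' @param gate_w list of Q gate matrices ((Q*C) x C)
#' @param gate_b optional list of Q length-C biases
#' @return L x C matrix
#' @export
gated_multiscale_fusion <- function(features, gate_w, gate_b = NULL) {
  shapes <- vapply(features, function(f) paste(dim(as.matrix(f)),
                                               collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop_data("gated_multiscale_fusion: feature shapes differ")
  fn <- lapply(features, function(f) ad_const(as.matrix(f)))
  wn <- lapply(gate_w, function(w) ad_const(as.matrix(w)))
  bn <- if (is.null(gate_b)) NULL else
    lapply(gate_b, function(b) ad_const(matrix(b, nrow = 1)))
  ad_value(.gated_fusion_ad(fn, wn, bn))
}

#' Fuse global (embedder) and local (DCC) features
#'
#' @param f_esm L x C global branch
#' @param f_dcc L x C local branch
#' @param w_g (2C) x C fusion gate matrix
#' @param b_g optional length-C bias
#' @return L x C fused matrix X_h
#' @export
fuse_global_local <- function(f_esm, f_dcc, w_g, b_g = NULL) {
  f_esm <- as.matrix(f_esm); f_dcc <- as.matrix(f_dcc)
  if (!all(dim(f_esm) == dim(f_dcc)))
    stop_data("fuse_global_local: branch shapes differ")
  b <- if (is.null(b_g)) NULL else ad_const(matrix(b_g, nrow = 1))
  ad_value(.fuse_global_local_ad(ad_const(f_esm), ad_const(f_dcc),
                                 ad_const(as.matrix(w_g)), b))
}

#' Pool residue-level features to one protein vector
#'
#' @param x_h L x C matrix
#' @param method `"mean"` (default) or `"max"`
#' @return length-C numeric vector
#' @export
pool_to_protein <- function(x_h, method = c("mean", "max")) {
  method <- match.arg(method)
  x_h <- as.matrix(x_h)
  if (method == "mean") colMeans(x_h) else apply(x_h, 2, max)
}
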