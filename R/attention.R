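#' Protein functional attention with sparse top-k normalization
#'
#' Two bilinear correlation matrices are learned from the hidden tensor
#' X (N_F x N_P x C): a function-function matrix F and a protein-protein
#' matrix P.  Each node obtains a query and a key vector by contracting the
#' other node axis (mean) and the channels (learned projections); scores
#' are a bilinear form squashed by a sigmoid and scaled by a learned gain:
#'
#'   F = V_f * sigmoid(Q U2 K' + b_f),  Q = Xm U1, K = Xm U3
#'
#' Rows are then sparsified: only each node's k largest correlations are
#' kept and softmax-normalized, the rest set to zero.  k defaults to
#' max(1, floor(N/4)).
#'
#' @name attention
NULL

#' Create attention parameters
#'
#' @param channels hidden channel width C of the incoming tensor
#' @param dim query/key width d (defaults to `channels`)
#' @param seed integer seed for initialization
#' @return list(u1, u2, u3, v, b) of numeric matrices (v, b are 1 x 1)
#' @export
attention_params <- function(channels, dim = channels, seed = 1L) {
  withr_seed(seed, {
    sd <- 1 / sqrt(channels)
    list(u1 = matrix(stats::rnorm(channels * dim, 0, sd), channels, dim),
         u2 = matrix(stats::rnorm(dim * dim, 0, 1 / sqrt(dim)), dim, dim),
         u3 = matrix(stats::rnorm(channels * dim, 0, sd), channels, dim),
         v = matrix(1, 1, 1), b = matrix(0, 1, 1))
  })
}

# ad-level correlation; x flat (nf*np) x C, params: list of ad nodes
.correlation_ad <- function(x, params, nf, np,
                            side = c("function", "protein")) {
  side <- match.arg(side)
  if (side == "function") {
    xm <- ad_mix_nodes(x, matrix(1 / np, 1, np), nf, np, "protein") # nf x C
  } else {
    xm <- ad_mix_nodes(x, matrix(1 / nf, 1, nf), nf, np, "function") # np x C
  }
  q <- ad_matmul(xm, params$u1)
  k <- ad_matmul(xm, params$u3)
  s <- ad_add_scalar(ad_matmul(ad_matmul(q, params$u2), ad_t(k)), params$b)
  ad_scale_node(ad_sigmoid(s), params$v)
}

corr_numeric <- function(state, params, side) {
  stopifnot(length(dim(state)) == 3)
  nf <- dim(state)[1]; np <- dim(state)[2]; C <- dim(state)[3]
  if (nrow(params$u1) != C)
    stop_data("attention params do not match channel width ", C)
  pn <- lapply(params, function(m) ad_const(as.matrix(m)))
  x <- ad_const(matrix(state, nf * np, C))
  ad_value(.correlation_ad(x, pn, nf, np, side))
}

#' Function-function correlation matrix
#'
#' @param state N_F x N_P x C array (hidden tensor)
#' @param params list(u1, u2, u3, v, b), see [attention_params()]
#' @return dense N_F x N_F matrix
#' @export
function_correlation <- function(state, params) {
  corr_numeric(state, params, "function")
}

#' Protein-protein correlation matrix
#'
#' @inheritParams function_correlation
#' @return dense N_P x N_P matrix
#' @export
protein_correlation <- function(state, params) {
  corr_numeric(state, params, "protein")
}

#' Number of retained entries per attention row
#'
#' `max(1, floor(n_nodes * ratio))`; the default ratio 1/4 gives the usual
#' k = floor(N/4) sparsity level.
#'
#' @param n_nodes number of nodes N
#' @param ratio retention ratio in (0, 1]
#' @export
resolve_k <- function(n_nodes, ratio = 0.25) {
  if (n_nodes < 1) stop_config("n_nodes must be >= 1")
  max(1L, as.integer(floor(n_nodes * ratio)))
}

#' Sparse top-k row normalization
#'
#' Keeps each row's k largest scores (ties resolved toward the lowest
#' column index), applies a softmax over the kept entries and zeroes the
#' rest, so every row has at most k nonzeros summing to one.
#'
#' @param scores N x N real matrix
#' @param k retained entries per row (clamped to N)
#' @return sparse (mostly zero) N x N matrix with row sums 1
#' @export
sparse_topk_normalize <- function(scores, k) {
  if (k < 1) stop_config("k must be >= 1")
  ad_value(ad_topk_softmax(ad_const(as.matrix(scores)), k))
}
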