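#' Adaptive diffusion graph convolution blocks
#'
#' Two blocks share one scheme: features diffuse over N steps through
#' powers of fixed prior transition matrices and of the learned sparse
#' attention, each step with its own channel weights.  The function block
#' is unidirectional (GO edges are directed):
#'
#'   Z_F = sum_n  A_F^n X W_{n,1}  +  Ftilde^n X W_{n,2}
#'
#' and the protein block is bidirectional (interactions are reciprocal):
#'
#'   Z_P = sum_n  R_f^n X U_{n,1} + R_b^n X U_{n,2} + Ptilde^n X U_{n,3}
#'
#' Both map an N_F x N_P x C_in tensor to N_F x N_P x C_out, mixing only
#' along their own node axis.  The priors (A_F, R_f, R_b) are read-only:
#' the blocks never modify them — adaptivity lives entirely in the
#' attention term.
#'
#' @name graphconv
NULL

#' Create diffusion-convolution weights
#'
#' @param c_in,c_out channel widths
#' @param steps number of diffusion steps N
#' @param n_terms how many weighted terms per step (2 for the function
#'   block, 3 for the protein block)
#' @param seed integer seed
#' @return list of `n_terms` lists, each with N matrices c_in x c_out
#' @export
graphconv_params <- function(c_in, c_out, steps = 2L, n_terms = 2L,
                             seed = 1L) {
  withr_seed(seed, {
    sd <- 1 / sqrt(c_in * steps)
    lapply(seq_len(n_terms), function(i)
      lapply(seq_len(steps), function(n)
        matrix(stats::rnorm(c_in * c_out, 0, sd), c_in, c_out)))
  })
}

# row-normalize a nonnegative prior; zero rows stay zero
normalize_prior <- function(a) {
  rs <- rowSums(a)
  nz <- rs > 0
  a[nz, ] <- a[nz, , drop = FALSE] / rs[nz]
  a
}

# ad-level N-step diffusion sum along one axis.
# operators: list of (const matrix | ad node | NULL); weights: parallel
# list of per-step weight-node lists.  NULL operators are skipped.
.diffusion_sum_ad <- function(x, operators, weights, steps, nf, np, side) {
  acc <- NULL
  pow <- operators          # current n-th powers
  for (n in seq_len(steps)) {
    if (n > 1) {
      pow <- lapply(seq_along(pow), function(i) {
        if (is.null(pow[[i]])) return(NULL)
        if (inherits(pow[[i]], "ad_node"))
          ad_matmul(pow[[i]], operators[[i]])
        else pow[[i]] %*% operators[[i]]
      })
    }
    for (i in seq_along(pow)) {
      if (is.null(pow[[i]])) next
      term <- ad_matmul(ad_mix_nodes(x, pow[[i]], nf, np, side),
                        weights[[i]][[n]])
      acc <- if (is.null(acc)) term else ad_add(acc, term)
    }
  }
  if (is.null(acc)) {
    cout <- ncol(weights[[1]][[1]]$value)
    acc <- ad_const(matrix(0, nf * np, cout))
  }
  acc
}

conv_numeric <- function(x, operators, weights, side) {
  stopifnot(length(dim(x)) == 3)
  nf <- dim(x)[1]; np <- dim(x)[2]; C <- dim(x)[3]
  steps <- length(weights[[1]])
  wn <- lapply(weights, function(ws) lapply(ws, ad_const))
  z <- .diffusion_sum_ad(ad_const(matrix(x, nf * np, C)), operators, wn,
                         steps, nf, np, side)
  array(z$value, c(nf, np, ncol(z$value)))
}

#' Function-graph diffusion convolution (unidirectional)
#'
#' @param x N_F x N_P x C_in array
#' @param a_f binary function adjacency (prior), left unmodified
#' @param f_att sparse normalized function attention matrix
#' @param params list(w1, w2): per-step weight lists, see
#'   [graphconv_params()] with `n_terms = 2`
#' @param normalize add row normalization to the prior before taking
#'   powers (default TRUE; FALSE uses raw adjacency powers)
#' @return N_F x N_P x C_out array
#' @export
function_graph_conv <- function(x, a_f, f_att, params, normalize = TRUE) {
  af <- if (normalize) normalize_prior(a_f) else a_f
  conv_numeric(x, list(af, as.matrix(f_att)), params, "function")
}

#' Function-graph convolution without the prior term
#'
#' @inheritParams function_graph_conv
#' @param params list with one weight list (the attention-term weights)
#' @export
function_graph_conv_adaptive_only <- function(x, f_att, params) {
  w <- if (length(params) > 1) params[2] else params
  conv_numeric(x, list(as.matrix(f_att)), w, "function")
}

#' Protein-graph diffusion convolution (bidirectional)
#'
#' @param x N_F x N_P x C_in array
#' @param diff list(forward, backward) from [diffusion_matrices()]
#' @param p_att sparse normalized protein attention matrix
#' @param params list(u1, u2, u3): per-step weight lists, see
#'   [graphconv_params()] with `n_terms = 3`
#' @return N_F x N_P x C_out array
#' @export
protein_graph_conv <- function(x, diff, p_att, params) {
  conv_numeric(x, list(diff$forward, diff$backward, as.matrix(p_att)),
               params, "protein")
}

#' Protein-graph convolution without the prior terms
#'
#' @inheritParams protein_graph_conv
#' @param params list with one weight list (the attention-term weights)
#' @export
protein_graph_conv_adaptive_only <- function(x, p_att, params) {
  w <- if (length(params) > 2) params[3] else params[length(params)]
  conv_numeric(x, list(as.matrix(p_att)), w, "protein")
}
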