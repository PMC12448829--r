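# Independent brute-force reference implementations.  Deliberately naive
# (explicit loops, set arithmetic); they share no code path with the
# package internals they check.

# dilated causal convolution, double loop over positions and taps
naive_dcc <- function(input, kernels, bias = NULL, dilation = 1) {
  input <- as.matrix(input)
  if (!is.list(kernels))
    kernels <- lapply(as.numeric(kernels), function(v) matrix(v, 1, 1))
  L <- nrow(input)
  cout <- ncol(kernels[[1]])
  out <- matrix(0, L, cout)
  for (t in seq_len(L)) {
    for (s in seq_along(kernels)) {
      src <- t - dilation * (s - 1)
      if (src >= 1)
        out[t, ] <- out[t, ] + input[src, , drop = FALSE] %*% kernels[[s]]
    }
    if (!is.null(bias)) out[t, ] <- out[t, ] + bias
  }
  out
}

# index-wise bilinear correlation (both attention sides)
naive_attention <- function(state, params, side = c("function", "protein")) {
  side <- match.arg(side)
  nf <- dim(state)[1]; np <- dim(state)[2]; C <- dim(state)[3]
  n <- if (side == "function") nf else np
  xm <- matrix(0, n, C)
  for (i in seq_len(n)) for (c in seq_len(C)) {
    xm[i, c] <- if (side == "function") mean(state[i, , c])
                else mean(state[, i, c])
  }
  d <- ncol(params$u1)
  q <- matrix(0, n, d); k <- matrix(0, n, d)
  for (i in seq_len(n)) for (a in seq_len(d)) {
    q[i, a] <- sum(xm[i, ] * params$u1[, a])
    k[i, a] <- sum(xm[i, ] * params$u3[, a])
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (a in seq_len(d)) for (b in seq_len(d))
      s <- s + q[i, a] * params$u2[a, b] * k[j, b]
    out[i, j] <- params$v[1, 1] / (1 + exp(-(s + params$b[1, 1])))
  }
  out
}

# row-wise top-k softmax, one row at a time
naive_topk_softmax <- function(scores, k) {
  scores <- as.matrix(scores)
  n <- ncol(scores)
  k <- min(k, n)
  out <- matrix(0, nrow(scores), n)
  for (i in seq_len(nrow(scores))) {
    ord <- order(scores[i, ], seq_len(n) * -1, decreasing = TRUE)
    kept <- sort(ord[seq_len(k)])
    e <- exp(scores[i, kept])
    out[i, kept] <- e / sum(e)
  }
  out
}

# explicit N-step power-sum diffusion along one tensor axis.
# mats: list of operator matrices, weights: parallel list of per-step
# weight-matrix lists
naive_diffusion <- function(x, mats, weights, steps,
                            side = c("function", "protein")) {
  side <- match.arg(side)
  nf <- dim(x)[1]; np <- dim(x)[2]
  cout <- ncol(weights[[1]][[1]])
  z <- array(0, c(nf, np, cout))
  for (i in seq_along(mats)) {
    pow <- diag(nrow(mats[[i]]))
    for (n in seq_len(steps)) {
      pow <- pow %*% mats[[i]]
      if (side == "function") {
        for (p in seq_len(np))
          z[, p, ] <- z[, p, ] + pow %*% x[, p, ] %*% weights[[i]][[n]]
      } else {
        for (f in seq_len(nf))
          z[f, , ] <- z[f, , ] + pow %*% x[f, , ] %*% weights[[i]][[n]]
      }
    }
  }
  z
}

# exhaustive protein-centric Fmax from raw sets
sweep_fmax <- function(scores, truth, grid = seq(0.01, 1, 0.01)) {
  best <- 0
  terms <- seq_len(ncol(scores))
  for (h in grid) {
    pre <- numeric(nrow(scores)); rec <- numeric(nrow(scores))
    for (j in seq_len(nrow(scores))) {
      P <- terms[scores[j, ] >= h]
      T_ <- terms[truth[j, ] == 1]
      inter <- length(intersect(P, T_))
      pre[j] <- if (length(P)) inter / length(P) else 0
      rec[j] <- inter / length(T_)
    }
    mp <- mean(pre); mr <- mean(rec)
    f <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
    if (f > best) best <- f
  }
  best
}

# pair-counting Mann-Whitney AUC with half credit for ties
mannwhitney_auc <- function(scores, labels) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Kahn's algorithm: TRUE iff the child->parent edge set is acyclic
kahn_is_dag <- function(terms, edges) {
  indeg <- stats::setNames(integer(length(terms)), terms)
  adj <- split(edges$parent, edges$child)
  for (p in edges$parent) indeg[p] <- indeg[p] + 1
  queue <- names(indeg)[indeg == 0]
  seen <- 0
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1
      if (indeg[w] == 0) queue <- c(queue, w)
    }
  }
  seen == length(terms)
}

# all ancestors of a term by BFS over the raw edge table
bfs_ancestors <- function(term, edges) {
  out <- character(0); queue <- term
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    parents <- edges$parent[edges$child == v]
    new <- setdiff(parents, out)
    out <- c(out, new); queue <- c(queue, new)
  }
  out
}
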