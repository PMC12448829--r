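# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every node is an environment holding a value, its parent nodes and a
# backward closure returning the gradient contribution for each parent.
# Graphs are rebuilt on every forward pass; parameters are plain matrices
# wrapped in ad_param() at the start of a pass and their gradients read
# back after ad_backward().  Only what the model needs is implemented.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0

ad_node <- function(value, parents = list(), backward = NULL, is_param = FALSE) {
  # force arguments before taking an id so creation order is topological
  force(value); force(parents); force(backward)
  .ad$counter <- .ad$counter + 1
  node <- new.env(parent = emptyenv())
  node$id <- .ad$counter
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$is_param <- is_param
  class(node) <- "ad_node"
  node
}

ad_const <- function(x) ad_node(as.matrix(x))

ad_param <- function(x) ad_node(as.matrix(x), is_param = TRUE)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

#' @noRd
ad_matmul <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(g, node) {
    list(g %*% t(node$parents[[2]]$value), t(node$parents[[1]]$value) %*% g)
  })
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g, node) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g, node) list(g, -g))
}

# bias: 1 x C row vector broadcast over rows of a
ad_add_rowvec <- function(a, bias) {
  nr <- nrow(a$value)
  ad_node(sweep(a$value, 2, as.numeric(bias$value), "+"), list(a, bias),
          function(g, node) list(g, matrix(colSums(g), nrow = 1)))
}

# scalar node (1x1) broadcast-added to every entry
ad_add_scalar <- function(a, s) {
  ad_node(a$value + s$value[1, 1], list(a, s),
          function(g, node) list(g, matrix(sum(g), 1, 1)))
}

# scalar node (1x1) broadcast-multiplied over every entry
ad_scale_node <- function(a, s) {
  ad_node(a$value * s$value[1, 1], list(a, s), function(g, node) {
    list(g * node$parents[[2]]$value[1, 1],
         matrix(sum(g * node$parents[[1]]$value), 1, 1))
  })
}

ad_scale <- function(a, k) {         # k: plain numeric constant
  force(k)
  ad_node(a$value * k, list(a), function(g, node) list(g * k))
}

ad_mul <- function(a, b) {
  ad_node(a$value * b$value, list(a, b), function(g, node) {
    list(g * node$parents[[2]]$value, g * node$parents[[1]]$value)
  })
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  node <- ad_node(y, list(a))
  node$backward <- function(g, node) list(g * node$value * (1 - node$value))
  node
}

ad_tanh <- function(a) {
  y <- tanh(a$value)
  node <- ad_node(y, list(a))
  node$backward <- function(g, node) list(g * (1 - node$value^2))
  node
}

ad_relu <- function(a) {
  node <- ad_node(pmax(a$value, 0), list(a))
  node$backward <- function(g, node) list(g * (node$parents[[1]]$value > 0))
  node
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$value), 1, 1), list(a), function(g, node) {
    list(matrix(g[1, 1], nrow(node$parents[[1]]$value),
                ncol(node$parents[[1]]$value)))
  })
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$value))

# column-wise mean: L x C -> 1 x C
ad_colmeans <- function(a) {
  nr <- nrow(a$value)
  ad_node(matrix(colMeans(a$value), nrow = 1), list(a), function(g, node) {
    n <- nrow(node$parents[[1]]$value)
    matrix(rep(as.numeric(g) / n, each = n), nrow = n) |> list()
  })
}

ad_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), 1L)
  ad_node(do.call(cbind, lapply(nodes, ad_value)), nodes, function(g, node) {
    stops <- cumsum(widths)
    starts <- c(1, head(stops, -1) + 1)
    lapply(seq_along(widths), function(i) g[, starts[i]:stops[i], drop = FALSE])
  })
}

ad_t <- function(a) {
  ad_node(t(a$value), list(a), function(g, node) list(t(g)))
}

# column-major reshape; gradient reshapes back
ad_reshape <- function(a, nr, nc) {
  dims <- dim(a$value)
  ad_node(matrix(a$value, nr, nc), list(a),
          function(g, node) list(matrix(g, dims[1], dims[2])))
}

# shift rows down by k (causal shift for dilated convolution); zero-fill top
ad_shift_rows <- function(a, k) {
  force(k)
  v <- a$value
  L <- nrow(v)
  out <- matrix(0, L, ncol(v))
  if (k < L) out[(k + 1):L, ] <- v[seq_len(L - k), , drop = FALSE]
  ad_node(out, list(a), function(g, node) {
    gi <- matrix(0, L, ncol(g))
    if (k < L) gi[seq_len(L - k), ] <- g[(k + 1):L, , drop = FALSE]
    list(gi)
  })
}

# Mode products on a flattened N_F x N_P x C tensor stored as an
# (nf*np) x C matrix with the function index varying fastest.
# M may be rectangular (b x nf or b x np), so the same op does both graph
# mixing (square M) and axis reduction (b = 1, M a row of weights).
# side "function": Y[a,p,c] = sum_f M[a,f] X[f,p,c]   -> (b*np) x C
# side "protein" : Y[f,a,c] = sum_p M[a,p] X[f,p,c]   -> (nf*b) x C
ad_mix_nodes <- function(x, m, nf, np, side = c("function", "protein")) {
  side <- match.arg(side)
  C <- ncol(x$value)
  m_node <- inherits(m, "ad_node")
  mval <- ad_value(m)
  b <- nrow(mval)
  if (side == "function") {
    stopifnot(ncol(mval) == nf)
    y <- matrix(mval %*% matrix(x$value, nf, np * C), b * np, C)
  } else {
    stopifnot(ncol(mval) == np)
    arr <- aperm(array(x$value, c(nf, np, C)), c(2, 1, 3))   # p, f, c
    yo <- mval %*% matrix(arr, np, nf * C)                   # b, f*c
    y <- matrix(aperm(array(yo, c(b, nf, C)), c(2, 1, 3)), nf * b, C)
  }
  parents <- if (m_node) list(x, m) else list(x)
  ad_node(y, parents, function(g, node) {
    xv <- node$parents[[1]]$value
    if (side == "function") {
      gm <- matrix(g, b, np * C)
      gx <- matrix(t(mval) %*% gm, nf * np, C)
      out <- list(gx)
      if (m_node) out[[2]] <- gm %*% t(matrix(xv, nf, np * C))
    } else {
      gp <- aperm(array(g, c(nf, b, C)), c(2, 1, 3))         # b, f, c
      gm <- matrix(gp, b, nf * C)
      gx <- matrix(aperm(array(t(mval) %*% gm, c(np, nf, C)), c(2, 1, 3)),
                   nf * np, C)
      out <- list(gx)
      if (m_node) {
        xp <- aperm(array(xv, c(nf, np, C)), c(2, 1, 3))
        out[[2]] <- gm %*% t(matrix(xp, np, nf * C))
      }
    }
    out
  })
}

# row gather: Y = X[idx, ]; backward sums gradient rows back by index
ad_index_rows <- function(a, idx) {
  force(idx)
  nr <- nrow(a$value)
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g, node) {
    gi <- matrix(0, nr, ncol(g))
    agg <- rowsum(g, group = idx)
    gi[as.integer(rownames(agg)), ] <- agg
    list(gi)
  })
}

# Row-wise top-k masked softmax (sparse attention normalization).
# Ties broken toward the lowest column index; k clamped to ncol.
# Gradients flow only through retained entries (straight-through mask).
ad_topk_softmax <- function(scores, k) {
  s <- scores$value
  n <- ncol(s)
  k <- min(max(1L, as.integer(k)), n)
  mask <- matrix(FALSE, nrow(s), n)
  for (i in seq_len(nrow(s))) {
    ord <- order(s[i, ], -seq_len(n), decreasing = TRUE)
    mask[i, ord[seq_len(k)]] <- TRUE
  }
  y <- matrix(0, nrow(s), n)
  for (i in seq_len(nrow(s))) {
    kept <- s[i, mask[i, ]]
    e <- exp(kept - max(kept))
    y[i, mask[i, ]] <- e / sum(e)
  }
  node <- ad_node(y, list(scores))
  node$backward <- function(g, node) {
    yv <- node$value
    gs <- matrix(0, nrow(yv), ncol(yv))
    for (i in seq_len(nrow(yv))) {
      idx <- mask[i, ]
      yi <- yv[i, idx]
      gi <- g[i, idx]
      gs[i, idx] <- yi * (gi - sum(gi * yi))
    }
    list(gs)
  }
  node
}

# Numerically stable binary cross-entropy with logits, mean over entries.
# labels: plain binary matrix (constant).
ad_bce_logits <- function(logits, labels) {
  x <- logits$value
  loss <- mean(pmax(x, 0) - x * labels + log1p(exp(-abs(x))))
  ad_node(matrix(loss, 1, 1), list(logits), function(g, node) {
    xv <- node$parents[[1]]$value
    list(g[1, 1] * (1 / (1 + exp(-xv)) - labels) / length(xv))
  })
}

# Reverse pass: seeds the scalar output with 1 and accumulates gradients
# into each node's $grad field (parameters keep theirs for the optimizer).
ad_backward <- function(out) {
  stopifnot(length(out$value) == 1)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(out)
  nodes <- list()
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(node$id)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      nodes[[length(nodes) + 1]] <- node
      for (p in node$parents) stack[[length(stack) + 1]] <- p
    }
  }
  ord <- order(vapply(nodes, function(n) n$id, 1), decreasing = TRUE)
  nodes <- nodes[ord]
  for (n in nodes) n$grad <- NULL
  out$grad <- matrix(1, 1, 1)
  for (n in nodes) {
    if (is.null(n$grad) || is.null(n$backward)) next
    pg <- n$backward(n$grad, n)
    for (i in seq_along(n$parents)) {
      if (i > length(pg) || is.null(pg[[i]])) next
      p <- n$parents[[i]]
      p$grad <- if (is.null(p$grad)) pg[[i]] else p$grad + pg[[i]]
    }
  }
  invisible(out)
}

ad_rbind <- function(nodes) {
  heights <- vapply(nodes, function(n) nrow(n$value), 1L)
  ad_node(do.call(rbind, lapply(nodes, ad_value)), nodes, function(g, node) {
    stops <- cumsum(heights)
    starts <- c(1, head(stops, -1) + 1)
    lapply(seq_along(heights), function(i) g[starts[i]:stops[i], , drop = FALSE])
  })
}

# broadcast-multiply each row of a by the 1 x C vector v
ad_mul_rowvec <- function(a, v) {
  ad_node(sweep(a$value, 2, as.numeric(v$value), "*"), list(a, v),
          function(g, node) {
    av <- node$parents[[1]]$value
    vv <- as.numeric(node$parents[[2]]$value)
    list(sweep(g, 2, vv, "*"), matrix(colSums(g * av), nrow = 1))
  })
}

# elementwise 1/sqrt(x + eps)
ad_rsqrt_eps <- function(a, eps = 1e-6) {
  y <- 1 / sqrt(a$value + eps)
  node <- ad_node(y, list(a))
  node$backward <- function(g, node) list(-0.5 * g * node$value^3)
  node
}

# z-score each column over rows (feature standardization layer);
# fully differentiable, eps guards constant columns
ad_standardize_cols <- function(a, eps = 1e-6) {
  mu <- ad_colmeans(a)
  centered <- ad_add_rowvec(a, ad_scale(mu, -1))
  ad_mul_rowvec(centered,
                ad_rsqrt_eps(ad_colmeans(ad_mul(centered, centered)), eps))
}
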