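#' Sequence-similarity network (SSN) and diffusion matrices
#'
#' The protein graph prior is a binary adjacency built from all-vs-all
#' BLAST E-values: proteins j, j' are connected iff their best E-value in
#' either direction is strictly below a threshold E.  Because interactions
#' are reciprocal, the matrix is symmetrized by the minimum directional
#' E-value.  Forward/backward row-normalized transition matrices (with
#' self-loops) drive the bidirectional diffusion convolution.
#'
#' @name protein_graph
NULL

#' Read a 12-column BLAST tabular (outfmt 6) file
#'
#' Self-hits are dropped and duplicate (query, subject) pairs are collapsed
#' to their minimum E-value.
#'
#' @param path BLAST outfmt-6 TSV (E-value in column 11)
#' @param protein_ids character vector of known IDs used to resolve rows
#' @param on_unknown `"error"` (default) or `"skip"` rows whose IDs are not
#'   in `protein_ids` (skips are reported via message)
#' @return data.frame(query, subject, evalue)
#' @export
read_blast_tabular <- function(path, protein_ids,
                               on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  if (!file.exists(path)) stop_data("BLAST file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_data("malformed BLAST tabular file: ",
                                  conditionMessage(e)))
  if (ncol(df) != 12)
    stop_data("expected 12 outfmt-6 columns, got ", ncol(df))
  tab <- data.frame(query = as.character(df[[1]]),
                    subject = as.character(df[[2]]),
                    evalue = as.numeric(df[[11]]),
                    stringsAsFactors = FALSE)
  if (anyNA(tab$evalue)) stop_data("non-numeric E-value in column 11")
  bad <- !(tab$query %in% protein_ids) | !(tab$subject %in% protein_ids)
  if (any(bad)) {
    if (on_unknown == "error")
      stop_data("unknown protein ID(s) in BLAST table: ",
                paste(unique(c(tab$query[bad], tab$subject[bad])),
                      collapse = ", "))
    message("read_blast_tabular: skipping ", sum(bad),
            " row(s) with unknown IDs")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab <- tab[tab$query != tab$subject, , drop = FALSE]   # self-hits
  if (nrow(tab)) {
    key <- paste(tab$query, tab$subject)
    tab <- do.call(rbind, lapply(split(tab, key), function(d)
      d[which.min(d$evalue), , drop = FALSE]))
    tab <- tab[order(tab$query, tab$subject), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Build the SSN adjacency from an E-value table
#'
#' `A[j, j'] = A[j', j] = 1` iff the minimum directional E-value between j
#' and j' is strictly below `threshold`.
#'
#' @param table data.frame(query, subject, evalue)
#' @param threshold positive E-value cutoff E (strict `<`); default 1e-10
#' @param protein_ids IDs fixing matrix order (defaults to IDs seen in the
#'   table)
#' @return symmetric binary N_P x N_P matrix with zero diagonal
#' @export
build_ssn <- function(table, threshold = 1e-10, protein_ids = NULL) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop_config("threshold must be > 0")
  if (is.null(protein_ids))
    protein_ids <- sort(unique(c(table$query, table$subject)))
  n <- length(protein_ids)
  a <- matrix(0, n, n, dimnames = list(protein_ids, protein_ids))
  hit <- table[table$evalue < threshold, , drop = FALSE]
  if (nrow(hit)) {
    a[cbind(hit$query, hit$subject)] <- 1
    a[cbind(hit$subject, hit$query)] <- 1
  }
  diag(a) <- 0
  a
}

#' Row-normalized forward/backward diffusion matrices
#'
#' Adds self-loops (by default) before normalizing each nonzero row to sum
#' one; zero rows are left zero, so isolated proteins pass no information.
#' The backward matrix applies the same normalization to the transpose.
#'
#' @param adj square binary adjacency
#' @param add_self_loops add the identity before normalization
#' @return list(forward, backward)
#' @export
diffusion_matrices <- function(adj, add_self_loops = TRUE) {
  stopifnot(nrow(adj) == ncol(adj))
  a <- adj
  if (add_self_loops) a <- a + diag(nrow(a))
  norm_rows <- function(m) {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
    m
  }
  list(forward = norm_rows(a), backward = norm_rows(t(a)))
}

#' Sequence of matrix powers T^1 .. T^N
#'
#' @param m square matrix
#' @param n_steps number of diffusion steps N (>= 1)
#' @return list of length N
#' @export
matrix_power_sequence <- function(m, n_steps) {
  if (!is.numeric(n_steps) || n_steps < 1)
    stop_config("n_steps must be >= 1")
  out <- vector("list", n_steps)
  out[[1]] <- m
  for (n in seq_len(n_steps)[-1]) out[[n]] <- out[[n - 1]] %*% m
  out
}

#' Export an adjacency matrix as an edge-list TSV
#'
#' @param adj matrix with dimnames
#' @param path output TSV (from, to, weight)
#' @export
write_edge_list <- function(adj, path) {
  idx <- which(adj != 0, arr.ind = TRUE)
  df <- data.frame(from = rownames(adj)[idx[, 1]],
                   to = colnames(adj)[idx[, 2]],
                   weight = adj[idx])
  df <- df[order(df$from, df$to), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
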