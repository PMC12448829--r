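#' Deterministic synthetic-data generators
#'
#' Every external input of the pipeline — GO ontology (OBO), protein
#' sequences (FASTA), protein-to-term annotations (TSV) and all-vs-all
#' BLAST hits (tabular outfmt 6) — can be emulated by these generators, so
#' the whole model is testable offline.  All generators are pure functions
#' of their configuration: the same `fixture_config()` (seed included)
#' yields byte-identical output.
#'
#' @param n_terms number of GO terms in the toy ontology (>= 2)
#' @param n_proteins number of proteins
#' @param seq_len_range integer vector `c(min, max)` sequence length
#' @param edge_density fraction of protein pairs with a BLAST hit, in \[0,1\]
#' @param annotation_rate fraction of leaf terms directly annotated per
#'   protein, in \[0,1\] (floored at one term per protein)
#' @param seed integer seed driving all randomness
#' @return an object of class `fixture_config`
#' @export
fixture_config <- function(n_terms = 10L, n_proteins = 20L,
                           seq_len_range = c(30L, 120L),
                           edge_density = 0.3, annotation_rate = 0.3,
                           seed = 42L) {
  if (!is.numeric(n_terms) || n_terms < 2)
    stop_config("n_terms must be >= 2")
  if (!is.numeric(n_proteins) || n_proteins < 1)
    stop_config("n_proteins must be >= 1")
  if (length(seq_len_range) != 2 || seq_len_range[1] < 1 ||
      seq_len_range[2] < seq_len_range[1])
    stop_config("seq_len_range must be c(min, max) with min >= 1")
  if (edge_density < 0 || edge_density > 1)
    stop_config("edge_density must be in [0, 1]")
  if (annotation_rate < 0 || annotation_rate > 1)
    stop_config("annotation_rate must be in [0, 1]")
  structure(list(n_terms = as.integer(n_terms),
                 n_proteins = as.integer(n_proteins),
                 seq_len_range = as.integer(seq_len_range),
                 edge_density = edge_density,
                 annotation_rate = annotation_rate,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

toy_term_ids <- function(n) sprintf("GO:%07d", seq_len(n))

toy_protein_ids <- function(n) sprintf("P%05d", seq_len(n))

#' Generate a rooted toy GO DAG
#'
#' Term 1 is the root; every later term receives one `is_a` parent among the
#' earlier terms and, with some probability, an extra `part_of` parent, so
#' the result is always a rooted DAG in which every non-root term has at
#' least one `is_a` parent.
#'
#' @param config a [fixture_config()]
#' @return an `ontology_graph` (see [ontology_graph()])
#' @export
generate_toy_ontology <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_terms
  ids <- toy_term_ids(n)
  withr_seed(config$seed, {
    child <- character(0); parent <- character(0); relation <- character(0)
    for (i in 2:n) {
      p <- if (i == 2) 1L else sample.int(i - 1L, 1L)
      child <- c(child, ids[i]); parent <- c(parent, ids[p])
      relation <- c(relation, "is_a")
      if (i > 2 && stats::runif(1) < 0.3) {
        q <- sample.int(i - 1L, 1L)
        if (q != p) {
          child <- c(child, ids[i]); parent <- c(parent, ids[q])
          relation <- c(relation, "part_of")
        }
      }
    }
    ontology_graph(terms = ids,
                   edges = data.frame(child = child, parent = parent,
                                      relation = relation,
                                      stringsAsFactors = FALSE),
                   names = paste("toy term", seq_len(n)))
  })
}

#' Generate a toy proteome
#'
#' @param config a [fixture_config()]
#' @return named character vector of amino-acid sequences (20-letter
#'   alphabet), names are protein IDs
#' @export
generate_toy_proteome <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  withr_seed(config$seed + 1L, {
    rng <- seq(config$seq_len_range[1], config$seq_len_range[2])
    lens <- rng[sample.int(length(rng), config$n_proteins, replace = TRUE)]
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
    names(seqs) <- toy_protein_ids(config$n_proteins)
    seqs
  })
}

#' Generate a sparse symmetric table of BLAST E-values
#'
#' Each unordered protein pair is kept with probability `edge_density`; its
#' E-value is drawn log-uniformly in \[1e-30, 1e-2\] (so the usual threshold
#' sweep 1e-15 ... 1e-5 partitions the edges non-trivially) and emitted in
#' both directions.
#'
#' @param config a [fixture_config()]
#' @return data.frame with columns query, subject, evalue
#' @export
generate_evalue_table <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  if (config$n_proteins < 2)
    stop_config("generate_evalue_table needs n_proteins >= 2")
  ids <- toy_protein_ids(config$n_proteins)
  pairs <- utils::combn(config$n_proteins, 2)
  withr_seed(config$seed + 2L, {
    keep <- stats::runif(ncol(pairs)) < config$edge_density
    pairs <- pairs[, keep, drop = FALSE]
    ev <- 10^stats::runif(ncol(pairs), min = -30, max = -2)
    data.frame(query = ids[c(pairs[1, ], pairs[2, ])],
               subject = ids[c(pairs[2, ], pairs[1, ])],
               evalue = c(ev, ev), stringsAsFactors = FALSE)
  })
}

#' Generate true-path-consistent labels
#'
#' Direct annotations are drawn at the leaves of the ontology, then closed
#' upward over is_a/part_of edges so that every positive term implies all
#' its ancestors (the true-path rule the CAFA metrics assume).  Every
#' protein gets at least one direct annotation.
#'
#' @param ontology an `ontology_graph`
#' @param n_proteins number of proteins (rows)
#' @param config a [fixture_config()]
#' @return binary matrix n_proteins x n_terms, dimnames = (protein, term)
#' @export
generate_labels <- function(ontology, n_proteins, config) {
  stopifnot(inherits(ontology, "ontology_graph"))
  leaves <- ontology_leaves(ontology)
  anc <- ontology_ancestors(ontology)   # term -> ancestors incl. itself
  y <- matrix(0L, n_proteins, length(ontology$terms),
              dimnames = list(toy_protein_ids(n_proteins), ontology$terms))
  withr_seed(config$seed + 3L, {
    for (j in seq_len(n_proteins)) {
      ndirect <- max(1L, stats::rbinom(1L, length(leaves),
                                       config$annotation_rate))
      direct <- sample(leaves, min(ndirect, length(leaves)))
      for (term in direct) y[j, anc[[term]]] <- 1L
    }
  })
  y
}

#' Deterministic per-residue embedding stub
#'
#' A weight-free test double for a frozen protein language model.  Row `t`
#' of the output depends only on (residue identity at `t`, position `t`,
#' seed): a seeded per-letter base vector plus a fixed sinusoidal positional
#' code, squashed by tanh into (-1, 1).  Same input, same bytes.
#'
#' @param sequence non-empty amino-acid string
#' @param dim embedding width (default 1280, the usual transformer width)
#' @param seed integer seed for the per-letter table
#' @return L x dim numeric matrix
#' @export
stub_embedder <- function(sequence, dim = 1280L, seed = 1L) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop_data("stub_embedder: sequence must be a non-empty string")
  letters21 <- c(AA_ALPHABET, "X")
  res <- strsplit(toupper(sequence), "")[[1]]
  res[!res %in% letters21] <- "X"
  base <- withr_seed(seed, matrix(stats::runif(21 * dim, -1, 1), 21, dim,
                                  dimnames = list(letters21, NULL)))
  L <- length(res)
  k <- seq_len(dim)
  posfreq <- 1 / 10000^((k - 1) / dim)
  pos <- outer(seq_len(L), posfreq, function(t, w) sin(t * w))
  tanh(base[res, , drop = FALSE] + pos)
}

#' Build an embedder adapter from the stub
#'
#' Returns a callable `function(sequence) -> L x dim matrix`, the adapter
#' contract the sequence-processing block expects from any embedder.
#'
#' @inheritParams stub_embedder
#' @export
make_stub_embedder <- function(dim = 1280L, seed = 1L) {
  force(dim); force(seed)
  function(sequence) stub_embedder(sequence, dim = dim, seed = seed)
}

# run expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write fixture files in their standard on-disk formats
#'
#' Writes a minimal OBO, a FASTA, a two-column annotation TSV
#' (protein_id, go_id) and a 12-column BLAST outfmt-6 TSV.
#'
#' @param config a [fixture_config()]
#' @param dir output directory (created if missing)
#' @return invisibly, a named list of the four file paths
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ont <- generate_toy_ontology(config)
  prot <- generate_toy_proteome(config)
  ev <- generate_evalue_table(config)
  lab <- generate_labels(ont, config$n_proteins, config)
  paths <- list(obo = file.path(dir, "ontology.obo"),
                fasta = file.path(dir, "proteome.fasta"),
                annotations = file.path(dir, "annotations.tsv"),
                blast = file.path(dir, "blast.tsv"))
  write_obo(ont, paths$obo)
  write_fasta(prot, paths$fasta)
  write_annotations(lab, paths$annotations)
  write_blast_tabular(ev, prot, paths$blast)
  invisible(paths)
}

#' @rdname write_fixtures
#' @param sequences named character vector of sequences
#' @param path output file
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an amino-acid FASTA file into a named character vector
#' @param path FASTA file
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_data("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname write_fixtures
#' @param labels binary protein x term matrix with dimnames
#' @export
write_annotations <- function(labels, path) {
  idx <- which(labels == 1, arr.ind = TRUE)
  df <- data.frame(protein_id = rownames(labels)[idx[, 1]],
                   go_id = colnames(labels)[idx[, 2]])
  df <- df[order(df$protein_id, df$go_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column annotation table (protein_id TAB go_id)
#' @param path TSV file
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_data("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein_id", "go_id"),
                          stringsAsFactors = FALSE)
  df
}

#' @rdname write_fixtures
#' @param evalue_table data.frame(query, subject, evalue)
#' @param sequences named character vector (for alignment-length dummies)
#' @export
write_blast_tabular <- function(evalue_table, sequences, path) {
  len <- pmin(nchar(sequences[evalue_table$query]),
              nchar(sequences[evalue_table$subject]))
  # qseqid sseqid pident length mismatch gapopen qstart qend sstart send
  # evalue bitscore -- the standard 12 outfmt-6 columns
  df <- data.frame(evalue_table$query, evalue_table$subject,
                   formatC(35 + 60 * exp(log10(evalue_table$evalue) / 5),
                           digits = 2, format = "f"),
                   len, pmax(0L, round(len * 0.3)), 0L, 1L, len, 1L, len,
                   formatC(evalue_table$evalue, digits = 2, format = "e"),
                   round(50 - 1.5 * log10(evalue_table$evalue), 1))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

stop_config <- function(...) {
  stop(structure(class = c("gofunnet_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("gofunnet_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
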