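#' Expression matrix constructor
#'
#' A genes x samples numeric matrix of (RMA-style, log-scale) expression
#' values with unique gene and sample identifiers and no missing values.
#'
#' @param values numeric matrix with rownames (genes) and colnames (samples).
#' @param species species label attached to the matrix.
#' @return The matrix with class `expression_matrix` and a `species` attribute.
#' @export
expression_matrix <- function(values, species = "unknown") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("expression values must be finite (no NA/Inf)")
  structure(values, species = species,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix (", attr(x, "species"), "): ", nrow(x), " genes x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids. The
#' reader rejects (never repairs) duplicated ids, non-numeric cells and
#' ragged rows, reporting the offending line.
#'
#' @param path file path.
#' @param species species label to attach.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, species = "unknown") {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_samp <- length(header) - 1L
  if (n_samp < 1) stop("expression file has no sample columns: ", path)
  n_gene <- length(lines) - 1L
  vals <- matrix(NA_real_, n_gene, n_samp)
  genes <- character(n_gene)
  for (i in seq_len(n_gene)) {
    f <- fields[[i + 1L]]
    if (length(f) != n_samp + 1L) {
      stop("ragged row at line ", i + 1L, " of ", path, " (", length(f),
           " fields, expected ", n_samp + 1L, ")")
    }
    genes[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(v))) {
      stop("non-numeric or missing value at line ", i + 1L, " of ", path)
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    stop("duplicated gene id '", genes[duplicated(genes)][1], "' in ", path)
  }
  if (anyDuplicated(header[-1])) stop("duplicated sample id in ", path)
  rownames(vals) <- genes
  colnames(vals) <- header[-1]
  expression_matrix(vals, species)
}

#' Write an expression matrix to TSV
#'
#' Full double precision is preserved, so write -> read round-trips exactly.
#'
#' @param x an [expression_matrix()] (or plain named matrix).
#' @param path file path.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Read OrthoMCL-style ortholog groups
#'
#' Lines of the form `GROUP_ID: sp|gene sp|gene ...`. An optional side table
#' of per-pair BLAST bit-scores (`geneA<TAB>geneB<TAB>score`) can be given.
#'
#' @param path groups file path.
#' @param bitscore_path optional bit-score TSV path.
#' @return An [ortholog_map()].
#' @export
read_ortholog_groups <- function(path, bitscore_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed group line ", i, " in ", path)
    grp <- trimws(parts[1])
    toks <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    sp_gene <- strsplit(toks, "|", fixed = TRUE)
    bad <- vapply(sp_gene, function(t) length(t) != 2 || !all(nzchar(t)), TRUE)
    if (any(bad)) {
      stop("malformed member token '", toks[bad][1], "' at line ", i, " of ", path)
    }
    rows[[i]] <- data.frame(group = grp,
                            species = vapply(sp_gene, `[`, "", 1),
                            gene = vapply(sp_gene, `[`, "", 2),
                            stringsAsFactors = FALSE)
  }
  members <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group = character(0), species = character(0), gene = character(0))
  }
  bitscores <- NULL
  if (!is.null(bitscore_path)) {
    bs <- utils::read.table(bitscore_path, sep = "\t", header = FALSE,
                            col.names = c("gene_a", "gene_b", "score"),
                            colClasses = c("character", "character", "numeric"))
    bitscores <- bs
  }
  ortholog_map(members, bitscores)
}

#' Write an ortholog map to OrthoMCL-style files
#'
#' @param map an [ortholog_map()].
#' @param path groups file path.
#' @param bitscore_path optional path for the bit-score side table.
#' @export
write_ortholog_groups <- function(map, path, bitscore_path = NULL) {
  m <- map$members
  grp <- split(paste(m$species, m$gene, sep = "|"), m$group)
  lines <- vapply(names(grp), function(g) {
    paste0(g, ": ", paste(grp[[g]], collapse = " "))
  }, "")
  writeLines(lines, path)
  if (!is.null(bitscore_path) && !is.null(map$bitscores)) {
    keys <- strsplit(names(map$bitscores), "\r", fixed = TRUE)
    bs <- data.frame(gene_a = vapply(keys, `[`, "", 1),
                     gene_b = vapply(keys, `[`, "", 2),
                     score = unname(map$bitscores))
    utils::write.table(bs, bitscore_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a transcription-factor list
#'
#' One gene id per line; `#` starts a comment.
#' @param path file path.
#' @return Character vector of TF ids.
#' @export
read_tf_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' @rdname read_tf_list
#' @param tfs character vector of TF ids.
#' @export
write_tf_list <- function(tfs, path) {
  writeLines(tfs, path)
  invisible(path)
}

#' Read a gene-to-GO annotation map
#'
#' TSV with two columns: gene id and GO term id, one pair per line.
#' @param path file path.
#' @return data.frame with columns `gene`, `term`.
#' @export
read_go_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "term"),
                          colClasses = "character")
  if (any(!nzchar(df$gene)) || any(!nzchar(df$term))) {
    stop("empty gene or term field in ", path)
  }
  unique(df)
}

#' @rdname read_go_map
#' @param go data.frame with columns `gene`, `term`.
#' @export
write_go_map <- function(go, path) {
  utils::write.table(go[, c("gene", "term")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transfer GO annotations through orthologs
#'
#' Every gene of the target species receives the union of the GO terms of all
#' its orthologs in the source species; genes without annotated orthologs are
#' absent from the result.
#'
#' @param go source-species annotation data.frame (columns `gene`, `term`).
#' @param map an [ortholog_map()].
#' @param from,to source and target species labels.
#' @return data.frame with columns `gene`, `term` for the target species.
#' @export
transfer_annotations <- function(go, map, from, to) {
  stopifnot(nrow(go) > 0)
  tab <- ortholog_table(map, from = to, to = from)  # target gene -> source orthologs
  terms_by_gene <- split(go$term, go$gene)
  out <- lapply(names(tab), function(g) {
    terms <- unique(unlist(terms_by_gene[tab[[g]]], use.names = FALSE))
    if (length(terms) == 0) return(NULL)
    data.frame(gene = g, term = terms, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(gene = character(0), term = character(0)) else out
}

#' Write a network edge list
#'
#' TSV with columns `source`, `target`, `clr_score`, `directed` (0/1). The
#' undirected co-expression edges are written with directed = 0; the derived
#' regulation edges are recoverable from the TF list, so only the undirected
#' view is serialized.
#'
#' @param net a `gene_network`.
#' @param path file path.
#' @export
write_network <- function(net, path) {
  df <- data.frame(source = net$edges$from, target = net$edges$to,
                   clr_score = format(net$edges$score, digits = 17, trim = TRUE),
                   directed = 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("source\ttarget\tclr_score\tdirected", con)
  if (nrow(df) > 0) {
    writeLines(paste(df$source, df$target, df$clr_score, df$directed,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network edge list written by [write_network()]
#'
#' @param path file path.
#' @param tf_ids TF identifiers used to rebuild the directed regulation view.
#' @param universe optional full gene universe (isolated genes included);
#'   defaults to the genes present in the edge list.
#' @param threshold CLR threshold recorded on the returned network.
#' @return A `gene_network`.
#' @export
read_network <- function(path, tf_ids = character(0), universe = NULL,
                         threshold = NA_real_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "numeric", "integer"))
  genes <- universe %||% sort(unique(c(df$source, df$target)))
  new_gene_network(genes, df$source, df$target, df$clr_score, tf_ids, threshold)
}
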