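#' Ortholog map
#'
#' Container for cross-species ortholog groups in the OrthoMCL sense: genes in
#' the same group from different species are predicted orthologs, genes in the
#' same group from the same species are predicted paralogs. Optionally carries
#' per-pair BLAST bit-scores used to rank a gene's orthologs by sequence
#' similarity.
#'
#' @param members data.frame with columns `group`, `species`, `gene`. Each
#'   (species, gene) pair may appear in at most one group.
#' @param bitscores optional data.frame with columns `gene_a`, `gene_b`,
#'   `score` (symmetric; one row per unordered pair suffices).
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(members, bitscores = NULL) {
  stopifnot(is.data.frame(members))
  if (nrow(members) > 0) {
    stopifnot(all(c("group", "species", "gene") %in% names(members)))
    key <- paste(members$species, members$gene, sep = "|")
    dup <- duplicated(key)
    if (any(dup)) {
      bad <- unique(key[dup])
      # same (species, gene) twice in one group is harmless duplication; in
      # two different groups it violates the partition invariant
      per_gene_groups <- tapply(members$group, key, function(g) length(unique(g)))
      if (any(per_gene_groups > 1)) {
        stop("gene(s) present in more than one ortholog group: ",
             paste(names(per_gene_groups)[per_gene_groups > 1], collapse = ", "))
      }
      members <- members[!dup, , drop = FALSE]
    }
  }
  bs <- NULL
  if (!is.null(bitscores) && nrow(bitscores) > 0) {
    stopifnot(all(c("gene_a", "gene_b", "score") %in% names(bitscores)))
    bs <- bitscores$score
    names(bs) <- edge_key(bitscores$gene_a, bitscores$gene_b)
  }
  gene_group <- stats::setNames(members$group, members$gene)
  structure(
    list(members = members, gene_group = gene_group, bitscores = bs),
    class = "ortholog_map"
  )
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("Ortholog map:", length(unique(x$members$group)), "groups,",
      nrow(x$members), "members,",
      length(unique(x$members$species)), "species\n")
  invisible(x)
}

group_of <- function(map, gene) {
  g <- map$gene_group[names(map$gene_group) == gene]
  if (length(unique(g)) > 1) {
    stop("gene id '", gene, "' is ambiguous across species in this map")
  }
  if (length(g) == 0) NA_character_ else unname(g[1])
}

#' Predicted orthologs of a gene
#'
#' Genes in the same ortholog group as `gene` but from a different species
#' (optionally restricted to one target species).
#'
#' @param map an [ortholog_map()].
#' @param gene gene identifier.
#' @param species optional target species label.
#' @return Character vector of gene ids (empty if the gene is in no group).
#' @export
orthologs <- function(map, gene, species = NULL) {
  grp <- group_of(map, gene)
  if (is.na(grp)) return(character(0))
  m <- map$members[map$members$group == grp, , drop = FALSE]
  own_species <- m$species[m$gene == gene][1]
  out <- m[m$species != own_species, , drop = FALSE]
  if (!is.null(species)) out <- out[out$species == species, , drop = FALSE]
  unique(out$gene)
}

#' Predicted paralogs of a gene
#'
#' Genes in the same ortholog group as `gene` and from the same species.
#'
#' @inheritParams orthologs
#' @return Character vector of gene ids.
#' @export
paralogs <- function(map, gene) {
  grp <- group_of(map, gene)
  if (is.na(grp)) return(character(0))
  m <- map$members[map$members$group == grp, , drop = FALSE]
  own_species <- m$species[m$gene == gene][1]
  setdiff(unique(m$gene[m$species == own_species]), gene)
}

#' BLAST bit-score for a gene pair
#'
#' Missing scores are returned as `NA`; callers ranking orthologs by
#' similarity must treat `NA` as "least similar", never as a tie for best.
#'
#' @inheritParams orthologs
#' @param gene_a,gene_b gene identifiers.
#' @return Numeric bit-score or `NA`.
#' @export
bitscore <- function(map, gene_a, gene_b) {
  if (is.null(map$bitscores)) return(NA_real_)
  v <- map$bitscores[edge_key(gene_a, gene_b)]
  unname(v)
}

#' All genes of a species present in the map
#' @inheritParams orthologs
#' @return Character vector of gene ids.
#' @export
map_genes <- function(map, species) {
  unique(map$members$gene[map$members$species == species])
}

# fast lookup table: for every gene of species `to` in the map, nothing; we
# need the reverse: given genes in species `from`, their orthologs in `to`.
# Returns a named list gene -> character vector.
ortholog_table <- function(map, from, to) {
  m <- map$members
  from_m <- m[m$species == from, , drop = FALSE]
  to_m <- m[m$species == to, , drop = FALSE]
  to_by_group <- split(to_m$gene, to_m$group)
  res <- to_by_group[from_m$group]
  names(res) <- from_m$gene
  res[!vapply(res, is.null, logical(1))]
}
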