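#' @title Multilocus placement of a focal genome
#' @name mlsa_phylogeny
#' @description Housekeeping genes shared between a focal genome bin and a
#'   panel of reference genomes are selected by a strict-majority rule,
#'   concatenated in a fixed order, and compared with an alignment-free
#'   k-mer set distance; a neighbor-joining tree then places the focal
#'   genome among the references. This is a reproducible, qualitative
#'   placement: it does not attempt maximum-likelihood inference.
NULL

#' Build a gene presence matrix
#'
#' @param gene_sets named list (one element per genome) of named character
#'   vectors mapping housekeeping gene symbol to nucleotide sequence.
#' @return a `GenePresenceMatrix`: list with `genomes`, `genes` (union, in
#'   first-seen order), `present` (logical genomes x genes matrix) and
#'   `sequences` (the input list).
#' @export
gene_presence_matrix <- function(gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  genes <- unique(unlist(lapply(gene_sets, names), use.names = FALSE))
  genomes <- names(gene_sets)
  present <- t(vapply(gene_sets, function(gs) genes %in% names(gs),
                      logical(length(genes))))
  dimnames(present) <- list(genomes, genes)
  structure(list(genomes = genomes, genes = genes, present = present,
                 sequences = gene_sets),
            class = "GenePresenceMatrix")
}

#' Select housekeeping genes shared with the majority of references
#'
#' A gene is selected when it is present in the focal genome AND in
#' strictly more than `majority_fraction` of the non-focal genomes (a gene
#' found in exactly half of the references is excluded). Output preserves
#' the matrix gene order, so concatenation is stable across runs.
#'
#' @param matrix a `GenePresenceMatrix`.
#' @param focal genome id of the focal bin.
#' @param majority_fraction exclusive reference-presence threshold
#'   (default 0.5 — strict majority).
#' @return character vector of selected gene symbols.
#' @export
select_housekeeping_genes <- function(matrix, focal, majority_fraction = 0.5) {
  stopifnot(is(matrix, "GenePresenceMatrix"))
  if (!focal %in% matrix$genomes) stop("focal genome not in matrix: ", focal)
  refs <- setdiff(matrix$genomes, focal)
  if (!length(refs)) stop("no reference genomes")
  frac <- colMeans(matrix$present[refs, , drop = FALSE])
  sel <- matrix$genes[matrix$present[focal, ] & frac > majority_fraction]
  if (!length(sel))
    stop("no housekeeping gene is shared between '", focal,
         "' and the majority of references; add more reference genomes")
  sel
}

#' Concatenate selected genes per genome
#'
#' Joins each genome's copies of the selected genes in the given order.
#' Genomes missing any selected gene are dropped with a warning naming
#' them (a concatenate with holes is not comparable).
#'
#' @param matrix a `GenePresenceMatrix`.
#' @param genes gene symbols to concatenate, in order.
#' @return named character vector of concatenated sequences.
#' @export
concatenate_genes <- function(matrix, genes) {
  stopifnot(is(matrix, "GenePresenceMatrix"), length(genes) >= 1L)
  pres <- vapply(genes, function(g)
    if (g %in% matrix$genes) matrix$present[, g] else
      rep(FALSE, length(matrix$genomes)), logical(length(matrix$genomes)))
  pres <- base::matrix(pres, nrow = length(matrix$genomes))
  has_all <- rowSums(pres) == length(genes)
  dropped <- matrix$genomes[!has_all]
  if (length(dropped))
    warning("dropping genomes missing selected genes: ",
            paste(dropped, collapse = ", "))
  keep <- matrix$genomes[has_all]
  if (!length(keep)) stop("all genomes missing at least one selected gene")
  vapply(matrix$sequences[keep],
         function(gs) paste(unlist(gs[genes]), collapse = ""), "")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Alignment-free k-mer set distance
#'
#' Jaccard index `j` of the two k-mer sets, transformed to an
#' evolutionary-distance-like scale by `-(1/k) * ln(2j / (1 + j))`
#' (the Mash-style transform). Disjoint k-mer sets (`j = 0`) map to the
#' configured cap.
#'
#' @param a,b nucleotide sequences (character scalars), each of length
#'   at least `k`.
#' @param k k-mer size (default 12).
#' @param cap distance assigned when the k-mer sets are disjoint
#'   (default 1).
#' @return non-negative scalar.
#' @export
kmer_distance <- function(a, b, k = 12, cap = 1.0) {
  if (nchar(a) < k || nchar(b) < k)
    stop("sequence shorter than k = ", k)
  sa <- kmer_set(a, k); sb <- kmer_set(b, k)
  j <- length(intersect(sa, sb)) / length(union(sa, sb))
  if (j == 0) return(cap)
  max(0, -(1 / k) * log(2 * j / (1 + j)))
}

#' Pairwise k-mer distance matrix
#'
#' @param seqs named character vector of sequences.
#' @inheritParams kmer_distance
#' @return symmetric numeric matrix with zero diagonal.
#' @export
mlsa_distance_matrix <- function(seqs, k = 12, cap = 1.0) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n))
    d[i, j] <- d[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], k, cap)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration over a symmetric distance
#' matrix; negative branch lengths (an NJ artifact on non-additive input)
#' are clamped to zero.
#'
#' @param d symmetric numeric matrix with labels, at least 3 taxa.
#' @return an unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Run the multilocus placement end to end
#'
#' Gene selection, concatenation, k-mer distances and neighbor joining in
#' one call; optionally writes the tree in newick format.
#'
#' @param gene_sets as for [gene_presence_matrix()].
#' @param focal focal genome id.
#' @param genes optional restriction of the candidate gene set.
#' @param majority_fraction see [select_housekeeping_genes()].
#' @param k,cap see [kmer_distance()].
#' @param newick_path optional output path for the tree.
#' @return list with `selected_genes`, `concatenated`, `distances`, `tree`.
#' @export
run_mlsa <- function(gene_sets, focal, genes = NULL, majority_fraction = 0.5,
                     k = 12, cap = 1.0, newick_path = NULL) {
  gpm <- gene_presence_matrix(gene_sets)
  if (!is.null(genes)) {
    gpm$genes <- intersect(gpm$genes, genes)
    gpm$present <- gpm$present[, gpm$genes, drop = FALSE]
  }
  sel <- select_housekeeping_genes(gpm, focal, majority_fraction)
  concat <- concatenate_genes(gpm, sel)
  d <- mlsa_distance_matrix(concat, k, cap)
  tr <- nj_tree(d)
  if (!is.null(newick_path)) ape::write.tree(tr, newick_path)
  list(selected_genes = sel, concatenated = concat, distances = d, tree = tr)
}
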