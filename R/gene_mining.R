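#' Default benzoyl-CoA pathway gene pattern table
#'
#' One row per matching pattern, several per canonical gene. Patterns are
#' case-insensitive regular expressions applied to the annotation's gene
#' symbol (`symbol_pattern`) or product description (`product_pattern`).
#' The table covers the anaerobic benzoyl-CoA degradation route from the
#' activation steps (benzoate-CoA ligase badA; 4-hydroxybenzoyl-CoA
#' reductase hcrABC) through both dearomatizing reductase systems — the
#' class-I ATP-dependent bcrABCD of facultative anaerobes and the class-II
#' ATP-independent bamB of obligate anaerobes — to the ring-opening steps
#' ending at 3-hydroxypimeloyl-CoA (dch, had, oah). More specific patterns
#' come first; the first matching row wins for each annotation.
#'
#' @param path optional TSV overriding the bundled table; must carry columns
#'   `pathway_gene, symbol_pattern, product_pattern, pathway_role`.
#' @return data.frame pattern table.
#' @export
default_gene_patterns <- function(path = NULL) {
  if (!is.null(path)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("pathway_gene", "symbol_pattern", "product_pattern", "pathway_role")
    if (!all(need %in% names(tab)))
      stop("pattern table must have columns: ", paste(need, collapse = ", "))
    return(tab[need])
  }
  row <- function(gene, sym, prod, role)
    data.frame(pathway_gene = gene, symbol_pattern = sym,
               product_pattern = prod, pathway_role = role,
               stringsAsFactors = FALSE)
  rbind(
    row("bcrA", "^bcrA($|_)", "benzoyl.?CoA reductase subunit (A|alpha)\\b",
        "class_I_reductase"),
    row("bcrB", "^bcrB($|_)", "benzoyl.?CoA reductase subunit (B|beta)\\b",
        "class_I_reductase"),
    row("bcrC", "^bcrC($|_)", "benzoyl.?CoA reductase subunit (C|gamma)\\b",
        "class_I_reductase"),
    row("bcrD", "^bcrD($|_)", "benzoyl.?CoA reductase subunit (D|delta)\\b",
        "class_I_reductase"),
    row("bamB", "^bamB($|_)",
        "(class.?II benzoyl.?CoA reductase|benzoyl.?CoA reductase.*BamB)",
        "class_II_reductase"),
    row("badA", "^badA($|_)", "benzoate.?-?CoA ligase", "upstream_activation"),
    row("hcrA", "^hcrA($|_)",
        "4.?hydroxybenzoyl.?CoA reductase subunit (alpha|A)\\b",
        "upstream_activation"),
    row("hcrB", "^hcrB($|_)",
        "4.?hydroxybenzoyl.?CoA reductase subunit (beta|B)\\b",
        "upstream_activation"),
    row("hcrC", "^hcrC($|_)",
        "4.?hydroxybenzoyl.?CoA reductase subunit (gamma|C)\\b",
        "upstream_activation"),
    row("dch", "^(dch|badK)($|_)",
        "cyclohexa.?1,5.?diene.?1.?carbonyl.?CoA hydratase",
        "downstream_ring_cleavage"),
    row("had", "^(had|badH)($|_)",
        "6.?hydroxycyclohex.?1.?ene.?1.?carbonyl.?CoA dehydrogenase",
        "downstream_ring_cleavage"),
    row("oah", "^(oah|bamA|badI)($|_)",
        "6.?oxocyclohex.?1.?ene.?1?.?carbonyl.?CoA hydrolase",
        "downstream_ring_cleavage"))
}

CLASS_I_GENES <- c("bcrA", "bcrB", "bcrC", "bcrD")
REDUCTASE_GENES <- c(CLASS_I_GENES, "bamB")

#' Scan annotations for benzoyl-CoA pathway genes
#'
#' Each annotation is matched against the pattern table: gene symbols are
#' tried first across the whole table, then product descriptions; the first
#' matching row (table order) assigns the canonical pathway gene, so every
#' annotation yields at most one hit. Matching is case-insensitive.
#'
#' @param assembly an `Assembly` with annotations attached.
#' @param patterns pattern table, see [default_gene_patterns()].
#' @return data.frame of hits: `contig_id, pathway_gene, pathway_role,
#'   feature_type, gene_symbol, product, start, end, strand`.
#' @export
scan_annotations <- function(assembly, patterns = default_gene_patterns()) {
  stopifnot(is(assembly, "Assembly"))
  if (!nrow(patterns)) stop("empty gene pattern table")
  ann <- assembly$annotations
  if (!nrow(ann))
    return(data.frame(contig_id = character(), pathway_gene = character(),
                      pathway_role = character(), feature_type = character(),
                      gene_symbol = character(), product = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  assigned <- rep(NA_integer_, nrow(ann))
  for (i in seq_len(nrow(patterns))) {  # pass 1: gene symbols
    hit <- is.na(assigned) & nzchar(ann$gene_symbol) &
      grepl(patterns$symbol_pattern[i], ann$gene_symbol, ignore.case = TRUE)
    assigned[hit] <- i
  }
  for (i in seq_len(nrow(patterns))) {  # pass 2: product text
    hit <- is.na(assigned) & nzchar(ann$product) &
      grepl(patterns$product_pattern[i], ann$product, ignore.case = TRUE)
    assigned[hit] <- i
  }
  keep <- which(!is.na(assigned))
  out <- ann[keep, , drop = FALSE]
  out$pathway_gene <- patterns$pathway_gene[assigned[keep]]
  out$pathway_role <- patterns$pathway_role[assigned[keep]]
  rownames(out) <- NULL
  out[c("contig_id", "pathway_gene", "pathway_role", "feature_type",
        "gene_symbol", "product", "start", "end", "strand")]
}

#' Marker-gene frequency per million CDS
#'
#' Normalizes a hit count by the assembly's coding-sequence total, the way
#' marker abundance is compared across metagenomes of different size:
#' `count / total_cds * 1e6`.
#'
#' @param hits hit table from [scan_annotations()].
#' @param total_cds number of CDS features in the assembly (> 0).
#' @param gene_subset canonical symbols to count; defaults to bcrABCD.
#' @return non-negative scalar.
#' @export
hits_per_million_cds <- function(hits, total_cds, gene_subset = CLASS_I_GENES) {
  if (!is.numeric(total_cds) || length(total_cds) != 1L || total_cds <= 0)
    stop("total_cds must be a positive count")
  sum(hits$pathway_gene %in% gene_subset) / total_cds * 1e6
}

#' Select anchor contigs for binning
#'
#' An anchor must carry at least one hit among the required marker genes
#' (class-I benzoyl-CoA reductase subunits bcrABCD by default) and pass two
#' strict filters: length greater than `min_length_bp` and coverage greater
#' than `min_coverage`. Class-II (bamB) hits never qualify a contig as an
#' anchor. Anchors are returned in descending length order (ties by id).
#'
#' @param assembly an `Assembly`.
#' @param hits hit table from [scan_annotations()].
#' @param min_length_bp exclusive length floor in bp (default 7000).
#' @param min_coverage exclusive coverage floor (default 5).
#' @param required_genes marker genes that qualify an anchor.
#' @return an `AnchorSet`: list with `assembly_id`, `anchors` (contig ids)
#'   and `filter_params`.
#' @export
select_anchor_contigs <- function(assembly, hits,
                                  min_length_bp = 7000,
                                  min_coverage = 5,
                                  required_genes = CLASS_I_GENES) {
  stopifnot(is(assembly, "Assembly"))
  cand_ids <- unique(hits$contig_id[hits$pathway_gene %in% required_genes])
  ctg <- assembly$contigs[match(cand_ids, assembly$contigs$contig_id), , drop = FALSE]
  no_cov <- cand_ids[is.na(ctg$coverage)]
  if (length(no_cov))
    stop("anchor candidate contig lacks coverage: ",
         paste(no_cov, collapse = ", "),
         " (supply SPAdes-style headers or a coverage sidecar table)")
  pass <- ctg$length > min_length_bp & ctg$coverage > min_coverage
  ctg <- ctg[pass, , drop = FALSE]
  ord <- order(-ctg$length, ctg$contig_id)
  structure(list(assembly_id = assembly$assembly_id,
                 anchors = ctg$contig_id[ord],
                 filter_params = list(min_length_bp = min_length_bp,
                                      min_coverage = min_coverage,
                                      required_genes = required_genes)),
            class = "AnchorSet")
}

#' Mine an assembly for anchors in one step
#'
#' Convenience wrapper: [scan_annotations()] followed by
#' [select_anchor_contigs()].
#'
#' @inheritParams select_anchor_contigs
#' @inheritParams scan_annotations
#' @return list with `hits` and `anchor_set`.
#' @export
mine_anchors <- function(assembly, patterns = default_gene_patterns(),
                         min_length_bp = 7000, min_coverage = 5,
                         required_genes = CLASS_I_GENES) {
  hits <- scan_annotations(assembly, patterns)
  list(hits = hits,
       anchor_set = select_anchor_contigs(assembly, hits, min_length_bp,
                                          min_coverage, required_genes))
}
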