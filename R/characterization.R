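#' N50 of a set of contig lengths
#'
#' The contig length at which the cumulative sum of descending-sorted
#' lengths first reaches at least half of the total length (the standard
#' assembly-statistics convention). Always a member of the input multiset.
#'
#' @param lengths positive integer vector of contig lengths.
#' @return scalar N50 in bp.
#' @examples
#' n50(c(500, 400, 300, 200, 100))  # 400
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Summary statistics for a genome bin
#'
#' Computes the bin report statistics block: total length, contig count,
#' mean/median contig length (median uses the midpoint convention for even
#' counts), N50, maximum contig length, and pooled GC content. GC is
#' `100 * (G + C) / (A + C + G + T)` over all member sequences; ambiguous
#' bases count in neither numerator nor denominator, so N-rich contigs do
#' not bias the estimate.
#'
#' @param bin a `GenomeBin`.
#' @param assembly the parent `Assembly`.
#' @return a `BinReport`: list of the statistics fields plus empty slots
#'   for marker tallies and classifications (see [characterize_bin()]).
#' @export
bin_summary <- function(bin, assembly) {
  ids <- bin$member_ids
  if (!length(ids)) stop("empty bin: ", bin$bin_id)
  missing <- setdiff(ids, assembly$contigs$contig_id)
  if (length(missing))
    stop("bin members not in assembly: ", paste(missing, collapse = ", "))
  len <- assembly$contigs$length[match(ids, assembly$contigs$contig_id)]
  base_counts <- colSums(Biostrings::letterFrequency(
    assembly$sequences[ids], letters = c("A", "C", "G", "T")))
  gc <- 100 * sum(base_counts[c("C", "G")]) / sum(base_counts)
  structure(list(bin_id = bin$bin_id,
                 total_length_bp = sum(len),
                 total_contigs = length(ids),
                 mean_contig_bp = mean(len),
                 median_contig_bp = stats::median(len),
                 n50_bp = n50(len),
                 max_contig_bp = max(len),
                 gc_percent = gc,
                 marker_tallies = NULL,
                 pathway_class = NA_character_,
                 draft_quality = NA_character_),
            class = "BinReport")
}

#' Tally pathway-gene hits inside a bin
#'
#' Restricts an assembly-wide hit table to the bin's member contigs and
#' counts one per hit for every canonical pathway gene in the pattern
#' table (zeros included).
#'
#' @param bin a `GenomeBin`.
#' @param hits hit table from [scan_annotations()].
#' @param patterns pattern table defining the tally vocabulary.
#' @return named integer vector, one entry per canonical pathway gene.
#' @export
pathway_presence <- function(bin, hits, patterns = default_gene_patterns()) {
  genes <- unique(patterns$pathway_gene)
  inside <- hits[hits$contig_id %in% bin$member_ids, , drop = FALSE]
  tab <- table(factor(inside$pathway_gene, levels = genes))
  setNames(as.integer(tab), genes)
}

#' Default core steps of the benzoyl-CoA degradation route
#'
#' The ordered enzymatic steps from benzoyl-CoA to 3-hydroxypimeloyl-CoA.
#' The dearomatizing reductase step is satisfied by any class-I subunit
#' (bcrABCD) or the class-II bamB; the remaining steps are the modified
#' beta-oxidation ring-opening enzymes.
#'
#' @return named list; each element is the set of gene symbols satisfying
#'   that step.
#' @export
core_pathway_steps <- function() {
  list(reductase = REDUCTASE_GENES, dch = "dch", had = "had", oah = "oah")
}

#' Classify benzoyl-CoA pathway completeness
#'
#' `complete` when every core step has at least one gene tallied;
#' `near_complete` when exactly one step is missing; `partial` when at
#' least one step is present but two or more are missing; `absent` when no
#' step is present. Presence of any dearomatizing reductase (bcrABCD or
#' bamB) is additionally reported alongside.
#'
#' @param tallies named counts from [pathway_presence()].
#' @param core_set step definition, see [core_pathway_steps()].
#' @return list with `pathway_class`, `missing_steps`, `has_reductase`.
#' @export
classify_pathway <- function(tallies, core_set = core_pathway_steps()) {
  if (!length(core_set)) stop("empty core step set")
  step_present <- vapply(core_set, function(genes) {
    sum(tallies[intersect(genes, names(tallies))]) > 0
  }, TRUE)
  n_missing <- sum(!step_present)
  cls <- if (n_missing == 0L) "complete"
         else if (n_missing == 1L) "near_complete"
         else if (any(step_present)) "partial"
         else "absent"
  list(pathway_class = cls,
       missing_steps = names(core_set)[!step_present],
       has_reductase = sum(tallies[intersect(REDUCTASE_GENES,
                                             names(tallies))]) > 0)
}

#' Classify draft genome quality
#'
#' Follows the community draft-quality convention for MAGs: a high-quality
#' draft needs > 90% completeness, < 5% contamination, a recovered 16S
#' rRNA gene and at least 18 tRNAs; a medium-quality draft needs >= 50%
#' completeness and < 10% contamination; anything else is low quality.
#' Completeness and contamination are consumed as external scores; when
#' absent the bin is unevaluable.
#'
#' @param completeness,contamination external scores in percent.
#' @param has_16s logical; was a 16S rRNA gene recovered in the bin?
#' @param trna_count number of distinct tRNAs recovered.
#' @return one of `"high"`, `"medium"`, `"low"`, `"unevaluable"`.
#' @export
classify_draft_quality <- function(completeness, contamination,
                                   has_16s = FALSE, trna_count = 0L) {
  if (is.na(completeness) || is.na(contamination)) return("unevaluable")
  if (completeness > 90 && contamination < 5 && isTRUE(has_16s) &&
      trna_count >= 18) return("high")
  if (completeness >= 50 && contamination < 10) return("medium")
  "low"
}

#' Full bin report
#'
#' Combines [bin_summary()], [pathway_presence()], [classify_pathway()]
#' and [classify_draft_quality()] into one `BinReport`.
#'
#' @inheritParams bin_summary
#' @inheritParams pathway_presence
#' @inheritParams classify_draft_quality
#' @return a complete `BinReport`.
#' @export
characterize_bin <- function(bin, assembly, hits,
                             patterns = default_gene_patterns(),
                             completeness = NA_real_,
                             contamination = NA_real_,
                             has_16s = FALSE, trna_count = 0L) {
  rep <- bin_summary(bin, assembly)
  rep$marker_tallies <- pathway_presence(bin, hits, patterns)
  pw <- classify_pathway(rep$marker_tallies)
  rep$pathway_class <- pw$pathway_class
  rep$has_reductase <- pw$has_reductase
  rep$completeness <- completeness
  rep$contamination <- contamination
  rep$draft_quality <- classify_draft_quality(completeness, contamination,
                                              has_16s, trna_count)
  rep
}

#' @export
print.BinReport <- function(x, ...) {
  cat(sprintf(paste0("BinReport '%s': %.2f Mbp in %d contigs, N50 %d bp, ",
                     "GC %.1f%%, pathway %s, quality %s\n"),
              x$bin_id, x$total_length_bp / 1e6, x$total_contigs, x$n50_bp,
              x$gc_percent, x$pathway_class, x$draft_quality))
  invisible(x)
}

#' Combined report table for several bins
#'
#' One row per bin with lengths reported in Mbp at two decimals (raw bp
#' stay in the individual reports).
#'
#' @param reports list of `BinReport`.
#' @return data.frame.
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(bin_id = r$bin_id,
               total_length_mbp = round(r$total_length_bp / 1e6, 2),
               total_contigs = r$total_contigs,
               mean_contig_mbp = round(r$mean_contig_bp / 1e6, 2),
               median_contig_mbp = round(r$median_contig_bp / 1e6, 2),
               n50_mbp = round(r$n50_bp / 1e6, 2),
               max_contig_mbp = round(r$max_contig_bp / 1e6, 2),
               gc_percent = round(r$gc_percent, 1),
               total_bcr_subunits = if (is.null(r$marker_tallies)) NA_integer_
                 else sum(r$marker_tallies[intersect(CLASS_I_GENES,
                                                     names(r$marker_tallies))]),
               pathway_class = r$pathway_class,
               draft_quality = r$draft_quality,
               stringsAsFactors = FALSE)
  }))
}
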