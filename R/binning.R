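#' @title Trinucleotide-signature binning
#' @name composition_binning
#' @description A contig's compositional fingerprint is the proportion of
#'   each of the 64 possible trinucleotides among its overlapping 3-bp
#'   windows, taken on the strand as written (no reverse-complement
#'   collapsing, so the vector keeps all 64 dimensions). Windows containing
#'   any non-ACGT character are skipped entirely, which keeps the vector a
#'   true probability distribution. Contigs are assigned to a bin when their
#'   signature's Pearson correlation with an anchor signature exceeds a
#'   strict threshold (default R > 0.95), over the candidate universe of
#'   contigs of at least 1000 bp.
NULL

TRIMERS <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3L)

#' Trinucleotide proportion signature of one contig
#'
#' @param sequence a [Biostrings::DNAString], single-element DNAStringSet,
#'   or character scalar.
#' @param contig_id optional identifier carried on the result.
#' @return a `TrimerSignature`: list with `contig_id`, `proportions` (named
#'   64-vector summing to 1) and `valid_windows`.
#' @examples
#' sig <- trimer_signature("ACGTACGT")
#' sig$proportions[sig$proportions > 0]
#' @export
trimer_signature <- function(sequence, contig_id = NA_character_) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (is(sequence, "DNAStringSet")) sequence <- sequence[[1L]]
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = 3L)
  n <- sum(counts)
  if (n == 0L)
    stop("degenerate trimer signature for contig '", contig_id,
         "': no valid ACGT 3-mer window (length < 3 or all windows ambiguous)")
  structure(list(contig_id = contig_id,
                 proportions = counts / n,
                 valid_windows = as.integer(n)),
            class = "TrimerSignature")
}

#' Trimer signature matrix for an assembly
#'
#' Computes signatures for every contig of at least `min_len` bp in one
#' vectorized pass. Contigs without any valid window are dropped with a
#' warning (they cannot take part in correlation binning).
#'
#' @param assembly an `Assembly`.
#' @param min_len inclusive candidate length floor in bp (default 1000).
#' @return numeric matrix, one row per contig (rownames = contig ids), 64
#'   columns in lexicographic trimer order; attribute `valid_windows`.
#' @export
signature_matrix <- function(assembly, min_len = 1000) {
  stopifnot(is(assembly, "Assembly"))
  keep <- assembly$contigs$length >= min_len
  seqs <- assembly$sequences[assembly$contigs$contig_id[keep]]
  if (!length(seqs)) stop("no contigs of at least ", min_len, " bp")
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 3L)
  n <- rowSums(counts)
  if (any(n == 0L)) {
    warning("dropping contigs with no valid 3-mer window: ",
            paste(names(seqs)[n == 0L], collapse = ", "))
    counts <- counts[n > 0L, , drop = FALSE]
    seqs <- seqs[n > 0L]
    n <- n[n > 0L]
  }
  prop <- counts / n
  rownames(prop) <- names(seqs)
  attr(prop, "valid_windows") <- as.integer(n)
  prop
}

as_signature_vector <- function(x) {
  if (is(x, "TrimerSignature")) x$proportions else as.numeric(x)
}

#' Pearson correlation between two trimer signatures
#'
#' Standard product-moment correlation over the 64 raw proportion
#' components (no standardization beyond what the correlation itself
#' applies).
#'
#' @param a,b `TrimerSignature` objects or 64-component numeric vectors.
#' @return scalar in \[-1, 1\].
#' @export
pearson_r <- function(a, b) {
  va <- as_signature_vector(a); vb <- as_signature_vector(b)
  stopifnot(length(va) == length(vb))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("undefined correlation: zero-variance signature vector")
  stats::cor(va, vb)
}

new_genome_bin <- function(bin_id, anchor_ids, member_ids, threshold_used,
                           assembly_id) {
  member_ids <- unique(member_ids)
  stopifnot(all(anchor_ids %in% member_ids), length(member_ids) >= 1L)
  structure(list(bin_id = bin_id, anchor_ids = anchor_ids,
                 member_ids = member_ids, threshold_used = threshold_used,
                 assembly_id = assembly_id),
            class = "GenomeBin")
}

#' @export
print.GenomeBin <- function(x, ...) {
  cat(sprintf("GenomeBin '%s': %d contigs (%d anchor%s), R > %.2f, assembly '%s'\n",
              x$bin_id, length(x$member_ids), length(x$anchor_ids),
              if (length(x$anchor_ids) == 1L) "" else "s",
              x$threshold_used, x$assembly_id))
  invisible(x)
}

#' Collect a bin around one anchor contig
#'
#' Members are the anchor plus every contig of at least `min_contig_bp`
#' whose signature correlates with the anchor signature strictly above
#' `r_threshold`. The anchor is always a member (self-correlation is 1).
#'
#' @param anchor_id contig id of the anchor.
#' @param assembly an `Assembly`.
#' @param min_contig_bp inclusive candidate length floor (default 1000).
#' @param r_threshold exclusive Pearson-R threshold (default 0.95).
#' @param sig optional precomputed [signature_matrix()] (at `min_contig_bp`).
#' @param bin_id identifier for the returned bin.
#' @return a `GenomeBin`.
#' @export
bin_by_anchor <- function(anchor_id, assembly, min_contig_bp = 1000,
                          r_threshold = 0.95, sig = NULL,
                          bin_id = paste0("bin_", anchor_id)) {
  if (is.null(sig)) sig <- signature_matrix(assembly, min_contig_bp)
  if (!anchor_id %in% assembly$contigs$contig_id)
    stop("anchor contig not in assembly: ", anchor_id)
  if (!anchor_id %in% rownames(sig)) {
    # anchor below the candidate floor or degenerate: compute directly
    a <- trimer_signature(assembly$sequences[[anchor_id]], anchor_id)$proportions
  } else a <- sig[anchor_id, ]
  if (stats::sd(a) == 0) stop("degenerate anchor signature: ", anchor_id)
  r <- apply(sig, 1L, function(v) if (stats::sd(v) == 0) NA_real_ else stats::cor(a, v))
  members <- unique(c(anchor_id, rownames(sig)[!is.na(r) & r > r_threshold]))
  new_genome_bin(bin_id, anchor_id, members, r_threshold,
                 assembly$assembly_id)
}

#' Build bins from an anchor set
#'
#' Anchors whose mutual signature correlation already exceeds the binning
#' threshold are treated as anchors of one genome and share a bin (member
#' union); otherwise each anchor seeds its own bin. Bins are numbered in
#' anchor-set order.
#'
#' @param anchors an `AnchorSet` or character vector of anchor contig ids.
#' @inheritParams bin_by_anchor
#' @return list of `GenomeBin`.
#' @export
build_bins <- function(anchors, assembly, min_contig_bp = 1000,
                       r_threshold = 0.95, sig = NULL) {
  ids <- if (is(anchors, "AnchorSet")) anchors$anchors else as.character(anchors)
  if (!length(ids)) return(list())
  if (is.null(sig)) sig <- signature_matrix(assembly, min_contig_bp)
  k <- length(ids)
  # group anchors by mutual correlation > threshold (graph components)
  grp <- seq_len(k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
      ri <- tryCatch(pearson_r(sig[ids[i], ], sig[ids[j], ]),
                     error = function(e) NA_real_)
      if (!is.na(ri) && ri > r_threshold) grp[grp == grp[j]] <- grp[i]
    }
  }
  out <- list()
  for (g in unique(grp)) {
    g_ids <- ids[grp == g]
    parts <- lapply(g_ids, bin_by_anchor, assembly = assembly,
                    min_contig_bp = min_contig_bp, r_threshold = r_threshold,
                    sig = sig)
    bin_id <- sprintf("bin_%d", length(out) + 1L)
    out[[bin_id]] <- new_genome_bin(
      bin_id, g_ids, unlist(lapply(parts, `[[`, "member_ids")),
      r_threshold, assembly$assembly_id)
  }
  out
}

#' Remove coverage-aberrant contigs from a bin
#'
#' A reproducible stand-in for manual inspection of per-contig depth: the
#' reference depth is the median coverage of the bin's anchor contigs, and
#' members whose coverage falls outside the symmetric band
#' `[ref / fold, ref * fold]` are removed. Anchors are never removed.
#'
#' @param bin a `GenomeBin`.
#' @param assembly the parent `Assembly`.
#' @param fold band half-width as a fold change, must exceed 1 (default 2.5).
#' @return the filtered `GenomeBin`.
#' @export
coverage_filter <- function(bin, assembly, fold = 2.5) {
  if (!is.numeric(fold) || fold <= 1)
    stop("fold must be > 1 (got ", fold, ")")
  cov <- assembly$contigs$coverage[match(bin$member_ids,
                                         assembly$contigs$contig_id)]
  if (anyNA(cov))
    stop("bin member lacks coverage: ",
         paste(bin$member_ids[is.na(cov)], collapse = ", "))
  ref <- stats::median(cov[bin$member_ids %in% bin$anchor_ids])
  keep <- (cov >= ref / fold & cov <= ref * fold) |
    bin$member_ids %in% bin$anchor_ids
  new_genome_bin(bin$bin_id, bin$anchor_ids, bin$member_ids[keep],
                 bin$threshold_used, bin$assembly_id)
}

#' Group similar bins
#'
#' Pairwise similarity is the Jaccard index of member sets for bins from
#' the same assembly, and the anchors' signature correlation rescaled from
#' \[-1, 1\] to \[0, 1\] via `(r + 1) / 2` for bins from different
#' assemblies (membership sets are incomparable across assemblies).
#' Single-linkage clustering cut at `link_threshold` yields the partition:
#' bins joined whenever similarity >= `link_threshold` along some chain.
#'
#' @param bins list of `GenomeBin`.
#' @param link_threshold similarity at which bins join a group (default 0.5).
#' @param assemblies named list of `Assembly` objects (by assembly id);
#'   required only when bins span more than one assembly.
#' @return list with `groups` (data.frame `bin_id`, `group_id`) and
#'   `similarity` (matrix).
#' @export
compare_bins <- function(bins, link_threshold = 0.5, assemblies = NULL) {
  if (!length(bins)) stop("no bins to compare")
  ids <- vapply(bins, `[[`, "", "bin_id")
  k <- length(bins)
  sim <- matrix(1, k, k, dimnames = list(ids, ids))
  anchor_sig <- function(b) {
    asm <- assemblies[[b$assembly_id]]
    if (is.null(asm))
      stop("cross-assembly comparison needs the 'assemblies' argument")
    trimer_signature(asm$sequences[[b$anchor_ids[1L]]],
                     b$anchor_ids[1L])$proportions
  }
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    a <- bins[[i]]; b <- bins[[j]]
    s <- if (identical(a$assembly_id, b$assembly_id)) {
      length(intersect(a$member_ids, b$member_ids)) /
        length(union(a$member_ids, b$member_ids))
    } else {
      (stats::cor(anchor_sig(a), anchor_sig(b)) + 1) / 2
    }
    sim[i, j] <- sim[j, i] <- s
  }
  group_id <- if (k == 1L) 1L else {
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
    unname(stats::cutree(hc, h = 1 - link_threshold))
  }
  list(groups = data.frame(bin_id = ids,
                           group_id = paste0("group_", group_id),
                           stringsAsFactors = FALSE),
       similarity = sim)
}

#' Flag chimeric or low-quality bins
#'
#' A bin is rejected when it is too large to be a single genome or when
#' externally supplied completeness/contamination scores are unacceptable.
#' The numeric cutoffs are configuration; the defaults reject bins above
#' 8 Mbp, below 50% completeness, or above 5% contamination. Bins without
#' scores are reported unevaluable rather than rejected.
#'
#' @param report a `BinReport` from [bin_summary()] (total length is read
#'   from it).
#' @param completeness,contamination external scores in percent (e.g. from
#'   CheckM), or `NA` when unavailable.
#' @param max_size_mbp,min_completeness,max_contamination cutoffs.
#' @return one of `"acceptable"`, `"chimeric_or_low_quality"`,
#'   `"unevaluable"`.
#' @export
flag_chimeric <- function(report, completeness = NA_real_,
                          contamination = NA_real_, max_size_mbp = 8.0,
                          min_completeness = 50.0, max_contamination = 5.0) {
  if (report$total_length_bp > max_size_mbp * 1e6)
    return("chimeric_or_low_quality")
  if (is.na(completeness) || is.na(contamination)) return("unevaluable")
  if (completeness < min_completeness || contamination > max_contamination)
    return("chimeric_or_low_quality")
  "acceptable"
}
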