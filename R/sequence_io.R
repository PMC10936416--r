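#' @title Assembly container and standard-format readers
#' @name sequence_io
#' @description Readers and writers for the formats the pipeline touches:
#'   assembled contigs in FASTA (SPAdes-style `NODE_<n>_length_<L>_cov_<c>`
#'   headers or a coverage sidecar table), gene annotations in GFF3 or flat
#'   TSV, and per-bin FASTA output. All coordinates are 1-based inclusive,
#'   matching GFF3; sequences are upper-cased on read.
NULL

FEATURE_VOCAB <- c("CDS", "rRNA", "tRNA", "tmRNA")

new_assembly <- function(assembly_id, contigs, sequences,
                         annotations = empty_annotations()) {
  stopifnot(is.character(assembly_id), length(assembly_id) == 1L)
  obj <- structure(
    list(assembly_id = assembly_id,
         contigs = contigs,
         sequences = sequences,
         annotations = annotations,
         total_cds = sum(annotations$feature_type == "CDS")),
    class = "Assembly")
  validate_assembly(obj)
  obj
}

empty_annotations <- function() {
  data.frame(contig_id = character(), feature_type = character(),
             gene_symbol = character(), product = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

validate_assembly <- function(x) {
  ctg <- x$contigs
  if (anyDuplicated(ctg$contig_id))
    stop("duplicate contig_id in assembly: ",
         paste(unique(ctg$contig_id[duplicated(ctg$contig_id)]), collapse = ", "))
  if (any(!nzchar(ctg$contig_id))) stop("empty contig_id")
  if (!identical(ctg$length, unname(Biostrings::width(x$sequences))))
    stop("contig length field disagrees with sequence length")
  if (any(!is.na(ctg$coverage) & ctg$coverage < 0))
    stop("negative coverage")
  ann <- x$annotations
  if (nrow(ann)) {
    bad <- !(ann$contig_id %in% ctg$contig_id)
    if (any(bad))
      stop("annotation references unknown contig: ",
           paste(unique(ann$contig_id[bad]), collapse = ", "))
    len <- ctg$length[match(ann$contig_id, ctg$contig_id)]
    oob <- ann$start < 1L | ann$end < ann$start | ann$end > len
    if (any(oob)) {
      i <- which(oob)[1L]
      stop(sprintf("annotation coordinates outside contig %s: %d-%d (contig length %d)",
                   ann$contig_id[i], ann$start[i], ann$end[i], len[i]))
    }
  }
  invisible(x)
}

#' @export
print.Assembly <- function(x, ...) {
  cat(sprintf("Assembly '%s': %d contigs (%.2f Mbp), %d annotations (%d CDS)\n",
              x$assembly_id, nrow(x$contigs), sum(x$contigs$length) / 1e6,
              nrow(x$annotations), x$total_cds))
  invisible(x)
}

# Parse SPAdes-style headers; returns NA coverage/length for other dialects.
parse_spades_header <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  m <- regmatches(id, regexec("^NODE_\\d+_length_(\\d+)_cov_([0-9.eE+-]+)", id))
  len <- vapply(m, function(g) if (length(g)) as.numeric(g[2L]) else NA_real_, 0)
  cov <- vapply(m, function(g) if (length(g)) as.numeric(g[3L]) else NA_real_, 0)
  data.frame(contig_id = id, header_length = len, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Read assembled contigs into an Assembly
#'
#' Reads a contig FASTA and normalizes coverage metadata. Coverage is parsed
#' from SPAdes-style headers (`NODE_<n>_length_<L>_cov_<c>`) when present; a
#' two-column sidecar table (contig_id, coverage; tab-separated, no header
#' required) overrides header values for the contigs it lists. Contigs with
#' neither source carry `NA` coverage, and downstream anchor selection on
#' such contigs errors rather than guessing. The `length_<L>` header field is
#' cross-checked against the actual sequence length; on disagreement a
#' warning is raised and the actual length wins.
#'
#' @param fasta_path path to a contig FASTA file.
#' @param coverage_table optional path to a sidecar TSV of per-contig depth.
#' @param assembly_id identifier for the assembly; defaults to the file stem.
#' @return An `Assembly`: contig table (`contig_id`, `length`, `coverage`),
#'   the sequences as a [Biostrings::DNAStringSet], and an empty annotation
#'   table (see [read_annotations()] and [set_annotations()]).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">NODE_1_length_8_cov_6.2", "ACGTACGT"), fa)
#' asm <- read_contigs(fa)
#' asm$contigs
#' @export
read_contigs <- function(fasta_path, coverage_table = NULL,
                         assembly_id = sub("\\.[^.]*$", "", basename(fasta_path))) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e) stop("malformed FASTA '", fasta_path,
                                            "': ", conditionMessage(e)))
  hdr <- parse_spades_header(names(seqs))
  names(seqs) <- hdr$contig_id
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  actual_len <- unname(Biostrings::width(seqs))
  mismatch <- !is.na(hdr$header_length) & hdr$header_length != actual_len
  if (any(mismatch))
    warning("header length disagrees with sequence length for ",
            paste(hdr$contig_id[mismatch], collapse = ", "),
            "; using actual sequence length")
  cov <- hdr$coverage
  if (!is.null(coverage_table)) {
    side <- read.delim(coverage_table, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("contig_id", "coverage"))
    if (is.character(side$coverage)) {  # tolerate a header row
      side <- side[suppressWarnings(!is.na(as.numeric(side$coverage))), , drop = FALSE]
      side$coverage <- as.numeric(side$coverage)
    }
    hit <- match(hdr$contig_id, side$contig_id)
    cov[!is.na(hit)] <- side$coverage[hit[!is.na(hit)]]
  }
  contigs <- data.frame(contig_id = hdr$contig_id, length = actual_len,
                        coverage = cov, stringsAsFactors = FALSE)
  new_assembly(assembly_id, contigs, seqs)
}

#' Read gene annotations from GFF3 or flat TSV
#'
#' GFF3 input (detected by a `##gff-version` first line or a .gff/.gff3
#' extension) is parsed with percent-decoding of attribute values; the gene
#' symbol is taken from the `gene` attribute and the description from
#' `product`. TSV input must carry the header
#' `contig_id, feature_type, gene_symbol, product, start, end, strand`.
#' Missing gene symbols become empty strings. Feature types outside
#' CDS/rRNA/tRNA/tmRNA are kept verbatim but never counted toward the CDS
#' total.
#'
#' @param path annotation file (GFF3 or TSV).
#' @return data.frame of annotation records.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L)
  is_gff <- grepl("^##gff-version", first) || grepl("\\.gff3?$", path)
  if (is_gff) {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    get_col <- function(nm) {
      if (nm %in% colnames(md)) {
        v <- as.character(md[[nm]])
        v[is.na(v)] <- ""
        v
      } else rep("", length(gr))
    }
    ann <- data.frame(
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      feature_type = as.character(md$type),
      gene_symbol = get_col("gene"),
      product = get_col("product"),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  } else {
    ann <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig_id", "feature_type", "gene_symbol", "product",
              "start", "end", "strand")
    miss <- setdiff(need, names(ann))
    if (length(miss))
      stop("annotation TSV missing columns: ", paste(miss, collapse = ", "))
    ann <- ann[need]
    ann$gene_symbol[is.na(ann$gene_symbol)] <- ""
    ann$product[is.na(ann$product)] <- ""
  }
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ann
}

#' Attach annotations to an assembly
#'
#' Validates that every record resolves to a contig and lies inside it, then
#' recomputes the CDS total (`total_cds` counts `feature_type == "CDS"`
#' records only, whatever else the table contains).
#'
#' @param assembly an `Assembly`.
#' @param annotations annotation data.frame as from [read_annotations()].
#' @return the updated `Assembly`.
#' @export
set_annotations <- function(assembly, annotations) {
  stopifnot(is(assembly, "Assembly"))
  assembly$annotations <- annotations
  assembly$total_cds <- sum(annotations$feature_type == "CDS")
  validate_assembly(assembly)
  assembly
}

#' Write a bin's contigs to FASTA
#'
#' Emits exactly the bin's member contigs with their original identifiers,
#' in lexicographic contig-id order so output is deterministic.
#'
#' @param bin a `GenomeBin` (see [bin_by_anchor()]).
#' @param assembly the parent `Assembly`.
#' @param out_path output FASTA path.
#' @return `out_path`, invisibly.
#' @export
write_bin_fasta <- function(bin, assembly, out_path) {
  ids <- sort(bin$member_ids)
  missing <- setdiff(ids, assembly$contigs$contig_id)
  if (length(missing))
    stop("bin contig ids not in assembly: ", paste(missing, collapse = ", "))
  if (!length(ids)) {
    warning("writing empty bin '", bin$bin_id, "'")
    file.create(out_path)
    return(invisible(out_path))
  }
  Biostrings::writeXStringSet(assembly$sequences[ids], out_path, width = 80L)
  invisible(out_path)
}
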