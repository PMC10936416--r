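# In-code fixtures and independent oracles shared across test files.

# Build a tiny Assembly from named character sequences.
make_assembly <- function(seqs, coverage = NULL, annotations = NULL,
                          assembly_id = "test_asm") {
  fa <- tempfile(fileext = ".fasta")
  writeLines(unlist(Map(function(id, s) c(paste0(">", id), s),
                        names(seqs), seqs)), fa)
  side <- NULL
  if (!is.null(coverage)) {
    side <- tempfile(fileext = ".tsv")
    write.table(data.frame(names(seqs), coverage), side, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  asm <- read_contigs(fa, coverage_table = side, assembly_id = assembly_id)
  if (!is.null(annotations)) asm <- set_annotations(asm, annotations)
  asm
}

ann_row <- function(contig_id, gene = "", product = "", type = "CDS",
                    start = 1L, end = 90L, strand = "+") {
  data.frame(contig_id = contig_id, feature_type = type, gene_symbol = gene,
             product = product, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# A random ACGT (optionally ambiguous) sequence.
random_seq <- function(n, p_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (p_n > 0) s[runif(n) < p_n] <- "N"
  paste(s, collapse = "")
}

# Brute-force trimer oracle: explicit window walk, independent of Biostrings.
oracle_trimer_counts <- function(seq) {
  trimers <- anchormag:::TRIMERS
  counts <- setNames(rep(0L, 64L), trimers)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) >= 3) for (i in 1:(length(chars) - 2)) {
    w <- paste(chars[i:(i + 2)], collapse = "")
    if (w %in% trimers) counts[w] <- counts[w] + 1L
  }
  counts
}

# Brute-force N50 oracle: enumerate prefixes of the descending-sorted set.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  for (i in seq_along(s)) if (sum(s[1:i]) >= total / 2) return(s[i])
}

# Explicit product-moment formula, independent of stats::cor.
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# Brute-force k-mer set oracle with an index loop.
oracle_kmer_jaccard <- function(a, b, k) {
  km <- function(s) {
    out <- character(0)
    for (i in 1:(nchar(s) - k + 1)) out <- c(out, substr(s, i, i + k - 1))
    unique(out)
  }
  ka <- km(a); kb <- km(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Two-genome community small enough for fast binning tests.
small_two_genome_community <- function(seed = 42L) {
  models <- list(
    gA = genome_model("gA", gc = 0.60, genome_length_bp = 120000,
                      mean_coverage = 8,
                      planted_genes = c(bcrB = 1L), model_seed = 11L),
    gB = genome_model("gB", gc = 0.35, genome_length_bp = 120000,
                      mean_coverage = 20, model_seed = 22L))
  simulate_community(models, seed = seed)
}
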