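#' @title Synthetic metagenome communities with ground truth
#' @name synthetic_community
#' @description Source genomes are sampled from order-2 Markov chains over
#'   {A,C,G,T}: the transition matrix (next base conditional on the
#'   previous dinucleotide) directly controls trinucleotide composition —
#'   exactly the statistic the binning method reads — so compositional
#'   separability between genomes is a generator parameter, not an
#'   accident. Genomes are fragmented into contigs with lognormal lengths,
#'   given noisy per-contig coverage around a genome mean, and a minority
#'   of contigs receive planted benzoyl-CoA pathway gene annotations among
#'   filler CDS calls. Every contig carries a ground-truth genome label.
NULL

DINUCS <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 2L)
BASES <- c("A", "C", "G", "T")

MARKER_PRODUCTS <- c(
  bcrA = "benzoyl-CoA reductase subunit A",
  bcrB = "benzoyl-CoA reductase subunit B",
  bcrC = "benzoyl-CoA reductase subunit C",
  bcrD = "benzoyl-CoA reductase subunit D",
  bamB = "class II benzoyl-CoA reductase subunit BamB",
  badA = "benzoate--CoA ligase",
  hcrA = "4-hydroxybenzoyl-CoA reductase subunit alpha",
  hcrB = "4-hydroxybenzoyl-CoA reductase subunit beta",
  hcrC = "4-hydroxybenzoyl-CoA reductase subunit gamma",
  dch  = "cyclohexa-1,5-diene-1-carbonyl-CoA hydratase",
  had  = "6-hydroxycyclohex-1-ene-1-carbonyl-CoA dehydrogenase",
  oah  = "6-oxocyclohex-1-ene-1-carbonyl-CoA hydrolase")

#' Build an order-2 Markov genome model
#'
#' The transition matrix starts from the base composition implied by the
#' target GC content and is tilted by fixed log-normal perturbations (one
#' draw per transition cell, reproducible from `model_seed`), giving each
#' genome an individual dinucleotide-context preference on top of its GC
#' level. The realized stationary GC therefore differs slightly from
#' `gc`; use [stationary_gc()] for the exact value the chain converges to.
#'
#' @param genome_id genome label.
#' @param gc target GC content in (0, 1).
#' @param genome_length_bp genome size, at least 10 kb.
#' @param mean_coverage genome mean read depth (> 0).
#' @param planted_genes named integer vector: pathway gene -> copy count.
#' @param tilt sd of the log-scale perturbation (0 = i.i.d. base model).
#' @param model_seed seed fixing the perturbation draw.
#' @return a `GenomeModel` list.
#' @export
genome_model <- function(genome_id, gc, genome_length_bp, mean_coverage,
                         planted_genes = integer(), tilt = 0.35,
                         model_seed = 1L) {
  stopifnot(gc > 0, gc < 1, genome_length_bp >= 10000, mean_coverage > 0)
  base <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  set.seed(model_seed)
  pert <- matrix(exp(stats::rnorm(64L, 0, tilt)), 16L, 4L)
  tm <- sweep(pert, 2L, base, `*`)
  tm <- tm / rowSums(tm)
  dimnames(tm) <- list(DINUCS, BASES)
  structure(list(genome_id = genome_id, markov_order = 2L, transition = tm,
                 genome_length_bp = as.integer(genome_length_bp),
                 mean_coverage = mean_coverage,
                 planted_genes = planted_genes),
            class = "GenomeModel")
}

validate_transition <- function(tm) {
  if (!is.matrix(tm) || !all(dim(tm) == c(16L, 4L)) ||
      any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0))
    stop("invalid transition matrix: must be 16x4 with rows summing to 1")
  invisible(tm)
}

# Stationary distribution over the 16 dinucleotide states of the chain.
stationary_dinuc <- function(model) {
  tm <- validate_transition(model$transition)
  P <- matrix(0, 16L, 16L, dimnames = list(DINUCS, DINUCS))
  for (s in seq_len(16L)) {
    b <- (s - 1L) %% 4L + 1L          # second base of state s
    for (z in seq_len(4L)) P[s, (b - 1L) * 4L + z] <- tm[s, z]
  }
  pi2 <- rep(1 / 16, 16L)
  for (i in seq_len(400L)) pi2 <- pi2 %*% P
  drop(pi2 / sum(pi2))
}

#' Stationary GC content of a genome model
#'
#' GC fraction of the Markov chain's stationary base distribution; the
#' oracle a long sampled genome converges to.
#'
#' @param model a `GenomeModel`.
#' @return scalar in (0, 1).
#' @export
stationary_gc <- function(model) {
  pi2 <- stationary_dinuc(model)
  second <- rep(BASES, times = 4L)
  sum(pi2[second %in% c("C", "G")])
}

#' Stationary trimer signature implied by a genome model
#'
#' The 64-component trinucleotide distribution of the chain at
#' stationarity: `p(xyz) = pi(xy) * T[xy, z]`. Signatures of sampled
#' genomes converge to this vector as length grows.
#'
#' @param model a `GenomeModel`.
#' @return named 64-vector summing to 1, lexicographic trimer order.
#' @export
stationary_trimer_signature <- function(model) {
  pi2 <- stationary_dinuc(model)
  p <- as.vector(t(model$transition * pi2))  # row-major: state-major order
  names(p) <- paste0(rep(DINUCS, each = 4L), BASES)
  p[TRIMERS] / sum(p)
}

#' Sample a genome sequence from a model
#'
#' @param model a `GenomeModel`.
#' @param seed RNG seed; identical seeds give identical sequences.
#' @return character scalar of `genome_length_bp` bases.
#' @export
sample_genome <- function(model, seed) {
  tm <- validate_transition(model$transition)
  set.seed(seed)
  L <- model$genome_length_bp
  cum <- t(apply(tm, 1L, cumsum))
  out <- integer(L)
  # start from the stationary dinucleotide distribution (no burn-in needed)
  state <- sample.int(16L, 1L, prob = stationary_dinuc(model))
  out[1L] <- (state - 1L) %/% 4L + 1L
  out[2L] <- (state - 1L) %% 4L + 1L
  u <- stats::runif(L)
  for (i in 3:L) {
    z <- 1L + (u[i] > cum[state, 1L]) + (u[i] > cum[state, 2L]) +
      (u[i] > cum[state, 3L])
    out[i] <- z
    state <- (out[i - 1L] - 1L) * 4L + z
  }
  paste(BASES[out], collapse = "")
}

#' Fragment a genome into contigs with noisy coverage
#'
#' Non-overlapping fragments tile the whole genome (total length is
#' conserved). Fragment lengths are lognormal(`mu`, `sigma`) draws clamped
#' below at `min_len` and above at the remaining sequence. Per-contig
#' coverage is the genome mean times lognormal noise with coefficient of
#' variation `coverage_noise_cv` (0 means exactly the mean). Contigs get
#' SPAdes-style headers `NODE_<n>_length_<L>_cov_<c>`.
#'
#' @param sequence genome sequence (character scalar).
#' @param genome_id truth label for the emitted contigs.
#' @param mean_coverage genome mean depth.
#' @param mu,sigma lognormal fragment-length parameters (log-bp scale).
#' @param min_len fragment-length clamp floor in bp.
#' @param coverage_noise_cv coefficient of variation of coverage noise.
#' @param seed RNG seed.
#' @param node_offset first NODE number minus one (for multi-genome ids).
#' @return list: `contigs` data.frame (`contig_id, length, coverage,
#'   genome_id, start, end`) and `sequences` ([Biostrings::DNAStringSet]).
#' @export
fragment_and_cover <- function(sequence, genome_id, mean_coverage,
                               mu = log(8000), sigma = 0.7, min_len = 1000,
                               coverage_noise_cv = 0.15, seed = 1L,
                               node_offset = 0L) {
  stopifnot(sigma >= 0, min_len > 0, coverage_noise_cv >= 0)
  if (exp(mu + sigma^2 / 2) < min_len)
    stop("fragment-length parameters give mean length below min_len")
  set.seed(seed)
  L <- nchar(sequence)
  starts <- integer(); lens <- integer(); pos <- 1L
  while (pos <= L) {
    want <- round(stats::rlnorm(1L, mu, sigma))
    len <- min(max(want, min_len), L - pos + 1L)
    starts <- c(starts, pos); lens <- c(lens, as.integer(len))
    pos <- pos + len
  }
  n <- length(lens)
  cov <- if (coverage_noise_cv == 0) rep(mean_coverage, n) else {
    s2 <- log(1 + coverage_noise_cv^2)
    mean_coverage * stats::rlnorm(n, -s2 / 2, sqrt(s2))
  }
  ids <- sprintf("NODE_%d_length_%d_cov_%s", node_offset + seq_len(n), lens,
                 sprintf("%.6g", cov))
  seqs <- Biostrings::DNAStringSet(substring(sequence, starts,
                                             starts + lens - 1L))
  names(seqs) <- ids
  list(contigs = data.frame(contig_id = ids, length = lens, coverage = cov,
                            genome_id = genome_id, start = starts,
                            end = starts + lens - 1L,
                            stringsAsFactors = FALSE),
       sequences = seqs)
}

#' Plant marker-gene annotations and filler CDS calls
#'
#' For each genome's `planted_genes`, emits CDS annotation records with the
#' canonical gene symbol and a realistic product string at random CDS-like
#' coordinates on randomly chosen contigs of the owning genome. Class-I
#' reductase subunits (bcrABCD) are placed on contigs longer than
#' `anchor_min_bp` when `require_anchorable` is set, so that anchor mining
#' can succeed; if the genome has no such contig, an error is raised.
#' Filler CDS records ("hypothetical protein") are added at `cds_density`
#' per bp so the community's CDS total is realistic.
#'
#' @param contigs truth contig table from [fragment_and_cover()] (possibly
#'   several genomes' tables row-bound).
#' @param planted named list: genome_id -> named integer vector of
#'   pathway gene -> copy count.
#' @param seed RNG seed.
#' @param cds_density filler CDS per bp (default 0.001 = 1 per kb).
#' @param cds_len planted/filler CDS length in bp.
#' @param require_anchorable enforce a > `anchor_min_bp` home for class-I
#'   subunits.
#' @param anchor_min_bp anchor length floor the pipeline will apply.
#' @return list: `annotations` data.frame, `planted` data.frame
#'   (`contig_id, pathway_gene`).
#' @export
plant_markers <- function(contigs, planted, seed = 1L, cds_density = 0.001,
                          cds_len = 900L, require_anchorable = TRUE,
                          anchor_min_bp = 7000) {
  set.seed(seed)
  ann <- list(); truth <- list(); n_rec <- 0L
  pick_pos <- function(len) {
    if (len <= cds_len) c(1L, len) else {
      st <- sample.int(len - cds_len, 1L); c(st, st + cds_len - 1L)
    }
  }
  for (g in names(planted)) {
    genes <- planted[[g]]
    own <- contigs[contigs$genome_id == g, , drop = FALSE]
    if (!nrow(own)) stop("no contigs for genome ", g)
    for (gene in names(genes)) for (copy in seq_len(genes[[gene]])) {
      pool <- own
      if (require_anchorable && gene %in% CLASS_I_GENES) {
        pool <- own[own$length > anchor_min_bp, , drop = FALSE]
        if (!nrow(pool))
          stop("genome ", g, " has no contig > ", anchor_min_bp,
               " bp to carry anchorable marker ", gene)
      }
      row <- pool[sample.int(nrow(pool), 1L), ]
      pos <- pick_pos(row$length)
      n_rec <- n_rec + 1L
      ann[[n_rec]] <- data.frame(
        contig_id = row$contig_id, feature_type = "CDS", gene_symbol = gene,
        product = unname(MARKER_PRODUCTS[gene]), start = pos[1L],
        end = pos[2L], strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
      truth[[n_rec]] <- data.frame(contig_id = row$contig_id,
                                   pathway_gene = gene,
                                   stringsAsFactors = FALSE)
    }
  }
  # filler CDS: round(length * density) per contig
  for (i in seq_len(nrow(contigs))) {
    k <- round(contigs$length[i] * cds_density)
    if (k < 1) next
    for (j in seq_len(k)) {
      pos <- pick_pos(contigs$length[i])
      n_rec <- n_rec + 1L
      ann[[n_rec]] <- data.frame(
        contig_id = contigs$contig_id[i], feature_type = "CDS",
        gene_symbol = "", product = "hypothetical protein",
        start = pos[1L], end = pos[2L], strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
    }
  }
  list(annotations = do.call(rbind, ann),
       planted = if (length(truth)) do.call(rbind, truth) else
         data.frame(contig_id = character(), pathway_gene = character()))
}

#' Default three-genome community models
#'
#' One rare, GC-rich genome carries the full benzoyl-CoA degradation gene
#' set (all four class-I reductase subunits plus the ring-opening genes)
#' at the lowest mean coverage; two more abundant genomes of lower GC act
#' as background, one carrying a lone activation gene as a non-anchor
#' distractor. Mean coverages 20/10/6 give the long-tailed abundance
#' structure; GC levels 0.45/0.35/0.65 plus per-genome transition tilts
#' keep the trinucleotide signatures well separated.
#'
#' @return named list of three `GenomeModel`s.
#' @export
default_community_models <- function() {
  list(
    gBackgroundA = genome_model("gBackgroundA", gc = 0.45,
                                genome_length_bp = 400000, mean_coverage = 20,
                                planted_genes = c(badA = 1L),
                                model_seed = 101L),
    gBackgroundB = genome_model("gBackgroundB", gc = 0.35,
                                genome_length_bp = 350000, mean_coverage = 10,
                                planted_genes = integer(),
                                model_seed = 202L),
    gBcrCarrier = genome_model("gBcrCarrier", gc = 0.65,
                               genome_length_bp = 300000, mean_coverage = 6,
                               planted_genes = c(bcrA = 1L, bcrB = 1L,
                                                 bcrC = 1L, bcrD = 1L,
                                                 dch = 1L, had = 1L,
                                                 oah = 1L),
                               model_seed = 303L))
}

#' Simulate a synthetic metagenome community
#'
#' Samples each genome model, fragments it, plants markers and filler CDS,
#' and assembles everything into an `Assembly` plus a `CommunityTruth`.
#' All randomness flows from the single `seed` (per-genome sub-seeds are
#' derived from it).
#'
#' @param models named list of `GenomeModel`s.
#' @param seed top-level RNG seed.
#' @param mu,sigma,min_len,coverage_noise_cv see [fragment_and_cover()].
#' @param cds_density filler CDS per bp.
#' @param assembly_id id for the generated assembly.
#' @return list with `assembly` (an `Assembly`) and `truth`
#'   (`contig_genome` map, `planted` table, `seed`, `params`).
#' @export
simulate_community <- function(models = default_community_models(), seed = 42L,
                               mu = log(8000), sigma = 0.7, min_len = 1000,
                               coverage_noise_cv = 0.15, cds_density = 0.001,
                               assembly_id = sprintf("synthetic_seed%d", seed)) {
  frags <- list()
  for (i in seq_along(models)) {
    m <- models[[i]]
    gseq <- sample_genome(m, seed = seed + 1000L * i)
    frags[[i]] <- fragment_and_cover(
      gseq, m$genome_id, m$mean_coverage, mu, sigma, min_len,
      coverage_noise_cv, seed = seed + 1000L * i + 1L,
      node_offset = if (i == 1L) 0L else
        sum(vapply(frags[seq_len(i - 1L)], function(f) nrow(f$contigs), 0L)))
  }
  contigs <- do.call(rbind, lapply(frags, `[[`, "contigs"))
  seqs <- do.call(c, lapply(frags, `[[`, "sequences"))
  planted <- lapply(models, `[[`, "planted_genes")
  names(planted) <- vapply(models, `[[`, "", "genome_id")
  planted <- planted[vapply(planted, length, 0L) > 0L]
  pm <- plant_markers(contigs, planted, seed = seed + 77L,
                      cds_density = cds_density)
  asm <- new_assembly(assembly_id,
                      contigs[c("contig_id", "length", "coverage")],
                      seqs)
  asm <- set_annotations(asm, pm$annotations)
  truth <- structure(list(
    contig_genome = contigs[c("contig_id", "genome_id", "length")],
    planted = pm$planted,
    seed = seed,
    params = list(mu = mu, sigma = sigma, min_len = min_len,
                  coverage_noise_cv = coverage_noise_cv,
                  cds_density = cds_density,
                  genomes = names(planted))), class = "CommunityTruth")
  list(assembly = asm, truth = truth)
}

gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write a simulated community to disk
#'
#' Emits `contigs.fasta`, `annotations.gff3`, `truth.tsv` and a
#' `provenance.json` recording the seed and generation parameters (the
#' GFF3 and truth files additionally carry the provenance as comment
#' lines; FASTA has no comment syntax, hence the JSON).
#'
#' @param community result of [simulate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  asm <- community$assembly; truth <- community$truth
  prov <- sprintf("seed=%d params=%s", truth$seed,
                  jsonlite::toJSON(truth$params, auto_unbox = TRUE))
  Biostrings::writeXStringSet(asm$sequences, file.path(dir, "contigs.fasta"),
                              width = 80L)
  ann <- asm$annotations
  gff <- c("##gff-version 3", paste0("#provenance ", prov),
           sprintf("%s\tanchormag_sim\t%s\t%d\t%d\t.\t%s\t0\tID=sim%d;%sproduct=%s",
                   ann$contig_id, ann$feature_type, ann$start, ann$end,
                   ann$strand, seq_len(nrow(ann)),
                   ifelse(nzchar(ann$gene_symbol),
                          paste0("gene=", gff_escape(ann$gene_symbol), ";"), ""),
                   gff_escape(ann$product)))
  writeLines(gff, file.path(dir, "annotations.gff3"))
  tt <- file.path(dir, "truth.tsv")
  writeLines(paste0("# provenance ", prov), tt)
  suppressWarnings(write.table(truth$contig_genome, tt, sep = "\t",
                               quote = FALSE, row.names = FALSE, append = TRUE))
  jsonlite::write_json(c(list(seed = truth$seed), truth$params),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Score recovered bins against ground truth
#'
#' For each bin: precision is the fraction of member contigs (or bp) that
#' belong to the bin's plurality genome; recall is the fraction of that
#' genome's contigs (or bp) at or above the binning length floor that the
#' bin captured; F1 is their harmonic mean. Both count-based and bp-based
#' versions are reported.
#'
#' @param bins list of `GenomeBin`.
#' @param truth a `CommunityTruth`.
#' @param min_len the binning candidate length floor (recall denominator).
#' @return data.frame, one row per bin.
#' @export
evaluate_bins <- function(bins, truth, min_len = 1000) {
  tg <- truth$contig_genome
  do.call(rbind, lapply(bins, function(b) {
    idx <- match(b$member_ids, tg$contig_id)
    if (anyNA(idx))
      stop("unlabeled contig in bin ", b$bin_id, ": ",
           paste(b$member_ids[is.na(idx)], collapse = ", "))
    g <- tg$genome_id[idx]; len <- tg$length[idx]
    bp_by_genome <- tapply(len, g, sum)
    plurality <- names(which.max(bp_by_genome))
    own <- g == plurality
    denom <- tg[tg$genome_id == plurality & tg$length >= min_len, , drop = FALSE]
    p_cnt <- mean(own)
    r_cnt <- sum(own) / nrow(denom)
    p_bp <- sum(len[own]) / sum(len)
    r_bp <- sum(len[own]) / sum(denom$length)
    f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(bin_id = b$bin_id, genome_id = plurality,
               precision_count = p_cnt, recall_count = r_cnt,
               f1_count = f1(p_cnt, r_cnt),
               precision_bp = p_bp, recall_bp = r_bp, f1_bp = f1(p_bp, r_bp),
               stringsAsFactors = FALSE)
  }))
}
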