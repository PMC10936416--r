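test_that("genome sampling is reproducible and honours degenerate models", {
  m <- genome_model("g", gc = 0.5, genome_length_bp = 10000,
                    mean_coverage = 5, model_seed = 3L)
  expect_identical(sample_genome(m, seed = 8L), sample_genome(m, seed = 8L))
  expect_false(identical(sample_genome(m, seed = 8L),
                         sample_genome(m, seed = 9L)))

  forced_a <- m
  forced_a$transition[] <- rep(c(1, 0, 0, 0), each = 16)
  expect_equal(sample_genome(forced_a, 1L),
               paste(rep("A", 10000), collapse = ""))
  bad <- m; bad$transition[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(sample_genome(bad, 1L), "transition")
})

test_that("realized GC converges to the stationary-distribution oracle", {
  m <- genome_model("gcrich", gc = 0.70, genome_length_bp = 100000,
                    mean_coverage = 5, tilt = 0.25, model_seed = 91L)
  target <- stationary_gc(m)
  s <- sample_genome(m, seed = 14L)
  counts <- table(strsplit(s, "")[[1]])
  realized <- sum(counts[c("C", "G")]) / sum(counts)
  expect_lt(abs(realized - target), 0.02)
})

test_that("sampled-genome signatures converge to the stationary trimer signature", {
  m <- genome_model("g", gc = 0.55, genome_length_bp = 10000,
                    mean_coverage = 5, model_seed = 7L)
  target <- stationary_trimer_signature(m)
  expect_equal(sum(target), 1)
  sig10k <- trimer_signature(sample_genome(m, 2L))$proportions
  m$genome_length_bp <- 500000L
  sig500k <- trimer_signature(sample_genome(m, 2L))$proportions
  err <- function(sig) sum(abs(sig - target))
  expect_lt(err(sig500k), err(sig10k))
  expect_gt(pearson_r(sig500k, target), 0.999)
})

test_that("fragmentation conserves the genome and controls coverage noise", {
  m <- genome_model("g", gc = 0.5, genome_length_bp = 100000,
                    mean_coverage = 12, model_seed = 5L)
  s <- sample_genome(m, 6L)
  fr <- fragment_and_cover(s, "g", mean_coverage = 12, mu = log(10000),
                           sigma = 0.6, seed = 21L)
  expect_equal(sum(fr$contigs$length), 100000L)          # conservation
  expect_equal(paste(as.character(fr$sequences), collapse = ""), s)
  expect_true(all(grepl("^NODE_\\d+_length_\\d+_cov_", fr$contigs$contig_id)))
  fr2 <- fragment_and_cover(s, "g", mean_coverage = 12, mu = log(10000),
                            sigma = 0.6, seed = 21L)
  expect_identical(fr$contigs, fr2$contigs)              # determinism

  exact <- fragment_and_cover(s, "g", mean_coverage = 12,
                              coverage_noise_cv = 0, seed = 3L)
  expect_true(all(exact$contigs$coverage == 12))
  expect_error(fragment_and_cover(s, "g", 12, mu = log(100), sigma = 0.1),
               "min_len")
})

test_that("marker planting places anchors on long contigs and sizes the CDS total", {
  sim <- simulate_community(seed = 42L)
  asm <- sim$assembly; truth <- sim$truth
  # every planted bcr subunit sits on a contig of the carrier genome
  planted <- truth$planted
  carrier <- truth$contig_genome$contig_id[
    truth$contig_genome$genome_id == "gBcrCarrier"]
  bcr <- planted[planted$pathway_gene %in% c("bcrA", "bcrB", "bcrC", "bcrD"), ]
  expect_equal(nrow(bcr), 4L)
  expect_true(all(bcr$contig_id %in% carrier))
  long <- asm$contigs$length[match(bcr$contig_id, asm$contigs$contig_id)]
  expect_true(all(long > 7000))
  # filler density 1 per kb: CDS total tracks community length
  expect_lt(abs(asm$total_cds - sum(asm$contigs$length) / 1000),
            nrow(asm$contigs) / 2 + nrow(planted) + 1)
  # each contig labeled exactly once
  expect_setequal(truth$contig_genome$contig_id, asm$contigs$contig_id)
  expect_equal(anyDuplicated(truth$contig_genome$contig_id), 0L)

  tiny <- list(gX = genome_model("gX", 0.5, 10000, 5, c(bcrB = 1L),
                                 model_seed = 1L))
  seq_x <- sample_genome(tiny$gX, 1L)
  fr <- fragment_and_cover(seq_x, "gX", 5, mu = log(2000), sigma = 0.1,
                           seed = 2L)
  expect_true(all(fr$contigs$length <= 7000))
  expect_error(plant_markers(fr$contigs, list(gX = c(bcrB = 1L))),
               "no contig > 7000")
})

test_that("written community files round-trip through the standard readers", {
  sim <- small_two_genome_community(seed = 6L)
  dir <- tempfile("community")
  write_community(sim, dir)
  asm <- read_contigs(file.path(dir, "contigs.fasta"))
  asm <- set_annotations(asm, read_annotations(file.path(dir, "annotations.gff3")))
  expect_equal(asm$contigs$contig_id, sim$assembly$contigs$contig_id)
  expect_equal(asm$contigs$coverage, sim$assembly$contigs$coverage,
               tolerance = 1e-5)                      # header-encoded depth
  expect_equal(asm$total_cds, sim$assembly$total_cds)
  hits_disk <- scan_annotations(asm)
  hits_mem <- scan_annotations(sim$assembly)
  expect_setequal(paste(hits_disk$contig_id, hits_disk$pathway_gene),
                  paste(hits_mem$contig_id, hits_mem$pathway_gene))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 6L)
})

test_that("bin scoring against truth counts precision and recall correctly", {
  truth <- structure(list(contig_genome = data.frame(
    contig_id = c("a1", "a2", "a3", "a4", "b1", "tiny"),
    genome_id = c("A", "A", "A", "A", "B", "A"),
    length = c(2000, 2000, 2000, 2000, 2000, 500))), class = "CommunityTruth")
  mk <- function(members) anchormag:::new_genome_bin("b", members[1],
                                                     members, 0.95, "x")
  perfect <- evaluate_bins(list(mk(c("a1", "a2", "a3", "a4"))), truth)
  expect_equal(perfect$precision_bp, 1)
  expect_equal(perfect$recall_bp, 1)   # "tiny" below the 1000 bp floor
  expect_equal(perfect$f1_bp, 1)
  half <- evaluate_bins(list(mk(c("a1", "a2"))), truth)
  expect_equal(half$precision_count, 1)
  expect_equal(half$recall_count, 0.5)
  mixed <- evaluate_bins(list(mk(c("a1", "a2", "a3", "b1"))), truth)
  expect_equal(mixed$precision_count, 0.75)
  expect_error(evaluate_bins(list(mk(c("a1", "ghost"))), truth), "unlabeled")
})

test_that("within-genome signature correlation exceeds between-genome correlation", {
  # separability property of the default models, across many seeds
  models <- default_community_models()
  for (seed in 1:20) {
    sigs <- lapply(models, function(m) {
      short <- m; short$genome_length_bp <- 20000L
      g <- sample_genome(short, seed = seed * 7L + match(m$genome_id,
                                                         names(models)))
      halves <- c(substr(g, 1, 10000), substr(g, 10001, 20000))
      lapply(halves, function(h) trimer_signature(h)$proportions)
    })
    within <- mean(vapply(sigs, function(p) pearson_r(p[[1]], p[[2]]), 0))
    pairs <- combn(length(sigs), 2)
    between <- mean(apply(pairs, 2, function(ij)
      pearson_r(sigs[[ij[1]]][[1]], sigs[[ij[2]]][[1]])))
    expect_gt(within, between)
  }
})
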