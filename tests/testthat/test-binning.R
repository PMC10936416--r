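test_that("trimer signatures match a brute-force window oracle", {
  sig <- trimer_signature("AAAA")
  expect_equal(sig$valid_windows, 2L)
  expect_equal(unname(sig$proportions["AAA"]), 1)
  expect_equal(sum(sig$proportions), 1)

  sig <- trimer_signature("ACGTACGT")
  expect_equal(unname(sig$proportions[c("ACG", "CGT", "GTA", "TAC")]),
               c(2, 2, 1, 1) / 6)

  expect_error(trimer_signature("ACNGT"), "degenerate")
  expect_error(trimer_signature("AC"), "degenerate")

  set.seed(101)
  for (i in 1:15) {
    s <- random_seq(sample(3:10000, 1), p_n = sample(c(0, 0.02), 1))
    oracle <- oracle_trimer_counts(s)
    if (sum(oracle) == 0) {
      expect_error(trimer_signature(s), "degenerate")
    } else {
      sig <- trimer_signature(s)
      expect_equal(sig$proportions, oracle / sum(oracle))
      expect_equal(sig$valid_windows, sum(oracle))
      expect_true(sig$valid_windows <= nchar(s) - 2)
    }
  }
})

test_that("signature matrix agrees with per-contig signatures", {
  sim <- small_two_genome_community(seed = 5L)
  asm <- sim$assembly
  sig <- signature_matrix(asm, min_len = 1000)
  expect_true(all(asm$contigs$length[match(rownames(sig),
                                           asm$contigs$contig_id)] >= 1000))
  id <- rownames(sig)[1]
  expect_equal(sig[id, ], trimer_signature(asm$sequences[[id]], id)$proportions)
  expect_equal(unname(rowSums(sig)), rep(1, nrow(sig)))
})

test_that("pearson_r matches the closed-form formula and its invariances", {
  a <- c(0.5, 0.5, rep(0, 62))
  b <- c(0, 0, 0.5, 0.5, rep(0, 60))
  expect_equal(pearson_r(a, b), oracle_pearson(a, b))
  expect_equal(pearson_r(a, a), 1)
  expect_error(pearson_r(rep(1 / 64, 64), a), "zero-variance")

  set.seed(7)
  for (i in 1:10) {
    x <- runif(64); y <- runif(64)
    expect_equal(pearson_r(x, y), pearson_r(y, x))
    expect_true(abs(pearson_r(x, y)) <= 1)
    expect_equal(pearson_r(2.5 * x + 3, y), pearson_r(x, y))  # affine invariance
  }
})

test_that("bin membership honours the strict R threshold and the anchor", {
  sim <- small_two_genome_community(seed = 9L)
  asm <- sim$assembly
  sig <- signature_matrix(asm)
  anchor <- rownames(sig)[which.max(asm$contigs$length[
    match(rownames(sig), asm$contigs$contig_id)])]

  bin <- bin_by_anchor(anchor, asm, sig = sig)
  expect_true(anchor %in% bin$member_ids)
  r <- apply(sig, 1, function(v) cor(sig[anchor, ], v))
  expect_setequal(bin$member_ids, rownames(sig)[r > 0.95])
  # a contig at exactly the threshold is excluded
  at <- names(which(r <= 0.95))
  expect_true(!any(at %in% bin$member_ids))

  # raising the threshold never grows the bin
  prev <- bin$member_ids
  for (thr in c(0.97, 0.99, 0.999)) {
    b <- bin_by_anchor(anchor, asm, r_threshold = thr, sig = sig)
    expect_true(all(b$member_ids %in% prev))
    prev <- b$member_ids
  }
  # at threshold 1 the bin is the anchor alone
  expect_equal(bin_by_anchor(anchor, asm, r_threshold = 1, sig = sig)$member_ids,
               anchor)
})

test_that("anchor binning recovers a Markov genome from a 2-genome mix", {
  sim <- small_two_genome_community(seed = 42L)
  asm <- sim$assembly; tg <- sim$truth$contig_genome
  mined <- mine_anchors(asm)
  expect_gte(length(mined$anchor_set$anchors), 1L)
  bin <- bin_by_anchor(mined$anchor_set$anchors[1], asm)
  g <- tg$genome_id[match(bin$member_ids, tg$contig_id)]
  big_a <- tg$contig_id[tg$genome_id == "gA" & tg$length >= 5000]
  expect_gte(mean(big_a %in% bin$member_ids), 0.9)   # >= 90% of gA >= 5 kb
  expect_lte(mean(g == "gB"), 0.1)                   # <= 10% contamination
})

test_that("coverage filter applies the fold band around the anchor and is idempotent", {
  seqs <- setNames(replicate(4, random_seq(1500)), c("a", "m1", "m2", "m3"))
  asm <- make_assembly(seqs, coverage = c(10, 11, 9, 50))
  bin <- anchormag:::new_genome_bin("b", "a", names(seqs), 0.95, "test_asm")
  filt <- coverage_filter(bin, asm, fold = 2.5)
  expect_setequal(filt$member_ids, c("a", "m1", "m2"))  # 50 is aberrant
  expect_equal(coverage_filter(filt, asm, fold = 2.5)$member_ids,
               filt$member_ids)                         # idempotent

  same <- make_assembly(seqs, coverage = rep(7, 4))
  expect_setequal(coverage_filter(bin, same)$member_ids, names(seqs))
  expect_error(coverage_filter(bin, asm, fold = 1), "fold")
  expect_error(coverage_filter(bin, make_assembly(seqs)), "coverage")

  # anchors survive even when their own coverage is outside the band
  low_anchor <- make_assembly(seqs, coverage = c(100, 11, 9, 10))
  expect_true("a" %in% coverage_filter(bin, low_anchor)$member_ids)
})

test_that("bin grouping uses Jaccard within and signature correlation across assemblies", {
  mk_bin <- function(id, members, asm_id = "A", anchors = members[1])
    anchormag:::new_genome_bin(id, anchors, members, 0.95, asm_id)
  b1 <- mk_bin("b1", c("a", "b", "c"))
  b2 <- mk_bin("b2", c("b", "c", "d"))
  b3 <- mk_bin("b3", c("x", "y"))
  cmp <- compare_bins(list(b1, b2, b3), link_threshold = 0.5)
  expect_equal(cmp$similarity["b1", "b2"], 0.5)
  g <- setNames(cmp$groups$group_id, cmp$groups$bin_id)
  expect_equal(g[["b1"]], g[["b2"]])   # joined at similarity 0.5
  expect_false(g[["b3"]] == g[["b1"]])

  # identical member sets: similarity exactly 1
  cmp2 <- compare_bins(list(b1, mk_bin("b1copy", c("a", "b", "c"))))
  expect_equal(cmp2$similarity["b1", "b1copy"], 1)

  # cross-assembly similarity from anchor signatures, (r+1)/2 scaled
  simA <- small_two_genome_community(seed = 3L)
  simB <- small_two_genome_community(seed = 4L)
  minedA <- mine_anchors(simA$assembly); minedB <- mine_anchors(simB$assembly)
  binA <- bin_by_anchor(minedA$anchor_set$anchors[1], simA$assembly,
                        bin_id = "binA")
  binA$assembly_id <- simA$assembly$assembly_id
  binB <- bin_by_anchor(minedB$anchor_set$anchors[1], simB$assembly,
                        bin_id = "binB")
  binB$assembly_id <- simB$assembly$assembly_id
  assemblies <- setNames(list(simA$assembly, simB$assembly),
                         c(simA$assembly$assembly_id, simB$assembly$assembly_id))
  cmp3 <- compare_bins(list(binA, binB), assemblies = assemblies)
  r <- pearson_r(
    trimer_signature(simA$assembly$sequences[[binA$anchor_ids[1]]]),
    trimer_signature(simB$assembly$sequences[[binB$anchor_ids[1]]]))
  expect_equal(cmp3$similarity["binA", "binB"], (r + 1) / 2)
  # same underlying genome in both runs: anchors correlate, bins group
  expect_equal(cmp3$groups$group_id[1], cmp3$groups$group_id[2])
})

test_that("chimera flagging applies size, completeness and contamination rules", {
  rep_of <- function(total_bp) list(total_length_bp = total_bp)
  expect_equal(flag_chimeric(rep_of(4.18e6), 94.51, 1.1), "acceptable")
  expect_equal(flag_chimeric(rep_of(12e6), 99, 0), "chimeric_or_low_quality")
  expect_equal(flag_chimeric(rep_of(2e6), 20, 0), "chimeric_or_low_quality")
  expect_equal(flag_chimeric(rep_of(2e6), 80, 7), "chimeric_or_low_quality")
  expect_equal(flag_chimeric(rep_of(2e6)), "unevaluable")
})
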