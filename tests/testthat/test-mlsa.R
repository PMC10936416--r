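make_gene_sets <- function(present, seqs = NULL) {
  # present: named list genome -> gene symbols; sequences defaulted
  lapply(present, function(genes)
    setNames(vapply(genes, function(g) paste(rep("ACGT", 30), collapse = ""),
                    ""), genes))
}

test_that("housekeeping gene selection requires focal presence and strict majority", {
  gs <- list(
    focal = c("gyrB", "recA", "rpoB", "efp"),
    r1 = c("gyrB", "recA", "efp"),
    r2 = c("gyrB", "recA"),
    r3 = c("gyrB", "rpoB"),
    r4 = c("gyrB", "atpD"))
  gpm <- gene_presence_matrix(make_gene_sets(gs))
  sel <- select_housekeeping_genes(gpm, "focal")
  # gyrB in 4/4 refs; recA 2/4 = exactly half -> excluded; rpoB 1/4; efp 1/4
  expect_equal(sel, "gyrB")
  # atpD absent from focal -> excluded no matter the references
  expect_false("atpD" %in% sel)
  # selection shrinks (or stays) as the majority fraction rises
  prev <- select_housekeeping_genes(gpm, "focal", 0.2)
  for (f in c(0.4, 0.6, 0.9)) {
    cur <- tryCatch(select_housekeeping_genes(gpm, "focal", f),
                    error = function(e) character())
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(select_housekeeping_genes(gpm, "focal", 1), "reference")
})

test_that("concatenation joins selected genes in order and drops incomplete genomes", {
  gs <- list(
    g1 = c(geneA = random_seq(900), geneB = random_seq(1200)),
    g2 = c(geneA = random_seq(900), geneB = random_seq(1200)),
    g3 = c(geneA = random_seq(900)))
  gpm <- gene_presence_matrix(gs)
  expect_warning(cc <- concatenate_genes(gpm, c("geneA", "geneB")), "g3")
  expect_equal(unname(nchar(cc)), c(2100, 2100))
  expect_equal(cc[["g1"]], paste0(gs$g1[["geneA"]], gs$g1[["geneB"]]))
  only3 <- gene_presence_matrix(gs["g3"])
  expect_error(suppressWarnings(concatenate_genes(only3, c("geneA", "geneB"))),
               "all genomes")

  # the six-gene selection used for a focal bin placement concatenates in order
  six <- c("adenylosuccinate_synthase", "atp_synthase_beta",
           "elongation_factor_G", "elongation_factor_P",
           "malate_dehydrogenase", "recA")
  gs6 <- replicate(3, setNames(replicate(6, random_seq(300)), six),
                   simplify = FALSE)
  names(gs6) <- c("bin", "ref1", "ref2")
  gpm6 <- gene_presence_matrix(gs6)
  sel6 <- select_housekeeping_genes(gpm6, "bin")
  expect_equal(sel6, six)
  expect_equal(unname(nchar(concatenate_genes(gpm6, sel6))), rep(1800, 3))
})

test_that("k-mer distance matches a set-enumeration oracle and is a premetric", {
  set.seed(11)
  a <- random_seq(100)
  expect_equal(kmer_distance(a, a), 0)
  b <- a
  pos <- 50
  substr(b, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, pos, pos))[1]
  j <- oracle_kmer_jaccard(a, b, 12)
  expect_equal(kmer_distance(a, b), -(1 / 12) * log(2 * j / (1 + j)))
  expect_equal(kmer_distance(a, b), kmer_distance(b, a))
  # disjoint k-mer sets hit the cap
  expect_equal(kmer_distance(paste(rep("A", 30), collapse = ""),
                             paste(rep("C", 30), collapse = ""), cap = 1), 1)
  expect_error(kmer_distance("ACGT", a), "shorter")
})

test_that("neighbor joining recovers quartet topology from additive distances", {
  # additive matrix for ((A,B),(C,D)) with internal branch 3
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 5,
                10, 11, 5, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  # brute force over the 3 quartet topologies via the four-point condition
  sums <- c(AB_CD = d["A", "B"] + d["C", "D"],
            AC_BD = d["A", "C"] + d["B", "D"],
            AD_BC = d["A", "D"] + d["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")
  split_ab <- ape::drop.tip(tr, c("C", "D"))
  expect_equal(sort(split_ab$tip.label), c("A", "B"))
  truth <- ape::read.tree(text = "((A:1,B:2):3,(C:2,D:3):0);")
  expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(tr),
                                            ape::unroot(truth))), 0)

  three <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
                  dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(ape::Ntip(nj_tree(three)), 3L)
  expect_error(nj_tree(three[1:2, 1:2]), "at least 3")
  asym <- d; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
})

test_that("NJ recovers random additive 6-taxon trees exactly", {
  set.seed(77)
  for (i in 1:20) {
    true <- ape::rtree(6, br = function(n) runif(n, 0.2, 1.5))
    d <- ape::cophenetic.phylo(true)
    rec <- nj_tree(d[sample(6), sample(6)][rownames(d), rownames(d)])
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(true), rec)), 0)
  }
})

test_that("end-to-end MLSA places the focal genome next to its relative", {
  set.seed(33)
  base <- setNames(replicate(4, random_seq(600)), c("g1", "g2", "g3", "g4"))
  mutate <- function(s, n) {
    pos <- sample(nchar(s), n)
    for (p in pos) substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    s
  }
  # focal is a lightly mutated copy of ref1; ref2/ref3 are heavily mutated
  gene_sets <- list(
    focal = vapply(base, mutate, "", n = 10),
    ref1 = vapply(base, mutate, "", n = 12),
    ref2 = vapply(base, mutate, "", n = 200),
    ref3 = vapply(base, mutate, "", n = 220))
  res <- run_mlsa(gene_sets, focal = "focal",
                  newick_path = tmp <- tempfile(fileext = ".nwk"))
  expect_equal(res$selected_genes, names(base))
  expect_equal(names(which.min(res$distances["focal", -1])), "ref1")
  expect_true(file.exists(tmp))
  reread <- ape::read.tree(tmp)
  expect_setequal(reread$tip.label, names(gene_sets))
})
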