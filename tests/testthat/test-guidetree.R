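test_that("distances_for_class realizes the three regimes", {
  seqs <- c(a = "MKVLAAGHEW", b = "MKVLAAGHEW")
  for (k in c("HIGH", "MODERATE", "LOW"))
    expect_equal(unname(distances_for_class(seqs, k)),
                 matrix(0, 2, 2))

  # HIGH: d = 1 - PID_global; frozen pair PID_global = 0.3
  pairseqs <- c(x = "HEAGAWGHEE", y = "PAWHEAE")
  d_high <- distances_for_class(pairseqs, "HIGH")
  expect_equal(d_high["x", "y"], 0.7)

  # LOW: consensus of global and local estimates
  pg <- pid_matrix(pairseqs, align_params(mode = "global"))[1, 2]
  pl <- pid_matrix(pairseqs, align_params(mode = "local"))[1, 2]
  d_low <- distances_for_class(pairseqs, "LOW")
  expect_equal(d_low["x", "y"], 1 - (pg + pl) / 2)
  d_mod <- distances_for_class(pairseqs, "MODERATE")
  expect_equal(d_mod["x", "y"], 1 - pl)
})

test_that("upgma handles cherries, the worked 3-taxon case, and ties", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))  # height d/2

  # hand-executed average linkage: ((a,b) at height .1, +c at height .3)
  d3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- upgma(d3)
  expect_identical(ape::write.tree(t3), "((a:0.1,b:0.1):0.2,c:0.3);")

  # equidistant taxa: lowest-index pair joins first
  deq <- matrix(0.4, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(deq) <- 0
  expect_identical(ape::write.tree(upgma(deq)), "((x:0.2,y:0.2):0,z:0.2);")

  dbad <- d3; dbad[1, 2] <- dbad[2, 1] <- NaN
  expect_error(upgma(dbad), "NaN")
  dneg <- d3; dneg[1, 3] <- dneg[3, 1] <- -0.1
  expect_error(upgma(dneg), "negative")
})

test_that("upgma equals brute-force average linkage and is ultrametric", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(2:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    t1 <- upgma(d)
    expect_equal(robinson_foulds(t1, oracle_upgma(d)), 0)
    # ultrametric: all root-to-tip path lengths equal
    depths <- ape::node.depth.edgelength(t1)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
    # merge heights non-decreasing toward the root: branch lengths >= 0
    expect_true(all(t1$edge.length >= -1e-12))
  }
})

test_that("adaptive_guide_tree composes classification, distances and UPGMA", {
  seqs <- c(s1 = "MKVLAAGHEW", s2 = "MKVLAAGHDW", s3 = "MKVFSAGHEW",
            s4 = "MTVFSAGREW")
  tr <- adaptive_guide_tree(seqs)
  # frozen: HIGH family, UPGMA of 1 - PID joins (s1,s2) then (s3,s4)
  expect_identical(attr(tr, "klass"), "HIGH")
  expect_equal(attr(tr, "avg_pid"), 43 / 60)
  expect_equal(robinson_foulds(
    tr, ape::read.tree(text = "((s1,s2),(s3,s4));")), 0)
  # equals the composition done by hand
  d <- distances_for_class(seqs, "HIGH")
  expect_identical(ape::write.tree(tr), ape::write.tree(upgma(d)))

  expect_error(adaptive_guide_tree(seqs[1L]), "at least 2")

  same <- c(a = "ACDW", b = "ACDW", c = "ACDW")
  tr2 <- adaptive_guide_tree(same)
  expect_identical(attr(tr2, "klass"), "HIGH")
  expect_equal(length(tr2$tip.label), 3L)
  expect_true(ape::is.binary(tr2))
})

test_that("adaptive_guide_tree is permutation-equivariant on distinct distances", {
  set.seed(13)
  fam <- simulate_family(evolution_params(n_taxa = 5, root_length = 40),
                         seed = 99)
  seqs <- fam$sequences
  t1 <- adaptive_guide_tree(seqs)
  t2 <- adaptive_guide_tree(seqs[c(3, 1, 5, 2, 4)])
  expect_equal(robinson_foulds(t1, t2), 0)
})

test_that("random_tree is seeded, uniform-law sequential coalescence", {
  t2 <- random_tree(c("a", "b"), seed = 1)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(t2$Nnode, 1L)

  n5 <- paste0("t", 1:5)
  s1 <- ape::write.tree(random_tree(n5, seed = 77))
  s2 <- ape::write.tree(random_tree(n5, seed = 77))
  expect_identical(s1, s2)
  s3 <- ape::write.tree(random_tree(n5, seed = 78))
  expect_true(ape::is.binary(random_tree(n5, seed = 78)))
  expect_error(random_tree("a", seed = 1), "at least 2")
  expect_error(random_tree(n5), "seed")
})

test_that("load_reference_tree binarizes, roots and checks the leaf set", {
  tr <- ape::read.tree(text = "((a,b,c),d);")
  b <- load_reference_tree(tr, c("a", "b", "c", "d"))
  expect_identical(ape::write.tree(b), "(((a,b),c),d);")

  bin <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(ape::write.tree(load_reference_tree(bin, letters[1:4])),
                   "((a,b),(c,d));")

  err <- expect_error(load_reference_tree(tr, c("a", "b", "c", "e")),
                      "mismatch")
  expect_match(conditionMessage(err), "missing: e")
  expect_match(conditionMessage(err), "extra: d")

  unrooted <- ape::read.tree(text = "(a:1,b:2,(c:3,d:4):1);")
  m <- load_reference_tree(unrooted, letters[1:4])
  expect_true(ape::is.rooted(m) && ape::is.binary(m))
  expect_setequal(m$tip.label, letters[1:4])
})

test_that("nj_reference_tree recovers structure from a reference alignment", {
  # identical rows: star resolved deterministically
  same <- msa(c(a = "ACDW", b = "ACDW", c = "ACDW"))
  ts <- nj_reference_tree(same)
  expect_true(ape::is.binary(ts) && ape::is.rooted(ts))

  # two clear pairs: a~b and c~d similar, pairs far apart
  ref <- msa(c(a = "AAAAAAAAAAAAAAAAAAAA",
               b = "AAAAAAAAAAAAAAAAWWCC",
               c = "DDDDDDDDEEEEEEEEEEEE",
               d = "DDDDDDDDEEEEEEEEWWCC"))
  tj <- nj_reference_tree(ref)
  expect_equal(robinson_foulds(tj, ape::read.tree(text = "((a,b),(c,d));")), 0)

  # disjoint residue columns: p-distance undefined
  bad <- msa(c(a = "AC--", b = "--DW", c = "ACDW"))
  expect_error(nj_reference_tree(bad), "p-distance")
})

test_that("robinson_foulds counts split differences, matching phangorn", {
  q1 <- ape::read.tree(text = "((a,b),(c,d));")
  q2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(q1, q1), 0)
  expect_equal(robinson_foulds(q1, q2), 2)
  expect_error(robinson_foulds(q1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
  for (i in 1:40) {
    t1 <- random_tree(paste0("t", 1:8), seed = 300 + i)
    t2 <- random_tree(paste0("t", 1:8), seed = 600 + i)
    expect_equal(robinson_foulds(t1, t2),
                 as.integer(phangorn::RF.dist(ape::unroot(t1),
                                              ape::unroot(t2))))
  }
})
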