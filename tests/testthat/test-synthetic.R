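test_that("sample_tree is seeded and draws exponential branch lengths", {
  t2 <- sample_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(length(t2$edge.length), 2L)

  a <- sample_tree(6, seed = 9)
  b <- sample_tree(6, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_error(sample_tree(1, seed = 1), "at least 2")

  # law of large numbers on the exponential mean (pendant branches)
  bm <- 0.2
  lens <- unlist(lapply(1:400, function(i) {
    tr <- sample_tree(4, branch_mean = bm, seed = 10000 + i)
    tr$edge.length[tr$edge[, 2L] <= 4L]
  }))
  expect_lt(abs(mean(lens) - bm) / bm, 0.05)
})

test_that("no-evolution limit: leaves identical to root, gap-free true MSA", {
  ep <- evolution_params(n_taxa = 5, root_length = 30, sub_prob = 0,
                         indel_rate = 0)
  fam <- evolve_family(sample_tree(5, seed = 2), ep, seed = 3)
  expect_equal(length(unique(fam$sequences)), 1L)
  expect_false(any(grepl("-", unclass(fam$true_msa), fixed = TRUE)))
  expect_equal(fam$realized_avg_pid, 1.0)
})

test_that("substitution-only evolution produces a gap-free true MSA", {
  ep <- evolution_params(n_taxa = 6, root_length = 40, indel_rate = 0)
  fam <- evolve_family(sample_tree(6, seed = 4), ep, seed = 5, scale = 2)
  expect_false(any(grepl("-", unclass(fam$true_msa), fixed = TRUE)))
  expect_lt(fam$realized_avg_pid, 1.0)
})

test_that("evolution is deterministic under a fixed seed", {
  ep <- evolution_params(n_taxa = 6, root_length = 50)
  tr <- sample_tree(6, seed = 8)
  f1 <- evolve_family(tr, ep, seed = 21, scale = 1.5)
  f2 <- evolve_family(tr, ep, seed = 21, scale = 1.5)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(unclass(f1$true_msa), unclass(f2$true_msa))
  expect_identical(f1$realized_avg_pid, f2$realized_avg_pid)
  f3 <- evolve_family(tr, ep, seed = 22, scale = 1.5)
  expect_false(identical(f1$sequences, f3$sequences))
})

test_that("true MSA rows gap-strip to the leaf sequences (scoring precondition)", {
  for (i in 1:10) {
    fam <- simulate_family(evolution_params(n_taxa = 6, root_length = 40),
                           seed = 300 + i, scale = sample(c(0.5, 2, 6), 1))
    expect_identical(unname(ungap(fam$true_msa)), unname(fam$sequences))
    expect_setequal(names(fam$sequences), fam$true_tree$tip.label)
    # and the family satisfies the scoring precondition by construction
    expect_equal(sp_score(fam$true_msa, fam$true_msa), 100)
  }
})

test_that("pairwise PID decreases with path length in the true tree", {
  ep <- evolution_params(n_taxa = 10, root_length = 80)
  cors <- vapply(1:5, function(i) {
    fam <- simulate_family(ep, seed = 800 + i, scale = 1.5)
    pid <- pid_matrix(fam$sequences)
    path <- cophenetic(fam$true_tree)[rownames(pid), colnames(pid)]
    cor(pid[upper.tri(pid)], path[upper.tri(path)], method = "spearman")
  }, numeric(1L))
  expect_lt(mean(cors), 0)
})

test_that("realized PID is monotone non-increasing in the branch scale", {
  ep <- evolution_params()
  scales <- c(0.1, 0.5, 1.5, 4, 12)
  mean_pid <- vapply(scales, function(s) {
    mean(vapply(1:4, function(i)
      simulate_family(ep, seed = 900 + i, scale = s)$realized_avg_pid,
      numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(mean_pid) < 0.02))  # monotone up to Monte-Carlo noise
  expect_lt(mean_pid[[5L]], 0.25)
  expect_gt(mean_pid[[1L]], 0.8)
})

test_that("calibrate_divergence hits the target and flags unreachable ones", {
  ep <- evolution_params()
  sc <- calibrate_divergence(0.5, ep, k = 6L, tol = 0.03, seed = 77)
  pid <- mean(vapply(1:6, function(i)
    simulate_family(ep, seed = 9000 + i, scale = sc)$realized_avg_pid,
    numeric(1L)))
  expect_lt(abs(pid - 0.5), 0.1)  # fresh seeds: calibration tol + noise
  expect_error(
    calibrate_divergence(0.99, ep, k = 3L, tol = 0.001,
                         bounds = c(0.5, 1), seed = 1),
    "unreachable")
  expect_error(calibrate_divergence(1.5, ep), "target")
})

test_that("parameter validation", {
  expect_error(evolution_params(n_taxa = 1), "n_taxa")
  expect_error(evolution_params(indel_p = 0), "indel_p")
  expect_error(evolution_params(branch_mean = -1), "branch_mean")
})
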