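test_that("count_motifs handles minimal chains per contract", {
  # 1 residue: tor1 can only count the k = 0 self pair
  d <- make_descriptor("L", "A", matrix(c(0, 0, 0), 1))
  ct <- count_motifs(d, "tor1")
  expect_equal(ct$n_total, 1)
  expect_equal(ct$counts["L@0", "A"], 1)

  # 3 residues, min_sep 2: exactly one (1,3) pair
  d3 <- make_descriptor(c("D", "A", "R"), c("A", "A", "A"),
                        rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  ct <- count_motifs(d3, "dist2", min_sep = 2)
  expect_equal(ct$n_total, 1)
  expect_equal(ct$counts["DR", as.character(bin_distance(4))], 1)
  # dist1 counts the pair once per member
  ct1 <- count_motifs(d3, "dist1", min_sep = 2)
  expect_equal(ct1$n_total, 2)
  expect_equal(ct1$counts["D", as.character(bin_distance(4))], 1)
  expect_equal(ct1$counts["R", as.character(bin_distance(4))], 1)
})

test_that("count_motifs equals the brute-force recount on random fixtures", {
  set.seed(97)
  for (rep in 1:6) {
    d <- random_descriptor(sample(4:12, 1))
    for (kind in c("tor1", "tor2", "dist1", "dist2")) {
      ct <- count_motifs(d, kind, window = 8, min_sep = 2)
      expect_equal(ct$counts, oracle_count(d, kind), info = kind)
    }
    # second torsion residue variant too
    ct <- count_motifs(d, "tor2", tor2_domain = "second")
    expect_equal(ct$counts, oracle_count(d, "tor2",
                                         tor2_domain = "second"))
  }
})

test_that("count tables are additive over proteins", {
  set.seed(13)
  ds <- lapply(1:3, function(i) random_descriptor(8, id = paste0("d", i)))
  for (kind in c("tor1", "dist2")) {
    joint <- count_motifs(ds, kind)
    summed <- sum_count_tables(lapply(ds, count_motifs, kind = kind))
    expect_equal(joint$counts, summed$counts)
  }
})

test_that("smoothing spreads counts geometrically and conserves mass", {
  b <- distance_binning()
  m <- matrix(0, 2, 27, dimnames = list(c("AA", "AC"),
                                        as.character(1:27)))
  m["AA", 12] <- 1          # core bin 10 (absolute column 12)
  ct <- count_table("dist2", m)
  expect_equal(smooth_distance_counts(ct, 0)$counts, ct$counts)

  sm <- smooth_distance_counts(ct, 0.5)
  core <- sm$counts["AA", 2:26]
  expect_equal(sum(core), 1, tolerance = 1e-12)
  # geometric decay around bin 10, symmetric
  expect_equal(unname(core[11] / core[10]), 2)  # weight 1 vs 0.5
  expect_equal(unname(core[9]), unname(core[13]))
  expect_equal(unname(core[10] / core[11]), 0.5)

  # direct evaluation oracle for the whole profile
  w <- 0.5^abs(seq_len(25) - 11)
  expect_equal(unname(core), w / sum(w), tolerance = 1e-12)

  expect_error(smooth_distance_counts(ct, 1), "lam")
  tor <- count_table("tor1", matrix(1, 2, 7))
  expect_error(smooth_distance_counts(tor, 0.5), "distance")
})

test_that("uniform core counts are a fixed point of smoothing away from edges", {
  m <- matrix(0, 1, 27, dimnames = list("DR", as.character(1:27)))
  m[1, 2:26] <- 1
  lam <- 0.2
  sm <- smooth_distance_counts(count_table("dist2", m), lam)
  core <- sm$counts[1, 2:26]
  expect_equal(sum(core), 25, tolerance = 1e-9)
  # oracle: each smoothed bin is the truncated kernel sum; central bins
  # deviate from one another only by the O(lam^10) truncation tails
  oracle <- vapply(1:25, function(b) sum(lam^abs(b - (1:25))), 0)
  oracle <- oracle / sum(oracle) * 25
  expect_equal(unname(core), oracle, tolerance = 1e-12)
  mid <- core[10:16]
  expect_lt(max(abs(mid - mid[1])) / mid[1], 1e-6)
  # edge bins lose kernel mass and end up below the center
  expect_lt(core[1], mid[1])
})

test_that("smoothing conserves per-motif mass on random tables", {
  set.seed(71)
  for (rep in 1:10) {
    m <- matrix(rpois(27 * 5, 3), 5, 27,
                dimnames = list(paste0("m", 1:5), as.character(1:27)))
    ct <- count_table("dist1", m)
    lam <- runif(1, 0, 0.95)
    sm <- smooth_distance_counts(ct, lam)
    expect_equal(rowSums(sm$counts), rowSums(ct$counts),
                 tolerance = 1e-9)
    expect_equal(sm$counts[, c(1, 27)], ct$counts[, c(1, 27)])
  }
})

test_that("Boltzmann inversion of independent counts is zero", {
  rowp <- c(2, 5, 1, 4); colp <- c(3, 1, 2)
  counts <- outer(rowp, colp) # factorized: f(c,s) = f(c) f(s)
  dimnames(counts) <- list(paste0("m", 1:4), paste0("s", 1:3))
  pot <- boltzmann_potential(count_table("tor1", counts), sigma = 0)
  expect_equal(max(abs(pot$values)), 0)
})

test_that("motifs without observations get zero potential rows", {
  counts <- rbind(A = c(3, 1), B = c(1, 3), C = c(0, 0))
  colnames(counts) <- c("s1", "s2")
  pot <- boltzmann_potential(count_table("tor1", counts), sigma = 0)
  expect_equal(unname(pot$values["C", ]), c(0, 0))
  pot10 <- boltzmann_potential(count_table("tor1", counts), sigma = 10)
  expect_equal(unname(pot10$values["C", ]), c(0, 0))
})

test_that("Boltzmann inversion matches the hand-computed toy table", {
  counts <- rbind(A = c(3, 1), B = c(1, 3))
  colnames(counts) <- c("b1", "b2")
  pot <- boltzmann_potential(count_table("dist2", counts,
                                         binning = distance_binning(3, 3.4,
                                                                    0.2)),
                             sigma = 0)
  # f(A,b1) = 3/8, f(A) = 1/2, f(b1) = 1/2 -> -ln(1.5)
  expect_equal(pot$values["A", "b1"], -log(1.5), tolerance = 1e-12)
  expect_equal(pot$values["A", "b2"], -log(0.5), tolerance = 1e-12)
  expect_equal(pot$values["B", "b1"], -log(0.5), tolerance = 1e-12)
  expect_equal(pot$values["B", "b2"], -log(1.5), tolerance = 1e-12)
  expect_equal(pot$values, oracle_boltzmann(counts, 0))
})

test_that("potential shrinks to zero monotonically as sigma grows", {
  set.seed(83)
  counts <- matrix(rpois(40, 4), 8, 5)
  dimnames(counts) <- list(paste0("m", 1:8), paste0("s", 1:5))
  ct <- count_table("tor2", counts)
  # monotone shrinkage holds for sigma > 0 (at sigma = 0 unobserved
  # cells sit at the 0 convention, below their small-sigma value)
  sigmas <- c(0.5, 1, 5, 20, 100, 1000, 1e6)
  vals <- lapply(sigmas, function(s) boltzmann_potential(ct, s)$values)
  for (k in 2:length(sigmas)) {
    expect_true(all(abs(vals[[k]]) <= abs(vals[[k - 1]]) + 1e-12))
  }
  expect_lt(max(abs(vals[[length(sigmas)]])), 1e-4)
  expect_equal(boltzmann_potential(ct, 0)$values,
               oracle_boltzmann(counts, 0), tolerance = 1e-12)
  expect_equal(boltzmann_potential(ct, 20)$values,
               oracle_boltzmann(counts, 20), tolerance = 1e-12)
  expect_error(boltzmann_potential(ct, -1), "non-negative")
})

test_that("sigma = 0 with abundant counts is plain Boltzmann inversion", {
  set.seed(89)
  counts <- matrix(rpois(40, 500) + 1, 8, 5)
  dimnames(counts) <- list(paste0("m", 1:8), paste0("s", 1:5))
  pot <- boltzmann_potential(count_table("tor1", counts), sigma = 0)
  f <- counts / sum(counts)
  plain <- -log(f / outer(rowSums(f), colSums(f)))
  expect_equal(pot$values, plain, tolerance = 1e-12)
})

test_that("variant averaging is a cell-wise mean", {
  set.seed(7)
  ds <- lapply(1:2, function(i) random_descriptor(10, id = paste0("v", i)))
  # identical variants average to themselves
  p <- derive_potential_set(ds, t_set = 50, sigmas = c(10, 10), lam = 0)
  p1 <- derive_potential_set(ds, t_set = 50, sigmas = 10, lam = 0)
  expect_equal(p$dist2$values, p1$dist2$values)
  # V and -V cancel
  tab <- boltzmann_potential(count_motifs(ds, "dist2"), 10)
  neg <- tab; neg$values <- -tab$values
  avg <- average_potentials(list(tab, neg))
  expect_equal(max(abs(avg$values)), 0)
  # 3 sets x 2 sigmas: mean of the six tables, verified directly
  sets <- lapply(1:3, function(i)
    list(random_descriptor(8, id = paste0("a", i))))
  ps <- derive_potential_set(sets, t_set = 60, sigmas = c(5, 25), lam = 0.3)
  manual <- list()
  for (s in sets) {
    ct <- smooth_distance_counts(count_motifs(s, "dist2"), 0.3)
    for (sg in c(5, 25)) {
      manual[[length(manual) + 1]] <- boltzmann_potential(ct, sg)$values
    }
  }
  expect_equal(ps$dist2$values, Reduce(`+`, manual) / 6, tolerance = 1e-12)
})
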