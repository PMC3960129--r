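test_that("Tm-Tenv regression recovers exact lines and rejects bad input", {
  r <- fit_tm_tenv_regression(make_records(c("a", "b", "c"),
                                           tm = c(0, 10, 20),
                                           tenv = c(0, 10, 20),
                                           tm_source = "measured"))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r, 1)

  r2 <- fit_tm_tenv_regression(make_records(c("a", "b"), tm = c(10, 10),
                                            tenv = c(0, 10),
                                            tm_source = "measured"))
  expect_equal(r2$slope, 0)
  expect_equal(r2$intercept, 10)

  expect_error(fit_tm_tenv_regression(make_records("a", tm = 5, tenv = 5,
                                                   tm_source = "measured")),
               "at least 2")
  expect_error(fit_tm_tenv_regression(make_records(c("a", "b"),
                                                   tm = c(5, 9),
                                                   tenv = c(7, 7),
                                                   tm_source = "measured")),
               "zero variance")
})

test_that("Tm-Tenv regression recovers a noisy planted line within 3 SE", {
  set.seed(101)
  tenv <- runif(20, 10, 90)
  tm <- 1.2 * tenv + 15 + rnorm(20, 0, 2)
  rec <- make_records(sprintf("p%02d", 1:20), tm = tm, tenv = tenv,
                      tm_source = "measured")
  r <- fit_tm_tenv_regression(rec)
  # closed-form OLS standard errors as the oracle
  se <- summary(lm(tm ~ tenv))$coefficients[, "Std. Error"]
  expect_lt(abs(r$slope - 1.2), 3 * se["tenv"])
  expect_lt(abs(r$intercept - 15), 3 * se["(Intercept)"])
  expect_gt(r$r, 0.9)
})

test_that("the three Tm estimation rules follow their contracts", {
  line <- structure(list(slope = 1, intercept = 20, r = 0.9, n = 10),
                    class = "tm_regression")
  rec <- make_records("x", tenv = 37)
  est <- estimate_tm(rec, "est_global_regression", global_line = line)
  expect_equal(est$tm, 57)
  expect_equal(est$tm_source, "est_global_regression")

  fam <- make_records(c("m1", "m2"), tm = c(40, 60), tenv = c(20, 40),
                      tm_source = "measured")
  est <- estimate_tm(rec, "est_family_regression", family_records = fam)
  expect_equal(est$tm, 57)  # slope 1, intercept 20 from the family line

  # identity transfer: single candidate, then max-identity candidate
  fam1 <- make_records("m1", tm = 75, tm_source = "measured",
                       sequence = "ACDEFGHIKL")
  rec$sequence <- "ACDEFGHIKL"
  est <- estimate_tm(rec, "est_seq_identity", family_records = fam1)
  expect_equal(est$tm, 75)

  fam2 <- make_records(c("m1", "m2"), tm = c(50, 80),
                       tm_source = "measured",
                       sequence = c("AAAA", "BBBB"))
  idm <- matrix(c(1, 0.4, 0.9, 0.4, 1, 0, 0.9, 0, 1), 3,
                dimnames = list(c("x", "m1", "m2"), c("x", "m1", "m2")))
  est <- estimate_tm(rec, "est_seq_identity", family_records = fam2,
                     idm = idm)
  expect_equal(est$tm, 80)  # 90% identity beats 40%

  expect_error(estimate_tm(rec, "est_family_regression",
                           family_records = fam1), ">= 2 measured")
  expect_error(estimate_tm(make_records("y", sequence = "AC"),
                           "est_seq_identity",
                           family_records = make_records("z")),
               ">= 1 measured")
})

test_that("pairwise identity matches exhaustive alignment enumeration", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  sm <- blosum62_matrix()
  o <- oracle_align_identities("ACDEF", "ACDF", sm)
  expect_true(any(abs(pairwise_identity("ACDEF", "ACDF") -
                        o$identities) < 1e-9))
  set.seed(23)
  for (t in 1:8) {
    a <- paste(sample(AA20, sample(3:5, 1), TRUE), collapse = "")
    b <- paste(sample(AA20, sample(3:5, 1), TRUE), collapse = "")
    o <- oracle_align_identities(a, b, sm)
    expect_true(any(abs(pairwise_identity(a, b) - o$identities) < 1e-9),
                info = paste(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "ACD"), "empty")
})

test_that("identity_matrix agrees with pairwise_identity", {
  set.seed(31)
  seqs <- setNames(vapply(1:4, function(i)
    paste(sample(AA20, 12, TRUE), collapse = ""), ""), paste0("s", 1:4))
  m <- identity_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["s1", "s3"], pairwise_identity(seqs["s1"], seqs["s3"]))
})

test_that("split_and_cull splits at the median with no-conflict identity", {
  rec <- make_records(paste0("p", 1:4), tm = c(40, 50, 60, 70),
                      tm_source = "measured")
  idm <- diag(1, 4); dimnames(idm) <- list(rec$id, rec$id)
  tr <- split_and_cull(rec, 0.25, idm = idm)
  expect_setequal(tr$meso$id, c("p1", "p2"))
  expect_setequal(tr$thermo$id, c("p3", "p4"))
  expect_equal(tr$t_meso, 45)
  expect_equal(tr$t_thermo, 65)
  expect_equal(tr$tm0, 60)
  expect_lt(tr$t_meso, tr$t_thermo)
  expect_error(split_and_cull(rec[1:3, ], idm = idm), "at least 4")
})

test_that("culling tie rules keep measured Tm, extreme Tm, and closest-to-mean", {
  mk_idm <- function(ids, pairs) {
    m <- diag(1, length(ids)); dimnames(m) <- list(ids, ids)
    for (p in pairs) m[p[1], p[2]] <- m[p[2], p[1]] <- 0.30
    m
  }
  # rule 1: measured beats estimated in the thermostable half
  rec <- make_records(paste0("p", 1:4), tm = c(10, 20, 60, 90),
                      tm_source = c("measured", "measured", "measured",
                                    "est_global_regression"))
  tr <- split_and_cull(rec, 0.25, idm = mk_idm(rec$id, list(c("p3", "p4"))))
  expect_equal(tr$thermo$id, "p3")
  # rule 2 thermo: both estimated, higher Tm wins
  rec$tm_source <- rep("est_global_regression", 4)
  tr <- split_and_cull(rec, 0.25, idm = mk_idm(rec$id, list(c("p3", "p4"))))
  expect_equal(tr$thermo$id, "p4")
  expect_equal(tr$thermo$tm, 90)
  # rule 2 meso: both estimated, lower Tm wins
  tr <- split_and_cull(rec, 0.25, idm = mk_idm(rec$id, list(c("p1", "p2"))))
  expect_equal(tr$meso$id, "p1")
  # average set: closest to the pre-culling mean (45) wins
  tr <- split_and_cull(rec, 0.25, idm = mk_idm(rec$id, list(c("p3", "p4"))))
  expect_true("p3" %in% tr$average$id)   # |60-45| < |90-45|
  expect_false("p4" %in% tr$average$id)
})

test_that("culling leaves no conflicting pair and never drops measured for estimated", {
  set.seed(47)
  for (rep in 1:5) {
    n <- 10
    ids <- sprintf("q%02d", 1:n)
    rec <- make_records(ids, tm = sample(30:95, n),
                        tm_source = sample(c("measured",
                                             "est_seq_identity"),
                                           n, TRUE))
    m <- matrix(runif(n * n, 0, 0.6), n); m <- (m + t(m)) / 2
    diag(m) <- 1; dimnames(m) <- list(ids, ids)
    tr <- split_and_cull(rec, 0.25, idm = m)
    for (sub in list(tr$meso, tr$thermo, tr$average)) {
      if (nrow(sub) < 2) next
      s <- m[sub$id, sub$id]
      expect_lte(max(s[upper.tri(s)]), 0.25)
    }
    # a measured protein may never be culled while a conflicting
    # estimated partner stays in its subset
    ord <- rec[order(rec$tm, rec$id), ]
    pre <- list(ord$id[1:(n %/% 2)], ord$id[(n %/% 2 + 1):n], ord$id)
    post <- list(tr$meso$id, tr$thermo$id, tr$average$id)
    for (s in 1:3) {
      dropped_meas <- setdiff(
        pre[[s]][rec$tm_source[match(pre[[s]], rec$id)] == "measured"],
        post[[s]])
      for (dm in dropped_meas) {
        partners <- post[[s]][m[dm, post[[s]]] > 0.25]
        expect_true(all(rec$tm_source[match(partners, rec$id)] ==
                          "measured"))
      }
    }
  }
})
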