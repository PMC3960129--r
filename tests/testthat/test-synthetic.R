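small_cfg <- function(seed, ...) {
  generator_config(n_families = 1, proteins_per_family = 6,
                   residues_per_protein = 30,
                   planted_pairs = data.frame(
                     aa1 = "D", aa2 = "R", d_lo = 3.8, d_hi = 4.2,
                     base = 3, slope = 0.05, stringsAsFactors = FALSE),
                   seed = seed, ...)
}

test_that("identical config and seed reproduce identical files byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_family(small_cfg(99), out_dir = d1)
  generate_family(small_cfg(99), out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 3)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed produces different output
  d3 <- withr::local_tempdir()
  generate_family(small_cfg(100), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "proteins.tsv")),
                         readLines(file.path(d3, "proteins.tsv"))))
})

test_that("generated metadata follows the configured Tm and Tenv models", {
  cfg <- generator_config(n_families = 2, proteins_per_family = 20,
                          residues_per_protein = 20, planted_pairs = NULL,
                          seed = 7)
  sf <- generate_family(cfg)
  rec <- sf$records
  expect_equal(nrow(rec), 40)
  expect_true(all(rec$tm_true >= 35 & rec$tm_true <= 95))
  expect_gte(sum(rec$tm_source %in% "measured"), 2 * 3)
  # inverting the tenv model recovers tm_true up to the configured noise
  back <- cfg$tenv_model$slope * rec$tenv + cfg$tenv_model$intercept
  expect_lt(abs(mean(back - rec$tm_true)), 3 * cfg$tenv_model$noise)
  expect_gt(cor(rec$tenv, rec$tm_true), 0.8)
  # measured tm equals true tm when tm_noise = 0
  meas <- rec[rec$tm_source %in% "measured", ]
  expect_equal(meas$tm, meas$tm_true)
})

test_that("planted contacts land in exactly the prescribed distance bins", {
  sf <- generate_family(small_cfg(41))
  for (id in names(sf$chains)) {
    con <- sf$contacts[[id]]
    if (nrow(con) == 0) next
    desc <- protein_descriptor(sf$chains[[id]])
    realized <- desc$dist[cbind(con$i, con$j)]
    expect_equal(bin_distance(realized), bin_distance(con$d))
    expect_true(all(bin_distance(realized) %in%
                      bin_distance(c(3.81, 4.19))))
    # the planted identities were forced into the sequence
    expect_true(all(desc$aa[con$i] == "D" & desc$aa[con$j] == "R"))
  }
})

test_that("planted contact counts scale with the planted slope", {
  cfg <- generator_config(n_families = 1, proteins_per_family = 20,
                          residues_per_protein = 60, seed = 11)
  sf <- generate_family(cfg)
  n_dr <- vapply(sf$contacts, function(co) sum(co$pair == "DR"), 0)
  n_il <- vapply(sf$contacts, function(co) sum(co$pair == "IL"), 0)
  tm <- sf$records$tm_true
  expect_gt(cor(n_dr, tm), 0.9)    # slope +0.1 per degree
  expect_lt(cor(n_il, tm), -0.9)   # slope -0.1 per degree
  expect_true(all(n_dr + n_il == 10))  # no overall-stability signal
})

test_that("the identity ladder spans the culling cutoff", {
  sf <- generate_family(generator_config(n_families = 1,
                                         proteins_per_family = 10,
                                         residues_per_protein = 50,
                                         seed = 19))
  idm <- identity_matrix(setNames(sf$records$sequence, sf$records$id))
  off <- idm[upper.tri(idm)]
  expect_gt(sum(off > 0.25), 0)
  expect_gt(sum(off < 0.25), 0)
})

test_that("the feature-level benchmark plants the stated linear model", {
  sim <- simulate_tm_features(n = 500, tau = 3, seed = 5)
  fit <- lm(sim$tm ~ sim$x)
  expect_equal(unname(coef(fit)[-1]), sim$beta, tolerance = 0.15)
  expect_equal(sd(residuals(fit)), 3, tolerance = 0.15)
  # tau = 0: features fully determine Tm, cross-validated error vanishes
  sim0 <- simulate_tm_features(n = 30, tau = 0, seed = 6)
  expect_lt(jackknife_tm(sim0$x, sim0$tm)$sigma, 1)
})
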