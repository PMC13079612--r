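# Multi-environment trial pipeline: generator, outliers, BLUEs, marker QC.

test_that("trial generator: noiseless limit and design structure", {
  tv <- setNames(c(1, 2, 3, 4), paste0("H", 1:4))
  rec <- simulate_trials(tv, n_locations = 2, n_years = 2, n_reps = 2,
                         env_sd = 0, rep_sd = 0, resid_sd = 0,
                         outlier_rate = 0, seed = 1)
  expect_equal(rec$value, unname(tv[rec$hybrid_id]))
  # every hybrid has exactly n_reps records per environment
  counts <- table(rec$hybrid_id, paste(rec$location, rec$year))
  expect_true(all(counts == 2))
  expect_equal(nrow(rec), 4 * 2 * 2 * 2)
})

test_that("environment effect variance matches its nominal level", {
  tv <- setNames(rep(0, 30), paste0("H", 1:30))
  rec <- simulate_trials(tv, n_locations = 40, n_years = 2, n_reps = 1,
                         env_sd = 2, rep_sd = 0, resid_sd = 0, seed = 2)
  env_means <- tapply(rec$value, paste(rec$location, rec$year), mean)
  expect_equal(sd(env_means), 2, tolerance = 0.4)
})

test_that("outlier removal finds exactly the planted gross error", {
  # several replicates per hybrid, so the hybrid effect absorbs little of
  # the planted error and only the perturbed record crosses the threshold
  set.seed(2)
  tv <- setNames(rnorm(12), paste0("H", 1:12))
  rec <- simulate_trials(tv, n_locations = 1, n_years = 1, n_reps = 4,
                         env_sd = 0, rep_sd = 0.3, resid_sd = 0.25, seed = 2)
  # plant one gross error, roughly 24 residual SDs
  rec$value[7] <- rec$value[7] + 6
  out <- remove_outliers(rec, k = 2)
  expect_equal(nrow(out$removed), 1)
  expect_equal(rownames(rec)[7], rownames(out$removed))
  # k = Inf keeps everything
  out_inf <- remove_outliers(rec, k = Inf)
  expect_equal(nrow(out_inf$records), nrow(rec))
  expect_equal(nrow(out_inf$removed), 0)
})

test_that("outlier removal keeps clean data nearly intact", {
  # with normal residuals roughly 4.6% of records sit beyond 2 SD; the
  # removal fraction must stay well below 8%
  set.seed(851)
  tv <- setNames(rnorm(40), paste0("H", 1:40))
  fracs <- vapply(1:5, function(s) {
    rec <- simulate_trials(tv, n_locations = 3, n_years = 2, n_reps = 2,
                           env_sd = 1, rep_sd = 0.3, resid_sd = 1, seed = s)
    out <- remove_outliers(rec, k = 2)
    nrow(out$removed) / nrow(rec)
  }, numeric(1))
  expect_lt(max(fracs), 0.08)
})

test_that("step-1 BLUEs: balanced design equals raw means, shifts carry through", {
  tv <- setNames(c(5, 7, 9), paste0("H", 1:3))
  rec <- simulate_trials(tv, n_locations = 1, n_years = 1, n_reps = 3,
                         env_sd = 0, rep_sd = 0.5, resid_sd = 0.4, seed = 4)
  b <- blues_step1(rec)
  raw <- tapply(rec$value, rec$hybrid_id, mean)
  expect_equal(b$blue, as.numeric(raw[b$hybrid_id]), tolerance = 1e-10)
  rec2 <- rec
  rec2$value <- rec2$value + 11
  b2 <- blues_step1(rec2)
  expect_equal(b2$blue, b$blue + 11, tolerance = 1e-10)
})

test_that("step-1 BLUEs on an unbalanced design solve the normal equations", {
  tv <- setNames(c(5, 7, 9), paste0("H", 1:3))
  rec <- simulate_trials(tv, n_locations = 1, n_years = 1, n_reps = 2,
                         env_sd = 0, rep_sd = 0.6, resid_sd = 0.3, seed = 5)
  rec <- rec[-2, ]  # drop one record: hybrid misses one replicate
  b <- blues_step1(rec)
  # explicit least squares with sum-to-zero constraints
  hy <- factor(rec$hybrid_id); rp <- factor(rec$replicate)
  Xh <- stats::model.matrix(~hy, contrasts.arg = list(hy = "contr.sum"))
  Xr <- stats::model.matrix(~rp, contrasts.arg = list(rp = "contr.sum"))[, -1, drop = FALSE]
  Xmat <- cbind(Xh, Xr)
  beta <- solve(crossprod(Xmat), crossprod(Xmat, rec$value))
  h_eff <- c(beta[2:3], -sum(beta[2:3]))
  oracle <- beta[1] + h_eff
  expect_equal(b$blue, unname(oracle), tolerance = 1e-8)
})

test_that("step-2 BLUEs: zero environment variance reduces to OLS", {
  set.seed(852)
  tv <- setNames(rnorm(10, 20, 2), paste0("H", sprintf("%02d", 1:10)))
  rec <- simulate_trials(tv, n_locations = 3, n_years = 2, n_reps = 2,
                         env_sd = 0, rep_sd = 0.2, resid_sd = 0.4, seed = 6)
  s1 <- blues_step1(rec)
  s2 <- blues_step2(s1)
  ols <- tapply(s1$blue, s1$hybrid_id, mean)
  expect_equal(s2$blue, as.numeric(ols[s2$hybrid_id]), tolerance = 1e-4)
})

test_that("step-2 hybrid contrasts ignore a constant environment shift", {
  mu <- c(H1 = 3, H2 = 5, H3 = 8, H4 = 1, H5 = 6)
  s1 <- data.frame(
    hybrid_id = rep(names(mu), 2),
    blue = c(mu, mu + 50),  # second environment shifted by +50
    n_obs = 2L,
    location = rep(c("locA", "locB"), each = 5),
    year = 2001L, step = "step1", estimable = TRUE
  )
  s2 <- blues_step2(s1)
  est <- setNames(s2$blue, s2$hybrid_id)
  expect_equal(est["H2"] - est["H1"], c(H2 = 2), tolerance = 1e-6)
  expect_equal(est["H3"] - est["H4"], c(H3 = 7), tolerance = 1e-6)
})

test_that("step-2 shrinkage improves on single-environment step-1 accuracy", {
  cors <- sapply(1:8, function(s) {
    set.seed(860 + s)
    tv <- setNames(rnorm(20, 0, 2), paste0("H", sprintf("%02d", 1:20)))
    rec <- simulate_trials(tv, n_locations = 3, n_years = 2, n_reps = 2,
                           env_sd = 2, rep_sd = 0.5, resid_sd = 1.5,
                           seed = 100 + s)
    s1 <- blues_step1(rec)
    s2 <- blues_step2(s1)
    env1 <- s1[paste(s1$location, s1$year) ==
                 paste(s1$location, s1$year)[1], ]
    c(step2 = cor(s2$blue, tv[s2$hybrid_id]),
      step1 = cor(env1$blue, tv[env1$hybrid_id]))
  })
  expect_gt(mean(cors["step2", ]), mean(cors["step1", ]))
})

test_that("single-environment step 2 degrades to fixed means with a warning", {
  tv <- setNames(c(1, 2, 3), paste0("H", 1:3))
  rec <- simulate_trials(tv, n_locations = 1, n_years = 1, n_reps = 2,
                         env_sd = 0, rep_sd = 0, resid_sd = 0.1, seed = 7)
  s1 <- blues_step1(rec)
  expect_warning(s2 <- blues_step2(s1), "single environment")
  expect_equal(nrow(s2), 3)
})

test_that("marker QC boundary semantics", {
  # locus A: counts (91, 8, 1) -> p_minor = 0.05 exactly -> retained
  locus_a <- rep(c(0, 1, 2), c(91, 8, 1))
  # locus B: monomorphic -> MAF 0 -> removed
  locus_b <- rep(0, 100)
  # locus C: 21% missing -> removed; locus D: exactly 20% missing -> kept
  locus_c <- c(rep(NA, 21), rep(c(0, 1, 2), length.out = 79))
  locus_d <- c(rep(NA, 20), rep(c(0, 1, 2), length.out = 80))
  mk <- marker_matrix(cbind(A = locus_a, B = locus_b, C = locus_c, D = locus_d),
                      allow_missing = TRUE)
  res <- filter_markers(mk, maf_min = 0.05, missing_max = 0.2)
  expect_equal(res$markers$locus_ids, c("A", "D"))
  expect_equal(res$report$n_dropped_maf, 1)
  expect_equal(res$report$n_dropped_missing, 1)
  expect_error(filter_markers(mk, maf_min = 0.9), "all loci removed")
})
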