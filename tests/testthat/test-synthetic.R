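test_that("the generator is deterministic under config + seed", {
  cfg <- synthetic_config(n_modern = 80, seed = 61)
  a <- generate_modern(cfg)
  b <- generate_modern(cfg)
  expect_identical(a$dataset$pollen$values, b$dataset$pollen$values)
  expect_identical(a$dataset$meta, b$dataset$meta)
  expect_identical(a$truth$samples, b$truth$samples)
  fa <- generate_fossil_core(cfg, resolution_yr = 200)
  fb <- generate_fossil_core(cfg, resolution_yr = 200)
  expect_identical(fa$record$pollen$values, fb$record$pollen$values)
})

test_that("generated counts close to 100% and labels follow the planted
           thresholds", {
  cfg <- synthetic_config(n_modern = 100, seed = 62)
  gm <- generate_modern(cfg)
  pct <- to_percentages(gm$dataset$pollen)
  expect_true(all(abs(rowSums(pct$values) - 100) < 1e-9))
  tr <- gm$truth$samples
  expect_true(all(tr$system[tr$hii <= 22] == "native"))
  expect_true(all(tr$system[tr$hii >= 38] == "artificial"))
  expect_true(all(tr$w[tr$system == "native"] == 0))
  expect_true(all(tr$w[tr$system == "secondary"] > 0 &
                    tr$w[tr$system == "secondary"] < 0.8))
})

test_that("theta1 = 64 disables distortion entirely", {
  cfg <- synthetic_config(n_modern = 60, theta1 = 64, seed = 63)
  gm <- generate_modern(cfg)
  expect_true(all(gm$truth$samples$system == "native"))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(theta1 = 40, theta2 = 30), "theta1 < theta2")
  expect_error(synthetic_config(theta1 = 0), "theta1")
  expect_error(synthetic_config(count_depth = 50), "count_depth")
})

test_that("abundance-weighted optima estimated from native samples track
           the generating optima", {
  # WA optimum estimates shrink toward the gradient centre under
  # compositional closure, so accuracy is asserted against the response
  # tolerance rather than a sampling SE that assumes unbiasedness.
  sm <- small_modern(n = 600, seed = 64)
  tr <- sm$truth
  native <- tr$samples$system == "native"
  Y <- sm$ds$pollen$values[native, , drop = FALSE]
  mat <- tr$samples$mat_true[native]
  est <- u <- numeric(0)
  for (j in seq_len(nrow(tr$taxa))) {
    uj <- tr$taxa$u_mat[j]
    # interior optima only: edge taxa are truncation-biased by design
    if (uj < 0 + tr$tol_mat || uj > 20 - tr$tol_mat) next
    yj <- Y[, tr$taxa$taxon[j]]
    if (sum(yj) < 50) next
    est <- c(est, sum(yj * mat) / sum(yj))
    u <- c(u, uj)
  }
  expect_gt(length(u), 5)
  expect_gt(cor(est, u), 0.9)
  expect_lt(max(abs(est - u)), tr$tol_mat / 2)
  expect_lt(mean(abs(est - u)), tr$tol_mat / 4)
})

test_that("cross-validated error magnitude increases native -> secondary
           -> artificial", {
  sm <- small_modern(n = 400, seed = 65)
  cv <- loo_cv(sm$ds, variable = "mat", method = "analogue", k = 5)
  ar <- abs(cv$residual)
  sys <- sm$truth$samples$system[match(cv$sample_id,
                                       sm$truth$samples$sample_id)]
  m <- tapply(ar, sys, mean)
  expect_gt(m[["secondary"]], m[["native"]])
  expect_gt(m[["artificial"]], m[["secondary"]])
  # stochastic ordering of the extremes, not just the means
  expect_gt(median(ar[sys == "artificial"]), median(ar[sys == "native"]))
})

test_that("fossil cores follow the phase plan and reject bad plans", {
  cfg <- synthetic_config(n_modern = 50, seed = 66)
  gf <- generate_fossil_core(cfg, resolution_yr = 100)
  tr <- gf$truth$samples
  expect_identical(length(unique(tr$phase)), 6L)
  expect_true(all(diff(gf$record$age_calbp) >= 0))
  expect_true(all(diff(gf$record$depth_cm) > 0))
  # ages youngest-first and within the plan span
  expect_lt(max(tr$age_calbp), 6600)
  expect_gte(min(tr$age_calbp), 0)

  expect_error(generate_fossil_core(cfg, plan = default_phase_plan()[0, ]),
               "empty")
  bad <- default_phase_plan()
  bad$age_young[1] <- 4000   # overlaps the next phase (5000-3700)
  expect_error(generate_fossil_core(cfg, plan = bad), "overlap")
  bad2 <- default_phase_plan()
  bad2$age_old[2] <- bad2$age_young[2]
  expect_error(generate_fossil_core(cfg, plan = bad2),
               "age_old > age_young")
})
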