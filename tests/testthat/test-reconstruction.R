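test_that("training-set comparison prefers the native calibration on
           distorted data", {
  sm <- small_modern(n = 400, seed = 81)
  spec <- radius_spec(120, 30, c(1200, 1400))
  cmp <- compare_training_sets(sm$ds, c(22, 38), spec)
  expect_s3_class(cmp, "training_comparison")
  expect_true(all(cmp$winners$subset == "native"))
  # RMSEP rises monotonically with the HII range included, per cell
  for (r in spec$radii_km) for (v in c("mat", "map")) {
    cell <- cmp$table[cmp$table$radius_km == r & cmp$table$variable == v, ]
    expect_lt(cell$rmsep[cell$subset == "native"],
              cell$rmsep[cell$subset == "all"])
  }
})

test_that("undersized subsets are marked unavailable without crashing", {
  sm <- small_modern(n = 120, seed = 82)
  spec <- radius_spec(120, 30, c(1400))
  # ip1 = 2 leaves (almost) no native samples
  cmp <- compare_training_sets(sm$ds, c(2, 38), spec)
  nat <- cmp$table[cmp$table$subset == "native", ]
  expect_true(all(!nat$available))
  expect_true(all(is.na(nat$rmsep)))
  expect_true(all(cmp$winners$subset != "native"))
})

test_that("reconstruction flags nonnative samples but never drops them", {
  sm <- small_modern(n = 250, seed = 83)
  labels <- assign_groups(sm$ds$meta, c(22, 38))
  lda_fit <- pollen_lda(sm$ds$pollen, labels)
  native <- eipdt:::ds_subset(sm$ds, which(sm$ds$meta$hii <= 22))
  m_mat <- wapls(native$pollen, native$meta$mat_c, k = 2,
                 warn_empty = FALSE)

  fc <- classify_fossil(lda_fit, sm$ds$pollen)
  rec <- reconstruct_climate(sm$ds$pollen, fc, mat_model = m_mat)
  expect_identical(nrow(rec), 250L)
  expect_identical(rec$reliable, fc$call == "native")
  # flag logic: reliable XOR nonnative, never both
  expect_false(any(rec$reliable & fc$call == "nonnative"))
  expect_true(all(is.finite(rec$mat_c)))

  # a fossil sample equal to a training sample gets its in-sample fitted
  probe <- native$pollen$values[3, , drop = FALSE]
  fc1 <- classify_fossil(lda_fit,
                         pollen_matrix(probe, basis = "percentages"))
  rec1 <- reconstruct_climate(pollen_matrix(probe, basis = "percentages"),
                              fc1, mat_model = m_mat)
  expect_equal(rec1$mat_c, unname(fitted(m_mat)[3]))

  # misaligned classification is rejected
  expect_error(reconstruct_climate(sm$ds$pollen, fc1, mat_model = m_mat),
               "not aligned")
})

test_that("bootstrap errors are seeded, and reduce to RMSEP at
           n_boot = 1", {
  sm <- small_modern(n = 120, seed = 84)
  native <- eipdt:::ds_subset(sm$ds, which(sm$ds$meta$hii <= 22))
  fossil <- pm_probe <- sm$ds$pollen$values[1:5, , drop = FALSE]
  fossil <- pollen_matrix(pm_probe, basis = "percentages")

  b1 <- bootstrap_errors(native, "mat", fossil, n_boot = 1, seed = 9)
  expect_equal(b1$err, rep(b1$rmsep, 5))
  expect_equal(b1$boot_sd, rep(0, 5))

  b2 <- bootstrap_errors(native, "mat", fossil, n_boot = 25, seed = 9)
  b3 <- bootstrap_errors(native, "mat", fossil, n_boot = 25, seed = 9)
  expect_identical(b2$err, b3$err)
  # quadrature combination keeps err at or above the RMSEP floor
  expect_true(all(b2$err >= b2$rmsep))
  expect_error(bootstrap_errors(native, "mat", fossil, n_boot = 5),
               "seed")
})
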