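meta_with_hii <- function(hii) {
  site_meta(data.frame(sample_id = paste0("s", seq_along(hii)),
                       lon = 0, lat = 0, mat_c = 10, map_mm = 500,
                       hii = hii))
}

test_that("group assignment follows the inclusive IP thresholds", {
  g <- assign_groups(meta_with_hii(c(10, 30, 50)), c(22, 38))
  expect_identical(g$group, c(1L, 2L, 3L))
  # boundary conventions: hii = 22 -> group 1, hii = 38 -> group 3
  g2 <- assign_groups(meta_with_hii(c(22, 38)), c(22, 38))
  expect_identical(g2$group, c(1L, 3L))
  # two-group rule when ip2 is absent
  g3 <- assign_groups(meta_with_hii(c(10, 50)), 22)
  expect_identical(g3$group, c(1L, 2L))
  expect_error(assign_groups(meta_with_hii(10), NA_real_), "ip1")
})

# two well-separated compositional groups as percentage assemblages
separated_groups <- function(n_per = 30, seed = 71, gap = 60) {
  set.seed(seed)
  prof1 <- c(gap, 100 - gap, 10, 10)
  prof2 <- c(100 - gap, gap, 10, 10)
  mk <- function(prof, ids) {
    v <- matrix(rep(prof, each = n_per), n_per) +
      matrix(runif(n_per * 4, 0, 4), n_per)
    v <- 100 * v / rowSums(v)
    dimnames(v) <- list(ids, c("A", "B", "C", "D"))
    v
  }
  v <- rbind(mk(prof1, paste0("x", seq_len(n_per))),
             mk(prof2, paste0("y", seq_len(n_per))))
  pm <- pollen_matrix(v, basis = "percentages")
  labels <- structure(data.frame(sample_id = pm$sample_ids,
                                 group = rep(1:2, each = n_per)),
                      class = c("group_labels", "data.frame"))
  list(pm = pm, labels = labels)
}

test_that("well-separated groups are classified perfectly", {
  d <- separated_groups()
  fit <- pollen_lda(d$pm, d$labels, min_presence = 0)
  pr <- predict(fit, d$pm)
  expect_identical(as.integer(as.character(pr$class)), d$labels$group)
  expect_true(all(abs(rowSums(pr$posterior) - 1) < 1e-12))
  conf <- loo_confusion(d$pm, d$labels, min_presence = 0)
  expect_true(all(conf$correct_pct == 100))
  expect_identical(sum(conf$counts), 60L)
})

test_that("duplicating every sample leaves the decision rule unchanged", {
  d <- separated_groups(seed = 72)
  fit1 <- pollen_lda(d$pm, d$labels, min_presence = 0)
  dup <- pollen_matrix(rbind(d$pm$values, d$pm$values),
                       sample_ids = c(d$pm$sample_ids,
                                      paste0(d$pm$sample_ids, "_b")),
                       taxa = d$pm$taxa, basis = "percentages")
  lab2 <- structure(data.frame(sample_id = dup$sample_ids,
                               group = rep(d$labels$group, 2)),
                    class = c("group_labels", "data.frame"))
  fit2 <- pollen_lda(dup, lab2, min_presence = 0)
  probe <- d$pm$values[c(1, 35), , drop = FALSE]
  expect_equal(predict(fit1, probe)$posterior,
               predict(fit2, probe)$posterior, tolerance = 1e-6)
})

test_that("classification is invariant to taxa column order", {
  d <- separated_groups(seed = 73)
  fit <- pollen_lda(d$pm, d$labels, min_presence = 0)
  shuffled <- d$pm$values[, c(3, 1, 4, 2)]
  expect_equal(predict(fit, shuffled)$posterior,
               predict(fit, d$pm)$posterior, tolerance = 1e-12)
})

test_that("leave-one-out confusion matches a hand-written Gaussian LDA
           oracle", {
  sm <- small_modern(n = 40, seed = 74)
  labels <- assign_groups(sm$ds$meta, c(22, 38))
  fit <- pollen_lda(sm$ds$pollen, labels, var_keep = 0.7)
  conf <- loo_confusion(sm$ds$pollen, labels, var_keep = 0.7)
  g <- fit$groups
  sc <- fit$scores
  pred <- vapply(seq_len(nrow(sc)), function(i) {
    post <- lda_posterior_oracle(sc[-i, , drop = FALSE], g[-i],
                                 fit$prior, sc[i, , drop = FALSE])
    fit$levels[which.max(post)]
  }, numeric(1))
  oracle_counts <- table(observed = factor(g, fit$levels),
                         predicted = factor(pred, fit$levels))
  expect_equal(unclass(conf$counts), unclass(oracle_counts),
               ignore_attr = TRUE)
})

test_that("randomly permuted labels classify near chance", {
  sm <- small_modern(n = 120, seed = 75)
  set.seed(99)
  labels <- structure(data.frame(sample_id = sm$ds$pollen$sample_ids,
                                 group = sample(rep(1:2, 60))),
                      class = c("group_labels", "data.frame"))
  conf <- loo_confusion(sm$ds$pollen, labels)
  acc <- sum(diag(conf$counts)) / sum(conf$counts)
  # binomial 95% band around 0.5 for n = 120
  expect_lt(abs(acc - 0.5), 1.96 * sqrt(0.25 / 120) + 0.05)
})

test_that("single-group input is rejected", {
  d <- separated_groups()
  d$labels$group <- 1L
  expect_error(pollen_lda(d$pm, d$labels, min_presence = 0),
               "at least 2 groups")
})

test_that("fossil classification merges groups 2+3 and calls at 0.5", {
  sm <- small_modern(n = 200, seed = 76)
  labels <- assign_groups(sm$ds$meta, c(22, 38))
  fit <- pollen_lda(sm$ds$pollen, labels)
  # a spectrum at the group-1 mean assemblage is called native
  g1 <- colMeans(sm$ds$pollen$values[labels$group == 1, , drop = FALSE])
  g1 <- matrix(100 * g1 / sum(g1), 1,
               dimnames = list("f1", sm$ds$pollen$taxa))
  fc <- classify_fossil(fit, pollen_matrix(g1, basis = "percentages"))
  expect_gt(fc$native_posterior, 0.5)
  expect_identical(fc$call, "native")
  # posteriors are a partition: native + nonnative = 1, call follows 0.5
  fc2 <- classify_fossil(fit, sm$ds$pollen)
  expect_equal(fc2$native_posterior + fc2$nonnative_posterior,
               rep(1, nrow(fc2)))
  expect_identical(fc2$call == "native", fc2$native_posterior > 0.5)
})

test_that("phases merge contiguous calls and absorb short runs", {
  calls <- c("native", "native", "nonnative", "nonnative", "native")
  ph <- call_phases(calls, ages = c(10, 20, 30, 40, 50), min_run = 1)
  expect_identical(nrow(ph), 3L)
  expect_identical(ph$call, c("native", "nonnative", "native"))
  expect_equal(ph$age_young, c(10, 30, 50))

  # all-native record: one phase
  ph1 <- call_phases(rep("native", 6), ages = 1:6)
  expect_identical(nrow(ph1), 1L)

  # a single intruding call is absorbed under the default minimum run
  ph2 <- call_phases(c("native", "native", "nonnative", "native",
                       "native"), ages = 1:5, min_run = 2)
  expect_identical(nrow(ph2), 1L)
  expect_identical(ph2$call, "native")
  expect_identical(ph2$n_samples, 5L)
})
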