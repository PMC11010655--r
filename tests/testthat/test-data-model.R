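test_that("pollen_matrix validates values, ids and percentage closure", {
  m <- matrix(c(10, 0, 0, 10), 2, 2,
              dimnames = list(c("a", "b"), c("A", "B")))
  pm <- pollen_matrix(m, basis = "counts")
  expect_s3_class(pm, "pollen_matrix")
  expect_identical(pm$values, m)

  expect_error(pollen_matrix(-m, basis = "counts"), "negative")
  expect_error(pollen_matrix(m, sample_ids = c("a", "a"), basis = "counts"),
               "duplicate sample ids")
  expect_error(pollen_matrix(matrix(c(30, 60), 1, 2,
                                    dimnames = list("s", c("A", "B"))),
                             basis = "percentages"), "sum to 100")
})

test_that("site_meta enforces the HII range and coordinate bounds", {
  df <- data.frame(sample_id = "s1", lon = 120, lat = 30, mat_c = 16,
                   map_mm = 1300, hii = 65)
  expect_error(site_meta(df), "hii outside \\[0, 64\\]")
  df$hii <- 64
  expect_s3_class(site_meta(df), "site_meta")
  df$lat <- 95
  expect_error(site_meta(df), "lat")
})

test_that("fossil_record requires monotone depth and consistent ages", {
  pm <- pollen_matrix(matrix(c(5, 5, 5, 5), 2, 2,
                             dimnames = list(c("f1", "f2"), c("A", "B"))),
                      basis = "counts")
  expect_error(fossil_record(pm, depth_cm = c(10, 5), age_calbp = c(0, 100)),
               "strictly increasing")
  expect_error(fossil_record(pm, depth_cm = c(5, 10), age_calbp = c(100, 0)),
               "nondecreasing")
  expect_s3_class(fossil_record(pm, c(5, 10), c(0, 100)), "fossil_record")
})

test_that("read_table round-trips a count table and reports bad cells", {
  df <- data.frame(sample_id = c("a", "b"), A = c(10, 0), B = c(0, 10))
  f <- tmp_table(df)
  pm <- read_table(f, "pollen")
  expect_identical(pm$basis, "counts")
  expect_equal(unname(pm$values), matrix(c(10, 0, 0, 10), 2, 2))

  # full-precision write/read round trip
  set.seed(1)
  vals <- matrix(runif(6) * 100, 2, 3,
                 dimnames = list(c("a", "b"), c("A", "B", "C")))
  pm2 <- pollen_matrix(vals, basis = "counts")
  f2 <- tempfile(fileext = ".tsv")
  write_eipdt_table(pm2, f2)
  back <- read_table(f2, "pollen")
  expect_equal(back$values, pm2$values, tolerance = 1e-9)

  df$A <- c("10", "oops")
  f3 <- tmp_table(df)
  expect_error(read_table(f3, "pollen"), "row 2, column 'A'")
})

test_that("read_table applies the meta and fossil schemas", {
  meta_df <- data.frame(sample_id = "s1", lon = 120, lat = 30, elev = 10,
                        mat_c = 16, map_mm = 1300, hii = 65)
  expect_error(read_table(tmp_table(meta_df), "meta"), "hii outside")
  meta_df$hii <- 20
  expect_s3_class(read_table(tmp_table(meta_df), "meta"), "site_meta")
  expect_error(read_table(tmp_table(meta_df[, -2]), "meta"), "lon")

  fos <- data.frame(sample_id = c("f1", "f2"), depth_cm = c(10, 5),
                    age_calbp = c(100, 200), A = c(1, 2), B = c(3, 4))
  expect_error(read_table(tmp_table(fos), "fossil"), "strictly increasing")
  fos$depth_cm <- c(5, 10)
  fos$age_calbp <- c(100, 200)
  expect_s3_class(read_table(tmp_table(fos), "fossil"), "fossil_record")
})

test_that("to_percentages closes rows, rejects zero sums, is idempotent", {
  pm <- pollen_matrix(matrix(c(30, 1, 70, 3), 2, 2,
                             dimnames = list(c("a", "b"), c("A", "B"))),
                      basis = "counts")
  pct <- to_percentages(pm)
  expect_equal(unname(pct$values), matrix(c(30, 25, 70, 75), 2, 2))
  expect_identical(to_percentages(pct), pct)

  zero <- pollen_matrix(matrix(0, 1, 2, dimnames = list("z", c("A", "B"))),
                        basis = "counts")
  expect_error(to_percentages(zero), "zero pollen sum.*z")
})

test_that("to_percentages supports a pollen-sum subset", {
  pm <- pollen_matrix(matrix(c(20, 20, 10), 1, 3,
                             dimnames = list("s", c("A", "B", "Aq"))),
                      basis = "counts")
  pct <- to_percentages(pm, sum_taxa = c("A", "B"))
  expect_equal(unname(pct$values), matrix(c(50, 50, 25), 1, 3))
})

test_that("harmonize_taxa intersects, re-closes and reports dropped mass", {
  mk <- function(taxa, vals)
    pollen_matrix(matrix(vals, 1, length(taxa),
                         dimnames = list("s", taxa)),
                  basis = "percentages")
  modern <- mk(c("A", "B", "C"), c(50, 30, 20))
  fossil <- mk(c("B", "C", "D"), c(10, 40, 50))
  h <- harmonize_taxa(modern, fossil)
  expect_identical(h$modern$taxa, c("B", "C"))
  expect_equal(rowSums(h$modern$values), c(s = 100), tolerance = 1e-6)
  expect_equal(rowSums(h$fossil$values), c(s = 100), tolerance = 1e-6)
  expect_identical(h$report$dropped_modern, "A")
  expect_equal(unname(h$report$mass_dropped_modern), 50)

  # identical taxa lists: unchanged; re-harmonizing is the identity
  same <- harmonize_taxa(h$modern, h$fossil)
  expect_equal(same$modern$values, h$modern$values)
  expect_equal(same$fossil$values, h$fossil$values)

  expect_error(harmonize_taxa(mk("A", 100), mk("B", 100)),
               "no taxa in common")
})

test_that("taxa are matched after trimming and case-folding", {
  a <- pollen_matrix(matrix(c(60, 40), 1, 2,
                            dimnames = list("s", c("Quercus ", "Pinus"))),
                     basis = "percentages")
  b <- pollen_matrix(matrix(c(70, 30), 1, 2,
                            dimnames = list("f", c("quercus", "Betula"))),
                     basis = "percentages")
  h <- harmonize_taxa(a, b)
  expect_identical(h$modern$taxa, "Quercus ")
  expect_equal(unname(h$modern$values[1, 1]), 100)
})
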