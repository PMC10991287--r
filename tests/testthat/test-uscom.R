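test_that("majority under-sampling keeps the rounded fraction, seeded", {
  ids <- 1:300
  kept <- undersample_majority(ids, 2 / 3, seed = 1)
  expect_length(kept, 200L)
  expect_false(any(duplicated(kept)))
  expect_identical(kept, undersample_majority(ids, 2 / 3, seed = 1))
  expect_setequal(undersample_majority(ids, 1, seed = 2), ids)
  expect_error(undersample_majority(integer(0), 0.5), "empty")
})

test_that("k-means SSE matches the hand-computed toy value and separates blobs", {
  tri <- matrix(c(0, 0, 2, 0, 0, 2), ncol = 2, byrow = TRUE)
  km1 <- kmeans_fit(tri, 1, seed = 1)
  expect_equal(unname(km1$centroids[1, ]), c(2 / 3, 2 / 3))
  expect_equal(km1$sse, 16 / 3, tolerance = 1e-9)

  expect_equal(kmeans_fit(tri, 3, seed = 1)$sse, 0)
  expect_error(kmeans_fit(tri, 4, seed = 1), "1..n")

  blobs <- hdpm:::with_seed(3, rbind(
    cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1)),
    cbind(rnorm(20, 100, 0.1), rnorm(20, 100, 0.1))))
  km2 <- kmeans_fit(blobs, 2, seed = 3)
  expect_length(unique(km2$assignment[1:20]), 1L)
  expect_length(unique(km2$assignment[21:40]), 1L)
  expect_false(km2$assignment[1] == km2$assignment[21])
})

test_that("the SSE elbow picks the true blob count and collapses for one blob", {
  blobs3 <- hdpm:::with_seed(4, do.call(rbind, lapply(c(0, 50, 100),
    function(m) cbind(rnorm(30, m, 0.5), rnorm(30, m, 0.5)))))
  expect_equal(choose_k(blobs3, 1:6, 0.1, seed = 5), 3L)

  one <- matrix(5, nrow = 40, ncol = 2)  # point mass: SSE flat at zero
  expect_equal(choose_k(one, 1:6, 0.1, seed = 6), 1L)
  expect_error(choose_k(one, integer(0), 0.1), "k_range")
})

test_that("8:1:1 splitting follows the small-n rounding rule and partitions", {
  s100 <- split_8_1_1(1:100, seed = 1)
  expect_equal(lengths(s100), c(train = 80L, validation = 10L, test = 10L))
  s10 <- split_8_1_1(1:10, seed = 1)
  expect_equal(lengths(s10), c(train = 8L, validation = 1L, test = 1L))
  s7 <- split_8_1_1(1:7, seed = 1)
  expect_equal(lengths(s7), c(train = 5L, validation = 1L, test = 1L))
  expect_setequal(unlist(s7), 1:7)
  expect_error(split_8_1_1(1:2, seed = 1), "at least 3")
})

test_that("SMOTE interpolates on the seed-neighbor segment", {
  set.seed(10)
  minority <- cbind(a = rnorm(30), b = rnorm(30, sd = 10))
  expect_equal(nrow(smote(minority, 0, seed = 1)), 0L)

  twin <- minority[c(1, 1), ]
  syn <- smote(twin, 5, seed = 2)
  expect_true(all(apply(syn, 1, function(r) all(r == minority[1, ]))))
  expect_error(smote(minority[1, , drop = FALSE], 3), "at least 2")

  syn <- smote(minority, 1000, k = 5, seed = 3)
  lo <- pmin(minority[attr(syn, "seed_idx"), ],
             minority[attr(syn, "neighbor_idx"), ])
  hi <- pmax(minority[attr(syn, "seed_idx"), ],
             minority[attr(syn, "neighbor_idx"), ])
  expect_true(all(syn >= lo - 1e-12 & syn <= hi + 1e-12))
})

test_that("USCOM balances the training set and quarantines synthetic rows", {
  g <- gen_tabular(tabular_spec(n = 90, p = 5, n_informative = 2,
                                effect_size = 1.5, class_ratio = c(2, 1),
                                seed = 20))
  b <- run_uscom(g$X, g$y, uscom_config(undersample_ratio = 1, seed = 21))
  counts <- table(b$train$y)
  expect_equal(unname(counts[1]), unname(counts[2]))
  expect_true(all(b$validation$provenance == "original"))
  expect_true(all(b$test$provenance == "original"))
  # original rows partition across roles
  orig <- c(b$train$row_ids[b$train$provenance == "original"],
            b$validation$row_ids, b$test$row_ids)
  expect_false(any(duplicated(orig)))

  expect_error(run_uscom(g$X, rep(0L, nrow(g$X)), uscom_config()),
               "both classes")
})

test_that("an already-balanced training set needs no synthetics", {
  set.seed(22)
  X <- cbind(a = rnorm(60), b = rnorm(60))
  y <- rep(0:1, 30)
  b <- run_uscom(X, y, uscom_config(undersample_ratio = 1,
                                    k_range = 1L, seed = 23))
  expect_equal(b$meta$n_synthetic, 0L)
})

test_that("bundles write three CSVs plus a manifest", {
  g <- gen_tabular(tabular_spec(n = 60, p = 4, class_ratio = c(3, 2),
                                seed = 24))
  b <- run_uscom(g$X, g$y, uscom_config(seed = 25))
  dir <- withr::local_tempdir()
  write_split_bundle(b, dir)
  expect_setequal(list.files(dir),
                  c("train.csv", "validation.csv", "test.csv",
                    "manifest.json"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$counts$train, length(b$train$y))
})
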