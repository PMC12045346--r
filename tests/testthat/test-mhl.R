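# The methylation haplotype load statistic, the sample x block matrix,
# missingness handling and KNN imputation.

test_that("mhl matches the substring-enumeration oracle on random pools", {
  set.seed(101)
  for (rep in 1:200) {
    pool <- random_patterns(sample(1:8, 1))
    expect_equal(mhl(pool$patterns, pool$counts),
                 oracle_mhl(pool$patterns, pool$counts),
                 tolerance = 1e-12)
  }
})

test_that("mhl boundary identities hold", {
  expect_equal(mhl(rep("111", 7), 3), 1)
  expect_equal(mhl(rep("000", 4)), 0)
  expect_true(is.na(mhl(character(0))))         # missing, not zero
  # 15 consecutive methylated CpGs: length cap at 10 still gives 1
  expect_equal(mhl(strrep("1", 15), max_len = 10), 1)
  expect_equal(mhl(strrep("1", 15), max_len = 10),
               oracle_mhl(strrep("1", 15), max_len = 10))
  # mixed example frozen against the oracle
  expect_equal(mhl(c("110", "011")), oracle_mhl(c("110", "011")))
  expect_error(mhl(c("112")), "strings over")
})

test_that("mhl is count-scale invariant and monotone in methylation", {
  set.seed(7)
  for (rep in 1:25) {
    pool <- random_patterns(5)
    expect_equal(mhl(pool$patterns, pool$counts),
                 mhl(pool$patterns, pool$counts * 3L))
    # flip one random 0 -> 1: MHL never decreases
    k <- sample(5, 1)
    p <- pool$patterns[k]
    zeros <- which(strsplit(p, "")[[1]] == "0")
    if (!length(zeros)) next
    j <- sample(zeros, 1)
    flipped <- pool$patterns
    substr(flipped[k], j, j) <- "1"
    expect_gte(mhl(flipped, pool$counts), mhl(pool$patterns, pool$counts))
  }
})

test_that("lengths with zero observed substrings are omitted, not zero", {
  # only 2-CpG reads: length-3 substrings unobservable; with the
  # omission convention MHL = (1*P1 + 2*P2) / (1 + 2)
  v <- mhl(c("11", "11", "10", "00"))
  p1 <- 5 / 8
  p2 <- 2 / 4
  expect_equal(v, (1 * p1 + 2 * p2) / 3)
})

test_that("matrix assembly records support and missingness correctly", {
  reg <- toy_region(6)
  blocks <- regions_as_blocks(reg)
  s1 <- toy_hap_set("s1", toy_pool(c("111111", "000000"), c(3L, 1L)))
  s2 <- toy_hap_set("s2", toy_pool(character(0)))
  m <- build_mhl_matrix(list(s1, s2), blocks)
  expect_equal(dim(m$values), c(2, 1))
  expect_equal(m$read_support["s1", 1], 4)
  expect_equal(m$read_support["s2", 1], 0)
  expect_true(is.na(m$values["s2", 1]))         # no reads -> missing
  expect_false(is.na(m$values["s1", 1]))
  # permuting samples permutes rows only
  m2 <- build_mhl_matrix(list(s2, s1), blocks)
  expect_equal(m2$values["s1", ], m$values["s1", ])
})

test_that("reads partially overlapping a block contribute their
           restriction", {
  reg <- toy_region(6)
  blocks <- discover_mhbs(
    toy_pool(rep(c("111111", "000000"), 30)), reg[1, ])
  expect_equal(nrow(blocks), 1)
  # a read covering CpGs 1-3 only partially overlaps the 6-CpG block
  s <- toy_hap_set("s", toy_pool(c("111", "111111"), c(2L, 1L),
                                 cpg_index = c(1L, 1L)))
  m <- build_mhl_matrix(list(s), blocks)
  expect_equal(m$values[1, 1],
               mhl(c("111", "111111"), c(2L, 1L)))
})

test_that("missingness filter uses a strict bound", {
  v <- matrix(NA_real_, 10, 3,
              dimnames = list(paste0("s", 1:10), paste0("b", 1:3)))
  v[1:2, 1] <- 0.5    # 80% missing: retained
  v[1, 2] <- 0.5      # 90% missing: removed
  v[, 3] <- 0.1       # complete
  m <- structure(list(values = v, read_support = (!is.na(v)) * 10,
                      sample_ids = rownames(v), mhb_ids = colnames(v)),
                 class = "mhl_matrix")
  out <- drop_high_missingness(m, 0.8)
  expect_equal(out$mhb_ids, c("b1", "b3"))
  expect_equal(attr(out, "n_dropped"), 1)
  # fully observed matrix unchanged
  full <- structure(list(values = v[, 3, drop = FALSE],
                         read_support = v[, 3, drop = FALSE] * 0 + 10,
                         sample_ids = rownames(v), mhb_ids = "b3"),
                    class = "mhl_matrix")
  expect_equal(drop_high_missingness(full)$values, full$values)
})

test_that("KNN imputation: identity, forced value, and beats column-mean
           on masked synthetic data", {
  set.seed(11)
  # no missing cells -> identity
  v <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("b", 1:5)))
  m <- structure(list(values = v, read_support = v * 0 + 10,
                      sample_ids = rownames(v), mhb_ids = colnames(v)),
                 class = "mhl_matrix")
  expect_equal(knn_impute(m)$values, v)
  # identical samples -> imputed value equals the common value
  v2 <- matrix(rep(c(0.2, 0.7, 0.4), each = 6), 6, 3,
               dimnames = list(paste0("s", 1:6), paste0("b", 1:3)))
  v2[3, 2] <- NA
  m2 <- structure(list(values = v2, read_support = (!is.na(v2)) * 10,
                       sample_ids = rownames(v2), mhb_ids = colnames(v2)),
                  class = "mhl_matrix")
  expect_equal(knn_impute(m2)$values[3, 2], 0.7)
  expect_false(anyNA(knn_impute(m2)$values))
  # random 10% mask of a correlated matrix: KNN RMSE < column-mean RMSE
  n <- 40; p <- 12
  f <- runif(n)
  truth <- sapply(1:p, function(j) pmin(1, pmax(0, f * runif(1, 0.5, 1) +
                                                  rnorm(n, 0, 0.05))))
  dimnames(truth) <- list(paste0("s", 1:n), paste0("b", 1:p))
  mask <- matrix(runif(n * p) < 0.1, n, p)
  v3 <- truth
  v3[mask] <- NA
  m3 <- structure(list(values = v3, read_support = (!is.na(v3)) * 10,
                       sample_ids = rownames(v3), mhb_ids = colnames(v3)),
                  class = "mhl_matrix")
  imp <- knn_impute(m3, k = 5)$values
  colmean <- v3
  for (j in 1:p) colmean[is.na(v3[, j]), j] <- mean(v3[, j], na.rm = TRUE)
  rmse <- function(x) sqrt(mean((x[mask] - truth[mask])^2))
  expect_lt(rmse(imp), rmse(colmean))
})
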