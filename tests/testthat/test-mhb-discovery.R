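# Linkage-disequilibrium r^2, block discovery and the CpG/read filter.

test_that("pairwise r2 matches the expanded-read Pearson oracle", {
  # perfect LD and balanced independence first
  p1 <- toy_pool(rep(c("11", "00"), c(50, 50)))
  expect_equal(pairwise_r2(p1, 1, 2)$r2, 1)
  p0 <- toy_pool(rep(c("11", "10", "01", "00"), each = 25))
  expect_equal(pairwise_r2(p0, 1, 2)$r2, 0)
  # the worked 2x2 example
  px <- toy_pool(rep(c("11", "10", "01", "00"), c(40, 10, 10, 40)))
  expect_equal(pairwise_r2(px, 1, 2)$r2, oracle_r2(40, 10, 10, 40),
               tolerance = 1e-12)
  # random tables
  set.seed(303)
  for (rep in 1:200) {
    n <- sample(4:60, 4, replace = TRUE)
    pool <- toy_pool(rep(c("11", "10", "01", "00"), n))
    got <- pairwise_r2(pool, 1, 2)
    want <- oracle_r2(n[1], n[2], n[3], n[4])
    if (is.na(want)) {
      expect_false(got$defined)
    } else {
      expect_equal(got$r2, want, tolerance = 1e-10)
      expect_equal(got$n_reads, sum(n))
    }
  }
})

test_that("r2 is symmetric in sites and under joint relabeling", {
  set.seed(9)
  pool <- toy_pool(replicate(80, paste(rbinom(3, 1, 0.5), collapse = "")),
                   counts = sample(1:5, 80, replace = TRUE))
  a <- pairwise_r2(pool, 1, 3)
  b <- pairwise_r2(pool, 3, 1)
  expect_equal(a$r2, b$r2)
  # relabel methylated <-> unmethylated at both sites simultaneously
  swapped <- pool
  swapped$pattern <- chartr("01", "10", pool$pattern)
  expect_equal(pairwise_r2(swapped, 1, 3)$r2, a$r2)
})

test_that("monomorphic sites leave r2 undefined and break blocks", {
  pool <- toy_pool(rep(c("111", "101"), c(30, 30)))  # site 2 varies, 1,3 not
  expect_false(pairwise_r2(pool, 1, 2)$defined)
  reg <- toy_region(3)
  expect_equal(nrow(discover_mhbs(pool, reg[1, ])), 0)
})

test_that("perfect-LD pools give one block spanning the region", {
  reg <- toy_region(6)
  pool <- toy_pool(rep(c("111111", "000000"), c(40, 40)))
  b <- discover_mhbs(pool, reg[1, ])
  expect_equal(nrow(b), 1)
  expect_equal(b$n_cpgs, 6)
  expect_equal(b$first_idx, 1)
  expect_equal(b$last_idx, 6)
  expect_equal(b$cpg_positions[[1]], reg$cpg_positions[[1]])
})

test_that("independent CpGs yield no blocks; planted runs are recovered
           exactly (oracle-checked adjacent pairs)", {
  set.seed(1234)
  reg <- toy_region(10)
  # per-read iid flips: no LD
  null_pool <- sim_pool(400, 10, function(n) rep(0.5, n))
  expect_equal(nrow(discover_mhbs(null_pool, reg[1, ])), 0)
  # plant perfect LD among sites 1-4 and 7-10, independence elsewhere
  plant <- function(n) {
    t(vapply(seq_len(n), function(i) {
      b1 <- rbinom(1, 1, 0.5)
      b2 <- rbinom(1, 1, 0.5)
      c(rep(b1, 4), rbinom(2, 1, 0.5), rep(b2, 4))
    }, numeric(10)))
  }
  m <- plant(400)
  pool <- toy_pool(apply(m, 1, paste, collapse = ""))
  b <- discover_mhbs(pool, reg[1, ])
  expect_equal(nrow(b), 2)
  expect_equal(b$first_idx, c(1, 7))
  expect_equal(b$last_idx, c(4, 10))
  # blocks are disjoint, sorted, inside the region
  expect_true(all(diff(b$start) > 0))
  expect_true(all(b$start >= reg$start[1] & b$end <= reg$end[1]))
  # oracle: every adjacent pair inside a block has r2 > 0.3 by direct
  # correlation of the planted columns; boundary pairs do not
  r2col <- function(i, j) suppressWarnings(cor(m[, i], m[, j])^2)
  expect_true(all(sapply(1:3, function(i) r2col(i, i + 1)) > 0.3))
  expect_true(all(sapply(7:9, function(i) r2col(i, i + 1)) > 0.3))
  expect_lt(r2col(4, 5), 0.3)
  expect_lt(r2col(6, 7), 0.3)
})

test_that("discovery is invariant to sample pooling order and respects
           min_pair_reads", {
  set.seed(77)
  reg <- toy_region(5)
  pool <- sim_pool(300, 5, function(n) ifelse(runif(n) < 0.4, 0.95, 0.05))
  perm <- pool[sample(nrow(pool)), ]
  b1 <- discover_mhbs(pool, reg[1, ])
  b2 <- discover_mhbs(perm, reg[1, ])
  expect_equal(b1$start, b2$start)
  expect_equal(b1$end, b2$end)
  # too few informative reads: nothing passes
  tiny <- toy_pool(rep(c("11111", "00000"), c(4, 4)))
  expect_equal(nrow(discover_mhbs(tiny, reg[1, ], min_pair_reads = 10)), 0)
  expect_equal(nrow(discover_mhbs(tiny, reg[1, ], min_pair_reads = 8)), 1)
})

test_that("regions with fewer than 3 CpGs produce no blocks, with a
           message", {
  reg <- toy_region(2)
  pool <- toy_pool(rep(c("11", "00"), c(20, 20)))
  expect_message(b <- discover_mhbs(pool, reg[1, ]), "<3")
  expect_equal(nrow(b), 0)
})

test_that("filter cascade retains exactly the blocks passing both
           criteria, with strict read boundary", {
  # 10 constructed blocks; 4 fail exactly one criterion each
  blocks <- data.frame(
    mhb_id = sprintf("b%02d", 1:10),
    chrom = "chr1", start = (1:10) * 1000L, end = (1:10) * 1000L + 100L,
    region_name = sprintf("T%04d", 1:10),
    region_class = c(rep("target", 8), "positive_control",
                     "negative_control"),
    first_idx = 1L, last_idx = 5L,
    n_cpgs = c(2L, 3L, 5L, 2L, 8L, 4L, 3L, 5L, 4L, 6L),
    stringsAsFactors = FALSE)
  blocks$cpg_positions <- replicate(10, 1:5, simplify = FALSE)
  class(blocks) <- c("mhb_set", "data.frame")
  med <- c(100, 50, 80, 90, 40, 120, 51, 200, 70, 90)
  supp <- matrix(rep(med, each = 5), 5, 10,
                 dimnames = list(paste0("s", 1:5), blocks$mhb_id))
  out <- filter_mhbs(blocks, supp, min_cpgs = 3, min_median_reads = 50)
  # b01 (2 CpGs), b02 (median exactly 50), b04 (2 CpGs), b05 (median 40)
  expect_equal(out$mhb_id, c("b03", "b06", "b07", "b08", "b09", "b10"))
  expect_equal(attr(out, "n_dropped"), 4)
  # control-overlapping blocks are labelled, not removed
  expect_equal(out$is_control,
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})
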