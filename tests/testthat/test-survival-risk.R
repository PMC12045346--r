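# Cox screening, panel selection, composite/risk scores, KM/log-rank and
# the ctDNA-fraction correlation screen.

sim_surv <- function(n, beta, x = rnorm(n), baseline_median = 20,
                     censor = 40, shape = 1) {
  t_event <- baseline_median * (-log(runif(n)) / log(2))^(1 / shape) *
    exp(-beta * x / shape)
  time <- pmin(t_event, censor)
  list(x = x, time = time, event = as.integer(t_event <= censor))
}

test_that("cox_univariate recovers a planted log-hazard and is affine
           equivariant", {
  set.seed(31)
  d <- sim_surv(300, beta = 0.8)
  fit <- cox_univariate(d$x, d$time, d$event)
  expect_lt(abs(fit$beta - 0.8), 0.2)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
  # doubling the covariate scale halves beta, keeps the linear predictor
  fit2 <- cox_univariate(2 * d$x, d$time, d$event)
  expect_equal(fit2$beta, fit$beta / 2, tolerance = 1e-6)
  expect_equal(fit2$p_value, fit$p_value, tolerance = 1e-6)
  expect_error(cox_univariate(rep(1, 300), d$time, d$event), "constant")
})

test_that("null Cox p-values are roughly uniform", {
  set.seed(32)
  p <- replicate(200, {
    d <- sim_surv(60, beta = 0)
    cox_univariate(d$x, d$time, d$event)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("panel selection collapses genes by max HR with deterministic
           ties", {
  fits <- list(
    m1 = list(p_value = 0.001, hr = 2.0, beta = log(2.0), flagged = FALSE),
    m2 = list(p_value = 0.002, hr = 3.0, beta = log(3.0), flagged = FALSE),
    m3 = list(p_value = 0.003, hr = 2.5, beta = log(2.5), flagged = FALSE),
    m4 = list(p_value = 0.500, hr = 1.1, beta = log(1.1), flagged = FALSE),
    m5 = list(p_value = 0.004, hr = 2.5, beta = log(2.5), flagged = FALSE))
  cand <- data.frame(
    mhb_id = paste0("m", 1:5),
    gene = c("A", "A", "B", "C", "B"),
    rank_p = c(1e-5, 2e-5, 3e-5, 4e-5, 5e-5),
    start = c(100, 200, 300, 400, 250))
  expect_warning(panel <- select_panel(cand, fits, top_k = 5, alpha = 0.05),
                 "significant candidates")
  # m4 fails the Cox gate; gene A -> m2 (higher HR); gene B: m3 vs m5 tie
  # on HR -> leftmost start wins (m5 at 250)
  expect_setequal(panel$mhb_id, c("m2", "m5"))
  # distinct genes: panel = top_k by rank_p
  cand2 <- cand
  cand2$gene <- paste0("G", 1:5)
  p2 <- select_panel(cand2, fits, top_k = 3)
  expect_equal(nrow(p2), 3)
  p3 <- select_panel(cand2, fits, top_k = 2)
  expect_equal(p3$mhb_id, c("m1", "m2"))
})

test_that("composite score is exact linear arithmetic", {
  v <- matrix(c(0.1, 0.2, 0.3,
                0.0, 0.5, 1.0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("b1", "b2", "b3")))
  m <- structure(list(values = v, read_support = v * 0 + 10,
                      sample_ids = rownames(v), mhb_ids = colnames(v)),
                 class = "mhl_matrix")
  panel <- data.frame(mhb_id = c("b1", "b2", "b3"),
                      beta = c(1.5, -0.5, 2.0))
  C <- composite_score(panel, m)
  expect_equal(unname(C), c(1.5 * 0.1 - 0.5 * 0.2 + 2.0 * 0.3,
                            1.5 * 0 - 0.5 * 0.5 + 2.0 * 1.0))
  # all-zero MHL rows give 0; single member gives beta * M
  expect_equal(unname(composite_score(panel, m)[v[, 1] == 99]), numeric(0))
  one <- composite_score(panel[2, ], m)
  expect_equal(unname(one), -0.5 * v[, 2], ignore_attr = TRUE)
})

test_that("risk score: median split sizes, tie-to-low, order invariance", {
  set.seed(41)
  n <- 49
  d <- sim_surv(n, beta = 1, x = rnorm(n))
  comp <- data.frame(a = d$x, b = rnorm(n) * 0.1)
  rs <- risk_score(comp, d$time, d$event)
  expect_equal(sort(as.vector(table(rs$group))), c(floor(n / 2), ceiling(n / 2)))
  expect_true(all(rs$score[rs$group == "high"] > rs$median))
  expect_true(all(rs$score[rs$group == "low"] <= rs$median))
  # permuting patients permutes scores identically
  perm <- sample(n)
  rs2 <- risk_score(comp[perm, ], d$time[perm], d$event[perm])
  expect_equal(unname(rs2$score), unname(rs$score[perm]), tolerance = 1e-8)
  # composite-only model preserves patient ranking
  rs3 <- risk_score(comp["a"], d$time, d$event)
  expect_equal(order(rs3$score), order(comp$a))
  # constant covariate dropped with warning
  expect_warning(risk_score(cbind(comp, k = 1), d$time, d$event),
                 "constant")
})

test_that("km_logrank matches the O-E oracle and the Cox score test", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 60
    g <- rep(c("low", "high"), each = n / 2)
    d <- sim_surv(n, beta = 0.7, x = as.numeric(g == "high"))
    km <- km_logrank(g, d$time, d$event)
    orc <- oracle_logrank(d$time, d$event, g)
    expect_equal(km$chisq, orc$chisq, tolerance = 1e-8)
    expect_equal(km$p_value, orc$p, tolerance = 1e-8)
    # known equivalence with the score (log-rank) test of a binary Cox fit
    cf <- survival::coxph(survival::Surv(d$time, d$event) ~ I(g == "high"),
                          ties = "breslow")
    expect_equal(km$chisq, unname(summary(cf)$sctest["test"]),
                 tolerance = 1e-6)
  }
})

test_that("km medians: identical groups agree; zero-event group not
           reached", {
  time <- c(5, 10, 15, 20, 5, 10, 15, 20)
  event <- c(1, 1, 1, 1, 1, 1, 1, 1)
  g <- rep(c("a", "b"), each = 4)
  km <- km_logrank(g, time, event)
  expect_equal(km$medians[["a"]], km$medians[["b"]])
  expect_gt(km$p_value, 0.99)
  km2 <- km_logrank(g, time, c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_true(is.na(km2$medians[["b"]]))
})

test_that("ctDNA screen: exact linear column flagged, missing and
           low-fraction exclusions enforced", {
  set.seed(61)
  n <- 20
  frac <- c(runif(8, 0, 0.01), runif(12, 0.02, 0.6))  # 8 ineligible
  v <- matrix(runif(n * 3), n, 3,
              dimnames = list(paste0("s", 1:n), c("lin", "noise", "holey")))
  v[, "lin"] <- 0.1 + 0.5 * frac                      # exact linear
  v[frac > 0.01, "holey"][1:8] <- NA                  # >50% missing
  m <- structure(list(values = v, read_support = (!is.na(v)) * 10,
                      sample_ids = rownames(v), mhb_ids = colnames(v)),
                 class = "mhl_matrix")
  scr <- ctdna_correlation_screen(m, frac)
  expect_equal(scr$n_eligible, 12)
  tab <- scr$table
  expect_equal(tab$r[tab$mhb_id == "lin"], 1, tolerance = 1e-10)
  expect_true(tab$flagged[tab$mhb_id == "lin"])
  expect_true(tab$skipped[tab$mhb_id == "holey"])
  # eligibility count check: only fraction > 1% patients enter
  expect_equal(tab$n[tab$mhb_id == "lin"], 12)
  # abort with too few eligible patients
  expect_error(ctdna_correlation_screen(m, rep(0.001, n)), "aborted")
})
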