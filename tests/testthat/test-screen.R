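make_tm <- function(cols, groups) {
  v <- do.call(cbind, cols)
  rownames(v) <- paste0("g", seq_len(nrow(v)))
  trait_matrix(v, groups)
}

test_that("frequency filter applies strict 1%/99% bounds", {
  n <- 1000L
  cols <- list(rare = c(rep(1L, 5), rep(0L, n - 5)),        # f = 0.005
               boundary = c(rep(1L, 10), rep(0L, n - 10)),  # f = 0.010 exactly
               mid = rep(c(1L, 0L), n / 2),                 # f = 0.5
               ubiq = c(rep(1L, n - 5), rep(0L, 5)))        # f = 0.995
  tm <- make_tm(cols, c("system", "system", "system", "cas"))
  kept <- suppressMessages(frequency_filter(tm))
  expect_identical(kept, "mid")
  expect_error(frequency_filter(tm, lo = 0.5, hi = 0.2), "lo must be < hi")
  expect_message(frequency_filter(tm), "rare")
})

test_that("contingency tables count joint presence/absence correctly", {
  tm <- make_tm(list(X = c(1L, 1L, 0L, 0L), Y = c(1L, 0L, 1L, 0L)),
                c("system", "cas"))
  ct <- contingency_table(tm, "X", "Y")
  expect_equal(unclass(ct)[c("a", "b", "c", "d")],
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  tm2 <- make_tm(list(X = c(1L, 0L), Y = c(1L, 0L)), c("system", "cas"))
  expect_equal(as.integer(contingency_table(tm2, "X", "Y")), c(1L, 0L, 0L, 1L))
  # swapping traits transposes: (a, c, b, d)
  ct_xy <- contingency_table(tm, "X", "Y")
  ct_yx <- contingency_table(tm, "Y", "X")
  expect_equal(as.integer(ct_yx), as.integer(ct_xy)[c(1L, 3L, 2L, 4L)])
  expect_error(contingency_table(tm, "X", "nope"), "unknown trait id")
})

test_that("phi matches direct evaluation and flags zero margins", {
  expect_equal(phi_coef(c(a = 1, b = 1, c = 1, d = 1)), 0)
  expect_equal(phi_coef(c(a = 5, b = 0, c = 0, d = 5)), 1)
  expect_equal(phi_coef(c(a = 40, b = 10, c = 10, d = 40)), 0.6)
  expect_warning(res <- phi_coef(c(a = 0, b = 0, c = 3, d = 5)), "undefined")
  expect_true(is.na(res))
})

test_that("phi equals the Pearson correlation of the binary indicators", {
  set.seed(101)
  for (i in 1:200) {
    t <- random_contingency()
    x <- rep(c(1, 1, 0, 0), t)
    y <- rep(c(1, 0, 1, 0), t)
    expect_equal(phi_coef(t), suppressWarnings(cor(x, y)), tolerance = 1e-12)
  }
})

test_that("phi is antisymmetric under complement and symmetric under swap", {
  set.seed(202)
  for (i in 1:50) {
    t <- unname(random_contingency())
    # complementing X swaps rows: (a,b,c,d) -> (c,d,a,b)
    expect_equal(phi_coef(t[c(3L, 4L, 1L, 2L)]), -phi_coef(t), tolerance = 1e-12)
    # swapping traits transposes: (a,c,b,d)
    expect_equal(phi_coef(t[c(1L, 3L, 2L, 4L)]), phi_coef(t), tolerance = 1e-12)
  }
})

test_that("fisher p matches enumeration on canonical tables", {
  expect_equal(fisher_exact_p(c(a = 1, b = 1, c = 1, d = 1)), 1)
  expect_equal(fisher_exact_p(c(a = 3, b = 1, c = 1, d = 3)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_p(c(a = 5, b = 0, c = 0, d = 5)), 2 / 252,
               tolerance = 1e-12)
})

test_that("fisher p agrees with the hypergeometric enumeration oracle", {
  set.seed(303)
  for (i in 1:300) {
    t <- random_contingency(n_max = 40L)
    expect_equal(fisher_exact_p(t),
                 oracle_fisher(t[["a"]], t[["b"]], t[["c"]], t[["d"]]),
                 tolerance = 1e-12)
  }
})

test_that("control matching filters by frequency and widens when thin", {
  n <- 1000L
  freqs <- c(target = 0.50, near1 = 0.495, near2 = 0.505, far = 0.60)
  cols <- lapply(freqs, function(f) c(rep(1L, round(f * n)),
                                      rep(0L, n - round(f * n))))
  tm <- make_tm(cols, c("system", "control", "control", "control"))
  sel <- match_controls("target", c("near1", "near2", "far"), tm, k = 2L,
                        seed = 1)
  expect_setequal(sel, c("near1", "near2"))
  # margin must widen (with a message) to reach k = 3
  expect_message(
    sel3 <- match_controls("target", c("near1", "near2", "far"), tm, k = 3L,
                           seed = 1),
    "widened")
  expect_setequal(sel3, c("near1", "near2", "far"))
  expect_identical(match_controls("target", c("near1", "near2", "far"), tm,
                                  k = 2L, seed = 7),
                   match_controls("target", c("near1", "near2", "far"), tm,
                                  k = 2L, seed = 7))
  expect_error(match_controls("target", c("near1"), tm, k = 2L, seed = 1),
               "smaller than k")
})

test_that("delta-phi t-test matches the closed-form t distribution", {
  res <- delta_phi_test(c(0.1, 0.2, 0.3))
  expect_equal(res$t, 3.4641016, tolerance = 1e-6)
  # df = 2 one-sided tail: p = 0.5 - t / (2 sqrt(t^2 + 2))
  expect_equal(res$p, 0.5 - res$t / (2 * sqrt(res$t^2 + 2)), tolerance = 1e-12)
  expect_equal(res$p, 0.0371, tolerance = 1e-3)

  expect_warning(res0 <- delta_phi_test(c(0, 0, 0)), "zero-variance")
  expect_equal(res0$p, 1)
  expect_warning(resp <- delta_phi_test(c(0.2, 0.2, 0.2)), "zero-variance")
  expect_equal(resp$p, 0)

  sym <- delta_phi_test(c(-0.4, 0.4))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 0.5)
  expect_error(delta_phi_test(0.3), "at least 2")
})

test_that("bonferroni uses the run-defined test count and is monotone", {
  b <- bonferroni_select(setNames(c(1e-4, 1e-3), c("p1", "p2")), alpha = 0.05)
  expect_equal(b$m, 2L)
  # with the m = 246 of a large screen: 1e-4 passes, 1e-3 fails
  ps <- setNames(runif(246, 0.3, 1), paste0("x", 1:246))
  ps[1] <- 1e-4; ps[2] <- 1e-3
  b246 <- bonferroni_select(ps, alpha = 0.05)
  expect_true(b246$significant[[1L]])
  expect_false(b246$significant[[2L]])
  expect_equal(b246$threshold, 0.05 / 246)
  # m = 1 reduces to p <= alpha
  expect_true(bonferroni_select(c(p = 0.049))$significant[[1L]])
  expect_false(bonferroni_select(c(p = 0.051))$significant[[1L]])
  # monotone: decreasing any p never removes a call
  ps2 <- ps; ps2[3] <- ps[3] / 10
  b2 <- bonferroni_select(ps2, alpha = 0.05)
  expect_true(all(b2$significant >= b246$significant))
})

test_that("screen flags an identical system/cas column pair as strongest", {
  set.seed(11)
  n <- 400L
  shared <- rbinom(n, 1L, 0.5)
  cols <- c(list(sysA = shared, sysB = rbinom(n, 1L, 0.5), casX = shared,
                 casY = rbinom(n, 1L, 0.5)),
            setNames(lapply(1:12, function(i) rbinom(n, 1L, 0.5)),
                     paste0("ctrl", 1:12)))
  tm <- make_tm(cols, c("system", "system", "cas", "cas", rep("control", 12)))
  scr <- suppressMessages(
    screen_associations(tm, k_controls = 5L, seed = 99))
  rec <- scr$records
  hit <- rec[rec$system == "sysA" & rec$cas == "casX", ]
  expect_equal(hit$phi, 1)
  expect_equal(hit$fisher_p, min(rec$fisher_p))
  expect_true(hit$bonferroni_significant)
  expect_equal(hit$sign, 1)
  expect_equal(unique(rec$m_tests), 4L)
  # determinism of the whole screen
  scr2 <- suppressMessages(screen_associations(tm, k_controls = 5L, seed = 99))
  expect_identical(scr$records, scr2$records)
})

test_that("under a global null the Bonferroni screen controls FWER", {
  # 150 replicate screens of i.i.d. traits; family-wise error <= alpha
  set.seed(404)
  hits <- vapply(1:150, function(r) {
    n <- 120L
    cols <- c(setNames(lapply(1:3, function(i) rbinom(n, 1L, 0.5)),
                       paste0("sys", 1:3)),
              setNames(lapply(1:3, function(i) rbinom(n, 1L, 0.5)),
                       paste0("cas", 1:3)),
              setNames(lapply(1:8, function(i) rbinom(n, 1L, 0.5)),
                       paste0("ctrl", 1:8)))
    tm <- make_tm(cols, c(rep("system", 3), rep("cas", 3), rep("control", 8)))
    scr <- suppressMessages(
      screen_associations(tm, k_controls = 4L, seed = 1000 + r))
    any(scr$records$bonferroni_significant)
  }, TRUE)
  # binomial 3 SD above alpha = 0.05: 0.05 + 3 sqrt(.05*.95/150) ~ 0.103
  expect_lt(mean(hits), 0.11)
})
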