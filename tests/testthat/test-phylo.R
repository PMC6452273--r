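test_that("build_generator maps rates to the 4-state generator", {
  Z <- build_generator(independent_model(0, 0, 0, 0))
  expect_equal(Z, matrix(0, 4, 4, dimnames = dimnames(Z)))

  Q1 <- build_generator(independent_model(1, 1, 1, 1))
  off <- Q1; diag(off) <- 0
  # allowed moves have rate 1, double transitions are exactly 0
  expect_equal(sort(unique(as.vector(off))), c(0, 1))
  expect_true(all(diag(Q1) == -2))
  expect_identical(Q1[1, 4], 0); expect_identical(Q1[4, 1], 0)
  expect_identical(Q1[2, 3], 0); expect_identical(Q1[3, 2], 0)
  expect_equal(unname(rowSums(Q1)), rep(0, 4))

  im <- independent_model(0.3, 1.1, 2.2, 0.7)
  expect_identical(build_generator(im), build_generator(as_dependent(im)))
  expect_error(dependent_model(1, 1, -2, 1, 1, 1, 1, 1), "negative rate")
})

test_that("transition matrices are stochastic and stationary dist is fixed", {
  set.seed(55)
  for (i in 1:20) {
    Q <- build_generator(random_pair_model())
    for (t in c(0, 1e-4, 0.5, 3, 100)) {
      P <- transition_matrix(Q, t)
      expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
      expect_true(all(P >= 0))
    }
    pi <- stationary_dist(Q)
    expect_equal(as.numeric(pi %*% Q), rep(0, 4), tolerance = 1e-10)
  }
})

test_that("pruning handles frozen chains exactly", {
  tr <- read_newick(text = "(A:0,B:0);")
  frozen <- independent_model(0, 0, 0, 0)
  tm <- make_tiny_tm(tr, x = c(A = 1L, B = 1L), y = c(A = 1L, B = 1L))
  # zero-length branches, zero rates: likelihood = P(root = (1,1)) = 1/4
  expect_equal(pruning_loglik(tr, tm, frozen), log(0.25), tolerance = 1e-12)
  tm_bad <- make_tiny_tm(tr, x = c(A = 1L, B = 0L), y = c(A = 1L, B = 1L))
  expect_identical(pruning_loglik(tr, tm_bad, frozen), -Inf)
})

test_that("pruning matches exhaustive enumeration on small trees", {
  set.seed(66)
  for (i in 1:40) {
    n <- sample(3:6, 1L)
    tr <- simulate_tree(n, 1, seed = 7000 + i)
    model <- random_pair_model()
    tm <- make_tiny_tm(tr, x = rbinom(n, 1L, 0.5), y = rbinom(n, 1L, 0.5))
    for (prior in c("uniform", "stationary")) {
      expect_equal(pruning_loglik(tr, tm, model, root_prior = prior),
                   oracle_pruning(tr, tm, model, root_prior = prior),
                   tolerance = 1e-8)
    }
  }
})

test_that("pruning errors when a tip lacks trait values", {
  tr <- simulate_tree(5, 1, seed = 1)
  tm <- make_tiny_tm(tr, x = rbinom(5, 1, 0.5), y = rbinom(5, 1, 0.5))
  tm_small <- subset_traits(tm, genomes = tr$tip.label[1:4])
  expect_error(pruning_loglik(tr, tm_small, independent_model(1, 1, 1, 1)),
               "missing from trait matrix")
})

test_that("likelihood is invariant to re-rooting under a stationary prior", {
  # reversible (independent, embedded) model + stationary root prior:
  # the unrooted tree determines the likelihood
  set.seed(77)
  tr <- simulate_tree(10, 1, seed = 19)
  tm <- make_tiny_tm(tr, x = rbinom(10, 1, 0.5), y = rbinom(10, 1, 0.5))
  model <- independent_model(0.7, 1.3, 0.4, 0.9)
  base <- pruning_loglik(tr, tm, model, root_prior = "stationary")
  un <- ape::unroot(tr)
  for (og in c(3L, 7L)) {
    rr <- ape::root(un, outgroup = tr$tip.label[og], resolve.root = TRUE)
    rr$edge.length[is.na(rr$edge.length)] <- 0
    expect_equal(pruning_loglik(rr, tm, model, root_prior = "stationary"),
                 base, tolerance = 1e-8)
  }
})

test_that("fit_pair_model recovers independent rates and is deterministic", {
  errs <- sapply(1:8, function(i) {
    tr <- simulate_tree(400, 2, seed = 300 + i)
    tm <- simulate_pair_traits(tr, independent_model(1, 1, 1, 1),
                               seed = 400 + i)
    f <- fit_pair_model(tr, tm, "independent", n_starts = 3L, seed = 500 + i)
    max(abs(log(f$rates)))   # log-error relative to true rates of 1
  })
  expect_lt(median(errs), log(2)) # median fit within a factor of 2
  tr <- simulate_tree(60, 2, seed = 1)
  tm <- simulate_pair_traits(tr, independent_model(1, 1, 1, 1), seed = 2)
  f1 <- fit_pair_model(tr, tm, "dependent", n_starts = 3L, seed = 3)
  f2 <- fit_pair_model(tr, tm, "dependent", n_starts = 3L, seed = 3)
  expect_identical(f1, f2)
})

test_that("dependent fit never falls below the independent fit (nesting)", {
  for (i in 1:10) {
    tr <- simulate_tree(80, 2, seed = 600 + i)
    model <- if (i %% 2) independent_model(1, 1, 1, 1) else
      dependent_model(1, 1, 1, 3, 1, 1, 1, 0.5)
    tm <- simulate_pair_traits(tr, model, seed = 700 + i)
    res <- suppressMessages(
      correlation_test(tr, tm, n_starts = 2L, seed = 800 + i))
    expect_gte(res$lnl_dep, res$lnl_indep - 1e-4)
  }
})

test_that("the LRT uses the chi-square(4) tail in closed form", {
  fake_fit <- function(kind, ll, id = "x") {
    structure(list(kind = kind, loglik = ll, data_id = id),
              class = "pair_fit")
  }
  eq <- lrt(fake_fit("independent", -100), fake_fit("dependent", -100))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # survival of chi^2_4 at x: exp(-x/2) (1 + x/2)
  s6 <- lrt(fake_fit("independent", -100), fake_fit("dependent", -97))
  expect_equal(s6$statistic, 6)
  expect_equal(s6$p, exp(-3) * 4, tolerance = 1e-12)
  expect_equal(s6$p, 0.19915, tolerance = 1e-4)
  s20 <- lrt(fake_fit("independent", -110), fake_fit("dependent", -100))
  expect_equal(s20$p, exp(-10) * 11, tolerance = 1e-12)
  expect_equal(s20$p, 4.994e-4, tolerance = 1e-3)
  # clipped at zero under optimizer noise
  neg <- lrt(fake_fit("independent", -100), fake_fit("dependent", -100.001))
  expect_equal(neg$statistic, 0)
  expect_error(lrt(fake_fit("dependent", -1), fake_fit("dependent", -1)),
               "independent fit")
  expect_error(lrt(fake_fit("independent", -1, "x"),
                   fake_fit("dependent", -1, "y")),
               "different data")
})

test_that("median decision rule follows the strict threshold convention", {
  expect_equal(cooccurphylo:::median_even_mean(rep(0.005, 100)), 0.005)
  # even count: mean of the two middle order statistics
  expect_equal(cooccurphylo:::median_even_mean(c(rep(0.005, 50), rep(0.5, 50))),
               0.2525)
  expect_equal(cooccurphylo:::median_even_mean(c(0.3, 0.1, 0.2)), 0.2)
  # boundary: median exactly at the threshold is NOT significant
  tr <- simulate_tree(30, 2, seed = 4)
  tm <- simulate_pair_traits(tr, independent_model(1, 1, 1, 1), seed = 5)
  ct <- correlation_test(tr, tm, n_starts = 2L, seed = 6,
                         threshold = 0.01)
  expect_identical(ct$significant, ct$median_p < 0.01)
  ct2 <- correlation_test(tr, tm, n_starts = 2L, seed = 6,
                          threshold = ct$median_p)
  expect_false(ct2$significant)
})

test_that("bootstrap trees feed the median and errors name the tree", {
  tr <- simulate_tree(40, 2, seed = 9)
  tm <- simulate_pair_traits(tr, dependent_model(1, 1, 1, 5, 1, 1, 1, 0.2),
                             seed = 10)
  boots <- jitter_trees(tr, 4, length_cv = 0.15, seed = 11)
  ct <- suppressMessages(
    correlation_test(tr, tm, boot_trees = boots, n_starts = 2L, seed = 12))
  expect_length(ct$bootstrap_ps, 4L)
  expect_equal(ct$median_p,
               cooccurphylo:::median_even_mean(ct$bootstrap_ps))
  bad <- boots
  bad[[3L]] <- ape::drop.tip(bad[[3L]], tr$tip.label[1L])
  expect_error(
    suppressMessages(correlation_test(tr, tm, boot_trees = bad,
                                      n_starts = 2L, seed = 12)),
    "bootstrap tree 3")
})

test_that("fits agree with an independent Pagel-test implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(60, 2, seed = 21)
  tm <- simulate_pair_traits(tr, dependent_model(1, 1, 1, 4, 1, 1, 1, 0.25),
                             seed = 22)
  x <- setNames(tm$values[, 1L], rownames(tm$values))
  y <- setNames(tm$values[, 2L], rownames(tm$values))
  ref <- phytools::fitPagel(tr, factor(x), factor(y), method = "fitMk",
                            pi = "equal")
  mine <- correlation_test(tr, tm, n_starts = 4L, seed = 23)
  expect_equal(mine$lnl_indep, as.numeric(ref$independent.logL),
               tolerance = 0.05)
  expect_equal(mine$lnl_dep, as.numeric(ref$dependent.logL),
               tolerance = 0.05)
  expect_equal(mine$statistic,
               as.numeric(2 * (ref$dependent.logL - ref$independent.logL)),
               tolerance = 0.1)
})

test_that("deep clade structure fools Fisher more often than the LRT rule", {
  # two deep sister clades with short internal branches: independent slow
  # traits produce clade-level blocks that look associated across tips
  clade <- ape::stree(16, "balanced")
  clade$edge.length <- rep(0.08, nrow(clade$edge))
  c1 <- clade; c1$tip.label <- paste0("a", 1:16)
  c2 <- clade; c2$tip.label <- paste0("b", 1:16)
  nw <- paste0("(", sub(";$", "", ape::write.tree(c1)), ":4,",
               sub(";$", "", ape::write.tree(c2)), ":4);")
  deep <- read_newick(text = nw)
  slow <- independent_model(0.25, 0.25, 0.25, 0.25)
  res <- t(sapply(1:20, function(i) {
    tm <- simulate_pair_traits(deep, slow, seed = 900 + i)
    ct <- contingency_table(tm, "sys1", "cas1")
    fisher_hit <- !is.na(suppressWarnings(phi_coef(ct))) &&
      fisher_exact_p(ct) < 0.05 / 10
    lrt_hit <- suppressMessages(
      correlation_test(deep, tm, n_starts = 2L, seed = 950 + i))$median_p < 0.01
    c(fisher = fisher_hit, lrt = lrt_hit)
  }))
  expect_gt(mean(res[, "fisher"]), mean(res[, "lrt"]))
  expect_gt(mean(res[, "fisher"]), 0.3) # the confound is real on this tree
})
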