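#' Log-likelihood of a trait pair on a tree by Felsenstein pruning
#'
#' Computes the likelihood of the tip presence/absence patterns of two binary
#' traits under a `pair_model`, by post-order pruning over the 4 joint states
#' with per-branch transition matrices `exp(Q * t)`. The root partial
#' likelihoods are combined with the chosen prior. Data that are impossible
#' under the model (e.g. discordant tips under a frozen chain) yield `-Inf`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tm a [trait_matrix] with exactly two columns (X first, Y second)
#'   covering every tip of `tree`.
#' @param model a `pair_model`.
#' @param root_prior `"uniform"` (0.25 per joint state, the default) or
#'   `"stationary"` (the model's stationary distribution).
#' @return log-likelihood in natural-log units (possibly `-Inf`).
#' @export
pruning_loglik <- function(tree, tm, model,
                           root_prior = c("uniform", "stationary")) {
  root_prior <- match.arg(root_prior)
  dat <- pruning_data(tree, tm)
  Q <- build_generator(model)
  prior <- if (root_prior == "uniform") rep(0.25, 4L) else stationary_dist(Q)
  pruning_loglik_cpp(dat$edge, dat$edge_length, dat$n_tip, dat$tip_state,
                     Q, prior)
}

# Precompute the post-order edge list and tip joint states once per dataset;
# model fitting re-evaluates the likelihood hundreds of times on this.
pruning_data <- function(tree, tm) {
  stopifnot(inherits(tree, "phylo"), inherits(tm, "trait_matrix"))
  if (ncol(tm$values) != 2L) {
    stop("pruning requires a 2-column trait matrix (X, Y)")
  }
  missing <- setdiff(tree$tip.label, rownames(tm$values))
  if (length(missing)) {
    stop("tip(s) missing from trait matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  po <- ape::reorder.phylo(tree, "postorder")
  v <- tm$values[po$tip.label, , drop = FALSE]
  tip_state <- 1L + 2L * v[, 1L] + v[, 2L]  # 1=(0,0) 2=(0,1) 3=(1,0) 4=(1,1)
  list(edge = po$edge, edge_length = po$edge.length,
       n_tip = ape::Ntip(po), tip_state = as.integer(tip_state),
       data_id = paste(ape::Ntip(po), paste(colnames(v), collapse = "|"),
                       sum(tip_state * seq_along(tip_state)), sep = ":"))
}

# Fast generator assembly from a bare rate vector (no S3 validation); rates
# ordered as in independent_model()/dependent_model().
generator_from_rates <- function(rates, kind) {
  Q <- matrix(0, 4L, 4L)
  if (kind == "independent") {
    a1 <- rates[1L]; b1 <- rates[2L]; a2 <- rates[3L]; b2 <- rates[4L]
    Q[1L, 2L] <- a2; Q[1L, 3L] <- a1
    Q[2L, 1L] <- b2; Q[2L, 4L] <- a1
    Q[3L, 1L] <- b1; Q[3L, 4L] <- a2
    Q[4L, 2L] <- b1; Q[4L, 3L] <- b2
  } else {
    Q[1L, 2L] <- rates[1L]; Q[1L, 3L] <- rates[2L]
    Q[2L, 1L] <- rates[3L]; Q[2L, 4L] <- rates[4L]
    Q[3L, 1L] <- rates[5L]; Q[3L, 4L] <- rates[6L]
    Q[4L, 2L] <- rates[7L]; Q[4L, 3L] <- rates[8L]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

rate_names <- function(kind) {
  if (kind == "independent") c("alpha1", "beta1", "alpha2", "beta2")
  else c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
}

#' Maximum-likelihood fit of a pair model to tip data
#'
#' Maximizes [pruning_loglik()] over the model's rates by bounded
#' quasi-Newton search on log-rates (bounds `[1e-8, 1e3]`), from `n_starts`
#' starting points: a moment-based initialization (rates tuned so each
#' trait's stationary frequency matches its tip frequency, at an overall rate
#' of ~2 expected events per root-to-tip depth), seeded random perturbations
#' of it, and any supplied warm starts. The best converged start is returned.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tm a 2-column [trait_matrix].
#' @param kind `"independent"` (4 rates) or `"dependent"` (8 rates).
#' @param n_starts number of optimizer starts (default 5).
#' @param seed integer seed for the random starts.
#' @param root_prior as in [pruning_loglik()].
#' @param init list of extra warm-start rate vectors (on the natural scale).
#' @return a `pair_fit`: list with `kind`, `rates` (named), `loglik`,
#'   `n_starts`, `converged`, `best_start` and a data fingerprint.
#' @export
fit_pair_model <- function(tree, tm, kind = c("independent", "dependent"),
                           n_starts = 5L, seed = NULL,
                           root_prior = c("uniform", "stationary"),
                           init = NULL) {
  kind <- match.arg(kind)
  root_prior <- match.arg(root_prior)
  dat <- pruning_data(tree, tm)
  k <- if (kind == "independent") 4L else 8L
  lo <- log(1e-8); hi <- log(1e3)

  negll <- function(lr) {
    Q <- generator_from_rates(exp(lr), kind)
    prior <- if (root_prior == "uniform") rep(0.25, 4L) else
      tryCatch(stationary_dist(Q), error = function(e) rep(0.25, 4L))
    ll <- pruning_loglik_cpp(dat$edge, dat$edge_length, dat$n_tip,
                             dat$tip_state, Q, prior)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # moment-based start: stationary frequency per trait = tip frequency,
  # total rate per trait = 2 / mean root-to-tip depth
  v <- tm$values[, , drop = FALSE]
  fx <- min(max(mean(v[, 1L]), 0.02), 0.98)
  fy <- min(max(mean(v[, 2L]), 0.02), 0.98)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(mean(depths), 1e-6)
  r0 <- 2 / h
  mom4 <- pmin(pmax(c(r0 * fx, r0 * (1 - fx), r0 * fy, r0 * (1 - fy)),
                    1e-6), 1e2)
  mom <- if (kind == "independent") mom4 else
    mom4[c(3L, 1L, 4L, 1L, 2L, 3L, 2L, 4L)] # embedded-independent layout
  starts <- c(lapply(init, function(r) log(pmin(pmax(r, 1.1e-8), 0.9e3))),
              list(log(mom)))
  n_random <- max(0L, n_starts - length(starts))
  if (n_random > 0L) {
    rand <- with_seed(seed, lapply(seq_len(n_random), function(i) {
      log(mom) + stats::rnorm(k, 0, 1.5)
    }))
    starts <- c(starts, rand)
  }

  best <- NULL
  best_i <- NA_integer_
  conv <- logical(length(starts))
  for (i in seq_along(starts)) {
    res <- tryCatch(
      stats::nlminb(pmin(pmax(starts[[i]], lo), hi), negll,
                    lower = lo, upper = hi,
                    control = list(rel.tol = 1e-10, iter.max = 500L)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv[i] <- res$convergence == 0L
    if (is.null(best) || res$objective < best$objective) {
      best <- res
      best_i <- i
    }
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e10) {
    stop("fit_pair_model: no start converged to a finite likelihood (",
         kind, " model, ", dat$n_tip, " tips)")
  }
  structure(list(kind = kind,
                 rates = setNames(exp(best$par), rate_names(kind)),
                 loglik = -best$objective,
                 n_starts = length(starts),
                 converged = any(conv),
                 best_start = best_i,
                 root_prior = root_prior,
                 data_id = dat$data_id),
            class = "pair_fit")
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf("pair_fit (%s): lnL = %.4f\n  rates: %s\n", x$kind, x$loglik,
              paste(sprintf("%s=%.4g", names(x$rates), x$rates),
                    collapse = ", ")))
  invisible(x)
}

#' Likelihood-ratio test of correlated evolution
#'
#' Compares a dependent (8-rate) fit against a nested independent (4-rate)
#' fit of the same data: statistic `2 * (lnL_dep - lnL_indep)`, clipped at 0
#' (small negative values are optimizer noise under nesting), referred to a
#' chi-square distribution with 4 degrees of freedom (the difference in free
#' rates).
#'
#' @param fit_indep,fit_dep `pair_fit` objects from [fit_pair_model()] on the
#'   same data.
#' @return list with `statistic`, `df` (4) and `p`.
#' @export
lrt <- function(fit_indep, fit_dep) {
  stopifnot(inherits(fit_indep, "pair_fit"), inherits(fit_dep, "pair_fit"))
  if (fit_indep$kind != "independent" || fit_dep$kind != "dependent") {
    stop("lrt() expects an independent fit and a dependent fit, in that order")
  }
  if (!identical(fit_indep$data_id, fit_dep$data_id)) {
    stop("fits come from different data")
  }
  stat <- max(0, 2 * (fit_dep$loglik - fit_indep$loglik))
  list(statistic = stat, df = 4L,
       p = pchisq(stat, df = 4L, lower.tail = FALSE))
}

# Fit both models on one tree and return the LRT; the dependent fit is
# warm-started at the embedded independent MLE so nesting holds numerically.
fit_both_lrt <- function(tree, tm, n_starts, seed, root_prior,
                         init_indep = NULL, init_dep = NULL) {
  fi <- fit_pair_model(tree, tm, "independent", n_starts = n_starts,
                       seed = seed, root_prior = root_prior,
                       init = init_indep)
  embedded <- unname(as_dependent(
    independent_model(fi$rates[["alpha1"]], fi$rates[["beta1"]],
                      fi$rates[["alpha2"]], fi$rates[["beta2"]]))$rates)
  fd <- fit_pair_model(tree, tm, "dependent", n_starts = n_starts,
                       seed = if (is.null(seed)) NULL else seed + 1L,
                       root_prior = root_prior,
                       init = c(list(embedded), init_dep))
  list(fit_indep = fi, fit_dep = fd, lrt = lrt(fi, fd))
}

#' Correlated-evolution test with a bootstrap-tree median decision rule
#'
#' Runs the independent-vs-dependent likelihood-ratio test on the main tree
#' and on each supplied bootstrap tree, and calls the pair significant iff
#' the median of the per-tree LRT p-values is strictly below `threshold`
#' (default 0.01). With no bootstrap trees the main-tree p-value stands in
#' for the median. Bootstrap-tree fits are warm-started at the main-tree
#' maximum-likelihood rates.
#'
#' @param tree main `phylo` tree.
#' @param tm a 2-column [trait_matrix].
#' @param boot_trees optional list of bootstrap `phylo` trees (same tips).
#' @param n_starts optimizer starts per fit (default 5; bootstrap fits use
#'   `max(2, n_starts - 2)` plus the warm start).
#' @param threshold significance threshold on the median p (default 0.01,
#'   strict `<`).
#' @param seed integer seed.
#' @param root_prior as in [pruning_loglik()].
#' @return a `correlation_test`: list with `lnl_indep`, `lnl_dep`,
#'   `statistic`, `df`, `p_main`, `bootstrap_ps`, `median_p`, `n_trees`,
#'   `threshold`, `significant`, and the two main-tree fits.
#' @export
correlation_test <- function(tree, tm, boot_trees = NULL, n_starts = 5L,
                             threshold = 0.01, seed = NULL,
                             root_prior = c("uniform", "stationary")) {
  root_prior <- match.arg(root_prior)
  rec <- reconcile(tree, tm, "strict")
  main <- fit_both_lrt(rec$tree, rec$traits, n_starts, seed, root_prior)
  boot_ps <- if (length(boot_trees)) {
    ns_boot <- max(2L, n_starts - 2L)
    vapply(seq_along(boot_trees), function(i) {
      bt <- tryCatch(reconcile(boot_trees[[i]], tm, "strict"),
                     error = function(e) {
                       stop("bootstrap tree ", i, ": ", conditionMessage(e))
                     })
      res <- fit_both_lrt(bt$tree, bt$traits, ns_boot,
                          if (is.null(seed)) NULL else seed + 100L + i,
                          root_prior,
                          init_indep = list(unname(main$fit_indep$rates)),
                          init_dep = list(unname(main$fit_dep$rates)))
      res$lrt$p
    }, 0)
  } else {
    main$lrt$p
  }
  median_p <- median_even_mean(boot_ps)
  structure(list(lnl_indep = main$fit_indep$loglik,
                 lnl_dep = main$fit_dep$loglik,
                 statistic = main$lrt$statistic,
                 df = 4L,
                 p_main = main$lrt$p,
                 bootstrap_ps = boot_ps,
                 median_p = median_p,
                 n_trees = length(boot_ps),
                 threshold = threshold,
                 significant = median_p < threshold,
                 fit_indep = main$fit_indep,
                 fit_dep = main$fit_dep),
            class = "correlation_test")
}

# standard median: mean of the two middle order statistics for even counts
median_even_mean <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf(paste0(
    "correlated-evolution test: LRT = %.3f (df = %d), main-tree p = %.4g\n",
    "  median p over %d tree(s) = %.4g -> %ssignificant at %.3g\n"),
    x$statistic, x$df, x$p_main, x$n_trees, x$median_p,
    if (x$significant) "" else "not ", x$threshold))
  invisible(x)
}
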