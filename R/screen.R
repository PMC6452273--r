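#' Filter traits by presence frequency
#'
#' Keeps traits present in strictly more than `lo` and strictly less than
#' `hi` of the genomes; near-ubiquitous and near-absent traits carry almost
#' no co-occurrence information and are excluded from association testing.
#'
#' @param tm a [trait_matrix].
#' @param lo,hi frequency bounds (defaults 0.01 and 0.99); strict
#'   inequalities, so a trait at exactly `lo` or `hi` is excluded.
#' @return character vector of retained trait ids; excluded traits are
#'   reported via `message()` with their frequency.
#' @export
frequency_filter <- function(tm, lo = 0.01, hi = 0.99) {
  if (lo >= hi) stop("lo must be < hi")
  f <- trait_freq(tm)
  keep <- f > lo & f < hi
  if (any(!keep)) {
    message("frequency_filter: excluded ",
            paste(sprintf("%s (f=%.4f)", names(f)[!keep], f[!keep]),
                  collapse = ", "))
  }
  names(f)[keep]
}

#' Build a 2x2 contingency table for a trait pair
#'
#' Cell convention: `a` = both present, `b` = X present only, `c` = Y present
#' only, `d` = both absent. With this convention a positive phi coefficient
#' means co-occurrence and a negative one avoidance.
#'
#' @param tm a [trait_matrix].
#' @param x,y trait ids (X and Y).
#' @return named integer vector `c(a, b, c, d)` of class `contingency_table`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), ncol = 2,
#'             dimnames = list(paste0("g", 1:4), c("X", "Y")))
#' contingency_table(trait_matrix(m, c("system", "cas")), "X", "Y")
#' @export
contingency_table <- function(tm, x, y) {
  stopifnot(inherits(tm, "trait_matrix"))
  for (id in c(x, y)) {
    if (!id %in% colnames(tm$values)) stop("unknown trait id: ", id)
  }
  vx <- tm$values[, x]
  vy <- tm$values[, y]
  ct <- c(a = sum(vx == 1L & vy == 1L), b = sum(vx == 1L & vy == 0L),
          c = sum(vx == 0L & vy == 1L), d = sum(vx == 0L & vy == 0L))
  structure(as.integer(ct), names = names(ct), class = "contingency_table")
}

as_counts <- function(t) {
  t <- unclass(t)
  stopifnot(length(t) == 4L, all(t >= 0))
  if (is.null(names(t))) names(t) <- c("a", "b", "c", "d")
  t[c("a", "b", "c", "d")]
}

#' Phi association coefficient of a 2x2 table
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`, identical to the Pearson
#' correlation of the two binary indicator vectors; lies in `[-1, 1]`.
#' If any margin is zero the coefficient is undefined: the function returns
#' `NA` with a warning so the pair can be reported untestable rather than
#' silently scored 0.
#'
#' @param t a `contingency_table` or numeric vector `c(a, b, c, d)`.
#' @return phi in `[-1, 1]`, or `NA` for a zero margin.
#' @examples
#' phi_coef(c(a = 40, b = 10, c = 10, d = 40)) # 0.6
#' @export
phi_coef <- function(t) {
  t <- as_counts(t)
  a <- t[["a"]]; b <- t[["b"]]; cc <- t[["c"]]; d <- t[["d"]]
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    warning("phi undefined: zero margin in contingency table")
    return(NA_real_)
  }
  (a * d - b * cc) / sqrt(prod(margins))
}

#' Two-sided Fisher exact test p-value of a 2x2 table
#'
#' Thin wrapper over [stats::fisher.test()], which sums hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (the minimum-likelihood
#' two-sided convention).
#'
#' @param t a `contingency_table` or numeric vector `c(a, b, c, d)`.
#' @return two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_p <- function(t) {
  t <- as_counts(t)
  if (sum(t) < 1) stop("empty contingency table")
  m <- matrix(t[c("a", "b", "c", "d")], nrow = 2L, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Sample frequency-matched control traits
#'
#' Draws `k` control traits uniformly without replacement among pool members
#' whose presence frequency is within `margin` (absolute) of the target
#' trait's frequency. If fewer than `k` qualify the margin is widened in
#' steps of +0.01 (each widening reported) until `k` are available.
#'
#' @param target trait id whose frequency is to be matched.
#' @param pool character vector of candidate control trait ids.
#' @param tm a [trait_matrix] containing both.
#' @param k number of controls (default 10).
#' @param margin initial frequency margin (default 0.01).
#' @param seed integer seed.
#' @return character vector of `k` control trait ids.
#' @export
match_controls <- function(target, pool, tm, k = 10L, margin = 0.01,
                           seed = NULL) {
  stopifnot(inherits(tm, "trait_matrix"), length(pool) >= 1L)
  if (length(pool) < k) {
    stop("control pool (", length(pool), ") smaller than k = ", k,
         " for trait ", target)
  }
  f <- trait_freq(tm)
  f_target <- f[[target]]
  f_pool <- f[pool]
  m <- margin
  repeat {
    eligible <- pool[abs(f_pool - f_target) <= m + 1e-12]
    if (length(eligible) >= k) break
    if (m >= 0.5) {
      stop("cannot find ", k, " controls for ", target,
           " even at margin 0.5 (", length(eligible), " eligible)")
    }
    m <- min(m + 0.01, 0.5)
    message(sprintf("match_controls: margin widened to %.2f for %s", m, target))
  }
  with_seed(seed, sample(eligible, k))
}

#' One-sided t-test that the mean delta-phi is positive
#'
#' Delta-phi for a pair is `|phi|` of the focal association minus the mean
#' `|phi|` of its frequency-matched controls with the same partner trait.
#' Tests H0: mean(delta) <= 0 against H1: mean(delta) > 0 with a one-sample
#' Student t-test. Zero-variance input is degenerate: p is 0 if the common
#' value is positive and 1 otherwise, with a warning.
#'
#' @param deltas numeric vector of delta-phi values (length >= 2).
#' @return list with `mean`, `t`, `p` (one-sided) and `n`.
#' @examples
#' delta_phi_test(c(0.1, 0.2, 0.3))
#' @export
delta_phi_test <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  n <- length(deltas)
  if (n < 2L) stop("need at least 2 delta-phi values")
  m <- mean(deltas)
  s <- sd(deltas)
  if (s == 0) {
    warning("zero-variance delta-phi input; degenerate p-value")
    return(list(mean = m, t = if (m > 0) Inf else if (m < 0) -Inf else 0,
                p = if (m > 0) 0 else 1, n = n))
  }
  t_stat <- m / (s / sqrt(n))
  list(mean = m, t = t_stat, p = pt(t_stat, df = n - 1L, lower.tail = FALSE),
       n = n)
}

#' Bonferroni correction over a family of tests
#'
#' A pair is significant iff `p <= alpha / m` where `m` is the number of
#' tests actually performed in this run (always reported alongside).
#'
#' @param pvals named numeric vector of p-values.
#' @param alpha family-wise error level (default 0.05).
#' @return list with logical vector `significant`, `m` and the per-test
#'   `threshold`.
#' @export
bonferroni_select <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  if (m < 1L) stop("no p-values supplied")
  list(significant = pvals <= alpha / m, m = m, threshold = alpha / m)
}

#' Phylogeny-naive association screen
#'
#' Runs the full screening stage over a trait matrix: frequency-filters the
#' system and cas traits, builds all (system, cas) contingency tables,
#' computes phi for each pair and for `k_controls` frequency-matched control
#' genes per system trait, aggregates the delta-phi one-sided t-test over all
#' pairs, computes Fisher exact p-values, and applies a Bonferroni correction
#' at level `alpha` with `m` = number of pairs tested.
#'
#' @param tm a [trait_matrix] with system, cas and control traits.
#' @param k_controls controls per system trait (default 10).
#' @param margin frequency-matching margin (default 0.01).
#' @param alpha family-wise error level (default 0.05).
#' @param lo,hi frequency filter bounds (defaults 0.01, 0.99), applied to
#'   system and cas traits.
#' @param seed integer seed controlling control-gene sampling.
#' @return list of class `screen_result`:
#'   * `records`: data.frame with columns `system`, `cas`, `a`, `b`, `c`,
#'     `d`, `phi`, `mean_abs_phi_controls`, `delta_phi`, `fisher_p`,
#'     `m_tests`, `bonferroni_significant`, `sign`;
#'   * `delta_phi`: the [delta_phi_test()] result over all pairs;
#'   * `m_tests`, `alpha`, `controls` (the matched control ids per system).
#' @export
screen_associations <- function(tm, k_controls = 10L, margin = 0.01,
                                alpha = 0.05, lo = 0.01, hi = 0.99,
                                seed = NULL) {
  stopifnot(inherits(tm, "trait_matrix"))
  kept <- frequency_filter(tm, lo, hi)
  systems <- intersect(traits_in_group(tm, "system"), kept)
  cas <- intersect(traits_in_group(tm, "cas"), kept)
  pool <- traits_in_group(tm, "control")
  if (!length(systems)) stop("no system traits survive the frequency filter")
  if (!length(cas)) stop("no cas traits survive the frequency filter")

  control_sets <- lapply(seq_along(systems), function(i) {
    match_controls(systems[i], pool, tm, k = k_controls, margin = margin,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, paste0("controls_", systems[i])))
  })
  names(control_sets) <- systems

  rows <- list()
  for (s in systems) {
    ctrl_ids <- control_sets[[s]]
    for (ca in cas) {
      ct <- contingency_table(tm, s, ca)
      ph <- suppressWarnings(phi_coef(ct))
      ctrl_phi <- vapply(ctrl_ids, function(cid) {
        suppressWarnings(abs(phi_coef(contingency_table(tm, cid, ca))))
      }, 0)
      mean_ctrl <- mean(ctrl_phi, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        system = s, cas = ca,
        a = ct[["a"]], b = ct[["b"]], c = ct[["c"]], d = ct[["d"]],
        phi = ph,
        mean_abs_phi_controls = mean_ctrl,
        delta_phi = if (is.na(ph)) NA_real_ else abs(ph) - mean_ctrl,
        fisher_p = if (is.na(ph)) NA_real_ else fisher_exact_p(ct),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  testable <- !is.na(records$phi)
  if (any(!testable)) {
    message("screen: ", sum(!testable), " pair(s) untestable (zero margin)")
  }
  m_tests <- sum(testable)
  if (m_tests < 1L) stop("no testable (system, cas) pairs")
  bonf <- bonferroni_select(records$fisher_p[testable], alpha = alpha)
  records$m_tests <- m_tests
  records$bonferroni_significant <- FALSE
  records$bonferroni_significant[testable] <- bonf$significant
  records$sign <- ifelse(records$bonferroni_significant,
                         sign(records$phi), 0L)
  dphi <- if (m_tests >= 2L) {
    delta_phi_test(records$delta_phi[testable])
  } else {
    message("screen: only one testable pair; delta-phi t-test undefined")
    list(mean = records$delta_phi[testable][1L], t = NA_real_,
         p = NA_real_, n = m_tests)
  }
  structure(list(records = records, delta_phi = dphi, m_tests = m_tests,
                 alpha = alpha, controls = control_sets),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0(
    "association screen: %d pairs tested (Bonferroni threshold %.3g)\n",
    "  significant: %d positive, %d negative\n",
    "  delta-phi: mean %.4f, t = %.3f, one-sided p = %.4g (n = %d)\n"),
    x$m_tests, x$alpha / x$m_tests,
    sum(x$records$sign == 1, na.rm = TRUE),
    sum(x$records$sign == -1, na.rm = TRUE),
    x$delta_phi$mean, x$delta_phi$t, x$delta_phi$p, x$delta_phi$n))
  invisible(x)
}
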