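# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: matrix exponentials are computed by a
# plain series expansion, Fisher p-values by direct hypergeometric
# enumeration, likelihoods by exhaustive summation over internal states, and
# single-linkage clusterings by an O(n^3) agglomeration.

# --- matrix exponential: scaling and squaring of the Taylor series ---------
oracle_expm <- function(A) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  B <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in 1:30) {
    term <- term %*% B / k
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# --- two-sided Fisher exact p by hypergeometric enumeration ----------------
# Sums P(tables with the observed margins) over tables whose probability is
# <= that observed (up to the standard 1e-7 relative slack for ties).
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b   # X present
  n_tot <- a + b + c + d
  k <- a + c    # Y present
  lo <- max(0L, k - (n_tot - m1))
  hi <- min(m1, k)
  support <- lo:hi
  logp <- dhyper(support, m1, n_tot - m1, k, log = TRUE)
  obs <- logp[support == a]
  sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
}

# --- likelihood by exhaustive enumeration over internal-node states --------
oracle_pruning <- function(tree, tm, model, root_prior = "uniform") {
  Q <- build_generator(model)
  prior <- if (root_prior == "uniform") rep(0.25, 4) else
    unname(stationary_dist(Q))
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  v <- tm$values[tree$tip.label, , drop = FALSE]
  tip_state <- 1L + 2L * v[, 1L] + v[, 2L]
  P_edge <- lapply(seq_len(nrow(tree$edge)),
                   function(e) oracle_expm(Q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    state <- c(tip_state, grid[g, ])
    p <- prior[state[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * P_edge[[e]][state[tree$edge[e, 1L]], state[tree$edge[e, 2L]]]
    }
    total <- total + p
  }
  unname(log(total))
}

# --- O(n^3) single-linkage agglomeration, reported as cophenetic matrix ----
# (cophenetic distances are the tie-break-invariant summary of single
# linkage: the merge height of i and j is the minimax path between them)
oracle_single_linkage_cophenetic <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        dij <- min(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(j, i)
        }
      }
    }
    for (x in clusters[[best[1L]]]) for (y in clusters[[best[2L]]]) {
      coph[x, y] <- coph[y, x] <- best_d
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# --- small fixtures --------------------------------------------------------
random_contingency <- function(n_max = 60L) {
  repeat {
    t <- as.integer(rmultinom(1L, sample(8:n_max, 1L), prob = runif(4, 0.05, 1)))
    names(t) <- c("a", "b", "c", "d")
    margins <- c(t[1] + t[2], t[3] + t[4], t[1] + t[3], t[2] + t[4])
    if (all(margins > 0)) return(t)
  }
}

random_pair_model <- function(max_rate = 3) {
  dependent_model(runif(1, 0.05, max_rate), runif(1, 0.05, max_rate),
                  runif(1, 0.05, max_rate), runif(1, 0.05, max_rate),
                  runif(1, 0.05, max_rate), runif(1, 0.05, max_rate),
                  runif(1, 0.05, max_rate), runif(1, 0.05, max_rate))
}

make_tiny_tm <- function(tree, x, y, ids = c("sysA", "casB")) {
  v <- cbind(x, y)
  dimnames(v) <- list(tree$tip.label, ids)
  trait_matrix(v, c("system", "cas"))
}
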