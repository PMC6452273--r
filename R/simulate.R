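#' Simulate a pure-birth (Yule) tree
#'
#' Grows a Yule tree lineage by lineage: while `k` lineages are active the
#' waiting time to the next split is exponential with rate `k * birth_rate`
#' and a uniformly chosen lineage splits. After the n-th tip appears the tree
#' is extended by one final exponential epoch, so the expected root-to-tip
#' height is `sum_{k=2}^{n} 1 / (k * birth_rate)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0), per unit branch length.
#' @param seed integer seed; the same seed gives an identical tree.
#' @return a rooted `phylo` object with tips labelled `t1 ... t<n>`.
#' @examples
#' tr <- simulate_tree(10, birth_rate = 1, seed = 1)
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  with_seed(seed, {
    max_nodes <- 2L * n_tips - 1L
    parent <- integer(max_nodes)
    len <- numeric(max_nodes)
    parent[2L] <- parent[3L] <- 1L   # node 1 is the root split
    active <- c(2L, 3L)
    next_id <- 4L
    k <- 2L
    while (k < n_tips) {
      dt <- rexp(1L, rate = k * birth_rate)
      len[active] <- len[active] + dt
      j <- active[sample.int(k, 1L)]
      kids <- c(next_id, next_id + 1L)
      parent[kids] <- j
      len[kids] <- 0
      active <- c(active[active != j], kids)
      next_id <- next_id + 2L
      k <- k + 1L
    }
    len[active] <- len[active] + rexp(1L, rate = n_tips * birth_rate)
    build_phylo(parent[seq_len(next_id - 1L)], len[seq_len(next_id - 1L)],
                tips = sort(active))
  })
}

# Convert parent/length arrays (internal ids created in preorder, node 1 =
# root) into an ape phylo with standard numbering (tips 1..n, root n+1).
build_phylo <- function(parent, len, tips) {
  n <- length(tips)
  internals <- setdiff(seq_along(parent), tips)
  id_map <- integer(length(parent))
  id_map[tips] <- seq_len(n)
  id_map[internals] <- n + seq_along(internals)
  child <- which(parent > 0L)
  edge <- cbind(id_map[parent[child]], id_map[child])
  tree <- structure(list(edge = edge,
                         edge.length = len[child],
                         tip.label = paste0("t", seq_len(n)),
                         Nnode = length(internals)),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate a pair of binary traits evolving on a tree
#'
#' Samples the 4-state joint chain (states (0,0), (0,1), (1,0), (1,1) of
#' traits X and Y) down the tree: the root state is drawn (or fixed) and each
#' branch transition is sampled from `exp(Q * t)` of the model's generator.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param model a `pair_model` ([independent_model()] or [dependent_model()]).
#' @param root_state `"drawn_uniform"` (default), `"stationary"`, or an
#'   integer joint state in 1..4 (1 = both absent ... 4 = both present).
#' @param seed integer seed.
#' @param trait_ids length-2 character: ids for trait X and trait Y.
#' @param groups length-2 character group labels (default system, cas).
#' @return a [trait_matrix] with two columns over the tree's tips.
#' @export
simulate_pair_traits <- function(tree, model, root_state = "drawn_uniform",
                                 seed = NULL,
                                 trait_ids = c("sys1", "cas1"),
                                 groups = c("system", "cas")) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "pair_model"))
  Q <- build_generator(model)
  tree <- ape::reorder.phylo(tree, "cladewise") # parents before children
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  with_seed(seed, {
    states <- integer(n_node)
    root <- n_tip + 1L
    states[root] <- if (identical(root_state, "drawn_uniform")) {
      sample.int(4L, 1L)
    } else if (identical(root_state, "stationary")) {
      sample.int(4L, 1L, prob = stationary_dist(Q))
    } else {
      s <- as.integer(root_state)
      if (is.na(s) || s < 1L || s > 4L) stop("root_state must be in 1..4")
      s
    }
    # transition matrices cached per unique branch length
    ulen <- unique(tree$edge.length)
    len_idx <- match(tree$edge.length, ulen)
    P_list <- lapply(ulen, function(t) transition_matrix(Q, t))
    for (e in seq_len(nrow(tree$edge))) {
      P <- P_list[[len_idx[e]]]
      from <- states[tree$edge[e, 1L]]
      states[tree$edge[e, 2L]] <- sample.int(4L, 1L, prob = P[from, ])
    }
    tip_states <- states[seq_len(n_tip)]
    vals <- cbind(as.integer(tip_states >= 3L),        # X present in states 3,4
                  as.integer(tip_states %in% c(2L, 4L))) # Y present in states 2,4
    dimnames(vals) <- list(tree$tip.label, trait_ids)
    trait_matrix(vals, groups)
  })
}

#' Simulate background control traits
#'
#' Control genes are background traits whose frequency is matched to a focal
#' trait in the phi screen. By default each control column is i.i.d.
#' Bernoulli across genomes (a phylogeny-free null). With `mode = "on_tree"`
#' each control evolves as a two-state chain on `tree` with gain/loss rates
#' `rate_scale * p` and `rate_scale * (1 - p)`, whose stationary frequency is
#' the target `p`, so controls carry phylogenetic signal.
#'
#' @param genome_ids character vector of genome ids (rows).
#' @param frequencies numeric vector of target presence frequencies in
#'   `[0, 1]`; one control column per entry.
#' @param seed integer seed.
#' @param mode `"bernoulli"` (default) or `"on_tree"`.
#' @param tree required for `mode = "on_tree"`; tips must match `genome_ids`.
#' @param rate_scale total gain+loss rate for `"on_tree"` controls.
#' @param prefix trait-id prefix (columns are `<prefix>1 ...`).
#' @return a [trait_matrix] of group `"control"` columns.
#' @export
simulate_controls <- function(genome_ids, frequencies, seed = NULL,
                              mode = c("bernoulli", "on_tree"), tree = NULL,
                              rate_scale = 2, prefix = "ctrl") {
  mode <- match.arg(mode)
  if (any(frequencies < 0 | frequencies > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  n <- length(genome_ids)
  ids <- paste0(prefix, seq_along(frequencies))
  with_seed(seed, {
    vals <- if (mode == "bernoulli") {
      vapply(frequencies, function(p) rbinom(n, 1L, p), integer(n))
    } else {
      stopifnot(inherits(tree, "phylo"), setequal(tree$tip.label, genome_ids))
      vapply(frequencies, function(p) {
        col <- simulate_binary_on_tree(tree, alpha = rate_scale * p,
                                       beta = rate_scale * (1 - p))
        col[genome_ids]
      }, integer(n))
    }
    dimnames(vals) <- list(genome_ids, ids)
    trait_matrix(vals, rep("control", length(frequencies)))
  })
}

# One binary trait on a tree under a 2-state chain; root drawn from the
# stationary distribution alpha/(alpha+beta). Uses the caller's RNG state.
simulate_binary_on_tree <- function(tree, alpha, beta) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- ape::Ntip(tree)
  states <- integer(n_tip + tree$Nnode)
  p_stat <- if (alpha + beta > 0) alpha / (alpha + beta) else 0.5
  states[n_tip + 1L] <- rbinom(1L, 1L, p_stat)
  for (e in seq_len(nrow(tree$edge))) {
    t <- tree$edge.length[e]
    s <- states[tree$edge[e, 1L]]
    # 2-state chain: P(1 at end | start s) in closed form
    if (alpha + beta == 0) {
      p1 <- s
    } else {
      decay <- exp(-(alpha + beta) * t)
      p1 <- p_stat + (s - p_stat) * decay
    }
    states[tree$edge[e, 2L]] <- rbinom(1L, 1L, p1)
  }
  setNames(states[seq_len(n_tip)], tree$tip.label)
}

#' Jitter branch lengths to emulate bootstrap-tree uncertainty
#'
#' Returns `n` copies of the tree whose branch lengths are each multiplied by
#' an independent lognormal factor with mean 1 and coefficient of variation
#' `length_cv`; topology is unchanged. This stands in for trees inferred from
#' bootstrap-resampled alignments when only a point-estimate tree exists.
#'
#' @param tree a `phylo` with branch lengths.
#' @param n number of jittered copies (>= 1).
#' @param length_cv coefficient of variation of the multiplier (>= 0; 0 gives
#'   identical copies).
#' @param seed integer seed.
#' @return list of `n` `phylo` objects.
#' @export
jitter_trees <- function(tree, n, length_cv = 0.2, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n >= 1L, length_cv >= 0)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      out <- tree
      if (length_cv > 0) {
        sdlog <- sqrt(log1p(length_cv^2))
        mult <- rlnorm(length(tree$edge.length),
                       meanlog = -sdlog^2 / 2, sdlog = sdlog)
        out$edge.length <- tree$edge.length * mult
      }
      out
    })
  })
}

#' Simulate a phylogeny-free trait pair with a planted phi coefficient
#'
#' Draws `n` genomes i.i.d. from the 2x2 joint distribution with margins
#' `fx`, `fy` and Pearson/phi correlation `phi`
#' (`P(1,1) = fx*fy + phi*sqrt(fx(1-fx)fy(1-fy))`). Used to calibrate the
#' screening stage at a known effect size without tree simulation.
#'
#' @param genome_ids character vector of genome ids.
#' @param fx,fy marginal presence frequencies in (0, 1).
#' @param phi target phi coefficient; must yield valid cell probabilities.
#' @param seed integer seed.
#' @param trait_ids,groups column ids and groups as in [simulate_pair_traits()].
#' @return a [trait_matrix] with two columns.
#' @export
simulate_planted_pair <- function(genome_ids, fx, fy, phi, seed = NULL,
                                  trait_ids = c("sys1", "cas1"),
                                  groups = c("system", "cas")) {
  stopifnot(fx > 0, fx < 1, fy > 0, fy < 1)
  p11 <- fx * fy + phi * sqrt(fx * (1 - fx) * fy * (1 - fy))
  p10 <- fx - p11
  p01 <- fy - p11
  p00 <- 1 - p11 - p10 - p01
  probs <- c(p00, p01, p10, p11)
  if (any(probs < -1e-12)) {
    stop("phi = ", phi, " is infeasible for margins (", fx, ", ", fy, ")")
  }
  probs[probs < 0] <- 0
  n <- length(genome_ids)
  with_seed(seed, {
    cell <- sample.int(4L, n, replace = TRUE, prob = probs)
    vals <- cbind(as.integer(cell >= 3L), as.integer(cell %in% c(2L, 4L)))
    dimnames(vals) <- list(genome_ids, trait_ids)
    trait_matrix(vals, groups)
  })
}
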