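#' Two-trait Markov models of gain and loss
#'
#' Constructors for the two continuous-time Markov models of a pair of binary
#' traits evolving along a tree, over the joint states
#' 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1) (trait X first, trait Y
#' second). Double transitions (both traits changing at once) have rate 0.
#'
#' * The **independent** model has 4 free rates: `alpha1`/`beta1` are the
#'   gain/loss rates of trait X and `alpha2`/`beta2` of trait Y, each trait
#'   evolving regardless of the other.
#' * The **dependent** model has 8 free rates `q12, q13, q21, q24, q31, q34,
#'   q42, q43` indexed by joint states, so each trait's gain/loss rate may
#'   depend on the partner's current state. The independent model embeds as
#'   `q13 = q24 = alpha1`, `q31 = q42 = beta1`, `q12 = q34 = alpha2`,
#'   `q21 = q43 = beta2`.
#'
#' Rates are per unit branch length and must be non-negative.
#'
#' @param alpha1,beta1,alpha2,beta2 independent-model gain/loss rates.
#' @param q12,q13,q21,q24,q31,q34,q42,q43 dependent-model transition rates.
#' @return a `pair_model` object (list with `kind` and `rates`).
#' @examples
#' independent_model(1, 1, 1, 1)
#' dependent_model(1, 1, 1, 5, 1, 1, 0.2, 1)
#' @export
independent_model <- function(alpha1, beta1, alpha2, beta2) {
  rates <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2)
  check_rates(rates)
  structure(list(kind = "independent", rates = rates), class = "pair_model")
}

#' @rdname independent_model
#' @export
dependent_model <- function(q12, q13, q21, q24, q31, q34, q42, q43) {
  rates <- c(q12 = q12, q13 = q13, q21 = q21, q24 = q24,
             q31 = q31, q34 = q34, q42 = q42, q43 = q43)
  check_rates(rates)
  structure(list(kind = "dependent", rates = rates), class = "pair_model")
}

check_rates <- function(rates) {
  if (anyNA(rates) || !is.numeric(rates)) stop("rates must be numeric")
  if (any(rates < 0)) {
    stop("negative rate: ", paste(names(rates)[rates < 0], collapse = ", "))
  }
  invisible(rates)
}

#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf("pair_model (%s): %s\n", x$kind,
              paste(sprintf("%s=%.4g", names(x$rates), x$rates),
                    collapse = ", ")))
  invisible(x)
}

#' Embed an independent model as a dependent model
#'
#' @param model a `pair_model`.
#' @return a dependent-form `pair_model` with identical generator.
#' @export
as_dependent <- function(model) {
  stopifnot(inherits(model, "pair_model"))
  if (model$kind == "dependent") return(model)
  r <- model$rates
  dependent_model(q12 = r[["alpha2"]], q13 = r[["alpha1"]],
                  q21 = r[["beta2"]], q24 = r[["alpha1"]],
                  q31 = r[["beta1"]], q34 = r[["alpha2"]],
                  q42 = r[["beta1"]], q43 = r[["beta2"]])
}

#' Build the 4x4 generator matrix of a pair model
#'
#' Off-diagonal entries follow the joint-state rate mapping of
#' [independent_model()]/[dependent_model()]; double-transition entries are
#' exactly 0; each diagonal is minus its row sum, so rows sum to 0.
#'
#' @param model a `pair_model`.
#' @return a 4x4 numeric generator matrix (states `00`, `01`, `10`, `11`).
#' @export
build_generator <- function(model) {
  stopifnot(inherits(model, "pair_model"))
  q <- as_dependent(model)$rates
  Q <- matrix(0, 4L, 4L, dimnames = list(c("00", "01", "10", "11"),
                                         c("00", "01", "10", "11")))
  Q[1L, 2L] <- q[["q12"]]; Q[1L, 3L] <- q[["q13"]]
  Q[2L, 1L] <- q[["q21"]]; Q[2L, 4L] <- q[["q24"]]
  Q[3L, 1L] <- q[["q31"]]; Q[3L, 4L] <- q[["q34"]]
  Q[4L, 2L] <- q[["q42"]]; Q[4L, 3L] <- q[["q43"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over a branch
#'
#' Computes `exp(Q * t)` for a 4x4 generator by Pade scaling-and-squaring
#' (Armadillo). Rows of the result sum to 1 within 1e-10; tiny negative
#' entries from roundoff are clipped to 0 and rows renormalized.
#'
#' @param Q 4x4 generator matrix.
#' @param t branch length (>= 0).
#' @return 4x4 stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(is.matrix(Q), all(dim(Q) == 4L), t >= 0)
  P <- expm_generator(Q, t)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Stationary distribution of a pair-model generator
#'
#' @param Q 4x4 generator matrix with an irreducible chain.
#' @return numeric vector of 4 stationary probabilities.
#' @export
stationary_dist <- function(Q) {
  stopifnot(is.matrix(Q), all(dim(Q) == 4L))
  # left null vector of Q: solve t(Q) pi = 0 with sum(pi) = 1
  A <- rbind(t(Q), rep(1, 4L))
  b <- c(rep(0, 4L), 1)
  pi <- qr.solve(A, b)
  if (any(pi < -1e-8)) stop("chain is reducible; no valid stationary distribution")
  pi[pi < 0] <- 0
  setNames(pi / sum(pi), c("00", "01", "10", "11"))
}
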