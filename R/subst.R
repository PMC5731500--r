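#' HKY substitution model with discrete-gamma rate variation
#'
#' The generator Q follows the HKY85 parameterisation (transitions scaled
#' by kappa relative to transversions, arbitrary stationary frequencies)
#' and is normalised so the expected rate at stationarity is one
#' substitution per site per time unit; branch rates are therefore in
#' substitutions/site/time-unit.  Among-site rate variation uses the
#' equal-probability discrete gamma with mean-of-category rates.
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param pi stationary frequencies (A, C, G, T), positive, summing to 1.
#' @param alpha gamma shape for among-site rate variation, > 0.
#' @param n_cats number of discrete gamma categories, >= 1.
#' @return an object of class `hky_params` carrying the parameters, the
#'   category rates, and a cached symmetric eigendecomposition of Q used
#'   to evaluate transition matrices.
#' @export
hky_params <- function(kappa = 2, pi = rep(0.25, 4), alpha = 1, n_cats = 4) {
  stopifnot(kappa > 0, alpha > 0, n_cats >= 1,
            length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  obj <- list(kappa = kappa, pi = pi, alpha = alpha, n_cats = as.integer(n_cats),
              cat_rates = gamma_category_rates(alpha, n_cats),
              eig = hky_eigen(kappa, pi))
  class(obj) <- "hky_params"
  obj
}

#' Discrete-gamma category rates (mean-of-category)
#'
#' Equal-probability categories of a Gamma(shape = alpha, rate = alpha)
#' distribution (mean 1); the rate of each category is its conditional
#' mean, computed through the incomplete-gamma identity
#' `E[X | a < X < b] * P(a < X < b) = F_{alpha+1}(b) - F_{alpha+1}(a)`.
#' The rates average exactly to 1.
#'
#' @param alpha gamma shape, > 0.
#' @param K number of categories.
#' @return numeric vector of K rates.
#' @export
gamma_category_rates <- function(alpha, K) {
  if (alpha <= 0) stop("alpha must be positive")
  K <- as.integer(K)
  if (K == 1L) return(1)
  qb <- stats::qgamma(seq_len(K - 1) / K, shape = alpha, rate = alpha)
  Fb <- c(0, stats::pgamma(qb, shape = alpha + 1, rate = alpha), 1)
  rates <- K * diff(Fb)
  rates / mean(rates)  # guards rounding at extreme alpha; mean is 1 already
}

# symmetric eigendecomposition of the mean-rate-1 HKY generator
hky_eigen <- function(kappa, pi) {
  # order A C G T; transitions: A<->G, C<->T
  R <- matrix(1, 4, 4)
  R[1, 3] <- R[3, 1] <- kappa
  R[2, 4] <- R[4, 2] <- kappa
  Q <- R * rep(pi, each = 4)      # Q_ij = R_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))        # mean rate at stationarity
  Q <- Q / mu
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))      # diag(sp) Q diag(1/sp), symmetric
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = (1 / sp) * e$vectors,        # diag(1/sp) V
       left = t(e$vectors * sp))            # V' diag(sp)
}

#' HKY transition probability matrix
#'
#' `P(d) = exp(Q d)` for the mean-rate-1 HKY generator, via the cached
#' symmetric eigendecomposition.
#'
#' @param params an [hky_params()].
#' @param d expected substitutions per site, >= 0.
#' @return 4x4 stochastic matrix, rows = parent state, cols = child state.
#' @export
transition_matrix <- function(params, d) {
  if (d < 0) stop("branch distance must be nonnegative")
  e <- params$eig
  P <- e$right %*% (exp(e$values * d) * e$left)
  P[P < 0] <- 0                    # clip eigendecomposition roundoff
  P / rowSums(P)
}

#' Transition matrices for every branch and gamma category
#'
#' The distance on the branch above node v in category k is
#' `(age[parent(v)] - age[v]) * rate[v] * cat_rate[k]`.
#'
#' @param tree a [species_tree].
#' @param rates numeric vector of per-branch rates indexed by child node id
#'   (entry at the root is ignored).
#' @param params an [hky_params()].
#' @return list indexed by child node id; each element a list of K 4x4
#'   matrices, one per gamma category.
#' @export
branch_tpms <- function(tree, rates, params) {
  out <- vector("list", tree$n_nodes)
  for (v in seq_len(tree$n_nodes)) {
    if (is.na(tree$parent[v])) next
    dur <- tree$ages[tree$parent[v]] - tree$ages[v]
    out[[v]] <- lapply(params$cat_rates, function(cr)
      transition_matrix(params, dur * rates[v] * cr))
  }
  out
}

# leaf emission basis: identity columns for A,C,G,T plus all-ones column
# for the unknown code (marginalises the leaf state)
.leaf_basis <- cbind(diag(4), rep(1, 4))

# Blocked transition matrix for one branch: the K gamma categories are
# stacked into one 4K x 4K block-diagonal matrix (leaf branches are
# pre-multiplied by the emission basis, giving 4K x 5), so a node's
# partial update is a single matrix product across all categories.
node_tpms <- function(tree, v, rates, params) {
  dur <- tree$ages[tree$parent[v]] - tree$ages[v]
  if (dur < 0) stop("negative branch duration above node ", v)
  K <- params$n_cats
  e <- params$eig
  ds <- dur * rates[v] * params$cat_rates
  E <- exp(e$values %o% ds)                       # 4 x K
  B <- matrix(e$left, 4, 4 * K) * E[, rep(seq_len(K), each = 4), drop = FALSE]
  P_all <- e$right %*% B                          # 4 x 4K, category blocks
  P_all[P_all < 0] <- 0
  Pbd <- matrix(0, 4 * K, 4 * K)
  for (k in seq_len(K)) {
    idx <- (k - 1L) * 4L + 1:4
    Pbd[idx, idx] <- P_all[, idx]
  }
  if (v <= tree$n_leaves) {
    Pbd %*% .leaf_basis[rep(1:4, K), , drop = FALSE]
  } else {
    Pbd
  }
}
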