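#' Exact phylogenetic likelihood with subtree site-pattern compression
#'
#' Every inner node of the fixed tree deduplicates the alignment columns
#' projected onto its own leaf set: a hash over the concatenated leaf
#' codes maps each column to a row of the node's site lookup table, and
#' the partial likelihood of each unique subtree pattern is computed only
#' once.  A lookup row stores, for each child, either the child's code at
#' that column (a column of the child's leaf emission block, for leaf
#' children) or the row index in the child's own compressed likelihood
#' vector (for inner children).  The root additionally carries a repeat
#' count per row, aggregating the full-site-compression weights of all
#' columns that map to the same root pattern.
#'
#' The structures depend only on the data and the topology, are built once,
#' and never change during MCMC; per-node hash tables are dropped after
#' construction (only the lookup tables and row counts are needed to
#' evaluate likelihoods).
#'
#' @name compressed_likelihood
NULL

#' Build the per-node compression structures for one gene
#'
#' Bottom-up over the tree: a node's pattern key per column is the pair of
#' its children's row indices, which is in bijection with the concatenated
#' leaf codes below the node.
#'
#' @param tree a [species_tree].
#' @param enc a full-site-compressed `encoded_gene`
#'   (see [full_site_compress()]).
#' @return list with `lookup` (per internal node id: list `li`, `ri`,
#'   `npat`), `npat` (vector over all nodes; 5 at leaves for the emission
#'   block width), and `root_w` (repeat count per root pattern row).
#' @export
build_compression <- function(tree, enc) {
  if (is.null(enc$site_weights))
    stop("gene must be full-site compressed before building subtree patterns")
  s <- ncol(enc$codes)
  patidx <- vector("list", tree$n_nodes)
  npat <- integer(tree$n_nodes)
  lookup <- vector("list", tree$n_nodes)
  for (v in seq_len(tree$n_leaves)) {
    patidx[[v]] <- enc$codes[v, ] + 1L
    npat[v] <- 5L
  }
  for (v in tree$postorder) {
    c1 <- tree$child1[v]; c2 <- tree$child2[v]
    key <- (as.numeric(patidx[[c1]]) - 1) * npat[c2] + patidx[[c2]]
    first <- !duplicated(key)
    lookup[[v]] <- list(li = patidx[[c1]][first], ri = patidx[[c2]][first],
                        npat = sum(first))
    npat[v] <- lookup[[v]]$npat
    patidx[[v]] <- match(key, key[first])
  }
  root_w <- as.vector(rowsum(as.numeric(enc$site_weights), patidx[[tree$root]]))
  list(lookup = lookup, npat = npat, root_w = root_w, s_kept = s)
}

#' Per-node pattern counts and the compression ratio for a gene
#'
#' @param tree a [species_tree].
#' @param enc a full-site-compressed `encoded_gene`.
#' @return data frame with one row per internal node: node id, number of
#'   leaves below, pattern count, and the kept-site count; attribute
#'   `ratio` gives total likelihood-vector rows over
#'   `(#internal nodes) * kept_sites` (smaller = more compression).
#' @export
compression_summary <- function(tree, enc) {
  comp <- build_compression(tree, enc)
  below <- leaves_below(tree)
  ids <- tree$postorder
  df <- data.frame(
    node = ids,
    leaves_below = vapply(below[ids], length, 0L),
    n_patterns = comp$npat[ids],
    kept_sites = comp$s_kept)
  attr(df, "ratio") <- sum(comp$npat[ids]) / (length(ids) * comp$s_kept)
  df
}

.SCALE_FLOOR <- 1e-100

#' Create a likelihood engine for one gene
#'
#' The engine is an environment holding the static compression structures
#' and the mutable per-branch transition matrices, per-node compressed
#' partial-likelihood vectors with scaling logs, and the cached gene
#' log-likelihood.  [engine_propose_update()] / [engine_revert()] /
#' [engine_accept()] implement the incremental MCMC contract.
#'
#' @param tree a [species_tree].
#' @param enc a full-site-compressed `encoded_gene`.
#' @param params an [hky_params()].
#' @param rates per-branch rates indexed by child node id.
#' @return the engine environment; `$loglik` is current.
#' @export
likelihood_engine <- function(tree, enc, params, rates) {
  eng <- new.env(parent = emptyenv())
  eng$tree <- tree
  eng$comp <- build_compression(tree, enc)
  eng$name <- enc$name
  eng$n_recompute <- 0L
  engine_refresh_all(eng, tree$ages, rates, params)
  eng
}

#' Recompute every transition matrix and partial in an engine
#'
#' Used at initialisation and whenever a global parameter (kappa, alpha,
#' base frequencies) changes.
#'
#' @param eng engine from [likelihood_engine()].
#' @param ages node ages.
#' @param rates per-branch rates indexed by child node id.
#' @param params an [hky_params()].
#' @return the new log-likelihood (invisibly); engine caches updated.
#' @export
engine_refresh_all <- function(eng, ages, rates, params) {
  tree <- eng$tree
  tree$ages <- ages
  eng$params <- params
  K <- eng$K <- params$n_cats
  # block-diagonal stationary-frequency row vector for the root sum
  eng$pi_big <- matrix(0, K, 4 * K)
  for (k in seq_len(K)) eng$pi_big[k, (k - 1L) * 4L + 1:4] <- params$pi
  eng$tpm <- vector("list", tree$n_nodes)
  for (v in seq_len(tree$n_nodes)) {
    if (!is.na(tree$parent[v])) eng$tpm[[v]] <- node_tpms(tree, v, rates, params)
  }
  eng$partial <- vector("list", tree$n_nodes)
  eng$scale <- vector("list", tree$n_nodes)
  for (v in tree$postorder) .compute_node_partial(eng, v)
  eng$loglik <- .root_loglik(eng)
  invisible(eng$loglik)
}

# partial likelihoods for one internal node from current child partials
# and TPMs; the K gamma categories are stacked as row blocks (4K x npat)
.compute_node_partial <- function(eng, v) {
  tree <- eng$tree
  lk <- eng$comp$lookup[[v]]
  c1 <- tree$child1[v]; c2 <- tree$child2[v]
  leaf1 <- c1 <= tree$n_leaves; leaf2 <- c2 <= tree$n_leaves
  K <- eng$K
  A <- if (leaf1) eng$tpm[[c1]][, lk$li, drop = FALSE]
       else (eng$tpm[[c1]] %*% eng$partial[[c1]])[, lk$li, drop = FALSE]
  B <- if (leaf2) eng$tpm[[c2]][, lk$ri, drop = FALSE]
       else (eng$tpm[[c2]] %*% eng$partial[[c2]])[, lk$ri, drop = FALSE]
  L <- A * B
  S <- NULL
  if (!leaf1 && !is.null(eng$scale[[c1]]))
    S <- eng$scale[[c1]][lk$li, , drop = FALSE]
  if (!leaf2 && !is.null(eng$scale[[c2]])) {
    S2 <- eng$scale[[c2]][lk$ri, , drop = FALSE]
    S <- if (is.null(S)) S2 else S + S2
  }
  # fast path: no column of any category block can need rescaling
  if (min(L) < .SCALE_FLOOR) {
    if (is.null(S)) S <- matrix(0, lk$npat, K)
    for (k in seq_len(K)) {
      rw <- (k - 1L) * 4L + 1:4
      cm <- pmax(L[rw[1], ], L[rw[2], ], L[rw[3], ], L[rw[4], ])
      idx <- which(cm < .SCALE_FLOOR & cm > 0)
      if (length(idx)) {
        L[rw, idx] <- L[rw, idx, drop = FALSE] / rep(cm[idx], each = 4L)
        S[idx, k] <- S[idx, k] + log(cm[idx])
      }
    }
  }
  eng$partial[[v]] <- L
  eng$scale[v] <- list(S)        # S may be NULL (= all-zero scale logs)
  eng$n_recompute <- eng$n_recompute + 1L
}

# weighted log-likelihood over root pattern rows, mixing gamma categories
.root_loglik <- function(eng) {
  root <- eng$tree$root
  K <- eng$K
  site <- t(eng$pi_big %*% eng$partial[[root]])   # npat x K
  S <- eng$scale[[root]]
  if (is.null(S)) {
    lnsite <- log(.rowSums(site, nrow(site), K) / K)
  } else {
    Mx <- S[, 1]
    for (k in seq_len(K)[-1]) Mx <- pmax(Mx, S[, k])
    lnsite <- Mx + log(rowSums(site * exp(S - Mx)) / K)
  }
  sum(eng$comp$root_w * lnsite)
}

#' Incrementally update an engine after age or rate changes
#'
#' Recomputes only the transition matrices of the listed branches and the
#' partials of the affected internal nodes and their ancestors, saving the
#' previous values so the proposal can be reverted.
#'
#' @param eng engine.
#' @param ages node ages (after the proposed change).
#' @param rates per-branch rates (after the proposed change).
#' @param changed_branches child node ids whose branch distance changed.
#' @return the new log-likelihood; `eng$loglik` updated.
#' @export
engine_propose_update <- function(eng, ages, rates, changed_branches) {
  tree <- eng$tree
  tree$ages <- ages
  changed_branches <- changed_branches[!is.na(tree$parent[changed_branches])]
  affected <- unique(tree$parent[changed_branches])
  anc <- integer(0)
  for (v in affected) {
    u <- tree$parent[v]
    while (!is.na(u)) { anc <- c(anc, u); u <- tree$parent[u] }
  }
  nodes <- intersect(tree$postorder, unique(c(affected, anc)))  # postorder order
  snap <- list(branches = changed_branches,
               tpm = eng$tpm[changed_branches],
               nodes = nodes,
               partial = eng$partial[nodes],
               scale = eng$scale[nodes],
               loglik = eng$loglik)
  for (b in changed_branches) eng$tpm[[b]] <- node_tpms(tree, b, rates, eng$params)
  for (v in nodes) .compute_node_partial(eng, v)
  eng$snapshot <- snap
  eng$loglik <- .root_loglik(eng)
  eng$loglik
}

#' Revert the last proposed engine update
#' @param eng engine with a pending snapshot.
#' @export
engine_revert <- function(eng) {
  snap <- eng$snapshot
  if (is.null(snap)) stop("no pending update to revert")
  eng$tpm[snap$branches] <- snap$tpm
  eng$partial[snap$nodes] <- snap$partial
  eng$scale[snap$nodes] <- snap$scale
  eng$loglik <- snap$loglik
  eng$snapshot <- NULL
  invisible(eng$loglik)
}

#' Accept the last proposed engine update
#' @param eng engine with a pending snapshot.
#' @export
engine_accept <- function(eng) {
  eng$snapshot <- NULL
  invisible(eng$loglik)
}

#' Gene log-likelihood via subtree site compression
#'
#' Convenience wrapper: builds the engine and returns the natural-log
#' likelihood of one gene.
#'
#' @inheritParams likelihood_engine
#' @return log-likelihood (natural log).
#' @export
gene_log_likelihood <- function(tree, enc, params, rates) {
  likelihood_engine(tree, enc, params, rates)$loglik
}

#' Plain Felsenstein pruning log-likelihood (verification oracle)
#'
#' Standard pruning over the full-site-compressed columns, one partial
#' vector per column at every node, without any subtree pattern sharing.
#' Kept deliberately independent of the compression engine.
#'
#' @inheritParams likelihood_engine
#' @return log-likelihood (natural log).
#' @export
plain_pruning_log_likelihood <- function(tree, enc, params, rates) {
  if (is.null(enc$site_weights)) enc <- full_site_compress(enc)
  s <- ncol(enc$codes)
  K <- params$n_cats
  sitemat <- matrix(0, s, K)
  Smat <- matrix(0, s, K)
  for (k in seq_len(K)) {
    cr <- params$cat_rates[k]
    L <- vector("list", tree$n_nodes)
    slog <- vector("list", tree$n_nodes)
    for (v in tree$postorder) {
      contrib <- function(ch) {
        dur <- tree$ages[v] - tree$ages[ch]
        P <- transition_matrix(params, dur * rates[ch] * cr)
        if (ch <= tree$n_leaves) {
          (P %*% .leaf_basis)[, enc$codes[ch, ] + 1L, drop = FALSE]
        } else {
          P %*% L[[ch]]
        }
      }
      c1 <- tree$child1[v]; c2 <- tree$child2[v]
      Lv <- contrib(c1) * contrib(c2)
      sl <- numeric(s)
      if (c1 > tree$n_leaves) sl <- sl + slog[[c1]]
      if (c2 > tree$n_leaves) sl <- sl + slog[[c2]]
      cm <- pmax(Lv[1, ], Lv[2, ], Lv[3, ], Lv[4, ])
      idx <- which(cm < .SCALE_FLOOR & cm > 0)
      if (length(idx)) {
        Lv[, idx] <- Lv[, idx] / rep(cm[idx], each = 4L)
        sl[idx] <- sl[idx] + log(cm[idx])
      }
      L[[v]] <- Lv
      slog[[v]] <- sl
    }
    sitemat[, k] <- as.vector(params$pi %*% L[[tree$root]])
    Smat[, k] <- slog[[tree$root]]
  }
  Mx <- Smat[, 1]
  if (K > 1) for (k in 2:K) Mx <- pmax(Mx, Smat[, k])
  lnsite <- Mx + log(rowSums(sitemat * exp(Smat - Mx)) / K)
  sum(enc$site_weights * lnsite)
}
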