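#' Birth-death-sampling kernel density and CDF for node ages
#'
#' Density of the age of an interior node conditional on the root age
#' `t_R` under the birth-death-sampling process with birth rate `lam`,
#' death rate `mu` and sampling fraction `rho`.  For `lam != mu`,
#' `g(t) = lam * p1(t) / v`, where
#' `p1(t) = rho^-1 P(0,t)^2 exp((mu-lam) t)`,
#' `P(0,t) = rho (lam-mu) / (rho lam + (lam (1-rho) - mu) exp((mu-lam) t))`
#' and `v = 1 - rho^-1 P(0,t_R) exp((mu-lam) t_R)`; the `lam == mu` limit
#' has the closed form `g(t) = (1 + q t_R) / (t_R (1 + q t)^2)` with
#' `q = lam * rho`.  `G` integrates to exactly 1 at `t_R`.
#'
#' @param t age(s) in (0, t_R); vectorized.
#' @param lam birth rate, > 0.
#' @param mu death rate, >= 0.
#' @param rho sampling fraction in (0, 1].
#' @param t_R root age, > 0.
#' @return density / CDF / quantile values.
#' @export
bds_pdf <- function(t, lam, mu, rho, t_R) {
  stopifnot(lam > 0, mu >= 0, rho > 0, rho <= 1, t_R > 0)
  if (any(t <= 0 | t >= t_R)) stop("ages must lie strictly inside (0, t_R)")
  q <- lam * rho
  if (isTRUE(all.equal(lam, mu, tolerance = 1e-12))) {
    return((1 + q * t_R) / (t_R * (1 + q * t)^2))
  }
  m <- mu - lam
  a <- rho * lam
  b <- lam * (1 - rho) - mu
  v <- a * (1 - exp(m * t_R)) / (a + b * exp(m * t_R))
  lam * rho * m^2 * exp(m * t) / (a + b * exp(m * t))^2 / v
}

#' @rdname bds_pdf
#' @export
bds_cdf <- function(t, lam, mu, rho, t_R) {
  stopifnot(lam > 0, mu >= 0, rho > 0, rho <= 1, t_R > 0)
  if (any(t < 0 | t > t_R)) stop("ages must lie inside [0, t_R]")
  q <- lam * rho
  if (isTRUE(all.equal(lam, mu, tolerance = 1e-12))) {
    return((1 + q * t_R) * t / (t_R * (1 + q * t)))
  }
  m <- mu - lam
  a <- rho * lam
  b <- lam * (1 - rho) - mu
  v <- a * (1 - exp(m * t_R)) / (a + b * exp(m * t_R))
  if (abs(b) < 1e-12 * lam) {
    lam * rho * m * (exp(m * t) - 1) / a^2 / v
  } else {
    -(lam * rho * m / b) * (1 / (a + b * exp(m * t)) + 1 / m) / v
  }
}

#' @rdname bds_pdf
#' @param u probabilities in (0, 1); vectorized.
#' @export
bds_quantile <- function(u, lam, mu, rho, t_R) {
  stopifnot(all(u > 0 & u < 1))
  q <- lam * rho
  if (isTRUE(all.equal(lam, mu, tolerance = 1e-12))) {
    C <- (1 + q * t_R) / t_R
    return(u / (C - q * u))
  }
  m <- mu - lam
  a <- rho * lam
  b <- lam * (1 - rho) - mu
  v <- a * (1 - exp(m * t_R)) / (a + b * exp(m * t_R))
  if (abs(b) < 1e-12 * lam) {
    log1p(u * a^2 * v / (lam * rho * m)) / m
  } else {
    x <- 1 / (a + b) - u * b * v / (lam * rho * m)
    log((1 / x - a) / b) / m
  }
}

# per-segment log h (factorial of the non-calibration count) and
# log G' (segment CDF mass to that power), from 1-based calibration ranks
# r (ascending) and matching CDF values gvals; n2 = number of non-root
# internal nodes.  Segments are i = 0..c (returned 1-indexed, length c+1).
.segment_terms <- function(r, gvals, n2) {
  br <- c(0, r, n2 + 1)
  bg <- c(0, gvals, 1)
  args <- diff(br) - 1
  if (any(args < 0)) stop("invalid calibration ranks (negative segment count)")
  base <- diff(bg)
  ln_h <- lfactorial(args)
  ln_gp <- numeric(length(args))
  pos <- args > 0 & base > 0
  ln_gp[pos] <- args[pos] * log(base[pos])
  ln_gp[args > 0 & base <= 0] <- -Inf   # ranks inconsistent with CDF values
  list(ln_h = ln_h, ln_gp = ln_gp, args = args)
}

#' Log factorial of one segment's non-calibration count
#'
#' Segment 0 holds the `R_1 - 1` nodes below the lowest calibration,
#' middle segments `R_i - R_(i-1) - 1` nodes, and the last segment
#' `n - 2 - R_c` nodes; the counts always partition `n - 2 - c`.
#'
#' @param i segment index, 0..c.
#' @param ranks 1-based APV positions of the calibration nodes, ascending.
#' @param n number of leaves.
#' @param c number of non-root calibration nodes.
#' @return `ln h(i)`.
#' @export
segment_log_h <- function(i, ranks, n, c) {
  stopifnot(length(ranks) == c, i >= 0, i <= c)
  .segment_terms(ranks, rep(0.5, c), n - 2)$ln_h[i + 1]
}

#' Log of one segment's CDF-mass power term
#'
#' `G'(0) = G(t_1)^(R_1-1)`, middle segments
#' `(G(t_i) - G(t_(i-1)))^(R_i - R_(i-1) - 1)`, last segment
#' `(1 - G(t_c))^(n-2-R_c)`; a zero exponent gives `ln G' = 0` regardless
#' of the base.
#'
#' @param i segment index, 0..c.
#' @param gvals CDF values of the calibration ages, in rank order.
#' @inheritParams segment_log_h
#' @return `ln G'(i)`.
#' @export
segment_log_gprime <- function(i, gvals, ranks, n, c) {
  stopifnot(length(ranks) == c, length(gvals) == c, i >= 0, i <= c)
  .segment_terms(ranks, gvals, n - 2)$ln_gp[i + 1]
}

# single-CDF shortcut for the change in one segment's ln G' when only one
# bounding CDF value moved: exponent * (log new base - log old base)
.delta_gprime_one_cdf <- function(exponent, base_new, base_old) {
  if (exponent == 0) return(0)
  exponent * (log(base_new) - log(base_old))
}

#' Full recomputation of the node-age log prior (oracle and baseline)
#'
#' Computes `ln f(t_nc | t_c, t_R) = sum ln g + sum ln h - sum ln G'` from
#' scratch: sorts the non-root internal ages, finds the calibration ranks,
#' and evaluates every term.  Also returns the total soft-bound
#' calibration log density (root included).  This is the from-scratch
#' baseline the incremental transaction path is verified against.
#'
#' @param tree a [species_tree] (its `ages` are used).
#' @param cal_map resolved calibrations from [resolve_calibrations()].
#' @param bds list with `lam`, `mu`, `rho`.
#' @return list with `ln_f`, `ln_fcal_total`, `total`, and the pieces
#'   (`ranks`, `seg_h`, `seg_gp`).
#' @export
full_log_prior <- function(tree, cal_map, bds) {
  root <- tree$root
  t_R <- tree$ages[root]
  nodes <- setdiff((tree$n_leaves + 1L):tree$n_nodes, root)
  n2 <- length(nodes)
  is_cal <- as.character(nodes) %in% names(cal_map)
  ord <- order(tree$ages[nodes], nodes)
  apv <- nodes[ord]
  apv_cal <- as.character(apv) %in% names(cal_map)
  ranks <- which(apv_cal)
  gvals <- vapply(apv[ranks],
                  function(v) bds_cdf(tree$ages[v], bds$lam, bds$mu, bds$rho, t_R),
                  0)
  seg <- .segment_terms(ranks, gvals, n2)
  noncal <- nodes[!is_cal]
  ln_g_sum <- if (length(noncal))
    sum(log(bds_pdf(tree$ages[noncal], bds$lam, bds$mu, bds$rho, t_R))) else 0
  ln_f <- ln_g_sum + sum(seg$ln_h) - sum(seg$ln_gp)
  ln_fcal_total <- sum(vapply(names(cal_map), function(key) {
    calibration_logpdf(cal_map[[key]], tree$ages[as.integer(key)])
  }, 0))
  list(ln_f = ln_f, ln_fcal_total = ln_fcal_total,
       total = ln_f + ln_fcal_total,
       ranks = ranks, seg_h = seg$ln_h, seg_gp = seg$ln_gp)
}

#' Initialise the incremental prior state
#'
#' Builds the Age Pointer Vector (non-root internal nodes sorted by age,
#' ties broken by node id), the per-node cached `ln g` / `G` values, and
#' the conditional density vector of per-segment `ln h` and `ln G'`
#' terms.  The structures are built once; MCMC proposals only adjust them
#' through [propose_age_update()] / [propose_root_age_update()].
#'
#' @inheritParams full_log_prior
#' @return prior-state environment; `$ln_f`, `$ln_fcal_total` current.
#' @export
init_prior_state <- function(tree, cal_map, bds) {
  ps <- new.env(parent = emptyenv())
  ps$root <- tree$root
  ps$n_leaves <- tree$n_leaves
  ps$n_nodes <- tree$n_nodes
  ps$bds <- bds
  ps$cal_map <- cal_map
  ps$nodes <- setdiff((tree$n_leaves + 1L):tree$n_nodes, tree$root)
  ps$n2 <- length(ps$nodes)
  ps$is_cal <- logical(tree$n_nodes)
  ps$is_cal[as.integer(names(cal_map))] <- TRUE
  ps$txn_counts <- c(noncal_stay = 0L, noncal_move = 0L,
                     cal_stay = 0L, cal_move = 0L, root = 0L)
  .prior_rebuild_caches(ps, tree$ages)
  ps
}

# (re)fill every cache from the ages vector; APV order refreshed too
.prior_rebuild_caches <- function(ps, ages) {
  ps$t_R <- ages[ps$root]
  ord <- order(ages[ps$nodes], ps$nodes)
  ps$apv <- ps$nodes[ord]
  ps$pos <- integer(ps$n_nodes)
  ps$pos[ps$apv] <- seq_len(ps$n2)
  ps$ln_g <- rep(NA_real_, ps$n_nodes)
  ps$Gval <- rep(NA_real_, ps$n_nodes)
  ps$ln_fcal <- rep(NA_real_, ps$n_nodes)
  for (v in ps$nodes) {
    if (ps$is_cal[v]) {
      ps$Gval[v] <- bds_cdf(ages[v], ps$bds$lam, ps$bds$mu, ps$bds$rho, ps$t_R)
    } else {
      ps$ln_g[v] <- log(bds_pdf(ages[v], ps$bds$lam, ps$bds$mu, ps$bds$rho, ps$t_R))
    }
  }
  for (key in names(ps$cal_map)) {
    v <- as.integer(key)
    ps$ln_fcal[v] <- calibration_logpdf(ps$cal_map[[key]], ages[v])
  }
  .prior_refresh_segments(ps)
  ps$ln_f <- sum(ps$ln_g[ps$nodes[!ps$is_cal[ps$nodes]]]) +
    sum(ps$seg_h) - sum(ps$seg_gp)
  ps$ln_fcal_total <- sum(ps$ln_fcal, na.rm = TRUE)
  invisible(ps)
}

.prior_refresh_segments <- function(ps) {
  cal_in_apv <- ps$is_cal[ps$apv]
  ps$cal_ranks <- which(cal_in_apv)
  ps$cal_rank_nodes <- ps$apv[ps$cal_ranks]
  seg <- .segment_terms(ps$cal_ranks, ps$Gval[ps$cal_rank_nodes], ps$n2)
  ps$seg_h <- seg$ln_h
  ps$seg_gp <- seg$ln_gp
  ps$seg_args <- seg$args
  invisible(ps)
}

#' Current total log prior held by the state
#' @param ps prior state from [init_prior_state()].
#' @return `ln_f + ln_fcal_total`.
#' @export
prior_log_total <- function(ps) ps$ln_f + ps$ln_fcal_total

#' Propose a new age for a non-root internal node
#'
#' Repositions the node in the APV by adjacent swaps, classifies the
#' transaction (calibration node or not, position changed or not), and
#' recomputes exactly the conditional-density segments whose rank or CDF
#' boundaries changed; for a calibration node that keeps its position only
#' the two bordering segments' `G'` terms are recomputed from the single
#' new CDF value.  The change is uncommitted until [commit_age_update()]
#' or [revert_age_update()].
#'
#' @param ps prior state.
#' @param node a non-root internal node id.
#' @param new_age proposed age; the caller guarantees it respects the
#'   parent/child ordering of the tree.
#' @param ages current node-age vector (still holding the old age).
#' @return change in the total log prior (`ln_f + ln_fcal_total`).
#' @export
propose_age_update <- function(ps, node, new_age, ages) {
  if (!is.null(ps$txn)) stop("uncommitted transaction pending")
  if (node == ps$root) stop("use propose_root_age_update() for the root")
  is_cal <- ps$is_cal[node]
  snap <- list(node = node,
               apv = ps$apv, pos = ps$pos,
               cal_ranks = ps$cal_ranks, cal_rank_nodes = ps$cal_rank_nodes,
               seg_h = ps$seg_h, seg_gp = ps$seg_gp, seg_args = ps$seg_args,
               ln_g = ps$ln_g[node], Gval = ps$Gval[node],
               ln_fcal = ps$ln_fcal[node],
               ln_f = ps$ln_f, ln_fcal_total = ps$ln_fcal_total,
               kind = "inner")
  old_total <- ps$ln_f + ps$ln_fcal_total
  br_old <- c(0, ps$cal_ranks, ps$n2 + 1)
  bg_old <- c(0, ps$Gval[ps$cal_rank_nodes], 1)

  age_of <- function(v) if (v == node) new_age else ages[v]
  p <- ps$pos[node]
  # adjacent-swap repositioning (ages move few slots per proposal)
  while (p > 1L && age_of(ps$apv[p - 1L]) > new_age) {
    ps$apv[c(p - 1L, p)] <- ps$apv[c(p, p - 1L)]
    ps$pos[ps$apv[p]] <- p
    p <- p - 1L
  }
  while (p < ps$n2 && age_of(ps$apv[p + 1L]) < new_age) {
    ps$apv[c(p, p + 1L)] <- ps$apv[c(p + 1L, p)]
    ps$pos[ps$apv[p]] <- p
    p <- p + 1L
  }
  ps$pos[node] <- p
  moved <- p != snap$pos[node]

  if (is_cal) {
    ps$Gval[node] <- bds_cdf(new_age, ps$bds$lam, ps$bds$mu, ps$bds$rho, ps$t_R)
    spec <- ps$cal_map[[as.character(node)]]
    ps$ln_fcal[node] <- calibration_logpdf(spec, new_age)
    ps$ln_fcal_total <- ps$ln_fcal_total + ps$ln_fcal[node] - snap$ln_fcal
  } else {
    ps$ln_g[node] <- log(bds_pdf(new_age, ps$bds$lam, ps$bds$mu,
                                 ps$bds$rho, ps$t_R))
    ps$ln_f <- ps$ln_f + ps$ln_g[node] - snap$ln_g
  }

  # recompute only the segments whose boundaries changed
  cal_in_apv <- ps$is_cal[ps$apv]
  ps$cal_ranks <- which(cal_in_apv)
  ps$cal_rank_nodes <- ps$apv[ps$cal_ranks]
  if (is_cal && !moved) {
    # ranks unchanged: G of `node` moved; its two bordering segments via
    # the single-CDF shortcut
    j <- match(node, ps$cal_rank_nodes)
    bg_new <- c(0, ps$Gval[ps$cal_rank_nodes], 1)
    bg_prev <- bg_new; bg_prev[j + 1] <- snap$Gval
    changed <- c(j, j + 1)  # segment indices in 1..c+1
    for (i in changed) {
      ps$seg_gp[i] <- ps$seg_gp[i] +
        .delta_gprime_one_cdf(ps$seg_args[i],
                              bg_new[i + 1] - bg_new[i],
                              bg_prev[i + 1] - bg_prev[i])
    }
    ps$ln_f <- ps$ln_f - sum(ps$seg_gp[changed]) + sum(snap$seg_gp[changed])
    ps$last_nseg <- 2L
    ps$txn_counts[["cal_stay"]] <- ps$txn_counts[["cal_stay"]] + 1L
  } else {
    seg_new <- .segment_terms(ps$cal_ranks, ps$Gval[ps$cal_rank_nodes], ps$n2)
    br_new <- c(0, ps$cal_ranks, ps$n2 + 1)
    bg_new <- c(0, ps$Gval[ps$cal_rank_nodes], 1)
    changed <- which(br_new[-length(br_new)] != br_old[-length(br_old)] |
                     br_new[-1] != br_old[-1] |
                     bg_new[-length(bg_new)] != bg_old[-length(bg_old)] |
                     bg_new[-1] != bg_old[-1])
    if (length(changed)) {
      ps$ln_f <- ps$ln_f +
        sum(seg_new$ln_h[changed] - ps$seg_h[changed]) -
        sum(seg_new$ln_gp[changed] - ps$seg_gp[changed])
      ps$seg_h[changed] <- seg_new$ln_h[changed]
      ps$seg_gp[changed] <- seg_new$ln_gp[changed]
      ps$seg_args[changed] <- seg_new$args[changed]
    }
    ps$last_nseg <- length(changed)
    key <- if (is_cal) "cal_move" else if (moved) "noncal_move" else "noncal_stay"
    ps$txn_counts[[key]] <- ps$txn_counts[[key]] + 1L
  }
  ps$txn <- snap
  (ps$ln_f + ps$ln_fcal_total) - old_total
}

#' Propose a new root age
#'
#' The kernel g and CDF G condition on the root age, so a root move
#' invalidates every cached density value; all caches are recomputed
#' (the APV order itself is unaffected).  Revertable like any
#' transaction.
#'
#' @param ps prior state.
#' @param new_t_R proposed root age (> oldest non-root internal age).
#' @param ages current node-age vector (still holding the old root age).
#' @return change in the total log prior.
#' @export
propose_root_age_update <- function(ps, new_t_R, ages) {
  if (!is.null(ps$txn)) stop("uncommitted transaction pending")
  snap <- list(kind = "root",
               t_R = ps$t_R, ln_g = ps$ln_g, Gval = ps$Gval,
               ln_fcal = ps$ln_fcal,
               cal_ranks = ps$cal_ranks, cal_rank_nodes = ps$cal_rank_nodes,
               seg_h = ps$seg_h, seg_gp = ps$seg_gp, seg_args = ps$seg_args,
               ln_f = ps$ln_f, ln_fcal_total = ps$ln_fcal_total)
  old_total <- ps$ln_f + ps$ln_fcal_total
  ages2 <- ages
  ages2[ps$root] <- new_t_R
  .prior_rebuild_caches(ps, ages2)
  ps$txn_counts[["root"]] <- ps$txn_counts[["root"]] + 1L
  ps$txn <- snap
  (ps$ln_f + ps$ln_fcal_total) - old_total
}

#' Revert the pending age transaction
#' @param ps prior state with an uncommitted transaction.
#' @export
revert_age_update <- function(ps) {
  snap <- ps$txn
  if (is.null(snap)) stop("no pending transaction")
  if (snap$kind == "root") {
    ps$t_R <- snap$t_R
    ps$ln_g <- snap$ln_g
    ps$Gval <- snap$Gval
    ps$ln_fcal <- snap$ln_fcal
  } else {
    v <- snap$node
    ps$apv <- snap$apv
    ps$pos <- snap$pos
    ps$ln_g[v] <- snap$ln_g
    ps$Gval[v] <- snap$Gval
    ps$ln_fcal[v] <- snap$ln_fcal
  }
  ps$cal_ranks <- snap$cal_ranks
  ps$cal_rank_nodes <- snap$cal_rank_nodes
  ps$seg_h <- snap$seg_h
  ps$seg_gp <- snap$seg_gp
  ps$seg_args <- snap$seg_args
  ps$ln_f <- snap$ln_f
  ps$ln_fcal_total <- snap$ln_fcal_total
  ps$txn <- NULL
  invisible(ps)
}

#' Commit the pending age transaction
#' @param ps prior state with an uncommitted transaction.
#' @export
commit_age_update <- function(ps) {
  if (is.null(ps$txn)) stop("no pending transaction")
  ps$txn <- NULL
  invisible(ps)
}
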