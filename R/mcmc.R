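#' Metropolis-Hastings sampler for divergence times
#'
#' The posterior is the product of four components: the exact multi-gene
#' likelihood (compressed engines), the birth-death-sampling
#' order-statistics prior on node ages with soft-bound calibrations, the
#' independent log-normal prior on per-branch per-gene rates, and the
#' hyperpriors on the substitution and clock parameters.  One MCMC step is
#' one full sweep of single-parameter proposals: every internal node age
#' (sliding window reflected into its valid interval), every branch rate
#' (log-scale window), and each hyperparameter.  Age proposals use the
#' incremental prior transactions and likelihood path updates; nothing is
#' rebuilt from scratch inside the chain.
#'
#' @name mcmc_engine
NULL

# reflect x into (lo, hi); hi may be Inf (reflect at lo only)
.reflect <- function(x, lo, hi) {
  if (is.infinite(hi)) {
    if (x < lo) x <- lo + (lo - x)
    return(x)
  }
  w <- hi - lo
  x <- (x - lo) %% (2 * w)
  if (x > w) x <- 2 * w - x
  lo + x
}

#' Build a chain state
#'
#' @param tree a [species_tree]; its ages seed the chain (rescaled so the
#'   root starts at the midpoint of its calibration bounds).
#' @param genes list of full-site-compressed `encoded_gene` objects (may
#'   be empty for prior-only runs).
#' @param calibrations list of [calibration_spec()]; must resolve to
#'   include the root.
#' @param bds list with `lam`, `mu`, `rho` (fixed, not sampled).
#' @param kappa,alpha,n_cats initial substitution-model values.
#' @param pi base frequencies; `NULL` = empirical from the data.
#' @param mean_rate prior mean of the per-gene mean rate
#'   (substitutions/site/time-unit); also the initial rate value.
#' @param sigma2 initial per-gene log-rate variance.
#' @param prior_mean_kappa,prior_mean_alpha means of the Gamma(2, 2/mean)
#'   hyperpriors.
#' @param fix_kappa,fix_alpha,fix_root_age hold the parameter at its
#'   initial value instead of sampling it.
#' @return a chain-state environment.
#' @export
chain_state <- function(tree, genes, calibrations, bds,
                        kappa = 2, alpha = 0.5, n_cats = 4, pi = NULL,
                        mean_rate = 1, sigma2 = 0.1,
                        prior_mean_kappa = 2, prior_mean_alpha = 1,
                        fix_kappa = FALSE, fix_alpha = FALSE,
                        fix_root_age = FALSE) {
  ch <- new.env(parent = emptyenv())
  ch$tree <- tree
  cal_map <- resolve_calibrations(tree, calibrations)
  root_spec <- cal_map[[as.character(tree$root)]]
  # rescale initial ages so the root starts mid-calibration
  target <- (root_spec$t_L + root_spec$t_U) / 2
  ages <- tree$ages * target / tree$ages[tree$root]
  ch$ages <- ages
  ch$tree$ages <- ages
  ch$cal_map <- cal_map
  ch$bds <- bds
  ch$genes <- genes
  ch$n_genes <- length(genes)
  if (is.null(pi)) pi <- empirical_base_freqs(genes)
  ch$params <- hky_params(kappa = kappa, pi = pi, alpha = alpha,
                          n_cats = n_cats)
  ch$mu <- rep(mean_rate, ch$n_genes)
  ch$sigma2 <- rep(sigma2, ch$n_genes)
  ch$log_rates <- lapply(seq_len(ch$n_genes), function(g)
    ifelse(is.na(tree$parent), NA_real_, log(mean_rate)))
  ch$engines <- lapply(seq_len(ch$n_genes), function(g)
    likelihood_engine(ch$tree, genes[[g]], ch$params,
                      exp(ch$log_rates[[g]])))
  ch$ps <- init_prior_state(ch$tree, cal_map, bds)
  ch$rateprior <- vapply(seq_len(ch$n_genes), function(g)
    .gene_rate_logprior(ch, g), 0)
  ch$hyper <- list(mean_rate = mean_rate,
                   prior_mean_kappa = prior_mean_kappa,
                   prior_mean_alpha = prior_mean_alpha)
  ch$fix <- list(kappa = fix_kappa, alpha = fix_alpha,
                 root_age = fix_root_age)
  ch$w <- list(age = 0.05 * ages[tree$root], root = 0.05 * ages[tree$root],
               rate = 0.3, kappa = 0.3, alpha = 0.3, mu = 0.3, sigma2 = 0.5)
  ch$acc <- ch$try <- sapply(names(ch$w), function(x) 0L)
  ch
}

.gene_rate_logprior <- function(ch, g) {
  x <- ch$log_rates[[g]]
  x <- x[!is.na(x)]
  m <- log(ch$mu[g]) - ch$sigma2[g] / 2
  sum(stats::dnorm(x, m, sqrt(ch$sigma2[g]), log = TRUE))
}

.hyper_logprior <- function(ch) {
  h <- ch$hyper
  out <- sum(stats::dgamma(ch$mu, 2, rate = 2 / h$mean_rate, log = TRUE)) +
    sum(stats::dgamma(ch$sigma2, 1, rate = 1, log = TRUE))
  if (!ch$fix$kappa)
    out <- out + stats::dgamma(ch$params$kappa, 2,
                               rate = 2 / h$prior_mean_kappa, log = TRUE)
  if (!ch$fix$alpha)
    out <- out + stats::dgamma(ch$params$alpha, 2,
                               rate = 2 / h$prior_mean_alpha, log = TRUE)
  out
}

#' Cached log posterior of a chain state
#' @param ch chain state.
#' @return numeric log posterior (up to the model's normalising constant).
#' @export
log_posterior <- function(ch) {
  sum(vapply(ch$engines, function(e) e$loglik, 0)) +
    prior_log_total(ch$ps) + sum(ch$rateprior) + .hyper_logprior(ch)
}

#' Cold recomputation of the log posterior (oracle)
#'
#' Rebuilds every likelihood engine and the full node-age prior from
#' scratch; used to verify that the incrementally maintained caches never
#' drift.
#'
#' @param ch chain state.
#' @return numeric log posterior.
#' @export
cold_log_posterior <- function(ch) {
  tree <- ch$tree
  tree$ages <- ch$ages
  ll <- 0
  for (g in seq_len(ch$n_genes)) {
    ll <- ll + gene_log_likelihood(tree, ch$genes[[g]], ch$params,
                                   exp(ch$log_rates[[g]]))
  }
  fp <- full_log_prior(tree, ch$cal_map, ch$bds)
  rp <- sum(vapply(seq_len(ch$n_genes), function(g)
    .gene_rate_logprior(ch, g), 0))
  ll + fp$total + rp + .hyper_logprior(ch)
}

.mh_accept <- function(delta) {
  is.finite(delta) && (delta >= 0 || stats::runif(1) < exp(delta))
}

.bump <- function(ch, key, ok) {
  ch$try[key] <- ch$try[key] + 1L
  if (ok) ch$acc[key] <- ch$acc[key] + 1L
}

# a full sweep; proposals use the incremental update/revert contracts
.sweep <- function(ch) {
  tree <- ch$tree
  internal <- tree$postorder
  for (v in internal) {
    if (v == tree$root) {
      if (ch$fix$root_age) next
      lo <- max(ch$ages[c(tree$child1[v], tree$child2[v])])
      na <- .reflect(ch$ages[v] + stats::runif(1, -ch$w$root, ch$w$root),
                     lo, Inf)
      dprior <- propose_root_age_update(ch$ps, na, ch$ages)
      delta <- dprior + .propose_ages_lik(ch, v, na)
      if (.mh_accept(delta)) {
        commit_age_update(ch$ps)
        for (e in ch$engines) engine_accept(e)
        ch$ages[v] <- na
        .bump(ch, "root", TRUE)
      } else {
        revert_age_update(ch$ps)
        for (e in ch$engines) engine_revert(e)
        .bump(ch, "root", FALSE)
      }
    } else {
      lo <- max(ch$ages[c(tree$child1[v], tree$child2[v])])
      hi <- ch$ages[tree$parent[v]]
      na <- .reflect(ch$ages[v] + stats::runif(1, -ch$w$age, ch$w$age), lo, hi)
      dprior <- propose_age_update(ch$ps, v, na, ch$ages)
      delta <- dprior + .propose_ages_lik(ch, v, na)
      if (.mh_accept(delta)) {
        commit_age_update(ch$ps)
        for (e in ch$engines) engine_accept(e)
        ch$ages[v] <- na
        .bump(ch, "age", TRUE)
      } else {
        revert_age_update(ch$ps)
        for (e in ch$engines) engine_revert(e)
        .bump(ch, "age", FALSE)
      }
    }
  }
  # branch rates, per gene
  for (g in seq_len(ch$n_genes)) {
    eng <- ch$engines[[g]]
    m <- log(ch$mu[g]) - ch$sigma2[g] / 2
    sdv <- sqrt(ch$sigma2[g])
    for (v in seq_len(tree$n_nodes)) {
      if (is.na(tree$parent[v])) next
      x <- ch$log_rates[[g]][v]
      xn <- x + stats::runif(1, -ch$w$rate, ch$w$rate)
      dpr <- stats::dnorm(xn, m, sdv, log = TRUE) -
        stats::dnorm(x, m, sdv, log = TRUE)
      rates2 <- exp(ch$log_rates[[g]])
      rates2[v] <- exp(xn)
      dlik <- -eng$loglik +
        engine_propose_update(eng, ch$ages, rates2, v)
      if (.mh_accept(dpr + dlik)) {
        engine_accept(eng)
        ch$log_rates[[g]][v] <- xn
        ch$rateprior[g] <- ch$rateprior[g] + dpr
        .bump(ch, "rate", TRUE)
      } else {
        engine_revert(eng)
        .bump(ch, "rate", FALSE)
      }
    }
  }
  # clock hyperparameters (no likelihood term)
  for (g in seq_len(ch$n_genes)) {
    for (par in c("mu", "sigma2")) {
      old <- if (par == "mu") ch$mu[g] else ch$sigma2[g]
      u <- stats::runif(1, -ch$w[[par]], ch$w[[par]])
      new <- old * exp(u)
      if (par == "mu") ch$mu[g] <- new else ch$sigma2[g] <- new
      rp_new <- .gene_rate_logprior(ch, g)
      dhyp <- if (par == "mu") {
        stats::dgamma(new, 2, rate = 2 / ch$hyper$mean_rate, log = TRUE) -
          stats::dgamma(old, 2, rate = 2 / ch$hyper$mean_rate, log = TRUE)
      } else {
        stats::dgamma(new, 1, rate = 1, log = TRUE) -
          stats::dgamma(old, 1, rate = 1, log = TRUE)
      }
      delta <- rp_new - ch$rateprior[g] + dhyp + u  # +u: log-scale jacobian
      if (.mh_accept(delta)) {
        ch$rateprior[g] <- rp_new
        .bump(ch, par, TRUE)
      } else {
        if (par == "mu") ch$mu[g] <- old else ch$sigma2[g] <- old
        .bump(ch, par, FALSE)
      }
    }
  }
  # substitution-model parameters (full likelihood refresh)
  if (ch$n_genes > 0) {
    for (par in c("kappa", "alpha")) {
      if (ch$fix[[par]]) next
      old <- ch$params[[par]]
      u <- stats::runif(1, -ch$w[[par]], ch$w[[par]])
      new <- old * exp(u)
      pm <- if (par == "kappa") ch$hyper$prior_mean_kappa
            else ch$hyper$prior_mean_alpha
      dhyp <- stats::dgamma(new, 2, rate = 2 / pm, log = TRUE) -
        stats::dgamma(old, 2, rate = 2 / pm, log = TRUE) + u
      params2 <- hky_params(
        kappa = if (par == "kappa") new else ch$params$kappa,
        pi = ch$params$pi,
        alpha = if (par == "alpha") new else ch$params$alpha,
        n_cats = ch$params$n_cats)
      dlik <- 0
      for (g in seq_len(ch$n_genes)) {
        e <- ch$engines[[g]]
        dlik <- dlik - e$loglik +
          .engine_propose_params(e, ch$ages, exp(ch$log_rates[[g]]), params2)
      }
      if (.mh_accept(dhyp + dlik)) {
        for (e in ch$engines) .engine_accept_params(e)
        ch$params <- params2
        .bump(ch, par, TRUE)
      } else {
        for (e in ch$engines) .engine_revert_params(e)
        .bump(ch, par, FALSE)
      }
    }
  }
  invisible(ch)
}

# likelihood delta for an age move at node v; leaves engines in the
# proposed state (caller accepts or reverts)
.propose_ages_lik <- function(ch, v, na) {
  if (ch$n_genes == 0) return(0)
  ages2 <- ch$ages
  ages2[v] <- na
  branches <- c(v, ch$tree$child1[v], ch$tree$child2[v])
  dlik <- 0
  for (g in seq_len(ch$n_genes)) {
    e <- ch$engines[[g]]
    dlik <- dlik - e$loglik +
      engine_propose_update(e, ages2, exp(ch$log_rates[[g]]), branches)
  }
  dlik
}

# full-refresh proposal for substitution parameters, with revert support
.engine_propose_params <- function(eng, ages, rates, params) {
  eng$param_snapshot <- list(tpm = eng$tpm, partial = eng$partial,
                             scale = eng$scale, loglik = eng$loglik,
                             params = eng$params, K = eng$K)
  engine_refresh_all(eng, ages, rates, params)
  eng$loglik
}

.engine_revert_params <- function(eng) {
  s <- eng$param_snapshot
  eng$tpm <- s$tpm; eng$partial <- s$partial; eng$scale <- s$scale
  eng$loglik <- s$loglik; eng$params <- s$params; eng$K <- s$K
  eng$param_snapshot <- NULL
  invisible(eng$loglik)
}

.engine_accept_params <- function(eng) {
  eng$param_snapshot <- NULL
  invisible(eng$loglik)
}

#' Advance a chain by one MCMC step (one full sweep)
#' @param ch chain state.
#' @return the chain state, invisibly.
#' @export
step_chain <- function(ch) {
  .sweep(ch)
  invisible(ch)
}

# multiplicative width adaptation toward ~30% acceptance (burn-in only)
.tune <- function(ch) {
  for (key in names(ch$w)) {
    if (ch$try[key] > 0) {
      rate <- ch$acc[key] / ch$try[key]
      ch$w[[key]] <- min(max(ch$w[[key]] * exp(rate - 0.3), 1e-6), 1e3)
    }
    ch$acc[key] <- ch$try[key] <- 0L
  }
}

#' Run an MCMC chain
#'
#' @param ch chain state from [chain_state()].
#' @param steps total MCMC steps (sweeps).
#' @param burnin steps discarded (proposal widths adapt during burn-in).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed RNG seed (mandatory; the chain is bit-reproducible).
#' @param tune_interval sweeps between width adaptations during burn-in.
#' @param verbose print progress and transaction diagnostics.
#' @return a `sample_log` data frame: one row per retained sweep with the
#'   log posterior, substitution and clock parameters, and every internal
#'   node age (`age_<node id>` columns).  Attribute `txn_counts` carries
#'   the prior transaction-class diagnostics.
#' @export
run_chain <- function(ch, steps, burnin, thin = 1, seed = 1,
                      tune_interval = 50, verbose = FALSE) {
  if (burnin >= steps) stop("burnin must be smaller than steps")
  set.seed(seed)
  internal <- ch$tree$postorder
  keep <- seq(burnin + thin, steps, by = thin)
  out <- vector("list", length(keep))
  ki <- 1L
  for (it in seq_len(steps)) {
    .sweep(ch)
    if (it <= burnin && it %% tune_interval == 0) .tune(ch)
    if (ki <= length(keep) && it == keep[ki]) {
      row <- c(step = it, logpost = log_posterior(ch),
               loglik = sum(vapply(ch$engines, function(e) e$loglik, 0)),
               kappa = ch$params$kappa, alpha = ch$params$alpha)
      if (ch$n_genes > 0) {
        row <- c(row, stats::setNames(ch$mu, paste0("mu_", seq_len(ch$n_genes))),
                 stats::setNames(ch$sigma2,
                                 paste0("sigma2_", seq_len(ch$n_genes))))
      }
      row <- c(row, stats::setNames(ch$ages[internal],
                                    paste0("age_", internal)))
      out[[ki]] <- row
      ki <- ki + 1L
    }
    if (verbose && it %% 500 == 0)
      message(sprintf("step %d/%d logpost %.3f", it, steps, log_posterior(ch)))
  }
  df <- as.data.frame(do.call(rbind, out))
  attr(df, "txn_counts") <- ch$ps$txn_counts
  class(df) <- c("sample_log", "data.frame")
  if (verbose) {
    tc <- ch$ps$txn_counts
    message("prior transactions: ", paste(names(tc), tc, collapse = ", "))
  }
  df
}

#' Posterior summaries per internal node age
#'
#' @param samples a `sample_log` from [run_chain()].
#' @return data frame: node id, posterior mean, median, and equal-tailed
#'   95% credibility interval per age column.
#' @export
summarize_ages <- function(samples) {
  cols <- grep("^age_", names(samples), value = TRUE)
  if (!length(cols) || nrow(samples) == 0) stop("no age samples")
  do.call(rbind, lapply(cols, function(cn) {
    x <- samples[[cn]]
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(node = as.integer(sub("^age_", "", cn)),
               mean = mean(x), median = q[2], lower95 = q[1], upper95 = q[3])
  }))
}

#' Relative date differences between two age sets
#'
#' The per-node relative difference normalised by the mean of the two
#' dates: `d = 2 (d1 - d2) / (d1 + d2)`.
#'
#' @param d1,d2 numeric age vectors over the same node set.
#' @return list with per-node `d` and `max_abs = max(|d|)`.
#' @export
compare_dates <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("age sets differ in length")
  d <- 2 * (d1 - d2) / (d1 + d2)
  list(d = d, max_abs = max(abs(d)))
}
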