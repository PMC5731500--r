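#' Synthetic-data generator
#'
#' Emulates the study conditions the package is validated under:
#' birth-death-sampling trees of 20-200 taxa and HKY+Gamma sequences
#' (kappa = 2, 4 discrete gamma categories) across 10-100 genes of
#' 1,000-10,000 sites.  Tree ages are drawn directly from the BDS kernel
#' (root at age 1 by convention, the remaining n-2 ages i.i.d. from
#' `G^-1(uniform)`) and attached to a random coalescent-style topology
#' consistent with the age ordering -- exactly the prior the inference
#' assumes, which keeps prior-only and recovery checks coherent.
#' Sequence evolution is simulated natively (root states from the
#' stationary frequencies, states propagated down each branch by sampling
#' transition-matrix rows per site and gamma category); no external
#' simulator binary is involved.
#'
#' @name simulate
NULL

#' Configuration for the synthetic generator
#'
#' @param n_taxa number of leaves (study range 20-200; smaller values are
#'   used for unit-scale fixtures).
#' @param lam,mu,rho birth-death-sampling rates shaping node ages.
#' @param n_genes number of genes.
#' @param sites_per_gene alignment length per gene.
#' @param kappa,alpha,n_cats HKY+Gamma parameters (defaults are the study
#'   conditions: kappa 2, 4 categories).
#' @param pi stationary base frequencies.
#' @param mean_rate mean branch rate in substitutions/site/time-unit.
#' @param sigma2 variance of log branch rates (independent log-normal
#'   clock).
#' @param seed mandatory RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 20, lam = 2, mu = 1, rho = 0.5,
                       n_genes = 10, sites_per_gene = 2000,
                       kappa = 2, alpha = 0.5, n_cats = 4,
                       pi = rep(0.25, 4), mean_rate = 0.5, sigma2 = 0.02,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_taxa >= 2, n_genes >= 1, sites_per_gene >= 1)
  structure(list(n_taxa = n_taxa, lam = lam, mu = mu, rho = rho,
                 n_genes = n_genes, sites_per_gene = sites_per_gene,
                 kappa = kappa, alpha = alpha, n_cats = n_cats, pi = pi,
                 mean_rate = mean_rate, sigma2 = sigma2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a species tree with true ages
#'
#' Root age 1; the other `n - 2` internal ages are i.i.d. draws from the
#' BDS kernel CDF inverse.  Ages are sorted and attached bottom-up by
#' merging two uniformly chosen active lineages at each age, so every
#' parent is strictly older than its children.
#'
#' @param config a [sim_config()] (only the tree fields are used).
#' @return a [species_tree] with true ages; leaves are `t1..tn`.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  n <- config$n_taxa
  ages_new <- if (n > 2)
    sort(bds_quantile(stats::runif(n - 2), config$lam, config$mu,
                      config$rho, 1)) else numeric(0)
  parent <- rep(NA_integer_, 2L * n - 1L)
  child1 <- parent; child2 <- parent
  agev <- numeric(2L * n - 1L)
  active <- 1:n
  nxt <- n + 2L
  for (k in seq_len(n - 1L)) {
    i <- sample(length(active), 2L)
    v <- if (k == n - 1L) n + 1L else nxt
    agev[v] <- if (k == n - 1L) 1 else ages_new[k]
    child1[v] <- active[i[1]]
    child2[v] <- active[i[2]]
    parent[active[i]] <- v
    active <- c(active[-i], v)
    if (k < n - 1L) nxt <- nxt + 1L
  }
  new_species_tree(parent, child1, child2, agev,
                   c(paste0("t", 1:n), rep(NA_character_, n - 1L)), n)
}

#' Simulate branch rates under the independent log-normal clock
#'
#' `ln r ~ Normal(ln mean_rate - sigma2/2, sigma2)` independently per
#' branch, so `E[r] = mean_rate`.
#'
#' @param tree a [species_tree].
#' @param mean_rate,sigma2 clock parameters.
#' @return per-branch rates indexed by child node id (`NA` at the root).
#' @export
simulate_branch_rates <- function(tree, mean_rate, sigma2) {
  r <- exp(stats::rnorm(tree$n_nodes, log(mean_rate) - sigma2 / 2,
                        sqrt(sigma2)))
  r[is.na(tree$parent)] <- NA_real_
  r
}

#' Simulate one gene alignment along a tree
#'
#' Root states are drawn from the stationary frequencies; per site, a
#' gamma category is drawn once and the state evolves down every branch
#' by sampling from the corresponding transition-matrix row.
#'
#' @param tree a [species_tree] with ages.
#' @param rates per-branch rates indexed by child node id.
#' @param params an [hky_params()].
#' @param length number of sites.
#' @param name gene name.
#' @return a `gene_alignment`.
#' @export
simulate_alignment <- function(tree, rates, params, length, name = "gene") {
  s <- length
  K <- params$n_cats
  cat_of_site <- sample.int(K, s, replace = TRUE)
  states <- matrix(0L, nrow = tree$n_nodes, ncol = s)
  states[tree$root, ] <- sample.int(4L, s, replace = TRUE, prob = params$pi)
  for (v in rev(tree$postorder)) {  # parents before children
    for (ch in c(tree$child1[v], tree$child2[v])) {
      dur <- tree$ages[v] - tree$ages[ch]
      for (k in seq_len(K)) {
        P <- transition_matrix(params, dur * rates[ch] * params$cat_rates[k])
        for (x in 1:4) {
          idx <- which(cat_of_site == k & states[v, ] == x)
          if (length(idx))
            states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                          prob = P[x, ])
        }
      }
    }
  }
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(tree$n_leaves), function(i)
    paste0(bases[states[i, ]], collapse = ""), "")
  new_gene_alignment(name, tree$labels[seq_len(tree$n_leaves)], seqs)
}

#' Write a complete synthetic fixture to disk
#'
#' Produces a newick tree with true ages, one FASTA per gene, a
#' calibration config whose root bound tightly brackets the true root age
#' (+/- 10%, soft), and a tab-separated truth table of internal node
#' ages.
#'
#' @param config a [sim_config()].
#' @param outdir writable directory (created if absent).
#' @return invisibly, a list with the tree, gene alignments, branch
#'   rates, and file paths.
#' @export
make_fixture <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(config)     # seeds the RNG
  params <- hky_params(kappa = config$kappa, pi = config$pi,
                       alpha = config$alpha, n_cats = config$n_cats)
  genes <- vector("list", config$n_genes)
  rates <- vector("list", config$n_genes)
  paths <- character(config$n_genes)
  for (g in seq_len(config$n_genes)) {
    rates[[g]] <- simulate_branch_rates(tree, config$mean_rate, config$sigma2)
    genes[[g]] <- simulate_alignment(tree, rates[[g]], params,
                                     config$sites_per_gene,
                                     name = sprintf("gene%02d", g))
    paths[g] <- file.path(outdir, paste0(genes[[g]]$name, ".fa"))
    write_alignment_fasta(genes[[g]], paths[g])
  }
  tree_path <- file.path(outdir, "tree.nwk")
  writeLines(write_newick(tree), tree_path)
  t_R <- tree$ages[tree$root]
  cal <- calibration_spec(tree$labels[seq_len(tree$n_leaves)],
                          t_L = 0.9 * t_R, t_U = 1.1 * t_R)
  cal_path <- file.path(outdir, "calibrations.cfg")
  write_calibration_config(list(cal), cal_path)
  truth_path <- file.path(outdir, "true_ages.tsv")
  internal <- tree$postorder
  utils::write.table(
    data.frame(node = internal, age = tree$ages[internal]),
    truth_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(tree = tree, genes = genes, rates = rates,
                 paths = list(tree = tree_path, genes = paths,
                              calibrations = cal_path, truth = truth_path)))
}
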