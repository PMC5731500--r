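# Shared fixture builders.  All randomness uses the session RNG so tests
# control reproducibility with set.seed() at the call site.

# random ultrametric binary tree: root age 1, other internal ages iid
# uniform, attached coalescent-style (uniform random merges)
rand_ultrametric_tree <- function(n) {
  ages <- sort(stats::runif(n - 2))
  parent <- rep(NA_integer_, 2L * n - 1L)
  ch1 <- parent; ch2 <- parent
  agev <- numeric(2L * n - 1L)
  nxt <- n + 2L
  ids <- 1:n
  for (k in seq_len(n - 1L)) {
    i <- sample(length(ids), 2L)
    v <- if (k == n - 1L) n + 1L else nxt
    agev[v] <- if (k == n - 1L) 1 else ages[k]
    ch1[v] <- ids[i[1]]; ch2[v] <- ids[i[2]]
    parent[ids[i]] <- v
    ids <- c(ids[-i], v)
    if (k < n - 1L) nxt <- nxt + 1L
  }
  chronosite:::new_species_tree(parent, ch1, ch2, agev,
                                c(paste0("t", 1:n), rep(NA, n - 1L)), n)
}

# caterpillar (fully unbalanced) newick with ages: spine nodes at
# equally spaced ages up to 1
caterpillar_tree <- function(n) {
  stopifnot(n >= 3)
  ages <- seq_len(n - 1) / (n - 1)
  nwk <- "t1"
  prev_age <- 0
  for (i in 2:n) {
    a <- ages[i - 1]
    nwk <- sprintf("(%s:%.10f,t%d:%.10f)", nwk, a - prev_age, i, a)
    prev_age <- a
  }
  parse_newick(paste0(nwk, ";"))
}

# balanced tree on n = 2^k leaves, level ages 1, 1/2, 1/4, ...
balanced_tree <- function(n) {
  stopifnot(n >= 2, bitwAnd(n, n - 1L) == 0L)
  build <- function(lo, hi, age) {
    if (lo == hi) return(sprintf("t%d:%.10f", lo, age))
    mid <- (lo + hi) %/% 2
    sprintf("(%s,%s):%.10f", build(lo, mid, age / 2),
            build(mid + 1, hi, age / 2), age)
  }
  mid <- n %/% 2
  parse_newick(paste0("(", build(1, mid, 0.5), ",",
                      build(mid + 1, n, 0.5), ");"))
}

# random gene over a tree's leaves: iid columns with a little missing data
rand_gene <- function(tree, s, unknown_frac = 0.05, name = "g") {
  n <- tree$n_leaves
  chars <- sample(c("A", "C", "G", "T", "-", "N"), n * s, replace = TRUE,
                  prob = c(rep((1 - unknown_frac) / 4, 4),
                           unknown_frac / 2, unknown_frac / 2))
  m <- matrix(chars, nrow = n)
  aln <- chronosite:::new_gene_alignment(
    name, tree$labels[seq_len(n)], apply(m, 1L, paste0, collapse = ""))
  full_site_compress(encode_gene(aln, tree$labels[seq_len(n)]))
}

# random calibration map: the root plus `c_extra` random internal nodes,
# each soft bound centred on the node's current age
rand_cal_map <- function(tree, c_extra = 0) {
  n <- tree$n_leaves
  specs <- list(calibration_spec(tree$labels[1:n], 0.9, 1.1))
  others <- setdiff((n + 1):(2 * n - 1), tree$root)
  if (c_extra > 0) {
    for (v in sample(others, min(c_extra, length(others)))) {
      a <- tree$ages[v]
      lab <- tree$labels[chronosite:::leaves_below(tree)[[v]]]
      specs[[length(specs) + 1L]] <-
        calibration_spec(lab, max(a - 0.1, a / 2), a + 0.1)
    }
  }
  resolve_calibrations(tree, specs)
}

# brute-force count of distinct projected column tuples below each node
brute_pattern_counts <- function(tree, enc) {
  below <- chronosite:::leaves_below(tree)
  vapply(tree$postorder, function(v) {
    sub <- enc$codes[below[[v]], , drop = FALSE]
    length(unique(apply(sub, 2L, paste0, collapse = ",")))
  }, 0L)
}

test_bds <- list(lam = 2, mu = 1, rho = 0.5)
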