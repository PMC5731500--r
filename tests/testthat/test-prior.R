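# tree with ages replaced (value semantics keep the original intact)
within_tree <- function(tr, ages) { tr$ages <- ages; tr }

test_that("the BDS kernel normalises, differentiates and inverts correctly", {
  set.seed(30)
  cases <- list(c(2, 1, 0.5), c(1.5, 1.5, 0.8),  # lam = mu closed form
                c(2, 0, 1),                       # b = 0 (pure birth, rho 1)
                c(3, 0.5, 0.1))
  for (cs in cases) {
    lam <- cs[1]; mu <- cs[2]; rho <- cs[3]; t_R <- 1.3
    g <- function(t) bds_pdf(t, lam, mu, rho, t_R)
    expect_equal(stats::integrate(g, 1e-10, t_R - 1e-10)$value, 1,
                 tolerance = 1e-6)
    expect_equal(bds_cdf(t_R, lam, mu, rho, t_R), 1, tolerance = 1e-12)
    expect_equal(bds_cdf(0, lam, mu, rho, t_R), 0, tolerance = 1e-12)
    # finite differences of G reproduce g at random interior points
    ts <- stats::runif(50, 0.05, t_R - 0.05)
    h <- 1e-6
    fd <- (bds_cdf(ts + h, lam, mu, rho, t_R) -
             bds_cdf(ts - h, lam, mu, rho, t_R)) / (2 * h)
    expect_equal(fd, g(ts), tolerance = 1e-6)
    # quantile inverts the CDF
    us <- stats::runif(20, 0.01, 0.99)
    expect_equal(bds_cdf(bds_quantile(us, lam, mu, rho, t_R),
                         lam, mu, rho, t_R), us, tolerance = 1e-9)
    expect_true(all(diff(bds_cdf(sort(ts), lam, mu, rho, t_R)) > 0))
  }
  expect_error(bds_pdf(1.5, 2, 1, 0.5, 1), "inside")
})

test_that("the lam = mu closed form is the limit of the general form", {
  t_R <- 1
  ts <- c(0.1, 0.4, 0.8)
  for (mu in c(0.5, 2)) {
    eps <- mu * 1e-6
    up <- bds_pdf(ts, mu + eps, mu, 0.6, t_R)
    dn <- bds_pdf(ts, mu - eps, mu, 0.6, t_R)
    at <- bds_pdf(ts, mu, mu, 0.6, t_R)
    expect_equal((up + dn) / 2, at, tolerance = 1e-8)
    expect_equal(bds_cdf(ts, mu + eps, mu, 0.6, t_R),
                 bds_cdf(ts, mu, mu, 0.6, t_R), tolerance = 1e-6)
  }
})

test_that("the soft-uniform calibration density has the stated shape", {
  spec <- calibration_spec(c("A", "B"), 0.5, 1.0, tail_prob = 0.025)
  f <- function(t) exp(calibration_logpdf(spec, t))
  expect_equal(stats::integrate(f, 1e-9, 20)$value, 1, tolerance = 1e-6)
  expect_equal(calibration_logpdf(spec, 0.75),
               log((1 - 2 * 0.025) / 0.5))
  outside <- stats::integrate(f, 1e-9, 0.5)$value +
    stats::integrate(f, 1.0, 20)$value
  expect_equal(outside, 2 * 0.025, tolerance = 1e-6)
  # continuity at the bounds
  expect_equal(f(0.5 - 1e-9), f(0.5 + 1e-9), tolerance = 1e-6)
  expect_equal(f(1.0 - 1e-9), f(1.0 + 1e-9), tolerance = 1e-6)
})

test_that("segment factorial terms follow the rank partition", {
  # adjacent calibrations leave an empty middle segment
  expect_equal(segment_log_h(1, c(2, 3), 10, 2), 0)
  # n = 6 (4 free ages), one calibration at rank 2: counts (1, 2)
  expect_equal(segment_log_h(0, 2, 6, 1), lfactorial(1))
  expect_equal(segment_log_h(1, 2, 6, 1), lfactorial(2))
  # partition identity: factorial arguments sum to n - 2 - c
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    c_n <- sample(0:min(5, n - 3), 1)
    ranks <- sort(sample(n - 2, c_n))
    seg <- chronosite:::.segment_terms(ranks, sort(stats::runif(c_n)), n - 2)
    expect_equal(sum(seg$args), n - 2 - c_n)
  }
})

test_that("segment CDF-power terms reduce to the c = 1 identity", {
  expect_equal(segment_log_gprime(0, 0.4, 1, 8, 1), 0)  # exponent 0
  n <- 9; r0 <- 3; G0 <- 0.55
  got <- segment_log_gprime(0, G0, r0, n, 1) +
    segment_log_gprime(1, G0, r0, n, 1)
  expect_equal(got, (r0 - 1) * log(G0) + (n - 2 - r0) * log(1 - G0))
  # inconsistent ordering (rank says mass below, CDF says none) -> -Inf
  expect_equal(segment_log_gprime(0, 0, 3, 9, 1), -Inf)
})

test_that("the conditional density normalises within each rank sector", {
  # n = 4: one calibration at t_c plus one free age.  Conditional on the
  # calibration age and the observed ranking, the density of the free age
  # is g(t) / G(t_c) below the calibration and g(t) / (1 - G(t_c)) above
  # it; each sector must integrate to exactly 1.
  bds <- test_bds
  t_R <- 1
  for (t_c in c(0.3, 0.7)) {
    G <- function(t) bds_cdf(t, bds$lam, bds$mu, bds$rho, t_R)
    g <- function(t) bds_pdf(t, bds$lam, bds$mu, bds$rho, t_R)
    f <- function(t) {
      vapply(t, function(ti) {
        ranks <- if (t_c < ti) 1L else 2L
        seg <- chronosite:::.segment_terms(ranks, G(t_c), 2)
        exp(log(g(ti)) + sum(seg$ln_h) - sum(seg$ln_gp))
      }, 0)
    }
    below <- stats::integrate(f, 1e-9, t_c - 1e-9, rel.tol = 1e-9)$value
    above <- stats::integrate(f, t_c + 1e-9, t_R - 1e-9, rel.tol = 1e-9)$value
    expect_equal(below, 1, tolerance = 1e-6)
    expect_equal(above, 1, tolerance = 1e-6)
  }
})

test_that("the full prior reproduces a hand calculation on a toy tree", {
  # ((A,B),(C,D)): root 7 at 1.0; node 5 = AB at 0.3 (calibrated),
  # node 6 = CD at 0.6 (free).  APV = [5, 6], calibration rank 1.
  tr <- parse_newick("((A:0.3,B:0.3):0.7,(C:0.6,D:0.6):0.4);")
  expect_equal(tr$ages[tr$root], 1.0)
  cal <- resolve_calibrations(tr, list(
    calibration_spec(c("A", "C"), 0.9, 1.1),
    calibration_spec(c("A", "B"), 0.2, 0.4)))
  bds <- test_bds
  ab <- mrca_node(tr, c("A", "B")); cd <- mrca_node(tr, c("C", "D"))
  G5 <- bds_cdf(tr$ages[ab], bds$lam, bds$mu, bds$rho, 1)
  by_hand <- log(bds_pdf(tr$ages[cd], bds$lam, bds$mu, bds$rho, 1)) +
    (lfactorial(0) + lfactorial(0)) -          # h(0), h(1): counts 0 and 1-1=...
    (0 + 1 * log(1 - G5))                      # G'(0) exp 0; G'(1) exp 1
  fp <- full_log_prior(tr, cal, bds)
  expect_equal(fp$ln_f, by_hand, tolerance = 1e-12)
  expect_equal(fp$ln_fcal_total,
               calibration_logpdf(cal[[as.character(tr$root)]], 1.0) +
                 calibration_logpdf(cal[[as.character(ab)]], tr$ages[ab]),
               tolerance = 1e-12)
})

test_that("prior state initialisation builds sorted APV and c+1 segments", {
  set.seed(32)
  # c = 0: root-only calibration; one segment, ln f = sum ln g + ln((n-2)!)
  tr <- rand_ultrametric_tree(7)
  cal <- rand_cal_map(tr, 0)
  ps <- init_prior_state(tr, cal, test_bds)
  expect_length(ps$seg_h, 1)
  noncal <- setdiff(tr$postorder, tr$root)
  expect_equal(ps$ln_f,
               sum(log(bds_pdf(tr$ages[noncal], 2, 1, 0.5, 1))) +
                 lfactorial(5), tolerance = 1e-12)
  expect_equal(ps$apv, ps$apv[order(tr$ages[ps$apv])])

  # 4-leaf tree with 1 internal calibration: APV length 2, CDV length 2
  tr2 <- parse_newick("((A:0.3,B:0.3):0.7,(C:0.6,D:0.6):0.4);")
  cal2 <- resolve_calibrations(tr2, list(
    calibration_spec(c("A", "D"), 0.9, 1.1),
    calibration_spec(c("A", "B"), 0.2, 0.4)))
  ps2 <- init_prior_state(tr2, cal2, test_bds)
  expect_length(ps2$apv, 2)
  expect_length(ps2$seg_h, 2)
  expect_equal(prior_log_total(ps2), full_log_prior(tr2, cal2, test_bds)$total,
               tolerance = 1e-12)
})

test_that("incremental transactions track the full recomputation oracle", {
  set.seed(33)
  for (trial in 1:8) {
    n <- sample(5:25, 1)
    tr <- rand_ultrametric_tree(n)
    cal <- rand_cal_map(tr, sample(0:3, 1))
    ps <- init_prior_state(tr, cal, test_bds)
    ages <- tr$ages
    for (j in 1:300) {
      v <- sample(setdiff(tr$postorder, tr$root), 1)
      lo <- max(ages[c(tr$child1[v], tr$child2[v])])
      hi <- ages[tr$parent[v]]
      na <- stats::runif(1, lo, hi)
      dl <- propose_age_update(ps, v, na, ages)
      tr2 <- tr; tr2$ages <- ages; tr2$ages[v] <- na
      oracle <- full_log_prior(tr2, cal, test_bds)$total
      expect_equal(prior_log_total(ps), oracle, tolerance = 1e-9)
      expect_equal(dl, oracle - full_log_prior(
        within_tree(tr, ages), cal, test_bds)$total, tolerance = 1e-9)
      if (stats::runif(1) < 0.5) {
        commit_age_update(ps); ages[v] <- na
      } else {
        revert_age_update(ps)
        expect_equal(prior_log_total(ps), full_log_prior(
          within_tree(tr, ages), cal, test_bds)$total, tolerance = 1e-12)
      }
    }
    # APV equals a fresh initialisation after the whole history
    tr$ages <- ages
    ps2 <- init_prior_state(tr, cal, test_bds)
    expect_identical(ps$apv, ps2$apv)
    expect_equal(prior_log_total(ps), prior_log_total(ps2), tolerance = 1e-9)
  }
})

test_that("root-age transactions recondition every kernel term", {
  set.seed(34)
  tr <- rand_ultrametric_tree(10)
  cal <- rand_cal_map(tr, 2)
  ps <- init_prior_state(tr, cal, test_bds)
  ages <- tr$ages
  top <- max(ages[setdiff(tr$postorder, tr$root)])
  for (j in 1:20) {
    na <- stats::runif(1, max(top, 0.85), 1.3)
    dl <- propose_root_age_update(ps, na, ages)
    tr2 <- tr; tr2$ages <- ages; tr2$ages[tr$root] <- na
    expect_equal(prior_log_total(ps), full_log_prior(tr2, cal, test_bds)$total,
                 tolerance = 1e-9)
    if (j %% 2 == 0) {
      commit_age_update(ps); ages[tr$root] <- na
    } else {
      revert_age_update(ps)
      expect_equal(prior_log_total(ps), full_log_prior(
        within_tree(tr, ages), cal, test_bds)$total, tolerance = 1e-12)
    }
  }
})

test_that("a free node crossing two calibrations touches exactly 3 segments", {
  tr <- balanced_tree(8)
  # cherries sit at ages 0.25 (three) under parents at 0.5; retime them
  below <- chronosite:::leaves_below(tr)
  cherries <- tr$postorder[vapply(tr$postorder, function(v)
    tr$child1[v] <= 8 && tr$child2[v] <= 8, TRUE)]
  mids <- setdiff(tr$postorder, c(cherries, tr$root))
  tr$ages[cherries] <- c(0.10, 0.20, 0.30, 0.40)
  tr$ages[mids] <- c(0.80, 0.90)
  tr$ages[tr$root] <- 1.0
  expect_length(validate_ages(tr), 0)
  specs <- list(calibration_spec(tr$labels[1:8], 0.9, 1.1))
  for (v in cherries[2:3]) {
    specs[[length(specs) + 1]] <- calibration_spec(
      tr$labels[below[[v]]], tr$ages[v] - 0.05, tr$ages[v] + 0.05)
  }
  cal <- resolve_calibrations(tr, specs)
  ps <- init_prior_state(tr, cal, test_bds)
  expect_equal(ps$cal_ranks, c(2L, 3L))
  # move the youngest (free) cherry past both calibrated cherries
  dl <- propose_age_update(ps, cherries[1], 0.35, tr$ages)
  expect_equal(ps$last_nseg, 3L)
  tr2 <- tr; tr2$ages[cherries[1]] <- 0.35
  expect_equal(prior_log_total(ps), full_log_prior(tr2, cal, test_bds)$total,
               tolerance = 1e-12)
  revert_age_update(ps)

  # a calibrated cherry moving in place touches its 2 bordering segments
  dl <- propose_age_update(ps, cherries[2], 0.22, tr$ages)
  expect_equal(ps$last_nseg, 2L)
  tr3 <- tr; tr3$ages[cherries[2]] <- 0.22
  expect_equal(prior_log_total(ps), full_log_prior(tr3, cal, test_bds)$total,
               tolerance = 1e-12)
  revert_age_update(ps)
})

test_that("the single-CDF shortcut equals direct segment recomputation", {
  n2 <- 8
  ranks <- c(3L, 6L)
  gv_old <- c(0.35, 0.7)
  gv_new <- c(0.42, 0.7)   # only the first calibration's CDF moved
  old <- chronosite:::.segment_terms(ranks, gv_old, n2)
  new <- chronosite:::.segment_terms(ranks, gv_new, n2)
  for (i in 1:2) {  # segments bordering calibration 1
    shortcut <- chronosite:::.delta_gprime_one_cdf(
      old$args[i],
      c(0, gv_new, 1)[i + 1] - c(0, gv_new, 1)[i],
      c(0, gv_old, 1)[i + 1] - c(0, gv_old, 1)[i])
    expect_equal(shortcut, new$ln_gp[i] - old$ln_gp[i], tolerance = 1e-12)
  }
})
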