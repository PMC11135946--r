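test_that("birth-death trees honor tip count, root age and the Yule kernel", {
  set.seed(10)
  cfg <- simulation_config(n_tips = 12, root_age = 2000, lambda = 0.5, mu = 0.2)
  tr <- simulate_birth_death_tree(cfg)
  expect_equal(length(tr$tip.label), 12)
  expect_equal(tr$Nnode, 11)
  expect_equal(unname(node_ages(tr)[13]), 2000)

  # two tips: a single cherry at the root age
  tr2 <- simulate_birth_death_tree(simulation_config(n_tips = 2, root_age = 500))
  expect_equal(unname(node_ages(tr2)[3]), 500)
  expect_equal(nrow(tr2$edge), 2)

  # Yule (mu = 0): non-root node ages are iid from the truncated-exponential
  # kernel; pool ages over replicates and compare with the analytic CDF
  set.seed(11)
  lam <- 0.8; t1 <- 1500
  cfgy <- simulation_config(n_tips = 6, root_age = t1, lambda = lam, mu = 0)
  ages <- unlist(lapply(1:500, function(i) {
    a <- node_ages(simulate_birth_death_tree(cfgy))
    a[8:11]   # the four non-root internal nodes (root is node 7)
  }))
  cdf <- function(t) (1 - exp(-lam * t / 100)) / (1 - exp(-lam * t1 / 100))
  expect_lt(ks_dist(ages, cdf), 0.04)
})

test_that("the kernel sampler matches the kernel density for all regimes", {
  set.seed(12)
  for (pars in list(c(0.7, 0), c(0.5, 0.3), c(0.4, 0.4), c(0.3, 0.5))) {
    x <- chronodate:::r_bd_kernel(8000, pars[1], pars[2], 2000)
    expect_true(all(x > 0 & x < 2000))
    # CDF by numerical integration of the exported kernel density
    dens <- function(t) exp(tree_prior_logdensity(t, pars[1], pars[2], 2000))
    grid_cdf <- function(t) vapply(t, function(tt)
      integrate(dens, 1e-9, tt, rel.tol = 1e-8)$value, 0)
    qs <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9))
    expect_equal(unname(grid_cdf(qs)), c(0.1, 0.25, 0.5, 0.75, 0.9),
                 tolerance = 0.03)
  }
})

test_that("branch rates follow the declared clock models", {
  set.seed(13)
  cfg <- simulation_config(n_tips = 10, clock = "strict", mean_rate = 0.03)
  tr <- simulate_birth_death_tree(cfg)
  expect_true(all(simulate_branch_rates(tr, cfg) == 0.03))

  # IR: lognormal with mean-preserving parameterization
  cfg_ir <- simulation_config(n_tips = 10, clock = "IR", mean_rate = 0.03,
                              sigma2 = 0.3)
  r <- replicate(6000, simulate_branch_rates(tr, cfg_ir))
  expect_equal(mean(r), 0.03, tolerance = 0.01)
  expect_equal(sd(log(r)), sqrt(0.3), tolerance = 0.02)

  # AR degenerates to strict as sigma2 -> 0
  cfg_ar <- simulation_config(n_tips = 10, clock = "AR", mean_rate = 0.03,
                              sigma2 = 1e-12)
  expect_equal(unname(simulate_branch_rates(tr, cfg_ar)),
               rep(0.03, nrow(tr$edge)), tolerance = 1e-4)
  expect_error(simulation_config(clock = "IR", sigma2 = 0), "strict")
})

test_that("sequence evolution matches its closed-form expectations", {
  # near-zero tree length: tips identical to each other (the root state)
  set.seed(14)
  cfg0 <- simulation_config(n_tips = 5, mean_rate = 1e-12, sites = 200)
  tr <- simulate_birth_death_tree(cfg0)
  aln <- evolve_alignment(tr, simulate_branch_rates(tr, cfg0), cfg0)
  expect_true(all(apply(aln$x, 2, function(col) length(unique(col)) == 1)))

  # two-taxon JC: observed p-distance matches the closed form
  b <- 0.3
  tr2 <- timetree(ape::read.tree(text = "(x:50,y:50);"))
  cfg2 <- simulation_config(n_tips = 2, sites = 1e5, mean_rate = b / 0.5)
  rates <- setNames(rep(cfg2$mean_rate, 2), tr2$edge[, 2])
  a2 <- evolve_alignment(tr2, rates, cfg2)
  p_obs <- mean(a2$x[1, ] != a2$x[2, ])
  p_exp <- 3 / 4 * (1 - exp(-4 / 3 * 2 * b))
  expect_equal(p_obs, p_exp, tolerance = 4 * sqrt(p_exp * (1 - p_exp) / 1e5) / p_exp)

  # HKY stationary frequencies are preserved empirically
  set.seed(15)
  fr <- c(0.4, 0.3, 0.2, 0.1)
  cfg3 <- simulation_config(n_tips = 8, sites = 4000, mean_rate = 0.03,
                            model = subst_model("HKY", freqs = fr, kappa = 3))
  tr3 <- simulate_birth_death_tree(cfg3)
  a3 <- evolve_alignment(tr3, simulate_branch_rates(tr3, cfg3), cfg3)
  emp <- tabulate(a3$x, 4) / length(a3$x)
  expect_equal(emp, fr, tolerance = 0.05)
})

test_that("NNI perturbation changes topology and respects age ordering", {
  set.seed(16)
  tr <- simulate_birth_death_tree(simulation_config(n_tips = 8))
  expect_identical(perturb_gene_tree(tr, 0), tr)
  for (i in 1:20) {
    pt <- perturb_gene_tree(tr, sample(1:3, 1))
    expect_gt(ape::dist.topo(ape::unroot(pt), ape::unroot(tr)), 0)
    expect_s3_class(pt, "timetree")   # implies valid ordering/ultrametric
  }
  tiny <- timetree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
  expect_error(perturb_gene_tree(tiny, 1), "too small")

  # 4 tips, 1 move: always one of the two alternative unrooted quartets
  q <- parse_newick("((a:1,b:1):2,(c:2,d:2):1);")
  alt_ids <- replicate(20, {
    pt <- ape::unroot(perturb_gene_tree(q, 1))
    if (ape::is.monophyletic(pt, c("a", "c"))) "ac" else
      if (ape::is.monophyletic(pt, c("a", "d"))) "ad" else "other"
  })
  expect_true(all(alt_ids %in% c("ac", "ad")))
})

test_that("generated calibrations bracket the true ages", {
  tr <- parse_newick("((A:1000,B:1000):1000,C:2000);")
  cal <- generate_calibrations(tr, list(list(tips = c("A", "B"),
                                             kind = "joint")),
                               style = list(offset = 0.2))[[1]]
  expect_equal(c(cal$tL, cal$tU), c(800, 1200))
  calm <- generate_calibrations(tr, list(list(tips = c("A", "C"),
                                              kind = "min")),
                                style = list(min_frac = 0.8))[[1]]
  expect_equal(calm$tL, 1600)

  set.seed(17)
  for (i in 1:100) {
    trr <- simulate_birth_death_tree(simulation_config(
      n_tips = sample(5:10, 1), root_age = runif(1, 1000, 4000)))
    ages <- node_ages(trr)
    rt <- length(trr$tip.label) + 1L
    nd <- sample(setdiff(which(ages > 0), rt), 1)
    sp <- span_tips(trr, nd)
    kind <- sample(c("joint", "min", "max"), 1)
    cal <- generate_calibrations(trr, list(list(tips = sp, kind = kind)))[[1]]
    tt <- ages[nd]
    if (kind %in% c("joint", "min")) expect_lte(cal$tL, tt)
    if (kind %in% c("joint", "max")) expect_gte(cal$tU, tt)
  }
})

test_that("presence/absence simulation plants the declared associations", {
  set.seed(18)
  tr <- simulate_birth_death_tree(simulation_config(n_tips = 20))
  grp <- setNames(rep(c("in", "out"), each = 10), tr$tip.label)
  spec <- list(groups = grp, focal_groups = "in", n_focal = 1, effect = 0,
               n_background = 2, switch_rate = 0.5, p0 = 0.4)

  # effect 0: focal column independent of groups (type-I uniformity)
  pvals <- replicate(300, {
    pa <- simulate_presence_absence(tr, spec)
    m <- table(factor(pa[, 1], 0:1), factor(grp[rownames(pa)] == "in",
                                            c(FALSE, TRUE)))
    fisher.test(m)$p.value
  })
  expect_lt(mean(pvals < 0.05), 0.09)

  # effect 1: presence iff in group, odds ratio sentinel Inf
  spec1 <- spec; spec1$effect <- 1
  pa1 <- simulate_presence_absence(tr, spec1)
  expect_equal(unname(pa1[, 1]), as.integer(grp[rownames(pa1)] == "in"))
  tab <- table(factor(pa1[, 1], 0:1), grp[rownames(pa1)] == "in")
  expect_equal(unname(fisher.test(tab)$estimate), Inf)

  # infinite conservation (no switches): background constant at root state
  spec0 <- spec; spec0$switch_rate <- 0
  pa0 <- simulate_presence_absence(tr, spec0)
  expect_true(all(apply(pa0[, 2:3, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))
})

test_that("simulators are pure functions of the seed", {
  cfg <- simulation_config(n_tips = 10, sites = 50)
  set.seed(99); t1 <- simulate_birth_death_tree(cfg)
  set.seed(99); t2 <- simulate_birth_death_tree(cfg)
  expect_identical(t1, t2)
  set.seed(99); a1 <- { r <- simulate_branch_rates(t1, cfg)
                        evolve_alignment(t1, r, cfg) }
  set.seed(99); a2 <- { r <- simulate_branch_rates(t1, cfg)
                        evolve_alignment(t1, r, cfg) }
  expect_identical(a1, a2)
})
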