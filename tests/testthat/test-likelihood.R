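test_that("pruning likelihood matches closed forms and brute force", {
  m <- subst_model("JC")

  # zero branch lengths, identical sequences: n_sites * log(freq of state)
  a0 <- alignment(matrix(c("A", "A", "C", "C"), 2, 2,
                         dimnames = list(c("x", "y"), NULL)), alphabet = "nt")
  t0 <- ape::read.tree(text = "(x:0,y:0);")
  expect_equal(pruning_loglik(a0, t0, m), 2 * log(0.25))

  # two-taxon JC at separation b: closed-form site likelihoods
  a2 <- alignment(matrix(c("A", "A", "C", "C", "G", "T"), 2, 3,
                         dimnames = list(c("x", "y"), NULL)), alphabet = "nt")
  tb <- ape::read.tree(text = "(x:0.08,y:0.12);")
  b <- 0.2
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * b / 3)
  p_diff <- (1 - p_same) / 3
  expect_equal(pruning_loglik(a2, tb, m),
               2 * log(p_same / 4) + log(p_diff / 4))

  # four-taxon tree vs exhaustive enumeration over internal states
  set.seed(20)
  cfg <- simulation_config(n_tips = 4, sites = 30, mean_rate = 0.05)
  tr <- simulate_birth_death_tree(cfg)
  aln <- evolve_alignment(tr, simulate_branch_rates(tr, cfg), cfg)
  bl <- runif(6, 0.01, 0.5)
  names(bl) <- tr$edge[, 2]
  P <- lapply(bl, function(x)
    0.25 + (diag(4) - 0.25) * exp(-4 * x / 3))   # JC transition matrix
  brute <- 0
  post <- tr$edge                                 # nodes 5 (root), 6, 7
  inner <- setdiff(unique(tr$edge[, 1]), integer(0))
  for (s in seq_len(30)) {
    tot <- 0
    for (i5 in 1:4) for (i6 in 1:4) for (i7 in 1:4) {
      st <- c(aln$x[match(tr$tip.label, aln$taxa), s], i5, i6, i7)
      pr <- 0.25
      for (e in seq_len(nrow(tr$edge)))
        pr <- pr * P[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
      tot <- tot + pr
    }
    brute <- brute + log(tot)
  }
  expect_equal(pruning_loglik(aln, tr, m, brlen = bl), brute)
})

test_that("pruning likelihood agrees with an independent implementation", {
  set.seed(21)
  cfg <- simulation_config(n_tips = 10, sites = 300, mean_rate = 0.04)
  tr <- simulate_birth_death_tree(cfg)
  rates <- simulate_branch_rates(tr, cfg)
  aln <- evolve_alignment(tr, rates, cfg)
  b <- rates[as.character(tr$edge[, 2])] * tr$edge.length / 100
  chars <- matrix(c("a", "c", "g", "t")[aln$x], nrow = nrow(aln$x))
  rownames(chars) <- aln$taxa
  tr2 <- tr; tr2$edge.length <- as.numeric(b)
  fit <- phangorn::pml(tr2, phangorn::phyDat(chars, type = "DNA"))
  expect_equal(pruning_loglik(aln, tr, subst_model("JC"), brlen = b),
               fit$logLik, tolerance = 1e-8)
})

test_that("HKY transition probabilities match the matrix exponential", {
  fr <- c(0.35, 0.15, 0.3, 0.2); kap <- 4
  m <- subst_model("HKY", freqs = fr, kappa = kap)
  # rate matrix, normalized to mean rate 1, exponentiated by eigen
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    ti <- (i %in% c(1, 3)) == (j %in% c(1, 3))
    Q[i, j] <- fr[j] * (if (ti) kap else 1)
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * fr)
  eg <- eigen(Q)
  for (b in c(0.05, 0.4, 2)) {
    Pexp <- Re(eg$vectors %*% diag(exp(eg$values * b)) %*% solve(eg$vectors))
    expect_equal(chronodate:::trans_prob(m, b), Pexp, tolerance = 1e-9)
    expect_equal(rowSums(chronodate:::trans_prob(m, b)), rep(1, 4))
  }
})

test_that("ambiguous characters are marginalized as missing", {
  m <- subst_model("JC")
  a1 <- alignment(matrix(c("A", "N"), 2, 1, dimnames = list(c("x", "y"), NULL)),
                  alphabet = "nt")
  tb <- ape::read.tree(text = "(x:0.1,y:0.1);")
  # summing the two-taxon likelihood over y's state equals treating y as N
  ll_marg <- log(sum(vapply(c("A", "C", "G", "T"), function(s) {
    aa <- alignment(matrix(c("A", s), 2, 1,
                           dimnames = list(c("x", "y"), NULL)), alphabet = "nt")
    exp(pruning_loglik(aa, tb, m))
  }, 0)))
  expect_equal(pruning_loglik(a1, tb, m), ll_marg)
})

test_that("analytic gradient matches finite differences", {
  set.seed(22)
  for (mod in list(subst_model("JC"),
                   subst_model("HKY", freqs = c(0.3, 0.2, 0.3, 0.2), kappa = 3))) {
    cfg <- simulation_config(n_tips = 6, sites = 200, mean_rate = 0.04,
                             model = mod)
    tr <- simulate_birth_death_tree(cfg)
    aln <- evolve_alignment(tr, simulate_branch_rates(tr, cfg), cfg)
    b0 <- setNames(runif(nrow(tr$edge), 0.05, 0.4), tr$edge[, 2])
    g <- chronodate:::loglik_grad(aln, tr, mod, b0)$gradient
    num <- vapply(seq_along(b0), function(e) {
      bp <- b0; bp[e] <- bp[e] + 1e-6
      bm <- b0; bm[e] <- bm[e] - 1e-6
      (pruning_loglik(aln, tr, mod, brlen = bp) -
         pruning_loglik(aln, tr, mod, brlen = bm)) / 2e-6
    }, 0)
    expect_equal(g, num, tolerance = 1e-5)
  }
})

test_that("branch-length ML is consistent at large site counts", {
  set.seed(23)
  cfg <- simulation_config(n_tips = 5, sites = 20000, mean_rate = 0.02,
                           root_age = 2000)
  tr <- simulate_birth_death_tree(cfg)
  rates <- simulate_branch_rates(tr, cfg)
  aln <- evolve_alignment(tr, rates, cfg)
  btrue <- setNames(rates[as.character(tr$edge[, 2])] * tr$edge.length / 100,
                    tr$edge[, 2])
  ml <- optimize_branch_lengths(aln, tr, subst_model("JC"))
  # compare the well-identified branches (the two root-child branches are
  # confounded in the unrooted likelihood: compare their sum)
  rt <- 6L
  kids <- as.character(tr$edge[tr$edge[, 1] == rt, 2])
  others <- setdiff(names(btrue), kids)
  # each identifiable branch within ~4 standard errors (SE ~ sqrt(b/n))
  se <- sqrt(pmax(btrue[others], 0.005) / 20000)
  expect_true(all(abs(ml$brlen[others] - btrue[others]) < 4 * se + 1e-4))
  expect_equal(sum(ml$brlen[kids]), sum(btrue[kids]), tolerance = 0.04)
})

test_that("the quadratic surface matches the exact likelihood locally", {
  set.seed(24)
  cfg <- simulation_config(n_tips = 8, sites = 1000, mean_rate = 0.03)
  tr <- simulate_birth_death_tree(cfg)
  aln <- evolve_alignment(tr, simulate_branch_rates(tr, cfg), cfg)
  m <- subst_model("JC")
  surf <- fit_approx_surface(aln, tr, m)
  expect_true(isSymmetric(surf$hessian, tol = 1e-8))
  interior <- !surf$clamped
  expect_lt(max(abs(surf$gradient[interior])), 0.2)
  # exact at the expansion point
  expect_equal(approx_loglik(surf, surf$bhat), surf$loglik0)
  # close under perturbations with |b - bhat| <= 0.05
  for (i in 1:5) {
    db <- runif(length(surf$bhat), -0.005, 0.005)
    b2 <- pmax(1e-8, surf$bhat + db)
    ll_ex <- pruning_loglik(aln, tr, m,
                            brlen = setNames(b2, surf$edge_nodes))
    ll_ap <- approx_loglik(surf, b2)
    expect_lt(abs(ll_ex - ll_ap), 0.5)   # third-order remainder only
  }
})
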