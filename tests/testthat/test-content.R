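test_that("Manhattan distances count differing gene families", {
  m <- rbind(g1 = c(1, 0, 1), g2 = c(0, 0, 1), g3 = c(1, 1, 0))
  colnames(m) <- paste0("f", 1:3)
  d <- manhattan_matrix(pa_matrix(m))
  expect_equal(d["g1", "g2"], 1)
  expect_equal(d["g1", "g3"], 2)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(d))
  # triangle inequality on random binary matrices
  set.seed(80)
  for (r in 1:5) {
    x <- matrix(rbinom(80, 1, 0.4), 8, 10,
                dimnames = list(paste0("g", 1:8), paste0("f", 1:10)))
    dd <- manhattan_matrix(x)
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  }
  expect_error(manhattan_matrix(matrix(numeric(0), 0, 0)), "empty")
  expect_error(pa_matrix(matrix(2, 1, 1, dimnames = list("a", "b"))), "0/1")
})

test_that("MinHash sketches estimate Jaccard within binomial error", {
  set.seed(81)
  a <- random_dna(10000)
  b <- mutate_dna(a, 0.05)
  for (s in c(500, 1000)) {
    jhat <- minhash_jaccard(a, b, k = 21, sketch_size = s)
    jex <- exact_jaccard(a, b, 21)
    se <- sqrt(jex * (1 - jex) / s)
    expect_lt(abs(jhat - jex), 3 * se)
  }
  # identical sequences: j = 1, d = 0; disjoint k-mer sets: capped distance
  d <- mash_matrix(c(x = a, y = a), k = 21, sketch_size = 200)
  expect_equal(d["x", "y"], 0)
  disj <- c(p = strrep("A", 200), q = strrep("C", 200))
  d2 <- mash_matrix(disj, k = 11, sketch_size = 100, max_dist = 1)
  expect_equal(d2["p", "q"], 1)
  expect_error(mash_matrix(c(s = "ACGT"), k = 21), "larger than a sequence")
  # deterministic given (k, sketch, seed)
  expect_identical(mash_matrix(c(x = a, y = b), seed = 9),
                   mash_matrix(c(x = a, y = b), seed = 9))
  expect_false(identical(minhash_jaccard(a, b, seed = 1),
                         minhash_jaccard(a, b, seed = 2)) &&
               FALSE) # different seeds may differ; equality not required
})

test_that("NMDS recovers planar configurations and reports stress", {
  set.seed(82)
  pts <- matrix(rnorm(60), 30, 2)
  rownames(pts) <- paste0("g", 1:30)
  d <- as.matrix(dist(pts))
  em <- nmds_embed(d, dims = 2, seed = 1)
  expect_lt(em$stress, 0.01)
  expect_equal(rownames(em$points), rownames(pts))
  # more dimensions never fit worse (same initialization scheme)
  hi <- matrix(rnorm(150), 30, 5)
  dh <- as.matrix(dist(hi)); rownames(dh) <- colnames(dh) <- paste0("g", 1:30)
  s2 <- nmds_embed(dh, dims = 2, seed = 1)$stress
  s3 <- nmds_embed(dh, dims = 3, seed = 1)$stress
  expect_lte(s3, s2 + 1e-6)
  # duplicate items land on coincident coordinates
  pts2 <- rbind(pts, g31 = pts[1, ])
  d2 <- as.matrix(dist(pts2))
  em2 <- nmds_embed(d2, dims = 2, seed = 1)
  expect_lt(sqrt(sum((em2$points["g31", ] - em2$points["g1", ])^2)),
            0.02 * max(dist(em2$points)))
  expect_error(nmds_embed(d[1:2, 1:2], dims = 2), "at least")
})

test_that("configuration stress is invariant to similarity transforms", {
  set.seed(83)
  x <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(matrix(rnorm(100), 20, 5)))
  s0 <- kruskal_stress(d, x)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(kruskal_stress(d, x %*% rot), s0, tolerance = 1e-10)
  expect_equal(kruskal_stress(d, 3.7 * x), s0, tolerance = 1e-10)
  expect_equal(kruskal_stress(d, sweep(x, 2, c(5, -2), "+")), s0,
               tolerance = 1e-10)
})

test_that("the convergence permutation test is valid and powerful", {
  set.seed(84)
  ids <- paste0("g", 1:16)
  A <- ids[1:4]; B <- ids[5:8]
  rand_d <- function() {
    m <- as.matrix(dist(matrix(rnorm(16 * 6), 16, 6)))
    dimnames(m) <- list(ids, ids); m
  }
  # null: the two metrics are independent of the groups
  pvals <- replicate(120, {
    convergence_permutation_test(rand_d(), rand_d(), A, B, n_perm = 99,
                                 seed = sample.int(1e6, 1))$p_value
  })
  expect_lt(mean(pvals <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 120) + 0.02)
  expect_gte(min(pvals), 1 / 100)          # add-one rule floor

  # identical matrices: statistic exactly zero
  d1 <- rand_d()
  t0 <- convergence_permutation_test(d1, d1, A, B, n_perm = 99, seed = 1)
  expect_equal(t0$statistic, 0)

  # planted convergence: A and B metabolically close, nucleotide distant
  met <- rand_d() / 10
  met[A, B] <- met[A, B] / 10; met[B, A] <- t(met[A, B])
  nuc <- rand_d()
  nuc[A, B] <- nuc[A, B] + 5; nuc[B, A] <- t(nuc[A, B])
  diag(met) <- diag(nuc) <- 0
  pp <- convergence_permutation_test(met, nuc, A, B, n_perm = 199, seed = 2)
  expect_lt(pp$p_value, 0.05)

  expect_error(convergence_permutation_test(d1, d1, A, B, n_perm = 50),
               ">= 99")
  expect_error(convergence_permutation_test(d1, d1, A, A, n_perm = 99),
               "disjoint")
})

test_that("phylogenetic signal separates Brownian traits from noise", {
  set.seed(85)
  tr <- simulate_birth_death_tree(simulation_config(n_tips = 30))
  lam_bm <- vapply(1:10, function(i)
    phylo_signal(tr, ape::rTraitCont(tr, sigma = 1))$lambda, 0)
  expect_gte(median(lam_bm), 0.8)
  expect_lte(median(lam_bm), 1.02)
  noise <- phylo_signal(tr, setNames(rnorm(30), tr$tip.label))
  expect_lt(noise$lambda, 0.2)
  # ML definition: fitted lambda beats lambda = 0
  bm <- phylo_signal(tr, ape::rTraitCont(tr, sigma = 1))
  expect_gte(bm$logL, bm$logL0 - 1e-6)
  expect_error(phylo_signal(tr, setNames(rep(1, 30), tr$tip.label)),
               "variance")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(86)
  brute_bh <- function(p) {
    m <- length(p); o <- order(p); ranked <- p[o]
    adj <- pmin(1, rev(cummin(rev(ranked * m / seq_len(m)))))
    out <- numeric(m); out[o] <- adj; out
  }
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("the association battery wires Fisher, Pearson and phylosig", {
  set.seed(87)
  tr <- simulate_birth_death_tree(simulation_config(n_tips = 10))
  grp <- setNames(rep(c("in", "out"), each = 5), tr$tip.label)
  m <- cbind(focal = as.integer(grp == "in"),
             same = as.integer(grp == "in"),
             noise = rbinom(10, 1, 0.5))
  rownames(m) <- tr$tip.label
  pa <- pa_matrix(m, groups = grp)
  bat <- association_battery(pa, tree = NULL,
                             contrasts = list(c1 = list(groups_in = "in")),
                             focal_gene = "focal")
  same_row <- bat[bat$gene == "same", ]
  # perfect 5/5 split: two-sided Fisher p = 2/choose(10,5) = 2/252
  expect_equal(same_row$fisher_p, 2 / 252, tolerance = 1e-10)
  expect_equal(same_row$pearson_r, 1)
  expect_true(all(bat$fisher_p_adj >= bat$fisher_p - 1e-12))
  expect_identical(bat$pass, bat$fisher_p_adj < 0.05)
  expect_error(association_battery(pa, NULL,
    contrasts = list(bad = list(groups_in = "nope")), focal_gene = "focal"),
    "empty group")
})
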