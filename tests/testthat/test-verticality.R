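test_that("delta LL separates congruent from discordant genes", {
  set.seed(70)
  cfg <- simulation_config(n_tips = 5, root_age = 1200, sites = 800,
                           mean_rate = 0.05)
  tr <- parse_newick(
    "(((a:200,b:200):600,c:800):400,(d:700,e:700):500);")
  alt <- parse_newick(
    "(((a:200,c:200):600,b:800):400,(d:700,e:700):500);")
  g_cong <- evolve_alignment(tr, simulate_branch_rates(tr, cfg), cfg)
  d_cong <- compute_delta_ll(g_cong, tr, subst_model("JC"))
  expect_lt(d_cong$delta_ll, 1e-6)   # species topology attains the maximum

  g_inc <- evolve_alignment(alt, simulate_branch_rates(alt, cfg), cfg)
  d_inc <- compute_delta_ll(g_inc, tr, subst_model("JC"))
  expect_gt(d_inc$delta_ll, 5)
  # hill-climbing finds the exhaustive optimum on 5 taxa
  d_nni <- compute_delta_ll(g_inc, tr, subst_model("JC"), search = "nni")
  expect_equal(d_nni$delta_ll, d_inc$delta_ll, tolerance = 1e-6)

  # invariant to taxon input order
  perm <- g_inc
  ord <- sample(length(g_inc$taxa))
  perm$taxa <- g_inc$taxa[ord]; perm$x <- g_inc$x[ord, , drop = FALSE]
  d_perm <- compute_delta_ll(perm, tr, subst_model("JC"))
  expect_equal(d_perm$delta_ll, d_inc$delta_ll, tolerance = 1e-5)

  tiny <- structure(list(taxa = g_inc$taxa[1:3], x = g_inc$x[1:3, ],
                         alphabet = "nt", n_sites = g_inc$n_sites),
                    class = "chrono_alignment")
  expect_error(compute_delta_ll(tiny, tr, subst_model("JC")), "4 taxa")
})

test_that("gene-removal series drops the most discordant genes stepwise", {
  set.seed(71)
  genes <- screening_genes(n_cong = 5, n_inc = 3, sites = 200)
  st <- screening_trees()
  dll <- chronodate:::gene_dll_table(genes, st$species, subst_model("JC"),
                                     search = "nni")
  # discordant genes rank on top
  expect_true(all(grepl("^inc", dll$gene[1:3])))

  cal <- root_joint_cal(st$species, 2400, 3600)
  date_fn <- function(aln) {
    surf <- fit_approx_surface(aln, st$species, subst_model("JC"))
    run_chain(surf, st$species, list(cal), clock = clock_model("strict"),
              settings = quick_settings(n_iter = 3000))
  }
  traj <- gene_removal_series(genes, st$species, date_fn, st$cladeA,
                              st$cladeB, step = 2, floor = 4,
                              dll = dll)
  expect_equal(traj$n_genes, c(8, 6, 4))             # drops exactly 2 per step
  expect_true(all(diff(traj$mean_dll) <= 1e-9))      # non-increasing
  expect_true(all(c("age_gap", "ageA_mean", "ageB_hi") %in% names(traj)))

  expect_error(gene_removal_series(genes[1:3], st$species, date_fn,
                                   st$cladeA, st$cladeB, step = 2, floor = 4),
               "at least")
})

test_that("sliding windows cover the delta-LL gradient at fixed gene count", {
  set.seed(72)
  genes <- screening_genes(n_cong = 4, n_inc = 3, sites = 150)
  st <- screening_trees()
  dll <- chronodate:::gene_dll_table(genes, st$species, subst_model("JC"),
                                     search = "nni")
  cal <- root_joint_cal(st$species, 2400, 3600)
  date_fn <- function(aln) {
    surf <- fit_approx_surface(aln, st$species, subst_model("JC"))
    run_chain(surf, st$species, list(cal), clock = clock_model("strict"),
              settings = quick_settings(n_iter = 3000))
  }
  traj <- sliding_window_series(genes, st$species, date_fn, st$cladeA,
                                st$cladeB, k = 4, dll = dll)
  expect_equal(nrow(traj), 7 - 4 + 1)
  expect_true(all(diff(traj$mean_dll) >= -1e-9))   # windows slide upward
  expect_error(sliding_window_series(genes, st$species, date_fn, st$cladeA,
                                     st$cladeB, k = 10, dll = dll),
               "window size")

  # k = n: single window, identical gene set to dating on everything
  set.seed(5)
  traj_all <- sliding_window_series(genes, st$species, date_fn, st$cladeA,
                                    st$cladeB, k = 7, dll = dll)
  expect_equal(nrow(traj_all), 1)
  expect_setequal(strsplit(traj_all$genes_retained, ",")[[1]], names(genes))
})

test_that("clade age gaps follow the stated sign convention", {
  set.seed(73)
  st <- screening_trees()
  cal <- root_joint_cal(st$species, 2400, 3600)
  post <- run_chain(NULL, st$species, list(cal),
                    settings = quick_settings(n_iter = 4000))
  expect_equal(clade_age_gap(post, st$cladeA, st$cladeA), 0)
  gap <- clade_age_gap(post, st$cladeA, st$cladeB)
  # brute force from the trace
  ndA <- clade_node(st$species, st$cladeA)
  ndB <- clade_node(st$species, st$cladeB)
  expect_equal(gap, mean(post$ages[, paste0("n", ndB)]) -
                 mean(post$ages[, paste0("n", ndA)]))
  # negative when A is older, by construction of a shifted posterior
  p2 <- post
  p2$ages[, paste0("n", ndA)] <- p2$ages[, paste0("n", ndB)] + 100
  expect_equal(clade_age_gap(p2, st$cladeA, st$cladeB), -100)
})

test_that("dating failures truncate the trajectory with a warning", {
  set.seed(74)
  genes <- screening_genes(n_cong = 4, n_inc = 2, sites = 100)
  st <- screening_trees()
  dll <- chronodate:::gene_dll_table(genes, st$species, subst_model("JC"),
                                     search = "nni")
  boom <- local({
    calls <- 0
    function(aln) {
      calls <<- calls + 1
      if (calls >= 2) stop("sampler exploded")
      cal <- root_joint_cal(st$species, 2400, 3600)
      run_chain(NULL, st$species, list(cal),
                settings = quick_settings(n_iter = 2000))
    }
  })
  expect_warning(
    traj <- gene_removal_series(genes, st$species, boom, st$cladeA,
                                st$cladeB, step = 2, floor = 2, dll = dll),
    "truncated")
  expect_equal(nrow(traj), 1)
})
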