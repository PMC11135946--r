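# shared fixtures and small utilities, all built in code

# one tip label from each child subtree of `nd`, so their MRCA is `nd`
span_tips <- function(tr, nd) {
  n <- length(tr$tip.label)
  kids <- tr$edge[tr$edge[, 1] == nd, 2]
  tip1 <- function(k) if (k <= n) tr$tip.label[k] else
    ape::extract.clade(tr, k)$tip.label[1]
  c(tip1(kids[1]), tip1(kids[2]))
}

root_joint_cal <- function(tr, tL, tU, name = "root") {
  sp <- span_tips(tr, length(tr$tip.label) + 1L)
  calibration(name, sp[1], sp[2], "joint", tL = tL, tU = tU)
}

# exact KS distance between a sample and a cdf function
ks_dist <- function(x, cdf) {
  xs <- sort(x); n <- length(xs); Fx <- cdf(xs)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

quick_settings <- function(n_iter = 6000, thin = 3, lambda = 0.4, mu = 0.1, ...)
  chain_settings(n_iter = n_iter, thin = thin, lambda = lambda, mu = mu, ...)

# screening fixture: species timetree and an age-shifted, NNI-perturbed
# donor tree with a planted gap between the total groups of clades A and B.
# Species truth: total(A) = 1200 Ma, total(B) = 2400 Ma, gap = +1200 Ma;
# donor: total(A) = 2600, total(B) = 1100 (and swapped subtrees), so genes
# from the donor pull the estimated gap down.
screening_trees <- function() {
  sp <- parse_newick(paste0(
    "(((A1:500,A2:500):700,(X1:800,X2:800):400):1800,",
    "((B1:1800,B2:1800):600,(Y1:900,Y2:900):1500):600);"))
  donor <- parse_newick(paste0(
    "(((A1:500,X1:500):2100,(A2:800,X2:800):1800):400,",
    "((B1:800,Y1:800):300,(B2:900,Y2:900):200):1900);"))
  list(species = sp, donor = donor,
       cladeA = clade_ref("A", "A1", "A2", scope = "total"),
       cladeB = clade_ref("B", "B1", "B2", scope = "total"),
       true_gap = 1200)
}

# gene mixture on the screening fixture
screening_genes <- function(n_cong = 10, n_inc = 6, sites = 250,
                            mean_rate = 0.02) {
  st <- screening_trees()
  cfg <- simulation_config(n_tips = 8, sites = sites, mean_rate = mean_rate)
  genes <- list()
  for (i in seq_len(n_cong)) {
    r <- simulate_branch_rates(st$species, cfg)
    genes[[sprintf("cong_%02d", i)]] <- evolve_alignment(st$species, r, cfg)
  }
  for (i in seq_len(n_inc)) {
    r <- simulate_branch_rates(st$donor, cfg)
    genes[[sprintf("inc_%02d", i)]] <- evolve_alignment(st$donor, r, cfg)
  }
  genes
}

# exact canonical k-mer Jaccard (set-based oracle for MinHash)
exact_jaccard <- function(a, b, k) {
  kmers <- function(s) {
    n <- nchar(s)
    u <- substring(s, 1:(n - k + 1), k:n)
    rc <- chartr("ACGT", "TGCA",
                 vapply(lapply(strsplit(u, ""), rev), paste, "", collapse = ""))
    unique(pmin(u, rc))
  }
  ka <- kmers(a); kb <- kmers(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_dna <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  i <- runif(length(v)) < p
  v[i] <- sample(c("A", "C", "G", "T"), sum(i), TRUE)
  paste(v, collapse = "")
}
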