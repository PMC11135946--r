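#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Units: ages in Ma;
#' birth/death rates in events per lineage per 100 Ma; substitution rates in
#' substitutions per site per 100 Ma; `sigma2` is the variance of log branch
#' rates (per 100 Ma of elapsed time for the autocorrelated clock).
#'
#' @param seed integer seed recorded with the config.
#' @param n_tips number of extant tips (>= 4 for most downstream use).
#' @param lambda,mu birth and death rates.
#' @param root_age true root age in Ma.
#' @param clock `"strict"`, `"IR"` (independent lognormal) or `"AR"`
#'   (autocorrelated, geometric Brownian).
#' @param mean_rate mean branch rate m.
#' @param sigma2 log-rate variance (0 only for strict).
#' @param model a [subst_model] (or name passed to it).
#' @param sites sites per gene.
#' @param n_congruent,n_incongruent gene family counts for mixtures.
#' @param nni_moves NNI perturbations per incongruent family.
#' @param cal_offset relative offset of generated calibration bounds around
#'   true ages (joint bounds at (1 +/- offset) x true).
#' @export
simulation_config <- function(seed = 1L, n_tips = 16L, lambda = 0.4, mu = 0.1,
                              root_age = 3000, clock = c("strict", "IR", "AR"),
                              mean_rate = 0.02, sigma2 = 0.2,
                              model = subst_model("JC"), sites = 500L,
                              n_congruent = 10L, n_incongruent = 6L,
                              nni_moves = 2L, cal_offset = 0.2) {
  clock <- match.arg(clock)
  if (is.character(model)) model <- subst_model(model)
  if (lambda <= 0 || mu < 0) stop("rates must satisfy lambda > 0, mu >= 0")
  if (mean_rate <= 0 || root_age <= 0) stop("all rates and ages must be positive")
  if (sigma2 < 0) stop("sigma2 >= 0 required")
  if (sigma2 == 0 && clock != "strict") stop("sigma2 = 0 only for the strict clock")
  if (n_tips < 2) stop("n_tips >= 2 required")
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 lambda = lambda, mu = mu, root_age = root_age, clock = clock,
                 mean_rate = mean_rate, sigma2 = sigma2, model = model,
                 sites = as.integer(sites), n_congruent = as.integer(n_congruent),
                 n_incongruent = as.integer(n_incongruent),
                 nni_moves = as.integer(nni_moves), cal_offset = cal_offset),
            class = "simulation_config")
}

#' Birth-death kernel density of node ages
#'
#' Density of an interior node age conditional on the root age under a
#' birth-death process with complete sampling (the node-age prior used by
#' the dating engine, and the exact distribution the tree simulator draws
#' from). The lambda = mu case is handled by its limit form.
#'
#' @param ages node ages in Ma (strictly between 0 and `root_age`).
#' @param lambda,mu birth and death rates per lineage per 100 Ma.
#' @param root_age root age in Ma.
#' @return log-density values (per Ma).
#' @export
tree_prior_logdensity <- function(ages, lambda, mu, root_age) {
  if (any(ages <= 0) || any(ages >= root_age))
    stop("age ordering violated: node ages must lie strictly inside (0, root age)")
  cpp_bd_kernel_logdens(ages / 100, root_age / 100, lambda, mu) - log(100)
}

# inverse-CDF sampler of the birth-death kernel (Ma)
r_bd_kernel <- function(n, lambda, mu, root_age) {
  t1 <- root_age / 100
  u <- runif(n)
  t <- if (mu < 1e-12) {
    -log(1 - u * (1 - exp(-lambda * t1))) / lambda
  } else if (abs(lambda - mu) < 1e-10) {
    cc <- u * t1 / (1 + lambda * t1)
    cc / (1 - lambda * cc)
  } else {
    r <- lambda - mu
    E1 <- exp(-r * t1)
    V <- (1 - E1) / (lambda - mu * E1)
    cc <- u * V
    -log((1 - cc * lambda) / (1 - cc * mu)) / r
  }
  100 * t
}

#' Simulate a birth-death timetree
#'
#' Conditioned on the number of extant tips and the root age: the n - 2
#' non-root node ages are drawn iid from the birth-death kernel density
#' given the root age, sorted, and each split is attached to a uniformly
#' chosen extant lineage — the exact generative counterpart of the dating
#' engine's node-age prior.
#'
#' @param cfg a [simulation_config] (fields `n_tips`, `lambda`, `mu`,
#'   `root_age` are used).
#' @return a [timetree] with tips `t1..tn`.
#' @export
simulate_birth_death_tree <- function(cfg) {
  n <- cfg$n_tips
  ages_int <- sort(r_bd_kernel(n - 2, cfg$lambda, cfg$mu, cfg$root_age),
                   decreasing = TRUE)
  n_nodes <- 2L * n - 1L
  root <- n + 1L
  parent_of <- integer(n_nodes)
  age <- numeric(n_nodes)
  age[root] <- cfg$root_age
  active <- c(root, root)   # parent of each open lineage
  next_int <- root + 1L
  for (t in ages_int) {
    j <- sample.int(length(active), 1)
    parent_of[next_int] <- active[j]
    age[next_int] <- t
    active <- c(active[-j], next_int, next_int)
    next_int <- next_int + 1L
  }
  # remaining open lineages become the extant tips, in random order
  ord <- sample.int(length(active))
  for (i in seq_len(n)) parent_of[i] <- active[ord[i]]
  edge <- cbind(parent_of[-root], seq_len(n_nodes)[-root])
  tr <- structure(list(edge = edge,
                       edge.length = age[edge[, 1]] - age[edge[, 2]],
                       Nnode = n - 1L,
                       tip.label = paste0("t", seq_len(n))),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  timetree(tr)
}

#' Simulate branch rates under a clock model
#'
#' Strict: every branch gets rate m. IR: iid lognormal with mean-preserving
#' parameterization (log-mean `log m - sigma2/2`). AR: geometric Brownian
#' along the tree — each branch's log-rate is normal around its parent
#' branch's log-rate with drift `-sigma2 dt / 2` and variance `sigma2 dt`,
#' where dt is the branch duration in 100 Ma; the root's children start from
#' the mean rate.
#'
#' @param tree a [timetree].
#' @param cfg a [simulation_config] (`clock`, `mean_rate`, `sigma2`).
#' @return named vector of rates (subst/site/100 Ma), names = child node id
#'   of each branch.
#' @export
simulate_branch_rates <- function(tree, cfg) {
  if (cfg$sigma2 < 0) stop("sigma2 >= 0 required")
  edge <- tree$edge
  nb <- nrow(edge)
  child <- edge[, 2]
  m <- cfg$mean_rate; s2 <- cfg$sigma2
  rates <- switch(cfg$clock,
    strict = rep(m, nb),
    IR = rlnorm(nb, log(m) - s2 / 2, sqrt(s2)),
    AR = {
      root <- length(tree$tip.label) + 1L
      dur <- tree$edge.length / 100
      r <- numeric(nb)
      # parents appear before children in cladewise order
      branch_of <- match(seq_len(root + tree$Nnode - 1L), child)
      for (i in seq_len(nb)) {
        p <- edge[i, 1]
        pr <- if (p == root) m else r[branch_of[p]]
        if (s2 == 0) r[i] <- pr
        else r[i] <- rlnorm(1, log(pr) - s2 * dur[i] / 2, sqrt(s2 * dur[i]))
      }
      r
    })
  names(rates) <- child
  rates
}

#' Evolve an alignment along a timetree
#'
#' Sites evolve independently; the expected number of substitutions on a
#' branch is `rate x duration` (duration in 100 Ma). The simulator uses the
#' same closed-form transition probabilities as the likelihood, so the
#' generator is the exact twin of the inference model.
#'
#' @param tree a [timetree].
#' @param rates named per-branch rates from [simulate_branch_rates()].
#' @param cfg a [simulation_config] (`model`, `sites`).
#' @return an [alignment].
#' @export
evolve_alignment <- function(tree, rates, cfg) {
  model <- cfg$model
  S <- model$nstates
  n <- length(tree$tip.label)
  root <- n + 1L
  sites <- cfg$sites
  states <- matrix(NA_integer_, root + tree$Nnode - 1L, sites)
  states[root, ] <- sample.int(S, sites, replace = TRUE, prob = model$freqs)
  edge <- tree$edge
  b <- rates[as.character(edge[, 2])] * tree$edge.length / 100
  for (i in seq_len(nrow(edge))) {   # cladewise: parents before children
    P <- trans_prob(model, b[i])
    par_states <- states[edge[i, 1], ]
    ch <- integer(sites)
    for (s in seq_len(S)) {
      idx <- which(par_states == s)
      if (length(idx))
        ch[idx] <- sample.int(S, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[edge[i, 2], ] <- ch
  }
  letters_of <- if (model$alphabet == "nt") NT_STATES else AA_STATES
  m <- matrix(toupper(letters_of)[states[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(m) <- tree$tip.label
  alignment(m, alphabet = model$alphabet)
}

#' Perturb a gene tree by rooted NNI moves
#'
#' Applies `n_moves` random nearest-neighbor interchanges on internal edges,
#' re-drawing the node age where an interchange would violate the age
#' ordering, and re-draws the whole move sequence if the final topology is
#' identical to the input (guaranteed different for `n_moves >= 1`).
#'
#' @param tree a [timetree] with >= 4 tips.
#' @param n_moves number of NNI moves (0 returns the tree unchanged).
#' @param max_tries re-draw attempts before giving up.
#' @return a [timetree] with the perturbed topology (ages adjusted only
#'   where ordering required it).
#' @export
perturb_gene_tree <- function(tree, n_moves, max_tries = 50) {
  if (length(tree$tip.label) < 4) stop("tree too small for NNI (< 4 tips)")
  if (n_moves == 0) return(tree)
  for (try in seq_len(max_tries)) {
    out <- tree
    for (k in seq_len(n_moves)) out <- nni_once(out)
    if (ape::dist.topo(ape::unroot(out), ape::unroot(tree)) > 0) return(out)
  }
  stop("failed to produce a distinct topology after ", max_tries, " tries")
}

# one random rooted NNI that always changes the unrooted topology.
# For a pivot edge (p, c) with p below the root: swap a random child of c
# with c's sibling. A pivot at the root would only re-root the tree, so
# there the move exchanges a child of c with a child of c's (internal)
# sibling across the root. Node ages are re-drawn uniformly inside the new
# valid interval where a swap breaks the ordering.
nni_once <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  ages <- node_ages(tree)
  edge <- tree$edge
  is_tip <- function(nd) nd <= n
  eligible <- which(vapply(seq_len(nrow(edge)), function(i) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    if (is_tip(ch)) return(FALSE)
    if (p != root) return(TRUE)
    sib <- setdiff(edge[edge[, 1] == p, 2], ch)
    !is_tip(sib)          # cross-root exchange needs an internal sibling
  }, TRUE))
  if (!length(eligible)) stop("tree too small for NNI (< 4 tips)")
  ei <- eligible[sample.int(length(eligible), 1)]
  p <- edge[ei, 1]; cnode <- edge[ei, 2]
  kids_c <- edge[edge[, 1] == cnode, 2]
  sib <- setdiff(edge[edge[, 1] == p, 2], cnode)
  g <- kids_c[sample.int(2, 1)]
  fix_age <- function(nd) {
    lo <- max(ages[edge[edge[, 1] == nd, 2]])
    hi <- ages[edge[edge[, 2] == nd, 1]]
    if (ages[nd] <= lo || ages[nd] >= hi)
      ages[nd] <<- runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
  }
  if (p != root) {
    # swap: g moves up under p, sib moves down under c
    edge[edge[, 1] == cnode & edge[, 2] == g, 1] <- p
    edge[edge[, 1] == p & edge[, 2] == sib, 1] <- cnode
  } else {
    # exchange g with a random child of the internal sibling
    u <- edge[edge[, 1] == sib, 2][sample.int(2, 1)]
    edge[edge[, 1] == cnode & edge[, 2] == g, 1] <- sib
    edge[edge[, 1] == sib & edge[, 2] == u, 1] <- cnode
  }
  tree$edge <- edge
  fix_age(cnode)
  if (p == root) fix_age(sib)
  tree$edge.length <- ages[edge[, 1]] - ages[edge[, 2]]
  attr(tree, "order") <- NULL   # edges changed; force a true reorder
  tree <- ape::reorder.phylo(tree, "cladewise")
  timetree(tree)
}

#' Generate calibrations bracketing true node ages
#'
#' Each calibration brackets the true node age: joint bounds at
#' `(1 -/+ offset) x true`, min bounds at `frac x true` (the purple-sulfur-
#' bacteria-style minimum), max bounds at `(1 + offset) x true` (the
#' root-maximum style).
#'
#' @param true_tree the true [timetree].
#' @param nodes list of node specs, each `list(tips = c(a, b), kind =
#'   "joint"|"min"|"max", name = ...)`.
#' @param style list with `offset` (default 0.2) and `min_frac` (default
#'   0.8).
#' @return list of [calibration] objects.
#' @export
generate_calibrations <- function(true_tree, nodes,
                                  style = list(offset = 0.2, min_frac = 0.8)) {
  ages <- node_ages(true_tree)
  offset <- if (is.null(style$offset)) 0.2 else style$offset
  min_frac <- if (is.null(style$min_frac)) 0.8 else style$min_frac
  n_tip <- length(true_tree$tip.label)
  lapply(nodes, function(sp) {
    nd <- mrca_node(true_tree, sp$tips)
    if (nd <= n_tip) stop("calibration anchor resolves to a tip")
    tt <- ages[nd]
    # anchor on one tip from each child subtree so the pair's MRCA is nd
    kids <- true_tree$edge[true_tree$edge[, 1] == nd, 2]
    first_tip <- function(k) if (k <= n_tip) true_tree$tip.label[k] else
      ape::extract.clade(true_tree, k)$tip.label[1]
    anchor <- c(first_tip(kids[1]), first_tip(kids[2]))
    kind <- if (is.null(sp$kind)) "joint" else sp$kind
    nm <- if (is.null(sp$name)) paste0("node", nd) else sp$name
    if (kind == "joint") {
      cal <- calibration(nm, anchor[1], anchor[2], "joint",
                         tL = (1 - offset) * tt, tU = (1 + offset) * tt)
    } else if (kind == "min") {
      cal <- calibration(nm, anchor[1], anchor[2], "min", tL = min_frac * tt)
    } else {
      cal <- calibration(nm, anchor[1], anchor[2], "max", tU = (1 + offset) * tt)
    }
    if ((kind == "joint" && (cal$tL > tt || cal$tU < tt)) ||
        (kind == "min" && cal$tL > tt) || (kind == "max" && cal$tU < tt))
      stop("style produces empty bracket at node ", nd)
    cal
  })
}

#' Simulate a binary gene presence/absence matrix
#'
#' Focal columns are Bernoulli with presence probability shifted by group
#' membership (`p_in = (1-e) p0 + e`, `p_out = (1-e) p0`; effect e = 0 makes
#' the column independent of the groups, e = 1 makes presence equivalent to
#' membership). Background columns evolve as a symmetric two-state Markov
#' process along the tree (phylogenetic signal only); `switch_rate = 0`
#' (infinite conservation) freezes the root state.
#'
#' @param tree a [timetree] whose tips are the genomes.
#' @param assoc_spec list with `groups` (named character vector
#'   genome -> group label), `focal_groups` (labels counting as "in"),
#'   `n_focal`, `effect`, `n_background`, `switch_rate` (flips per 100 Ma),
#'   `p0` baseline prevalence.
#' @return matrix of 0/1 (genomes x gene families) with attributes `groups`
#'   and `focal` (focal column names); class `pa_matrix`.
#' @export
simulate_presence_absence <- function(tree, assoc_spec) {
  sp <- assoc_spec
  tips <- tree$tip.label
  p0 <- if (is.null(sp$p0)) 0.25 else sp$p0
  e <- sp$effect
  if (e < 0 || e > 1) stop("effect must lie in [0, 1]")
  p_in <- (1 - e) * p0 + e
  p_out <- (1 - e) * p0
  if (p_in > 1 || p_out < 0) stop("probabilities outside [0,1]")
  ingrp <- sp$groups[tips] %in% sp$focal_groups
  focal <- matrix(0L, length(tips), sp$n_focal)
  for (j in seq_len(sp$n_focal))
    focal[, j] <- rbinom(length(tips), 1, ifelse(ingrp, p_in, p_out))
  # background: two-state symmetric Markov chain along the tree
  nu <- sp$switch_rate
  n <- length(tips); root <- n + 1L
  bg <- matrix(0L, n, sp$n_background)
  edge <- tree$edge
  pflip <- 0.5 * (1 - exp(-2 * nu * tree$edge.length / 100))
  for (j in seq_len(sp$n_background)) {
    st <- integer(root + tree$Nnode - 1L)
    st[root] <- rbinom(1, 1, 0.5)
    for (i in seq_len(nrow(edge))) {
      flip <- rbinom(1, 1, pflip[i])
      st[edge[i, 2]] <- if (flip) 1L - st[edge[i, 1]] else st[edge[i, 1]]
    }
    bg[, j] <- st[seq_len(n)]
  }
  m <- cbind(focal, bg)
  rownames(m) <- tips
  colnames(m) <- c(sprintf("focal_%02d", seq_len(sp$n_focal)),
                   sprintf("bg_%03d", seq_len(sp$n_background)))
  structure(m, groups = sp$groups[tips], focal = colnames(m)[seq_len(sp$n_focal)],
            class = c("pa_matrix", "matrix", "array"))
}

#' Simulate a congruent/incongruent gene family mixture
#'
#' Congruent families evolve on the species timetree; incongruent
#' ("transferred") families evolve on an alternative timetree (NNI-perturbed
#' topology, optionally with shifted node ages) supplied by the caller or
#' generated here.
#'
#' @param species_tree the species [timetree].
#' @param cfg a [simulation_config].
#' @param alt_tree optional alternative timetree for incongruent families;
#'   default: `perturb_gene_tree(species_tree, cfg$nni_moves)` drawn once.
#' @return list with `genes` (named list of alignments), `congruent`
#'   (logical vector), `alt_tree`.
#' @export
simulate_gene_mixture <- function(species_tree, cfg, alt_tree = NULL) {
  if (is.null(alt_tree) && cfg$n_incongruent > 0)
    alt_tree <- perturb_gene_tree(species_tree, cfg$nni_moves)
  genes <- list(); congruent <- logical(0)
  for (i in seq_len(cfg$n_congruent)) {
    rates <- simulate_branch_rates(species_tree, cfg)
    genes[[sprintf("cong_%02d", i)]] <- evolve_alignment(species_tree, rates, cfg)
    congruent <- c(congruent, TRUE)
  }
  for (i in seq_len(cfg$n_incongruent)) {
    rates <- simulate_branch_rates(alt_tree, cfg)
    genes[[sprintf("inc_%02d", i)]] <- evolve_alignment(alt_tree, rates, cfg)
    congruent <- c(congruent, FALSE)
  }
  list(genes = genes, congruent = congruent, alt_tree = alt_tree)
}
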