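#' Exact phylogenetic log-likelihood (pruning algorithm)
#'
#' Felsenstein pruning over site patterns; gaps/ambiguities are marginalized
#' as fully uncertain states. The tree may be rooted-binary or carry a basal
#' trifurcation (the unrooted case under a reversible model).
#'
#' @param aln an [alignment].
#' @param tree a phylo whose tip labels are a subset of `aln$taxa`; branch
#'   lengths in expected substitutions per site unless `brlen` is given.
#' @param model a [subst_model].
#' @param brlen optional per-branch lengths, named by child node id or in
#'   `tree$edge` row order.
#' @return the log-likelihood (a scalar).
#' @export
pruning_loglik <- function(aln, tree, model, brlen = NULL) {
  bl <- branch_vector(tree, brlen)
  if (any(bl < 0, na.rm = TRUE)) stop("branch lengths must be >= 0")
  idx <- tree_index(tree, taxa = aln$taxa)
  pat <- aln_patterns(aln)
  cpp_prune_loglik(idx, bl, pat$tipstates, pat$weights,
                   model$code, model$freqs, model$kappa)
}

# branch lengths as a vector indexed by node id (entry for root unused)
branch_vector <- function(tree, brlen = NULL) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  bl <- numeric(n_nodes)
  if (is.null(brlen)) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    bl[tree$edge[, 2]] <- tree$edge.length
  } else if (!is.null(names(brlen))) {
    bl[as.integer(names(brlen))] <- brlen
  } else {
    bl[tree$edge[, 2]] <- brlen
  }
  bl
}

# loglik + gradient wrt branch lengths (by child node id)
loglik_grad <- function(aln, tree, model, brlen) {
  idx <- tree_index(tree, taxa = aln$taxa)
  pat <- aln_patterns(aln)
  res <- cpp_prune_loglik_grad(idx, branch_vector(tree, brlen), pat$tipstates,
                               pat$weights, model$code, model$freqs, model$kappa)
  edge_nodes <- tree$edge[, 2]
  list(loglik = res$loglik, gradient = res$gradient[edge_nodes],
       edge_nodes = edge_nodes)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' L-BFGS-B with the analytic gradient of the pruning likelihood.
#'
#' @inheritParams pruning_loglik
#' @param init initial branch length.
#' @param lower,upper box constraints (substitutions/site).
#' @param maxit optimizer iteration cap.
#' @return list with `brlen` (named by child node id), `loglik`,
#'   `convergence`, `clamped` (branches at the bounds).
#' @export
optimize_branch_lengths <- function(aln, tree, model, init = 0.1,
                                    lower = 1e-7, upper = 20, maxit = 200) {
  idx <- tree_index(tree, taxa = aln$taxa)
  pat <- aln_patterns(aln)
  edge_nodes <- tree$edge[, 2]
  nb <- length(edge_nodes)
  n_nodes <- idx$n_nodes
  to_full <- function(b) { bl <- numeric(n_nodes); bl[edge_nodes] <- b; bl }
  fn <- function(b) -cpp_prune_loglik(idx, to_full(b), pat$tipstates,
                                      pat$weights, model$code, model$freqs,
                                      model$kappa)
  gr <- function(b) {
    res <- cpp_prune_loglik_grad(idx, to_full(b), pat$tipstates, pat$weights,
                                 model$code, model$freqs, model$kappa)
    -res$gradient[edge_nodes]
  }
  b0 <- rep(init, nb)
  # phase 1 under a conservative upper bound: an unconstrained first line
  # search from a cold start can throw several branches at once onto the
  # saturation plateau (where the likelihood is jointly flat and coordinate
  # moves cannot escape); phase 2 releases the bound from a good start
  fit1 <- optim(b0, fn, gr, method = "L-BFGS-B", lower = lower,
                upper = min(2, upper),
                control = list(maxit = maxit, factr = 1e7))
  fit <- optim(fit1$par, fn, gr, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = maxit, factr = 1e7))
  # a line-search abort still returns a usable point; the coordinate polish
  # below finishes the job and we verify the gradient at the end
  # gradient-guided coordinate polish: quasi-Newton steps can strand long
  # branches on the saturation plateau, so re-optimize any branch whose
  # gradient says it is not at a (boundary-)optimum; the conditional
  # likelihood in a single branch length is unimodal, so golden-section
  # search is plateau-immune
  b <- fit$par
  val <- -fit$value
  for (round in 1:10) {
    g <- -gr(b)
    at_lo <- b <= lower * 1.0001; at_hi <- b >= upper * 0.9999
    stuck <- which(abs(g) > 0.1 & !(at_lo & g < 0) & !(at_hi & g > 0))
    if (!length(stuck)) break
    for (e in stuck) {
      f1 <- function(x) { bb <- b; bb[e] <- x; fn(bb) }
      o <- stats::optimize(f1, c(lower, upper), tol = 1e-6)
      if (-o$objective > val) { b[e] <- o$minimum; val <- -o$objective }
    }
  }
  clamped <- b <= lower * 1.0001 | b >= upper * 0.9999
  if (any(b >= upper * 0.9999))
    warning("some ML branch lengths hit the upper bound (uninformative data?)")
  g <- -gr(b)
  interior <- !clamped
  if (any(interior) && max(abs(g[interior])) > 1)
    stop("branch-length optimizer failed to converge: |gradient| = ",
         format(max(abs(g[interior])), digits = 3), " after polish")
  list(brlen = setNames(b, edge_nodes), loglik = val,
       convergence = fit$convergence, clamped = clamped)
}

#' Fit the approximate (quadratic) log-likelihood surface
#'
#' Finds the ML branch lengths b-hat and expands the exact log-likelihood to
#' second order around them: `l(b) ~ l0 + g'(b - bhat) + (b - bhat)' H
#' (b - bhat) / 2`. The Hessian comes from central finite differences of the
#' analytic gradient and is symmetrized. Dating with this surface is the
#' approximate-likelihood method; it is exact at b-hat by construction.
#'
#' @inheritParams pruning_loglik
#' @param h_rel relative step for the Hessian finite differences.
#' @return an object of class `approx_surface`.
#' @export
fit_approx_surface <- function(aln, tree, model, h_rel = 1e-4) {
  ml <- optimize_branch_lengths(aln, tree, model)
  edge_nodes <- as.integer(names(ml$brlen))
  nb <- length(edge_nodes)
  # shared pattern/index context so the Hessian loop does no re-compression
  idx <- tree_index(tree, taxa = aln$taxa)
  pat <- aln_patterns(aln)
  n_nodes <- idx$n_nodes
  grad_at <- function(b) {
    bl <- numeric(n_nodes); bl[edge_nodes] <- b
    cpp_prune_loglik_grad(idx, bl, pat$tipstates, pat$weights, model$code,
                          model$freqs, model$kappa)$gradient[edge_nodes]
  }
  g0 <- list(gradient = grad_at(ml$brlen))
  # forward differences of the analytic gradient, then symmetrized
  H <- matrix(0, nb, nb)
  for (e in seq_len(nb)) {
    h <- max(1e-6, h_rel * (ml$brlen[e] + 0.05))
    bp <- ml$brlen; bp[e] <- bp[e] + h
    H[, e] <- (grad_at(bp) - g0$gradient) / h
  }
  H <- (H + t(H)) / 2
  # the surface must be concave: boundary branches (bhat at a bound) can
  # leave the numerical Hessian with positive curvature directions, which
  # would make the quadratic likelihood unbounded above inside the sampler
  eh <- eigen(H, symmetric = TRUE)
  if (any(eh$values > -1e-8)) {
    vals <- pmin(eh$values, -1e-8)
    H <- eh$vectors %*% (vals * t(eh$vectors))
    H <- (H + t(H)) / 2
  }
  structure(list(tree = tree, edge_nodes = edge_nodes, bhat = unname(ml$brlen),
                 gradient = g0$gradient, hessian = H, loglik0 = ml$loglik,
                 model = model, n_sites = aln$n_sites,
                 clamped = ml$clamped),
            class = "approx_surface")
}

#' Evaluate the quadratic surface at branch lengths b
#'
#' @param surface an [fit_approx_surface()] result.
#' @param brlen branch lengths in the surface's edge order (or named by
#'   child node id).
#' @export
approx_loglik <- function(surface, brlen) {
  b <- if (!is.null(names(brlen)))
    brlen[as.character(surface$edge_nodes)] else brlen
  d <- b - surface$bhat
  as.numeric(surface$loglik0 + sum(surface$gradient * d) +
             0.5 * t(d) %*% surface$hessian %*% d)
}

#' @export
print.approx_surface <- function(x, ...) {
  cat("approximate likelihood surface:", length(x$bhat), "branches, l0 =",
      format(x$loglik0, digits = 8), "\n")
  cat("  max |gradient| at bhat:", format(max(abs(x$gradient)), digits = 3), "\n")
  invisible(x)
}
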