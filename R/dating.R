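#' Clock model specification
#'
#' Hyperpriors: the mean rate and (for relaxed clocks) the log-rate variance
#' sigma2 carry gamma priors parameterized by shape and mean. The IR model
#' draws branch rates iid lognormal with mean-preserving log-mean
#' `log m - sigma2/2`; the AR model is geometric Brownian along the tree
#' with drift `-sigma2 dt/2` (dt in 100 Ma), so the mean rate is
#' identifiable under both.
#'
#' @param kind `"strict"`, `"IR"` or `"AR"`.
#' @param mean_rate prior mean of the mean rate (subst/site/100 Ma).
#' @param mean_rate_shape gamma shape of the mean-rate prior.
#' @param sigma2_mean,sigma2_shape gamma prior on sigma2 (relaxed clocks).
#' @export
clock_model <- function(kind = c("strict", "IR", "AR"), mean_rate = 0.02,
                        mean_rate_shape = 2, sigma2_mean = 0.5,
                        sigma2_shape = 1) {
  kind <- match.arg(kind)
  if (mean_rate <= 0 || mean_rate_shape <= 0 || sigma2_mean <= 0 ||
      sigma2_shape <= 0) stop("hyperprior parameters must be > 0")
  structure(list(kind = kind, code = match(kind, c("strict", "IR", "AR")) - 1L,
                 mu_shape = mean_rate_shape,
                 mu_rate = mean_rate_shape / mean_rate,
                 s2_shape = sigma2_shape, s2_rate = sigma2_shape / sigma2_mean),
            class = "clock_model")
}

#' MCMC settings
#'
#' @param n_iter total sweeps.
#' @param burnin_frac fraction of sweeps discarded as burn-in (step sizes
#'   are auto-tuned toward 20-40% acceptance during burn-in).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param lambda,mu birth-death node-age prior rates (per lineage/100 Ma)
#'   for uncalibrated nodes.
#' @param beta power on the likelihood (1 = posterior; used by
#'   stepping-stone rungs).
#' @param tune auto-tune proposal steps during burn-in.
#' @export
chain_settings <- function(n_iter = 20000, burnin_frac = 0.25, thin = 5,
                           lambda = 1, mu = 0, beta = 1, tune = TRUE) {
  stopifnot(n_iter > 0, burnin_frac >= 0, burnin_frac < 1, thin >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 burnin = as.integer(floor(n_iter * burnin_frac)),
                 thin = as.integer(thin), lambda = lambda, mu = mu,
                 beta = beta, tune = tune),
            class = "chain_settings")
}

# build the C++ calibration block; `scale` = 100 (Ma -> internal units)
build_cal_block <- function(tree, calibrations, root_max_int) {
  n <- length(calibrations)
  node <- integer(n); kind <- integer(n)
  params <- matrix(0, n, 4)
  pL <- pU <- lognorm <- trunc_hi <- numeric(n)
  for (i in seq_len(n)) {
    cal <- calibrations[[i]]
    node[i] <- mrca_node(tree, c(cal$tip_a, cal$tip_b))
    kind[i] <- cal_kind_code(cal)
    params[i, ] <- cal_params_vec(cal, scale = 100)
    pL[i] <- cal$pL; pU[i] <- cal$pU
    if (kind[i] >= 4L) {
      trunc_hi[i] <- root_max_int
      # normalizer on the internal scale: mass is scale-invariant
      cal_scaled <- cal
      cal_scaled$density_params <- cal_params_vec(cal, scale = 100)[
        seq_along(cal$density_params)]
      lognorm[i] <- cal_lognorm(cal_scaled,
                                if (root_max_int > 0) root_max_int else 0)
    }
  }
  if (anyDuplicated(node)) stop("two calibrations resolve to the same node")
  list(node = node, kind = kind, params = params, pL = pL, pU = pU,
       lognorm = lognorm, trunc_hi = trunc_hi)
}

# upper limit (Ma) implied by the root calibration, Inf if none
root_upper_limit <- function(cal) {
  if (cal$kind %in% c("max", "joint")) return(cal$tU)
  if (cal$kind == "fitted_density") {
    f <- fitted_density_funs(cal$density_family, cal$density_params)
    # generous: far right tail of the fitted density
    for (q in c(1e4, 1e5, 1e6)) if (f$cdf(q) > 0.99999) return(q)
    return(Inf)
  }
  Inf
}

#' Run the dating MCMC
#'
#' Metropolis-within-Gibbs over node ages (random-walk proposals reflected
#' inside the (oldest child, parent) interval), branch rates and
#' hyperparameters, plus a whole-tree scale move (ages x c, rates / c).
#' The joint prior takes each calibrated node's marginal from its
#' calibration density and every uncalibrated interior node from the
#' birth-death kernel conditional on the root age; the root must carry a
#' max, joint or fitted calibration. The likelihood is exact (pruning) when
#' `data` is an alignment, the quadratic approximation when `data` is an
#' [fit_approx_surface()] result, and switched off when `data` is `NULL`
#' or `prior_only = TRUE`.
#'
#' @param data an [alignment], an `approx_surface`, or `NULL`.
#' @param tree rooted binary topology ([timetree] or phylo); node ids anchor
#'   the posterior columns.
#' @param calibrations list of [calibration] objects (>= 1; one must sit on
#'   the root).
#' @param clock a [clock_model].
#' @param settings a [chain_settings].
#' @param model a [subst_model] for exact likelihood (ignored otherwise).
#' @param prior_only force the likelihood off.
#' @param chain_id label stored with the sample.
#' @return a `chrono_posterior`: retained draws of node ages (Ma), branch
#'   rates, hyperparameters and log-densities, plus chain metadata.
#' @export
run_chain <- function(data, tree, calibrations, clock = clock_model(),
                      settings = chain_settings(), model = subst_model("JC"),
                      prior_only = FALSE, chain_id = 1L) {
  n <- length(tree$tip.label)
  root <- n + 1L
  if (length(calibrations) < 1) stop("at least one calibration required")
  cal_nodes <- vapply(calibrations, function(cal)
    mrca_node(tree, c(cal$tip_a, cal$tip_b)), 0L)
  root_i <- which(cal_nodes == root)
  if (length(root_i) != 1 ||
      !calibrations[[root_i]]$kind %in% c("max", "joint", "fitted_density"))
    stop("the root must carry a max, joint or fitted calibration")
  root_cal <- calibrations[[root_i]]
  root_max <- root_upper_limit(root_cal)
  cal_block <- build_cal_block(tree, calibrations,
                               if (is.finite(root_max)) root_max / 100 else 0)

  if (prior_only) data <- NULL
  lik <- if (is.null(data)) {
    list(mode = 0L, beta = settings$beta)
  } else if (inherits(data, "approx_surface")) {
    if (!setequal(data$tree$tip.label, tree$tip.label))
      stop("surface and tree disagree on taxa")
    list(mode = 1L, beta = settings$beta, ell0 = data$loglik0,
         bhat = data$bhat, gradient = data$gradient, hessian = data$hessian,
         edge_nodes = data$edge_nodes)
  } else if (inherits(data, "chrono_alignment")) {
    pat <- aln_patterns(subset_alignment(data, data$taxa))
    list(mode = 2L, beta = settings$beta, tipstates = pat$tipstates,
         weights = pat$weights, freqs = model$freqs, model_code = model$code,
         kappa = model$kappa)
  } else stop("data must be an alignment, an approx_surface, or NULL")
  idx <- tree_index(tree, taxa = if (inherits(data, "chrono_alignment"))
    data$taxa else NULL)

  # starting state: root inside its calibration, descendants nested below
  init_ages <- function() {
    ages <- numeric(idx$n_nodes)
    r0 <- if (root_cal$kind == "joint")
      runif(1, root_cal$tL, root_cal$tU)
    else if (root_cal$kind == "max") runif(1, 0.4, 0.9) * root_cal$tU
    else median(r_calibration(64, root_cal))
    ages[root] <- r0 / 100
    assign_down <- function(nd) {
      for (ch in idx$children[[nd]]) {
        if (length(idx$children[[ch]]) == 0) next
        ages[ch] <<- ages[nd] * runif(1, 0.55, 0.92)
        assign_down(ch)
      }
    }
    assign_down(root)
    ages
  }
  start_ok <- function(ages) {
    for (i in seq_along(cal_block$node)) {
      ld <- cpp_cal_logdens(cal_block$kind[i], cal_block$params[i, ],
                            cal_block$pL[i], cal_block$pU[i],
                            cal_block$lognorm[i], cal_block$trunc_hi[i],
                            ages[cal_block$node[i]])
      if (!is.finite(ld)) return(FALSE)
    }
    TRUE
  }
  ages0 <- NULL
  for (try in 1:200) {
    a <- init_ages()
    if (start_ok(a)) { ages0 <- a; break }
  }
  if (is.null(ages0))
    stop("no valid starting state found within calibration bounds")

  mu0 <- clock$mu_shape / clock$mu_rate
  s20 <- clock$s2_shape / clock$s2_rate
  nb <- idx$n_nodes - 1L
  res <- cpp_mcmc(idx, lik, cal_block,
                  list(lambda = settings$lambda, mu = settings$mu),
                  list(kind = clock$code, mu_shape = clock$mu_shape,
                       mu_rate = clock$mu_rate, s2_shape = clock$s2_shape,
                       s2_rate = clock$s2_rate),
                  list(n_iter = settings$n_iter, burnin = settings$burnin,
                       thin = settings$thin, tune = settings$tune),
                  list(ages = ages0, mu_r = mu0, s2 = s20,
                       rates = rep(mu0, nb)))
  ages <- res$ages * 100
  colnames(ages) <- paste0("n", res$internal_nodes)
  rates <- res$rates
  if (ncol(rates)) colnames(rates) <- paste0("b", res$edge_nodes)
  structure(list(ages = ages, rates = rates, mu_r = res$mu_r, s2 = res$s2,
                 loglik = res$loglik, logprior = res$logprior,
                 tree = tree, clock = clock, settings = settings,
                 calibrations = calibrations, accept = res$accept,
                 prior_only = is.null(data) || lik$mode == 0L,
                 chain_id = chain_id),
            class = "chrono_posterior")
}

#' @export
print.chrono_posterior <- function(x, ...) {
  cat("posterior sample:", nrow(x$ages), "retained draws,",
      ncol(x$ages), "internal nodes",
      if (x$prior_only) "(prior-only)" else "", "\n")
  cat("  acceptance: ages", round(x$accept[["ages"]], 2),
      "| scale", round(x$accept[["scale"]], 2), "\n")
  invisible(x)
}

#' Shortest (highest-density) posterior interval
#'
#' @param x numeric sample.
#' @param prob interval mass.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(xs[1], xs[n]))
  widths <- xs[m:n] - xs[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(xs[i], xs[i + m - 1])
}

# integrated-autocorrelation ESS (Geyer initial positive sequence)
ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  lag_max <- min(n - 1, 500)
  rho <- acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  tau <- 1; k <- 1
  while (k + 1 <= length(rho)) {
    g <- rho[k] + rho[k + 1]
    if (g <= 0) break
    tau <- tau + 2 * g
    k <- k + 2
  }
  n / tau
}

#' Summarize posterior node ages
#'
#' Mean and 95% highest-posterior-density interval per node; the HPD is the
#' shortest interval containing the target mass.
#'
#' @param posterior a `chrono_posterior`.
#' @param nodes internal node ids to include (default all sampled).
#' @param prob HPD mass.
#' @return data.frame with node, mean, hpd_lo, hpd_hi, ess.
#' @export
summarize_posterior <- function(posterior, nodes = NULL, prob = 0.95) {
  if (nrow(posterior$ages) < 100) stop("too few draws for an HPD summary")
  cols <- if (is.null(nodes)) colnames(posterior$ages) else paste0("n", nodes)
  miss <- setdiff(cols, colnames(posterior$ages))
  if (length(miss)) stop("nodes not sampled: ", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(cols, function(cn) {
    x <- posterior$ages[, cn]
    h <- hpd_interval(x, prob)
    data.frame(node = as.integer(sub("^n", "", cn)), mean = mean(x),
               hpd_lo = h[1], hpd_hi = h[2], ess = ess(x))
  }))
  rownames(out) <- NULL
  out
}

#' Compare two independent chains
#'
#' Per-node posterior-mean scatter (correlation and regression slope),
#' maximum absolute mean difference, and per-node effective sample sizes.
#' The comparison passes when correlation > 0.99 and the largest mean
#' difference is below `tol_ma`; chains whose minimum ESS falls below
#' `ess_floor` are flagged with an "insufficient ESS" warning.
#'
#' @param chain1,chain2 `chrono_posterior` objects from identical
#'   model/settings, different seeds.
#' @param tol_ma tolerance on node-age means (Ma); default 2% of the mean
#'   root age.
#' @param ess_floor minimum acceptable ESS per node.
#' @export
check_convergence <- function(chain1, chain2, tol_ma = NULL, ess_floor = 100) {
  if (!identical(colnames(chain1$ages), colnames(chain2$ages)) ||
      !identical(chain1$tree$tip.label, chain2$tree$tip.label) ||
      ape::dist.topo(ape::unroot(chain1$tree), ape::unroot(chain2$tree)) > 0)
    stop("chains come from different topologies")
  m1 <- colMeans(chain1$ages); m2 <- colMeans(chain2$ages)
  if (is.null(tol_ma)) {
    root_col <- paste0("n", length(chain1$tree$tip.label) + 1L)
    tol_ma <- 0.02 * mean(c(m1[root_col], m2[root_col]))
  }
  r <- if (sd(m1) == 0 || sd(m2) == 0) 1 else cor(m1, m2)
  slope <- if (sd(m1) == 0) 1 else sum((m1 - mean(m1)) * (m2 - mean(m2))) /
    sum((m1 - mean(m1))^2)
  ess1 <- apply(chain1$ages, 2, ess); ess2 <- apply(chain2$ages, 2, ess)
  max_diff <- max(abs(m1 - m2))
  warn <- character(0)
  if (min(ess1, ess2) < ess_floor) {
    warn <- c(warn, "insufficient ESS")
    warning("insufficient ESS: minimum ", round(min(ess1, ess2), 1),
            " below floor ", ess_floor)
  }
  structure(list(correlation = r, slope = slope, max_mean_diff = max_diff,
                 tol_ma = tol_ma, ess1 = ess1, ess2 = ess2,
                 pass = (r > 0.99) && (max_diff < tol_ma),
                 warnings = warn),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("convergence:", if (x$pass) "PASS" else "FAIL",
      "| cor =", format(x$correlation, digits = 4),
      "| slope =", format(x$slope, digits = 4),
      "| max mean diff =", format(x$max_mean_diff, digits = 4), "Ma",
      "(tol", format(x$tol_ma, digits = 4), "Ma)\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Draw node ages from the dating prior (rejection sampling)
#'
#' Samples the exact joint time prior the sampler targets: the root age from
#' its calibration density, the remaining interior node ages iid from the
#' birth-death kernel, accepted only when every parent is older than its
#' children. Used by simulation-based calibration checks.
#'
#' @param tree rooted binary topology.
#' @param root_cal the root [calibration].
#' @param lambda,mu birth-death kernel rates (per 100 Ma).
#' @param max_tries rejection cap.
#' @return ages vector (Ma) indexed by node id (tips 0).
#' @export
sample_time_prior <- function(tree, root_cal, lambda, mu, max_tries = 20000) {
  idx <- tree_index(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  internal <- setdiff(which(lengths(idx$children) > 0), root)
  for (i in seq_len(max_tries)) {
    ages <- numeric(idx$n_nodes)
    ages[root] <- r_calibration(1, root_cal)
    ages[internal] <- r_bd_kernel(length(internal), lambda, mu, ages[root])
    ok <- all(ages[tree$edge[, 1]] > ages[tree$edge[, 2]])
    if (ok) return(ages)
  }
  stop("rejection sampling failed; tree too constrained")
}
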