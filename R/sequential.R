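#' Fit a parametric density to posterior node ages
#'
#' Candidate families — lognormal, gamma, skew-normal and zero-truncated
#' normal — are each fitted by maximum likelihood; the winner is the family
#' with the smallest Kolmogorov-Smirnov distance to the empirical sample
#' (AIC is reported as a diagnostic). These four cover right-skewed,
#' symmetric and bounded posterior shapes.
#'
#' @param samples posterior age draws (Ma), >= 500 of them.
#' @param families candidate family names.
#' @param min_draws minimum sample size.
#' @return class `fitted_density`: `family`, `params`, `ks`, `aic`, and a
#'   per-family diagnostic table `candidates`.
#' @export
fit_posterior_density <- function(samples,
                                  families = c("lognormal", "gamma",
                                               "skew_normal", "truncated_normal"),
                                  min_draws = 500) {
  if (length(samples) < min_draws)
    stop("need >= ", min_draws, " draws to fit a density")
  if (sd(samples) == 0) stop("degenerate (zero-variance) sample")
  if (any(samples <= 0)) stop("ages must be positive")
  fits <- lapply(families, function(fam)
    tryCatch(fit_family_ml(fam, samples), error = function(e) NULL))
  names(fits) <- families
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no candidate family could be fitted")
  ks <- vapply(fits, function(f) ks_statistic(samples, f$cdf), 0)
  aic <- vapply(fits, function(f) 2 * f$k - 2 * f$loglik, 0)
  best <- names(fits)[which.min(ks)]
  structure(list(family = best, params = fits[[best]]$params,
                 ks = unname(ks[best]), aic = unname(aic[best]),
                 candidates = data.frame(family = names(fits), ks = unname(ks),
                                         aic = unname(aic),
                                         row.names = NULL)),
            class = "fitted_density")
}

# exact KS distance between an ecdf and a fitted cdf
ks_statistic <- function(x, cdf) {
  xs <- sort(x); n <- length(xs)
  Fx <- cdf(xs)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

fit_family_ml <- function(family, x) {
  n <- length(x)
  if (family == "lognormal") {
    lx <- log(x)
    par <- c(mean(lx), sqrt(mean((lx - mean(lx))^2)))
    ll <- sum(dlnorm(x, par[1], par[2], log = TRUE))
    return(list(params = par, loglik = ll, k = 2,
                cdf = function(q) plnorm(q, par[1], par[2])))
  }
  if (family == "gamma") {
    m <- mean(x); v <- var(x)
    init <- log(c(m^2 / v, m / v))
    fit <- optim(init, function(p)
      -sum(dgamma(x, shape = exp(p[1]), rate = exp(p[2]), log = TRUE)),
      method = "BFGS")
    par <- exp(fit$par)
    return(list(params = par, loglik = -fit$value, k = 2,
                cdf = function(q) pgamma(q, shape = par[1], rate = par[2])))
  }
  if (family == "skew_normal") {
    init <- c(mean(x), sd(x), 1)
    nll <- function(p) {
      if (p[2] <= 0) return(1e10)
      z <- (x - p[1]) / p[2]
      -sum(log(2) + dnorm(z, log = TRUE) - log(p[2]) +
             pnorm(p[3] * z, log.p = TRUE))
    }
    fit <- optim(init, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000))
    par <- fit$par
    f <- fitted_density_funs("skew_normal", par)
    return(list(params = par, loglik = -fit$value, k = 3, cdf = f$cdf))
  }
  if (family == "truncated_normal") {
    init <- c(mean(x), sd(x))
    nll <- function(p) {
      if (p[2] <= 0) return(1e10)
      -sum(dnorm(x, p[1], p[2], log = TRUE) -
             pnorm(0, p[1], p[2], lower.tail = FALSE, log.p = TRUE))
    }
    fit <- optim(init, nll, method = "Nelder-Mead")
    par <- fit$par
    f <- fitted_density_funs("truncated_normal", par)
    return(list(params = par, loglik = -fit$value, k = 2, cdf = f$cdf))
  }
  stop("unknown family: ", family)
}

#' @export
print.fitted_density <- function(x, ...) {
  cat("fitted density:", x$family, "(",
      paste(format(x$params, digits = 4), collapse = ", "),
      ") KS =", format(x$ks, digits = 3), "\n")
  invisible(x)
}

#' Propagate first-step posteriors as second-step calibrations
#'
#' For each shared node, fits a parametric density to the step-1 posterior
#' ages of that node and emits a `fitted_density` calibration anchored by
#' tip labels valid in the step-2 tree. An empty map yields an empty list.
#'
#' @param step1_posterior `chrono_posterior` from the first dating step.
#' @param shared_nodes data.frame with columns `step1_tip_a, step1_tip_b,
#'   step2_tip_a, step2_tip_b` (optionally `name`).
#' @param step2_tree the step-2 topology (to validate anchors).
#' @return list of [calibration] objects (kind `fitted_density`) with the
#'   fit objects attached as attribute `fits`.
#' @export
propagate_calibrations <- function(step1_posterior, shared_nodes,
                                   step2_tree = NULL) {
  if (is.null(shared_nodes) || nrow(shared_nodes) == 0) return(list())
  cals <- list(); fits <- list()
  for (i in seq_len(nrow(shared_nodes))) {
    r <- shared_nodes[i, ]
    nd <- mrca_node(step1_posterior$tree, c(r$step1_tip_a, r$step1_tip_b))
    col <- paste0("n", nd)
    if (!col %in% colnames(step1_posterior$ages))
      stop("shared node ", nd, " not sampled in step 1")
    if (!is.null(step2_tree)) {
      miss <- setdiff(c(r$step2_tip_a, r$step2_tip_b), step2_tree$tip.label)
      if (length(miss))
        stop("shared node unresolvable in step-2 tree: missing tips ",
             paste(miss, collapse = ", "))
    }
    fit <- fit_posterior_density(step1_posterior$ages[, col])
    nm <- if (!is.null(r$name) && !is.na(r$name)) r$name else paste0("prop_", col)
    cals[[i]] <- calibration(nm, r$step2_tip_a, r$step2_tip_b,
                             kind = "fitted_density",
                             density_family = fit$family,
                             density_params = fit$params)
    fits[[i]] <- fit
  }
  attr(cals, "fits") <- fits
  cals
}

#' Two-step sequential dating
#'
#' Step 1 is dated with its own (fossil) calibrations; parametric densities
#' are fitted to the step-1 posterior ages of the shared nodes and imposed,
#' together with the step-2 fossils, as independent marginal priors in the
#' second dating step. Fitted densities are truncated at the step-2 root
#' maximum inside the sampler. Correlations between step-1 nodes are
#' deliberately discarded — the method's stated simplification.
#'
#' @param step1,step2 lists with elements `data` (alignment, surface or
#'   NULL), `tree`, `calibrations`, and optionally `model`.
#' @param shared_map data.frame mapping step-1 anchor tips to step-2 anchor
#'   tips (see [propagate_calibrations()]).
#' @param clock a [clock_model] used for both steps.
#' @param settings a [chain_settings] used for both steps.
#' @return list with `step1_posterior`, `fitted` (per-node fit table),
#'   `propagated` (calibration list), `step2_posterior`, `provenance`.
#' @export
run_sequential <- function(step1, step2, shared_map, clock = clock_model(),
                           settings = chain_settings()) {
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(label, ": ", conditionMessage(e), call. = FALSE))
  }
  post1 <- stage("step1", run_chain(step1$data, step1$tree, step1$calibrations,
                                    clock = clock, settings = settings,
                                    model = step1$model %||% subst_model("JC")))
  prop <- stage("propagate", propagate_calibrations(post1, shared_map,
                                                    step2_tree = step2$tree))
  fits <- attr(prop, "fits")
  fitted_tab <- if (length(prop)) do.call(rbind, lapply(seq_along(prop),
    function(i) data.frame(node = prop[[i]]$clade_name,
                           family = fits[[i]]$family,
                           params = paste(format(fits[[i]]$params, digits = 6),
                                          collapse = ","),
                           ks = fits[[i]]$ks))) else
    data.frame(node = character(0), family = character(0),
               params = character(0), ks = numeric(0))
  post2 <- stage("step2", run_chain(step2$data, step2$tree,
                                    c(step2$calibrations, prop),
                                    clock = clock, settings = settings,
                                    model = step2$model %||% subst_model("JC")))
  list(step1_posterior = post1, fitted = fitted_tab, propagated = prop,
       step2_posterior = post2,
       provenance = list(n_shared = length(prop),
                         step1_cals = length(step1$calibrations),
                         step2_cals = length(step2$calibrations),
                         settings = settings, clock = clock))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
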