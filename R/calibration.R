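#' Node-age calibrations
#'
#' A calibration constrains the age of the MRCA of two named tips. Bounds
#' are soft: a `joint` calibration is uniform on `[tL, tU]` with power-decay
#' tails carrying masses `pL` and `pU`; a `min` calibration places mass `pL`
#' below `tL` as a power ramp and a heavy (Pareto) tail above; a `max`
#' calibration is uniform on `(0, tU)` with a power-decay tail above.
#' `fitted_density` calibrations carry a parametric density (lognormal,
#' gamma, skew-normal or zero-truncated normal), typically fitted to a
#' first-step posterior by [fit_posterior_density()]. All kinds are proper
#' densities on (0, Inf).
#'
#' @param clade_name label for the calibrated node.
#' @param tip_a,tip_b anchoring tip labels (their MRCA is calibrated).
#' @param kind one of `"min"`, `"max"`, `"joint"`, `"fitted_density"`.
#' @param tL,tU lower / upper bounds in Ma (as required by `kind`).
#' @param pL,pU soft-tail probabilities in (0, 0.5); default 0.025 each.
#' @param density_family,density_params family name and parameter vector for
#'   `kind = "fitted_density"`; parameters are on the Ma scale (`lognormal`:
#'   meanlog, sdlog; `gamma`: shape, rate; `skew_normal`: xi, omega, alpha;
#'   `truncated_normal`: mean, sd).
#' @param min_tail_shape Pareto shape of the heavy upper tail of a `min`
#'   bound.
#' @export
calibration <- function(clade_name, tip_a, tip_b,
                        kind = c("min", "max", "joint", "fitted_density"),
                        tL = NA_real_, tU = NA_real_, pL = 0.025, pU = 0.025,
                        density_family = NA_character_, density_params = NULL,
                        min_tail_shape = 2) {
  kind <- match.arg(kind)
  if (!is.na(tL) && !is.na(tU) && tL >= tU) stop("tL < tU required")
  if (pL <= 0 || pL >= 0.5 || pU <= 0 || pU >= 0.5)
    stop("tail probabilities must lie in (0, 0.5)")
  if (kind == "min" && is.na(tL)) stop("min calibration needs tL")
  if (kind == "max" && is.na(tU)) stop("max calibration needs tU")
  if (kind == "joint" && (is.na(tL) || is.na(tU)))
    stop("joint calibration needs tL and tU")
  if (kind == "fitted_density") {
    if (!density_family %in% c("lognormal", "gamma", "skew_normal", "truncated_normal"))
      stop("unknown density family: ", density_family)
    if (length(density_params) < 2) stop("density_params required")
  }
  structure(list(clade_name = clade_name, tip_a = tip_a, tip_b = tip_b,
                 kind = kind, tL = tL, tU = tU, pL = pL, pU = pU,
                 density_family = density_family,
                 density_params = as.numeric(density_params),
                 min_tail_shape = min_tail_shape),
            class = "calibration")
}

# integer codes shared with the C++ kernel
cal_kind_code <- function(cal) {
  if (cal$kind == "min") return(1L)
  if (cal$kind == "max") return(2L)
  if (cal$kind == "joint") return(3L)
  switch(cal$density_family, lognormal = 4L, gamma = 5L,
         skew_normal = 6L, truncated_normal = 7L)
}

# parameter vector (length 4) on an arbitrary time scale; `scale` divides
# time-dimension parameters (for the internal 100-Ma units)
cal_params_vec <- function(cal, scale = 1) {
  code <- cal_kind_code(cal)
  p <- numeric(4)
  if (code == 1L) p[1:2] <- c(cal$tL / scale, cal$min_tail_shape)
  else if (code == 2L) p[1] <- cal$tU / scale
  else if (code == 3L) p[1:2] <- c(cal$tL, cal$tU) / scale
  else if (code == 4L) p[1:2] <- c(cal$density_params[1] - log(scale), cal$density_params[2])
  else if (code == 5L) p[1:2] <- c(cal$density_params[1], cal$density_params[2] * scale)
  else p[1:3] <- c(cal$density_params[1:2] / scale,
                   if (length(cal$density_params) >= 3) cal$density_params[3] else 0)
  p
}

# log of the density mass inside (0, trunc_hi) for fitted kinds (0 outside
# truncation is handled in the kernel); trunc_hi <= 0 means no upper cut
cal_lognorm <- function(cal, trunc_hi = 0) {
  if (cal_kind_code(cal) < 4L) return(0)
  f <- fitted_density_funs(cal$density_family, cal$density_params)
  hi <- if (trunc_hi > 0) trunc_hi else Inf
  log(f$cdf(hi) - f$cdf(0))
}

#' Calibration log-density
#'
#' Evaluates the calibration's prior density over node age (a proper density
#' on (0, Inf); see [calibration] for the soft-bound shapes).
#'
#' @param cal a [calibration].
#' @param age node age(s) in Ma.
#' @param trunc_hi optional upper truncation (Ma) applied to fitted
#'   densities (a fitted density must not place mass above the root
#'   maximum); 0 disables.
#' @return log-density values (per Ma).
#' @export
calibration_log_density <- function(cal, age, trunc_hi = 0) {
  if (any(age <= 0)) stop("age must be positive")
  cpp_cal_logdens(cal_kind_code(cal), cal_params_vec(cal), cal$pL, cal$pU,
                  cal_lognorm(cal, trunc_hi), trunc_hi, age)
}

#' Calibration CDF
#'
#' Closed-form piecewise CDF for bound calibrations; numerical for
#' skew-normal fitted densities. Used by prior-recovery checks.
#'
#' @inheritParams calibration_log_density
#' @export
calibration_cdf <- function(cal, age, trunc_hi = 0) {
  code <- cal_kind_code(cal)
  if (code == 1L) {
    tL <- cal$tL; pL <- cal$pL; beta <- cal$min_tail_shape
    thetaL <- beta * (1 - pL) / pL
    ifelse(age < tL, pL * (age / tL)^thetaL,
           pL + (1 - pL) * (1 - (tL / age)^beta))
  } else if (code == 2L) {
    tU <- cal$tU; pU <- cal$pU
    h <- (1 - pU) / tU
    alpha <- 1 + h * tU / pU
    ifelse(age < tU, h * age, 1 - pU * (tU / age)^(alpha - 1))
  } else if (code == 3L) {
    tL <- cal$tL; tU <- cal$tU; pL <- cal$pL; pU <- cal$pU
    h <- (1 - pL - pU) / (tU - tL)
    thetaL <- h * tL / pL
    alpha <- 1 + h * tU / pU
    ifelse(age < tL, pL * (age / tL)^thetaL,
           ifelse(age <= tU, pL + h * (age - tL),
                  1 - pU * (tU / age)^(alpha - 1)))
  } else {
    f <- fitted_density_funs(cal$density_family, cal$density_params)
    hi <- if (trunc_hi > 0) trunc_hi else Inf
    lo_mass <- f$cdf(0)
    mass <- f$cdf(hi) - lo_mass
    pmin(1, pmax(0, (f$cdf(pmin(age, hi)) - lo_mass) / mass))
  }
}

#' Sample node ages from a calibration density
#'
#' Inverse-CDF sampling for bound calibrations, direct or rejection sampling
#' for fitted densities; used to build prior-predictive draws.
#'
#' @param n number of draws.
#' @inheritParams calibration_log_density
#' @export
r_calibration <- function(n, cal, trunc_hi = 0) {
  code <- cal_kind_code(cal)
  u <- runif(n)
  if (code == 1L) {
    tL <- cal$tL; pL <- cal$pL; beta <- cal$min_tail_shape
    thetaL <- beta * (1 - pL) / pL
    ifelse(u < pL, tL * (u / pL)^(1 / thetaL),
           tL * (1 - (u - pL) / (1 - pL))^(-1 / beta))
  } else if (code == 2L) {
    tU <- cal$tU; pU <- cal$pU
    h <- (1 - pU) / tU
    alpha <- 1 + h * tU / pU
    ifelse(u < 1 - pU, u / h, tU * ((1 - u) / pU)^(-1 / (alpha - 1)))
  } else if (code == 3L) {
    tL <- cal$tL; tU <- cal$tU; pL <- cal$pL; pU <- cal$pU
    h <- (1 - pL - pU) / (tU - tL)
    thetaL <- h * tL / pL
    alpha <- 1 + h * tU / pU
    ifelse(u < pL, tL * (u / pL)^(1 / thetaL),
           ifelse(u < 1 - pU, tL + (u - pL) / h,
                  tU * ((1 - u) / pU)^(-1 / (alpha - 1))))
  } else {
    f <- fitted_density_funs(cal$density_family, cal$density_params)
    hi <- if (trunc_hi > 0) trunc_hi else Inf
    out <- numeric(0)
    for (it in 1:1000) {
      x <- f$rand(2 * n)
      x <- x[x > 0 & x < hi]
      out <- c(out, x)
      if (length(out) >= n) break
    }
    if (length(out) < n) stop("rejection sampling failed for fitted density")
    out[seq_len(n)]
  }
}

# density/cdf/sampler bundles for the fitted families (Ma scale)
fitted_density_funs <- function(family, par) {
  switch(family,
    lognormal = list(
      logpdf = function(x) dlnorm(x, par[1], par[2], log = TRUE),
      cdf = function(x) plnorm(x, par[1], par[2]),
      rand = function(n) rlnorm(n, par[1], par[2])),
    gamma = list(
      logpdf = function(x) dgamma(x, shape = par[1], rate = par[2], log = TRUE),
      cdf = function(x) pgamma(x, shape = par[1], rate = par[2]),
      rand = function(n) rgamma(n, shape = par[1], rate = par[2])),
    skew_normal = list(
      logpdf = function(x) {
        z <- (x - par[1]) / par[2]
        log(2) + dnorm(z, log = TRUE) - log(par[2]) + pnorm(par[3] * z, log.p = TRUE)
      },
      cdf = local({
        p1 <- par
        # F(x) = Phi(z) - 2 T(z, alpha) with Owen's T as a finite integral
        owen_t <- function(h, a) {
          if (a == 0) return(0)
          s <- sign(a); a <- abs(a)
          if (a > 35) return(s * 0.5 * pnorm(-abs(h)))   # T(h, Inf) limit
          s * integrate(function(x) exp(-h^2 * (1 + x^2) / 2) / (1 + x^2),
                        0, a, rel.tol = 1e-10)$value / (2 * pi)
        }
        function(x) {
          vapply(x, function(xx) {
            if (!is.finite(xx)) return(if (xx > 0) 1 else 0)
            z <- (xx - p1[1]) / p1[2]
            min(1, max(0, pnorm(z) - 2 * owen_t(z, p1[3])))
          }, 0)
        }
      }),
      rand = function(n) {
        delta <- par[3] / sqrt(1 + par[3]^2)
        u0 <- rnorm(n); u1 <- rnorm(n)
        par[1] + par[2] * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
      }),
    truncated_normal = list(
      logpdf = function(x) ifelse(x > 0, dnorm(x, par[1], par[2], log = TRUE) -
                                    pnorm(0, par[1], par[2], lower.tail = FALSE, log.p = TRUE), -Inf),
      cdf = function(x) {
        lo <- pnorm(0, par[1], par[2])
        pmax(0, (pnorm(x, par[1], par[2]) - lo) / (1 - lo))
      },
      rand = function(n) {
        x <- rnorm(3 * n, par[1], par[2]); x <- x[x > 0]
        while (length(x) < n) x <- c(x, abs(rnorm(n, par[1], par[2])))
        x[seq_len(n)]
      }),
    stop("unknown density family: ", family))
}

#' Read a calibration table
#'
#' Tab-separated with columns `clade_name, tip_a, tip_b, kind, tL, tU, pL,
#' pU, density_family, density_params` (params comma-separated; empty cells
#' allowed where a column does not apply).
#'
#' @param path TSV file path.
#' @return a list of [calibration] objects.
#' @export
read_calibrations <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#")
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pars <- if (!is.null(r$density_params) && nzchar(as.character(r$density_params)) &&
                !is.na(r$density_params))
      as.numeric(strsplit(as.character(r$density_params), ",")[[1]]) else NULL
    calibration(r$clade_name, r$tip_a, r$tip_b, kind = r$kind,
                tL = if (is.na(r$tL)) NA_real_ else as.numeric(r$tL),
                tU = if (is.na(r$tU)) NA_real_ else as.numeric(r$tU),
                pL = if (is.null(r$pL) || is.na(r$pL)) 0.025 else r$pL,
                pU = if (is.null(r$pU) || is.na(r$pU)) 0.025 else r$pU,
                density_family = if (is.null(r$density_family) || is.na(r$density_family))
                  NA_character_ else r$density_family,
                density_params = pars)
  })
}

#' Write a calibration table
#'
#' @param cals list of [calibration] objects.
#' @param path output TSV path.
#' @export
write_calibrations <- function(cals, path) {
  df <- do.call(rbind, lapply(cals, function(cal) {
    data.frame(clade_name = cal$clade_name, tip_a = cal$tip_a, tip_b = cal$tip_b,
               kind = cal$kind, tL = cal$tL, tU = cal$tU, pL = cal$pL, pU = cal$pU,
               density_family = cal$density_family,
               density_params = paste(cal$density_params, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
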