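# Fluorescence correlation spectroscopy: 2D single-species diffusion model
# with multiplicative exponential relaxations, curve fitting, and
# hydrodynamic molecular-weight inference against a dye reference.

#' Construct an FCS correlation curve
#'
#' @param lags lag times in seconds, positive and strictly increasing
#'   (log-spaced is typical).
#' @param G dimensionless correlation amplitudes, same length.
#' @param duration_s optional accumulation time metadata.
#' @param concentration optional sample concentration metadata.
#' @return object of class `fcs_curve`.
#' @export
fcs_curve <- function(lags, G, duration_s = NA_real_,
                      concentration = NA_real_) {
  lags <- as.numeric(lags); G <- as.numeric(G)
  if (length(lags) != length(G)) stop("lags and G must have the same length")
  if (any(lags <= 0)) stop("lag times must be positive")
  if (any(diff(lags) <= 0)) stop("lag times must be strictly increasing")
  structure(list(lags = lags, G = G, duration_s = duration_s,
                 concentration = concentration),
            class = "fcs_curve")
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("<fcs_curve> %d lags, %.3g-%.3g s, G(min lag) = %.4g\n",
              length(x$lags), min(x$lags), max(x$lags), x$G[1]))
  invisible(x)
}

#' FCS autocorrelation model: 2D diffusion with exponential relaxations
#'
#' Single-species two-dimensional diffusion with a multiplicative
#' fast-relaxation factor:
#' \deqn{G(\tau) = \frac{1}{N}\left(1+\frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1 + \sum_i a_i e^{-\tau/\tau_i}\right)}
#' where `N` is the mean number of molecules in the confocal volume and
#' \eqn{\tau_D} the translational diffusion time. This is the single place
#' the correlation-model convention lives; an additive-relaxation variant
#' can be swapped here without touching the fitting code.
#'
#' @param lag lag time(s) in seconds, >= 0.
#' @param N mean molecules in the confocal volume (> 0).
#' @param tau_d translational diffusion time, seconds (> 0).
#' @param relax_a amplitudes \eqn{a_i} of the relaxation components (may be
#'   empty for pure diffusion).
#' @param relax_tau time constants \eqn{\tau_i} (seconds) of the relaxation
#'   components, typically \eqn{\tau_i < \tau_D}.
#' @return G at `lag`.
#' @examples
#' fcs_model(0, N = 2, tau_d = 1e-4)        # 1/N
#' fcs_model(1e-4, N = 2, tau_d = 1e-4)     # 1/(2N)
#' @export
fcs_model <- function(lag, N, tau_d, relax_a = numeric(0),
                      relax_tau = numeric(0)) {
  stopifnot(N > 0, tau_d > 0, length(relax_a) == length(relax_tau),
            all(relax_tau > 0), all(lag >= 0))
  relax <- rep(1, length(lag))
  for (i in seq_along(relax_a))
    relax <- relax + relax_a[i] * exp(-lag / relax_tau[i])
  (1 / N) / (1 + lag / tau_d) * relax
}

# Linear solve for c = (1/N, a_i/N) given diffusion and relaxation taus:
# G = (1 + lag/tau_d)^-1 (c0 + sum_i c_i exp(-lag/tau_i)).
.fcs_lls <- function(lags, G, tau_d, relax_tau, w) {
  D <- 1 / (1 + lags / tau_d)
  X <- cbind(D, vapply(relax_tau, function(tt) D * exp(-lags / tt),
                       numeric(length(lags))))
  fit <- tryCatch(stats::lm.fit(X * sqrt(w), G * sqrt(w)),
                  error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  list(coef = fit$coefficients, ssr = sum(fit$residuals^2))
}

#' Fit the FCS model to a correlation curve
#'
#' Deterministic multi-start weighted least squares. Starts scan a
#' log-spaced diffusion-time grid over the lag range combined with
#' relaxation-time candidates below each diffusion time (amplitudes by
#' linear least squares given the time scales); the best starts are refined
#' by Levenberg--Marquardt with `N` and all time scales parameterized on the
#' log scale. Relaxation times are reported sorted ascending; a fit is
#' flagged when a relaxation time does not resolve below the diffusion time
#' or an amplitude is indistinguishable from zero.
#'
#' @param curve an [fcs_curve()].
#' @param n_relaxations number of exponential relaxation components, 0--3.
#' @param weights `"uniform"` (default) or `"1/G"` (weight 1/G^2, i.e.
#'   relative residuals).
#' @param n_grid diffusion-time grid size.
#' @param n_refine number of best starts to polish.
#' @return object of class `fcs_fit`: `N`, `tau_d`, `relax_a`, `relax_tau`,
#'   `se` (same names), `fitted`, `residuals`, `ssr`, `degenerate`,
#'   `at_bound`, `converged`.
#' @export
fit_fcs <- function(curve, n_relaxations = 2,
                    weights = c("uniform", "1/G"),
                    n_grid = 12, n_refine = 5) {
  stopifnot(inherits(curve, "fcs_curve"),
            n_relaxations >= 0, n_relaxations <= 3)
  weights <- match.arg(weights)
  lags <- curve$lags; G <- curve$G
  w <- if (weights == "1/G") 1 / pmax(G, 1e-12)^2 else rep(1, length(G))
  nr <- n_relaxations

  tau_grid <- exp(seq(log(min(lags)), log(max(lags)), length.out = n_grid))
  sub <- exp(seq(log(min(lags)), log(max(lags)), length.out = 7))

  cand <- list()
  for (td in tau_grid) {
    below <- sub[sub < td]
    if (nr == 0) {
      cand[[length(cand) + 1L]] <- list(tau_d = td, relax = numeric(0))
    } else if (length(below) >= nr) {
      cc <- utils::combn(length(below), nr)
      for (j in seq_len(ncol(cc)))
        cand[[length(cand) + 1L]] <- list(tau_d = td, relax = below[cc[, j]])
    }
  }
  if (length(cand) == 0) stop("no feasible start combinations")

  scored <- vapply(cand, function(s) {
    fit <- .fcs_lls(lags, G, s$tau_d, s$relax, w)
    if (is.null(fit) || fit$coef[1] <= 0) return(Inf)
    fit$ssr
  }, numeric(1))
  ord <- order(scored)[seq_len(min(n_refine, length(cand)))]

  resid_fn <- function(par) {
    N <- exp(par[1]); td <- exp(par[2])
    a <- if (nr > 0) par[3:(2 + nr)] else numeric(0)
    rt <- if (nr > 0) exp(par[(3 + nr):(2 + 2 * nr)]) else numeric(0)
    sqrt(w) * (G - fcs_model(lags, N, td, a, rt))
  }

  best <- NULL
  for (j in ord) {
    s <- cand[[j]]
    lin <- .fcs_lls(lags, G, s$tau_d, s$relax, w)
    if (is.null(lin) || lin$coef[1] <= 0) next
    N0 <- 1 / lin$coef[1]
    a0 <- if (nr > 0) lin$coef[-1] / lin$coef[1] else numeric(0)
    par0 <- unname(c(log(N0), log(s$tau_d), a0,
                     if (nr > 0) log(s$relax) else numeric(0)))
    # time scales are kept inside the sampled lag range: a relaxation far
    # below the shortest lag is unidentifiable and only biases tau_D
    lower <- c(-50, log(min(lags) / 3), rep(-20, nr),
               rep(log(min(lags) / 3), nr))
    upper <- c(50, log(max(lags) * 100), rep(20, nr),
               rep(log(max(lags)), nr))
    out <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(out)) next
    ssr <- sum(out$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12 * abs(best$ssr))
      best <- list(ssr = ssr, par = out$par, obj = out)
  }
  if (is.null(best)) stop("fit_fcs: no start converged")

  par <- unname(best$par)
  n <- length(G); p <- length(par)
  s2 <- best$ssr / max(n - p, 1)
  cov <- tryCatch(s2 * solve(best$obj$hessian),
                  error = function(e) matrix(NA_real_, p, p))
  se_par <- sqrt(pmax(diag(cov), 0))

  N <- exp(par[1]); td <- exp(par[2])
  se_N <- N * se_par[1]; se_td <- td * se_par[2]
  if (nr > 0) {
    a <- par[3:(2 + nr)]
    rt <- exp(par[(3 + nr):(2 + 2 * nr)])
    se_a <- se_par[3:(2 + nr)]
    se_rt <- rt * se_par[(3 + nr):(2 + 2 * nr)]
    o <- order(rt)
    a <- a[o]; rt <- rt[o]; se_a <- se_a[o]; se_rt <- se_rt[o]
  } else {
    a <- rt <- se_a <- se_rt <- numeric(0)
  }

  fitted <- fcs_model(lags, N, td, a, rt)
  structure(list(
    N = N, tau_d = td, relax_a = a, relax_tau = rt,
    se = list(N = se_N, tau_d = se_td, relax_a = se_a, relax_tau = se_rt),
    weights = weights,
    fitted = fitted, residuals = G - fitted, ssr = best$ssr,
    degenerate = (nr > 0) && (any(!is.finite(se_a)) ||
                                any(abs(a) < 2 * se_a, na.rm = TRUE)),
    at_bound = (nr > 0) && any(rt >= td),
    converged = TRUE),
    class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> N = %.4g +/- %.2g, tau_D = %.4g +/- %.2g s%s\n",
              x$N, x$se$N, x$tau_d, x$se$tau_d,
              if (isTRUE(x$degenerate)) " [degenerate relaxation]" else ""))
  for (i in seq_along(x$relax_a))
    cat(sprintf("  relaxation %d: a = %.4g +/- %.2g, tau = %.4g s\n",
                i, x$relax_a[i], x$se$relax_a[i], x$relax_tau[i]))
  invisible(x)
}

#' Molecular weight from a diffusion-time ratio
#'
#' For compact species the diffusion time through the confocal volume scales
#' with the hydrodynamic radius, and mass with its cube, giving
#' \deqn{M = M_{ref}\,(\tau_D / \tau_{D,ref})^3.}
#' A monomeric dye (e.g. Cy3-maleimide, 0.767 kD) serves as reference.
#' Uncertainty is propagated to first order from the supplied diffusion-time
#' standard errors. This function is the single home of the mass-scaling
#' convention (no shape or hydration corrections).
#'
#' @param tau_d_sample sample diffusion time, seconds.
#' @param tau_d_ref reference diffusion time, seconds.
#' @param mw_ref reference molecular weight, kD.
#' @param tau_d_se,tau_d_ref_se optional standard errors of the two
#'   diffusion times.
#' @return object of class `mw_estimate`: `mw` (kD), `mw_se` (kD, `NA` when
#'   no errors supplied), `ratio`, plus the inputs.
#' @examples
#' estimate_mw(2e-4, 1e-4, 10)$mw  # 80: cube law
#' @export
estimate_mw <- function(tau_d_sample, tau_d_ref, mw_ref,
                        tau_d_se = NA_real_, tau_d_ref_se = NA_real_) {
  stopifnot(tau_d_sample > 0, tau_d_ref > 0, mw_ref > 0)
  ratio <- tau_d_sample / tau_d_ref
  mw <- mw_ref * ratio^3
  mw_se <- NA_real_
  if (is.finite(tau_d_se) || is.finite(tau_d_ref_se)) {
    rel2 <- 0
    if (is.finite(tau_d_se)) rel2 <- rel2 + (tau_d_se / tau_d_sample)^2
    if (is.finite(tau_d_ref_se)) rel2 <- rel2 + (tau_d_ref_se / tau_d_ref)^2
    mw_se <- mw * 3 * sqrt(rel2)
  }
  structure(list(mw = mw, mw_se = mw_se, ratio = ratio,
                 tau_d_sample = tau_d_sample, tau_d_ref = tau_d_ref,
                 mw_ref = mw_ref),
            class = "mw_estimate")
}

#' Invert the mass scaling: diffusion time expected for a target mass
#'
#' @param mw target molecular weight, kD.
#' @param tau_d_ref,mw_ref reference diffusion time (s) and weight (kD).
#' @return expected diffusion time, seconds.
#' @export
tau_d_for_mw <- function(mw, tau_d_ref, mw_ref) {
  stopifnot(mw > 0, tau_d_ref > 0, mw_ref > 0)
  tau_d_ref * (mw / mw_ref)^(1 / 3)
}

#' @export
print.mw_estimate <- function(x, ...) {
  cat(sprintf("<mw_estimate> %.1f kD%s (tau_D ratio %.3g, ref %.3g kD)\n",
              x$mw, if (is.finite(x$mw_se)) sprintf(" +/- %.1f", x$mw_se)
              else "", x$ratio, x$mw_ref))
  invisible(x)
}

#' Check a complex mass against a 1:1 stoichiometry
#'
#' A measured complex mass is consistent with a 1:1 assembly of the given
#' components when its relative deviation from their summed mass is within
#' `tolerance` (default 10%): e.g. 85.8 kD against 39 kD + 50 kD deviates by
#' 3.6% and is consistent.
#'
#' @param mw_complex measured complex weight, kD.
#' @param mw_components component weights, kD.
#' @param tolerance maximum relative deviation (default 0.1).
#' @return list with `consistent` (logical), `deviation` (relative),
#'   `expected` (sum of components).
#' @export
stoichiometry_check <- function(mw_complex, mw_components, tolerance = 0.1) {
  stopifnot(mw_complex > 0, all(mw_components > 0))
  expected <- sum(mw_components)
  dev <- abs(mw_complex - expected) / expected
  list(consistent = dev <= tolerance, deviation = dev, expected = expected)
}

# ---- curve IO ------------------------------------------------------------

#' Read / write an FCS curve as two-column CSV
#'
#' Columns `lag_s,G`, optional `# key: value` metadata lines.
#'
#' @param path CSV file.
#' @return [read_fcs_curve()]: an `fcs_curve`; [write_fcs_curve()]: `path`.
#' @export
read_fcs_curve <- function(path) {
  lines <- readLines(path)
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  if (!all(c("lag_s", "G") %in% names(df)))
    stop("FCS CSV must have columns lag_s, G: ", path)
  fcs_curve(df$lag_s, df$G)
}

#' @rdname read_fcs_curve
#' @param curve an [fcs_curve()].
#' @export
write_fcs_curve <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("lag_s,G", con)
  writeLines(sprintf("%.10g,%.10g", curve$lags, curve$G), con)
  invisible(path)
}

#' Export an FCS fit (and optional mass estimate) as a JSON report
#'
#' @param fit an `fcs_fit` from [fit_fcs()].
#' @param mw optional `mw_estimate` from [estimate_mw()].
#' @param path output JSON file (optional).
#' @return the report list.
#' @export
fcs_report_json <- function(fit, mw = NULL, path = NULL) {
  stopifnot(inherits(fit, "fcs_fit"))
  rep <- list(
    schema_version = 1L,
    N = fit$N, N_se = fit$se$N,
    tau_d_s = fit$tau_d, tau_d_se_s = fit$se$tau_d,
    relaxations = lapply(seq_along(fit$relax_a), function(i) list(
      a = fit$relax_a[i], a_se = fit$se$relax_a[i],
      tau_s = fit$relax_tau[i], tau_se_s = fit$se$relax_tau[i])),
    degenerate = fit$degenerate)
  if (!is.null(mw))
    rep$mw <- list(kd = mw$mw, kd_se = mw$mw_se, ratio = mw$ratio,
                   mw_ref_kd = mw$mw_ref)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
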