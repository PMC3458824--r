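# Stopped-flow kinetic traces: multi-exponential modelling, deterministic
# multi-start least-squares fitting, exponential-order selection, and
# directionality inference from site-resolved fast-phase time constants.

#' Construct a stopped-flow kinetic trace
#'
#' @param times seconds, strictly increasing; points before the instrument
#'   dead time are retained here and excluded at fit time.
#' @param intensities fluorescence, arbitrary units, same length as `times`.
#' @param channel one of `"self_quench"`, `"fret_acceptor"`, `"absorbance"`.
#' @param label_site optional [site_label()] describing the dye position.
#' @param dead_time instrument dead time in seconds (default 0.0024).
#' @return object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, intensities,
                          channel = c("self_quench", "fret_acceptor",
                                      "absorbance"),
                          label_site = NULL, dead_time = 0.0024) {
  channel <- match.arg(channel)
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("times and intensities must have the same length")
  if (length(times) < 20L)
    stop("a kinetic trace needs at least 20 points for fitting")
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("non-finite values in trace")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, intensities = intensities, channel = channel,
                 label_site = label_site, dead_time = dead_time),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, %.3g-%.3g s, channel %s%s\n",
              length(x$times), min(x$times), max(x$times), x$channel,
              if (!is.null(x$label_site))
                paste0(", site ", x$label_site$site) else ""))
  invisible(x)
}

#' Multi-exponential relaxation model
#'
#' Sum-of-exponentials intensity model
#' \deqn{F(t) = F_\infty + \sum_i A_i e^{-t/\tau_i}}
#' with signed amplitudes so both rising (negative A) and decaying
#' (positive A) phases are represented.
#'
#' @param t time(s) in seconds.
#' @param baseline asymptotic intensity \eqn{F_\infty}.
#' @param amplitudes signed pre-exponential amplitudes \eqn{A_i}.
#' @param time_constants time constants \eqn{\tau_i} in seconds, all > 0.
#' @return model intensity at `t`.
#' @examples
#' multiexp_model(0, 1, c(-0.5, 0.3), c(0.1, 10)) # 1 - 0.5 + 0.3
#' @export
multiexp_model <- function(t, baseline, amplitudes, time_constants) {
  stopifnot(length(amplitudes) == length(time_constants),
            all(time_constants > 0))
  out <- rep(baseline, length(t))
  for (i in seq_along(amplitudes))
    out <- out + amplitudes[i] * exp(-t / time_constants[i])
  out
}

#' Exponential time constant to half-time, and back
#'
#' `half_time()` converts a fitted exponential time constant to the half-time
#' \eqn{t_{1/2} = \tau \ln 2}; `tau_from_half_time()` inverts it, e.g. a
#' subunit-exchange half-time of 128 s corresponds to tau = 184.66 s.
#'
#' @param tau time constant in seconds (> 0).
#' @param t_half half-time in seconds (> 0).
#' @return seconds.
#' @export
half_time <- function(tau) {
  stopifnot(all(tau > 0))
  tau * log(2)
}

#' @rdname half_time
#' @export
tau_from_half_time <- function(t_half) {
  stopifnot(all(t_half > 0))
  t_half / log(2)
}

# Linear least squares for (baseline, amplitudes) given fixed taus.
# Returns list(coef, ssr) or NULL if the design is degenerate.
.lls_given_tau <- function(t, y, taus) {
  X <- cbind(1, vapply(taus, function(tau) exp(-t / tau), numeric(length(t))))
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  list(coef = fit$coefficients, ssr = sum(fit$residuals^2))
}

#' Fit a multi-exponential model to a kinetic trace
#'
#' Deterministic multi-start nonlinear least squares. Start values come from
#' an exhaustive scan of a log-spaced time-constant grid spanning twice the
#' median sampling interval to the trace duration; for each grid combination
#' the baseline and amplitudes are solved by linear least squares, and the
#' best starts are refined by Levenberg--Marquardt (via \pkg{minpack.lm})
#' with time constants parameterized on the log scale to enforce positivity.
#' Points earlier than the instrument dead time are excluded.
#'
#' @param trace a [kinetic_trace()].
#' @param n_terms number of exponential terms, 1--3.
#' @param n_grid size of the log-spaced start grid per time constant.
#' @param n_refine how many best grid starts to polish.
#' @return object of class `exp_fit` with fields `n_terms`, `baseline`,
#'   `amplitudes`, `time_constants` (sorted ascending), `se` (list with
#'   `baseline`, `amplitudes`, `time_constants`), `residuals`, `fitted`,
#'   `times`, `ssr`, `residual_rms`, `residual_runs` (from [runs_test()]),
#'   `aicc`, `degenerate` (any amplitude indistinguishable from zero),
#'   `at_bound` (any time constant at the grid boundary), `converged`.
#' @export
fit_trace <- function(trace, n_terms, n_grid = 10, n_refine = 3) {
  stopifnot(inherits(trace, "kinetic_trace"),
            n_terms >= 1, n_terms <= 3)
  keep <- trace$times >= trace$dead_time
  t <- trace$times[keep]; y <- trace$intensities[keep]
  if (length(t) < 4 * n_terms + 2)
    stop("too few points after dead-time exclusion")
  t0 <- t[1]
  ts <- t - t0  # shift origin: improves conditioning, taus unchanged

  tau_lo <- 2 * stats::median(diff(t))
  tau_hi <- max(ts[length(ts)], tau_lo * 10)
  grid <- exp(seq(log(tau_lo), log(tau_hi), length.out = n_grid))
  combos <- utils::combn(n_grid, n_terms)

  starts <- apply(combos, 2, function(ix) {
    taus <- grid[ix]
    fit <- .lls_given_tau(ts, y, taus)
    if (is.null(fit)) return(c(Inf, taus))
    c(fit$ssr, taus)
  })
  ord <- order(starts[1, ])[seq_len(min(n_refine, ncol(starts)))]

  resid_fn <- function(par) {
    base <- par[1]
    amps <- par[2:(1 + n_terms)]
    taus <- exp(par[(2 + n_terms):(1 + 2 * n_terms)])
    y - multiexp_model(ts, base, amps, taus)
  }

  best <- NULL
  for (j in ord) {
    taus0 <- starts[-1, j]
    lin <- .lls_given_tau(ts, y, taus0)
    if (is.null(lin)) next
    par0 <- c(lin$coef, log(taus0))
    out <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(out)) next
    ssr <- sum(out$fvec^2)
    if (is.null(best) || ssr < best$ssr - 1e-12 * abs(best$ssr))
      best <- list(ssr = ssr, par = out$par, obj = out)
  }
  if (is.null(best))
    stop("fit_trace: no start converged; trace may be degenerate ",
         sprintf("(n = %d points, dynamic range %.3g)",
                 length(y), diff(range(y))))

  par <- unname(best$par)
  n <- length(y); p <- length(par)
  dof <- max(n - p, 1)
  s2 <- best$ssr / dof
  # covariance from local curvature J'J at the optimum
  cov <- tryCatch(s2 * solve(best$obj$hessian), error = function(e)
    matrix(NA_real_, p, p))
  se_par <- sqrt(pmax(diag(cov), 0))

  base <- par[1]
  amps <- par[2:(1 + n_terms)]
  ltaus <- par[(2 + n_terms):(1 + 2 * n_terms)]
  taus <- exp(ltaus)
  se_base <- se_par[1]
  se_amps <- se_par[2:(1 + n_terms)]
  se_taus <- taus * se_par[(2 + n_terms):(1 + 2 * n_terms)]  # delta method

  o <- order(taus)
  amps <- amps[o]; taus <- taus[o]; se_amps <- se_amps[o]; se_taus <- se_taus[o]

  fitted <- multiexp_model(ts, base, amps, taus)
  # amplitudes were estimated on the origin-shifted axis (t - t0); map them
  # back to the t = 0 convention A_i <- A_i * exp(t0 / tau_i)
  shift <- exp(t0 / taus)
  amps <- amps * shift
  se_amps <- se_amps * shift
  res <- y - fitted
  runs <- runs_test(res)

  structure(list(
    n_terms = as.integer(n_terms),
    baseline = base,
    amplitudes = amps,
    time_constants = taus,
    se = list(baseline = se_base, amplitudes = se_amps,
              time_constants = se_taus),
    times = t, fitted = fitted, residuals = res,
    ssr = best$ssr,
    residual_rms = sqrt(mean(res^2)),
    residual_runs = runs,
    aicc = aicc_from_ssr(best$ssr, n, p),
    degenerate = any(!is.finite(se_amps)) ||
      any(abs(amps) < 2 * se_amps, na.rm = TRUE) ||
      any(abs(amps) < 3 * sqrt(mean(res^2))),
    at_bound = any(taus < tau_lo / 2) || any(taus > 2 * tau_hi),
    converged = TRUE),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d term(s), F_inf = %.4g, residual rms %.3g%s\n",
              x$n_terms, x$baseline, x$residual_rms,
              if (isTRUE(x$degenerate)) " [degenerate amplitude]" else ""))
  for (i in seq_len(x$n_terms))
    cat(sprintf("  tau_%d = %s +/- %s   A_%d = %+.4g +/- %.2g\n",
                i, format_time_constant(x$time_constants[i]),
                format_time_constant(x$se$time_constants[i]),
                i, x$amplitudes[i], x$se$amplitudes[i]))
  invisible(x)
}

#' Choose the exponential order of a kinetic trace
#'
#' Sequential order selection between 1, 2 and 3 exponential terms. The
#' higher order is accepted only when (a) its small-sample-corrected
#' information criterion improves on the lower order by more than
#' `aicc_margin` and (b) the lower-order residuals show serial structure by a
#' one-sided runs test at level `runs_level`. Both thresholds are
#' configurable; residual structure alone or criterion improvement alone is
#' not enough.
#'
#' @param trace a [kinetic_trace()].
#' @param max_terms largest order to consider (default 3).
#' @param aicc_margin required information-criterion improvement (default 10).
#' @param runs_level runs-test level for residual structure (default 0.05).
#' @return list with `n_terms` (chosen order), `fit` (the chosen `exp_fit`),
#'   and `candidates` (all fitted orders, named `"1"`, `"2"`, ...).
#' @export
select_model <- function(trace, max_terms = 3, aicc_margin = 10,
                         runs_level = 0.05) {
  stopifnot(max_terms >= 1, max_terms <= 3)
  fits <- list()
  fits[["1"]] <- fit_trace(trace, 1)
  chosen <- 1L
  while (chosen < max_terms) {
    cand <- chosen + 1L
    fits[[as.character(cand)]] <- fit_trace(trace, cand)
    improves <- fits[[as.character(cand)]]$aicc <
      fits[[as.character(chosen)]]$aicc - aicc_margin
    structured <- fits[[as.character(chosen)]]$residual_runs$p_value <
      runs_level
    if (improves && structured) chosen <- cand else break
  }
  list(n_terms = chosen, fit = fits[[as.character(chosen)]],
       candidates = fits)
}

# ---- site labels and directionality --------------------------------------

.SKP_SITES <- c(K55C = 1L, E82C = 2L, D128C = 3L)   # bottom, waist, top
.OMP_SITES <- c(D25C = 1L, L139C = 2L, D290C = 3L)  # N, mid, C

#' Label a dye site on Skp or on the substrate OMP
#'
#' Skp sites K55C, E82C, D128C rank 1--3 from the bottom "mouth" through the
#' waist to the top of the tentacles; OmpC sites D25C, L139C, D290C rank 1--3
#' from the N- to the C-terminus.
#'
#' @param protein `"Skp"` or `"OMP"`.
#' @param site one of K55C/E82C/D128C (Skp) or D25C/L139C/D290C (OMP).
#' @return object of class `site_label` with `protein`, `site`, `axial_rank`.
#' @export
site_label <- function(protein = c("Skp", "OMP"), site) {
  protein <- match.arg(protein)
  tab <- if (protein == "Skp") .SKP_SITES else .OMP_SITES
  if (!site %in% names(tab))
    stop(sprintf("unknown %s site '%s' (expected one of %s)", protein, site,
                 paste(names(tab), collapse = ", ")))
  structure(list(protein = protein, site = site,
                 axial_rank = unname(tab[[site]])),
            class = "site_label")
}

#' Infer entry directionality from site-resolved fast-phase time constants
#'
#' Orders fitted fast-phase time constants by the axial rank of their label
#' sites and calls the entry direction. An adjacent pair is significantly
#' ordered when \eqn{|\Delta\tau_1| > z \sqrt{SE_a^2 + SE_b^2}}. The
#' conclusion is non-inconclusive only when every adjacent pair is
#' significant and the ordering is strictly monotone: increasing tau with
#' axial rank on Skp sites means the substrate meets the bottom mouth first
#' (`bottom_first`); on substrate sites it means the N-terminus leads
#' (`N_first`).
#'
#' @param sites list of [site_label()]s, one per measurement, or a character
#'   vector of site names (protein inferred).
#' @param tau1 fast-phase time constants, seconds (or any common unit).
#' @param se standard errors of `tau1`, same unit.
#' @param z significance multiplier for adjacent-pair comparisons (default 2).
#' @return object of class `directionality_report`: data.frame `table`
#'   (site, axial_rank, tau1, se), `monotonicity` (`"increasing"`,
#'   `"decreasing"` or `"non-monotone"`), `pair_significant` logical vector,
#'   `conclusion` in `bottom_first`, `top_first`, `N_first`, `C_first`,
#'   `inconclusive`.
#' @examples
#' infer_directionality(c("K55C", "E82C", "D128C"),
#'                      tau1 = c(0.0826, 0.125, 0.188),
#'                      se = c(0.0055, 0.0078, 0.012))
#' @export
infer_directionality <- function(sites, tau1, se, z = 2) {
  if (is.character(sites)) {
    sites <- lapply(sites, function(s)
      site_label(if (s %in% names(.SKP_SITES)) "Skp" else "OMP", s))
  }
  stopifnot(length(sites) == length(tau1), length(tau1) == length(se),
            length(sites) >= 1, all(se >= 0))
  protein <- unique(vapply(sites, `[[`, "", "protein"))
  if (length(protein) != 1L)
    stop("all sites must belong to the same protein")
  tab <- data.frame(
    site = vapply(sites, `[[`, "", "site"),
    axial_rank = vapply(sites, `[[`, 0L, "axial_rank"),
    tau1 = tau1, se = se, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$axial_rank))
    stop("sites must have distinct axial ranks")
  tab <- tab[order(tab$axial_rank), ]
  rownames(tab) <- NULL

  if (nrow(tab) < 2) {
    return(structure(list(table = tab, monotonicity = "non-monotone",
                          pair_significant = logical(0),
                          conclusion = "inconclusive", z = z),
                     class = "directionality_report"))
  }
  d <- diff(tab$tau1)
  sig <- abs(d) > z * sqrt(tab$se[-nrow(tab)]^2 + tab$se[-1]^2)
  mono <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing"
          else "non-monotone"
  conclusion <- "inconclusive"
  if (all(sig) && mono != "non-monotone") {
    conclusion <- if (protein == "Skp") {
      if (mono == "increasing") "bottom_first" else "top_first"
    } else {
      if (mono == "increasing") "N_first" else "C_first"
    }
  }
  structure(list(table = tab, monotonicity = mono, pair_significant = sig,
                 conclusion = conclusion, z = z),
            class = "directionality_report")
}

#' @export
print.directionality_report <- function(x, ...) {
  cat("<directionality_report>\n")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  rank %d  %-6s tau1 = %s +/- %s\n",
                x$table$axial_rank[i], x$table$site[i],
                format_time_constant(x$table$tau1[i]),
                format_time_constant(x$table$se[i])))
  cat(sprintf("  ordering %s; conclusion: %s\n", x$monotonicity,
              x$conclusion))
  invisible(x)
}

# ---- trace IO ------------------------------------------------------------

#' Read / write a kinetic trace as two-column CSV
#'
#' Format: optional `# key: value` metadata lines (channel, label fields,
#' dead_time_s), then a header `time_s,intensity` and the data.
#'
#' @param path CSV file.
#' @return [read_trace()]: a `kinetic_trace`; [write_trace()]: `path`,
#'   invisibly.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  df <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                          value = TRUE), collapse = "\n"))
  if (!all(c("time_s", "intensity") %in% names(df)))
    stop("trace CSV must have columns time_s, intensity: ", path)
  site <- NULL
  if (!is.null(meta$site) && !is.null(meta$protein))
    site <- site_label(meta$protein, meta$site)
  kinetic_trace(df$time_s, df$intensity,
                channel = meta$channel %||% "self_quench",
                label_site = site,
                dead_time = as.numeric(meta$dead_time_s %||% 0.0024))
}

#' @rdname read_trace
#' @param trace a [kinetic_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  hdr <- c(sprintf("# channel: %s", trace$channel),
           sprintf("# dead_time_s: %g", trace$dead_time))
  if (!is.null(trace$label_site))
    hdr <- c(hdr, sprintf("# protein: %s", trace$label_site$protein),
             sprintf("# site: %s", trace$label_site$site))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,intensity", con)
  writeLines(sprintf("%.10g,%.10g", trace$times, trace$intensities), con)
  invisible(path)
}

#' Export a multi-exponential fit as a JSON report
#'
#' Mirrors a time-constants/amplitudes table: per phase tau_i (s), A_i and
#' their standard errors, plus the baseline and residual diagnostics.
#'
#' @param fit an `exp_fit` from [fit_trace()].
#' @param path output JSON file (optional; when `NULL` the list is returned).
#' @return the report list, invisibly if written.
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "exp_fit"))
  rep <- list(
    schema_version = 1L,
    n_terms = fit$n_terms,
    baseline = fit$baseline,
    baseline_se = fit$se$baseline,
    phases = lapply(seq_len(fit$n_terms), function(i) list(
      tau_s = fit$time_constants[i], tau_se_s = fit$se$time_constants[i],
      amplitude = fit$amplitudes[i], amplitude_se = fit$se$amplitudes[i])),
    residual_rms = fit$residual_rms,
    runs_p_value = fit$residual_runs$p_value,
    degenerate = fit$degenerate)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
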