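#' Concentration after volumetric dilution
#'
#' Concentration of a solute after mixing `parts_stock` volumes of stock with
#' `parts_diluent` volumes of diluent, e.g. denaturant carried over when an
#' unfolded-protein stock is rapid-mixed into buffer. Mixing 8 M urea at a
#' 1:20 volume ratio gives 8/21 = 0.38 M (two decimals), the residual
#' denaturant concentration in a typical stopped-flow push.
#'
#' @param conc stock concentration (any unit).
#' @param parts_stock volumes of stock in the mix (default 1).
#' @param parts_diluent volumes of diluent in the mix (default 20).
#' @return final concentration, same unit as `conc`.
#' @examples
#' dilute_concentration(8, 1, 20) # 0.381 M
#' @export
dilute_concentration <- function(conc, parts_stock = 1, parts_diluent = 20) {
  stopifnot(is.numeric(conc), conc >= 0, parts_stock > 0, parts_diluent >= 0)
  conc * parts_stock / (parts_stock + parts_diluent)
}

#' Wald–Wolfowitz runs test on residual signs
#'
#' One-sided runs test for serial structure in fit residuals: structured
#' (e.g. under-fitted) residuals produce fewer sign runs than expected under
#' exchangeability. Normal approximation; zero residuals are dropped.
#'
#' @param residuals numeric vector in time order.
#' @return list with `n_runs`, `n_pos`, `n_neg`, `statistic` (z score) and
#'   `p_value` (one-sided, small when there are too few runs).
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n_pos <- sum(s > 0)
  n_neg <- sum(s < 0)
  n <- n_pos + n_neg
  if (n_pos == 0L || n_neg == 0L) {
    # one sign only: no evidence either way
    return(list(n_runs = as.integer(n > 0), n_pos = n_pos, n_neg = n_neg,
                statistic = 0, p_value = 1))
  }
  r <- 1L + sum(s[-1] != s[-length(s)])
  mu <- 2 * n_pos * n_neg / n + 1
  v <- 2 * n_pos * n_neg * (2 * n_pos * n_neg - n) / (n^2 * (n - 1))
  z <- (r - mu) / sqrt(v)
  list(n_runs = r, n_pos = n_pos, n_neg = n_neg,
       statistic = z, p_value = stats::pnorm(z))
}

# Small-sample-corrected Akaike information criterion from a Gaussian
# residual sum of squares; k counts mean-function parameters (+1 for the
# noise variance inside).
aicc_from_ssr <- function(ssr, n, k) {
  k <- k + 1
  aic <- n * log(ssr / n) + 2 * k
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

# seconds -> human-readable: ms below 1 s, else s
format_time_constant <- function(tau_s) {
  ifelse(tau_s < 1, sprintf("%.1f ms", tau_s * 1000), sprintf("%.3g s", tau_s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
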