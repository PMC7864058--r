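#' Fit a monoexponential intensity decay
#'
#' Least-squares fit of I(t) = I0 * exp(-R * t) to a peak-intensity decay,
#' the model used for both amide-proton transverse relaxation (PARA/DIA
#' samples) and the consolidated 15N R2-R1/2 decays. Starting values come
#' from a log-linear regression on the positive intensities; refinement
#' uses Levenberg-Marquardt.
#'
#' @param delays Relaxation delays, seconds (>= 4 points).
#' @param intensities Peak intensities, arbitrary units.
#' @param residue Optional residue index carried into the result.
#' @return A list with `residue`, `rate` (rad/s), `sigma` (NA until
#'   [monte_carlo_uncertainty()] is run), `amplitude` (fitted I0) and
#'   `status` (`"OK"` or `"MISSING"` with a `diagnostic` message when the
#'   fit fails or gives a non-positive rate).
#' @export
fit_monoexponential <- function(delays, intensities, residue = NA_integer_) {
  if (length(delays) != length(intensities))
    stop("delays and intensities must have equal length", call. = FALSE)
  if (length(delays) < 4L) stop("need at least 4 points", call. = FALSE)
  if (any(!is.finite(delays)) || any(delays <= 0))
    stop("delays must be finite and positive", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("intensities must be finite", call. = FALSE)
  if (diff(range(intensities)) == 0)
    stop("intensities are constant; decay rate undefined", call. = FALSE)

  miss <- function(msg) list(residue = residue, rate = NA_real_, sigma = NA_real_,
                             amplitude = NA_real_, status = "MISSING",
                             diagnostic = msg)

  pos <- intensities > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm.fit(cbind(1, delays[pos]), log(intensities[pos]))
    start <- list(I0 = exp(lf$coefficients[[1]]), R = max(-lf$coefficients[[2]], 1e-6))
  } else {
    start <- list(I0 = max(abs(intensities)), R = 1 / stats::median(delays))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-R * t),
                      data = list(y = intensities, t = delays),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(miss("nonlinear fit did not converge"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["R"]]) || cf[["R"]] <= 0)
    return(miss(sprintf("non-positive fitted rate (%.3g)", cf[["R"]])))
  list(residue = residue, rate = unname(cf[["R"]]), sigma = NA_real_,
       amplitude = unname(cf[["I0"]]), status = "OK", diagnostic = NULL)
}

#' Fit every series in a decay set
#'
#' @param decays Named list of decay series from [read_decay_table()] or
#'   [gen_decay_tables()].
#' @return A data.frame with columns `residue`, `rate`, `sigma`,
#'   `amplitude`, `status`.
#' @export
fit_decay_set <- function(decays) {
  rows <- lapply(decays, function(s) {
    f <- fit_monoexponential(s$delays, s$intensities, s$residue)
    data.frame(residue = f$residue, rate = f$rate, sigma = f$sigma,
               amplitude = f$amplitude, status = f$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate intensity noise from duplicate delays
#'
#' Pools the paired intensity differences at duplicated relaxation delays
#' over all residues and returns sigma = RMS(difference)/sqrt(2), the
#' single-measurement noise implied by duplicate spectra.
#'
#' @param decays Named list of decay series (see [read_decay_table()]).
#' @return Noise sigma in intensity units.
#' @export
estimate_noise <- function(decays) {
  diffs <- numeric(0)
  for (s in decays) {
    for (d in unique(s$delays[s$duplicate_mask])) {
      v <- s$intensities[s$delays == d]
      if (length(v) >= 2) {
        prs <- utils::combn(length(v), 2)
        diffs <- c(diffs, v[prs[1, ]] - v[prs[2, ]])
      }
    }
  }
  if (!length(diffs))
    stop("no duplicated delays found; supply an explicit noise sigma", call. = FALSE)
  sqrt(mean(diffs^2) / 2)
}

#' Monte Carlo uncertainty of a fitted decay rate
#'
#' Re-fits `n_draws` synthetic datasets generated from the fitted curve
#' with iid Gaussian noise of the given sigma and returns the standard
#' deviation of the refit rates. Deterministic for a fixed seed.
#'
#' @param delays,intensities The measured decay (used for the base fit).
#' @param sigma Intensity noise (1 SD).
#' @param n_draws Number of synthetic refits (default 500).
#' @param seed Integer seed.
#' @param fit Optional precomputed base fit from [fit_monoexponential()].
#' @return `sigma_rate`, the 1-SD rate uncertainty in rad/s.
#' @export
monte_carlo_uncertainty <- function(delays, intensities, sigma, n_draws = 500L,
                                    seed = 1L, fit = NULL) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (is.null(fit)) fit <- fit_monoexponential(delays, intensities)
  if (fit$status != "OK") stop("base fit failed; cannot run Monte Carlo", call. = FALSE)
  if (sigma == 0) return(0)
  model <- fit$amplitude * exp(-fit$rate * delays)
  rates <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      y <- model + stats::rnorm(length(delays), 0, sigma)
      f <- tryCatch(fit_monoexponential(delays, y), error = function(e) NULL)
      if (is.null(f) || f$status != "OK") NA_real_ else f$rate
    }, numeric(1))
  })
  fail <- mean(is.na(rates))
  if (fail > 0.2)
    stop(sprintf("%.0f%% of Monte Carlo refits failed", 100 * fail), call. = FALSE)
  stats::sd(rates[!is.na(rates)])
}

#' Apo-versus-bound domain mobility regression
#'
#' Ordinary least squares of the bound-state R2-R1/2 values (vertical axis)
#' on the apo-state values (horizontal axis), fitted separately per domain.
#' The per-domain slope reports the relative change in rotational mobility:
#' a shallower slope for one domain than the other means substrate binding
#' enhanced that domain's rotational mobility relative to the rest of the
#' protein. Residues with |studentized residual| > `outlier_sd` are flagged
#' but the fit is not repeated without them (outliers typically carry
#' exchange contributions and are interpreted against the global line).
#'
#' @param apo,bound Data.frames with columns `residue`, `rate`, `status`
#'   (only matched residues with status `"OK"` in both states are fitted).
#' @param ranges Domain ranges (see [assign_domain()]).
#' @param fit_domains Domains to fit (default WW and PPIASE; linker
#'   residues are reported in the matched table but excluded from fits).
#' @param intercept Include an intercept (default TRUE).
#' @param outlier_sd Studentized-residual cutoff (default 2).
#' @return A list with `fits` (per-domain list: `slope`, `intercept`,
#'   `corr_coeff`, `n`, `outliers`) and `data` (the matched table with
#'   domain labels).
#' @export
mobility_regression <- function(apo, bound, ranges = pin1_domains(),
                                fit_domains = c("WW", "PPIASE"),
                                intercept = TRUE, outlier_sd = 2) {
  m <- merge(apo[, c("residue", "rate", "status")],
             bound[, c("residue", "rate", "status")],
             by = "residue", suffixes = c("_apo", "_bound"))
  m <- m[m$status_apo == "OK" & m$status_bound == "OK", ]
  if (!nrow(m)) stop("no matched residues with status OK", call. = FALSE)
  m$domain <- assign_domain(m$residue, ranges)

  fits <- list()
  for (dom in fit_domains) {
    d <- m[m$domain == dom, ]
    if (nrow(d) < 3) stop("fewer than 3 usable residues in domain ", dom, call. = FALSE)
    if (stats::var(d$rate_apo) == 0)
      stop("degenerate apo-rate variance in domain ", dom, call. = FALSE)
    fm <- if (intercept) stats::lm(rate_bound ~ rate_apo, data = d)
          else stats::lm(rate_bound ~ rate_apo - 1, data = d)
    cf <- stats::coef(fm)
    # an essentially perfect fit has no meaningful studentized residuals
    fit_sigma <- suppressWarnings(summary(fm)$sigma)
    rs <- if (fit_sigma <= 1e-8 * stats::sd(d$rate_bound))
      rep(0, nrow(d)) else stats::rstudent(fm)
    fits[[dom]] <- list(
      domain = dom,
      slope = unname(cf[["rate_apo"]]),
      intercept = if (intercept) unname(cf[["(Intercept)"]]) else 0,
      corr_coeff = stats::cor(d$rate_apo, d$rate_bound),
      n = nrow(d),
      outliers = d$residue[is.finite(rs) & abs(rs) > outlier_sd])
  }
  list(fits = fits, data = m)
}

#' Physical-constant bundle for 15N relaxation
#'
#' One auditable place for the constants entering the R2-R1/2 to J_eff(0)
#' conversion: the 15N CSA term C_N = (omega_N * delta_sigma_N)^2 / 3 and
#' the 1H-15N dipolar term D_IN = ((mu0/4pi) hbar gamma_I gamma_N /
#' r_NH^3)^2 / 4, both in rad^2/s^2 (SI).
#'
#' @param field_mhz 1H Larmor frequency in MHz (default 700.13).
#' @param delta_sigma_n 15N CSA in ppm (default -170).
#' @param r_nh N-H bond length in Angstrom (default 1.02).
#' @return Named list with gyromagnetic ratios, field, `omega_h`,
#'   `omega_n` (rad/s), `c_n`, `d_in`.
#' @export
nmr_constants <- function(field_mhz = 700.13, delta_sigma_n = -170,
                          r_nh = 1.02) {
  gamma_h <- 2.6752218744e8   # rad s^-1 T^-1
  gamma_n <- -2.7116189e7
  hbar <- 1.054571817e-34
  mu0_4pi <- 1e-7
  b0 <- 2 * pi * field_mhz * 1e6 / gamma_h
  omega_h <- gamma_h * b0
  omega_n <- gamma_n * b0
  delta_n <- omega_n * delta_sigma_n * 1e-6
  c_n <- delta_n^2 / 3
  d_in <- (mu0_4pi * hbar * gamma_h * abs(gamma_n) / (r_nh * 1e-10)^3)^2 / 4
  if (c_n <= 0 || d_in <= 0) stop("non-positive constants", call. = FALSE)
  list(field_mhz = field_mhz, b0 = b0, gamma_h = gamma_h, gamma_n = gamma_n,
       omega_h = omega_h, omega_n = omega_n, delta_sigma_n = delta_sigma_n,
       r_nh = r_nh, c_n = c_n, d_in = d_in)
}

#' Convert an R2-R1/2 rate to J_eff(0) and an effective correlation time
#'
#' For slow isotropic tumbling, R2 - R1/2 = (2 C_N / 3)(1 + 3 D_IN / C_N)
#' J_eff(0) and J_eff(0) = 2 tau_c / 5, so the rate maps linearly onto the
#' effective rotational correlation time of the NH bond.
#'
#' @param rate R2 - R1/2 in rad/s (> 0); vectorized.
#' @param constants Bundle from [nmr_constants()].
#' @return Data.frame with `rate`, `jeff0` (s/rad) and `tau_c` (s).
#' @export
jeff0_tauc <- function(rate, constants = nmr_constants()) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("rate must be finite and > 0", call. = FALSE)
  denom <- (2 * constants$c_n / 3) * (1 + 3 * constants$d_in / constants$c_n)
  jeff0 <- rate / denom
  data.frame(rate = rate, jeff0 = jeff0, tau_c = 5 * jeff0 / 2)
}

#' Forward model: R2-R1/2 from a correlation time
#'
#' Inverse of [jeff0_tauc()]; used for round-trip checks and for building
#' synthetic relaxation data with a known tumbling time.
#'
#' @param tau_c Effective correlation time, seconds.
#' @param constants Bundle from [nmr_constants()].
#' @return Rate in rad/s.
#' @export
rate_from_tauc <- function(tau_c, constants = nmr_constants()) {
  if (any(tau_c <= 0)) stop("tau_c must be > 0", call. = FALSE)
  jeff0 <- 2 * tau_c / 5
  (2 * constants$c_n / 3) * (1 + 3 * constants$d_in / constants$c_n) * jeff0
}

#' Combined amide chemical-shift perturbation
#'
#' Combines 1H and 15N shift differences into a single amide CSP. The
#' default convention weights the nitrogen difference before squaring,
#' delta_NH = sqrt(dH^2 + (0.154 dN)^2); `convention = "scale_squared"`
#' instead scales the squared nitrogen term, sqrt(dH^2 + 0.154 dN^2).
#'
#' @param d_h,d_n 1H and 15N shift differences, ppm (vectorized).
#' @param weight Nitrogen weighting factor (default 0.154).
#' @param convention `"weight_squared"` (default) or `"scale_squared"`.
#' @return Combined CSP in ppm.
#' @export
combined_csp <- function(d_h, d_n, weight = 0.154,
                         convention = c("weight_squared", "scale_squared")) {
  convention <- match.arg(convention)
  if (any(!is.finite(d_h)) || any(!is.finite(d_n)))
    stop("shift differences must be finite", call. = FALSE)
  if (convention == "weight_squared") sqrt(d_h^2 + (weight * d_n)^2)
  else sqrt(d_h^2 + weight * d_n^2)
}
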