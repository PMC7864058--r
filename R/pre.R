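#' PREs from paramagnetic/diamagnetic rate pairs
#'
#' The paramagnetic relaxation enhancement of each amide proton is the
#' difference of its transverse rates in the spin-labelled (PARA) and
#' diamagnetic reference (DIA) samples, Gamma2 = R2_PARA - R2_DIA, with the
#' uncertainty combined in quadrature. Status propagation: a residue
#' missing in either state stays MISSING; a PARA peak broadened below
#' detection against a visible DIA peak is OVERFLOW (qualitatively "very
#' close to the label") and carries no finite Gamma2.
#'
#' @param para,dia Data.frames with columns `residue`, `rate`, `sigma`,
#'   `status` (`OK`/`OVERFLOW`/`MISSING`).
#' @return Data.frame with `residue`, `gamma2` (rad/s), `sigma`, `status`
#'   (`QUANTIFIED`/`OVERFLOW`/`MISSING`).
#' @export
compute_gamma2 <- function(para, dia) {
  m <- merge(para, dia, by = "residue", suffixes = c("_para", "_dia"))
  status <- ifelse(m$status_para == "MISSING" | m$status_dia == "MISSING",
                   "MISSING",
            ifelse(m$status_para == "OVERFLOW" & m$status_dia == "OK",
                   "OVERFLOW",
            ifelse(m$status_para == "OK" & m$status_dia == "OK",
                   "QUANTIFIED", "MISSING")))
  ok <- status == "QUANTIFIED"
  gamma2 <- ifelse(ok, m$rate_para - m$rate_dia, NA_real_)
  sigma <- ifelse(ok, sqrt(m$sigma_para^2 + m$sigma_dia^2), NA_real_)
  data.frame(residue = m$residue, gamma2 = gamma2, sigma = sigma,
             status = status, stringsAsFactors = FALSE)
}

#' Classify disappeared cross-peaks
#'
#' Compares per-residue maximum peak intensities of the DIA and PARA
#' spectra against a noise floor: a peak visible in DIA but absent in PARA
#' is OVERFLOW (completely broadened by the label); visible in both is
#' QUANTIFIED; absent in DIA is MISSING.
#'
#' @param dia_intensity,para_intensity Per-residue maximum intensities.
#' @param noise_floor Spectral noise level (> 0).
#' @param k Detection multiple of the noise floor (default 3).
#' @return Character vector of statuses.
#' @export
flag_disappeared <- function(dia_intensity, para_intensity, noise_floor, k = 3) {
  if (!is.finite(noise_floor) || noise_floor <= 0)
    stop("noise_floor must be > 0", call. = FALSE)
  lim <- k * noise_floor
  ifelse(dia_intensity <= lim, "MISSING",
         ifelse(para_intensity <= lim, "OVERFLOW", "QUANTIFIED"))
}

#' Three-pass trimmed significance threshold
#'
#' Computes the significance bounds used for PRE profiles. Pass 1: mean M1
#' and sample SD STD1 of all finite values; values strictly outside
#' [M1 - STD1, M1 + STD1] are dropped. Pass 2: the same filter with M2,
#' STD2 on the survivors. Pass 3: M3 and STD3 of the remaining core values
#' define the threshold M3 +/- 2*STD3. Values equal to a filter bound are
#' kept; sample SD uses ddof = 1 throughout.
#'
#' @param values Finite Gamma2 (or delta-Gamma2) values, length >= 3.
#' @return A list with `m3`, `std3`, `upper`, `lower`, `n_core`, `core`
#'   and the intermediate `m` / `std` vectors (passes 1-3).
#' @export
twice_filtered_threshold <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 finite values", call. = FALSE)
  ms <- stds <- numeric(3)
  for (pass in 1:2) {
    m <- mean(v)
    s <- if (length(v) > 1) stats::sd(v) else 0
    ms[pass] <- m; stds[pass] <- s
    keep <- v >= m - s & v <= m + s
    if (!any(keep))
      stop("all values filtered out at pass ", pass, call. = FALSE)
    v <- v[keep]
  }
  if (length(v) == 1) {
    warning("threshold core reduced to a single value; SD taken as 0")
    std3 <- 0
  } else std3 <- stats::sd(v)
  m3 <- mean(v)
  ms[3] <- m3; stds[3] <- std3
  list(m3 = m3, std3 = std3, upper = m3 + 2 * std3, lower = m3 - 2 * std3,
       n_core = length(v), core = v, m = ms, std = stds)
}

#' Apo-versus-bound PRE differences
#'
#' Forms delta-Gamma2 = Gamma2_apo - Gamma2_bound for residues quantified
#' in both states, with significance bounds from the three-pass trimmed
#' threshold applied to the delta values (the bounds are generally
#' asymmetric about zero). Residues that are OVERFLOW in one state but
#' quantified in the other are reported qualitatively: an apo-OVERFLOW
#' residue that becomes quantifiable on binding has "reappeared"
#' (contact loss); the converse has "disappeared" (contact gain).
#'
#' @param apo,bound PRE tables from [compute_gamma2()].
#' @return A list with `delta` (data.frame `residue`, `delta_gamma2`,
#'   `sigma`), `threshold` (see [twice_filtered_threshold()]) and
#'   `qualitative` (data.frame `residue`, `change`).
#' @export
delta_gamma2 <- function(apo, bound) {
  m <- merge(apo, bound, by = "residue", suffixes = c("_apo", "_bound"))
  both <- m$status_apo == "QUANTIFIED" & m$status_bound == "QUANTIFIED"
  if (sum(both) < 3)
    stop("fewer than 3 residues quantified in both states", call. = FALSE)
  delta <- data.frame(
    residue = m$residue[both],
    delta_gamma2 = m$gamma2_apo[both] - m$gamma2_bound[both],
    sigma = sqrt(m$sigma_apo[both]^2 + m$sigma_bound[both]^2),
    stringsAsFactors = FALSE)
  qual <- data.frame(residue = integer(0), change = character(0),
                     stringsAsFactors = FALSE)
  reapp <- m$status_apo == "OVERFLOW" & m$status_bound == "QUANTIFIED"
  disap <- m$status_apo == "QUANTIFIED" & m$status_bound == "OVERFLOW"
  persist <- m$status_apo == "OVERFLOW" & m$status_bound == "OVERFLOW"
  if (any(reapp | disap | persist))
    qual <- data.frame(
      residue = m$residue[reapp | disap | persist],
      change = c(rep("reappeared", sum(reapp)), rep("disappeared", sum(disap)),
                 rep("overflow_both", sum(persist)))[
        order(c(which(reapp), which(disap), which(persist)))],
      stringsAsFactors = FALSE)
  list(delta = delta,
       threshold = twice_filtered_threshold(delta$delta_gamma2),
       qualitative = qual)
}

#' Flag significant PREs against a trimmed threshold
#'
#' A quantified Gamma2 is significant when it exceeds the upper bound
#' strictly (the threshold is "more than 2 SD" beyond the trimmed mean);
#' for difference profiles both bounds apply (`two_sided = TRUE`).
#' OVERFLOW residues are always reported as significant-qualitative.
#'
#' @param values Data.frame with `residue`, a value column and `status`
#'   (`QUANTIFIED`/`OVERFLOW`/`MISSING`); the value column is `gamma2` if
#'   present, else the first numeric column.
#' @param threshold Output of [twice_filtered_threshold()].
#' @param two_sided Use both bounds (default FALSE: upper bound only).
#' @return The input with an added `significance` column:
#'   `"significant"`, `"significant_qualitative"` or `"ns"`.
#' @export
classify_significant <- function(values, threshold, two_sided = FALSE) {
  col <- if ("gamma2" %in% names(values)) "gamma2"
         else names(values)[vapply(values, is.numeric, logical(1)) &
                            names(values) != "residue"][1]
  v <- values[[col]]
  sig <- rep("ns", nrow(values))
  quant <- !is.na(values$status) & values$status == "QUANTIFIED"
  hit <- if (two_sided) v > threshold$upper | v < threshold$lower
         else v > threshold$upper
  sig[quant & !is.na(hit) & hit] <- "significant"
  sig[values$status == "OVERFLOW"] <- "significant_qualitative"
  values$significance <- sig
  values
}

#' Solomon-Bloembergen constant bundle
#'
#' Constants for the nitroxide-label transverse PRE: electron spin S = 1/2,
#' free-electron g factor, Bohr magneton, the 1H gyromagnetic ratio and
#' Larmor frequency at the configured field, and the unit-system prefactor
#' K (SI default, K = (mu0/4pi)^2; `prefactor = "plain"` drops it for
#' unit systems that absorb the factor into the moments).
#'
#' @param field_mhz 1H Larmor frequency, MHz (default 700.13).
#' @param s Electron spin quantum number (default 1/2).
#' @param g Electron g factor (default 2.00231930).
#' @param prefactor `"si"` or `"plain"`.
#' @return Named list with `s`, `g`, `mu_b`, `gamma_h`, `omega_h`, `k`.
#' @export
sb_constants <- function(field_mhz = 700.13, s = 0.5, g = 2.00231930,
                         prefactor = c("si", "plain")) {
  prefactor <- match.arg(prefactor)
  if (s <= 0 || g <= 0 || field_mhz <= 0) stop("non-positive constants", call. = FALSE)
  list(s = s, g = g, mu_b = 9.2740100783e-24, gamma_h = 2.6752218744e8,
       omega_h = 2 * pi * field_mhz * 1e6,
       k = if (prefactor == "si") 1e-14 else 1)  # (mu0/4pi)^2 = (1e-7)^2
}

#' Effective correlation time from tumbling and electron relaxation
#'
#' 1/tau_c = 1/tau_R + 1/tau_elec, assuming electron relaxation is
#' uncoupled from molecular tumbling.
#'
#' @param tau_r Rotational correlation time, s.
#' @param tau_elec Effective electron relaxation time, s.
#' @return tau_c in seconds.
#' @export
combine_tau <- function(tau_r, tau_elec) {
  if (any(tau_r <= 0) || any(tau_elec <= 0)) stop("times must be > 0", call. = FALSE)
  1 / (1 / tau_r + 1 / tau_elec)
}

# shared spectral part of the SB transverse PRE
sb_prefactor <- function(tau_c, constants) {
  if (any(tau_c <= 0)) stop("tau_c must be > 0", call. = FALSE)
  jterm <- 4 * tau_c + 3 * tau_c / (1 + (constants$omega_h * tau_c)^2)
  constants$k * constants$s * (constants$s + 1) *
    (constants$g * constants$mu_b * constants$gamma_h)^2 / 15 * jterm
}

#' Solomon-Bloembergen transverse PRE at a fixed distance
#'
#' Gamma2 = K S(S+1) (g mu_B gamma_I)^2 / 15 * r^-6 *
#' (4 tau_c + 3 tau_c / (1 + (omega_H tau_c)^2)), the point-dipole
#' transverse enhancement for a nitroxide electron at distance `r_is` from
#' the proton.
#'
#' @param r_is Electron-proton distance, Angstrom (> 0); vectorized.
#' @param tau_c Effective correlation time, seconds.
#' @param constants Bundle from [sb_constants()].
#' @return Gamma2 in rad/s.
#' @export
sb_gamma2 <- function(r_is, tau_c, constants = sb_constants()) {
  if (any(!is.finite(r_is)) || any(r_is <= 0))
    stop("r_is must be finite and > 0", call. = FALSE)
  sb_prefactor(tau_c, constants) * (r_is * 1e-10)^-6
}

#' Ensemble-averaged transverse PRE
#'
#' Substitutes the ensemble average <r^-6> = sum w_f r_f^-6 over trajectory
#' frames into the Solomon-Bloembergen expression, the quantity the
#' experimental PRE actually reports for a mobile system.
#'
#' @param distances Per-frame electron-proton distances, Angstrom.
#' @param tau_c Effective correlation time, seconds.
#' @param weights Optional frame weights (normalized internally);
#'   default uniform 1/N.
#' @param constants Bundle from [sb_constants()].
#' @return Gamma2 in rad/s.
#' @export
ensemble_gamma2 <- function(distances, tau_c, weights = NULL,
                            constants = sb_constants()) {
  if (!length(distances)) stop("empty distance series", call. = FALSE)
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("distances must be finite and > 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(distances), length(distances))
  if (length(weights) != length(distances) || any(weights < 0))
    stop("weights must be nonnegative and match the series length", call. = FALSE)
  w <- weights / sum(weights)
  r6 <- sum(w * (distances * 1e-10)^-6)
  sb_prefactor(tau_c, constants) * r6
}
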