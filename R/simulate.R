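#' Generate synthetic relaxation-decay tables
#'
#' Emits per-residue monoexponential decays I(t) = I0 exp(-R t) plus iid
#' Gaussian intensity noise, on the duplicate-containing delay schedule
#' used for amide-proton transverse relaxation series. Ground truth is
#' returned alongside the data for parameter-recovery tests.
#'
#' @param true_rates Named or plain numeric vector of decay rates, rad/s;
#'   names (or positions) become residue numbers.
#' @param delays Delay schedule in seconds; repeated values are duplicate
#'   measurements. Default: 4 (x2), 6, 8, 10, 12, 15, 20 (x2), 25, 30 ms.
#' @param sigma Intensity noise SD (default 2, i.e. 2% of I0 = 100).
#' @param i0 Common initial intensity (default 100).
#' @param seed Integer seed; generation is deterministic given
#'   (parameters, seed).
#' @param residues Residue numbers (default `seq_along(true_rates)`).
#' @return List with `decays` (same shape as [read_decay_table()]
#'   output), `table` (long data.frame with `residue`, `delay_ms`,
#'   `intensity`, writable with [write_results()]), and `truth`.
#' @export
gen_decay_tables <- function(true_rates,
                             delays = c(4, 4, 6, 8, 10, 12, 15, 20, 20, 25, 30) / 1000,
                             sigma = 2, i0 = 100, seed = 1L,
                             residues = seq_along(true_rates)) {
  if (any(true_rates <= 0)) stop("rates must be > 0", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  decays <- with_seed(seed, {
    out <- list()
    for (k in seq_along(true_rates)) {
      y <- i0 * exp(-true_rates[k] * delays)
      if (sigma > 0) y <- y + stats::rnorm(length(delays), 0, sigma)
      dup <- ave(delays, delays, FUN = length) > 1
      out[[as.character(residues[k])]] <- list(
        residue = as.integer(residues[k]), delays = delays, intensities = y,
        duplicate_mask = dup,
        replicate = as.integer(ave(seq_along(delays), delays, FUN = seq_along)))
    }
    out
  })
  tbl <- do.call(rbind, lapply(decays, function(s)
    data.frame(residue = s$residue, delay_ms = s$delays * 1000,
               intensity = s$intensities)))
  rownames(tbl) <- NULL
  list(decays = decays, table = tbl,
       truth = list(generator = "gen_decay_tables", seed = seed,
                    true_rates = stats::setNames(true_rates, residues),
                    sigma = sigma, i0 = i0, delays = delays))
}

# toy geometry tables for the two-state ensemble ----------------------------

# base backbone-like atoms of one residue row at height y, x-offset x0
toy_residue_atoms <- function(resno, y, x0 = 0) {
  data.frame(name = c("N", "H", "CA", "O"), resno = resno, resname = "GLY",
             element = c("N", "H", "C", "O"),
             x = x0 + c(0, 0, 1.5, 3.0), y = y, z = c(0, -1, 0, 0),
             stringsAsFactors = FALSE)
}

# designed hinge beads: closed/open positions; `reversed` beads are closed
# in the COMPACT interdomain state instead of the EXTENDED one
toy_bead_table <- function() {
  b <- function(name, resno, ele, cx, cy, cz, ox, oy, oz, reversed = FALSE)
    data.frame(name = name, resno = resno, resname = "GLY", element = ele,
               cx = cx, cy = cy, cz = cz, ox = ox, oy = oy, oz = oz,
               reversed = reversed, stringsAsFactors = FALSE)
  rbind(
    b("CB",  2, "C", 1.5, 10.0, 4.5, 1.5,  8.0, 12.0),
    b("CB",  4, "C", 1.5, 14.0, 4.5, 1.5, 16.0, 12.0),
    b("CB",  5, "C", 1.5, 28.0, 4.5, 1.5, 26.0, 12.0),
    b("CG",  5, "C", 1.5, 28.0, 8.0, 1.5, 26.0, 15.5),
    b("CB",  7, "C", 1.5, 32.0, 4.5, 1.5, 34.0, 12.0),
    b("CG",  7, "C", 1.5, 32.0, 8.0, 1.5, 34.0, 15.5),
    b("OD", 11, "O", 0.0, 48.0, -2.9, 0.0, 56.0, -8.0),
    b("CB", 12, "C", 1.5, 70.0, 4.5, 1.5, 68.0, 12.0),
    b("CB", 14, "C", 1.5, 74.0, 4.5, 1.5, 76.0, 12.0),
    b("CB", 16, "C", 1.5, 94.0, 4.5, 1.5, 92.0, 12.0, reversed = TRUE),
    b("CB", 18, "C", 1.5, 98.0, 4.5, 1.5, 100.0, 12.0, reversed = TRUE))
}

# designed per-state contact counts of the fluctuating WW-like pairs;
# sign says whether the contact closes with increasing domain separation
toy_contact_design <- function() {
  data.frame(i = c(2L, 5L, 9L, 12L, 16L), j = c(4L, 7L, 11L, 14L, 18L),
             count_extended = c(1L, 2L, 3L, 1L, 0L),
             count_compact = c(0L, 0L, 0L, 0L, 1L),
             sign = c(1, 1, 1, 1, -1))
}

#' Generate a two-state two-domain toy ensemble
#'
#' Builds a rigid 20-residue WW-like domain and a 30-residue PPIase-like
#' domain (N/H/CA/O rows plus designed hinge beads) and samples frames
#' from a latent compact/extended exchange: each frame draws a Bernoulli
#' state that sets the interdomain separation (Gaussian jitter around the
#' two design means) and the WW-like hinge, which closes designed contact
#' pairs and an N-H...O triad when the domains are far apart (and one
#' reversed pair when they are close). This plants, by construction, the
#' anticorrelation between interdomain separation and intradomain
#' geometry that the pipeline is meant to detect, with integer per-state
#' contact counts and exact closed-form planted correlations.
#'
#' The reference topology is written as a valid PDB and read back through
#' [read_structure_trajectory()], so the package's own readers are
#' exercised rather than bypassed. Per-frame spin-label-to-amide
#' distances are recorded for PRE forward modelling; the label site is
#' the CA of WW-like residue 10, and PPIase-like residues 32/34/36/38
#' carry a contact face that approaches the label in the compact state
#' (the remaining amides sit in two balanced distance clumps, so the
#' three-pass trimmed threshold separates face from bulk cleanly).
#'
#' @param p_compact Probability of the compact state (default 0.5).
#' @param n_frames Number of frames (default 2000).
#' @param seed Integer seed.
#' @param sep_means Compact/extended separation design means, Angstrom
#'   (default 32.7 and 50.1).
#' @param sep_sd Separation jitter SD, Angstrom (default 1.5).
#' @param frame_interval_ps Frame spacing, ps (default 200).
#' @return List with `topology`, `frames`, `ranges` (toy domain ranges:
#'   WW 1-20, PPIASE 21-50), and `truth`: `states`
#'   (`"COMPACT"`/`"EXTENDED"` per frame), `separations`, `contact_design`,
#'   planted correlation `r_true` per designed pair, `hbond` (donor
#'   residue 9 to acceptor residue 11, present when extended),
#'   `label_site`, `cluster_site`, `face_residues`, `label_distances`
#'   (frames x residues matrix of label-to-amide-N distances, Angstrom).
#' @export
gen_two_state_ensemble <- function(p_compact = 0.5, n_frames = 2000L, seed = 1L,
                                   sep_means = c(compact = 32.7, extended = 50.1),
                                   sep_sd = 1.5, frame_interval_ps = 200) {
  if (p_compact <= 0 || p_compact >= 1) stop("p_compact must be in (0, 1)", call. = FALSE)
  if (sep_means[1] >= sep_means[2]) stop("compact mean must be below extended", call. = FALSE)

  a_res <- 1:20; b_res <- 21:50
  face_res <- c(32L, 34L, 36L, 38L)
  label_res <- 10L

  # WW-like base rows (fixed in all frames)
  a_base <- do.call(rbind, lapply(a_res, function(r) toy_residue_atoms(r, 6 * (r - 1))))
  beads <- toy_bead_table()
  # PPIase-like rows at local x (translated by the per-frame separation).
  # Amide N/H positions are designed around the label height (y = 54):
  # the four face residues protrude 15 A toward the label; the remaining
  # 26 amides sit in two equal-size distance clumps ("medium" at local
  # x = -5, "distal" at +12) so the trimmed PRE threshold clears the
  # whole non-face profile by construction.
  bulk_res <- setdiff(b_res, face_res)
  b_base <- do.call(rbind, lapply(b_res, function(r) {
    at <- toy_residue_atoms(r, 6 * (r - 21) - 30)
    amide <- at$name %in% c("N", "H")
    if (r %in% face_res) {
      at$x[amide] <- -15
      at$y[amide] <- 48 + 4 * (match(r, face_res) - 1)  # 48/52/56/60
    } else {
      k <- match(r, bulk_res)
      at$x[amide] <- if (k %% 2 == 1) -5 else 12
      at$y[amide] <- 54 + 0.4 * (k - 13.5)
    }
    at
  }))

  n_a <- nrow(a_base); n_bead <- nrow(beads); n_b <- nrow(b_base)
  n_atoms <- n_a + n_bead + n_b

  draws <- with_seed(seed, {
    st <- stats::rbinom(n_frames, 1L, 1 - p_compact)  # 1 = extended
    list(extended = st == 1L,
         sep = ifelse(st == 1L, sep_means[2], sep_means[1]) +
           stats::rnorm(n_frames, 0, sep_sd))
  })
  extended <- draws$extended
  sep <- draws$sep

  xyz <- matrix(NA_real_, n_frames, 3L * n_atoms)
  put <- function(col0, x, y, z) {
    xyz[, col0 + 1L] <<- x; xyz[, col0 + 2L] <<- y; xyz[, col0 + 3L] <<- z
  }
  for (k in seq_len(n_a))
    put(3L * (k - 1L), a_base$x[k], a_base$y[k], a_base$z[k])
  for (k in seq_len(n_bead)) {
    closed <- extended != beads$reversed[k]
    put(3L * (n_a + k - 1L),
        ifelse(closed, beads$cx[k], beads$ox[k]),
        ifelse(closed, beads$cy[k], beads$oy[k]),
        ifelse(closed, beads$cz[k], beads$oz[k]))
  }
  for (k in seq_len(n_b))
    put(3L * (n_a + n_bead + k - 1L), sep + b_base$x[k], b_base$y[k], b_base$z[k])

  # reference PDB (first frame) -> topology via the real reader
  atoms <- rbind(a_base[, c("name", "resno", "resname", "element")],
                 beads[, c("name", "resno", "resname", "element")],
                 b_base[, c("name", "resno", "resname", "element")])
  atoms$eleno <- seq_len(n_atoms)
  ref_path <- tempfile(fileext = ".pdb")
  ref_frames <- frame_series(xyz[1, , drop = FALSE], frame_interval_ps)
  write_multimodel_pdb(atoms, ref_frames, ref_path, models = 1L)
  topo <- read_structure_trajectory(ref_path, frame_interval_ps = frame_interval_ps)$topology
  unlink(ref_path)

  frames <- frame_series(xyz, frame_interval_ps)

  # spin-label -> amide-N distances, frames x residues
  label_idx <- which(topo$resno == label_res & topo$name == "CA")
  lab <- c(frames$xyz[1, 3 * (label_idx - 1) + 1],
           frames$xyz[1, 3 * (label_idx - 1) + 2],
           frames$xyz[1, 3 * label_idx])
  all_res <- c(a_res, b_res)
  ldist <- matrix(NA_real_, n_frames, length(all_res),
                  dimnames = list(NULL, all_res))
  for (r in all_res) {
    nidx <- which(topo$resno == r & topo$name == "N")
    dx <- frames$xyz[, 3 * (nidx - 1) + 1] - lab[1]
    dy <- frames$xyz[, 3 * (nidx - 1) + 2] - lab[2]
    dz <- frames$xyz[, 3 * nidx] - lab[3]
    ldist[, as.character(r)] <- sqrt(dx^2 + dy^2 + dz^2)
  }

  design <- toy_contact_design()
  p <- p_compact; q <- 1 - p
  dmu <- sep_means[2] - sep_means[1]
  r_mag <- sqrt(p * q * dmu^2 / (p * q * dmu^2 + sep_sd^2))
  design$r_true <- design$sign * unname(r_mag)

  list(topology = topo, frames = frames,
       ranges = list(WW = c(1L, 20L), PPIASE = c(21L, 50L)),
       truth = list(generator = "gen_two_state_ensemble", seed = seed,
                    p_compact = p_compact, sep_means = sep_means,
                    sep_sd = sep_sd,
                    states = ifelse(extended, "EXTENDED", "COMPACT"),
                    separations = sep,
                    contact_design = design,
                    hbond = list(donor_res = 9L, acceptor_res = 11L,
                                 present_when = "EXTENDED"),
                    label_site = paste0("ca:", label_res),
                    cluster_site = "ca:35",
                    face_residues = face_res,
                    label_distances = ldist))
}

#' Generate a correlated series pair
#'
#' Bivariate standard normal with a target correlation; optionally the
#' second series is discretized into small integers (contact-number-like)
#' by equal-probability quantile thresholds, in which case the true
#' post-discretization correlation is recomputed in closed form and
#' stored as truth: for thresholds t_k, corr(x, sum_k 1\{y > t_k\}) =
#' rho * sum_k phi(t_k) / sqrt(Var(sum_k 1\{y > t_k\})).
#'
#' @param target_r Target correlation, |target_r| < 1.
#' @param n Series length.
#' @param seed Integer seed.
#' @param discretize Discretize `y` into integers (default FALSE).
#' @param levels Number of integer levels when discretizing (default 4).
#' @return List with `x`, `y` and `truth` (`target_r`, and `r_true` =
#'   the population correlation of the returned pair).
#' @export
gen_correlated_series <- function(target_r, n, seed = 1L, discretize = FALSE,
                                  levels = 4L) {
  if (abs(target_r) >= 1) stop("|target_r| must be < 1", call. = FALSE)
  sim <- with_seed(seed, {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    list(x = z1, y = target_r * z1 + sqrt(1 - target_r^2) * z2)
  })
  r_true <- target_r
  y <- sim$y
  if (discretize) {
    th <- stats::qnorm(seq_len(levels - 1) / levels)
    y <- vapply(y, function(v) sum(v > th), numeric(1))
    cov_yg <- sum(stats::dnorm(th))
    pg <- stats::pnorm(th, lower.tail = FALSE)
    var_g <- 0
    for (a in seq_along(th)) for (b in seq_along(th))
      var_g <- var_g + stats::pnorm(max(th[a], th[b]), lower.tail = FALSE) - pg[a] * pg[b]
    r_true <- target_r * cov_yg / sqrt(var_g)
  }
  list(x = sim$x, y = y,
       truth = list(generator = "gen_correlated_series", seed = seed,
                    target_r = target_r, discretize = discretize,
                    levels = if (discretize) levels else NA_integer_,
                    r_true = r_true))
}

#' Generate a labelled bimodal scalar series
#'
#' Two-component Gaussian mixture with known labels, the standing test
#' fixture for the two-cluster partition of an interdomain distance.
#'
#' @param n Series length.
#' @param means Component means (default the 32.7 / 50.1 Angstrom design
#'   pair).
#' @param sds Component SDs (default 3 and 3).
#' @param weight Probability of the first (lower-mean) component.
#' @param seed Integer seed.
#' @return List with `values`, `labels` (`"COMPACT"`/`"EXTENDED"` by
#'   component mean order) and `truth`.
#' @export
gen_bimodal_scalar <- function(n, means = c(32.7, 50.1), sds = c(3, 3),
                               weight = 0.5, seed = 1L) {
  if (means[1] == means[2]) stop("component means must differ", call. = FALSE)
  o <- order(means)
  means <- means[o]; sds <- rep_len(sds, 2)[o]
  sim <- with_seed(seed, {
    comp <- stats::rbinom(n, 1L, 1 - weight) + 1L  # 1 = lower-mean
    list(comp = comp,
         values = stats::rnorm(n, means[comp], sds[comp]))
  })
  list(values = sim$values,
       labels = ifelse(sim$comp == 1L, "COMPACT", "EXTENDED"),
       truth = list(generator = "gen_bimodal_scalar", seed = seed,
                    means = means, sds = sds, weight = weight))
}
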