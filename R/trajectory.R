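#' Resolve a site specifier to atoms and weights
#'
#' Mini-language for naming trajectory sites: `"ca:27"` is the CA atom of
#' residue 27, `"com:1-39"` the mass-weighted center of mass of residues
#' 1-39 (`mass_weighted = FALSE` gives the plain centroid), `"atom:5"` the
#' atom with PDB serial 5. A numeric vector is taken as raw topology row
#' indices with uniform weights.
#'
#' @param spec Site specifier string or integer vector.
#' @param topology Atom table (see [read_structure_trajectory()]).
#' @param mass_weighted Logical; mass-weight multi-atom sites.
#' @return List with `idx` (topology row indices) and `w` (weights summing
#'   to 1).
#' @export
resolve_site <- function(spec, topology, mass_weighted = TRUE) {
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
  } else {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("bad site specifier: ", spec, call. = FALSE)
    kind <- tolower(parts[1]); arg <- parts[2]
    idx <- switch(kind,
      ca = which(topology$name == "CA" & topology$resno == as.integer(arg)),
      atom = which(topology$eleno == as.integer(arg)),
      com = {
        rg <- as.integer(strsplit(arg, "-", fixed = TRUE)[[1]])
        if (length(rg) == 1) rg <- c(rg, rg)
        which(topology$resno >= rg[1] & topology$resno <= rg[2])
      },
      stop("unknown site kind: ", kind, call. = FALSE))
  }
  if (!length(idx)) stop("site specifier matches no atoms: ",
                         paste(spec, collapse = ","), call. = FALSE)
  w <- if (mass_weighted && length(idx) > 1) topology$mass[idx] else rep(1, length(idx))
  list(idx = idx, w = w / sum(w))
}

# weighted site position per frame: n_frames x 3
site_positions <- function(frames, site) {
  xs <- frames$xyz[, 3 * (site$idx - 1) + 1, drop = FALSE] %*% site$w
  ys <- frames$xyz[, 3 * (site$idx - 1) + 2, drop = FALSE] %*% site$w
  zs <- frames$xyz[, 3 * site$idx, drop = FALSE] %*% site$w
  cbind(xs, ys, zs)
}

#' Per-frame distance between two sites
#'
#' Euclidean distance between two resolved sites (atoms, residue CAs or
#' domain centers of mass) in every frame.
#'
#' @param frames Frame series.
#' @param topology Atom table.
#' @param a,b Site specifiers (see [resolve_site()]).
#' @param mass_weighted Mass-weight multi-atom sites (default TRUE).
#' @return A list with `label`, `values` (Angstrom, one per frame).
#' @export
distance_series <- function(frames, topology, a, b, mass_weighted = TRUE) {
  sa <- resolve_site(a, topology, mass_weighted)
  sb <- resolve_site(b, topology, mass_weighted)
  pa <- site_positions(frames, sa)
  pb <- site_positions(frames, sb)
  list(label = paste0(format(a), "|", format(b)),
       values = sqrt(rowSums((pa - pb)^2)))
}

#' Per-frame radius of gyration of a residue selection
#'
#' Rg = sqrt( sum_k m_k |x_k - xbar|^2 / sum_k m_k ), equal by construction
#' to the square root of the trace of the gyration-tensor eigenvalues.
#' A single-atom selection returns 0 with a warning.
#'
#' @param frames Frame series.
#' @param topology Atom table.
#' @param residues Integer vector of residue numbers (all atoms used).
#' @param mass_weighted Mass-weight (default TRUE); FALSE gives the
#'   geometric radius of gyration.
#' @return Numeric vector of per-frame Rg, Angstrom.
#' @export
gyration_radius_series <- function(frames, topology, residues,
                                   mass_weighted = TRUE) {
  idx <- which(topology$resno %in% residues)
  if (!length(idx)) stop("no atoms in the residue selection", call. = FALSE)
  if (length(idx) == 1) {
    warning("single-atom selection; radius of gyration is 0")
    return(rep(0, frames$n_frames))
  }
  w <- if (mass_weighted) topology$mass[idx] else rep(1, length(idx))
  w <- w / sum(w)
  xs <- frames$xyz[, 3 * (idx - 1) + 1, drop = FALSE]
  ys <- frames$xyz[, 3 * (idx - 1) + 2, drop = FALSE]
  zs <- frames$xyz[, 3 * idx, drop = FALSE]
  cx <- xs %*% w; cy <- ys %*% w; cz <- zs %*% w
  msd <- (xs - cx[, 1])^2 %*% w + (ys - cy[, 1])^2 %*% w + (zs - cz[, 1])^2 %*% w
  sqrt(msd[, 1])
}

#' Per-frame heavy-atom contact number for a residue pair
#'
#' Counts, in each frame, the heavy-atom pairs (one atom from each residue)
#' whose distance is at most `cutoff` Angstrom. Symmetric in (i, j).
#'
#' @param frames Frame series.
#' @param topology Atom table.
#' @param i,j Residue numbers (i != j).
#' @param cutoff Contact cutoff, Angstrom (default 4.5, inclusive).
#' @return List with `i`, `j` (ordered i < j), `sequence_separation`,
#'   `counts` (integer per frame).
#' @export
contact_number_series <- function(frames, topology, i, j, cutoff = 4.5) {
  if (i == j) stop("contact number needs two distinct residues", call. = FALSE)
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  ai <- which(topology$resno == i & topology$heavy)
  aj <- which(topology$resno == j & topology$heavy)
  if (!length(ai) || !length(aj))
    stop("residue without heavy atoms: ", if (!length(ai)) i else j, call. = FALSE)
  counts <- integer(frames$n_frames)
  cut2 <- cutoff^2
  for (a in ai) {
    dx <- frames$xyz[, 3 * (aj - 1) + 1, drop = FALSE] - frames$xyz[, 3 * (a - 1) + 1]
    dy <- frames$xyz[, 3 * (aj - 1) + 2, drop = FALSE] - frames$xyz[, 3 * (a - 1) + 2]
    dz <- frames$xyz[, 3 * aj, drop = FALSE] - frames$xyz[, 3 * a]
    counts <- counts + rowSums(dx^2 + dy^2 + dz^2 <= cut2)
  }
  list(i = i, j = j, sequence_separation = j - i, counts = as.integer(counts))
}

#' Contact-number series for all intradomain residue pairs
#'
#' @param frames Frame series.
#' @param topology Atom table.
#' @param ranges Domain ranges; pairs are formed within each listed domain.
#' @param domains Domains to scan (default all in `ranges`).
#' @param cutoff Contact cutoff, Angstrom.
#' @return Named list of contact series (names `"i-j"`), each as returned
#'   by [contact_number_series()] plus a `domain` field.
#' @export
intradomain_contacts <- function(frames, topology, ranges,
                                 domains = names(ranges), cutoff = 4.5) {
  out <- list()
  for (dom in domains) {
    res <- sort(unique(topology$resno[topology$resno >= ranges[[dom]][1] &
                                      topology$resno <= ranges[[dom]][2]]))
    if (length(res) < 2) next
    for (x in seq_along(res)[-length(res)]) {
      for (y in seq((x + 1), length(res))) {
        cs <- contact_number_series(frames, topology, res[x], res[y], cutoff)
        cs$domain <- dom
        out[[paste0(res[x], "-", res[y])]] <- cs
      }
    }
  }
  out
}

#' Select residue pairs with fluctuating contact numbers
#'
#' Retains intradomain pairs whose contact-number series has nonzero
#' variance; constant pairs (including all-zero) carry no correlation
#' information. Pairs at sequence separation >= `flag_separation` are
#' flagged, mirroring the convention of highlighting non-local contacts.
#'
#' @param contacts Named list of contact series (see
#'   [intradomain_contacts()]).
#' @param flag_separation Sequence-separation flag threshold (default 3).
#' @return Data.frame with `pair`, `i`, `j`, `domain`,
#'   `sequence_separation`, `nonlocal` (separation >= flag), `variance`;
#'   one row per retained pair. Per-domain counts are in
#'   `attr(, "domain_counts")`.
#' @export
select_fluctuating_pairs <- function(contacts, flag_separation = 3L) {
  keep <- lapply(names(contacts), function(nm) {
    cs <- contacts[[nm]]
    v <- stats::var(cs$counts)
    if (is.na(v) || v == 0) return(NULL)
    data.frame(pair = nm, i = cs$i, j = cs$j,
               domain = if (is.null(cs$domain)) NA_character_ else cs$domain,
               sequence_separation = cs$sequence_separation,
               nonlocal = cs$sequence_separation >= flag_separation,
               variance = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, keep)
  if (is.null(out)) out <- data.frame(pair = character(0), i = integer(0),
                                      j = integer(0), domain = character(0),
                                      sequence_separation = integer(0),
                                      nonlocal = logical(0), variance = numeric(0))
  rownames(out) <- NULL
  attr(out, "domain_counts") <- table(out$domain)
  out
}

#' Hydrogen-bond occupancies over a trajectory
#'
#' A hydrogen bond is present in a frame when the donor-heavy to
#' acceptor-heavy distance is at most `dist_cutoff` Angstrom and the
#' D-H...A angle (at the hydrogen; 180 degrees is linear) is at least
#' `angle_cutoff` degrees. Bonds are keyed by (donor hydrogen, acceptor
#' atom); the occupancy O of a bond is the fraction of frames in which it
#' is present, and the residue-pair metric Pi_XY is the sum of occupancies
#' of all bonds between residues X and Y.
#'
#' @param frames Frame series.
#' @param topology Atom table with donor/acceptor roles (see
#'   [read_structure_trajectory()]).
#' @param residues Optional residue subset to restrict both partners to.
#' @param dist_cutoff Heavy-heavy distance cutoff, Angstrom (default 3.2).
#' @param angle_cutoff D-H...A angle cutoff, degrees (default 135).
#' @param min_occupancy Drop bonds below this occupancy (default: keep
#'   any bond seen at least once).
#' @return A list with `bonds` (data.frame: `donor_res`, `acceptor_res`,
#'   `donor_atom`, `h_atom`, `acceptor_atom`, `occupancy`), `pairs`
#'   (data.frame: `donor_res`, `acceptor_res`, `pi` = summed occupancy,
#'   `n_bonds`) and `presence` (frames x bonds logical matrix, for
#'   per-cluster re-aggregation).
#' @export
hbond_occupancy <- function(frames, topology, residues = NULL,
                            dist_cutoff = 3.2, angle_cutoff = 135,
                            min_occupancy = NULL) {
  if (!any(topology$donor)) stop("topology has no annotated donors", call. = FALSE)
  hs <- which(!is.na(topology$h_of) & topology$donor[topology$h_of])
  acc <- which(topology$acceptor)
  if (!is.null(residues)) {
    hs <- hs[topology$resno[hs] %in% residues]
    acc <- acc[topology$resno[acc] %in% residues]
  }
  if (!length(hs)) stop("no donor hydrogens in the selection", call. = FALSE)
  cos_cut <- cos(angle_cutoff * pi / 180)
  cut2 <- dist_cutoff^2

  keys <- list(); pres <- list()
  for (h in hs) {
    d <- topology$h_of[h]
    a_cand <- acc[acc != d & topology$resno[acc] != topology$resno[d]]
    if (!length(a_cand)) next
    hx <- frames$xyz[, 3 * (h - 1) + 1]; hy <- frames$xyz[, 3 * (h - 1) + 2]
    hz <- frames$xyz[, 3 * h]
    dxd <- frames$xyz[, 3 * (d - 1) + 1] - hx
    dyd <- frames$xyz[, 3 * (d - 1) + 2] - hy
    dzd <- frames$xyz[, 3 * d] - hz
    nd <- sqrt(dxd^2 + dyd^2 + dzd^2)
    for (a in a_cand) {
      ddx <- frames$xyz[, 3 * (a - 1) + 1] - frames$xyz[, 3 * (d - 1) + 1]
      ddy <- frames$xyz[, 3 * (a - 1) + 2] - frames$xyz[, 3 * (d - 1) + 2]
      ddz <- frames$xyz[, 3 * a] - frames$xyz[, 3 * d]
      near <- ddx^2 + ddy^2 + ddz^2 <= cut2
      if (!any(near)) next
      axh <- frames$xyz[, 3 * (a - 1) + 1] - hx
      ayh <- frames$xyz[, 3 * (a - 1) + 2] - hy
      azh <- frames$xyz[, 3 * a] - hz
      na_ <- sqrt(axh^2 + ayh^2 + azh^2)
      cosang <- (dxd * axh + dyd * ayh + dzd * azh) / (nd * na_)
      present <- near & cosang <= cos_cut  # angle >= cutoff
      if (!any(present)) next
      keys[[length(keys) + 1L]] <- c(d, h, a)
      pres[[length(pres) + 1L]] <- present
    }
  }
  if (!length(keys)) {
    bonds <- data.frame(donor_res = integer(0), acceptor_res = integer(0),
                        donor_atom = integer(0), h_atom = integer(0),
                        acceptor_atom = integer(0), occupancy = numeric(0))
    return(list(bonds = bonds,
                pairs = data.frame(donor_res = integer(0), acceptor_res = integer(0),
                                   pi = numeric(0), n_bonds = integer(0)),
                presence = matrix(FALSE, frames$n_frames, 0)))
  }
  km <- do.call(rbind, keys)
  presence <- do.call(cbind, pres)
  occ <- colMeans(presence)
  bonds <- data.frame(donor_res = topology$resno[km[, 1]],
                      acceptor_res = topology$resno[km[, 3]],
                      donor_atom = km[, 1], h_atom = km[, 2],
                      acceptor_atom = km[, 3], occupancy = occ)
  if (!is.null(min_occupancy)) {
    keep <- occ >= min_occupancy
    bonds <- bonds[keep, , drop = FALSE]
    presence <- presence[, keep, drop = FALSE]
  }
  key <- paste(bonds$donor_res, bonds$acceptor_res)
  pairs <- do.call(rbind, lapply(split(seq_len(nrow(bonds)), key), function(rows)
    data.frame(donor_res = bonds$donor_res[rows[1]],
               acceptor_res = bonds$acceptor_res[rows[1]],
               pi = sum(bonds$occupancy[rows]), n_bonds = length(rows))))
  rownames(pairs) <- rownames(bonds) <- NULL
  list(bonds = bonds, pairs = pairs, presence = presence)
}
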