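#' Read a relaxation-decay table
#'
#' Parses a delimited text file of per-residue peak intensities versus
#' relaxation delay into a list of decay series. The file must have a
#' header naming a residue column, a delay column and an intensity column;
#' duplicate delays (repeat measurements used for noise estimation) are
#' preserved as separate rows, never averaged.
#'
#' Delays are stored in seconds internally. Files may carry delays in
#' milliseconds by naming the column `delay_ms`; a plain `delay` column is
#' taken as seconds.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @param min_delays Minimum number of distinct delays required per
#'   residue (default 4).
#' @return A named list of decay series, one per residue, each a list with
#'   `residue` (integer), `delays` (seconds), `intensities`,
#'   `duplicate_mask` (logical, TRUE for rows whose delay value occurs more
#'   than once) and `replicate` (integer replicate id within a delay).
#' @export
read_decay_table <- function(path, min_delays = 4L) {
  if (!file.exists(path)) stop("decay table not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(trimws(first)))
    stop("decay table is empty: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  tbl <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tbl) == 0L) stop("decay table has a header but no rows: ", path, call. = FALSE)
  cn <- tolower(names(tbl))
  res_col <- match("residue", cn)
  delay_col <- match("delay", cn)
  unit <- 1
  if (is.na(delay_col)) {
    delay_col <- match("delay_ms", cn)
    unit <- 1e-3
  }
  int_col <- match("intensity", cn)
  if (is.na(res_col) || is.na(delay_col) || is.na(int_col))
    stop("decay table must have columns residue, delay (or delay_ms), intensity",
         call. = FALSE)

  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
      stop("non-numeric ", what, " at data row ", bad[1], ": '", x[bad[1]], "'",
           call. = FALSE)
    v
  }
  residue <- num(tbl[[res_col]], "residue")
  delay <- num(tbl[[delay_col]], "delay") * unit
  intensity <- num(tbl[[int_col]], "intensity")
  if (any(!is.finite(delay)) || any(delay <= 0))
    stop("delays must be finite and > 0", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)

  out <- lapply(split(seq_len(nrow(tbl)), residue), function(rows) {
    d <- delay[rows]
    if (length(unique(d)) < min_delays)
      stop("residue ", residue[rows[1]], " has fewer than ", min_delays,
           " distinct delays", call. = FALSE)
    dup <- ave(d, d, FUN = length) > 1
    rep_id <- ave(seq_along(d), d, FUN = seq_along)
    list(residue = as.integer(residue[rows[1]]),
         delays = d,
         intensities = intensity[rows],
         duplicate_mask = dup,
         replicate = as.integer(rep_id))
  })
  names(out) <- vapply(out, function(s) as.character(s$residue), character(1))
  out
}

element_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38)

infer_elements <- function(pdb) {
  ele <- toupper(trimws(pdb$atom$elesy))
  bad <- is.na(ele) | !nzchar(ele)
  if (any(bad)) {
    # name-based fallback: strip digits, take leading element symbol
    nm <- toupper(gsub("[0-9'\"]", "", pdb$atom$elety[bad]))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    guess <- ifelse(two %in% c("SE", "FE", "ZN", "CL", "BR", "MG", "NA"), two, one)
    ele[bad] <- guess
  }
  ele
}

#' Read a structure and coordinate trajectory
#'
#' Loads a reference PDB structure plus a multi-frame trajectory
#' (multi-model PDB or DCD) and returns the atom topology together with the
#' per-frame coordinates in Angstrom. Elements come from the PDB element
#' column with a name-convention fallback; hydrogen-bond donor/acceptor
#' roles are annotated from the reference geometry (N/O heavy atoms with an
#' attached hydrogen within `h_attach` Angstrom are donors; N/O heavy atoms
#' are acceptors).
#'
#' @param structure Path to a single-model PDB file.
#' @param trajectory Path to a multi-model PDB or a DCD file; `NULL` uses
#'   the structure's own model(s) as the trajectory.
#' @param frame_interval_ps Time between saved frames, picoseconds.
#' @param h_attach Covalent H-attachment cutoff in Angstrom (default 1.25).
#' @return A list with `topology` (see Details) and `frames`, a frame
#'   series: list(`xyz` = frames x 3N matrix, `n_frames`, `n_atoms`,
#'   `frame_interval_ps`). The topology is a data.frame with one row per
#'   atom: `eleno`, `name`, `resno`, `resname`, `element`, `heavy`, `mass`,
#'   `donor` (heavy atom with attached H), `acceptor`, `h_of` (for
#'   hydrogens, the row index of the heavy donor they ride on).
#' @export
read_structure_trajectory <- function(structure, trajectory = NULL,
                                      frame_interval_ps = 200,
                                      h_attach = 1.25) {
  pdb <- tryCatch(bio3d::read.pdb(structure, verbose = FALSE),
                  error = function(e) stop("cannot read structure PDB '",
                                           structure, "': ", conditionMessage(e),
                                           call. = FALSE))
  ele <- infer_elements(pdb)
  heavy <- !(ele %in% c("H", "D"))
  mass <- unname(element_masses[ele])
  if (anyNA(mass)) {
    unknown <- unique(ele[is.na(mass)])
    stop("unknown element(s) in structure: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n_atoms <- nrow(pdb$atom)

  topo <- data.frame(eleno = pdb$atom$eleno,
                     name = trimws(pdb$atom$elety),
                     resno = pdb$atom$resno,
                     resname = trimws(pdb$atom$resid),
                     element = ele, heavy = heavy, mass = mass,
                     stringsAsFactors = FALSE)

  # hydrogen-bond roles from the reference coordinates
  ref <- matrix(pdb$xyz[1, , drop = TRUE][seq_len(3 * n_atoms)],
                ncol = 3, byrow = TRUE)
  topo$h_of <- NA_integer_
  hyd <- which(!heavy)
  for (h in hyd) {
    cand <- which(heavy & topo$resno == topo$resno[h])
    if (!length(cand)) next
    dd <- sqrt(colSums((t(ref[cand, , drop = FALSE]) - ref[h, ])^2))
    if (min(dd) <= h_attach) topo$h_of[h] <- cand[which.min(dd)]
  }
  topo$donor <- heavy & topo$element %in% c("N", "O") &
    seq_len(n_atoms) %in% topo$h_of[!is.na(topo$h_of)]
  topo$acceptor <- heavy & topo$element %in% c("N", "O")

  xyz <- if (is.null(trajectory)) {
    unclass(pdb$xyz)
  } else if (grepl("\\.dcd$", trajectory, ignore.case = TRUE)) {
    tryCatch(unclass(bio3d::read.dcd(trajectory, verbose = FALSE)),
             error = function(e) stop("cannot read DCD trajectory '", trajectory,
                                      "': ", conditionMessage(e), call. = FALSE))
  } else if (grepl("\\.xtc$", trajectory, ignore.case = TRUE)) {
    stop("XTC trajectories are not supported; convert to DCD or multi-model PDB",
         call. = FALSE)
  } else {
    tr <- tryCatch(bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE),
                   error = function(e) stop("cannot read trajectory PDB '",
                                            trajectory, "': ",
                                            conditionMessage(e), call. = FALSE))
    unclass(tr$xyz)
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_atoms)
    stop("atom-count mismatch: structure has ", n_atoms, " atoms, trajectory frames have ",
         ncol(xyz) / 3, call. = FALSE)
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory", call. = FALSE)

  frames <- frame_series(xyz, frame_interval_ps)
  list(topology = topo, frames = frames)
}

#' Construct a frame series from a coordinate matrix
#'
#' @param xyz Numeric matrix, frames x 3N, bio3d column order
#'   (x1, y1, z1, x2, ...), Angstrom.
#' @param frame_interval_ps Frame spacing in picoseconds.
#' @return A list with `xyz`, `n_frames`, `n_atoms`, `frame_interval_ps`.
#' @export
frame_series <- function(xyz, frame_interval_ps = 200) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) %% 3L != 0L) stop("xyz must have 3N columns", call. = FALSE)
  if (any(!is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  list(xyz = xyz, n_frames = nrow(xyz), n_atoms = ncol(xyz) %/% 3L,
       frame_interval_ps = frame_interval_ps)
}

# coordinates of one frame as an n_atoms x 3 matrix
frame_coords <- function(frames, f) {
  matrix(frames$xyz[f, ], ncol = 3, byrow = TRUE)
}

#' Write a results table
#'
#' Serializes a homogeneous results data.frame as tab-separated text with
#' full numeric precision (round-trip stable to well below 1e-9 relative
#' error); status flags and labels are written as plain strings.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame", call. = FALSE)
  rec <- records
  for (j in seq_along(rec))
    if (is.numeric(rec[[j]])) rec[[j]] <- sprintf("%.17g", rec[[j]])
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to a tab-separated results file.
#' @return A data.frame; columns that parse fully as numbers are numeric,
#'   the rest stay character.
#' @export
read_results <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (j in seq_along(tbl)) {
    v <- suppressWarnings(as.numeric(tbl[[j]]))
    if (!anyNA(v[!is.na(tbl[[j]]) & nzchar(tbl[[j]])])) {
      miss <- is.na(tbl[[j]]) | tbl[[j]] %in% c("", "NA")
      v[miss] <- NA_real_
      if (all(is.na(v) == miss)) tbl[[j]] <- v
    }
  }
  tbl
}

#' Write a multi-model PDB trajectory
#'
#' Emits a valid multi-model PDB so the package's own readers can be
#' exercised end-to-end on generated data.
#'
#' @param topology Atom table as produced by [read_structure_trajectory()]
#'   (columns `eleno`, `name`, `resno`, `resname`, `element` are used).
#' @param frames Frame series; `models` selects which frames to write.
#' @param path Output path.
#' @param models Integer vector of frame indices (default: all).
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(topology, frames, path, models = seq_len(frames$n_frames)) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(topology)
  for (m in models) {
    xyz <- frame_coords(frames, m)
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     topology$eleno, substr(topology$name, 1, 4),
                     substr(topology$resname, 1, 3), topology$resno,
                     xyz[, 1], xyz[, 2], xyz[, 3], topology$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
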