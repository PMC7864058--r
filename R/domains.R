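#' Default Pin1 domain boundaries
#'
#' Residue ranges for the three sequence regions of human Pin1: the
#' N-terminal WW domain (residues 1-39), the flexible interdomain linker
#' (40-52) and the C-terminal PPIase domain (53-163). Boundaries are
#' inclusive on both ends.
#'
#' @return A named list of length-2 integer vectors `c(start, end)` with
#'   elements `WW`, `LINKER`, `PPIASE`.
#' @export
#' @examples
#' pin1_domains()
pin1_domains <- function() {
  list(WW = c(1L, 39L), LINKER = c(40L, 52L), PPIASE = c(53L, 163L))
}

check_domain_ranges <- function(ranges) {
  if (!is.list(ranges) || is.null(names(ranges)) || any(!nzchar(names(ranges))))
    stop("`ranges` must be a named list of c(start, end) vectors", call. = FALSE)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2L || !is.numeric(rg) || any(!is.finite(rg)) || rg[1] > rg[2] || rg[1] < 1)
      stop("invalid range for domain '", nm, "'", call. = FALSE)
  }
  invisible(ranges)
}

#' Assign residues to domains
#'
#' Maps a 1-based residue index to its domain label. The assignment is a
#' pure function of the index given the configured ranges; boundaries are
#' inclusive, so with the defaults residue 39 is `WW`, 40 and 52 are
#' `LINKER`, and 53 is `PPIASE`.
#'
#' @param index Integer vector of residue positions (>= 1).
#' @param ranges Named list of inclusive `c(start, end)` ranges, as from
#'   [pin1_domains()].
#' @return Character vector of domain labels, same length as `index`.
#'   Indices outside every range raise an error (no silent `NA`s).
#' @export
#' @examples
#' assign_domain(c(27, 45, 98))
assign_domain <- function(index, ranges = pin1_domains()) {
  check_domain_ranges(ranges)
  if (any(!is.finite(index)) || any(index < 1) || any(index != round(index)))
    stop("residue index must be a positive integer", call. = FALSE)
  out <- rep(NA_character_, length(index))
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    hit <- index >= rg[1] & index <= rg[2]
    out[hit] <- nm
  }
  if (anyNA(out))
    stop("residue index unassigned by the configured domain ranges: ",
         paste(index[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Residue identifier table
#'
#' Small constructor for the per-residue bookkeeping used across the
#' package: index, 3-letter residue name, and domain label derived from
#' `ranges`.
#'
#' @param index Integer vector of 1-based residue positions.
#' @param name Character vector of 3-letter amino-acid codes (recycled).
#' @param ranges Domain ranges, see [assign_domain()].
#' @return A data.frame with columns `index`, `name`, `domain`.
#' @export
residue_id <- function(index, name = "ALA", ranges = pin1_domains()) {
  data.frame(index = as.integer(index),
             name = rep_len(toupper(name), length(index)),
             domain = assign_domain(index, ranges),
             stringsAsFactors = FALSE)
}
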