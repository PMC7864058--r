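#' Two-cluster average-linkage partition of a scalar series
#'
#' Agglomerative average-linkage clustering of a one-dimensional series
#' (typically a per-frame interdomain distance) cut at two clusters. In
#' one dimension average-linkage clusters are contiguous intervals of the
#' sorted values, and the average inter-cluster distance between two
#' disjoint intervals equals the difference of their means, so the exact
#' dendrogram is built by repeatedly merging the adjacent pair of runs
#' with the smallest mean difference (ties broken toward the lower sorted
#' position, i.e. lower frame index among equals). This matches naive
#' O(n^2) pairwise-matrix average linkage label-for-label.
#'
#' For very long series (`n > max_frames`) a deterministic stride
#' subsample is clustered and the remaining frames are assigned to the
#' nearer cluster mean; the stride is recorded in the result.
#'
#' @param values Numeric series with at least 2 distinct values.
#' @param max_frames Linkage size guard (default 50,000).
#' @return A list with `labels` (per-frame, `"COMPACT"` = lower-mean
#'   cluster, `"EXTENDED"` = higher), `means` (named, Angstrom if the
#'   input is), `sizes`, `stride`.
#' @export
average_linkage_2cluster <- function(values, max_frames = 50000L) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (diff(range(values)) == 0)
    stop("all values identical; no 2-cluster structure", call. = FALSE)

  stride <- 1L
  idx <- seq_len(n)
  if (n > max_frames) {
    stride <- ceiling(n / max_frames)
    idx <- seq(1L, n, by = stride)
  }
  v <- values[idx]
  o <- order(v)
  sv <- v[o]
  m <- length(sv)

  # contiguous runs over the sorted values: linked list with means/sizes
  mean_ <- sv
  size <- rep(1L, m)
  nxt <- c(2:m, NA_integer_)
  prv <- c(NA_integer_, 1:(m - 1))
  gap <- c(diff(mean_), Inf)           # gap[i] = mean(next(i)) - mean(i)
  active_gap <- c(rep(TRUE, m - 1), FALSE)
  n_clusters <- m
  while (n_clusters > 2L) {
    g <- gap
    g[!active_gap] <- Inf
    i <- which.min(g)                  # first minimum = lowest sorted position
    j <- nxt[i]
    tot <- size[i] + size[j]
    mean_[i] <- (mean_[i] * size[i] + mean_[j] * size[j]) / tot
    size[i] <- tot
    nxt[i] <- nxt[j]
    if (!is.na(nxt[j])) prv[nxt[j]] <- i
    active_gap[j] <- FALSE
    gap[i] <- if (is.na(nxt[i])) Inf else mean_[nxt[i]] - mean_[i]
    active_gap[i] <- !is.na(nxt[i])
    if (!is.na(prv[i])) gap[prv[i]] <- mean_[i] - mean_[prv[i]]
    n_clusters <- n_clusters - 1L
  }
  # two contiguous runs remain; boundary = size of the first
  head_id <- 1L
  while (!is.na(prv[head_id])) head_id <- prv[head_id]
  b <- size[head_id]
  lab_sorted <- rep(c(1L, 2L), c(b, m - b))
  lab_sub <- integer(m)
  lab_sub[o] <- lab_sorted
  mu <- c(mean(v[lab_sub == 1L]), mean(v[lab_sub == 2L]))
  lo <- which.min(mu)

  labels <- character(n)
  if (stride == 1L) {
    labels <- ifelse(lab_sub == lo, "COMPACT", "EXTENDED")
  } else {
    cutpt <- mean(c(max(sv[seq_len(b)]), min(sv[seq(b + 1L, m)])))
    labels <- ifelse((values <= cutpt) == (lo == 1L), "COMPACT", "EXTENDED")
  }
  means <- c(COMPACT = mean(values[labels == "COMPACT"]),
             EXTENDED = mean(values[labels == "EXTENDED"]))
  list(labels = labels, means = means,
       sizes = c(COMPACT = sum(labels == "COMPACT"),
                 EXTENDED = sum(labels == "EXTENDED")),
       stride = stride)
}

#' Per-cluster contrast of contacts and hydrogen bonds
#'
#' Recomputes mean contact numbers and hydrogen-bond occupancies over the
#' member frames of each cluster and tabulates the differences
#' (EXTENDED - COMPACT), the quantity used to ask how intradomain geometry
#' differs between the proximal- and distal-domain subensembles.
#'
#' @param labels Per-frame cluster labels (`"COMPACT"`/`"EXTENDED"`).
#' @param contacts Named list of contact series (each with `counts`).
#' @param hbonds Optional result of [hbond_occupancy()] (uses `presence`
#'   and `bonds`).
#' @return A list with `contacts` (data.frame `pair`, `mean_compact`,
#'   `mean_extended`, `difference`) and, when `hbonds` is given, `hbonds`
#'   (per-bond occupancies per cluster) and `hbond_pairs` (per residue
#'   pair: Pi per cluster and difference).
#' @export
cluster_contrast <- function(labels, contacts, hbonds = NULL) {
  cmp <- labels == "COMPACT"
  ext <- labels == "EXTENDED"
  if (!any(cmp) || !any(ext)) stop("empty cluster", call. = FALSE)

  ct <- do.call(rbind, lapply(names(contacts), function(nm) {
    v <- contacts[[nm]]$counts
    if (length(v) != length(labels)) stop("labels not aligned with frames", call. = FALSE)
    data.frame(pair = nm, mean_compact = mean(v[cmp]), mean_extended = mean(v[ext]),
               stringsAsFactors = FALSE)
  }))
  ct$difference <- ct$mean_extended - ct$mean_compact

  out <- list(contacts = ct)
  if (!is.null(hbonds) && ncol(hbonds$presence)) {
    if (nrow(hbonds$presence) != length(labels))
      stop("labels not aligned with frames", call. = FALSE)
    occ_c <- colMeans(hbonds$presence[cmp, , drop = FALSE])
    occ_e <- colMeans(hbonds$presence[ext, , drop = FALSE])
    hb <- hbonds$bonds
    hb$occupancy_compact <- occ_c
    hb$occupancy_extended <- occ_e
    hb$difference <- occ_e - occ_c
    key <- paste(hb$donor_res, hb$acceptor_res)
    hp <- do.call(rbind, lapply(split(seq_len(nrow(hb)), key), function(rows)
      data.frame(donor_res = hb$donor_res[rows[1]],
                 acceptor_res = hb$acceptor_res[rows[1]],
                 pi_compact = sum(occ_c[rows]), pi_extended = sum(occ_e[rows]))))
    hp$difference <- hp$pi_extended - hp$pi_compact
    rownames(hp) <- NULL
    out$hbonds <- hb
    out$hbond_pairs <- hp
  }
  out
}
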