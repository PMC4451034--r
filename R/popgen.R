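#' Segregating sites and pairwise diversity over a set of columns
#'
#' Columns containing any gap (`-`) or `N` are excluded (complete deletion
#' over the supplied columns). `S` counts polymorphic retained columns;
#' `pi_total` is the average over all sequence pairs of the number of
#' differing retained columns (total, not per site).
#'
#' @param aln a `clone_alignment` with >= 2 records.
#' @param columns columns to use (default all).
#' @return list with `S`, `pi_total`, `n` (sequences), `n_sites_used`.
#' @export
site_stats <- function(aln, columns = NULL) {
  n <- n_records(aln)
  if (n < 2L) stop("need >= 2 sequences")
  mat <- aln$seq
  if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
  keep <- colSums(mat == "-" | mat == "N") == 0L
  mat <- mat[, keep, drop = FALSE]
  n_used <- ncol(mat)
  if (n_used == 0L) {
    return(list(S = 0L, pi_total = 0, n = n, n_sites_used = 0L))
  }
  poly <- apply(mat, 2L, function(col) length(unique(col)) > 1L)
  S <- sum(poly)
  diffs <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diffs <- diffs + sum(mat[i, ] != mat[j, ])
    }
  }
  pi_total <- diffs / (n * (n - 1) / 2)
  list(S = as.integer(S), pi_total = pi_total, n = n,
       n_sites_used = as.integer(n_used))
}

harmonic_a1 <- function(n) sum(1 / seq_len(n - 1L))

#' Watterson's theta per site
#'
#' @param S segregating sites.
#' @param n number of sequences.
#' @param n_sites number of sites the estimate is scaled by.
#' @return theta_W per site = S / (a1 * n_sites).
#' @export
theta_watterson <- function(S, n, n_sites) {
  if (n < 2L) stop("need n >= 2")
  if (n_sites == 0L) return(NA_real_)
  S / (harmonic_a1(n) * n_sites)
}

#' Tajima's D from segregating sites and total pairwise diversity
#'
#' D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1)) with the standard
#' sample-size coefficients a1, a2, b1, b2, c1, c2, e1, e2. Undefined
#' (returned as `NA` with attribute `undefined = TRUE`) when S = 0.
#'
#' @param S segregating sites.
#' @param pi_total total (not per-site) mean pairwise differences.
#' @param n number of sequences (>= 2; >= 4 recommended).
#' @return numeric D, or NA when S = 0.
#' @export
tajimas_D <- function(S, pi_total, n) {
  if (n < 2L) stop("need n >= 2")
  if (S == 0L) return(structure(NA_real_, undefined = TRUE))
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Sliding-window diversity statistics
#'
#' Windows start at columns 0, step, 2*step, ... (0-based internally);
#' the default window of 100 bp with a 25 bp step matches the windowing
#' used in published cathelicidin scans. A trailing short window is
#' dropped unless `keep_tail = TRUE`. Windows with fewer than 10 gap-free
#' sites are flagged low-confidence.
#'
#' @param aln a `clone_alignment`.
#' @param window window length in alignment columns (default 100).
#' @param step step size (default 25); must satisfy window >= step >= 1.
#' @param keep_tail keep a trailing short window.
#' @return data.frame of window statistics, one row per window: `start`,
#'   `end` (1-based inclusive alignment columns), `n_sites_used`, `S`,
#'   `pi` and `theta_w` (per site), `tajima_D`, `low_confidence`.
#' @export
sliding_windows <- function(aln, window = 100L, step = 25L,
                            keep_tail = FALSE) {
  stopifnot(window >= step, step >= 1L)
  L <- n_columns(aln)
  if (window > L) {
    warning("window longer than alignment; using one full-length window")
    window <- L
  }
  starts <- seq.int(0L, max(L - window, 0L), by = step)
  if (keep_tail) {
    extra <- seq.int(0L, L - 1L, by = step)
    starts <- unique(c(starts, extra[extra + window > L]))
  }
  rows <- lapply(starts, function(s) {
    cols <- (s + 1L):min(s + window, L)
    st <- site_stats(aln, cols)
    per_site <- if (st$n_sites_used > 0L) st$n_sites_used else NA_integer_
    data.frame(
      start = s + 1L, end = min(s + window, L),
      n_sites_used = st$n_sites_used, S = st$S,
      pi = if (st$n_sites_used > 0) st$pi_total / st$n_sites_used else NA_real_,
      theta_w = theta_watterson(st$S, st$n, st$n_sites_used),
      tajima_D = as.numeric(tajimas_D(st$S, st$pi_total, st$n)),
      low_confidence = st$n_sites_used < 10L)
  })
  do.call(rbind, rows)
}

#' Four-gamete test over all pairs of biallelic sites
#'
#' Reports every pair of biallelic sites at which all four haplotype
#' combinations occur, the classic signature of recombination (or
#' recurrent mutation). Sequences with a gap at either site of a pair are
#' dropped pairwise.
#'
#' @param aln a `clone_alignment`.
#' @param maf_min minimum minor-allele count for a site to enter
#'   (default 1: all biallelic sites).
#' @return data.frame (site_i, site_j) of four-gamete pairs (1-based
#'   alignment columns); zero rows when none.
#' @export
four_gamete_pairs <- function(aln, maf_min = 1L) {
  sites <- biallelic_sites(aln, maf_min)
  out <- list()
  if (length(sites) >= 2L) {
    mat <- aln$seq
    for (a in seq_len(length(sites) - 1L)) {
      for (b in (a + 1L):length(sites)) {
        i <- sites[a]; j <- sites[b]
        ok <- !(mat[, i] %in% c("-", "N")) & !(mat[, j] %in% c("-", "N"))
        haps <- unique(paste0(mat[ok, i], mat[ok, j]))
        if (length(haps) == 4L) {
          out[[length(out) + 1L]] <- data.frame(site_i = i, site_j = j)
        }
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(site_i = integer(0), site_j = integer(0))
  } else {
    do.call(rbind, out)
  }
}
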