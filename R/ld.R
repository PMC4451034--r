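#' Biallelic sites passing a minor-allele-count filter
#'
#' Retains alignment columns with exactly two non-gap states where the
#' minor state occurs in at least `maf_min` sequences. The threshold is a
#' count (e.g. 3 of 36 sequences), mirroring how figure captions state it.
#' Columns containing a gap or N are excluded.
#'
#' @param aln a `clone_alignment`.
#' @param maf_min minimum minor-allele count (>= 1).
#' @return sorted integer vector of 1-based alignment columns.
#' @export
biallelic_sites <- function(aln, maf_min = 1L) {
  stopifnot(maf_min >= 1L)
  mat <- aln$seq
  keep <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (any(col == "-" | col == "N")) next
    tab <- table(col)
    if (length(tab) == 2L && min(tab) >= maf_min) keep[j] <- TRUE
  }
  which(keep)
}

#' Pairwise linkage disequilibrium D' for two biallelic sites
#'
#' With A, B the major alleles at the two sites (ties broken
#' alphabetically), D = p_AB - p_A * p_B and D' = D / Dmax, where Dmax is
#' min(p_A (1-p_B), (1-p_A) p_B) for D > 0 and
#' min(p_A p_B, (1-p_A)(1-p_B)) for D < 0; D = 0 gives D' = 0. Sequences
#' with a gap or N at either site are dropped pairwise.
#'
#' @param aln a `clone_alignment`.
#' @param i,j 1-based alignment columns, each biallelic over the retained
#'   sequences.
#' @return one-row data.frame: site_i, site_j, p_A, p_B, D, D_prime,
#'   n_haplotypes.
#' @export
dprime_pair <- function(aln, i, j) {
  mat <- aln$seq
  ok <- !(mat[, i] %in% c("-", "N")) & !(mat[, j] %in% c("-", "N"))
  a <- mat[ok, i]
  b <- mat[ok, j]
  ta <- sort(table(a), decreasing = TRUE)
  tb <- sort(table(b), decreasing = TRUE)
  if (length(ta) != 2L) stop("site ", i, " is not biallelic")
  if (length(tb) != 2L) stop("site ", j, " is not biallelic")
  A <- names(ta)[1L]
  B <- names(tb)[1L]
  pA <- ta[[1L]] / length(a)
  pB <- tb[[1L]] / length(b)
  pAB <- mean(a == A & b == B)
  D <- pAB - pA * pB
  Dp <- if (D > 0) {
    D / min(pA * (1 - pB), (1 - pA) * pB)
  } else if (D < 0) {
    D / min(pA * pB, (1 - pA) * (1 - pB))
  } else 0
  data.frame(site_i = i, site_j = j, p_A = pA, p_B = pB, D = D,
             D_prime = Dp, n_haplotypes = length(a))
}

#' D' over all pairs of filtered biallelic sites
#'
#' @param aln a `clone_alignment`.
#' @param maf_min minimum minor-allele count (see [biallelic_sites()]).
#' @return list with `sites` (retained columns), `matrix`
#'   (upper-triangular D' matrix, dimnames = columns) and `table`
#'   (long-format data.frame as from [dprime_pair()]). Fewer than 2
#'   retained sites gives an empty matrix with a warning.
#' @export
ld_matrix <- function(aln, maf_min = 1L) {
  sites <- biallelic_sites(aln, maf_min)
  k <- length(sites)
  if (k < 2L) {
    warning("fewer than 2 sites pass the minor-allele-count filter")
    return(list(sites = sites,
                matrix = matrix(NA_real_, 0, 0),
                table = data.frame()))
  }
  m <- matrix(NA_real_, k, k,
              dimnames = list(as.character(sites), as.character(sites)))
  rows <- list()
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      r <- dprime_pair(aln, sites[a], sites[b])
      m[a, b] <- r$D_prime
      rows[[length(rows) + 1L]] <- r
    }
  }
  list(sites = sites, matrix = m, table = do.call(rbind, rows))
}
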