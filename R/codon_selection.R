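.codon_env <- new.env(parent = emptyenv())

# amino-acid lookup for all 64 codons under the standard genetic code,
# built once from seqinr's translation table ("*" = stop)
codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    nts <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE),
                    1L, paste, collapse = "")
    aa <- vapply(codons,
                 function(cd) seqinr::translate(strsplit(cd, "")[[1L]]), "")
    .codon_env$tab <- stats::setNames(aa, codons)
  }
  .codon_env$tab
}

is_stop <- function(codon) codon_table()[codon] == "*"

sense_codons <- function() {
  tab <- codon_table()
  sort(names(tab)[tab != "*"])
}

codon_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1L]]
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(nts, chars[pos])) {
      nb <- chars
      nb[pos] <- nt
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  out
}

#' Expected synonymous and non-synonymous sites of a codon
#'
#' Nei–Gojobori style site counting: each of the nine single-nucleotide
#' neighbors of the codon is classified as synonymous or non-synonymous;
#' neighbors that are stop codons are excluded from both numerator and
#' denominator, so ES + EN = (9 - n_stop)/3 <= 3.
#'
#' @param codon a 3-mer over A,C,G,T; must be a sense codon.
#' @return c(ES = ..., EN = ...).
#' @export
ng_codon_sites <- function(codon) {
  tab <- codon_table()
  if (grepl("[^ACGT]", codon)) stop("ambiguous or gapped codon: ", codon)
  if (tab[codon] == "*") stop("stop codon: ", codon)
  nb <- codon_neighbors(codon)
  aa <- tab[nb]
  keep <- aa != "*"
  syn <- sum(aa[keep] == tab[codon])
  nonsyn <- sum(keep) - syn
  c(ES = syn / 3, EN = nonsyn / 3)
}

#' Synonymous / non-synonymous step counts between two codons
#'
#' Averages the number of synonymous and non-synonymous single-nucleotide
#' steps over all orderings of the differing positions, excluding pathways
#' that pass through a stop codon. When at least one legal pathway exists,
#' s + n equals the Hamming distance between the codons. If every pathway
#' passes through a stop, the counts are `NA` with attribute
#' `no_legal_path = TRUE`.
#'
#' @param codon_a,codon_b sense 3-mers over A,C,G,T.
#' @return c(s = ..., n = ...), possibly fractional.
#' @export
pathway_counts <- function(codon_a, codon_b) {
  tab <- codon_table()
  for (cd in c(codon_a, codon_b)) {
    if (grepl("[^ACGT]", cd)) stop("ambiguous or gapped codon: ", cd)
    if (tab[cd] == "*") stop("stop codon: ", cd)
  }
  a <- strsplit(codon_a, "")[[1L]]
  b <- strsplit(codon_b, "")[[1L]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  if (d == 0L) return(c(s = 0, n = 0))
  perms <- all_permutations(diff_pos)
  s_tot <- 0
  n_tot <- 0
  n_legal <- 0L
  for (p in perms) {
    cur <- a
    s <- 0
    n <- 0
    legal <- TRUE
    for (pos in p) {
      nxt <- cur
      nxt[pos] <- b[pos]
      cd_cur <- paste(cur, collapse = "")
      cd_nxt <- paste(nxt, collapse = "")
      if (tab[cd_nxt] == "*") {
        legal <- FALSE
        break
      }
      if (tab[cd_nxt] == tab[cd_cur]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (legal) {
      s_tot <- s_tot + s
      n_tot <- n_tot + n
      n_legal <- n_legal + 1L
    }
  }
  if (n_legal == 0L) {
    return(structure(c(s = NA_real_, n = NA_real_), no_legal_path = TRUE))
  }
  c(s = s_tot / n_legal, n = n_tot / n_legal)
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# upper binomial tail P(X >= k | size n, prob p), extended to fractional
# counts via the regularised incomplete beta function
binom_tail_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  stats::pbeta(p, k, n - k + 1)
}

#' Counting-based selection test for one codon site
#'
#' SLAC-style test: ancestral codons are reconstructed by Fitch parsimony
#' (ties broken towards the alphabetically first codon), synonymous and
#' non-synonymous changes are counted along every branch with
#' [pathway_counts()] and summed, expected site proportions are averaged
#' over the codons of all nodes (observed and reconstructed, weighted
#' equally), and one-tailed binomial tail probabilities compare the
#' observed split of changes to the expected non-synonymous proportion
#' EN/(EN+ES).
#'
#' @param codons named character vector: one codon (3-mer) per tree tip.
#' @param tree a `phylo` whose tip labels match `names(codons)`.
#' @return one-row data.frame: ES, EN, s_obs, n_obs, dS, dN, dn_minus_ds,
#'   p_pos, p_neg; all NA (with `excluded = TRUE`) when any codon is
#'   gapped/ambiguous or a stop.
#' @export
slac_site_test <- function(codons, tree) {
  if (!all(tree$tip.label %in% names(codons))) {
    stop("tree tips and codon alignment records do not match")
  }
  codons <- codons[tree$tip.label]
  tab <- codon_table()
  bad <- grepl("[^ACGT]", codons) | tab[codons] == "*"
  if (any(bad)) {
    return(data.frame(ES = NA_real_, EN = NA_real_, s_obs = NA_real_,
                      n_obs = NA_real_, dS = NA_real_, dN = NA_real_,
                      dn_minus_ds = NA_real_, p_pos = NA_real_,
                      p_neg = NA_real_, excluded = TRUE))
  }
  sc <- fitch_score(tree, codons)
  assignment <- attr(sc, "assignment")
  s_obs <- 0
  n_obs <- 0
  for (e in seq_len(nrow(tree$edge))) {
    ca <- assignment[tree$edge[e, 1L]]
    cb <- assignment[tree$edge[e, 2L]]
    if (ca != cb) {
      pc <- pathway_counts(ca, cb)
      if (!is.na(pc[["s"]])) {
        s_obs <- s_obs + pc[["s"]]
        n_obs <- n_obs + pc[["n"]]
      }
    }
  }
  site_mat <- vapply(assignment, ng_codon_sites, c(ES = 0, EN = 0))
  ES <- mean(site_mat["ES", ])
  EN <- mean(site_mat["EN", ])
  total <- s_obs + n_obs
  pN <- EN / (EN + ES)
  pS <- ES / (EN + ES)
  data.frame(
    ES = ES, EN = EN, s_obs = s_obs, n_obs = n_obs,
    dS = if (ES > 0) s_obs / ES else NA_real_,
    dN = if (EN > 0) n_obs / EN else NA_real_,
    dn_minus_ds = (if (EN > 0) n_obs / EN else 0) -
      (if (ES > 0) s_obs / ES else 0),
    p_pos = binom_tail_upper(n_obs, total, pN),
    p_neg = binom_tail_upper(s_obs, total, pS),
    excluded = FALSE)
}

#' Per-codon selection scan over an annotated region
#'
#' Reads the region's columns as consecutive codons in the annotation's
#' frame and runs [slac_site_test()] on each. Codons containing an indel
#' or ambiguity in any sequence are reported as excluded (so, as in
#' analyses that drop indel sites, only codon positions found in all
#' groups contribute), which keeps the reading frame intact.
#'
#' @param aln a `clone_alignment`.
#' @param tree a `phylo` over the alignment's records.
#' @param region_cols integer alignment columns of the region (e.g. from
#'   [project_annotation()]: `exon4`, or the concatenation of exons 1-3);
#'   length must be divisible by 3.
#' @return data.frame: codon (1-based within the region), ES, EN, s_obs,
#'   n_obs, dS, dN, dn_minus_ds, p_pos, p_neg, excluded, sig_pos_05/20
#'   and sig_neg_05/20 flags at the 0.05 and 0.2 reporting thresholds.
#' @export
region_scan <- function(aln, tree, region_cols) {
  mat <- aln$seq[, region_cols, drop = FALSE]
  if (ncol(mat) %% 3L != 0L) {
    stop("region length (", ncol(mat), ") is not divisible by 3")
  }
  n_codons <- ncol(mat) %/% 3L
  rows <- lapply(seq_len(n_codons), function(k) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    codons <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    names(codons) <- rownames(mat)
    res <- slac_site_test(codons, tree)
    cbind(codon = k, res)
  })
  out <- do.call(rbind, rows)
  out$sig_pos_05 <- !out$excluded & out$dn_minus_ds > 0 & out$p_pos < 0.05
  out$sig_pos_20 <- !out$excluded & out$dn_minus_ds > 0 & out$p_pos < 0.2
  out$sig_neg_05 <- !out$excluded & out$dn_minus_ds < 0 & out$p_neg < 0.05
  out$sig_neg_20 <- !out$excluded & out$dn_minus_ds < 0 & out$p_neg < 0.2
  out
}
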