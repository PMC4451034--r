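#' Assign clones to paralog clusters
#'
#' In `auto` mode, single-linkage clustering on pairwise p-distance
#' (gap-excluded) cut at `threshold` divergence separates paralogous gene
#' clusters, which diverge far more than alleles within a cluster. In
#' `user` mode labels are read from a two-column TSV (id, cluster).
#'
#' @param aln a `clone_alignment` with >= 2 records.
#' @param mode `"auto"` or `"user"`.
#' @param threshold divergence cut height in (0,1); default 0.10.
#' @param labels_file TSV path for `mode = "user"` (columns id, cluster).
#' @return a `cluster_assignment`: data.frame (id, cluster) with attribute
#'   `method`. Auto clusters are labelled C1..Ck in order of first
#'   appearance in the alignment.
#' @export
assign_clusters <- function(aln, mode = c("auto", "user"), threshold = 0.10,
                            labels_file = NULL) {
  mode <- match.arg(mode)
  if (n_records(aln) < 2L) stop("need >= 2 sequences to cluster")
  if (mode == "user") {
    df <- utils::read.delim(labels_file, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("id", "cluster")
    missing <- setdiff(rownames(aln$seq), df$id)
    if (length(missing) > 0L) {
      stop("cluster file lacks labels for: ", paste(missing, collapse = ", "))
    }
    df <- df[match(rownames(aln$seq), df$id), c("id", "cluster")]
    rownames(df) <- NULL
    return(structure(df, method = "user",
                     class = c("cluster_assignment", "data.frame")))
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0,1)")
  }
  d <- pdistance_matrix(aln, "pairwise")
  hc <- stats::hclust(as.dist(d), method = "single")
  grp <- stats::cutree(hc, h = threshold)
  # relabel in order of first appearance for determinism across inputs
  lab <- paste0("C", match(grp, unique(grp)))
  df <- data.frame(id = rownames(aln$seq), cluster = lab,
                   stringsAsFactors = FALSE)
  structure(df, method = "auto", threshold = threshold,
            class = c("cluster_assignment", "data.frame"))
}

cluster_of <- function(clusters, ids) {
  clusters$cluster[match(ids, clusters$id)]
}

#' Screen singleton sites in clone groups for PCR errors
#'
#' Within each individual-by-cluster group of clones, an alignment column
#' where exactly one clone differs from the rest of the group is a
#' singleton candidate: it is masked to the group-majority state
#' (`error_masked`) unless the same column is also variable among the
#' clones of at least one other individual in the same cluster, in which
#' case it is kept as a real SNP (`snp_retained`). Groups of size one are
#' never masked (no within-individual evidence). For two-clone groups that
#' disagree, both variants are singletons; if neither recurs elsewhere the
#' clone differing from the cluster-wide majority is masked, and a
#' cluster-wide tie leaves both untouched (`unresolved`). Indel characters
#' (`-`) count as a fifth state, so a one-clone gap is maskable; columns
#' where any group member has `N` are skipped.
#'
#' @param aln a `clone_alignment`; every record needs a parsed barcode.
#' @param clusters a `cluster_assignment` for the same records.
#' @return list with `corrected` (a `clone_alignment` with masked bases
#'   replaced by the group majority) and `report` (a `screen_report`:
#'   data.frame of decisions with columns clone, column, decision,
#'   evidence_individuals, plus attributes `groups` and `n_masked`).
#' @export
screen_singletons <- function(aln, clusters) {
  meta <- aln$meta
  if (any(is.na(meta$barcode))) {
    stop("clones lacking a parsed barcode: ",
         paste(meta$id[is.na(meta$barcode)], collapse = ", "))
  }
  cl <- cluster_of(clusters, meta$id)
  if (any(is.na(cl))) stop("cluster assignment missing for some clones")
  mat <- aln$seq
  L <- ncol(mat)
  group_key <- paste(meta$barcode, cl, sep = "|")
  groups <- split(seq_len(nrow(mat)), group_key)
  decisions <- list()
  for (cluster in unique(cl)) {
    in_cl <- which(cl == cluster)
    cl_groups <- groups[vapply(groups, function(g) cl[g[1L]] == cluster, TRUE)]
    for (gk in names(cl_groups)) {
      g <- cl_groups[[gk]]
      if (length(g) < 2L) next
      sub <- mat[g, , drop = FALSE]
      for (j in seq_len(L)) {
        col <- sub[, j]
        if (any(col == "N")) next
        tab <- table(col)
        if (length(tab) < 2L) next
        # recurrence: variable among the clones of >= 1 OTHER individual
        # in the same cluster at this column
        evidence <- character(0)
        for (ok in names(cl_groups)) {
          if (ok == gk) next
          og <- cl_groups[[ok]]
          if (length(og) < 2L) next
          ocol <- mat[og, j]
          ocol <- ocol[ocol != "N"]
          if (length(unique(ocol)) >= 2L) {
            evidence <- c(evidence, meta$barcode[og[1L]])
          }
        }
        recurrent <- length(evidence) > 0L
        if (length(g) == 2L && tab[1L] == 1L && tab[2L] == 1L) {
          # two-clone disagreement: both variants are singletons
          if (recurrent) {
            for (gi in seq_along(g)) {
              decisions[[length(decisions) + 1L]] <- data.frame(
                clone = rownames(mat)[g[gi]], column = j,
                decision = "snp_retained",
                evidence_individuals = paste(evidence, collapse = ","),
                stringsAsFactors = FALSE)
            }
          } else {
            allcol <- mat[in_cl, j]
            allcol <- allcol[allcol != "N"]
            cl_tab <- sort(table(allcol), decreasing = TRUE)
            counts_here <- cl_tab[names(cl_tab) %in% col]
            if (length(counts_here) >= 2L &&
                counts_here[1L] == counts_here[2L]) {
              for (gi in seq_along(g)) {
                decisions[[length(decisions) + 1L]] <- data.frame(
                  clone = rownames(mat)[g[gi]], column = j,
                  decision = "unresolved", evidence_individuals = "",
                  stringsAsFactors = FALSE)
              }
            } else {
              major <- names(cl_tab)[1L]
              loser <- g[col != major]
              if (length(loser) == 1L) {
                mat[loser, j] <- major
                decisions[[length(decisions) + 1L]] <- data.frame(
                  clone = rownames(aln$seq)[loser], column = j,
                  decision = "error_masked", evidence_individuals = "",
                  stringsAsFactors = FALSE)
              }
            }
          }
          next
        }
        if (min(tab) == 1L && length(tab) == 2L && max(tab) == length(g) - 1L) {
          minor_state <- names(tab)[which.min(tab)]
          major_state <- names(tab)[which.max(tab)]
          singleton <- g[col == minor_state]
          if (recurrent) {
            decisions[[length(decisions) + 1L]] <- data.frame(
              clone = rownames(mat)[singleton], column = j,
              decision = "snp_retained",
              evidence_individuals = paste(evidence, collapse = ","),
              stringsAsFactors = FALSE)
          } else {
            mat[singleton, j] <- major_state
            decisions[[length(decisions) + 1L]] <- data.frame(
              clone = rownames(aln$seq)[singleton], column = j,
              decision = "error_masked", evidence_individuals = "",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  dec <- if (length(decisions) > 0L) {
    do.call(rbind, decisions)
  } else {
    data.frame(clone = character(0), column = integer(0),
               decision = character(0), evidence_individuals = character(0),
               stringsAsFactors = FALSE)
  }
  corrected <- new_alignment(mat, aln$meta)
  report <- structure(dec,
                      class = c("screen_report", "data.frame"),
                      groups = group_key,
                      clusters = cl,
                      n_masked = sum(dec$decision == "error_masked"))
  list(corrected = corrected, report = report)
}

#' Select one representative per distinct corrected form
#'
#' Within each individual-by-cluster group, identical corrected sequences
#' collapse to a single record: a consensus id
#' `<barcode>-cons.<species>.<locality>` when the form is supported by two
#' or more clones (suffixed `cons2`, `cons3`, ... if one individual yields
#' several multi-clone forms), or the clone itself when a single clone
#' alone represents a form (including a clone that alone represents a
#' cluster for its individual, which is always included).
#'
#' @param corrected corrected `clone_alignment` from [screen_singletons()].
#' @param clusters a `cluster_assignment`.
#' @return a `clone_alignment` of representatives, with `meta` carrying a
#'   `cluster` and `n_clones` column (clones supporting each form).
#' @export
select_representatives <- function(corrected, clusters) {
  meta <- corrected$meta
  cl <- cluster_of(clusters, meta$id)
  mat <- corrected$seq
  key <- paste(meta$barcode, cl, sep = "|")
  reps <- list()
  for (gk in unique(key)) {
    g <- which(key == gk)
    seqs <- apply(mat[g, , drop = FALSE], 1L, paste, collapse = "")
    forms <- split(g, factor(seqs, levels = unique(seqs)))
    n_cons <- 0L
    for (f in forms) {
      if (length(f) >= 2L) {
        n_cons <- n_cons + 1L
        suffix <- if (n_cons == 1L) "" else as.character(n_cons)
        id <- format_clone_label(meta$barcode[f[1L]], NA_integer_,
                                 meta$species[f[1L]], meta$locality[f[1L]],
                                 cons_suffix = suffix)
      } else {
        id <- meta$id[f[1L]]
      }
      reps[[length(reps) + 1L]] <- list(
        id = id, row = f[1L], cluster = cl[f[1L]], n_clones = length(f),
        barcode = meta$barcode[f[1L]], species = meta$species[f[1L]],
        locality = meta$locality[f[1L]])
    }
  }
  rmat <- mat[vapply(reps, `[[`, 1L, "row"), , drop = FALSE]
  rownames(rmat) <- vapply(reps, `[[`, "", "id")
  rmeta <- data.frame(
    id = rownames(rmat),
    barcode = vapply(reps, `[[`, "", "barcode"),
    clone = vapply(reps, function(r) {
      p <- parse_clone_label(r$id); p$clone
    }, NA_integer_),
    species = vapply(reps, `[[`, "", "species"),
    locality = vapply(reps, `[[`, "", "locality"),
    cluster = vapply(reps, `[[`, "", "cluster"),
    n_clones = vapply(reps, `[[`, 1L, "n_clones"),
    stringsAsFactors = FALSE
  )
  new_alignment(rmat, rmeta)
}

#' Tabulate clones sequenced and distinct forms per individual
#'
#' Reproduces the bookkeeping table of a clone-library study: one row per
#' individual with its species.locality origin, number of clones sequenced
#' and number of distinct forms (alleles or paralogs) recovered, plus a
#' totals row counting individuals, distinct origins, clones and forms.
#'
#' @param corrected corrected `clone_alignment` from [screen_singletons()].
#' @param clusters a `cluster_assignment`.
#' @return data.frame (barcode, origin, n_clones, n_forms) with attribute
#'   `totals` = c(individuals, origins, clones, forms).
#' @export
tabulate_forms <- function(corrected, clusters) {
  meta <- corrected$meta
  if (nrow(meta) == 0L) {
    out <- data.frame(barcode = character(0), origin = character(0),
                      n_clones = integer(0), n_forms = integer(0))
    attr(out, "totals") <- c(individuals = 0L, origins = 0L,
                             clones = 0L, forms = 0L)
    return(out)
  }
  cl <- cluster_of(clusters, meta$id)
  rows <- list()
  for (bc in unique(meta$barcode)) {
    g <- which(meta$barcode == bc)
    seqs <- apply(corrected$seq[g, , drop = FALSE], 1L, paste, collapse = "")
    n_forms <- length(unique(paste(cl[g], seqs)))
    rows[[length(rows) + 1L]] <- data.frame(
      barcode = bc,
      origin = paste(meta$species[g[1L]], meta$locality[g[1L]], sep = "."),
      n_clones = length(g), n_forms = n_forms, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(individuals = nrow(out),
                           origins = length(unique(out$origin)),
                           clones = sum(out$n_clones),
                           forms = sum(out$n_forms))
  out
}
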