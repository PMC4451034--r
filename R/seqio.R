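#' @importFrom stats setNames
NULL

VALID_SPECIES <- c("Gmo", "Gma", "Gog", "Gch", "Bsa")
VALID_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Parse a clone label of the form `<barcode>-<clone>.<species>.<locality>`
#'
#' Clone libraries are labelled with a six-digit individual barcode, a clone
#' number separated by `-` (or `_`, a dialect seen in published tree tips),
#' a species mnemonic (e.g. Gmo for *Gadus morhua*) and a locality mnemonic
#' (e.g. Ice for Iceland). Consensus records produced by
#' [select_representatives()] use the token `cons` (optionally suffixed with
#' a digit) in place of the clone number.
#'
#' @param label character scalar, e.g. `"105746-3.Gmo.Gre"`.
#' @return A list with elements `barcode` (character, 6 digits),
#'   `clone` (integer, or `NA` for consensus records), `species`,
#'   `locality`, and `id`, the canonical `-`-separated form of the label.
#' @examples
#' parse_clone_label("105746-3.Gmo.Gre")
#' parse_clone_label("117757_1.Gmo.Ice")$id  # canonicalised to "-"
#' @export
parse_clone_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  m <- regmatches(label,
    regexec("^([0-9]{6})[-_](cons[0-9]*|[0-9]{1,2})\\.([A-Za-z]+)\\.([A-Za-z]+)$",
            label))[[1L]]
  if (length(m) == 0L) {
    stop("malformed clone label: '", label,
         "' (expected <6-digit barcode>-<clone>.<species>.<locality>)")
  }
  clone_tok <- m[3L]
  clone <- if (grepl("^cons", clone_tok)) NA_integer_ else as.integer(clone_tok)
  list(
    barcode = m[2L],
    clone = clone,
    species = m[4L],
    locality = m[5L],
    id = sprintf("%s-%s.%s.%s", m[2L], clone_tok, m[4L], m[5L])
  )
}

#' Format clone metadata back into a canonical label
#'
#' @param barcode 6-digit character barcode.
#' @param clone integer clone number, or `NA` for a consensus record.
#' @param species,locality character mnemonics.
#' @param cons_suffix optional suffix distinguishing multiple consensus
#'   records of one individual.
#' @return canonical label string.
#' @export
format_clone_label <- function(barcode, clone, species, locality,
                               cons_suffix = "") {
  tok <- if (is.na(clone)) paste0("cons", cons_suffix) else as.character(clone)
  sprintf("%s-%s.%s.%s", barcode, tok, species, locality)
}

new_alignment <- function(seq_mat, meta) {
  stopifnot(is.matrix(seq_mat), is.character(seq_mat))
  structure(list(seq = seq_mat, meta = meta), class = "clone_alignment")
}

#' Construct an alignment object from character sequences
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (names are record ids) or a character matrix (rows = records).
#' @param parse_labels attempt to parse clone metadata from the names.
#' @return a `clone_alignment`: list with `seq` (character matrix, one row
#'   per record, uppercase over A,C,G,T,N,-) and `meta` (data.frame with
#'   id, barcode, clone, species, locality).
#' @export
alignment <- function(seqs, parse_labels = TRUE) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names(seqs)[lens != lens[1L]]
      stop("ragged sequence lengths; offending records: ",
           paste(bad, collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    rownames(mat) <- names(seqs)
  }
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  bad <- setdiff(unique(as.vector(mat)), VALID_CHARS)
  if (length(bad) > 0L) {
    stop("disallowed sequence characters (IUPAC ambiguity codes other than ",
         "N are rejected): ", paste(bad, collapse = ", "))
  }
  meta <- parse_meta(rownames(mat), warn = parse_labels)
  new_alignment(mat, meta)
}

parse_meta <- function(ids, warn = TRUE) {
  rows <- lapply(ids, function(id) {
    p <- tryCatch(parse_clone_label(id), error = function(e) NULL)
    if (is.null(p)) {
      list(id = id, barcode = NA_character_, clone = NA_integer_,
           species = NA_character_, locality = NA_character_)
    } else {
      p[c("id", "barcode", "clone", "species", "locality")]
    }
  })
  meta <- data.frame(
    id = ids,
    barcode = vapply(rows, `[[`, "", "barcode"),
    clone = vapply(rows, `[[`, NA_integer_, "clone"),
    species = vapply(rows, `[[`, "", "species"),
    locality = vapply(rows, `[[`, "", "locality"),
    stringsAsFactors = FALSE
  )
  n_bad <- sum(is.na(meta$barcode))
  if (warn && n_bad > 0L) {
    warning(n_bad, " record label(s) do not conform to ",
            "<barcode>-<clone>.<species>.<locality>; metadata left NA")
  }
  meta
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat("clone_alignment:", nrow(x$seq), "records x", ncol(x$seq), "columns\n")
  sp <- table(x$meta$species, useNA = "ifany")
  cat("species:", paste(names(sp), sp, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of records / columns of an alignment
#' @param aln a `clone_alignment`.
#' @return integer.
#' @export
n_records <- function(aln) nrow(aln$seq)

#' @rdname n_records
#' @export
n_columns <- function(aln) ncol(aln$seq)

#' Subset an alignment by records and/or columns
#' @param aln a `clone_alignment`.
#' @param records row indices, logical mask, or record ids.
#' @param columns column indices.
#' @return a `clone_alignment`.
#' @export
subset_alignment <- function(aln, records = NULL, columns = NULL) {
  mat <- aln$seq
  meta <- aln$meta
  if (!is.null(records)) {
    if (is.character(records)) records <- match(records, rownames(mat))
    mat <- mat[records, , drop = FALSE]
    meta <- meta[records, , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
  new_alignment(mat, meta)
}

#' Read an aligned multi-FASTA of clone sequences
#'
#' Sequences are uppercased and `U` converted to `T`. Records whose labels
#' conform to the clone naming convention get parsed metadata; others are
#' kept with `NA` metadata and a warning. Ragged (unequal-length) input is
#' an error naming the offending records.
#'
#' @param path FASTA file of aligned sequences.
#' @return a `clone_alignment`.
#' @export
read_alignment <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             seqonly = FALSE)
  if (length(recs) == 0L) stop("no sequences in ", path)
  seqs <- vapply(recs, function(s) as.character(s)[1L], "")
  names(seqs) <- vapply(recs, function(s) attr(s, "name"), "")
  alignment(seqs)
}

#' Write an alignment to FASTA
#' @param aln a `clone_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$seq))) {
    writeLines(paste0(">", rownames(aln$seq)[i]), con)
    writeLines(paste(aln$seq[i, ], collapse = ""), con)
  }
  invisible(path)
}

REGION_NAMES <- c("UTR5", "exon1", "intron1", "exon2", "intron2",
                  "exon3", "intron3", "exon4", "UTR3")

#' Construct a gene annotation (exon/intron/UTR layout)
#'
#' Intervals are on the ungapped reference, 0-based half-open, matching the
#' BED convention used by [read_annotation()].
#'
#' @param regions data.frame with columns `name`, `start`, `end`.
#' @param reference_id id of the reference record the coordinates refer to.
#' @return a `gene_annotation` data.frame with attribute `reference_id`.
#' @export
gene_annotation <- function(regions, reference_id = NA_character_) {
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  if (any(regions$end <= regions$start)) stop("empty or inverted region")
  if (any(utils::head(regions$end, -1) > utils::tail(regions$start, -1))) {
    stop("overlapping annotation regions")
  }
  structure(regions, class = c("gene_annotation", "data.frame"),
            reference_id = reference_id)
}

#' Read a BED-like annotation TSV (name, start, end; 0-based half-open)
#' @param path TSV file with header columns name, start, end.
#' @param reference_id optional reference record id.
#' @return a `gene_annotation`.
#' @export
read_annotation <- function(path, reference_id = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_annotation(df, reference_id)
}

#' Project an ungapped-reference annotation onto alignment columns
#'
#' Each reference position maps to the alignment column holding that base of
#' the reference row; alignment columns that are insertions relative to the
#' reference (gap in the reference row) are assigned to the region of the
#' preceding reference base.
#'
#' @param ann a `gene_annotation` on the ungapped reference.
#' @param aln a `clone_alignment` containing the reference row.
#' @param ref_row record id of the reference row.
#' @return named list: region name -> sorted integer vector of 1-based
#'   alignment columns.
#' @export
project_annotation <- function(ann, aln, ref_row) {
  i <- match(ref_row, rownames(aln$seq))
  if (is.na(i)) stop("reference row '", ref_row, "' not in alignment")
  refseq <- aln$seq[i, ]
  ref_cols <- which(refseq != "-")          # alignment column of ref pos k
  ref_len <- length(ref_cols)
  if (max(ann$end) > ref_len) {
    stop("annotation extends beyond ungapped reference length (",
         max(ann$end), " > ", ref_len, ")")
  }
  # region index per reference position (0 = unannotated)
  pos_region <- integer(ref_len)
  for (r in seq_len(nrow(ann))) {
    pos_region[(ann$start[r] + 1L):ann$end[r]] <- r
  }
  # assign each alignment column to a reference position's region;
  # insertion columns inherit the region of the preceding reference base
  col_region <- integer(ncol(aln$seq))
  last <- 0L
  k <- 0L
  for (j in seq_len(ncol(aln$seq))) {
    if (refseq[j] != "-") {
      k <- k + 1L
      last <- pos_region[k]
    }
    col_region[j] <- last
  }
  out <- lapply(seq_len(nrow(ann)), function(r) which(col_region == r))
  names(out) <- ann$name
  out
}

#' Check that a projected annotation provides a region
#' @param proj result of [project_annotation()].
#' @param region region name, e.g. `"exon4"`.
#' @return the region's columns, or an error if absent/empty.
#' @export
region_columns <- function(proj, region) {
  if (!region %in% names(proj) || length(proj[[region]]) == 0L) {
    stop("annotation does not provide region '", region, "'")
  }
  proj[[region]]
}

#' Identity projection of an annotation (alignment in reference coordinates)
#'
#' For alignments whose columns are already the annotation's reference
#' coordinates (e.g. generator output, where indels are deletions relative
#' to the master sequence), every region maps to its own coordinate range.
#'
#' @param ann a `gene_annotation`.
#' @return named list region -> 1-based column vector.
#' @export
annotation_columns <- function(ann) {
  out <- lapply(seq_len(nrow(ann)), function(r) (ann$start[r] + 1L):ann$end[r])
  names(out) <- ann$name
  out
}
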