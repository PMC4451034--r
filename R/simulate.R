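#' Study design constants for the cod cathelicidin clone library
#'
#' The sampling design the generator emulates: 27 individuals (19 Atlantic
#' cod from eight localities plus two each of four related gadid species),
#' 97 clones in total, and the per-individual clone and form counts of the
#' study's bookkeeping table. The deposited representative set spans the
#' GenBank accession range KJ831349--KJ831391.
#'
#' @return list with `individuals` (data.frame: barcode, species,
#'   locality, n_clones, n_forms), `accession_first`, `accession_last`.
#' @export
study_design <- function() {
  individuals <- data.frame(
    barcode = c("105746", "104931", "140254", "140272", "118507", "125968",
                "118214", "117795", "117757", "140179", "140176", "140219",
                "140233", "152921", "152924", "115574", "114718", "200093",
                "200079", "103659", "104725", "103852", "104947", "152074",
                "152050", "152018", "152027"),
    species = c(rep("Gmo", 19), "Bsa", "Bsa", "Gog", "Gog", "Gma", "Gma",
                "Gch", "Gch"),
    locality = c("Gre", "Gre", "Bar", "Bar", "Ice", "Ice", "Ice", "Ice",
                 "Ice", "Cel", "Cel", "Bal", "Bal", "Nor", "Nor", "Far",
                 "Far", "Can", "Can", "Gre", "Gre", "Gre", "Gre", "Pac",
                 "Pac", "Pac", "Pac"),
    n_clones = c(3L, 3L, 3L, 6L, 12L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L,
                 3L, 2L, 6L, 6L, 3L, 3L, 2L, 3L, 3L, 3L, 3L, 3L, 3L),
    n_forms = c(2L, 2L, 1L, 3L, 3L, 2L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L,
                1L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 3L),
    stringsAsFactors = FALSE
  )
  list(individuals = individuals,
       accession_first = "KJ831349", accession_last = "KJ831391")
}

#' Count sequences in a contiguous GenBank accession range
#'
#' @param first,last accession strings sharing a letter prefix.
#' @return integer count, endpoints inclusive.
#' @export
accession_range_size <- function(first, last) {
  pre1 <- gsub("[0-9]+$", "", first)
  pre2 <- gsub("[0-9]+$", "", last)
  if (pre1 != pre2) stop("accession prefixes differ")
  n1 <- as.integer(gsub("^[A-Za-z]+", "", first))
  n2 <- as.integer(gsub("^[A-Za-z]+", "", last))
  n2 - n1 + 1L
}

#' Default gene annotation template used by the generator
#'
#' A 1300-bp cathelicidin-like layout: short UTRs, four exons and three
#' introns. The coding frame starts at exon1; exons 1--3 (411 bp) and
#' exon 4 (189 bp) are each divisible by three so per-region codon scans
#' are in frame. Coordinates 0-based half-open.
#'
#' @return a `gene_annotation`.
#' @export
default_annotation <- function() {
  lens <- c(UTR5 = 50L, exon1 = 150L, intron1 = 150L, exon2 = 129L,
            intron2 = 150L, exon3 = 132L, intron3 = 300L, exon4 = 189L,
            UTR3 = 50L)
  ends <- cumsum(lens)
  gene_annotation(data.frame(name = names(lens),
                             start = ends - lens, end = ends),
                  reference_id = "reference")
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: three
#' paralogous genes each carrying two ancient allele classes, five gadid
#' species with split times from the literature (generation time 5 years,
#' Ne = 10,000; deepest split ~8 mya, Atlantic/Pacific splits ~3.8-4 mya),
#' allele classes originating at 12 mya -- older than every species split,
#' hence >> the 4Ne neutral fixation time, the balancing regime -- and the
#' bookkeeping table's 27 individuals and 97 clones. The per-site,
#' per-generation mutation rate (1e-8) is chosen so that within-cluster
#' divergence lands in the 1-3% range observed for such data.
#'
#' @param n_paralogs number of paralogous genes G (default 3).
#' @param n_classes allele classes per paralog K (default 2).
#' @param t_anc allele-class origin, generations ago (default 2.4e6).
#' @param t_paralog paralog duplication time, generations ago (7.5e6).
#' @param mu per-site per-generation mutation rate (1e-8).
#' @param Ne effective population size (1e4); sets within-species
#'   coalescent depth in the neutral control.
#' @param error_rate per-clone per-site PCR error rate e (1e-3).
#' @param dropout per-paralog amplification dropout probability (0.5).
#' @param indel_prob probability an allele class carries a private
#'   intron-3 deletion (0.5); `paralog_indel_prob` likewise per paralog.
#' @param paralog_indel_prob see above (default 1/3).
#' @param annotation a `gene_annotation`; default [default_annotation()].
#' @param individuals data.frame (barcode, species, locality, n_clones);
#'   default the study design table.
#' @param resample_clones resample clone counts with replacement from the
#'   design column instead of using it verbatim.
#' @param seed RNG seed (mandatory).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_paralogs = 3L, n_classes = 2L,
                       t_anc = 2.4e6, t_paralog = 7.5e6,
                       mu = 1e-8, Ne = 1e4,
                       error_rate = 1e-3, dropout = 0.5,
                       indel_prob = 0.5, paralog_indel_prob = 1 / 3,
                       annotation = default_annotation(),
                       individuals = study_design()$individuals,
                       resample_clones = FALSE,
                       seed = 1L) {
  if (t_anc < 0 || t_paralog < t_anc) {
    stop("inconsistent times: need t_paralog >= t_anc >= 0")
  }
  stopifnot(mu >= 0, error_rate >= 0, dropout >= 0, dropout < 1,
            !is.null(seed))
  structure(list(
    n_paralogs = n_paralogs, n_classes = n_classes, t_anc = t_anc,
    t_paralog = t_paralog, mu = mu, Ne = Ne, error_rate = error_rate,
    dropout = dropout, indel_prob = indel_prob,
    paralog_indel_prob = paralog_indel_prob, annotation = annotation,
    individuals = individuals, resample_clones = resample_clones,
    seed = seed
  ), class = "sim_config")
}

# species tree with split times in generations ago (5-yr generations):
# Bsa splits deepest (~8 mya); Atlantic cod vs the Pacific clade ~4 mya;
# walleye pollock ~3.8 mya; Greenland cod is a recent re-invasion from
# Pacific cod (~0.75 mya)
species_tree_default <- function() {
  list(time = 1.6e6, left = "Bsa",
       right = list(time = 8e5, left = "Gmo",
                    right = list(time = 7.6e5, left = "Gch",
                                 right = list(time = 1.5e5,
                                              left = "Gma", right = "Gog"))))
}

# Jukes-Cantor mutation process: Poisson(mu * t * n_sites) hits placed
# uniformly over non-gap positions, each to a random different base
mutate_seq <- function(seq_chars, t, mu) {
  live <- which(seq_chars != "-")
  if (length(live) == 0L || t <= 0) return(seq_chars)
  n_mut <- stats::rpois(1L, mu * t * length(live))
  if (n_mut == 0L) return(seq_chars)
  pos <- sample(live, n_mut, replace = TRUE)
  for (p in pos) {
    seq_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1L)
  }
  seq_chars
}

evolve_species_tree <- function(seq_chars, t_top, node, mu) {
  if (is.character(node)) {
    out <- list()
    out[[node]] <- mutate_seq(seq_chars, t_top, mu)
    return(out)
  }
  s <- mutate_seq(seq_chars, t_top - node$time, mu)
  c(evolve_species_tree(s, node$time, node$left, mu),
    evolve_species_tree(s, node$time, node$right, mu))
}

apply_deletion <- function(seq_chars, region_cols, min_len = 10L,
                           max_len = 60L) {
  len <- sample(min_len:max_len, 1L)
  len <- min(len, length(region_cols) - 1L)
  start <- sample(seq_len(length(region_cols) - len), 1L)
  seq_chars[region_cols[start:(start + len - 1L)]] <- "-"
  seq_chars
}

random_gene_sequence <- function(annotation) {
  lens <- annotation$end - annotation$start
  total <- sum(lens)
  seq_chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  # lay sense codons across the coding frame so the reference is stop-free
  coding <- unlist(lapply(grep("^exon", annotation$name), function(r) {
    (annotation$start[r] + 1L):annotation$end[r]
  }))
  sense <- sense_codons()
  n_codon <- length(coding) %/% 3L
  cods <- sample(sense, n_codon, replace = TRUE)
  seq_chars[coding] <- unlist(strsplit(cods, ""))
  seq_chars
}

#' Simulate a clone library with trans-species balanced allele classes
#'
#' Paralogs diverge from a deep duplication root; within each paralog,
#' allele-class lineages originate at `t_anc` and, in the balancing
#' regime (`t_anc` older than every species split), every species
#' inherits every class, accumulating species-private mutations down the
#' species tree under a Jukes-Cantor process. Allele classes (and some
#' paralogs) may carry private intron-3 deletions. Each individual draws
#' up to two allele copies per amplifiable paralog (dropout applied, at
#' least one paralog always amplifiable), and its clones are drawn
#' uniformly from those copies with independent Poisson(e * L) singleton
#' PCR errors at uniform positions. Deterministic given `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @return a `sim_dataset` list: `aln` (observed `clone_alignment` with
#'   labels in the clone naming convention), `truth` (list: `clone_map`
#'   data.frame id/barcode/species/locality/paralog/class, `errors`
#'   data.frame id/column/from/to, `allele_seqs`), `config`.
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  ann <- cfg$annotation
  L <- max(ann$end)
  intron3 <- (ann$start[ann$name == "intron3"] + 1L):
    ann$end[ann$name == "intron3"]
  master <- random_gene_sequence(ann)
  sp_tree <- species_tree_default()
  t_root <- sp_tree$time

  # per (paralog, class, species) allele sequences
  allele_seqs <- list()
  for (g in seq_len(cfg$n_paralogs)) {
    par_anc <- mutate_seq(master, cfg$t_paralog - cfg$t_anc, cfg$mu)
    if (stats::runif(1L) < cfg$paralog_indel_prob) {
      par_anc <- apply_deletion(par_anc, intron3, 40L, 100L)
    }
    for (k in seq_len(cfg$n_classes)) {
      cls_anc <- mutate_seq(par_anc, cfg$t_anc - t_root, cfg$mu)
      if (stats::runif(1L) < cfg$indel_prob) {
        cls_anc <- apply_deletion(cls_anc, intron3)
      }
      tips <- evolve_species_tree(cls_anc, t_root, sp_tree, cfg$mu)
      for (sp in names(tips)) {
        allele_seqs[[sprintf("P%d.K%d.%s", g, k, sp)]] <- tips[[sp]]
      }
    }
  }

  sample_clones(cfg, allele_seqs,
                class_pool = function(sp, g) {
                  sprintf("P%d.K%d.%s", g, seq_len(cfg$n_classes), sp)
                })
}

#' Neutral control: allele lineages coalesce within species
#'
#' Identical machinery to [simulate_dataset()], but allele variation
#' arises only after speciation: each species carries per-paralog variants
#' that diverged ~2Ne generations ago within that species, so there are
#' no trans-species allele classes and species are monophyletic within
#' each paralog.
#'
#' @param cfg a `sim_config`.
#' @return a `sim_dataset` (see [simulate_dataset()]).
#' @export
neutral_control <- function(cfg) {
  set.seed(cfg$seed)
  ann <- cfg$annotation
  intron3 <- (ann$start[ann$name == "intron3"] + 1L):
    ann$end[ann$name == "intron3"]
  master <- random_gene_sequence(ann)
  sp_tree <- species_tree_default()
  t_root <- sp_tree$time

  allele_seqs <- list()
  for (g in seq_len(cfg$n_paralogs)) {
    par_anc <- mutate_seq(master, cfg$t_paralog - t_root, cfg$mu)
    if (stats::runif(1L) < cfg$paralog_indel_prob) {
      par_anc <- apply_deletion(par_anc, intron3, 40L, 100L)
    }
    tips <- evolve_species_tree(par_anc, t_root, sp_tree, cfg$mu)
    for (sp in names(tips)) {
      for (k in seq_len(cfg$n_classes)) {
        v <- mutate_seq(tips[[sp]], 2 * cfg$Ne, cfg$mu)
        allele_seqs[[sprintf("P%d.K%d.%s", g, k, sp)]] <- v
      }
    }
  }

  sample_clones(cfg, allele_seqs,
                class_pool = function(sp, g) {
                  sprintf("P%d.K%d.%s", g, seq_len(cfg$n_classes), sp)
                })
}

# shared individual/clone sampling and PCR-error injection
sample_clones <- function(cfg, allele_seqs, class_pool) {
  ind <- cfg$individuals
  n_clones <- ind$n_clones
  if (cfg$resample_clones) {
    n_clones <- sample(ind$n_clones, nrow(ind), replace = TRUE)
  }
  L <- max(cfg$annotation$end)
  seqs <- list()
  map_rows <- list()
  err_rows <- list()
  for (i in seq_len(nrow(ind))) {
    sp <- ind$species[i]
    # up to 2 allele copies per amplifiable paralog; >= 1 paralog present
    repeat {
      amplifiable <- stats::runif(cfg$n_paralogs) >= cfg$dropout
      if (any(amplifiable)) break
    }
    copies <- character(0)
    for (g in which(amplifiable)) {
      pool <- class_pool(sp, g)
      copies <- c(copies, sample(pool, 2L, replace = TRUE))
    }
    copies <- unique(copies)
    for (cn in seq_len(n_clones[i])) {
      src <- if (length(copies) == 1L) copies else sample(copies, 1L)
      s <- allele_seqs[[src]]
      id <- format_clone_label(ind$barcode[i], cn, sp, ind$locality[i])
      live <- which(s != "-")
      n_err <- stats::rpois(1L, cfg$error_rate * length(live))
      if (n_err > 0L) {
        pos <- sample(live, min(n_err, length(live)))
        for (p in pos) {
          old <- s[p]
          s[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          err_rows[[length(err_rows) + 1L]] <- data.frame(
            id = id, column = p, from = old, to = s[p],
            stringsAsFactors = FALSE)
        }
      }
      seqs[[id]] <- paste(s, collapse = "")
      parts <- strsplit(src, "\\.")[[1L]]
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        id = id, barcode = ind$barcode[i], species = sp,
        locality = ind$locality[i], paralog = parts[1L],
        class = paste(parts[1L], parts[2L], sep = "."),
        stringsAsFactors = FALSE)
    }
  }
  aln <- alignment(unlist(seqs))
  truth <- list(
    clone_map = do.call(rbind, map_rows),
    errors = if (length(err_rows) > 0L) do.call(rbind, err_rows) else
      data.frame(id = character(0), column = integer(0),
                 from = character(0), to = character(0)),
    allele_seqs = vapply(allele_seqs, paste, "", collapse = "")
  )
  structure(list(aln = aln, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", n_records(x$aln), "clones,",
      nrow(x$config$individuals), "individuals,",
      x$config$n_paralogs, "paralogs x", x$config$n_classes,
      "allele classes;", nrow(x$truth$errors), "injected PCR errors\n")
  invisible(x)
}

#' Simulate a codon alignment under counting-model selection regimes
#'
#' Evolves in-frame codon sequences along a coalescent tree under a
#' Jukes-Cantor mutation process with per-codon selection: mutation
#' attempts arise at rate 1 per site per unit branch length; attempts
#' creating stop codons are rejected; non-synonymous attempts are accepted
#' with probability `omega` at neutral codons (`omega = 1` accepts all,
#' the neutral regime) and with probability `omega_sel` (values > 1
#' instead *suppress* synonymous acceptance by `1/omega_sel`, keeping
#' dN/dS = omega_sel) at a fraction `sel_frac` of codons, emulating
#' diversifying selection at a subset of sites.
#'
#' @param n_taxa number of sequences (default 24).
#' @param n_codons number of codons (default 200).
#' @param depth total expected substitution attempts per site summed over
#'   the tree (tree length; default 8, deep enough that per-codon
#'   substitution counts make the binomial tails informative).
#' @param omega background non-synonymous acceptance probability (1).
#' @param sel_frac fraction of codons under `omega_sel` (0).
#' @param omega_sel dN/dS at selected codons (5).
#' @param seed RNG seed.
#' @return list: `aln` (a `clone_alignment` with generic ids), `tree`
#'   (the true `phylo`), `selected` (logical per codon).
#' @export
simulate_codon_alignment <- function(n_taxa = 24L, n_codons = 200L,
                                     depth = 8, omega = 1,
                                     sel_frac = 0, omega_sel = 5,
                                     seed = 1L) {
  set.seed(seed)
  tree <- ape::rcoal(n_taxa)
  tree$edge.length <- tree$edge.length * depth / sum(tree$edge.length)
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tab <- codon_table()
  sense <- sense_codons()
  selected <- stats::runif(n_codons) < sel_frac
  root_cod <- sample(sense, n_codons, replace = TRUE)
  nts <- c("A", "C", "G", "T")

  evolve_branch <- function(cods, t) {
    for (k in seq_len(n_codons)) {
      n_att <- stats::rpois(1L, 3 * t)
      if (n_att == 0L) next
      w <- if (selected[k]) omega_sel else omega
      p_nonsyn <- min(1, w)
      p_syn <- min(1, 1 / w)
      chars <- strsplit(cods[k], "")[[1L]]
      for (a in seq_len(n_att)) {
        pos <- sample.int(3L, 1L)
        nb <- chars
        nb[pos] <- sample(setdiff(nts, chars[pos]), 1L)
        cand <- paste(nb, collapse = "")
        if (tab[cand] == "*") next
        syn <- tab[cand] == tab[paste(chars, collapse = "")]
        acc <- if (syn) p_syn else p_nonsyn
        if (stats::runif(1L) < acc) chars <- nb
      }
      cods[k] <- paste(chars, collapse = "")
    }
    cods
  }

  n_node <- n_taxa + tree$Nnode
  states <- vector("list", n_node)
  root <- n_taxa + 1L
  states[[root]] <- root_cod
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1L]; ch <- pre[e, 2L]
    len <- tree$edge.length[which(tree$edge[, 1L] == p &
                                    tree$edge[, 2L] == ch)]
    states[[ch]] <- evolve_branch(states[[p]], len)
  }
  seqs <- vapply(seq_len(n_taxa), function(i) {
    paste(unlist(strsplit(states[[i]], "")), collapse = "")
  }, "")
  names(seqs) <- tree$tip.label
  aln <- alignment(seqs, parse_labels = FALSE)
  list(aln = aln, tree = tree, selected = selected)
}
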