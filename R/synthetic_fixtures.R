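# Generator of self-contained synthetic scenarios with planted ground
# truth: toy proteomes with isoforms and paralogs, HSP tables consistent
# with planted homology, block-model alignments with planted insertions,
# skipped-exon patterns and missing segments, labelled HMM training
# columns, and a species tree.  Scores use an identity model
# (bit score = 2 x matches + Gaussian noise); only their ordering matters
# downstream.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Scenario configuration
#'
#' Defaults describe the reference validation scenario: 8 species, 20
#' single-copy genes, 2 paralog pairs, 3 spurious insertions and 2
#' missing segments.
#'
#' @param n_species Number of species.
#' @param n_genes Number of (orthologous) genes.
#' @param n_paralog_pairs Species-local duplicate genes planted.
#' @param n_insertions Genes receiving a spurious insertion in one
#'   sequence.
#' @param n_missing Genes receiving a missing segment in one sequence.
#' @param n_skipped Genes receiving a skipped-exon block (half the
#'   species gapped over a block, phylogenetically discordant).
#' @param n_isoforms Genes where one species gets a second isoform.
#' @param core_len Core (conserved) sequence length in residues.
#' @param insertion_len Length of planted insertions.
#' @param missing_len Length of planted missing segments.
#' @param sub_prob Per-site substitution probability per unit branch
#'   length (identity model).
#' @param score_noise_sd Gaussian noise added to bit scores.
#' @export
scenario_config <- function(n_species = 8L, n_genes = 20L,
                            n_paralog_pairs = 2L, n_insertions = 3L,
                            n_missing = 2L, n_skipped = 0L,
                            n_isoforms = 0L, core_len = 100L,
                            insertion_len = 30L, missing_len = 25L,
                            sub_prob = 0.15, score_noise_sd = 0.5) {
  as.list(environment())
}

.mutate_seq <- function(chars, p, rng_n = length(chars)) {
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  }
  chars
}

#' Generate a planted scenario
#'
#' Produces, fully in memory and deterministically from the seed, a
#' species tree, per-species protein inventories (with planted paralogs
#' and isoforms), inter-genome and self-search HSP tables, per-gene
#' block-model alignments carrying the planted defects, per-column state
#' labels for the insertion model and per-position labels for the
#' missing-data model, and a ground-truth record of everything planted.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; regeneration with the same seed is
#'   identical.
#' @return A list of class \code{"planted_scenario"}; see fields
#'   \code{tree, proteins, gene_map, hsps, self_hsps, alignments,
#'   aln_meta, labels, truth}.
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1L) {
  if (config$n_insertions + config$n_missing + config$n_skipped >
      config$n_genes) {
    stop("more planted defects than genes")
  }
  set.seed(seed)
  ns <- config$n_species
  ng <- config$n_genes
  species <- sprintf("sp%02d", seq_len(ns))
  genes <- sprintf("g%02d", seq_len(ng))
  tree <- ape::rcoal(ns, tip.label = species)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  depth <- ape::node.depth.edgelength(tree)[seq_len(ns)]
  names(depth) <- tree$tip.label

  # Assign defects to distinct genes (paralogs/isoforms may overlap the
  # clean genes but not the defect genes, keeping the reference
  # single-copy alignments interpretable).
  defect_genes <- sample(genes, config$n_insertions + config$n_missing +
                           config$n_skipped)
  ins_genes <- defect_genes[seq_len(config$n_insertions)]
  mis_genes <- defect_genes[config$n_insertions + seq_len(config$n_missing)]
  skp_genes <- defect_genes[config$n_insertions + config$n_missing +
                              seq_len(config$n_skipped)]
  clean_genes <- setdiff(genes, defect_genes)
  par_genes <- sample(clean_genes, config$n_paralog_pairs)
  iso_genes <- sample(setdiff(clean_genes, par_genes), config$n_isoforms)

  # Core sequences: ancestral per gene, mutated per species by tip depth.
  L0 <- config$core_len
  core <- list()   # core[[gene]][[species]] = character vector of residues
  anc <- list()
  for (g in genes) {
    anc[[g]] <- sample(AA20, L0, replace = TRUE)
    core[[g]] <- list()
    for (s in species) {
      core[[g]][[s]] <- .mutate_seq(anc[[g]], config$sub_prob *
                                      (0.5 + depth[[s]]))
    }
  }

  # Planted defects: chosen species and intervals (on core coordinates).
  truth <- list(insertions = NULL, missing = NULL, skipped = NULL,
                paralog_pairs = NULL)
  ins_df <- data.frame(gene = character(0), species = character(0),
                       pos = integer(0))
  for (g in ins_genes) {
    ins_df <- rbind(ins_df, data.frame(
      gene = g, species = sample(species, 1L),
      pos = sample(20:(L0 - 20), 1L)))
  }
  mis_df <- data.frame(gene = character(0), species = character(0),
                       start = integer(0))
  for (g in mis_genes) {
    mis_df <- rbind(mis_df, data.frame(
      gene = g, species = sample(species, 1L),
      start = sample(20:(L0 - 20 - config$missing_len), 1L)))
  }
  skp_df <- data.frame(gene = character(0), start = integer(0))
  skp_species <- list()
  for (g in skp_genes) {
    skp_df <- rbind(skp_df, data.frame(
      gene = g, start = sample(20:(L0 - 40), 1L)))
    skp_species[[g]] <- sample(species, floor(ns / 2))
  }

  # Protein records.  Accessions: <species>_<gene>_p<i>.  Each record
  # also tracks the core coordinate of every residue (NA for inserted
  # residues) so that HSPs can be emitted per homologous segment, the way
  # a local search reports separate HSPs around indels.
  rec <- list()
  coords <- list()
  chars_of <- list()
  add_rec <- function(sp, gene, iso, seqchars, seqcoords) {
    acc <- sprintf("%s_%s_p%d", sp, gene, iso)
    rec[[length(rec) + 1L]] <<- data.frame(
      accession = acc, gene = gene, species = sp,
      sequence = paste(seqchars, collapse = ""),
      stringsAsFactors = FALSE)
    coords[[acc]] <<- seqcoords
    chars_of[[acc]] <<- seqchars
  }
  ins_seqs <- list()  # inserted residue strings per gene
  for (g in genes) {
    ins_row <- ins_df[ins_df$gene == g, ]
    mis_row <- mis_df[mis_df$gene == g, ]
    if (nrow(ins_row)) {
      ins_seqs[[g]] <- sample(AA20, config$insertion_len, replace = TRUE)
    }
    for (s in species) {
      chars <- core[[g]][[s]]
      crd <- seq_len(L0)
      if (nrow(mis_row) && mis_row$species == s) {
        drop <- mis_row$start:(mis_row$start + config$missing_len - 1L)
        chars <- chars[-drop]
        crd <- crd[-drop]
      }
      if (nrow(ins_row) && ins_row$species == s) {
        p <- ins_row$pos
        at <- which(crd == p)
        chars <- c(chars[seq_len(at)], ins_seqs[[g]],
                   chars[(at + 1L):length(chars)])
        crd <- c(crd[seq_len(at)], rep(NA_integer_, config$insertion_len),
                 crd[(at + 1L):length(crd)])
      }
      if (g %in% names(skp_species) && s %in% skp_species[[g]]) {
        row <- skp_df[skp_df$gene == g, ]
        drop <- which(crd %in% row$start:(row$start + 19L))
        chars <- chars[-drop]
        crd <- crd[-drop]
      }
      add_rec(s, g, 1L, chars, crd)
      if (g %in% iso_genes && s == species[1L]) {
        # second isoform: same gene, missing an internal block
        add_rec(s, g, 2L, chars[-(40:59)], crd[-(40:59)])
      }
    }
  }
  # Paralogs: duplicate of the species' own copy with light divergence.
  par_pairs <- data.frame(a = character(0), b = character(0))
  for (g in par_genes) {
    s <- sample(species, 1L)
    dup <- .mutate_seq(core[[g]][[s]], 0.05)
    pg <- paste0(g, "d")
    add_rec(s, pg, 1L, dup, seq_len(L0))
    par_pairs <- rbind(par_pairs, data.frame(
      a = sprintf("%s_%s_p1", s, g), b = sprintf("%s_%s_p1", s, pg)))
  }
  proteins <- do.call(rbind, rec)
  gene_map <- proteins[, c("species", "gene", "accession")]

  # HSP tables: one HSP per maximal homologous segment between
  # same-family sequences (gene g and its duplicate gd are one family),
  # scored as 2 x matches + noise, plus low-scoring distractor HSPs to a
  # different gene that the best-gene criterion must remove.
  fam <- sub("d$", "", proteins$gene)
  min_seg <- 5L
  mk_hsps <- function(i, j) {
    ci <- coords[[proteins$accession[i]]]
    cj <- coords[[proteins$accession[j]]]
    shared <- sort(intersect(ci[!is.na(ci)], cj[!is.na(cj)]))
    if (length(shared) == 0L) return(NULL)
    qpos <- match(shared, ci)
    spos <- match(shared, cj)
    brk <- c(0L, which(diff(qpos) != 1L | diff(spos) != 1L),
             length(shared))
    rows <- list()
    ql <- length(ci); sl <- length(cj)
    for (b in seq_len(length(brk) - 1L)) {
      sel <- (brk[b] + 1L):brk[b + 1L]
      if (length(sel) < min_seg) next
      m <- sum(chars_of[[proteins$accession[i]]][qpos[sel]] ==
                 chars_of[[proteins$accession[j]]][spos[sel]])
      bs <- max(2 * m + stats::rnorm(1L, 0, config$score_noise_sd), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = proteins$accession[i], sseqid = proteins$accession[j],
        bitscore = bs, evalue = exp(-bs),
        qstart = qpos[sel[1L]] - 1, qend = qpos[sel[length(sel)]],
        sstart = spos[sel[1L]] - 1, send = spos[sel[length(sel)]],
        qlen = ql, slen = sl, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  hsp_rows <- list()
  self_rows <- list()
  for (f in unique(fam)) {
    idx <- which(fam == f)
    for (i in idx) {
      for (j in idx) {
        if (i == j) next
        same_sp <- proteins$species[i] == proteins$species[j]
        blk <- mk_hsps(i, j)
        if (is.null(blk)) next
        if (same_sp) {
          self_rows[[length(self_rows) + 1L]] <- blk
        } else {
          hsp_rows[[length(hsp_rows) + 1L]] <- blk
        }
      }
    }
  }
  # Distractors: a weak full-ish HSP from each gene's first species
  # sequence to the NEXT gene in the same target species.  Score is far
  # below any true segment so best-gene extraction must discard it.
  for (gi in seq_len(ng)) {
    g <- genes[gi]
    g2 <- genes[gi %% ng + 1L]
    qacc <- sprintf("%s_%s_p1", species[1L], g)
    for (s in species[-1L]) {
      tacc <- sprintf("%s_%s_p1", s, g2)
      ql <- length(coords[[qacc]]); sl <- length(coords[[tacc]])
      w <- min(40L, ql, sl)
      hsp_rows[[length(hsp_rows) + 1L]] <- data.frame(
        qseqid = qacc, sseqid = tacc, bitscore = 30, evalue = exp(-30),
        qstart = 0, qend = w, sstart = 0, send = w,
        qlen = ql, slen = sl, stringsAsFactors = FALSE)
    }
  }
  hsps <- do.call(rbind, hsp_rows)
  self_hsps <- if (length(self_rows)) do.call(rbind, self_rows) else
    data.frame()

  # Reference single-copy alignments (block model) over the isoform-1
  # sequences of the 8 species, with planted defects in column space.
  alignments <- list()
  aln_meta <- list()
  labels <- list()
  truth_ins <- list()
  truth_mis <- list()
  truth_skp <- list()
  for (g in genes) {
    ins_row <- ins_df[ins_df$gene == g, ]
    mis_row <- mis_df[mis_df$gene == g, ]
    has_skp <- g %in% names(skp_species)
    ncols <- L0 + if (nrow(ins_row)) config$insertion_len else 0L
    rows <- list()
    for (s in species) {
      chars <- core[[g]][[s]]
      if (nrow(mis_row) && mis_row$species == s) {
        cols <- mis_row$start:(mis_row$start + config$missing_len - 1L)
        chars[cols] <- "-"
      }
      if (has_skp && s %in% skp_species[[g]]) {
        row <- skp_df[skp_df$gene == g, ]
        chars[row$start:(row$start + 19L)] <- "-"
      }
      if (nrow(ins_row)) {
        p <- ins_row$pos
        block <- if (ins_row$species == s) ins_seqs[[g]] else
          rep("-", config$insertion_len)
        chars <- c(chars[seq_len(p)], block,
                   chars[(p + 1L):length(chars)])
      }
      rows[[s]] <- paste(chars, collapse = "")
    }
    acc <- sprintf("%s_%s_p1", species, g)
    aln <- stats::setNames(unlist(rows[species]), acc)
    alignments[[g]] <- aln
    aln_meta[[g]] <- data.frame(accession = acc, species = species,
                                gene = g, stringsAsFactors = FALSE)
    lab <- rep(1L, ncols)
    if (nrow(ins_row)) {
      cols <- (ins_row$pos + 1L):(ins_row$pos + config$insertion_len)
      lab[cols] <- 3L
      truth_ins[[g]] <- data.frame(gene = g, species = ins_row$species,
                                   start = cols[1L],
                                   end = cols[length(cols)])
    }
    if (nrow(mis_row)) {
      truth_mis[[g]] <- data.frame(gene = g, species = mis_row$species,
                                   start = mis_row$start,
                                   end = mis_row$start +
                                     config$missing_len - 1L)
    }
    if (has_skp) {
      row <- skp_df[skp_df$gene == g, ]
      cols <- row$start:(row$start + 19L)
      if (nrow(ins_row) && ins_row$pos < row$start) {
        cols <- cols + config$insertion_len
      }
      lab[cols] <- 2L
      truth_skp[[g]] <- data.frame(gene = g, start = cols[1L],
                                   end = cols[length(cols)])
    }
    labels[[g]] <- lab
  }

  # Ground-truth orthogroups: one per gene family, paralogs included,
  # isoforms included.
  truth_groups <- lapply(unique(fam), function(f) {
    sort(proteins$accession[fam == f])
  })
  names(truth_groups) <- unique(fam)

  structure(list(
    config = config, seed = seed, tree = tree,
    proteins = proteins, gene_map = gene_map,
    hsps = hsps, self_hsps = self_hsps,
    alignments = alignments, aln_meta = aln_meta, labels = labels,
    truth = list(orthogroups = truth_groups,
                 paralog_pairs = par_pairs,
                 insertions = if (length(truth_ins))
                   do.call(rbind, truth_ins) else NULL,
                 missing = if (length(truth_mis))
                   do.call(rbind, truth_mis) else NULL,
                 skipped = if (length(truth_skp))
                   do.call(rbind, truth_skp) else NULL)),
    class = "planted_scenario")
}

#' Write a scenario's files to a directory
#'
#' Emits protein FASTA per species, a gene map TSV, inter-genome and
#' self-search HSP tables in BLAST tabular format (1-based closed
#' coordinates), per-gene aligned FASTA, the species tree in Newick, and
#' per-gene column-label TSVs.
#'
#' @param scenario A \code{planted_scenario}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pr <- scenario$proteins
  for (s in unique(pr$species)) {
    sub <- pr[pr$species == s, ]
    write_fasta(stats::setNames(sub$sequence, sub$accession),
                file.path(dir, paste0(s, ".fasta")))
  }
  utils::write.table(scenario$gene_map,
                     file.path(dir, "gene_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  wr_blast <- function(df, path) {
    out <- df
    out$qstart <- out$qstart + 1
    out$sstart <- out$sstart + 1
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  wr_blast(scenario$hsps, file.path(dir, "hsps_inter.tsv"))
  if (nrow(scenario$self_hsps)) {
    wr_blast(scenario$self_hsps, file.path(dir, "hsps_self.tsv"))
  }
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  for (g in names(scenario$alignments)) {
    write_fasta(scenario$alignments[[g]],
                file.path(dir, "alignments", paste0(g, ".fasta")))
    utils::write.table(
      data.frame(column = seq_along(scenario$labels[[g]]),
                 state = scenario$labels[[g]]),
      file.path(dir, "alignments", paste0(g, "_labels.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ape::write.tree(scenario$tree, file.path(dir, "species_tree.nwk"))
  invisible(dir)
}
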