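#' Read a FASTA file into a named character vector
#'
#' Minimal FASTA reader used for both unaligned protein/CDS sequences and
#' aligned (gapped) FASTA.  The full header line after ">" up to the first
#' whitespace becomes the name.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly gapped).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  names_all <- sub("^>\\s*", "", lines[hdr])
  names_all <- sub("\\s.*$", "", names_all)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- character(length(names_all))
  out[as.integer(names(seqs))] <- seqs
  names(out) <- names_all
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read BLAST+ tabular output
#'
#' Parses the custom tabular format
#' \code{-outfmt "6 qseqid sseqid bitscore evalue qstart qend sstart send qlen slen"}.
#' BLAST's 1-based closed residue coordinates are converted to 0-based
#' half-open intervals at parse time.
#'
#' @param path Path to the tabular file.  Lines starting with "#" (outfmt 7
#'   comments) are skipped.
#' @return A data.frame of HSPs with columns \code{qseqid, sseqid, bitscore,
#'   evalue, qstart, qend, sstart, send, qlen, slen} where start/end pairs
#'   are 0-based half-open.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "bitscore", "evalue",
            "qstart", "qend", "sstart", "send", "qlen", "slen")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols,
                          colClasses = c("character", "character",
                                         rep("numeric", 8)),
                          stringsAsFactors = FALSE)
  # 1-based closed -> 0-based half-open
  df$qstart <- df$qstart - 1
  df$sstart <- df$sstart - 1
  df
}

#' Read a gene-to-protein accession map
#'
#' @param path TSV with columns \code{species_id, gene_id, accession}
#'   (no header).
#' @return data.frame with columns \code{species, gene, accession}.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("species", "gene", "accession"),
                          colClasses = "character")
  df
}

#' Write an undirected edge list as TSV
#'
#' @param edges data.frame with columns \code{a, b, score}.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize phylo-HMM model parameters to a flat key-value text file
#'
#' One row per parameter: \code{state, component, parameter, value}.
#' Components are \code{start} (initial distribution), \code{trans}
#' (transition row, parameter names \code{to_<state>}), \code{ctmc}
#' (\code{rate01}: gap to non-gap, \code{rate10}: non-gap to gap),
#' \code{jump} (\code{eps}, \code{q}) and \code{stickiness} (\code{a},
#' \code{b}).
#'
#' @param spec An HMM specification as returned by [hmm_spec()] whose
#'   emission carries per-state phylogenetic parameters.
#' @param path Output path.
#' @export
write_hmm_params <- function(spec, path) {
  rows <- list()
  st <- spec$states
  for (i in seq_along(st)) {
    rows[[length(rows) + 1L]] <-
      data.frame(state = st[i], component = "start", parameter = "p",
                 value = spec$start[i])
    for (j in seq_along(st)) {
      rows[[length(rows) + 1L]] <-
        data.frame(state = st[i], component = "trans",
                   parameter = paste0("to_", st[j]),
                   value = spec$trans[i, j])
    }
    ep <- spec$emission_params[[i]]
    if (!is.null(ep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        state = st[i],
        component = c("ctmc", "ctmc", "jump", "jump",
                      "stickiness", "stickiness"),
        parameter = c("rate01", "rate10", "eps", "q", "a", "b"),
        value = c(ep$ctmc$rate01, ep$ctmc$rate10,
                  ep$jump$eps, ep$jump$q,
                  ep$stick$a, ep$stick$b))
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phylo-HMM model parameters written by [write_hmm_params()]
#'
#' @param path Path to the parameter TSV.
#' @return A list with \code{states}, \code{start}, \code{trans} and
#'   \code{emission_params} (per-state list of ctmc/jump/stick blocks).
#' @export
read_hmm_params <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "numeric"),
                          stringsAsFactors = FALSE)
  states <- unique(df$state)
  n <- length(states)
  start <- numeric(n)
  trans <- matrix(0, n, n, dimnames = list(states, states))
  em <- vector("list", n)
  for (i in seq_len(n)) {
    d <- df[df$state == states[i], ]
    start[i] <- d$value[d$component == "start"]
    for (j in seq_len(n)) {
      trans[i, j] <- d$value[d$component == "trans" &
                             d$parameter == paste0("to_", states[j])]
    }
    gv <- function(comp, par) {
      v <- d$value[d$component == comp & d$parameter == par]
      if (length(v)) v else NA_real_
    }
    if (any(d$component == "ctmc")) {
      em[[i]] <- emission_params(
        ctmc = binary_ctmc(gv("ctmc", "rate01"), gv("ctmc", "rate10")),
        jump = tip_jump(gv("jump", "eps"), gv("jump", "q")),
        stick = stickiness_params(gv("stickiness", "a"), gv("stickiness", "b")))
    }
  }
  list(states = states, start = start, trans = trans, emission_params = em)
}
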