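# Clustering of the reciprocal-best-hit graph into orthologous groups by
# k-clique percolation, with a k-core fallback for pathological components,
# paralog augmentation, gene-level grouping and single-copy selection.

#' Build a hit graph from an undirected edge list
#'
#' @param edges data.frame with columns \code{a, b, score}.
#' @param meta data.frame with columns \code{accession, species, gene}
#'   covering every node.
#' @return An \pkg{igraph} graph with vertex attributes \code{species} and
#'   \code{gene} and edge attribute \code{score}.
#' @export
build_hit_graph <- function(edges, meta) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  idx <- match(nodes, meta$accession)
  if (anyNA(idx)) stop("edge node(s) missing from metadata")
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = nodes,
                          species = meta$species[idx],
                          gene = meta$gene[idx],
                          stringsAsFactors = FALSE))
  igraph::E(g)$score <- edges$score
  igraph::simplify(g, edge.attr.comb = list(score = "max"))
}

timeout_condition <- function(msg) {
  structure(class = c("orthotrim_timeout", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Cluster one graph component by k-clique percolation
#'
#' Clusters are unions of k-cliques reachable from one another through
#' k-cliques sharing k-1 nodes.  Implemented progressively over maximal
#' cliques: two maximal cliques of size >= k belong to the same community
#' iff they share at least k-1 nodes, and each maximal clique is checked
#' against the cliques of known communities, merging communities when a
#' clique bridges several.  Clusters may overlap in nodes.
#'
#' @param g An \pkg{igraph} graph (typically one connected component).
#' @param k Clique size, >= 2.  k = 2 reduces to connected components and
#'   k = 3 to triangle percolation.
#' @param timeout Wall-clock seconds allowed for each of the two phases
#'   (maximal-clique enumeration; community accretion).  On expiry a
#'   condition of class \code{"orthotrim_timeout"} is signalled.
#' @param max_cliques Deterministic work budget: if more maximal cliques
#'   than this are found, the timeout condition is signalled (used to make
#'   fallback behaviour reproducible in tests).
#' @return List of character vectors of vertex names (possibly overlapping).
#' @export
clique_percolation <- function(g, k = 4L, timeout = 90,
                               max_cliques = Inf) {
  stopifnot(k >= 2L)
  t0 <- proc.time()[["elapsed"]]
  cl <- igraph::max_cliques(g, min = k)
  if (proc.time()[["elapsed"]] - t0 > timeout) {
    stop(timeout_condition("maximal clique enumeration timed out"))
  }
  if (length(cl) > max_cliques) {
    stop(timeout_condition("maximal clique budget exceeded"))
  }
  if (length(cl) == 0L) return(list())
  names_g <- igraph::V(g)$name
  cl <- lapply(cl, function(x) sort(as.integer(x)))
  t1 <- proc.time()[["elapsed"]]
  # communities: list of lists of clique vertex-id vectors
  communities <- list()
  for (ci in seq_along(cl)) {
    if (proc.time()[["elapsed"]] - t1 > timeout) {
      stop(timeout_condition("community accretion timed out"))
    }
    this <- cl[[ci]]
    joined <- integer(0)
    for (m in seq_along(communities)) {
      for (other in communities[[m]]) {
        if (length(intersect(this, other)) >= k - 1L) {
          joined <- c(joined, m)
          break
        }
      }
    }
    if (length(joined) == 0L) {
      communities[[length(communities) + 1L]] <- list(this)
    } else {
      tgt <- joined[1L]
      communities[[tgt]] <- c(communities[[tgt]], list(this))
      if (length(joined) > 1L) {
        for (m in rev(joined[-1L])) {
          communities[[tgt]] <- c(communities[[tgt]], communities[[m]])
          communities[[m]] <- NULL
        }
      }
    }
  }
  out <- lapply(communities, function(comm) {
    sort(names_g[sort(unique(unlist(comm)))])
  })
  # canonical order: clusters may overlap, so sort by the full member key
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

#' k-core fallback clustering
#'
#' Used when clique percolation times out on a component: returns the
#' connected components of the maximal subgraph in which every node has
#' degree at least k-1 (matching the internal degree of a k-clique's
#' nodes).
#'
#' @param g An \pkg{igraph} graph.
#' @param k Clique-size parameter shared with [clique_percolation()].
#' @return List of character vectors of vertex names.
#' @export
k_core_fallback <- function(g, k = 4L) {
  core <- igraph::coreness(g)
  sub <- igraph::induced_subgraph(g, which(core >= k - 1L))
  if (igraph::vcount(sub) == 0L) return(list())
  comp <- igraph::components(sub)
  out <- split(igraph::V(sub)$name, comp$membership)
  out <- lapply(unname(out), sort)
  out[order(vapply(out, `[`, character(1), 1L))]
}

#' Cluster every component of a hit graph, with timeout fallback
#'
#' @inheritParams clique_percolation
#' @return A list of orthogroups: each a list with \code{id} (zero-padded
#'   hex-free sequential label), \code{members}, and logical
#'   \code{fallback}.
#' @export
cluster_hit_graph <- function(g, k = 4L, timeout = 90, max_cliques = Inf) {
  comp <- igraph::components(g)
  groups <- list()
  for (ci in seq_len(comp$no)) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == ci))
    res <- tryCatch(
      list(clusters = clique_percolation(sub, k, timeout, max_cliques),
           fallback = FALSE),
      orthotrim_timeout = function(e) {
        list(clusters = k_core_fallback(sub, k), fallback = TRUE)
      })
    for (memb in res$clusters) {
      groups[[length(groups) + 1L]] <- list(members = memb,
                                            fallback = res$fallback)
    }
  }
  # deterministic ids: order groups by first member
  ord <- order(vapply(groups, function(gr) gr$members[1L], character(1)))
  groups <- groups[ord]
  for (i in seq_along(groups)) {
    groups[[i]]$id <- sprintf("OG%04d", i)
  }
  groups
}

#' Derive parent genes and species of a group
#'
#' @param group A group list with \code{members}.
#' @param meta data.frame with columns \code{accession, species, gene}.
#' @return The group with added \code{parent_genes} (character
#'   "species|gene" keys) and \code{species} fields.
#' @export
annotate_group <- function(group, meta) {
  idx <- match(group$members, meta$accession)
  if (anyNA(idx)) stop("group member(s) missing from metadata")
  group$parent_genes <- sort(unique(paste(meta$species[idx],
                                          meta$gene[idx], sep = "|")))
  group$species <- sort(unique(meta$species[idx]))
  group
}

#' Add paralogs to orthologous groups
#'
#' For each original member of a group every accession paired with it is
#' added.  Addition is one-step: pairs touching only added members do not
#' propagate.
#'
#' @param groups List of groups with \code{members}.
#' @param pairs data.frame of unordered pairs with columns \code{a, b}.
#' @return Groups with augmented member sets.
#' @export
add_paralogs <- function(groups, pairs) {
  if (nrow(pairs) == 0L) return(groups)
  partner <- split(c(pairs$b, pairs$a), c(pairs$a, pairs$b))
  lapply(groups, function(gr) {
    extra <- unlist(partner[gr$members], use.names = FALSE)
    gr$members <- sort(unique(c(gr$members, extra)))
    gr
  })
}

#' Group orthologous groups by parent gene
#'
#' Builds a gene-overlap graph with an edge between two orthogroups when
#' the intersection of their parent-gene sets is at least 50% of the
#' smaller set; gene groups are its connected components.
#'
#' @param groups List of annotated groups (see [annotate_group()]).
#' @return List of gene groups: each a list with \code{id},
#'   \code{orthogroup_ids} and \code{union_genes}.
#' @export
group_by_gene <- function(groups) {
  n <- length(groups)
  if (n == 0L) return(list())
  ids <- vapply(groups, `[[`, character(1), "id")
  gsets <- lapply(groups, `[[`, "parent_genes")
  # union-find over orthogroups
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- length(intersect(gsets[[i]], gsets[[j]]))
        if (ov >= 0.5 * min(length(gsets[[i]]), length(gsets[[j]]))) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  out <- lapply(comps, function(ix) {
    list(orthogroup_ids = sort(ids[ix]),
         union_genes = sort(unique(unlist(gsets[ix]))))
  })
  out <- unname(out)
  ord <- order(vapply(out, function(gg) gg$orthogroup_ids[1L], character(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- sprintf("GG%04d", i)
  out
}

#' Validate phylogenetic diversity criteria
#'
#' @param criteria List of criteria, each a list with \code{species}
#'   (character vector) and \code{min} (integer).
#' @param known_species Character vector of valid species ids.
#' @export
validate_criteria <- function(criteria, known_species) {
  for (cr in criteria) {
    unknown <- setdiff(cr$species, known_species)
    if (length(unknown)) {
      stop("criteria reference unknown species: ",
           paste(unknown, collapse = ", "))
    }
    if (cr$min > length(cr$species)) {
      stop("criterion minimum exceeds set size")
    }
  }
  invisible(TRUE)
}

#' Select single-copy orthologous groups
#'
#' Drops groups in which any species contributes two or more distinct
#' parent genes, drops groups failing any phylogenetic diversity
#' criterion (a minimum number of species present from each named set),
#' then keeps within each gene group the single orthogroup maximal by
#' (number of species, total edge score), ties broken by group id.
#'
#' @param groups List of annotated groups.
#' @param criteria Diversity criteria (see [validate_criteria()]); may be
#'   an empty list.
#' @param gene_groups Output of [group_by_gene()] over \code{groups}.
#' @param graph The hit graph (for total edge scores); may be \code{NULL},
#'   in which case scores count as 0.
#' @param known_species Species universe for criteria validation.
#' @return The selected subset of \code{groups}.
#' @export
select_single_copy <- function(groups, criteria, gene_groups, graph = NULL,
                               known_species = NULL) {
  if (is.null(known_species)) {
    known_species <- sort(unique(unlist(lapply(groups, `[[`, "species"))))
  }
  validate_criteria(criteria, known_species)
  ids <- vapply(groups, `[[`, character(1), "id")
  single <- vapply(groups, function(gr) {
    sp <- sub("\\|.*$", "", gr$parent_genes)
    !any(duplicated(sp))
  }, logical(1))
  meets <- vapply(groups, function(gr) {
    all(vapply(criteria, function(cr) {
      sum(cr$species %in% gr$species) >= cr$min
    }, logical(1)))
  }, logical(1))
  eligible <- single & meets
  score_of <- function(gr) {
    if (is.null(graph)) return(0)
    sub <- igraph::induced_subgraph(
      graph, intersect(gr$members, igraph::V(graph)$name))
    if (igraph::ecount(sub) == 0L) return(0)
    sum(igraph::E(sub)$score)
  }
  keep_ids <- character(0)
  for (gg in gene_groups) {
    cand <- which(ids %in% gg$orthogroup_ids & eligible)
    if (length(cand) == 0L) next
    nsp <- vapply(groups[cand], function(gr) length(gr$species), integer(1))
    sc <- vapply(groups[cand], score_of, numeric(1))
    ord <- order(-nsp, -sc, ids[cand])
    keep_ids <- c(keep_ids, ids[cand[ord[1L]]])
  }
  groups[ids %in% keep_ids]
}
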