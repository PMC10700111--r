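# Independent oracles used by the unit and acceptance tests.  These stay
# deliberately naive (enumeration, dynamic programming, direct counting)
# and never share code with the implementation paths they check.

# --- k-clique percolation oracle: enumerate all k-cliques, connect those
# sharing k-1 nodes, take connected components of that adjacency.
oracle_cpm <- function(g, k) {
  kcl <- igraph::cliques(g, min = k, max = k)
  if (length(kcl) == 0L) return(list())
  kcl <- lapply(kcl, as.integer)
  m <- length(kcl)
  adj <- matrix(FALSE, m, m)
  if (m > 1L) {
    for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
      adj[i, j] <- adj[j, i] <-
        length(intersect(kcl[[i]], kcl[[j]])) >= k - 1L
    }
  }
  seen <- rep(FALSE, m)
  comps <- list()
  for (i in seq_len(m)) {
    if (seen[i]) next
    stack <- i
    comp <- integer(0)
    while (length(stack)) {
      v <- stack[1L]
      stack <- stack[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- sort(unique(unlist(kcl[comp])))
  }
  out <- lapply(comps, function(ix) sort(igraph::V(g)$name[ix]))
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

# --- HMM total likelihood by explicit path enumeration (vectorised over
# paths; loops only over positions).
oracle_path_likelihood <- function(log_em, start, trans) {
  L <- nrow(log_em)
  S <- ncol(log_em)
  em <- exp(log_em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  v <- start[paths[, 1L]] * em[cbind(1L, paths[, 1L])]
  if (L > 1L) {
    for (t in 2L:L) {
      v <- v * trans[cbind(paths[, t - 1L], paths[, t])] *
        em[cbind(t, paths[, t])]
    }
  }
  sum(v)
}

# --- column likelihood by enumeration over internal-node states.
oracle_prune <- function(tree, ctmc, jump, column) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  root <- ntip + 1L
  tipP <- function(obs, x) {
    (1 - jump$eps) * (obs == x) +
      jump$eps * ifelse(obs == 1L, jump$q, 1 - jump$q)
  }
  total <- 0
  for (assign in 0:(2^nint - 1L)) {
    st <- integer(ntip + nint)
    for (k in seq_len(nint)) {
      st[ntip + k] <- bitwAnd(bitwShiftR(assign, k - 1L), 1L)
    }
    p <- ctmc$stationary[[st[root] + 1L]]
    for (e in seq_len(nrow(edge))) {
      P <- ctmc_pmatrix(ctmc, elen[e])
      par <- st[edge[e, 1L]]
      ch <- edge[e, 2L]
      if (ch <= ntip) {
        obs <- column[[tree$tip.label[ch]]]
        p <- p * sum(P[par + 1L, ] * c(tipP(obs, 0L), tipP(obs, 1L)))
      } else {
        p <- p * P[par + 1L, st[ch] + 1L]
      }
    }
    total <- total + p
  }
  total
}

# --- optimal weighted interval scheduling by dynamic programming
# (classic known solution); intervals are half-open [start, stop).
oracle_wis <- function(starts, stops, weights) {
  n <- length(starts)
  if (n == 0L) return(0)
  o <- order(stops)
  starts <- starts[o]; stops <- stops[o]; weights <- weights[o]
  opt <- numeric(n + 1L)
  for (i in seq_len(n)) {
    # last interval ending at or before starts[i]
    j <- 0L
    for (m in seq_len(i - 1L)) if (stops[m] <= starts[i]) j <- m
    opt[i + 1L] <- max(opt[i], opt[j + 1L] + weights[i])
  }
  opt[n + 1L]
}

# --- beta-binomial pmf by numerical integration of the Bernoulli
# likelihood over the beta density.
oracle_betabinom <- function(c, N, a, b) {
  choose(N, c) * stats::integrate(function(p) {
    p^c * (1 - p)^(N - c) * stats::dbeta(p, a, b)
  }, 0, 1, rel.tol = 1e-12)$value
}

# --- random HSP table builder for merge tests.
random_hsps <- function(n, qlen = 100L, seed_state = NULL) {
  starts <- sample.int(qlen - 5L, n, replace = TRUE) - 1L
  lens <- sample(3:40, n, replace = TRUE)
  stops <- pmin(starts + lens, qlen)
  data.frame(qseqid = "q", sseqid = "t",
             bitscore = round(stats::runif(n, 10, 200), 2),
             evalue = 1e-20,
             qstart = starts, qend = stops,
             sstart = starts, send = stops,
             qlen = qlen, slen = qlen,
             stringsAsFactors = FALSE)
}

# partition labels (element -> cluster id) from a list of member vectors
labels_from_groups <- function(groups) {
  memb <- lapply(groups, function(g) if (is.list(g)) g$members else g)
  ids <- if (!is.null(names(groups))) names(groups) else
    as.character(seq_along(groups))
  stats::setNames(rep(ids, lengths(memb)), unlist(memb))
}

# small fixed test tree used across phylo tests
fixture_tree <- function() {
  ape::read.tree(text = "((A:0.3,B:0.2):0.2,(C:0.4,D:0.1):0.3);")
}
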