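# Generic discrete HMM engine (forward/backward, posterior decoding,
# simulation, discriminative training) plus the phylogenetic emission
# architecture: per-state two-state CTMC on a species tree with a tip-level
# jump process, a beta-binomial gap-stickiness component, and
# posterior-probability emissions for the missing-data model.
#
# Binary symbols are coded 0 = gap, 1 = non-gap throughout.

#' Two-state continuous-time Markov chain on {gap, non-gap}
#'
#' @param rate01 Rate gap -> non-gap, >= 0.
#' @param rate10 Rate non-gap -> gap, >= 0.
#' @return List of class \code{"binary_ctmc"} with rates and the implied
#'   stationary distribution (uniform when both rates are 0).
#' @export
binary_ctmc <- function(rate01, rate10) {
  stopifnot(rate01 >= 0, rate10 >= 0)
  s <- rate01 + rate10
  pi <- if (s == 0) c(0.5, 0.5) else c(rate10, rate01) / s
  structure(list(rate01 = rate01, rate10 = rate10,
                 stationary = stats::setNames(pi, c("gap", "nongap"))),
            class = "binary_ctmc")
}

#' Transition probability matrix of a binary CTMC over a branch
#'
#' Closed form for two states: \code{P(t) = Pi + exp(-s t) (I - Pi)} with
#' \code{s} the total rate and \code{Pi} the stationary projector.
#'
#' @param ctmc A \code{binary_ctmc}.
#' @param t Branch length, >= 0.
#' @return 2x2 row-stochastic matrix, rows/cols ordered (gap, non-gap).
#' @export
ctmc_pmatrix <- function(ctmc, t) {
  if (t < 0) stop("negative branch length")
  s <- ctmc$rate01 + ctmc$rate10
  pi <- ctmc$stationary
  PI <- rbind(pi, pi)
  e <- exp(-s * t)
  P <- PI + e * (diag(2) - PI)
  dimnames(P) <- list(c("gap", "nongap"), c("gap", "nongap"))
  P
}

#' Tip jump process
#'
#' Observation-level noise at tree tips: with probability \code{eps} the
#' observed symbol is redrawn from a Bernoulli with P(non-gap) = \code{q},
#' independently of the tip's latent state.
#'
#' @param eps Jump probability in [0, 1].
#' @param q Bernoulli parameter P(non-gap) in [0, 1].
#' @export
tip_jump <- function(eps, q) {
  stopifnot(eps >= 0, eps <= 1, q >= 0, q <= 1)
  structure(list(eps = eps, q = q), class = "tip_jump")
}

#' Beta-binomial stickiness parameters
#'
#' @param a,b Beta shape parameters, > 0.
#' @export
stickiness_params <- function(a, b) {
  stopifnot(a > 0, b > 0)
  structure(list(a = a, b = b), class = "stickiness_params")
}

#' Per-state phylogenetic emission parameters
#'
#' @param ctmc A \code{binary_ctmc}.
#' @param jump A \code{tip_jump}.
#' @param stick A \code{stickiness_params}.
#' @export
emission_params <- function(ctmc, jump, stick) {
  structure(list(ctmc = ctmc, jump = jump, stick = stick),
            class = "emission_params")
}

#' Beta-binomial log pmf
#'
#' @param c Count(s) in 0..N.
#' @param N Number of trials.
#' @param a,b Beta shape parameters.
#' @return Log probability mass.
#' @export
dbetabinom_log <- function(c, N, a, b) {
  lchoose(N, c) + lbeta(c + a, N - c + b) - lbeta(a, b)
}

# Vectorised Felsenstein pruning over many columns.
# columns: integer matrix [n_tips x n_cols], rownames = tip labels,
#          values 0 (gap) / 1 (non-gap).
# Returns list(lik = numeric n_cols, root_partials = list of 2 matrices)
prune_columns <- function(tree, ctmc, jump, columns) {
  stopifnot(inherits(tree, "phylo"))
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  if (is.null(elen)) stop("tree must have branch lengths")
  if (any(elen < 0)) stop("negative branch length")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ncols <- ncol(columns)
  if (!all(tree$tip.label %in% rownames(columns))) {
    stop("column matrix missing tip(s): ",
         paste(setdiff(tree$tip.label, rownames(columns)), collapse = ", "))
  }
  columns <- columns[tree$tip.label, , drop = FALSE]
  eps <- jump$eps
  q <- jump$q
  # tip partials: P(obs | latent = gap), P(obs | latent = nongap)
  # obs gap:    (1-eps) * [latent == gap] + eps * (1 - q)
  # obs nongap: (1-eps) * [latent == nongap] + eps * q
  Lg <- vector("list", nnode)  # each: [ncols x 2]
  for (i in seq_len(ntip)) {
    obs <- columns[i, ]
    pg <- ifelse(obs == 0L, (1 - eps) + eps * (1 - q), eps * q)
    pn <- ifelse(obs == 0L, eps * (1 - q), (1 - eps) + eps * q)
    Lg[[i]] <- cbind(pg, pn)
  }
  scale_log <- rep(0, ncols)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]
    child <- edge[e, 2L]
    P <- ctmc_pmatrix(ctmc, elen[e])
    msg <- Lg[[child]] %*% t(P)  # [ncols x 2]: row x = sum_y P[x,y] L[y]
    if (is.null(Lg[[parent]])) {
      Lg[[parent]] <- msg
    } else {
      Lg[[parent]] <- Lg[[parent]] * msg
    }
    # rescale to avoid underflow on deep trees
    m <- pmax(Lg[[parent]][, 1L], Lg[[parent]][, 2L])
    bad <- m > 0 & (m < 1e-150 | m > 1e150)
    if (any(bad)) {
      Lg[[parent]][bad, ] <- Lg[[parent]][bad, ] / m[bad]
      scale_log[bad] <- scale_log[bad] + log(m[bad])
    }
  }
  root <- edge[nrow(edge), 1L]
  pi <- ctmc$stationary
  lik <- as.numeric(Lg[[root]] %*% pi)
  list(lik = lik, log_lik = log(lik) + scale_log)
}

#' Likelihood of one binary column under the phylogenetic emission
#'
#' Felsenstein pruning on the species tree with tip partials mixing the
#' latent symbol with the jump process:
#' \code{P(obs s | latent x) = (1 - eps) 1[s = x] + eps Bern_q(s)}.
#' The root is combined with the CTMC's stationary distribution.
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param ctmc A \code{binary_ctmc}.
#' @param jump A \code{tip_jump}.
#' @param column Named integer vector (0 = gap, 1 = non-gap) covering all
#'   tips.
#' @return P(column), a probability.
#' @export
prune_likelihood <- function(tree, ctmc, jump, column) {
  m <- matrix(column[tree$tip.label], ncol = 1,
              dimnames = list(tree$tip.label, NULL))
  prune_columns(tree, ctmc, jump, m)$lik[1L]
}

#' Posterior probability of a focal tip's symbol given all other tips
#'
#' Emission for the missing-data model:
#' \code{P(obs at focal | others) = P(column) / sum_s P(column with
#' focal = s)}, computed by two pruning passes.
#'
#' @inheritParams prune_likelihood
#' @param focal_tip Tip label whose symbol is conditioned on the rest.
#' @return A probability; the two focal symbol choices sum to 1.
#' @export
missing_emission <- function(tree, ctmc, jump, column, focal_tip) {
  stopifnot(focal_tip %in% names(column))
  full <- prune_likelihood(tree, ctmc, jump, column)
  alt <- column
  alt[focal_tip] <- 1L - column[[focal_tip]]
  full / (full + prune_likelihood(tree, ctmc, jump, alt))
}

# Vectorised missing emission across positions for one focal tip.
missing_emission_columns <- function(tree, ctmc, jump, columns, focal_tip) {
  full <- prune_columns(tree, ctmc, jump, columns)$log_lik
  alt <- columns
  alt[focal_tip, ] <- 1L - columns[focal_tip, ]
  other <- prune_columns(tree, ctmc, jump, alt)$log_lik
  1 / (1 + exp(other - full))
}

#' Column emission log-probability for the insertion model
#'
#' log P = log of the pruning likelihood of the column plus the
#' beta-binomial stickiness term on the number of tips whose symbol is
#' unchanged from the previous column; the first column (no predecessor)
#' omits the stickiness term.
#'
#' @param params An \code{emission_params} block for one hidden state.
#' @param tree Rooted \code{phylo}.
#' @param column Current column (named 0/1 vector over tips).
#' @param prev_column Previous column or \code{NULL}.
#' @param N Number of tips used by the stickiness component (defaults to
#'   the number of tips).
#' @return Log emission probability.
#' @export
column_emission <- function(params, tree, column, prev_column = NULL,
                            N = length(tree$tip.label)) {
  lp <- log(prune_likelihood(tree, params$ctmc, params$jump, column))
  if (!is.null(prev_column)) {
    cc <- sum(column[tree$tip.label] == prev_column[tree$tip.label])
    lp <- lp + dbetabinom_log(cc, N, params$stick$a, params$stick$b)
  }
  lp
}

#' HMM specification
#'
#' @param states Character vector of state labels.
#' @param start Initial distribution (sums to 1).
#' @param trans Row-stochastic transition matrix.
#' @param emission_params Optional per-state list of
#'   \code{emission_params} blocks (phylogenetic emissions).
#' @return List of class \code{"hmm_spec"}.
#' @export
hmm_spec <- function(states, start, trans, emission_params = NULL) {
  stopifnot(length(start) == length(states),
            nrow(trans) == length(states), ncol(trans) == length(states))
  if (abs(sum(start) - 1) > 1e-9) stop("start distribution must sum to 1")
  if (any(abs(rowSums(trans) - 1) > 1e-9)) {
    stop("transition rows must sum to 1")
  }
  dimnames(trans) <- list(states, states)
  structure(list(states = states, start = as.numeric(start), trans = trans,
                 emission_params = emission_params),
            class = "hmm_spec")
}

#' Scaled forward-backward recursions
#'
#' @param log_em Numeric matrix [T x S] of log emission probabilities.
#' @param start Initial distribution.
#' @param trans Row-stochastic transition matrix.
#' @return List with \code{posterior} ([T x S], rows sum to 1) and
#'   \code{log_lik}.
#' @export
forward_backward <- function(log_em, start, trans) {
  T_ <- nrow(log_em)
  S <- ncol(log_em)
  if (T_ == 0L) {
    return(list(posterior = matrix(numeric(0), 0, S), log_lik = 0))
  }
  # per-row max-shift keeps emissions finite for scaling
  shift <- apply(log_em, 1L, max)
  if (any(!is.finite(shift))) {
    stop("all-zero emission at position ", which(!is.finite(shift))[1L])
  }
  em <- exp(log_em - shift)
  alpha <- matrix(0, T_, S)
  cvec <- numeric(T_)
  a <- start * em[1L, ]
  cvec[1L] <- sum(a)
  if (cvec[1L] == 0) stop("all-zero emission at position 1")
  alpha[1L, ] <- a / cvec[1L]
  if (T_ > 1L) {
    for (t in 2L:T_) {
      a <- as.numeric(alpha[t - 1L, ] %*% trans) * em[t, ]
      cvec[t] <- sum(a)
      if (cvec[t] == 0) stop("all-zero emission at position ", t)
      alpha[t, ] <- a / cvec[t]
    }
  }
  beta <- matrix(0, T_, S)
  beta[T_, ] <- 1
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      beta[t, ] <- as.numeric(trans %*% (em[t + 1L, ] * beta[t + 1L, ])) /
        cvec[t + 1L]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, log_lik = sum(log(cvec)) + sum(shift))
}

#' Log emission matrix for the insertion phylo-HMM
#'
#' @param spec An \code{hmm_spec} with per-state \code{emission_params}.
#' @param tree Rooted \code{phylo}.
#' @param columns Integer matrix [n_tips x L], rownames = tip labels.
#' @return [L x S] log emission matrix.
#' @export
insertion_log_emissions <- function(spec, tree, columns) {
  L <- ncol(columns)
  S <- length(spec$states)
  N <- length(tree$tip.label)
  columns <- columns[tree$tip.label, , drop = FALSE]
  if (L == 0L) return(matrix(numeric(0), 0, S))
  cc <- if (L > 1L) {
    c(NA_integer_,
      colSums(columns[, -1L, drop = FALSE] ==
                columns[, -L, drop = FALSE]))
  } else NA_integer_
  out <- matrix(0, L, S)
  for (s in seq_len(S)) {
    ep <- spec$emission_params[[s]]
    out[, s] <- prune_columns(tree, ep$ctmc, ep$jump, columns)$log_lik
    if (L > 1L) {
      out[-1L, s] <- out[-1L, s] +
        dbetabinom_log(cc[-1L], N, ep$stick$a, ep$stick$b)
    }
  }
  out
}

#' Posterior decoding of alignment columns under the insertion model
#'
#' @inheritParams insertion_log_emissions
#' @return List with \code{posterior} ([L x S]) and \code{log_lik}.
#' @export
decode_insertion <- function(spec, tree, columns) {
  le <- insertion_log_emissions(spec, tree, columns)
  fb <- forward_backward(le, spec$start, spec$trans)
  colnames(fb$posterior) <- spec$states
  fb
}

#' Posterior decoding of one sequence under the missing-data model
#'
#' Emissions are the per-position posterior probabilities of the observed
#' symbol at the focal tip given all other tips, under each state's
#' phylogenetic parameters.
#'
#' @param spec A 2-state \code{hmm_spec} with per-state
#'   \code{emission_params} (stickiness unused).
#' @param tree Rooted \code{phylo}.
#' @param columns Integer matrix [n_tips x L].
#' @param focal_tip Tip label of the decoded sequence.
#' @return List with \code{posterior} ([L x S]) and \code{log_lik}.
#' @export
decode_missing <- function(spec, tree, columns, focal_tip) {
  L <- ncol(columns)
  S <- length(spec$states)
  le <- matrix(0, L, S)
  for (s in seq_len(S)) {
    ep <- spec$emission_params[[s]]
    le[, s] <- log(missing_emission_columns(tree, ep$ctmc, ep$jump,
                                            columns, focal_tip))
  }
  fb <- forward_backward(le, spec$start, spec$trans)
  colnames(fb$posterior) <- spec$states
  fb
}

#' Simulate a state path and binary alignment columns
#'
#' Samples the state path from the start/transition distributions, then
#' per column samples a root symbol from the state's CTMC stationary
#' distribution, evolves it down the tree with the CTMC transition
#' matrices, and applies the tip jump process.  Gap stickiness is emergent
#' from the CTMC, not separately sampled.
#'
#' @param spec An \code{hmm_spec} with per-state \code{emission_params}.
#' @param tree Rooted \code{phylo}.
#' @param length Number of columns.
#' @param seed Integer seed.
#' @return List with \code{path} (integer state indices) and
#'   \code{columns} (integer matrix [n_tips x length]).
#' @export
simulate_phylo_hmm <- function(spec, tree, length, seed) {
  set.seed(seed)
  S <- length(spec$states)
  ntip <- length(tree$tip.label)
  path <- integer(length)
  columns <- matrix(0L, ntip, length,
                    dimnames = list(tree$tip.label, NULL))
  if (length == 0L) return(list(path = path, columns = columns))
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  elen <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  root <- edge[1L, 1L]
  nnode <- ntip + tree$Nnode
  path[1L] <- sample.int(S, 1L, prob = spec$start)
  if (length > 1L) {
    for (t in 2L:length) {
      path[t] <- sample.int(S, 1L, prob = spec$trans[path[t - 1L], ])
    }
  }
  for (t in seq_len(length)) {
    ep <- spec$emission_params[[path[t]]]
    node_state <- integer(nnode)  # 1 = gap, 2 = nongap
    node_state[root] <- sample.int(2L, 1L, prob = ep$ctmc$stationary)
    for (e in seq_len(nrow(edge))) {
      P <- ctmc_pmatrix(ep$ctmc, elen[e])
      node_state[edge[e, 2L]] <-
        sample.int(2L, 1L, prob = P[node_state[edge[e, 1L]], ])
    }
    obs <- node_state[seq_len(ntip)] - 1L  # 0 gap / 1 nongap
    jumps <- stats::runif(ntip) < ep$jump$eps
    if (any(jumps)) {
      obs[jumps] <- as.integer(stats::runif(sum(jumps)) < ep$jump$q)
    }
    columns[, t] <- obs
  }
  list(path = path, columns = columns)
}
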