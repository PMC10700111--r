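# Discriminative training of the phylo-HMMs: minimise the per-position
# cross-entropy between the posterior decoding and manual state labels
# over an unconstrained reparameterisation (logits for distributions,
# log-rates for the CTMC).

.logit <- function(p) log(p / (1 - p))
.sigmoid <- function(x) 1 / (1 + exp(-x))
.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Flatten an hmm_spec (with phylogenetic emissions) into an unconstrained
# parameter vector, and back.
.spec_to_par <- function(spec) {
  S <- length(spec$states)
  par <- c(log(spec$start + 1e-12))
  for (i in seq_len(S)) par <- c(par, log(spec$trans[i, ] + 1e-12))
  for (i in seq_len(S)) {
    ep <- spec$emission_params[[i]]
    par <- c(par,
             log(ep$ctmc$rate01 + 1e-12), log(ep$ctmc$rate10 + 1e-12),
             .logit(min(max(ep$jump$eps, 1e-9), 1 - 1e-9)),
             .logit(min(max(ep$jump$q, 1e-9), 1 - 1e-9)),
             log(ep$stick$a), log(ep$stick$b))
  }
  par
}

.par_to_spec <- function(par, states) {
  S <- length(states)
  start <- .softmax(par[1:S])
  trans <- matrix(0, S, S)
  off <- S
  for (i in seq_len(S)) {
    trans[i, ] <- .softmax(par[off + 1:S])
    off <- off + S
  }
  em <- vector("list", S)
  for (i in seq_len(S)) {
    p <- par[off + 1:6]
    off <- off + 6L
    em[[i]] <- emission_params(
      ctmc = binary_ctmc(exp(p[1L]), exp(p[2L])),
      jump = tip_jump(.sigmoid(p[3L]), .sigmoid(p[4L])),
      stick = stickiness_params(exp(p[5L]), exp(p[6L])))
  }
  hmm_spec(states, start, trans, em)
}

#' Cross-entropy loss of posterior decoding against labels
#'
#' Mean over positions of \code{-log posterior[label]}, summed across the
#' labelled sequences.
#'
#' @param spec An \code{hmm_spec} with phylogenetic emissions.
#' @param tree Rooted \code{phylo}.
#' @param labeled List of examples, each a list with \code{columns}
#'   (integer matrix [n_tips x L]) and \code{labels} (integer state
#'   indices of length L).
#' @return Scalar loss (lower is better).
#' @export
decoding_loss <- function(spec, tree, labeled) {
  total <- 0
  n <- 0L
  for (ex in labeled) {
    fb <- decode_insertion(spec, tree, ex$columns)
    p <- fb$posterior[cbind(seq_along(ex$labels), ex$labels)]
    total <- total + sum(-log(pmax(p, 1e-300)))
    n <- n + length(ex$labels)
  }
  loss <- total / n
  if (!is.finite(loss)) stop("non-finite training loss")
  loss
}

#' Discriminative training of the insertion phylo-HMM
#'
#' Minimises [decoding_loss()] by derivative-free search (Nelder-Mead)
#' over the unconstrained reparameterisation, run in rounds so that the
#' reported loss trace is monotone non-increasing.  Returns the trained
#' spec if it strictly improves on the initial one, else the initial spec.
#'
#' @param spec0 Initial \code{hmm_spec} with phylogenetic emissions.
#' @param tree Rooted \code{phylo}.
#' @param labeled Labelled examples (see [decoding_loss()]).
#' @param rounds Number of optimisation rounds.
#' @param maxit Nelder-Mead iterations per round.
#' @return List with \code{spec}, \code{loss_trace} (initial loss followed
#'   by the best loss after each round) and \code{improved}.
#' @export
train_discriminative <- function(spec0, tree, labeled, rounds = 5L,
                                 maxit = 100L) {
  states <- spec0$states
  par <- .spec_to_par(spec0)
  obj <- function(p) {
    sp <- tryCatch(.par_to_spec(p, states), error = function(e) NULL)
    if (is.null(sp)) return(1e6)
    tryCatch(decoding_loss(sp, tree, labeled), error = function(e) 1e6)
  }
  loss0 <- obj(par)
  trace <- loss0
  best_par <- par
  best <- loss0
  for (r in seq_len(rounds)) {
    fit <- stats::optim(best_par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (fit$value < best) {
      best <- fit$value
      best_par <- fit$par
    }
    trace <- c(trace, best)
  }
  if (best < loss0) {
    list(spec = .par_to_spec(best_par, states), loss_trace = trace,
         improved = TRUE)
  } else {
    list(spec = spec0, loss_trace = trace, improved = FALSE)
  }
}

#' Gap-fraction-threshold baseline state classifier
#'
#' Memoryless baseline for benchmarking the phylo-HMM: assigns each column
#' to the state whose expected gap fraction (from the state's CTMC
#' stationary distribution mixed with its jump process) is nearest the
#' observed gap fraction; ties break to the lower state index.
#'
#' @param spec An \code{hmm_spec} with phylogenetic emissions.
#' @param columns Integer matrix [n_tips x L].
#' @return Integer vector of state indices of length L.
#' @export
gap_fraction_baseline <- function(spec, columns) {
  expected <- vapply(spec$emission_params, function(ep) {
    pg <- ep$ctmc$stationary[["gap"]]
    (1 - ep$jump$eps) * pg + ep$jump$eps * (1 - ep$jump$q)
  }, numeric(1))
  obs <- colMeans(columns == 0L)
  vapply(obs, function(o) which.min(abs(expected - o)), integer(1))
}
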