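# Unit tests for the CTMC, pruning likelihoods, emissions, the HMM
# engine, simulation and discriminative training.

test_that("ctmc_pmatrix is stochastic and converges to stationarity", {
  ctmc <- binary_ctmc(0.8, 0.5)
  for (t in c(0, 0.1, 1, 10)) {
    P <- ctmc_pmatrix(ctmc, t)
    expect_equal(rowSums(P), c(gap = 1, nongap = 1))
    expect_true(all(P >= 0))
  }
  expect_equal(ctmc_pmatrix(ctmc, 0), diag(2), ignore_attr = TRUE)
  Pinf <- ctmc_pmatrix(ctmc, 1e6)
  expect_equal(unname(Pinf[1, ]), unname(ctmc$stationary))
  # zero-rate chain is frozen
  expect_equal(ctmc_pmatrix(binary_ctmc(0, 0), 5), diag(2),
               ignore_attr = TRUE)
  expect_error(ctmc_pmatrix(ctmc, -1), "negative")
})

test_that("prune_likelihood matches trivial cases and the enumeration oracle", {
  # 1-tip tree, zero branch, no jump: stationary probability of the symbol
  t1 <- ape::read.tree(text = "(A:0);")
  ctmc <- binary_ctmc(0.3, 0.7)  # stationary (0.7 gap, 0.3 nongap)
  expect_equal(prune_likelihood(t1, ctmc, tip_jump(0, 0.5), c(A = 1L)), 0.3)
  expect_equal(prune_likelihood(t1, ctmc, tip_jump(0, 0.5), c(A = 0L)), 0.7)
  # eps = 1: tree falls away entirely
  tr <- fixture_tree()
  col <- c(A = 1L, B = 0L, C = 1L, D = 1L)
  jump1 <- tip_jump(1, 0.4)
  expect_equal(prune_likelihood(tr, binary_ctmc(2, 1), jump1, col),
               0.4 * 0.6 * 0.4 * 0.4, tolerance = 1e-12)
  # enumeration oracle on the 4-tip tree
  set.seed(4)
  for (rep in 1:10) {
    ctmc <- binary_ctmc(runif(1, 0.1, 3), runif(1, 0.1, 3))
    jmp <- tip_jump(runif(1), runif(1))
    col <- setNames(sample(0:1, 4, replace = TRUE), c("A", "B", "C", "D"))
    expect_equal(prune_likelihood(tr, ctmc, jmp, col),
                 oracle_prune(tr, ctmc, jmp, col), tolerance = 1e-12)
  }
  expect_error(prune_likelihood(tr, ctmc, jump1, c(A = 1L)), "missing")
})

test_that("prune_likelihood normalises over all tip columns", {
  set.seed(9)
  for (n in 3:5) {
    tree <- ape::rcoal(n, tip.label = paste0("t", seq_len(n)))
    ctmc <- binary_ctmc(runif(1, 0.1, 2), runif(1, 0.1, 2))
    jmp <- tip_jump(runif(1), runif(1))
    cols <- as.matrix(expand.grid(rep(list(0:1), n)))
    total <- sum(apply(cols, 1, function(cc) {
      prune_likelihood(tree, ctmc, jmp, setNames(as.integer(cc),
                                                 tree$tip.label))
    }))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("beta-binomial pmf is normalised and matches integration", {
  for (N in c(4L, 8L)) {
    for (ab in list(c(1, 1), c(2.5, 0.7), c(10, 1))) {
      pmf <- exp(dbetabinom_log(0:N, N, ab[1], ab[2]))
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      for (c in c(0L, N %/% 2L, N)) {
        expect_equal(pmf[c + 1L], oracle_betabinom(c, N, ab[1], ab[2]),
                     tolerance = 1e-9)
      }
    }
  }
  # uniform case: a = b = 1, N = 4 gives 1/5 for any count
  expect_equal(exp(dbetabinom_log(0:4, 4, 1, 1)), rep(0.2, 5))
})

test_that("column_emission composes pruning and stickiness terms", {
  tr <- fixture_tree()
  ep <- emission_params(binary_ctmc(0.5, 0.5), tip_jump(0.1, 0.5),
                        stickiness_params(1, 1))
  col <- c(A = 1L, B = 1L, C = 0L, D = 1L)
  # first column: no stickiness term
  expect_equal(column_emission(ep, tr, col, NULL),
               log(prune_likelihood(tr, ep$ctmc, ep$jump, col)))
  # identical previous column: c = N
  lp <- column_emission(ep, tr, col, col)
  expect_equal(lp, log(prune_likelihood(tr, ep$ctmc, ep$jump, col)) +
                 dbetabinom_log(4, 4, 1, 1))
})

test_that("missing_emission is a normalised posterior", {
  tr <- fixture_tree()
  ctmc <- binary_ctmc(0.7, 0.9)
  jmp <- tip_jump(0.15, 0.3)
  col <- c(A = 1L, B = 0L, C = 1L, D = 0L)
  p1 <- missing_emission(tr, ctmc, jmp, col, "C")
  col2 <- col
  col2[["C"]] <- 0L
  p2 <- missing_emission(tr, ctmc, jmp, col2, "C")
  expect_equal(p1 + p2, 1, tolerance = 1e-12)
  # single tip: posterior reduces to the normalised stationary/jump mix
  t1 <- ape::read.tree(text = "(A:0);")
  p <- missing_emission(t1, binary_ctmc(0.3, 0.7), tip_jump(0, 0.5),
                        c(A = 1L), "A")
  expect_equal(p, 0.3)
  # concordance limit: slow rates, all other tips non-gap
  star <- ape::read.tree(text = "(A:0.001,B:0.001,C:0.001);")
  pst <- missing_emission(star, binary_ctmc(0.01, 0.01), tip_jump(0, 0.5),
                          c(A = 1L, B = 1L, C = 1L), "A")
  expect_gt(pst, 0.95)
})

test_that("forward_backward matches path enumeration and edge cases", {
  # 1-state chain
  le <- matrix(log(c(0.2, 0.7, 0.4)), 3, 1)
  fb <- forward_backward(le, 1, matrix(1, 1, 1))
  expect_equal(fb$posterior, matrix(1, 3, 1))
  expect_equal(fb$log_lik, sum(le))
  # random instances vs the path-enumeration oracle
  set.seed(21)
  for (rep in 1:20) {
    S <- sample(2:4, 1)
    L <- sample(2:8, 1)
    start <- as.numeric(prop.table(runif(S) + 0.05))
    trans <- prop.table(matrix(runif(S * S) + 0.05, S), 1)
    le <- matrix(log(runif(L * S)), L, S)
    fb <- forward_backward(le, start, trans)
    expect_equal(fb$log_lik,
                 log(oracle_path_likelihood(le, start, trans)),
                 tolerance = 1e-10)
    expect_equal(rowSums(fb$posterior), rep(1, L), tolerance = 1e-9)
  }
  # deterministic emissions recover the generating path exactly
  S <- 3
  path <- c(1L, 1L, 2L, 3L, 3L, 2L)
  le <- matrix(-Inf, length(path), S)
  le[cbind(seq_along(path), path)] <- 0
  le[le == -Inf] <- -1e6
  trans <- matrix(1 / 3, 3, 3)
  fb <- forward_backward(le, rep(1 / 3, 3), trans)
  expect_equal(max.col(fb$posterior), path)
})

test_that("simulate_phylo_hmm is seeded, sized and equilibrated", {
  tr <- fixture_tree()
  spec <- default_insertion_model()
  z <- simulate_phylo_hmm(spec, tr, 0, seed = 1)
  expect_equal(length(z$path), 0L)
  expect_equal(ncol(z$columns), 0L)
  a <- simulate_phylo_hmm(spec, tr, 50, seed = 42)
  b <- simulate_phylo_hmm(spec, tr, 50, seed = 42)
  expect_identical(a, b)
  # single-state spec with no jump: tip gap frequency approaches the
  # CTMC stationary distribution (Monte-Carlo, 3 sigma)
  ctmc <- binary_ctmc(1.2, 0.8)
  one <- hmm_spec("s", 1, matrix(1, 1, 1),
                  list(emission_params(ctmc, tip_jump(0, 0.5),
                                       stickiness_params(1, 1))))
  sim <- simulate_phylo_hmm(one, tr, 10000, seed = 3)
  pg <- ctmc$stationary[["gap"]]
  se <- sqrt(pg * (1 - pg) / 10000)
  for (tip in rownames(sim$columns)) {
    expect_lt(abs(mean(sim$columns[tip, ] == 0L) - pg), 3 * se + 0.01)
  }
})

test_that("hmm_spec validates distributions", {
  expect_error(hmm_spec(c("a", "b"), c(0.6, 0.6),
                        matrix(0.5, 2, 2)), "sum to 1")
  expect_error(hmm_spec(c("a", "b"), c(0.5, 0.5),
                        matrix(c(0.9, 0.5, 0.2, 0.5), 2)), "rows")
})

test_that("training does not worsen a self-consistent start and separable
           two-state models decode accurately", {
  tr <- fixture_tree()
  two <- hmm_spec(
    c("lo", "hi"), c(0.5, 0.5),
    rbind(c(0.9, 0.1), c(0.1, 0.9)),
    list(emission_params(binary_ctmc(4, 0.2), tip_jump(0.02, 0.9),
                         stickiness_params(1, 1)),
         emission_params(binary_ctmc(0.2, 4), tip_jump(0.02, 0.1),
                         stickiness_params(1, 1))))
  sim <- simulate_phylo_hmm(two, tr, 2400, seed = 10)
  labeled <- list(list(columns = sim$columns[, 1:400],
                       labels = sim$path[1:400]))
  fit <- train_discriminative(two, tr, labeled, rounds = 2, maxit = 40)
  # labels generated by the spec itself: loss must not increase
  expect_true(all(diff(fit$loss_trace) <= 1e-9))
  # held-out decoding accuracy of the returned spec
  held <- 401:2400
  fb <- decode_insertion(fit$spec, tr, sim$columns[, held])
  acc <- mean(max.col(fb$posterior) == sim$path[held])
  expect_gte(acc, 0.95)
})

test_that("training on one-state labels drives self-transition upward", {
  tr <- fixture_tree()
  spec <- hmm_spec(
    c("a", "b"), c(0.5, 0.5),
    rbind(c(0.5, 0.5), c(0.5, 0.5)),
    list(emission_params(binary_ctmc(3, 0.3), tip_jump(0.05, 0.9),
                         stickiness_params(1, 1)),
         emission_params(binary_ctmc(0.3, 3), tip_jump(0.05, 0.1),
                         stickiness_params(1, 1))))
  sim <- simulate_phylo_hmm(spec, tr, 120, seed = 5)
  labeled <- list(list(columns = sim$columns,
                       labels = rep(1L, 120)))
  fit <- train_discriminative(spec, tr, labeled, rounds = 3, maxit = 80)
  expect_gt(fit$spec$trans[1, 1], spec$trans[1, 1])
})

test_that("model parameters round-trip through the flat text format", {
  spec <- default_insertion_model()
  path <- tempfile(fileext = ".tsv")
  write_hmm_params(spec, path)
  back <- read_hmm_params(path)
  expect_equal(back$states, spec$states)
  expect_equal(back$start, spec$start, tolerance = 1e-12)
  expect_equal(unname(back$trans), unname(spec$trans), tolerance = 1e-12)
  for (i in seq_along(spec$states)) {
    expect_equal(back$emission_params[[i]]$ctmc$rate01,
                 spec$emission_params[[i]]$ctmc$rate01)
    expect_equal(back$emission_params[[i]]$stick$b,
                 spec$emission_params[[i]]$stick$b)
  }
})
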