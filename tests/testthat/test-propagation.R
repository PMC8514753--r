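test_that("local_affinity sparsifies to KNN rows excluding self", {
  aff <- local_affinity(toy_kernel3(), 1)
  expect_equal(unname(aff$values),
               rbind(c(0, 1, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_true(all(diag(aff$values) == 0))

  set.seed(71)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    K <- random_kernel(n)
    aff <- local_affinity(K, sample(1:(n - 1), 1))
    expect_true(all(abs(rowSums(aff$values) - 1) < 1e-10))
    expect_true(all(diag(aff$values) == 0))
  }
})

test_that("as_printed propagation reproduces the hand iteration", {
  aff <- stoch_kernel(rbind(c(0, 1), c(1, 0)), dlabs(2), "row")
  A <- toy_assoc2()
  p <- lp_params(gamma = 0.2, max_iterations = 2, tolerance = 1e-12)
  out <- suppressWarnings(propagate_side(aff, A, "disease", p))
  D1 <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  D2 <- rbind(c(0.64, 0.36), c(0.36, 0.64))
  # score = D0 + D1 + D2
  expect_equal(unname(out$score), unname(A$values) + D1 + D2)
  expect_identical(out$state$iteration, 2L)
})

test_that("gamma = 0 stops immediately with score 2Y", {
  aff <- stoch_kernel(rbind(c(0, 1), c(1, 0)), dlabs(2), "row")
  A <- toy_assoc2()
  out <- propagate_side(aff, A, "disease", lp_params(gamma = 0))
  expect_identical(out$state$iteration, 1L)
  expect_true(out$state$converged)
  expect_equal(unname(out$score), 2 * unname(A$values))
})

test_that("as_printed iterates match the closed form and the contraction bound", {
  set.seed(72)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    m <- sample(3:10, 1)
    K <- random_kernel(n)
    A <- random_assoc(n, m)
    gamma <- runif(1, 0.05, 0.95)
    aff <- local_affinity(K, sample(2:(n - 1), 1))
    tmax <- sample(3:8, 1)
    p <- lp_params(gamma = gamma, max_iterations = tmax, tolerance = 1e-15)
    out <- suppressWarnings(propagate_side(aff, A, "disease", p))
    Y <- A$values
    affY <- aff$values %*% Y
    closed_score <- Y
    for (t in seq_len(tmax)) {
      closed_score <- closed_score +
        (1 - gamma)^t * Y + (1 - (1 - gamma)^t) * affY
    }
    expect_equal(unname(out$score), unname(closed_score), tolerance = 1e-10)

    # converged runs respect the (1 - gamma) contraction bound
    p2 <- lp_params(gamma = gamma, max_iterations = 10000, tolerance = 1e-6)
    out2 <- propagate_side(aff, A, "disease", p2)
    kd <- out2$state$iteration
    maxdiff0 <- max(abs(gamma * (affY - Y)))    # first-step change
    expect_true(out2$state$converged)
    expect_lte((1 - gamma)^kd * maxdiff0, p2$tolerance)
  }
})

test_that("recurrent mode implements conventional propagation", {
  set.seed(73)
  K <- random_kernel(6)
  A <- random_assoc(6, 5)
  aff <- local_affinity(K, 3)
  p <- lp_params(gamma = 0.4, mode = "recurrent", max_iterations = 3,
                 tolerance = 1e-15)
  out <- suppressWarnings(propagate_side(aff, A, "disease", p))
  Y <- A$values
  X <- Y
  score <- Y
  for (t in 1:3) {
    X <- 0.4 * (aff$values %*% X) + 0.6 * Y
    score <- score + X
  }
  expect_equal(unname(out$score), unname(score), tolerance = 1e-12)
})

test_that("ensemble_scores combines the transposed miRNA scores linearly", {
  set.seed(74)
  Fd <- matrix(runif(12), 3, 4)
  Fm <- matrix(runif(12), 4, 3)
  expect_equal(ensemble_scores(Fd, Fm, lp_params(alpha = 1)), Fd)
  expect_equal(ensemble_scores(Fd, t(Fd), lp_params(alpha = 0.5)), Fd)
  expect_equal(ensemble_scores(Fd, Fm, lp_params(alpha = 0.3)),
               0.3 * Fd + 0.7 * t(Fm))
  # linear in both arguments
  Fd2 <- matrix(runif(12), 3, 4)
  Fm2 <- matrix(runif(12), 4, 3)
  p <- lp_params(alpha = 0.3)
  expect_equal(ensemble_scores(Fd + Fd2, Fm + Fm2, p),
               ensemble_scores(Fd, Fm, p) + ensemble_scores(Fd2, Fm2, p))
  expect_error(ensemble_scores(Fd, t(Fd)[, 1:2], lp_params()), "shapes")
})

test_that("pipeline with gamma = 0 reduces to twice the densified matrix", {
  b <- small_benchmark()
  cfg <- pipeline_config(lp = lp_params(gamma = 0, alpha = 0.5))
  F <- fuselp_predict(b$assoc, b$disease_kernels, b$mirna_kernels, cfg)
  SD <- skf_fuse(c(b$disease_kernels,
                   list(gip_kernel(b$assoc, "disease", cfg$gip))), cfg$fusion)
  SM <- skf_fuse(c(b$mirna_kernels,
                   list(gip_kernel(b$assoc, "mirna", cfg$gip))), cfg$fusion)
  A2 <- wknkn_update(b$assoc, SD, SM, cfg$wknkn)
  expect_equal(unname(unclass(F)), 2 * unname(A2$values), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pipeline output is exactly equivariant under joint relabeling", {
  b <- small_benchmark()
  cfg <- fast_config()
  F <- fuselp_predict(b$assoc, b$disease_kernels, b$mirna_kernels, cfg)
  set.seed(75)
  pd <- sample(nrow(b$assoc$values))
  pm <- sample(ncol(b$assoc$values))
  Ap <- assoc_matrix(b$assoc$values[pd, pm],
                     b$assoc$disease_labels[pd], b$assoc$mirna_labels[pm])
  dk <- lapply(b$disease_kernels, function(k) {
    sim_kernel(k$values[pd, pd], k$labels[pd], "disease")
  })
  mk <- lapply(b$mirna_kernels, function(k) {
    sim_kernel(k$values[pm, pm], k$labels[pm], "mirna")
  })
  Fp <- fuselp_predict(Ap, dk, mk, cfg)
  strip <- function(m) {
    m <- unclass(m)
    attributes(m) <- list(dim = dim(m))
    m
  }
  expect_identical(strip(Fp), strip(F)[pd, pm])
})

test_that("pipeline scores are enriched at planted associations", {
  b <- generate_benchmark(synthetic_spec())
  F <- fuselp_predict(b$assoc, b$disease_kernels, b$mirna_kernels,
                      pipeline_config())
  pos <- b$assoc$values == 1
  expect_gt(mean(F[pos]), mean(F[!pos]))
})
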