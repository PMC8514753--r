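test_that("GIP kernel matches the hand-derived 2x2 value and error contract", {
  A <- toy_assoc2()
  K <- gip_kernel(A, "disease", gip_params(bandwidth_disease = 1))
  # profiles (1,0) and (0,1): mean squared norm 1, rho 1, distance^2 = 2
  expect_equal(K$values[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(attr(K, "bandwidth"), 1)
  expect_identical(diag(K$values), setNames(c(1, 1), dlabs(2)))

  empty <- assoc_matrix(matrix(0, 2, 2), dlabs(2), mlabs(2))
  expect_error(gip_kernel(empty, "disease"), "degenerate")

  # identical profiles give similarity exactly 1
  A2 <- assoc_matrix(rbind(c(1, 0), c(1, 0)), dlabs(2), mlabs(2))
  expect_equal(gip_kernel(A2, "disease")$values[1, 2], 1)
})

test_that("GIP kernel is symmetric, unit-diagonal, in (0,1], and scale-stable", {
  set.seed(21)
  for (rep in 1:20) {
    A <- random_assoc(sample(4:8, 1), sample(4:8, 1))
    for (side in c("disease", "mirna")) {
      K <- gip_kernel(A, side)
      expect_identical(K$values, t(K$values))
      expect_true(all(diag(K$values) == 1))
      expect_true(all(K$values > 0 & K$values <= 1))
    }
    # duplicating every miRNA column doubles both distances and the mean
    # profile norm, so the disease kernel is unchanged
    Adup <- assoc_matrix(cbind(A$values, A$values),
                         A$disease_labels,
                         c(A$mirna_labels, paste0(A$mirna_labels, "b")))
    expect_equal(gip_kernel(Adup, "disease")$values,
                 gip_kernel(A, "disease")$values, tolerance = 1e-12)
  }
})

test_that("GIP kernel is equivariant under entity relabeling permutations", {
  set.seed(22)
  A <- random_assoc(6, 7)
  perm <- sample(6)
  Ap <- assoc_matrix(A$values[perm, ], A$disease_labels[perm], A$mirna_labels)
  expect_equal(gip_kernel(Ap, "disease")$values,
               gip_kernel(A, "disease")$values[perm, perm],
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("normalize_kernel produces column-stochastic output and names failures", {
  I2 <- sim_kernel(diag(2), dlabs(2), "disease")
  expect_equal(unname(normalize_kernel(I2)$values), diag(2))
  ones <- sim_kernel(matrix(1, 3, 3), dlabs(3), "disease")
  expect_equal(unname(normalize_kernel(ones)$values), matrix(1 / 3, 3, 3))

  K <- matrix(c(1, 0.5, 0,
                0.5, 1, 0,
                0, 0, 0), 3, 3, byrow = TRUE)
  zk <- sim_kernel(K, dlabs(3), "disease")
  expect_error(normalize_kernel(zk), "D003")
})

test_that("neighbor_sets ranks by similarity with deterministic tie-breaks", {
  K <- toy_kernel3()
  nb <- neighbor_sets(K, 2, include_self = TRUE)
  expect_identical(nb$neighbors[[1]], c(1L, 2L))   # self + most similar
  expect_identical(nb$neighbors[[3]], c(3L, 2L))

  # k = n returns every entity
  nb_all <- neighbor_sets(K, 3, include_self = TRUE)
  expect_identical(sort(nb_all$neighbors[[2]]), 1:3)

  # tie between candidates 2 and 3 -> lower index wins
  tied <- sim_kernel(matrix(c(1, .5, .5, .5, 1, 0, .5, 0, 1), 3, 3),
                     dlabs(3), "disease")
  expect_identical(neighbor_sets(tied, 2, include_self = TRUE)$neighbors[[1]],
                   c(1L, 2L))
  expect_identical(neighbor_sets(tied, 1, include_self = FALSE)$neighbors[[1]],
                   2L)

  expect_warning(nb_clip <- neighbor_sets(K, 10, include_self = TRUE),
                 "clipping")
  expect_length(nb_clip$neighbors[[1]], 3)
})

test_that("neighbor_constraint_kernel row-normalizes over the neighbor set", {
  K <- toy_kernel3()
  C <- neighbor_constraint_kernel(K, neighbor_sets(K, 2, include_self = TRUE))
  expect_equal(unname(C$values[1, ]), c(1 / 1.9, 0.9 / 1.9, 0))
  expect_equal(rowSums(C$values), setNames(rep(1, 3), dlabs(3)))

  # k = n reduces to full row normalization
  Cfull <- neighbor_constraint_kernel(K, neighbor_sets(K, 3, include_self = TRUE))
  expect_equal(unname(Cfull$values), unname(K$values / rowSums(K$values)))

  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    Kr <- random_kernel(n)
    Cr <- neighbor_constraint_kernel(Kr, neighbor_sets(Kr, sample(2:(n - 1), 1),
                                                       include_self = TRUE))
    expect_true(all(abs(rowSums(Cr$values) - 1) < 1e-10))
  }
})

test_that("skf_fuse treats identical kernels symmetrically and ignores list order", {
  set.seed(41)
  K1 <- random_kernel(8)
  K2 <- random_kernel(8)
  K3 <- random_kernel(8)
  p <- fusion_params(k_neighbors = 4, max_iterations = 50)

  # two identical inputs: the cross-diffusion source for each kernel is the
  # other (identical) kernel, so iterates stay equal and fusion converges
  same <- skf_fuse(list(K1, K1), p)
  expect_true(attr(same, "converged"))

  f123 <- skf_fuse(list(K1, K2, K3), p)
  f321 <- skf_fuse(list(K3, K2, K1), p)
  expect_equal(f123$values, f321$values, tolerance = 1e-12)

  expect_identical(f123$values, t(f123$values))
  expect_true(all(f123$values >= 0))

  # degenerate single-kernel input returns the normalized kernel
  single <- skf_fuse(list(K1), p)
  P <- normalize_kernel(K1)$values
  expect_equal(single$values, (P + t(P)) / 2, ignore_attr = TRUE)

  mism <- random_kernel(8, side = "mirna")
  expect_error(skf_fuse(list(K1, mism), p), "side")
})

test_that("mutual-neighborhood weights match brute-force membership tests", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    K <- random_kernel(n)
    k <- sample(2:(n - 1), 1)
    nb <- neighbor_sets(K, k, include_self = TRUE)
    W <- mutual_neighbor_weights(nb)
    expect_true(all(W %in% c(0, 0.5, 1)))
    expect_true(all(diag(W) == 1))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        i_in_Nj <- i %in% nb$neighbors[[j]]
        j_in_Ni <- j %in% nb$neighbors[[i]]
        expected <- if (i_in_Nj && j_in_Ni) 1 else if (!i_in_Nj && !j_in_Ni) 0 else 0.5
        expect_identical(W[i, j], expected)
      }
    }
  }
})

test_that("average_fuse is the elementwise mean", {
  set.seed(51)
  K1 <- random_kernel(6)
  expect_equal(average_fuse(list(K1, K1))$values, K1$values)
  zero <- sim_kernel(matrix(0, 6, 6), dlabs(6), "disease")
  expect_equal(average_fuse(list(K1, zero))$values, K1$values / 2)
  K2 <- random_kernel(6)
  K3 <- random_kernel(6)
  expect_equal(average_fuse(list(K1, K2, K3))$values,
               (K1$values + K2$values + K3$values) / 3)
  expect_error(average_fuse(list()), "at least one")
})
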