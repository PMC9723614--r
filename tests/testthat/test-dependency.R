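test_that("pair counts tally joint states over doubly-covered reads", {
  m <- mod_matrix(cbind(c(1, 1, 0), c(1, 0, 0)))
  pc <- pair_counts(m, 1, 2)
  expect_equal(unlist(pc), c(n11 = 1, n10 = 1, n01 = 0, n00 = 1, n = 3))
  m2 <- mod_matrix(cbind(c(1, NA, 0, NA), c(NA, 1, NA, 0)))
  expect_equal(pair_counts(m2, 1, 2)$n, 0)
  m3 <- mod_matrix(cbind(c(1, 0), c(1, 0)))
  pc3 <- pair_counts(m3, 1, 2)
  expect_equal(c(pc3$n11, pc3$n00), c(1, 1))
})

test_that("mutual information matches closed forms and is symmetric/bounded", {
  expect_equal(mutual_information(list(n11 = 2, n10 = 0, n01 = 0, n00 = 2)),
               log(2))
  expect_equal(mutual_information(list(n11 = 0, n10 = 2, n01 = 0, n00 = 2)), 0)
  expect_equal(mutual_information(list(n11 = 0, n10 = 2, n01 = 2, n00 = 0)),
               log(2))
  set.seed(31)
  for (rep in 1:30) {
    u <- rbinom(40, 1, 0.5); v <- rbinom(40, 1, 0.5)
    pc <- pair_counts_from_vectors(u, v)
    pc_swapped <- list(n11 = pc$n11, n10 = pc$n01, n01 = pc$n10, n00 = pc$n00)
    mi <- mutual_information(pc)
    expect_equal(mi, mutual_information(pc_swapped))
    hu <- -sum(table(u) / 40 * log(table(u) / 40))
    hv <- -sum(table(v) / 40 * log(table(v) / 40))
    expect_gte(mi, 0)
    expect_lte(mi, min(hu, hv) + 1e-12)
  }
})

test_that("expected MI equals exhaustive enumeration and permutation estimates", {
  # constant margin: the only admissible table has MI 0
  expect_equal(expected_mi(list(n11 = 0, n10 = 0, n01 = 3, n00 = 2)), 0)
  # N=2, all margins (1,1): enumerate n11 in {0,1} by hand:
  # n11=1 -> table diag(1,1), MI = log 2, P = 1/2; n11=0 -> anti-diagonal,
  # MI = log 2, P = 1/2 => E[MI] = log 2
  expect_equal(expected_mi(list(n11 = 1, n10 = 0, n01 = 0, n00 = 1)), log(2))
  set.seed(33)
  for (rep in 1:6) {
    N <- sample(10:30, 1)
    u <- rbinom(N, 1, runif(1, 0.3, 0.7))
    v <- rbinom(N, 1, runif(1, 0.3, 0.7))
    if (length(unique(u)) < 2 || length(unique(v)) < 2) next
    pc <- pair_counts_from_vectors(u, v)
    est <- oracle_expected_mi_perm(u, v, B = 20000L)
    expect_lt(abs(expected_mi(pc) - est), 0.01)
  }
})

test_that("adjusted MI hits its fixed points and the reference implementation", {
  u <- c(rep(1, 6), rep(0, 6))
  expect_equal(adjusted_mi(pair_counts_from_vectors(u, u)), 1)
  expect_equal(adjusted_mi(list(n11 = 0, n10 = 0, n01 = 5, n00 = 7)), 0)
  set.seed(35)
  ind <- pair_counts_from_vectors(rbinom(1000, 1, 0.5), rbinom(1000, 1, 0.5))
  expect_lt(abs(adjusted_mi(ind)), 0.05)

  skip_if_not(sklearn_available(), "python/scikit-learn oracle not available")
  cases <- lapply(1:40, function(k) {
    N <- sample(10:500, 1)
    repeat {
      u <- rbinom(N, 1, runif(1, 0.2, 0.8))
      v <- rbinom(N, 1, runif(1, 0.2, 0.8))
      if (length(unique(u)) == 2 && length(unique(v)) == 2) break
    }
    list(u = u, v = v)
  })
  ref <- oracle_sklearn_ami(cases)
  ours <- vapply(cases, function(cs) {
    adjusted_mi(pair_counts_from_vectors(cs$u, cs$v))
  }, 0)
  expect_lt(max(abs(ours - ref)), 1e-9)
})

test_that("co-openness and co-agreement count shared states", {
  u <- c(1, 1, 0); v <- c(1, 0, 1)
  expect_equal(co_openness(pair_counts_from_vectors(u, v)), 1 / 3)
  expect_equal(co_openness(pair_counts_from_vectors(u, u)), 1)
  expect_equal(co_openness(pair_counts_from_vectors(c(1, 0, 0), c(0, 1, 0))), 0)
  expect_true(is.na(co_openness(pair_counts_from_vectors(c(0, 0), c(0, 0)))))
  dir <- co_openness(list(n11 = 2, n10 = 2, n01 = 0, n00 = 1),
                     directional = TRUE)
  expect_equal(dir$p_j_given_i, 0.5)
  expect_equal(dir$p_i_given_j, 1)

  expect_equal(co_agreement(pair_counts_from_vectors(u, u)), 1)
  expect_equal(co_agreement(pair_counts_from_vectors(u, 1 - u)), 0)
  expect_equal(co_agreement(pair_counts_from_vectors(c(1, 0, 0, 0),
                                                     c(0, 1, 0, 0))), 0.5)
  # conservation: agreement and disagreement fractions sum to one
  set.seed(37)
  for (rep in 1:20) {
    u <- rbinom(25, 1, 0.4); v <- rbinom(25, 1, 0.4)
    pc <- pair_counts_from_vectors(u, v)
    expect_equal(co_agreement(pc) + (pc$n10 + pc$n01) / 25, 1)
  }
})

test_that("distance z-scoring normalizes within each separation", {
  vals <- matrix(NA_real_, 4, 4)
  vals[1, 2] <- vals[2, 1] <- 0.1
  vals[2, 3] <- vals[3, 2] <- 0.3   # distance 1: {0.1, 0.3} -> z = -1, +1
  vals[1, 3] <- vals[3, 1] <- 0.5   # lone pair at distance 2
  z <- distance_zscore(vals)
  expect_equal(z[1, 2], -1)  # population sd of {0.1, 0.3} is 0.1
  expect_equal(z[2, 3], 1)
  expect_equal(z[1, 3], 0)   # single pair at its distance
  same <- matrix(0.4, 3, 3); diag(same) <- NA
  zs <- distance_zscore(same)
  expect_true(all(zs[upper.tri(zs)] == 0))
  expect_equal(z, t(z))
})

test_that("dependency map enforces coverage, symmetry and finds planted pairs", {
  set.seed(41)
  # pair (2, 7) co-modified, all else independent
  n <- 300
  x <- matrix(rbinom(n * 10, 1, 0.3), n, 10)
  driver <- rbinom(n, 1, 0.5)
  x[, 2] <- driver
  x[, 7] <- driver
  m <- mod_matrix(x)
  dm <- dependency_map(m)
  expect_equal(dm$ami, t(dm$ami))
  td <- tidy(dm)
  at_d5 <- td[td$distance == 5, ]
  expect_equal(at_d5$i[which.max(at_d5$dami)], 2)
  expect_equal(at_d5$j[which.max(at_d5$dami)], 7)
  # per-distance z-scores have mean ~0 and unit population sd
  for (d in unique(td$distance)) {
    zz <- td$dami[td$distance == d & !is.na(td$dami)]
    if (length(zz) >= 3) {
      expect_lt(abs(mean(zz)), 1e-8)
      expect_equal(sqrt(mean((zz - mean(zz))^2)), 1, tolerance = 1e-8)
    }
  }
})

test_that("pairs with insufficient joint coverage are ineligible", {
  x <- matrix(rbinom(60, 1, 0.5), 12, 5)
  x[1:3, 1] <- NA   # position 1 shares only 9 reads with the rest
  m <- mod_matrix(x)
  dm <- dependency_map(m, min_reads = 10)
  expect_true(all(is.na(dm$ami[1, -1])))
  expect_true(all(!is.na(dm$ami[2, 3])))
  expect_equal(dm$n[1, 2], 9)
})
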