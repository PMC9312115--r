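# Dice, accuracy, NMI, ARI against brute-force oracles.

test_that("Dice matches its closed-form cases and conventions", {
  x <- matrix(FALSE, 4, 4); y <- x
  x[1, 1:4] <- TRUE; y[1, 1:3] <- TRUE; y[2, 1:3] <- TRUE
  expect_equal(dice(x, x), 1)
  expect_equal(dice(x, y), 2 * 3 / (4 + 6))
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)  # empty-vs-empty
  a <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2); b <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2)
  expect_equal(dice(a, b), 0)
  expect_error(dice(a, matrix(TRUE, 3, 3)), "shape")
})

test_that("Dice is symmetric on random masks", {
  set.seed(4)
  for (i in 1:20) {
    x <- matrix(runif(64) > 0.5, 8); y <- matrix(runif(64) > 0.5, 8)
    expect_equal(dice(x, y), dice(y, x))
  }
})

test_that("accuracy follows the confusion-count definition", {
  expect_equal(accuracy(40, 50, 5, 5), 0.9)
  expect_equal(accuracy(10, 10, 0, 0), 1)
  expect_equal(accuracy(0, 0, 3, 2), 0)
  expect_error(accuracy(0, 0, 0, 0), "positive")
  expect_error(accuracy(-1, 2, 0, 0), "non-negative")
})

test_that("NMI hits its boundary values and is relabeling-invariant", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(2, 2, 0, 0, 1, 1)), 1)
  # independent 2x2 contingency: MI = 0 exactly
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # hand-evaluated contingency oracle
  b <- c(0, 0, 1, 1, 1, 2)
  tab <- table(a, b) / 6
  mi <- 0
  for (i in 1:3) for (j in 1:3) if (tab[i, j] > 0) {
    mi <- mi + tab[i, j] * log(tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
  }
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  expect_equal(nmi(a, b), mi / ((h(rowSums(tab)) + h(colSums(tab))) / 2))
  expect_error(nmi(a, a[-1]), "differ")
})

test_that("ARI matches brute-force pair counting and mclust", {
  brute_ari <- function(a, b) {
    n <- length(a)
    s_ab <- s_a <- s_b <- 0
    npairs <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      s_ab <- s_ab + (sa && sb); s_a <- s_a + sa; s_b <- s_b + sb
      npairs <- npairs + 1
    }
    exp_ab <- s_a * s_b / npairs
    (s_ab - exp_ab) / ((s_a + s_b) / 2 - exp_ab)
  }
  a <- c(0, 0, 1, 1, 2, 2); b <- c(0, 0, 1, 2, 1, 2)
  expect_equal(ari(a, b), brute_ari(a, b))
  expect_equal(ari(a, a), 1)
  expect_equal(ari(a, c(1, 1, 2, 2, 0, 0)), 1)   # permutation invariance
  set.seed(9)
  for (i in 1:10) {
    x <- sample(0:2, 12, replace = TRUE); y <- sample(0:1, 12, replace = TRUE)
    expect_equal(ari(x, y), brute_ari(x, y), tolerance = 1e-12)
    skip_if_not_installed("mclust")
    expect_equal(ari(x, y), mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("ARI is centered at zero for independent partitions", {
  set.seed(11)
  vals <- replicate(200, {
    a <- sample(rep(0:1, 50)); b <- sample(rep(0:1, 50))
    ari(a, b)
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("clustering accuracy equals 1 - normalized Hamming after matching", {
  set.seed(3)
  truth <- rbinom(100, 1, 0.5)
  pred <- truth; flip <- sample(100, 20); pred[flip] <- 1 - pred[flip]
  expect_equal(clustering_accuracy(pred, truth), 0.8)
  # optimal matching tolerates a global label swap
  expect_equal(clustering_accuracy(1 - pred, truth, matching = "optimal"), 0.8)
  expect_equal(clustering_accuracy(1 - pred, truth, matching = "majority"), 0.2)
})

test_that("label-map evaluation is invariant to cluster index swaps", {
  sl_lab <- matrix(c(0L, 1L, 2L, 1L, 2L, 1L, 0L, 2L, 1L), 3, 3)
  mask <- sl_lab > 0L
  truth <- imatq::tissue_label_map(sl_lab, mask)
  swapped <- sl_lab
  swapped[sl_lab == 1L] <- 2L; swapped[sl_lab == 2L] <- 1L
  pred <- imatq::tissue_label_map(swapped, mask)
  ev_same <- evaluate_labels(truth, truth)
  expect_equal(ev_same$nmi, 1)
  expect_equal(ev_same$ari, 1)
  ev_sw <- evaluate_labels(pred, truth)
  expect_equal(ev_sw$nmi, 1)   # NMI/ARI ignore the labeling permutation
  expect_equal(ev_sw$ari, 1)
})
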