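test_that("equal-frequency discretization matches the quantile-binning oracle", {
  # 40 distinct sorted values into 20 bins: value k lands in bin ceil(k/2)
  v <- sort(runif(40))
  m <- matrix(v, 4, 10)
  lab <- discretize(m, n_bins = 20)
  expect_equal(as.vector(lab)[order(as.vector(m))], ceiling(seq_len(40) / 2))
  # 20 distinct values into 20 bins: one label per value, order-preserving
  m2 <- matrix(sample(seq(0.1, 2, length.out = 20)), 4, 5)
  lab2 <- discretize(m2, n_bins = 20)
  expect_equal(as.vector(lab2), rank(as.vector(m2)))
  # constant matrix degenerates to all-1 labels with a warning
  expect_warning(lab3 <- discretize(matrix(0.5, 3, 4), 20), "constant")
  expect_true(all(lab3 == 1L))
})

test_that("discretization assigns tied values to the same bin and is rank-invariant", {
  set.seed(1)
  x <- matrix(sample(seq(0.05, 0.9, by = 0.05), 60, replace = TRUE), 6, 10)
  a <- discretize(x, 20)
  expect_true(all(tapply(as.vector(a), as.vector(x),
                         function(l) length(unique(l)) == 1L)))
  # strictly monotone transform leaves labels unchanged
  b <- discretize(exp(3 * x) - 1, 20)
  expect_identical(unclass(a), unclass(b))
})

test_that("entropy reproduces closed-form values and bounds", {
  expect_identical(shannon_entropy(c(1, 1, 2, 2)), 1)
  expect_identical(shannon_entropy(rep(1, 4)), 0)
  expect_identical(shannon_entropy(1:4), 2)
  expect_error(shannon_entropy(integer()), "non-empty")
  set.seed(42)
  for (i in 1:50) {
    v <- sample.int(20, sample(5:60, 1), replace = TRUE)
    H <- shannon_entropy(v)
    expect_gte(H, 0)
    expect_lte(H, log2(20) + 1e-12)
  }
})

test_that("mutual information reproduces closed-form examples exactly", {
  a <- c(1, 1, 2, 2)
  expect_equal(mutual_information(a, a), 1, tolerance = 1e-12)
  expect_equal(mutual_information(a, c(1, 2, 1, 2)), 0, tolerance = 1e-12)
  i_ref <- 1 + (-(1 / 4) * log2(1 / 4) - (3 / 4) * log2(3 / 4)) - 1.5
  expect_equal(mutual_information(a, c(1, 2, 2, 2)), i_ref, tolerance = 1e-12)
  expect_equal(i_ref, 0.311278, tolerance = 1e-6)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mutual information agrees with the joint-frequency-table oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    a <- sample.int(sample(2:8, 1), n, replace = TRUE)
    b <- sample.int(sample(2:8, 1), n, replace = TRUE)
    I <- mutual_information(a, b)
    expect_equal(I, oracle_mi(a, b), tolerance = 1e-12)
    expect_equal(I, mutual_information(b, a), tolerance = 1e-12)
    expect_lte(I, min(shannon_entropy(a), shannon_entropy(b)) + 1e-12)
    expect_gte(I, -1e-12)
  }
})

test_that("nmi matrix normalizes into [0,1] with the documented conventions", {
  lab <- rbind(g1 = c(1, 1, 2, 2), g2 = c(1, 2, 2, 2),
               g3 = c(1, 1, 2, 2), g4 = c(1, 2, 1, 2),
               g5 = c(3, 3, 3, 3))
  attr(lab, "n_bins") <- 4L
  net <- nmi_matrix(lab)
  # identical non-constant profiles -> nmi 1
  expect_equal(net$nmi["g1", "g3"], 1, tolerance = 1e-12)
  # constructed-independent pair -> 0
  expect_equal(net$nmi["g1", "g4"], 0, tolerance = 1e-12)
  # derived: I / min entropy
  expect_equal(net$nmi["g1", "g2"], 0.311278 / 0.811278, tolerance = 1e-6)
  # zero-entropy profile: nmi defined as 0 against anything
  expect_true(all(net$nmi["g5", ] == 0))
  # diagonal zero, symmetric, bounded
  expect_true(all(diag(net$nmi) == 0))
  expect_identical(net$nmi, t(net$nmi))
  expect_true(all(net$nmi >= 0 & net$nmi <= 1))
})

test_that("thresholding retains strict exceedances with reciprocal weights", {
  lab <- rbind(g1 = c(1, 1, 2, 2, 3, 3), g2 = c(1, 1, 2, 3, 3, 2),
               g3 = c(2, 1, 3, 1, 2, 3))
  attr(lab, "n_bins") <- 3L
  net <- nmi_matrix(lab)
  net$nmi[] <- 0
  net$nmi["g1", "g2"] <- net$nmi["g2", "g1"] <- 0.8
  net$nmi["g1", "g3"] <- net$nmi["g3", "g1"] <- 0.4
  dn <- threshold_and_distance(net, 0.5)
  expect_equal(nrow(dn$edges), 1L)
  expect_equal(dn$edges$weight, 1.25)
  expect_setequal(dn$nodes, c("g1", "g2", "g3"))   # isolated g3 kept
  dn0 <- threshold_and_distance(net, 0)
  expect_equal(sort(dn0$edges$weight), c(1.25, 2.5))
  # zero-nmi pairs have no edge at any threshold (infinite distance)
  expect_false(any(dn0$edges$source == "g2" & dn0$edges$target == "g3"))
  # threshold at an edge's exact value drops it (strict rule)
  expect_equal(nrow(threshold_and_distance(net, 0.8)$edges), 0L)
})

test_that("edge sets are nested along the threshold sweep", {
  set.seed(11)
  co <- generate_cohort(cohort_spec(20, conditions = c("C", "II"),
                                    samples_per_condition = c(25L, 25L),
                                    seed = 5L))
  net <- nmi_matrix(discretize(co$expr$C))
  thr <- default_thresholds()
  expect_length(thr, 18L)
  edge_key <- function(T) {
    e <- threshold_and_distance(net, T)$edges
    paste(e$source, e$target)
  }
  keys <- lapply(thr, edge_key)
  for (k in seq_len(length(thr) - 1L))
    expect_true(all(keys[[k + 1L]] %in% keys[[k]]))
})
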