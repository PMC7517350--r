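test_that("gaussian differential entropy obeys its closed form", {
  set.seed(3)
  x <- as.vector(scale(rnorm(500)))       # sample variance exactly 1
  expect_equal(differential_entropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  expect_equal(differential_entropy(x, base = 2),
               0.5 * log2(2 * pi * exp(1)), tolerance = 1e-12)
  expect_error(differential_entropy(rep(2, 10)), "zero variance")
  expect_error(differential_entropy(1), "at least 2")
})

test_that("gaussian entropy follows the scaling and translation laws", {
  set.seed(4)
  x <- rnorm(1000, sd = 3)
  for (a in c(0.2, -1.5, 7)) {
    expect_equal(differential_entropy(a * x),
                 differential_entropy(x) + log(abs(a)), tolerance = 1e-9)
  }
  expect_equal(differential_entropy(x + 42), differential_entropy(x),
               tolerance = 1e-12)
})

test_that("the histogram estimator converges to the gaussian closed form", {
  set.seed(6)
  x <- rnorm(100000)
  expect_lt(abs(differential_entropy(x, "histogram") -
                0.5 * log(2 * pi * exp(1))), 0.05)
  expect_error(differential_entropy(rep(1, 50), "histogram"), "distinct")
})

test_that("rank-sum exact enumeration matches hand-countable cases", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)                # 2/20 arrangements
  expect_identical(r$method, "exact")
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("rank-sum p matches the brute-force permutation oracle", {
  set.seed(13)
  for (rep in 1:3) {
    for (n1 in 1:5) {
      for (n2 in n1:(10 - n1)) {
        a <- sample(1:6, n1, replace = TRUE)  # ties likely
        b <- sample(1:6, n2, replace = TRUE)
        expect_equal(rank_sum_test(a, b, mode = "exact")$p_value,
                     brute_ranksum_p(a, b), tolerance = 1e-12)
      }
    }
  }
})

test_that("rank-sum agrees with stats::wilcox.test on tie-free data", {
  set.seed(14)
  a <- rnorm(7)
  b <- rnorm(6) + 0.8
  mine <- rank_sum_test(a, b, mode = "exact")
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$U, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  big_a <- rnorm(25)
  big_b <- rnorm(25) + 0.5
  mine_n <- rank_sum_test(big_a, big_b)
  expect_identical(mine_n$method, "normal")
  # the higher-order terms leave only a small gap to R's plain normal p
  ref_n <- wilcox.test(big_a, big_b, exact = FALSE, correct = TRUE)
  expect_equal(mine_n$p_value, ref_n$p.value, tolerance = 1e-2)
  expect_equal(2 * pnorm(-abs(mine_n$z_stat)), ref_n$p.value,
               tolerance = 1e-9)
})

test_that("normal approximation tracks the exact p at moderate n", {
  set.seed(15)
  for (rep in 1:5) {
    a <- rnorm(8)
    b <- rnorm(8) + runif(1, 0, 1.5)
    pe <- rank_sum_test(a, b, mode = "exact")$p_value
    pn <- rank_sum_test(a, b, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("swapping the samples flips Z but leaves p unchanged", {
  set.seed(16)
  a <- rnorm(9)
  b <- rnorm(11) + 1
  r1 <- rank_sum_test(a, b)
  r2 <- rank_sum_test(b, a)
  expect_equal(r1$z_stat, -r2$z_stat, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_error(rank_sum_test(numeric(0), b), "non-empty")
})

test_that("regional DE averages the region's nodes per subject and segment", {
  m <- default_montage()
  recs <- expand.grid(subject = c("s1", "s2"), segment = 1:2,
                      node = m$channels, stringsAsFactors = FALSE)
  recs$group <- "control"
  recs$de <- seq_len(nrow(recs))
  out <- regional_de(recs, m$frontal)
  expect_identical(nrow(out), 4L)
  cell <- recs[recs$subject == "s1" & recs$segment == 2 &
               recs$node %in% m$frontal$channels, ]
  expect_equal(out$de[out$subject == "s1" & out$segment == 2],
               mean(cell$de))
  # analytic case: values 1..7 average to 4
  one <- data.frame(subject = "s", group = "g", segment = 1,
                    node = m$frontal$channels, de = 1:7)
  expect_equal(regional_de(one, m$frontal)$de, 4)
  # order invariance
  shuf <- one[sample(nrow(one)), ]
  expect_equal(regional_de(shuf, m$frontal)$de, 4)
  expect_error(regional_de(one[-1, ], m$frontal), "Fp1")
})

test_that("group summaries report mean and sample SD per cell", {
  d <- data.frame(subject = c("a", "b", "a", "b"), group = "g",
                  segment = c(1, 1, 2, 2), region = "frontal",
                  de = c(1, 3, 5, 5))
  s <- group_summary(d)
  expect_equal(s$mean, c(2, 5))
  expect_equal(s$sd, c(sqrt(2), 0), tolerance = 1e-12)
  single <- data.frame(subject = "a", group = "g", segment = 1,
                       region = "r", de = 2)
  expect_warning(s1 <- group_summary(single), "single subject")
  expect_equal(s1$sd, 0)
  set.seed(17)
  big <- data.frame(subject = rep(letters[1:10], 2), group = "g",
                    segment = rep(1:2, each = 10), region = "r",
                    de = rnorm(20))
  sb <- group_summary(big)
  expect_equal(sb$mean[1], mean(big$de[big$segment == 1]))
  expect_equal(sb$sd[2], sd(big$de[big$segment == 2]))
})
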