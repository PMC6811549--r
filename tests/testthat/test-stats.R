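test_that("distribution-family selection identifies clear cases", {
  set.seed(6)
  hits_n <- vapply(1:20, function(i)
    select_family(rnorm(200, 10, 3))$family == "normal", logical(1))
  expect_gte(mean(hits_n), 0.9)
  hits_l <- vapply(1:20, function(i)
    select_family(rlnorm(200, 1, 0.9))$family == "log-normal", logical(1))
  expect_gte(mean(hits_l), 0.9)
  expect_error(select_family(rep(3, 20)), "constant")
  neg <- select_family(c(rnorm(30, 0, 1)))
  expect_equal(neg$family, "normal")
  expect_match(neg$note, "non-positive")
})

test_that("the omnibus normality statistic matches an external oracle", {
  # frozen from an independent implementation of the same K2 statistic
  x <- c(10.00246, 10.597491, 9.451724, 8.218816, 9.090658, 8.016707,
         10.120287, 12.68043, 9.015587, 8.75905, 10.979684, 10.713774,
         10.210828, 8.139064, 9.941496, 11.390606, 7.311571, 9.084768,
         6.197555, 7.420925, 6.31653, 9.529818, 7.465107, 10.542529,
         10.313502, 9.626138, 4.966481, 8.922614, 9.902998, 10.226618,
         6.939728, 9.044493, 8.042962, 8.382326, 12.121797, 8.384931,
         9.934957, 11.76878, 8.832799, 9.776596, 10.220928, 10.127564,
         7.549888, 10.15228, 12.717647, 6.905711, 11.718765, 10.238708,
         8.717059, 14.000833, 11.524519, 7.601422, 10.149032, 11.153379,
         9.622436, 11.365821, 9.866965, 11.334495, 12.877045, 8.648675)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 0.24481207901078705, tolerance = 1e-10)
  expect_equal(r$p_value, 0.8847890362533616, tolerance = 1e-10)
  y <- c(3.197953, 1.876398, 3.009623, 1.051528, 1.710112, 2.323427,
         5.579009, 6.794936, 0.942874, 1.439486, 4.560913, 0.55215,
         1.876605, 2.514743, 7.43064, 4.718652, 2.092227, 2.024129,
         2.225193, 9.196505, 1.930116, 2.13199, 3.604097, 2.46794,
         2.321405, 1.114879, 2.693342, 1.906244, 6.909534, 4.583536,
         2.666282, 4.639956, 2.071151, 6.307258, 2.706565, 4.334932,
         0.967815, 3.5871, 0.704291, 0.533518, 2.130632, 1.323206,
         3.099504, 16.375811, 1.397411, 1.650115, 3.203754, 4.032597,
         2.360504, 2.305404, 4.768207, 4.120301, 1.188937, 2.551432,
         2.796111, 1.169308, 3.346354, 1.36839, 5.915958, 3.171475)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 59.914597205808235, tolerance = 1e-8)
})

test_that("the normality gate selects the t-test for normal samples", {
  set.seed(10)
  picks <- vapply(1:100, function(i) {
    r <- exact_and_rank_tests(rnorm(30, 5, 1), rnorm(30, 5, 1), "unpaired")
    grepl("t-test", r$method)
  }, logical(1))
  expect_gte(mean(picks), 0.9)
})

test_that("rank tests handle skewed and identical samples sensibly", {
  set.seed(11)
  x <- rlnorm(40, 0, 1.2)
  r <- exact_and_rank_tests(x, x, "unpaired")
  expect_equal(r$method, "Mann-Whitney U-test")
  expect_gt(r$p_value, 0.95)
  rp <- exact_and_rank_tests(rlnorm(25, 0, 1.3), rlnorm(25, 0.8, 1.3),
                             design = "unpaired")
  expect_lt(rp$p_value, 1)
  pr <- exact_and_rank_tests(rnorm(20), rnorm(20), "paired")
  expect_true(pr$p_value >= 0 && pr$p_value <= 1)
})

test_that("Fisher's exact test matches hypergeometric enumeration exactly", {
  # the connectivity table: 33.6% of 110 pairs vs 14.8% of 54 pairs
  tab <- matrix(c(37, 73, 8, 46), nrow = 2, byrow = TRUE)
  r <- exact_and_rank_tests(tab, design = "contingency")
  expect_equal(r$p_value, fisher_enum_p(tab), tolerance = 1e-12)
  expect_lt(r$p_value, 0.05)
  expect_equal(round(r$p_value, 3), 0.015)
  # random tables with n <= 200, drawn by margins
  set.seed(12)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    r1 <- sample(1:(n - 1), 1)             # first-row total
    c1 <- sample(1:(n - 1), 1)             # first-column total
    rng <- max(0, c1 - (n - r1)):min(r1, c1)
    a <- rng[sample.int(length(rng), 1)]
    t2 <- matrix(c(a, r1 - a, c1 - a, n - r1 - c1 + a), 2, byrow = TRUE)
    r2 <- exact_and_rank_tests(t2, design = "contingency")
    expect_equal(r2$p_value, fisher_enum_p(t2), tolerance = 1e-9)
  }
  expect_error(exact_and_rank_tests(matrix(1:6, 2), design = "contingency"),
               "2x2")
})

test_that("regression F-test: exact nulls, self-comparison, separation", {
  # self-comparison: duplicating one group gives F ~ 0
  set.seed(13)
  d <- tibble::tibble(x = runif(30), g = rep(c("a", "b"), 15))
  d$y <- 2 * d$x + 1 + rnorm(30, 0, 0.1)
  d2 <- d; d2$y <- 2 * d2$x + 1            # identical noiseless halves
  r0 <- curve_compare_ftest(
    tibble::tibble(x = rep(d2$x[1:15], 2), y = rep(d2$y[1:15], 2),
                   g = rep(c("a", "b"), each = 15)),
    y = "y", x = "x", group = "g", model = "linear")
  expect_lt(r0$statistic, 1e-6)
  # null calibration: identical generating process -> p approx uniform
  pv <- replicate(100, {
    dd <- tibble::tibble(x = runif(40), g = rep(c("a", "b"), each = 20))
    dd$y <- 1.5 * dd$x + rnorm(40, 0, 1)
    curve_compare_ftest(dd, "y", "x", "g", "linear")$p_value
  })
  expect_gt(mean(pv > 0.05), 0.85)
  expect_gt(min(pv), 0)
  # sigmoids with midpoints 6 mV apart separate significantly
  v <- rep(seq(-50, -120, by = -10), each = 8)
  mk <- function(v12) 100 / (1 + exp((v - v12) / 8)) + rnorm(length(v), 0, 4)
  set.seed(15)
  dd <- tibble::tibble(x = c(v, v), y = c(mk(-86), mk(-92)),
                       g = rep(c("WT", "KO"), each = length(v)))
  rb <- curve_compare_ftest(dd, "y", "x", "g", "boltzmann")
  expect_lt(rb$p_value, 0.01)
})

test_that("hierarchical comparison: invariance, effect direction, metadata", {
  set.seed(16)
  mk_data <- function(shift = 0) {
    g <- rep(c("WT", "KO"), each = 20)
    animal <- paste0(g, rep(rep(1:4, each = 5), 2))
    litter <- paste0("L", rep(rep(1:2, each = 10), 2))
    tibble::tibble(value = rnorm(40, 10, 1) +
                     rnorm(8, 0, 0.5)[as.integer(factor(animal))] +
                     ifelse(g == "KO", shift, 0),
                   genotype = g, animal = animal, litter = litter)
  }
  d <- mk_data(2)
  r <- hierarchical_compare(d, family = "normal")
  expect_lt(r$p_value, 0.01)
  expect_gt(r$effect, 0)                   # KO larger
  expect_true("animal" %in% r$meta$random_effects)
  # invariance to row order
  r2 <- hierarchical_compare(d[sample(nrow(d)), ], family = "normal")
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-6)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-6)
  # preconditions
  expect_error(hierarchical_compare(d[d$animal %in% c("WT1", "KO1"), ]),
               "2 animals")
  td <- generics::tidy(r)
  expect_true(all(c("method", "statistic", "p.value") %in% names(td)))
})

test_that("binomial GLMM compares silent-spine style proportions", {
  set.seed(17)
  d <- tibble::tibble(
    genotype = rep(c("WT", "KO"), each = 10),
    animal = paste0(rep(c("w", "k"), each = 10), rep(1:5, 4)),
    trials = 24L)
  d$value <- rbinom(20, d$trials, ifelse(d$genotype == "KO", 0.18, 0.06))
  r <- hierarchical_compare(d, family = "binomial")
  expect_lt(r$p_value, 0.05)
  expect_gt(r$effect, 0)
})
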