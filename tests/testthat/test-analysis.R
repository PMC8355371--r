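# four-pass moment oracle, independent of the package implementation
kurtosis_oracle <- function(x) {
  n <- length(x)
  m1 <- sum(x) / n
  d <- x - m1
  m2 <- sum(d^2) / n
  m4 <- sum(d^4) / n
  m4 / m2^2 - 3
}

# wrap a plain response matrix (stimuli x neurons) as a harvested object
as_responses <- function(..., labels = NULL) {
  mats <- list(...)
  structure(list(responses = mats,
                 active = lapply(mats, function(m) apply(m, 2, max) > 0),
                 labels = labels, config = NULL),
            class = "dhpc_responses")
}

test_that("excess kurtosis matches population-moment values and closed forms", {
  expect_equal(excess_kurtosis(c(1, -1, 1, -1)), -2)
  # exact empirical Bernoulli sample: kurtosis equals the closed form
  p <- 0.01; n <- 1e5
  x <- rep(c(1, 0), c(n * p, n * (1 - p)))
  expect_equal(excess_kurtosis(x), (1 - 6 * p * (1 - p)) / (p * (1 - p)))
  # standard normal draws have excess kurtosis near 0
  set.seed(1)
  expect_lt(abs(excess_kurtosis(rnorm(1e5))), 0.1)
  # random Bernoulli draw agrees with the closed form within sampling error
  set.seed(2)
  xb <- rbinom(1e5, 1, p)
  expect_equal(excess_kurtosis(xb), (1 - 6 * p * (1 - p)) / (p * (1 - p)),
               tolerance = 0.15)
  # agreement with a naive four-pass oracle on random data
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    expect_equal(excess_kurtosis(x), kurtosis_oracle(x), tolerance = 1e-10)
  }
  # cross-check against an independent library implementation
  set.seed(3)
  x <- rexp(500)
  expect_equal(excess_kurtosis(x), e1071::kurtosis(x, type = 1),
               tolerance = 1e-12)
  expect_true(is.na(excess_kurtosis(rep(2, 10))))
  expect_error(excess_kurtosis(1:3), "at least 4")
})

test_that("selectivity is per-neuron kurtosis over stimuli, active neurons only", {
  set.seed(4)
  m <- matrix(rexp(100 * 6), 100, 6)
  m[, 3] <- 0                              # silent neuron
  m[, 5] <- 1                              # constant (but active) neuron
  resp <- as_responses(m)
  sel <- selectivity(resp, 1)
  expect_length(sel, 5)                    # silent neuron excluded
  expect_true(is.na(sel[4]))               # constant neuron flagged
  expect_equal(sel[1], kurtosis_oracle(m[, 1]))
  # a neuron responding to exactly 1 of 100 stimuli has Bernoulli kurtosis
  m2 <- cbind(matrix(runif(400), 100), c(1, rep(0, 99)))
  p <- 0.01
  expect_equal(selectivity(as_responses(m2), 1)[5],
               (1 - 6 * p * (1 - p)) / (p * (1 - p)))
  # permuting stimuli leaves selectivity unchanged
  perm <- sample(100)
  expect_equal(selectivity(as_responses(m[perm, ]), 1), sel)
})

test_that("sparseness normalizes per-neuron gain before per-stimulus kurtosis", {
  set.seed(5)
  m <- matrix(rexp(40 * 12), 40, 12)
  sp <- sparseness(as_responses(m), 1)
  expect_length(sp, 40)
  # scaling one neuron's gain does not change sparseness (up to rounding)
  m_gain <- m; m_gain[, 7] <- m_gain[, 7] * 10
  expect_equal(sparseness(as_responses(m_gain), 1), sp, tolerance = 1e-12)
  # power-of-two rescaling is exact in floating point: bitwise identical
  m_pow2 <- sweep(m, 2, 2^sample(-3:3, 12, replace = TRUE), "*")
  expect_identical(sparseness(as_responses(m_pow2), 1), sp)
  # global rescaling is also a per-neuron rescaling
  expect_identical(sparseness(as_responses(m * 4), 1), sp)
  # identical rows -> constant normalized population vector -> flagged
  m_const <- matrix(rep(runif(12), each = 8), 8, 12)
  expect_true(all(is.na(sparseness(as_responses(m_const), 1))))
  # permuting neurons leaves sparseness unchanged
  expect_equal(sparseness(as_responses(m[, sample(12)]), 1), sp)
})

test_that("dynamic range is the linear-interpolation interquartile range", {
  m <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(10, 0, 5, 2))
  dr <- dynamic_range(as_responses(m), 1)
  expect_equal(dr[1], 1.5)                  # 3.25 - 1.75
  expect_equal(dr[2], 0)
  expect_equal(dr[3], unname(quantile(m[, 3], 0.75) - quantile(m[, 3], 0.25)))
  # translation invariance
  expect_equal(dynamic_range(as_responses(m + 7), 1), dr)
})

test_that("ablation removes the top fraction by the requested score", {
  set.seed(6)
  # 19 broadly tuned neurons plus one hyper-selective neuron that dominates
  # population kurtosis
  m <- matrix(runif(50 * 19, 0.5, 1.5), 50, 19)
  spike <- rep(0.01, 50); spike[7] <- 30
  m <- cbind(m, spike)
  resp <- as_responses(m)
  all_sp <- ablation_sparseness(resp, 1, "all")
  expect_equal(all_sp, sparseness(resp, 1))
  snr <- ablation_sparseness(resp, 1, "snr", 0.10)   # drops 2 of 20 neurons
  expect_lt(mean(snr), mean(all_sp))
  # fraction 0 is a no-op for both modes
  expect_equal(ablation_sparseness(resp, 1, "snr", 0), all_sp)
  expect_equal(ablation_sparseness(resp, 1, "dnr", 0), all_sp)
  # dnr scores by IQR: removing broad-range neurons must leave the spike
  dnr <- ablation_sparseness(resp, 1, "dnr", 0.10)
  expect_length(dnr, 50)
  expect_error(ablation_sparseness(as_responses(m[, 1:4]), 1, "snr", 0.9),
               "fewer than 4")
})

test_that("activity correlations recover engineered relationships", {
  set.seed(7)
  # neurons whose selectivity decreases as mean rate increases
  n_stim <- 200
  m <- sapply(1:30, function(i) {
    rate <- i / 10
    x <- rexp(n_stim, rate = 1 / rate)^(1 + 2 / i)
    x / max(x) * rate
  })
  r <- activity_correlations(as_responses(m), 1)
  expect_lt(r$r_selectivity_activity, 0)
  # independent noise gives near-zero correlations
  m0 <- matrix(rexp(5000 * 20), 5000, 20)
  r0 <- activity_correlations(as_responses(m0), 1)
  expect_lt(abs(r0$r_sparseness_activity), 0.1)
})

test_that("area comparisons are two-sided Mann-Whitney with Bonferroni capping", {
  res <- compare_areas(list(a = 1:50, b = 101:150))
  expect_equal(nrow(res), 1)
  expect_lt(res$p_bonferroni, 1e-6)
  # identical samples: corrected p capped at 1
  res2 <- compare_areas(list(a = rep(1:5, 10), b = rep(1:5, 10),
                             c = rep(1:5, 10)))
  expect_equal(nrow(res2), 3)               # 3 pairwise tests for 3 areas
  expect_true(all(res2$p_bonferroni == 1))
  # four areas give six tests, correction is monotone and capped
  res3 <- compare_areas(list(rnorm(30), rnorm(30), rnorm(30), rnorm(30)))
  expect_equal(nrow(res3), 6)
  expect_equal(res3$p_bonferroni, pmin(1, res3$p_raw * 6))
})

test_that("linear readout separates separable representations and not shuffled ones", {
  set.seed(8)
  n <- 80
  labels <- factor(rep(c("a", "b"), each = n / 2))
  sep <- rbind(matrix(runif(n / 2 * 10, 0, 0.4), n / 2),
               matrix(runif(n / 2 * 10, 0.6, 1.0), n / 2))
  resp <- as_responses(sep, labels = labels)
  out <- linear_readout(resp, n_boot = 5, seed = 9)
  expect_equal(dim(out$accuracy), c(5L, 1L))
  expect_equal(out$mean_accuracy, 1)
  expect_lt(out$p_vs_chance, 0.05)
  # shuffled labels: accuracy compatible with chance
  resp_null <- as_responses(sep, labels = sample(labels))
  out_null <- linear_readout(resp_null, n_boot = 20, seed = 10)
  se <- sd(out_null$accuracy) / sqrt(20)
  expect_lt(abs(out_null$mean_accuracy - 0.5), max(3 * se, 0.12))
  # single repeat returns a single accuracy
  out1 <- linear_readout(resp, n_boot = 1, seed = 11)
  expect_length(out1$accuracy, 1)
  expect_error(linear_readout(as_responses(sep), n_boot = 2), "no stimulus labels")
})

test_that("rf weight images are min-max normalized receptive-field renderings", {
  cfg <- dhpc_config(input_size = c(8, 8, 3), population_sizes = c(4, 2),
                     rf_size = 3)
  net <- dhpc_network(cfg, seed = 12)
  imgs <- rf_weight_images(net, 1)
  expect_length(imgs, 4)
  expect_equal(dim(imgs[[1]]), c(3, 3, 3))
  expect_true(all(sapply(imgs, function(im) min(im) == 0 && max(im) == 1)))
  # scale invariance of the normalization
  net2 <- net; net2$weights[[1]] <- net$weights[[1]] * 2
  expect_equal(rf_weight_images(net2, 1), imgs)
  # symmetric weights map 0 to 0.5
  net3 <- net
  net3$weights[[1]][, 1, 1] <- seq(-1, 1, length.out = 27)
  im <- rf_weight_images(net3, 1, cbind(1, 1))[[1]]
  expect_equal(sort(as.vector(im))[14], 0.5)
  # constant weights render mid-gray
  net3$weights[[1]][, 1, 1] <- 3
  expect_true(all(rf_weight_images(net3, 1, cbind(1, 1))[[1]] == 0.5))
})

test_that("metrics_report bundles every per-area statistic coherently", {
  set.seed(13)
  labels <- factor(rep(c("a", "b"), each = 20))
  m1 <- matrix(rexp(40 * 10), 40, 10) +
    outer(as.integer(labels) - 1, runif(10))
  m2 <- matrix(rexp(40 * 8), 40, 8) +
    2 * outer(as.integer(labels) - 1, runif(8))
  rep_obj <- metrics_report(as_responses(m1, m2, labels = labels),
                            n_boot = 3, seed = 14)
  expect_s3_class(rep_obj, "dhpc_metrics")
  expect_named(rep_obj$per_area, c("area1", "area2"))
  a1 <- rep_obj$per_area$area1
  expect_length(a1$selectivity, 10)
  expect_length(a1$sparseness, 40)
  expect_equal(a1$ablation$all, a1$sparseness)
  expect_equal(nrow(rep_obj$selectivity_comparison), 1)
  expect_length(rep_obj$readout$mean_accuracy, 2)
})
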