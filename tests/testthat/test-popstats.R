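test_that("WBC size threshold is the empirical upper-tail quantile", {
  # sort-based oracle for type-7 interpolation on 1..1000 at p = 0.999:
  # h = 999 * 0.999 + 1 = 999.001 -> 999 + 0.001 * (1000 - 999)
  expect_equal(as.numeric(wbc_size_threshold(1:1000, 0.001)), 999.001)
  x <- rnorm(101)
  expect_equal(as.numeric(wbc_size_threshold(x, 0.5)), median(x))
  expect_warning(wbc_size_threshold(1:50, 0.001), "poorly resolved")
  expect_error(wbc_size_threshold(numeric(0)), "empty")
})

test_that("planted 99.9% quantile is recovered within a bootstrap CI", {
  cfg <- synth_config(seed = 41)
  pop <- sample_population(cfg, 10000, c(WBC = 1.0))
  thr <- wbc_size_threshold(pop$true_diameter_um)
  set.seed(42)
  boot <- replicate(200, as.numeric(wbc_size_threshold(
    sample(pop$true_diameter_um, replace = TRUE))))
  ci <- quantile(boot, c(0.005, 0.995))
  expect_gte(13.9, ci[[1]])
  expect_lte(13.9, ci[[2]])
  expect_equal(as.numeric(thr), 13.9, tolerance = 0.1)
})

test_that("equivalent EpCAM threshold is the (1 - yield) quantile", {
  expect_equal(equivalent_epcam_threshold(0:100, 0.40), 60)
  x <- rlnorm(500, 4, 1)
  expect_equal(equivalent_epcam_threshold(x, 0.99),
               unname(quantile(x, 0.01, type = 7)))
  expect_error(equivalent_epcam_threshold(1:5, 0.4), "at least 10")
  expect_error(equivalent_epcam_threshold(0:100, 1.2), "in \\(0, 1\\)")
})

test_that("planted yield quantile is recovered on a PC3-like population", {
  # lognormal with mean 369.7 a.u. built so that 40% of cells exceed
  # ~117 a.u.: sdlog solves mu + s^2/2 = log(369.7) with
  # (log(117) - mu)/s = qnorm(0.6)
  z <- qnorm(0.6)
  s <- z + sqrt(z^2 + 2 * (log(369.7) - log(117)))
  mu <- log(117) - z * s
  set.seed(43)
  x <- rlnorm(10000, mu, s)
  thr <- equivalent_epcam_threshold(x, 0.40)
  boot <- replicate(200, equivalent_epcam_threshold(
    sample(x, replace = TRUE), 0.40))
  ci <- quantile(boot, c(0.005, 0.995))
  expect_gte(117, ci[[1]])
  expect_lte(117, ci[[2]])
  # and by construction the threshold retains 40% of the population
  expect_equal(mean(x >= thr), 0.40, tolerance = 0.01)
})

test_that("consensus threshold is the order-invariant median", {
  # per-line equivalents with the interval entry collapsed to its lower end
  expect_equal(consensus_threshold(c(411, 117, 147)), 147)
  expect_equal(consensus_threshold(5), 5)
  set.seed(44)
  v <- runif(7, 50, 500)
  expect_equal(consensus_threshold(v), consensus_threshold(sample(v)))
  expect_error(consensus_threshold(numeric(0)), "no thresholds")
})

test_that("fraction below uses strict inequality", {
  expect_equal(fraction_below(c(10, 12, 15), 13.9), 100 * 2 / 3)
  expect_equal(fraction_below(c(20, 30), 13.9), 0)
  expect_equal(fraction_below(c(13.9, 14), 13.9), 0)  # ties go above
  expect_error(fraction_below(numeric(0), 1), "empty")
})

test_that("quadrant percentages partition the events", {
  q <- quadrant_percentages(c(10, 10, 20, 20), c(50, 200, 50, 200),
                            13.9, 147)
  expect_equal(unname(q), c(25, 25, 25, 25))
  q1 <- quadrant_percentages(rep(10, 5), rep(50, 5), 13.9, 147)
  expect_equal(unname(q1), c(100, 0, 0, 0))

  # brute-force double-loop oracle on a random cloud
  set.seed(45)
  size <- rlnorm(1000, log(12), 0.3)
  ep <- rlnorm(1000, 4, 1.2)
  q <- quadrant_percentages(size, ep, 13.9, 147)
  counts <- c(0, 0, 0, 0)
  for (i in seq_along(size)) {
    s <- size[i] < 13.9; e <- ep[i] < 147
    j <- if (s && e) 1 else if (s) 2 else if (e) 3 else 4
    counts[j] <- counts[j] + 1
  }
  expect_equal(unname(q), 100 * counts / 1000)
  expect_equal(sum(q), 100)
})

test_that("expected yield curve is one minus the empirical CDF", {
  cv <- expected_yield_curve(c(1, 2, 3), c(0, 2, 4))
  expect_equal(cv$yield, c(1, 2 / 3, 0))
  set.seed(46)
  x <- rlnorm(400, 2, 0.7)
  grid <- seq(0, 40, by = 0.5)
  cv <- expected_yield_curve(x, grid)
  oracle <- vapply(grid, function(t) sum(x >= t) / length(x), numeric(1))
  expect_equal(cv$yield, oracle)
  expect_true(all(diff(cv$yield) <= 0))
  expect_equal(cv$yield[1], 1)  # grid starts below the minimum
  expect_error(expected_yield_curve(x, c(3, 1)), "non-decreasing")
  # complementarity with fraction_below away from ties
  t0 <- 5.5
  expect_equal(100 * cv$yield[grid == t0][1] + fraction_below(x, t0), 100)
})

test_that("rank-sum test matches full enumeration for small layouts", {
  expect_equal(compare_distributions(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(compare_distributions(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  x <- c(5, 1, 9, 3); same <- compare_distributions(x, x)
  expect_equal(same$p.value, 1)

  set.seed(47)
  for (n1 in 1:9) for (n2 in 1:(10 - n1)) {
    vals <- sample(seq_len(200), n1 + n2)  # distinct -> no ties
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    res <- compare_distributions(a, b)
    expect_true(res$exact)
    expect_equal(res$p.value, enumerate_ranksum_p(a, b), tolerance = 1e-12,
                 label = sprintf("layout n1=%d n2=%d", n1, n2))
  }
})

test_that("shifted lognormal populations separate at p < 0.001", {
  set.seed(48)
  lines <- rlnorm(500, log(300), 0.5)   # cell-line-like expression
  ctcs <- rlnorm(500, log(120), 0.8)    # patient-CTC-like expression
  res <- compare_distributions(lines, ctcs)
  expect_false(res$exact)
  expect_lt(res$p.value, 0.001)
})

test_that("relative yield and carryover follow their definitions", {
  expect_equal(relative_yield(199, c(1, 0)), 0.995)
  expect_equal(relative_yield(0, c(5, 5)), 0)
  expect_equal(relative_yield(10, c(0, 0)), 1)
  expect_error(relative_yield(0, c(0, 0)), "no spiked cells")

  expect_equal(wbc_carryover(4450, 10), 445)
  expect_equal(wbc_carryover(0, 10), 0)
  expect_equal(wbc_carryover(8900, 20), wbc_carryover(4450, 10))
  expect_error(wbc_carryover(10, 0), "> 0")
})

test_that("spike concentration averages the four chambers", {
  expect_equal(spike_concentration(c(10, 10, 10, 10), 1), 10)
  expect_equal(spike_concentration(c(0, 10, 10, 20), 1), 10)
  cts <- c(3, 9, 12, 4)
  expect_equal(spike_concentration(cts, 2, 5),
               spike_concentration(sample(cts), 2, 5))
  expect_error(spike_concentration(c(1, 2, 3), 1), "exactly 4")
})

test_that("run accounting applies the per-mL reagent rules", {
  acc <- run_accounting(10, 5.5, 0.110)
  expect_equal(acc$cocktail_ul, 1800)
  expect_equal(acc$beads_mg, 12)
  expect_equal(acc$concentration_factor, 50)
  expect_equal(run_accounting(1, 2, 2)$concentration_factor, 1)
  expect_error(run_accounting(-1, 2, 2), "> 0")
})
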