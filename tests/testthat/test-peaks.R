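test_that("smoothing reproduces hand-computed convolutions", {
  # constant coverage stays constant
  sm <- merge_and_smooth(flat_pileup(101, 3))
  expect_true(all(sm$value == 3))
  expect_equal(sm$grid, seq(0, 100, by = 2))

  # unit impulse at base 10, window 5: value 0.2 wherever the window
  # covers base 10 (grid points 8, 10, 12), else 0
  cov <- numeric(101); cov[11] <- 1
  sm <- merge_and_smooth(pirch_pileup("tx", cov))
  hit <- sm$grid %in% c(8, 10, 12)
  expect_equal(sm$value[hit], rep(0.2, 3))
  expect_true(all(sm$value[!hit] == 0))

  # empty pileup -> all zeros; short transcript -> single global mean
  expect_true(all(merge_and_smooth(flat_pileup(50, 0))$value == 0))
  short <- merge_and_smooth(pirch_pileup("tx", c(1, 2, 3)))
  expect_equal(short$value, 2)
  expect_error(merge_and_smooth(flat_pileup(50), window = 4), "odd")
  expect_error(merge_and_smooth(list(flat_pileup(50), flat_pileup(40))),
               "length")
})

test_that("replicates are summed with optional depth rescaling", {
  r1 <- flat_pileup(60, 2)
  r2 <- flat_pileup(60, 4)
  expect_true(all(merge_and_smooth(list(r1, r2))$merged == 6))
  scaled <- merge_and_smooth(list(r1, r2), lib_sizes = c(1e7, 2e7))
  expect_true(all(scaled$merged == 4))
})

test_that("peak calling finds constructed spikes and nothing on flat", {
  expect_equal(nrow(call_peaks(merge_and_smooth(flat_pileup(500, 2)))), 0)
  expect_equal(nrow(call_peaks(merge_and_smooth(flat_pileup(500, 0)))), 0)

  # one 20x spike on background 1
  cov <- rep(1, 1001); cov[481:520] <- 20
  pk <- call_peaks(merge_and_smooth(pirch_pileup("tx", cov)))
  expect_equal(nrow(pk), 1)
  expect_true(pk$summit >= 480 && pk$summit < 520)
  expect_gte(pk$fold_median, 5)
  expect_true(pk$start <= pk$summit && pk$summit < pk$end)

  # two spikes separated by a sub-threshold valley
  cov <- rep(1, 1001); cov[201:240] <- 20; cov[701:740] <- 25
  pk <- call_peaks(merge_and_smooth(pirch_pileup("tx", cov)))
  expect_equal(nrow(pk), 2)
})

test_that("peak calls are invariant to uniform pileup scaling", {
  set.seed(17)
  sim <- simulate_pileup(1500, 300, 30,
                         peaks = data.frame(summit = 700, width = 60,
                                            amplitude = 15), seed = 17)
  pk1 <- call_peaks(merge_and_smooth(sim$pileup))
  scaled <- pirch_pileup("tx1", sim$pileup$coverage * 37.5)
  pk2 <- call_peaks(merge_and_smooth(scaled))
  expect_equal(pk1$summit, pk2$summit)
  expect_equal(pk1$fold_median, pk2$fold_median, tolerance = 1e-12)
})

test_that("bootstrap p-values behave as a calibrated add-one test", {
  # a height below the null median gives p > 0.5
  p_lo <- bootstrap_pvalue(0.5, 1000, 200, 30, B = 199, seed = 1)
  expect_gt(p_lo, 0.5)

  # monotone non-increasing in observed height
  hs <- c(5, 10, 20, 40)
  ps <- vapply(hs, function(h) {
    bootstrap_pvalue(h, 1000, 200, 30, B = 199, seed = 2)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))

  # a planted 20x peak is never reached by the null
  sim <- simulate_pileup(1000, 200, 30,
                         peaks = data.frame(summit = 500, width = 50,
                                            amplitude = 20), seed = 3)
  pk <- call_peaks(merge_and_smooth(sim$pileup))
  p <- bootstrap_pvalue(max(pk$height), 1000, sim$n_reads, 30, B = 500,
                        seed = 4)
  expect_equal(p, 1 / 501)

  expect_equal(bootstrap_pvalue(5, 1000, 0, 30), 1)
  expect_error(bootstrap_pvalue(5, 1000, 10, 30, B = 50), "B must")
})

test_that("fold over input follows the pseudocount arithmetic", {
  pk <- data.frame(start = 10L, end = 20L)
  expect_equal(fold_vs_input(pk, rep(4, 30), rep(4, 30)), 1)
  expect_equal(fold_vs_input(pk, rep(9, 30), rep(4, 30)), 2)
  expect_equal(fold_vs_input(pk, rep(9, 30), rep(0, 30)), 10)
})

test_that("planted peaks are recovered and filtered peaks beat input", {
  recalls <- vapply(1:15, function(s) {
    truth <- data.frame(summit = c(400, 1100), width = 60,
                        amplitude = 12)
    sim <- simulate_pileup(1600, 320, 30, peaks = truth, seed = s)
    pk <- call_peaks(merge_and_smooth(sim$pileup))
    all(vapply(truth$summit, function(sm) {
      any(abs(pk$summit - sm) <= 40)
    }, logical(1)))
  }, logical(1))
  expect_true(all(recalls))

  # end-to-end wrapper keeps the planted peak and reports input fold
  truth <- data.frame(summit = 500, width = 60, amplitude = 15)
  pd1 <- simulate_pileup(1000, 200, 30, truth, seed = 31)
  pd2 <- simulate_pileup(1000, 200, 30, truth, seed = 32)
  in1 <- simulate_pileup(1000, 200, 30, seed = 33)
  in2 <- simulate_pileup(1000, 200, 30, seed = 34)
  pk <- transcript_peaks(list(pd1$pileup, pd2$pileup),
                         list(in1$pileup, in2$pileup),
                         read_len = 30, B = 200, seed = 35)
  expect_gte(nrow(pk), 1)
  expect_true(any(abs(pk$summit - 500) <= 40))
  expect_true(all(pk$p_value < 0.05))
  expect_true(all(pk$fold_input > 1))
})

test_that("null transcripts rarely produce significant peaks", {
  n_sig <- sum(vapply(1:40, function(s) {
    sim <- simulate_pileup(1000, 200, 30, seed = 1000 + s)
    pk <- transcript_peaks(list(sim$pileup), n_reads = sim$n_reads,
                           read_len = 30, B = 199, seed = 2000 + s)
    nrow(pk) > 0
  }, logical(1)))
  # ~5% of 40 null transcripts; allow binomial slack
  expect_lte(n_sig, 7)
})
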