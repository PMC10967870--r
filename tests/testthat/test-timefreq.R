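# build an ersp_map by hand (bypassing the wavelet stage)
fake_ersp <- function(values, freq, time, edge = NULL) {
  structure(list(values = values, freq = freq, time = time,
                 edge = edge %||% matrix(FALSE, nrow(values), ncol(values)),
                 channel = "Cz", mask = NULL),
            class = "ersp_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("wavelet power peaks at the stimulus frequency and scales as amplitude squared", {
  rate <- 250
  tt <- seq(0, 8 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 10 * tt)
  tfr <- compute_tfr(x, rate, freqs = 4:30, decim = 5)
  profile <- rowMeans(tfr$power[, !tfr$edge[1, ], drop = FALSE])
  expect_equal(tfr$freq[which.max(profile)], 10)

  # amplitude step x2 at mid-series on a 20 Hz tone: power ratio ~ 4
  amp <- ifelse(tt < 4, 1, 2)
  x2 <- amp * sin(2 * pi * 20 * tt)
  tfr2 <- compute_tfr(x2, rate, freqs = 20, decim = 1)
  tt_d <- tt[tfr2$sample_idx]
  pre <- tfr2$power[1, tt_d > 1 & tt_d < 3.5]
  post <- tfr2$power[1, tt_d > 4.5 & tt_d < 7]
  expect_equal(mean(post) / mean(pre), 4, tolerance = 0.10)

  expect_true(all(compute_tfr(numeric(1000), rate, freqs = 10)$power == 0))
  expect_error(compute_tfr(x, 150, freqs = 4:100), "too low")
})

test_that("ERSP z-normalizes against its own baseline", {
  set.seed(50)
  ds_rate <- 250
  ep <- constant_epoch(0, 0, channels = "Cz", rate = ds_rate)
  ep$samples[] <- rnorm(length(ep$samples))
  em <- ersp_for_epoch(ep, "Cz", freqs = c(6, 10, 20), decim = 5)
  for (k in seq_along(em$freq)) {
    ok <- em$time < 0 & !em$edge[k, ]
    expect_lt(abs(mean(em$values[k, ok])), 0.05)
    expect_equal(sd(em$values[k, ok]), 1, tolerance = 0.05)
  }

  # affine invariance under global amplitude scaling
  ep2 <- ep
  ep2$samples <- ep2$samples * 3.7
  em2 <- ersp_for_epoch(ep2, "Cz", freqs = c(6, 10, 20), decim = 5)
  expect_equal(em2$values, em$values, tolerance = 1e-9)
})

test_that("a frequency-confined power increase yields a stable positive ERSP", {
  rate <- 250
  signs <- vapply(1:20, function(seed) {
    set.seed(seed)
    ep <- constant_epoch(0, 0, channels = "Cz", rate = rate)
    n <- length(ep$time)
    base <- rnorm(n)
    tone <- sin(2 * pi * 10 * seq_len(n) / rate + runif(1, 0, 2 * pi))
    gain <- ifelse(ep$time >= 0, sqrt(2), 1)     # power doubled in block
    ep$samples[1, ] <- base + 3 * gain * tone
    em <- ersp_for_epoch(ep, "Cz", freqs = 10, decim = 10)
    blk <- em$time >= 0.5 & em$time < 9.5
    sign(mean(em$values[1, blk]))
  }, numeric(1))
  expect_true(all(signs == 1))
})

test_that("degenerate permutation inputs give p = 1 and an empty mask", {
  nf <- 2; nt <- 40
  tt <- seq(-5, 10, length.out = nt)
  maps <- lapply(1:6, function(i)
    fake_ersp(matrix(0.5, nf, nt), c(8, 9), tt))
  expect_warning(mk <- baseline_permutation_mask(maps, n_perm = 50, seed = 1),
                 "coarse")
  expect_true(all(mk$p == 1, na.rm = TRUE))
  expect_false(any(mk$mask))
  expect_error(baseline_permutation_mask(maps, n_perm = 5), "permutation count")
})

test_that("the FDR mask stays nested as alpha shrinks", {
  set.seed(52)
  nf <- 5; nt <- 60
  tt <- seq(-5, 10, length.out = nt)
  maps <- lapply(1:6, function(i) {
    v <- matrix(rnorm(nf * nt), nf, nt)
    v[2, tt >= 0] <- v[2, tt >= 0] + 1.5
    fake_ersp(v, 8:12, tt)
  })
  m05 <- baseline_permutation_mask(maps, n_perm = 500, alpha = 0.05, seed = 9)
  m01 <- baseline_permutation_mask(maps, n_perm = 500, alpha = 0.01, seed = 9)
  expect_true(all(!m01$mask | m05$mask))   # m01 subset of m05
  expect_gt(sum(m05$mask), 0)
})

test_that("a sustained alpha desynchronization is localized by the mask", {
  ds <- small_design(subjects = 4, schemes = "FVS-1",
                     channels = c("Fz", "Cz", "Pz", "C3", "C4"))
  eff <- function(g, s) {
    p <- null_effects(); p$alpha_erd_depth <- 0.6; p$laterality_weight <- 1
    p$erd_adaptation_tau <- 1e9; p
  }
  man <- simulation_manifest(ds, 11, eff)
  maps <- list()
  for (i in 1:4) {
    rec <- simulate_trial(man$trials[i, ], man$effects[[i]], ds,
                          man$block_onsets)
    eps <- segment_epochs(rec)
    maps <- c(maps, lapply(eps, ersp_for_epoch, channel = "C3",
                           freqs = 4:30, decim = 10))
  }
  mk <- baseline_permutation_mask(maps, n_perm = 500, seed = 3)
  truth <- outer(mk$freq >= 8 & mk$freq < 12, mk$time >= 0 & mk$time < 10)
  jac <- sum(mk$mask & truth) / sum(mk$mask | truth)
  expect_gt(jac, 0.3)
  # masked alpha bins are negative (desynchronization)
  alpha_rows <- mk$freq >= 8 & mk$freq < 12
  expect_lt(mean(mk$values[alpha_rows, mk$time >= 0 & mk$time < 5]), 0)
})

test_that("ERD/ERS equals the window mean computed by a naive double loop", {
  set.seed(53)
  nf <- 12; nt <- 80
  freq <- 4:15
  tt <- seq(-5, 10, length.out = nt)
  em <- fake_ersp(matrix(rnorm(nf * nt), nf, nt), freq, tt)

  got <- compute_erd_ers(em, c(8, 12), window = c(0, 4))
  # independent oracle: explicit loop over bins
  acc <- 0; K <- 0
  for (i in seq_len(nf)) for (j in seq_len(nt)) {
    if (freq[i] >= 8 && freq[i] < 12 && tt[j] >= 0 && tt[j] < 4) {
      acc <- acc + em$values[i, j]; K <- K + 1
    }
  }
  expect_equal(got$value, acc / K, tolerance = 1e-12)
  expect_equal(got$K, K)

  # constant map and hand-sized windows
  em$values[] <- -2
  expect_equal(compute_erd_ers(em, c(8, 12), c(0, 4))$value, -2)
  em$values[] <- 0
  em$values[5:6, 10:11] <- c(1, -1, 3, 5)
  expect_equal(compute_erd_ers(em, c(freq[5], freq[7]),
                               c(tt[10], tt[12]))$value, 2)
  expect_error(compute_erd_ers(em, c(90, 95), c(0, 4)), "empty")
})
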