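test_that("perfect reconstruction holds across awkward lengths", {
  set.seed(101)
  for (n in c(129L, 512L, 1000L)) {
    x <- rnorm(n)
    dec <- dwt_decompose(x)
    expect_lt(max(abs(dwt_reconstruct(dec) - x)), 1e-8)
  }
})

test_that("decomposition structure: 4 details + 1 approximation, named bands", {
  dec <- dwt_decompose(rnorm(512))
  expect_named(dec$coeffs, c("A4", "D4", "D3", "D2", "D1"))
  expect_named(dec$band_signals,
               c("Delta", "Theta", "Alpha", "Beta", "Gamma"))
  expect_true(all(lengths(dec$band_signals) == 512L))
  expect_equal(dec$nominal_ranges$A4, c(0, 4))
  expect_equal(dec$nominal_ranges$D1, c(32, 64))
})

test_that("coefficient energy is conserved (orthogonal transform)", {
  set.seed(7)
  x <- rnorm(4096)                       # divisible by 2^4: no padding
  dec <- dwt_decompose(x)
  ratio <- sum(vapply(dec$coeffs, function(cc) sum(cc^2), numeric(1))) / sum(x^2)
  expect_lt(abs(ratio - 1), 1e-6)
  # short / odd lengths: padding leaks a little energy but stays within 1%
  x2 <- rnorm(1000)
  dec2 <- dwt_decompose(x2)
  ratio2 <- sum(vapply(dec2$coeffs, function(cc) sum(cc^2), numeric(1))) / sum(x2^2)
  expect_lt(abs(ratio2 - 1), 0.01)
})

test_that("band signals sum to the full reconstruction (linearity)", {
  set.seed(13)
  x <- rnorm(777)
  dec <- dwt_decompose(x)
  expect_lt(max(abs(Reduce(`+`, dec$band_signals) - dwt_reconstruct(dec))), 1e-8)
})

test_that("zero signal gives all-zero coefficients and bands", {
  dec <- dwt_decompose(numeric(512))
  expect_true(all(vapply(dec$coeffs, function(cc) all(cc == 0), logical(1))))
  expect_true(all(vapply(dec$band_signals, function(s) all(s == 0), logical(1))))
  expect_true(all(dwt_reconstruct(dec) == 0))
})

test_that("a 10 Hz tone localizes in the Alpha (D3) band", {
  tone <- sin(2 * pi * 10 * (0:511) / 128)
  dec <- dwt_decompose(tone, fs = 128)
  en <- vapply(dec$band_signals, function(s) sum(s^2), numeric(1))
  expect_gt(en[["Alpha"]] / sum(en), 0.70)
  # cross-check band assignment with the independent periodogram oracle
  expect_gt(periodogram_band_energy(tone, 128, 8, 16) /
              periodogram_band_energy(tone, 128, 0, 64), 0.95)
})

test_that("a 1 Hz tone survives approximation-only reconstruction", {
  tone <- sin(2 * pi * 1 * (0:511) / 128)
  dec <- dwt_decompose(tone, fs = 128)
  for (k in c("D1", "D2", "D3", "D4")) dec$coeffs[[k]][] <- 0
  approx_only <- dwt_reconstruct(dec)
  expect_gt(sum(approx_only^2) / sum(tone^2), 0.95)
})

test_that("input validation raises named failures", {
  expect_error(dwt_decompose(rnorm(4)), "too short")
  expect_error(dwt_decompose(c(rnorm(100), NA)), "non-finite")
  expect_error(wavelet_config(q = 0), "between 0 and 1")
  expect_error(wavelet_config(levels = 0), "levels")
  expect_error(wavelet_config(wavelet = "sym9"), "unknown wavelet")
})

test_that("sigma estimate: closed form, zero case, and MAD consistency", {
  dec <- dwt_decompose(rnorm(512))
  dec$coeffs$D1 <- c(0.6745, -0.6745, 0.6745, -0.6745)
  expect_equal(estimate_sigma(dec), 1.0)
  dec$coeffs$D1 <- numeric(4)
  expect_equal(estimate_sigma(dec), 0)
  # Monte-Carlo: white standard-normal input has unit-scale D1 coefficients
  set.seed(2024)
  dec2 <- dwt_decompose(rnorm(4096))
  expect_gt(estimate_sigma(dec2), 0.9)
  expect_lt(estimate_sigma(dec2), 1.1)
})

test_that("FDR denoising keeps structure and kills pure noise", {
  # all-zero details stay untouched
  dec <- dwt_decompose(numeric(256))
  den <- fdr_denoise(dec, sigma = 1)
  expect_identical(den$coeffs, dec$coeffs)
  # sigma = 0 returns the decomposition unchanged
  set.seed(5)
  dec2 <- dwt_decompose(rnorm(256))
  expect_identical(fdr_denoise(dec2, sigma = 0)$coeffs, dec2$coeffs)
  # vanishing q on pure noise leaves only the approximation band
  den2 <- fdr_denoise(dec2, q = 1e-12)
  detail_energy <- sum(vapply(den2$coeffs[c("D1", "D2", "D3", "D4")],
                              function(cc) sum(cc^2), numeric(1)))
  expect_equal(detail_energy, 0)
  ref <- dec2
  for (k in c("D1", "D2", "D3", "D4")) ref$coeffs[[k]][] <- 0
  expect_equal(dwt_reconstruct(den2), dwt_reconstruct(ref))
})

test_that("FDR denoising reduces MSE on the sparse-spike benchmark", {
  set.seed(31)
  n <- 1024
  clean_dec <- dwt_decompose(numeric(n))
  # plant 10 sparse coefficients of magnitude 10 sigma in the details
  sigma_true <- 1
  spots <- list(c("D2", 5L), c("D2", 40L), c("D3", 3L), c("D3", 60L),
                c("D1", 100L), c("D1", 200L), c("D4", 10L), c("D4", 30L),
                c("D2", 90L), c("D3", 20L))
  for (sp in spots) clean_dec$coeffs[[sp[[1]]]][as.integer(sp[[2]])] <- 10 * sigma_true
  clean <- dwt_reconstruct(clean_dec)
  noisy <- clean + rnorm(n, sd = sigma_true)
  den <- fdr_denoise(dwt_decompose(noisy))
  denoised <- dwt_reconstruct(den)
  mse <- function(a, b) mean((a - b)^2)
  expect_lt(mse(denoised, clean), mse(noisy, clean))
})

test_that("BH selection is monotone in q", {
  set.seed(77)
  dec <- dwt_decompose(rnorm(512) + c(rep(0, 400), rnorm(112, sd = 4)))
  sigma <- estimate_sigma(dec)
  qs <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  kept <- lapply(qs, function(q) {
    den <- fdr_denoise(dec, q = q, sigma = sigma)
    unlist(lapply(c("D1", "D2", "D3", "D4"),
                  function(k) den$coeffs[[k]] != 0))
  })
  for (i in seq_len(length(qs) - 1)) {
    # every coefficient kept at the lower q is still kept at the higher q
    expect_true(all(kept[[i + 1]][kept[[i]]]))
  }
})
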