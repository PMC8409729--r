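test_that("precursor-window removal is boundary-inclusive", {
  s <- spectrum("x", 400, cbind(c(200, 383.0, 390, 400, 417.0), rep(1, 5)))
  out <- remove_precursor_window(s, 17)
  expect_equal(unname(out$peaks[, "mz"]), 200) # 383, 417 exactly on the boundary
  s2 <- spectrum("x", 400, cbind(c(100, 200), c(1, 2)))
  expect_equal(remove_precursor_window(s2)$peaks, s2$peaks)
})

test_that("window filter keeps locally top-ranked peaks (brute-force check)", {
  # 8 peaks inside a 10-Da span, intensities 1..8: every peak's +/-50 window
  # holds all 8, so only the top 6 survive
  s <- spectrum("x", 900, cbind(seq(100, 108.5, length.out = 8), 1:8))
  out <- window_filter(s, top_k = 6, window = 50)
  expect_equal(unname(out$peaks[, "intensity"]), 3:8)

  # two clusters 200 Da apart are filtered independently
  s2 <- spectrum("x", 900, cbind(c(seq(100, 135, by = 5), seq(300, 335, by = 5)),
                                 c(1:8, 8:1)))
  out2 <- window_filter(s2, top_k = 6, window = 50)
  expect_equal(nrow(out2$peaks), 12)

  # property: agrees with the brute-force oracle on random spectra
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    mz <- sort(runif(n, 100, 600))
    int <- sample(1000, n) # distinct intensities
    s3 <- spectrum("r", 900, cbind(mz, int))
    got <- window_filter(s3, top_k = 6, window = 50)$peaks[, "mz"]
    keep <- oracle_window_filter_keep(s3$peaks[, "mz"], s3$peaks[, "intensity"])
    expect_equal(got, s3$peaks[keep, "mz"])
  }
  # small spectra pass through untouched
  s4 <- spectrum("x", 900, cbind(c(100, 200), c(1, 2)))
  expect_equal(window_filter(s4)$peaks, s4$peaks)
})

test_that("modified cosine scores self-similarity at 1 and disjoint spectra at 0", {
  s <- spectrum("a", 400, cbind(c(100, 150, 200, 250), c(10, 40, 20, 5)))
  res <- modified_cosine(s, s)
  expect_equal(res$score, 1, tolerance = 1e-12)
  expect_equal(res$matched_peaks, 4L)

  b <- spectrum("b", 400, cbind(c(110.5, 163.2), c(3, 4)))
  expect_equal(modified_cosine(s, b)$score, 0)

  empty <- spectrum("e", 400, matrix(numeric(0), ncol = 2))
  expect_equal(modified_cosine(s, empty)$score, 0)
  expect_equal(modified_cosine(s, empty)$matched_peaks, 0L)
})

test_that("precursor-shifted peaks match and the greedy score equals the optimum", {
  # b is a copy of a with two fragments shifted by the precursor delta
  a <- spectrum("a", 400, cbind(c(100, 150, 200, 250), c(10, 40, 20, 5)))
  b <- spectrum("b", 414.05, cbind(c(100, 150, 214.05, 264.05), c(10, 40, 20, 5)))
  res <- modified_cosine(a, b)
  expect_equal(res$matched_peaks, 4L)
  expect_equal(res$score, 1, tolerance = 1e-9)
  expect_setequal(res$matches$kind[res$matches$index_a %in% c(3, 4)],
                  "precursor_shifted")
  expect_equal(res$score, oracle_modified_cosine(a, b), tolerance = 1e-9)
})

test_that("greedy matching equals exhaustive assignment on random small spectra", {
  set.seed(11)
  for (rep in 1:25) {
    a <- random_spectrum("a", sample(2:7, 1))
    b <- random_spectrum("b", sample(2:7, 1))
    # plant overlap so matches exist: copy some peaks across, some shifted
    take <- seq_len(min(3, nrow(a$peaks)))
    pk <- rbind(b$peaks, cbind(a$peaks[take, 1, drop = FALSE] +
                                 c(0, a$precursor_mz - b$precursor_mz)[
                                   (take %% 2) + 1],
                               a$peaks[take, 2, drop = FALSE]))
    b <- spectrum("b", b$precursor_mz, pk)
    got <- modified_cosine(a, b)$score
    best <- oracle_modified_cosine(a, b)
    expect_lte(got, best + 1e-9)
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("modified cosine is symmetric and bounded", {
  set.seed(5)
  for (rep in 1:15) {
    a <- random_spectrum("a", sample(3:8, 1))
    b <- random_spectrum("b", sample(3:8, 1))
    ab <- modified_cosine(a, b)$score
    ba <- modified_cosine(b, a)$score
    expect_equal(ab, ba, tolerance = 1e-9)
    expect_gte(ab, 0)
    expect_lte(ab, 1)
  }
})

test_that("raising a matched peak's shared intensity never lowers the score", {
  base <- cbind(c(100, 150, 200), c(10, 20, 30))
  a1 <- spectrum("a", 400, base)
  b1 <- spectrum("b", 400, base)
  s1 <- modified_cosine(a1, b1)$score
  up <- base; up[1, 2] <- 60
  s2 <- modified_cosine(spectrum("a", 400, up), spectrum("b", 400, up))$score
  expect_gte(s2 + 1e-12, s1)
})
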