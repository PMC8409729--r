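test_that("the proportionality score reproduces its worked cases", {
  expect_equal(proportionality_score(5, 10, 5, 10), 0)
  expect_equal(proportionality_score(100, 10, 10, 10), 1)
  # zero numerator with the default pseudo-count: log10((1e-10/10+1e-10) / 1)
  expect_equal(proportionality_score(0, 10, 10, 10), -11.0, tolerance = 1e-6)
  expect_error(proportionality_score(1, 1, 1, 1, k = 0), "k must be")
  expect_error(proportionality_score(-1, 1, 1, 1), ">= 0")
})

test_that("the score is antisymmetric, scale-invariant and monotone", {
  set.seed(77)
  for (rep in 1:25) {
    v <- runif(4, 0, 1000)
    s <- proportionality_score(v[1], v[2], v[3], v[4])
    # swapping the two locations negates the score
    expect_equal(s, -proportionality_score(v[3], v[4], v[1], v[2]),
                 tolerance = 1e-12)
    # swapping the two features negates the score
    expect_equal(s, -proportionality_score(v[2], v[1], v[4], v[3]),
                 tolerance = 1e-12)
    # common positive scaling leaves the score essentially unchanged
    v1 <- v + 1 # areas >= 1 so the pseudo-count perturbation is tiny
    s1 <- proportionality_score(v1[1], v1[2], v1[3], v1[4])
    expect_equal(proportionality_score(7 * v1[1], 7 * v1[2], 7 * v1[3], 7 * v1[4]),
                 s1, tolerance = 1e-8)
    # raising n1 never lowers the score
    expect_gte(proportionality_score(v[1] + 50, v[2], v[3], v[4]), s)
  }
})

test_that("log base is configurable and sets the meaning of the cutoff", {
  expect_equal(proportionality_score(100, 10, 10, 10, base = exp(1)), log(10))
  expect_equal(proportionality_score(40, 10, 20, 10, base = 2), 1)
})

test_that("location pair schemes produce the documented pair chains", {
  chain <- location_pairs("chain")
  expect_equal(chain$pair, c("L:A", "A:B", "B:C", "C:D", "D:TT", "TT:TM", "TM:TB"))
  lva <- location_pairs("leaves_vs_all")
  expect_equal(lva$pair, c("L:A", "L:B", "L:C", "L:D", "L:TT", "L:TM", "L:TB"))
  custom <- location_pairs(data.frame(s1 = "A", s2 = "D"))
  expect_equal(custom$pair, "A:D")
  expect_error(location_pairs(data.frame(s1 = "A", s2 = "A")), "invalid")
  expect_error(location_pairs(data.frame(s1 = "A", s2 = "Q")), "invalid")
})

test_that("replicate aggregation honours the method and location grouping", {
  meta <- data.frame(feature_id = "f", mz = 100, rt = 1)
  areas <- matrix(c(2, 4, 9), nrow = 1, dimnames = list(NULL, c("a1", "a2", "b1")))
  tb <- feature_table(meta, areas)
  md <- sample_metadata(data.frame(sample_id = c("a1", "a2", "b1"),
                                   location = c("A", "A", "B")))
  expect_equal(aggregate_location(tb, md, "f", "A"), 3)
  expect_equal(aggregate_location(tb, md, "f", "A", method = "sum"), 6)
  expect_equal(aggregate_location(tb, md, "f", "B"), 9)
  expect_error(aggregate_location(tb, md, "f", "TT"), "no samples")
  expect_error(aggregate_location(tb, md, "g", "A"), "not in table")
})

test_that("score_network orients edges by precursor m/z and applies the scheme", {
  g <- tiny_garden(noise_sigma = 0)
  net <- build_network(g$spectra)
  scores <- score_network(net, g$table, g$metadata)
  rec <- scores$records
  # 7 chain pairs per edge
  expect_equal(nrow(rec), nrow(net$edges) * 7)
  # N is always the heavier member
  prec <- setNames(net$nodes$precursor_mz, net$nodes$feature_id)
  expect_true(all(prec[rec$id_n] >= prec[rec$id_m]))
  # stored areas reproduce the score exactly
  expect_equal(rec$score,
               proportionality_score(rec$n_s1, rec$m_s1, rec$n_s2, rec$m_s2),
               tolerance = 1e-12)
  # decaying parent / accumulating product: heavier member enriched later,
  # so chain scores are negative and beyond the cutoff
  h2 <- rec[rec$id_n == "flavonol_H2" & rec$id_m == "flavonol", ]
  expect_true(all(h2$score < -1))
  # all-constant table gives all-zero scores
  flat <- g$table; flat$areas[] <- 3
  s0 <- score_network(net, flat, g$metadata)
  expect_true(all(s0$records$score == 0))
  expect_equal(nrow(s0$prioritized), 0)

  # a node missing from the table is a named error
  sub <- g$table
  keep <- sub$meta$feature_id != "flavonol"
  sub <- feature_table(sub$meta[keep, ], sub$areas[keep, , drop = FALSE])
  expect_error(score_network(net, sub, g$metadata), "flavonol")
})
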