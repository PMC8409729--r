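# spectra whose pairwise similarity is easy to control: shared backbone with
# per-spectrum random extra peaks
controlled_spectra <- function(n, seed) {
  set.seed(seed)
  backbone <- cbind(seq(100, 240, by = 20), c(100, 90, 80, 70, 60, 50, 40, 30))
  lapply(seq_len(n), function(i) {
    extra <- sample(3:9, 1)
    pk <- rbind(backbone, cbind(runif(extra, 260, 460), runif(extra, 5, 120)))
    spectrum(sprintf("s%02d", i), 480 + i * runif(1, 0.5, 3), pk)
  })
}

test_that("score_all_pairs enumerates every unordered pair consistently", {
  sp <- controlled_spectra(5, seed = 3)
  cand <- score_all_pairs(sp)
  expect_equal(nrow(cand), choose(5, 2))
  expect_false(any(cand$id_a == cand$id_b))
  i <- which(cand$id_a == "s02" & cand$id_b == "s04")
  direct <- modified_cosine(sp[[2]], sp[[4]])
  expect_equal(cand$score[i], direct$score)
  expect_equal(cand$matched_peaks[i], direct$matched_peaks)
  expect_equal(cand$delta_mz[i], sp[[2]]$precursor_mz - sp[[4]]$precursor_mz)
  expect_error(score_all_pairs(sp[1]), "at least 2")
})

test_that("identical spectra form one fully connected family", {
  pk <- cbind(seq(100, 240, by = 20), 8:1)
  sp <- lapply(c("a", "b", "c"), function(id) spectrum(id, 500, pk))
  net <- apply_topology(sp, score_all_pairs(sp))
  expect_equal(nrow(net$edges), 3)
  expect_equal(length(unique(net$nodes$family_id)), 1)
})

test_that("mutual top-K pruning keeps only each node's best neighbours", {
  # star of 15 candidate edges all tied to a hub with distinct scores:
  # top_k = 10 must keep exactly the hub's 10 best satellites
  sp <- lapply(c("hub", sprintf("sat%02d", 1:15)), function(id) {
    spectrum(id, 500 + match(id, c("hub", sprintf("sat%02d", 1:15))) * 3,
             cbind(100, 1))
  })
  cand <- data.frame(
    id_a = "hub", id_b = sprintf("sat%02d", 1:15),
    score = 0.95 - (1:15) * 0.01, matched_peaks = 8L,
    delta_mz = -(1:15) * 3, abs_delta_mz = (1:15) * 3
  )
  net <- apply_topology(sp, cand, top_k = 10)
  expect_equal(nrow(net$edges), 10)
  expect_setequal(net$edges$id_b, sprintf("sat%02d", 1:10))
  # mutual rule is symmetric in node order: flipped edge orientation agrees
  flipped <- cand
  flipped$id_a <- cand$id_b; flipped$id_b <- cand$id_a
  flipped$delta_mz <- -cand$delta_mz
  net2 <- apply_topology(sp, flipped, top_k = 10)
  expect_setequal(edge_key(net$edges$id_a, net$edges$id_b),
                  edge_key(net2$edges$id_a, net2$edges$id_b))
})

test_that("family capping removes lowest-scoring edges until components fit", {
  # chain of 12 nodes with strictly increasing edge scores along the chain
  set.seed(2)
  backbone <- cbind(seq(100, 240, by = 20), c(100, 90, 80, 70, 60, 50, 40, 30))
  sp <- lapply(1:12, function(i) {
    pk <- rbind(backbone, cbind(250 + 10 * i + 0:2, rep(10 + 4 * i, 3)))
    spectrum(sprintf("n%02d", i), 500 + 3 * i, pk)
  })
  cand <- score_all_pairs(sp)
  # keep only chain edges as candidates
  chain <- cand[abs(match(cand$id_a, sprintf("n%02d", 1:12)) -
                    match(cand$id_b, sprintf("n%02d", 1:12))) == 1, ]
  net <- apply_topology(sp, chain, max_family_size = 4)
  sizes <- table(net$nodes$family_id)
  expect_true(all(sizes <= 4))
  # oracle comparison, same candidate set
  ref <- oracle_network(vapply(sp, `[[`, "", "feature_id"),
                        vapply(sp, `[[`, 0, "precursor_mz"),
                        chain, max_family_size = 4)
  expect_setequal(edge_key(net$edges$id_a, net$edges$id_b),
                  edge_key(ref$edges$id_a, ref$edges$id_b))
})

test_that("the network equals an independent brute-force reference on small sets", {
  for (seed in c(1, 7, 23)) {
    sp <- controlled_spectra(10, seed = seed)
    cleaned <- lapply(sp, function(s) window_filter(remove_precursor_window(s)))
    cand <- score_all_pairs(cleaned)
    net <- apply_topology(cleaned, cand, cosine_min = 0.5, min_matched = 5,
                          top_k = 3, max_family_size = 4)
    ref <- oracle_network(vapply(sp, `[[`, "", "feature_id"),
                          vapply(sp, `[[`, 0, "precursor_mz"), cand,
                          cosine_min = 0.5, min_matched = 5, top_k = 3,
                          max_family_size = 4)
    expect_setequal(edge_key(net$edges$id_a, net$edges$id_b),
                    edge_key(ref$edges$id_a, ref$edges$id_b))
    # identical partitions into families
    got <- split(net$nodes$feature_id, net$nodes$family_id)
    want <- split(names(ref$membership), ref$membership)
    expect_setequal(unname(lapply(got, sort)), unname(lapply(want, sort)))
    # pruning never adds edges
    thr <- cand[cand$score > 0.5 & cand$matched_peaks >= 5, ]
    expect_true(all(edge_key(net$edges$id_a, net$edges$id_b) %in%
                      edge_key(thr$id_a, thr$id_b)))
  }
})

test_that("library matching recovers planted noisy copies and respects thresholds", {
  set.seed(31)
  sp <- controlled_spectra(4, seed = 19)
  lib <- lapply(sp, function(s) {
    pk <- s$peaks
    pk[, 2] <- pk[, 2] * runif(nrow(pk), 0.95, 1.05) # 5% intensity jitter
    out <- spectrum(paste0("lib_", s$feature_id), s$precursor_mz, pk)
    out$annotation <- paste0("compound ", s$feature_id)
    out
  })
  hits <- library_match(sp, lib)
  best <- hits[hits$best, ]
  expect_equal(best$library_id[match(c("s01", "s02", "s03", "s04"),
                                     best$feature_id)],
               c("lib_s01", "lib_s02", "lib_s03", "lib_s04"))
  expect_true(all(best$score > 0.7 & best$matched_peaks >= 6))

  ident <- library_match(sp[1], lapply(sp[1], function(s) {
    s$feature_id <- "lib"; s
  }))
  expect_equal(ident$score, 1, tolerance = 1e-9)
  expect_equal(nrow(library_match(sp, list())), 0)
})
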