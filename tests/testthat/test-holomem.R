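test_that("bind is the commutative shift-multiply-sum with impulse identity", {
  set.seed(101)
  items <- random_items(2, 256, c("a", "b"))
  a <- items[[1L]]; b <- items[[2L]]
  id <- identity_item(256)

  expect_equal(bind(id, b)$vector, b$vector, tolerance = 1e-12)
  expect_equal(bind(a, b)$vector, bind(b, a)$vector, tolerance = 1e-12)
  expect_equal(unbind(b, id), b$vector, tolerance = 1e-12)
  expect_error(bind(a, identity_item(128)), "dimension")

  # near-norm-preservation for random vectors
  set.seed(102)
  for (rep in 1:5) {
    ab <- random_items(2, 1024)
    expect_lt(abs(sqrt(sum(bind(ab[[1]], ab[[2]])$vector^2)) - 1), 0.2)
  }
})

test_that("unbind recovers the bound partner and rejects foreign cues", {
  set.seed(103)
  v <- random_items(3, 1024, c("a", "b", "c"))
  tr <- bind(v[[1]], v[[2]])
  rec <- unbind(tr, v[[1]])
  expect_gt(cosine_sim(rec, v[[2]]$vector), 0.9)
  # unrelated cue decodes to chance-level correlation
  expect_lt(abs(cosine_sim(unbind(tr, v[[3]]), v[[2]]$vector)), 3 / sqrt(1024))
})

test_that("superposed pair memory is recalled through cleanup", {
  set.seed(104)
  cues <- random_items(10, 1024, paste0("k", 1:10))
  partners <- random_items(10, 1024, paste0("v", 1:10))
  mem <- pair_memory(cues, partners)
  expect_equal(mem$n_bindings, 10L)
  dict <- cleanup_dictionary(partners)
  for (i in 1:10) {
    res <- cleanup(unbind(mem, cues[[i]]), dict)
    expect_true(res$matched)
    expect_equal(res$label, paste0("v", i))
  }

  # superposition is order-invariant
  traces <- Map(bind, cues, partners)
  expect_equal(superpose_traces(traces)$vector,
               superpose_traces(rev(traces))$vector, tolerance = 1e-12)
  one <- superpose_traces(traces[1L])
  expect_equal(one$vector, traces[[1L]]$vector)
  expect_error(superpose_traces(list()), "non-empty")
})

test_that("cleanup scores, thresholds and tie-breaks correctly", {
  set.seed(105)
  items <- random_items(4, 1024, letters[1:4])
  dict <- cleanup_dictionary(items)
  exact <- cleanup(items[[2L]]$vector, dict)
  expect_equal(exact$label, "b")
  expect_equal(exact$score, 1, tolerance = 1e-9)

  zero <- cleanup(numeric(1024), dict)
  expect_false(zero$matched)
  expect_true(is.na(zero$label))

  noisy <- items[[3L]]$vector + rnorm(1024, 0, 0.5 / sqrt(1024))
  expect_equal(cleanup(noisy, dict)$label, "c")

  # duplicate vector: dictionary order decides
  dup <- cleanup_dictionary(list(holo_item(items[[1L]]$vector, "first"),
                                 holo_item(items[[1L]]$vector, "second")))
  expect_equal(cleanup(items[[1L]]$vector, dup)$label, "first")
  expect_error(cleanup_dictionary(list()), "non-empty")
})

test_that("stored sequences complete from a partial cue", {
  set.seed(106)
  items <- random_items(5, 2048, paste0("e", 1:5))
  mem <- sequence_memory(items)
  dict <- cleanup_dictionary(items)

  expect_equal(recall_sequence(mem, items[1L], dict, 4),
               paste0("e", 2:5))
  expect_equal(recall_sequence(mem, items[1L], dict, 0), character(0))

  outsider <- random_items(1, 2048, "x")[[1L]]
  expect_warning(out <- recall_sequence(mem, list(outsider), dict, 4),
                 "truncated")
  expect_equal(out, character(0))
})

test_that("recall degrades gracefully as the trace fragment shrinks", {
  set.seed(107)
  pair <- random_items(2, 1024, c("cue", "target"))
  tr <- bind(pair[[1L]], pair[[2L]])
  keep_grid <- c(1, 0.5, 0.25, 0.1)
  mean_cor <- vapply(keep_grid, function(kf) {
    mean(vapply(1:100, function(r) {
      cosine_sim(unbind(degrade(tr, kf), pair[[1L]]), pair[[2L]]$vector)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) <= 0))     # monotone non-increasing
  expect_gt(min(mean_cor), 0)               # never catastrophic

  expect_identical(degrade(tr, 1)$vector, tr$vector)

  # quarter fragment at n = 4096 stays above the chance bound
  set.seed(108)
  big <- random_items(2, 4096, c("cue", "target"))
  frag <- degrade(bind(big[[1L]], big[[2L]]), 0.25)
  expect_gt(cosine_sim(unbind(frag, big[[1L]]), big[[2L]]$vector),
            3 / sqrt(4096))
})

test_that("capacity improves with dimension and degrades with load", {
  with_mem <- function(n, n_pairs, seed, f) {
    set.seed(seed)
    cues <- random_items(n_pairs, n, paste0("k", seq_len(n_pairs)))
    partners <- random_items(n_pairs, n, paste0("v", seq_len(n_pairs)))
    mem <- pair_memory(cues, partners)
    dict <- cleanup_dictionary(partners, accept_threshold = 0)
    mean(vapply(seq_len(n_pairs), function(i) {
      f(cleanup(unbind(mem, cues[[i]]), dict), paste0("v", i))
    }, numeric(1)))
  }
  score <- function(res, truth) res$score
  hit <- function(res, truth) as.numeric(identical(res$label, truth))

  # recall correlation drops with superposed pairs at fixed n (crosstalk
  # from k - 1 other bindings scales like sqrt(k))
  expect_gt(with_mem(512, 4, 109, score), with_mem(512, 24, 109, score))

  # retrieval accuracy rises with n at fixed load: the correct-item score
  # is ~1/sqrt(k) at any n, but competitor scores shrink like sqrt(k / n)
  acc <- function(n) mean(vapply(1:5, function(s) {
    with_mem(n, 10, 110 + s, hit)
  }, numeric(1)))
  expect_gt(acc(2048), acc(64))
})

test_that("spike trains map to usable holographic operands", {
  st <- spike_train(seq(0.01, 0.99, by = 0.014), 1)
  item <- spike_train_item(st, n = 512, label = "pattern")
  expect_equal(sqrt(sum(item$vector^2)), 1, tolerance = 1e-12)
  expect_setequal(unique(sign(item$vector)), c(-1, 1))

  set.seed(111)
  other <- random_items(1, 512, "key")[[1L]]
  tr <- bind(other, item)
  dict <- cleanup_dictionary(list(item, random_items(1, 512, "noise")[[1L]]))
  expect_equal(cleanup(unbind(tr, other), dict)$label, "pattern")
})
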