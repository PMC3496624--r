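test_that("interleaving is site-major with padded lanes, and inverts exactly", {
  r0 <- parsimony_state_vector(c(1L, 2L), edge_id = 1L)
  r1 <- parsimony_state_vector(c(4L, 8L), edge_id = 2L)
  blk <- build_inter_reference(list(r0, r1), W = 4L)
  # layout: [r0[0], r1[0], pad, pad, r0[1], r1[1], pad, pad]
  expect_identical(blk$interleaved_states,
                   c(1L, 4L, 15L, 15L, 2L, 8L, 15L, 15L))
  expect_identical(blk$valid_mask, c(TRUE, TRUE, FALSE, FALSE))
  # W = 1 is the identity
  blk1 <- build_inter_reference(list(r0), W = 1L)
  expect_identical(blk1$interleaved_states, r0$states)
  # round trip through the inverse
  with_seed(201, {
    refs <- lapply(1:5, function(i)
      rand_profile(sample(3:9, 1)) |> (\(p) { p$edge_id <- i; p })())
    blk2 <- build_inter_reference(refs, W = 8L)
    expect_identical(split_inter_reference(blk2), refs)
  })
  expect_error(build_inter_reference(list(r0), W = 0L), "W")
  expect_error(build_inter_reference(list(), W = 4L))
})

test_that("5-bit packing stores 6 elements per 32-bit word, low bits first", {
  # six state-A elements (code 1, cgap clear): independent bit oracle
  blk <- build_inter_reference(list(parsimony_state_vector(rep(1L, 6))), W = 1L)
  pk <- pack_references(blk)
  expect_identical(pk$elements_per_word, 6L)
  expect_identical(pk$bits_per_element, 5L)
  expect_identical(pk$words[1], as.integer(sum(2^(5 * (0:5)))))  # 34636833
  # six zero... lowest representable states with cgap: element = state | cgap<<4
  blkcg <- build_inter_reference(
    list(parsimony_state_vector(rep(1L, 6), cgap = rep(TRUE, 6))), W = 1L)
  expect_identical(pack_references(blkcg)$words[1],
                   as.integer(sum(17 * 2^(5 * (0:5)))))
})

test_that("pack/unpack round trips and segments are padded to 32-word multiples", {
  with_seed(202, {
    for (trial in 1:10) {
      W <- sample(c(1L, 4L, 8L), 1)
      refs <- lapply(seq_len(sample(seq_len(W), 1)), function(i) {
        p <- rand_profile(sample(5:60, 1)); p$edge_id <- i; p
      })
      blk <- build_inter_reference(refs, W = W)
      hs <- sample(0:3, 1); ts <- sample(0:3, 1)
      pk <- pack_references(blk, head_sites = hs, tail_sites = ts)
      expect_identical(pk$head_words %% 32L, 0L)
      expect_identical(pk$mid_words %% 32L, 0L)
      expect_identical(pk$tail_words %% 32L, 0L)
      # word count before padding: one word per head/tail element,
      # ceil(mid/6) for the packed middle
      expect_gte(pk$mid_words, ceiling(pk$mid_elems / 6))
      expect_lt(pk$mid_words - 32L, ceiling(pk$mid_elems / 6))
      ub <- unpack_references(pk)
      expect_identical(ub$interleaved_states, blk$interleaved_states)
      expect_identical(ub$interleaved_cgap, blk$interleaved_cgap)
      expect_identical(split_inter_reference(ub), refs)
    }
  })
  # malformed stream is rejected
  blk <- build_inter_reference(list(rand_profile(10)), W = 1L)
  pk <- pack_references(blk)
  pk$words <- pk$words[-1]
  expect_error(unpack_references(pk), "malformed")
})

test_that("a schedule from the published configuration has 12-column blocks", {
  sch <- plan_blocks(3060, 15360, 320, 4)
  expect_identical(sch$cols_per_block, 12L)
  # degenerate: huge budget covers everything in one square block
  sch1 <- plan_blocks(10, 1e9, 1, 4)
  expect_identical(sch1$square_head, c(0L, 10L))
  expect_length(sch1$rect_blocks, 0L)
  expect_error(plan_blocks(10, 3, 320, 4), "too small")
})

test_that("schedules partition the reference columns for random parameterisations", {
  with_seed(203, {
    for (trial in 1:200) {
      n <- sample(1:500, 1)
      sch <- plan_blocks(n, sample(50:20000, 1), sample(1:64, 1),
                         sample(c(2L, 4L), 1))
      rng <- papara:::schedule_ranges(sch)
      expect_identical(rng[1, 1], 0L)
      expect_identical(rng[nrow(rng), 2], n)
      if (nrow(rng) > 1)
        expect_identical(rng[-1, 1], rng[-nrow(rng), 2])  # contiguous, no overlap
      w <- rng[, 2] - rng[, 1]
      expect_true(all(w >= 1))
      if (length(sch$rect_blocks))
        expect_true(all(vapply(sch$rect_blocks, diff, integer(1)) ==
                          sch$cols_per_block))
    }
  })
})

test_that("batch scores equal per-lane sequential scores, any W and schedule", {
  with_seed(204, {
    for (trial in 1:15) {
      W <- sample(c(1L, 4L, 8L), 1)
      refs <- lapply(seq_len(sample(seq_len(W), 1)), function(i) {
        p <- rand_profile(sample(10:120, 1)); p$edge_id <- i; p
      })
      q <- rand_query(sample(5:40, 1))
      blk <- build_inter_reference(refs, W)
      seq_scores <- vapply(refs, score_alignment, integer(1), query = q)
      bs <- batch_score(blk, q)
      expect_identical(bs$scores[seq_along(refs)], seq_scores)
      # masked lanes report the sentinel
      if (length(refs) < W)
        expect_true(all(bs$scores[-seq_along(refs)] == bs$sentinel))
      # blocked evaluation is bit-exact for several block widths
      for (cols in c(3L, 5L, 12L, 50L)) {
        sch <- plan_blocks(blk$n_max, cols * W * 4L, W, 4L)
        expect_identical(sch$cols_per_block, cols)
        bb <- blocked_batch_score(blk, q, schedule = sch)
        expect_identical(bb$scores, bs$scores, info = paste("cols", cols))
      }
    }
  })
})

test_that("W identical references give W identical scores", {
  ref <- rand_profile(20)
  q <- rand_query(10)
  blk <- build_inter_reference(rep(list(ref), 8), W = 8L)
  bs <- batch_score(blk, q)
  expect_identical(bs$scores, rep(score_alignment(ref, q), 8))
})

test_that("16-bit and 32-bit modes agree without overflow; overflow lanes are promoted", {
  with_seed(205, {
    for (trial in 1:10) {
      refs <- lapply(1:4, function(i) rand_profile(sample(10:50, 1)))
      q <- rand_query(sample(5:30, 1))
      blk <- build_inter_reference(refs, W = 4L)
      b16 <- batch_score(blk, q, score_width = 16L)
      b32 <- batch_score(blk, q, score_width = 32L)
      expect_false(any(b16$overflow))
      expect_identical(b16$scores[blk$valid_mask], b32$scores[blk$valid_mask])
    }
  })
  # a score beyond the 16-bit sentinel: 6000 forced insertions cost 18000
  big_q <- structure(list(name = "big", states = rep(1L, 6000),
                          raw = strrep("A", 6000), qualities = NULL),
                     class = "papara_query")
  blk <- build_inter_reference(list(parsimony_state_vector(2L)), W = 1L)
  b16 <- batch_score(blk, q = big_q, score_width = 16L)
  expect_true(b16$overflow[1])
  expect_identical(b16$scores[1], score_alignment(parsimony_state_vector(2L), big_q))
})
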