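test_that("anchor cases: exact match scores 0, forced mismatch scores the penalty", {
  expect_identical(score_alignment(state_vector_from_seq("ACGT"),
                                   encoded_query("q", "ACGT")), 0L)
  expect_identical(score_alignment(state_vector_from_seq("A"),
                                   encoded_query("q", "C")), 3L)
  expect_identical(brute_force_score(state_vector_from_seq("A"),
                                     encoded_query("q", "A")), 0L)
  expect_identical(brute_force_score(state_vector_from_seq("A"),
                                     encoded_query("q", "C")), 3L)
  expect_error(score_alignment(parsimony_state_vector(integer(0)),
                               encoded_query("q", "A")))
})

test_that("an internal deletion beats mismatches when flanks differ (frozen oracle value)", {
  ref <- state_vector_from_seq("ACTGATTT")
  q <- encoded_query("q", "ACGA")
  expect_identical(brute_force_score(ref, q), 4L)  # frozen from the enumerator
  expect_identical(score_alignment(ref, q), 4L)
  a <- traceback(fill_matrix(ref, q), ref, q)
  expect_identical(a$path, c("diag", "diag", "del", "diag", "diag"))
  expect_identical(a$gapped_query, "AC-GA")
})

test_that("row kernel equals the exhaustive path enumerator on random small instances", {
  with_seed(101, {
    for (trial in 1:300) {
      n <- sample(1:8, 1); m <- sample(1:8, 1)
      ref <- rand_profile(n)
      q <- rand_query(m)
      expect_identical(score_alignment(ref, q), brute_force_score(ref, q),
                       info = sprintf("trial %d n=%d m=%d", trial, n, m))
    }
  })
})

test_that("full-matrix fill agrees with the row kernel (independent implementations)", {
  with_seed(102, {
    for (trial in 1:25) {
      n <- sample(5:40, 1); m <- sample(3:25, 1)
      ref <- rand_profile(n)
      q <- rand_query(m)
      mats <- fill_matrix(ref, q)
      expect_identical(mats$score, score_alignment(ref, q))
      expect_identical(mats$score, min(mats$S[-1, m + 1]))
    }
  })
})

test_that("narrowing a query character's state set never decreases the score", {
  # shrinking the set of bases a query position can match (e.g. N -> one
  # base) can only turn matches into mismatches, never the reverse
  with_seed(103, {
    for (trial in 1:30) {
      n <- sample(4:10, 1)
      ref <- rand_profile(n)
      m <- sample(2:min(6, n), 1)
      q <- rand_query(m, n_prob = 1)       # all positions fully ambiguous
      s0 <- score_alignment(ref, q)
      qq <- q
      j <- sample(m, 1)
      qq$states[j] <- sample(c(1L, 2L, 4L, 8L), 1)
      s1 <- score_alignment(ref, qq)
      expect_gte(s1, s0)
      # narrowing further (still a subset) keeps the ordering
      qq2 <- qq
      qq2$states[setdiff(seq_len(m), j)] <- sample(c(1L, 2L, 4L, 8L), m - 1L,
                                                   replace = TRUE)
      expect_gte(score_alignment(ref, qq2), s1)
    }
  })
})

test_that("CGAP calibrates cells exactly: zero-cost gap runs, penalised diagonals", {
  # ref AC with cgap on site 2; query AC
  ref <- parsimony_state_vector(c(1L, 2L), cgap = c(FALSE, TRUE))
  q <- encoded_query("q", "AC")
  mats <- fill_matrix(ref, q)
  # D into site 2 opens with the cgap pair (0,0): D[2,1] = S[1,1] + 0
  expect_identical(mats$D[3, 2], mats$S[2, 2] + 0L)
  # the diagonal at site 2 pays M + CG = 0 + 3
  expect_identical(mats$S[3, 3], mats$S[2, 2] + 0L + 3L)
  expect_identical(mats$score, 3L)
  # same instance without cgap scores 0
  ref0 <- parsimony_state_vector(c(1L, 2L))
  expect_identical(score_alignment(ref0, q), 0L)
  # a run across cgap sites is free: skip two flagged sites entirely
  refrun <- parsimony_state_vector(c(1L, 4L, 8L, 2L),
                                   cgap = c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(score_alignment(refrun, encoded_query("q", "AC")), 0L)
})

test_that("traceback reproduces the score and respects the free-flank convention", {
  # all-match: m diagonal moves, gapped query equals the read
  ref <- state_vector_from_seq("TTACGTTT")
  q <- encoded_query("q", "ACGT")
  a <- traceback(fill_matrix(ref, q), ref, q)
  expect_identical(a$score, 0L)
  expect_identical(a$path, rep("diag", 4))
  expect_identical(a$gapped_query, "ACGT")
  expect_identical(unname(a$ref_span), c(2L, 6L))
  with_seed(104, {
    for (trial in 1:40) {
      refr <- rand_profile(sample(2:12, 1))
      qr <- rand_query(sample(1:8, 1))
      mats <- fill_matrix(refr, qr)
      ar <- traceback(mats, refr, qr)
      expect_identical(ar$score, mats$score)
      # path cost re-accounted independently
      expect_identical(
        papara:::alignment_path_cost(ar$path, refr, qr$states, scoring_params(),
                                     start_col = ar$ref_span[["start"]]),
        ar$score)
      # no deletions outside the spanned interval
      expect_false(ar$path[1] == "del")
      expect_false(ar$path[length(ar$path)] == "del")
      # query fully consumed
      expect_identical(sum(ar$path != "del"), length(qr$states))
    }
  })
})

test_that("insertions are kept as lowercase by default and can be dropped", {
  ref <- state_vector_from_seq("AATT")
  q <- encoded_query("q", "AAGTT")  # G must be inserted
  mats <- fill_matrix(ref, q)
  a <- traceback(mats, ref, q)
  expect_identical(a$gapped_query, "AAgTT")
  a2 <- traceback(mats, ref, q, keep_insertions = FALSE)
  expect_identical(a2$gapped_query, "AATT")
  expect_identical(a$score, 3L)
})

test_that("the score ignores mismatching reference columns appended beyond the alignment", {
  with_seed(105, {
    for (trial in 1:20) {
      n <- sample(3:8, 1); m <- sample(1:5, 1)
      ref <- parsimony_state_vector(sample(c(1L, 2L), n, replace = TRUE))
      q <- rand_query(m, n_prob = 0)
      q$states <- sample(c(1L, 2L), m, replace = TRUE)  # only A/C
      s0 <- score_alignment(ref, q)
      # flank columns G-only: never match, never flagged
      ext <- parsimony_state_vector(c(rep(4L, 3), ref$states, rep(4L, 3)))
      expect_identical(score_alignment(ext, q), s0)
    }
  })
})
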