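# Portable re-expression of the throughput-oriented designs: W references
# interleaved site-major (inter-reference layout), 5-bit element packing
# (6 per 32-bit word, segments padded to multiples of 32 words), W-lane
# batch scoring, and a blocked column schedule.  Everything is required to
# be bit-exact against the sequential kernel.

PAD_STATE <- 15L  # match-all; behaves as a free flank given the per-lane
                  # length restriction in the batch kernel

#' Interleave up to W reference profiles site-major
#'
#' Entry `i*W + k` (0-based) of the interleaved vector is site `i` of
#' reference `k`: all index-i elements are grouped together, and group
#' i+1 follows group i.  Shorter references are padded with neutral
#' match-all sites (state 15, CGAP clear); absent lanes are masked and can
#' never win a best-score comparison.
#'
#' @param refs List of `papara_profile` (length 1..W).
#' @param W Group width (number of lanes).
#' @return Object of class `papara_block`: `W`, `n_max`,
#'   `interleaved_states`, `interleaved_cgap`, `valid_mask`,
#'   `lane_lengths` (true per-lane reference lengths), `edge_ids`.
#' @export
build_inter_reference <- function(refs, W) {
  W <- as.integer(W)
  if (W < 1L) stop("W must be >= 1")
  if (length(refs) < 1L || length(refs) > W)
    stop("need between 1 and W references")
  refs <- lapply(refs, as_profile)
  lens <- vapply(refs, function(r) length(r$states), integer(1))
  n_max <- max(lens)
  st <- matrix(PAD_STATE, nrow = W, ncol = n_max)
  cg <- matrix(FALSE, nrow = W, ncol = n_max)
  for (k in seq_along(refs)) {
    st[k, seq_len(lens[k])] <- refs[[k]]$states
    cg[k, seq_len(lens[k])] <- refs[[k]]$cgap
  }
  structure(list(
    W = W, n_max = n_max,
    interleaved_states = as.integer(st),  # column-major = site-major groups
    interleaved_cgap = as.logical(cg),
    valid_mask = seq_len(W) <= length(refs),
    lane_lengths = c(lens, integer(W - length(refs))),
    edge_ids = c(vapply(refs, function(r) r$edge_id, integer(1)),
                 rep(NA_integer_, W - length(refs)))),
    class = "papara_block")
}

#' De-interleave an inter-reference block back into profiles
#'
#' Exact inverse of [build_inter_reference()] for the valid lanes.
#'
#' @param block A `papara_block`.
#' @return List of `papara_profile`, one per valid lane.
#' @export
split_inter_reference <- function(block) {
  st <- matrix(block$interleaved_states, nrow = block$W)
  cg <- matrix(block$interleaved_cgap, nrow = block$W)
  lapply(which(block$valid_mask), function(k) {
    len <- block$lane_lengths[k]
    parsimony_state_vector(st[k, seq_len(len)], cg[k, seq_len(len)],
                           edge_id = block$edge_ids[k])
  })
}

pad_to_32_words <- function(w) {
  pad <- (32L - length(w) %% 32L) %% 32L
  c(w, integer(pad))
}

#' Pack an inter-reference block 5 bits per element
#'
#' Each element needs 5 bits (4 state bits plus the CGAP bit), so one
#' 32-bit word stores 6 elements; element `t` of a word occupies bits
#' `5t .. 5t+4`, low bits first.  An optional uncompressed head and tail
#' (one element per word) bracket the packed middle — mirroring the fact
#' that square boundary blocks of the schedule are left uncompressed —
#' and all three segments are padded to a multiple of 32 words.
#'
#' @param block A `papara_block`.
#' @param head_sites,tail_sites Number of leading/trailing reference
#'   columns stored uncompressed (defaults 0).
#' @param schedule Optional `papara_schedule`; when given, the square
#'   head/tail column counts override `head_sites`/`tail_sites`.
#' @return Object of class `papara_packed` holding the word vector,
#'   segment geometry and the block metadata needed to invert.
#' @export
pack_references <- function(block, head_sites = 0L, tail_sites = 0L,
                            schedule = NULL) {
  stopifnot(inherits(block, "papara_block"))
  if (!is.null(schedule)) {
    head_sites <- schedule$square_head[2] - schedule$square_head[1]
    tail_sites <- schedule$square_tail[2] - schedule$square_tail[1]
  }
  head_sites <- as.integer(head_sites); tail_sites <- as.integer(tail_sites)
  if (head_sites < 0L || tail_sites < 0L ||
      head_sites + tail_sites > block$n_max)
    stop("head/tail segments exceed the block length")
  if (any(block$interleaved_states >= 16L | block$interleaved_states < 0L))
    stop("state codes must be < 16 to pack in 5 bits")
  elems <- bitwOr(block$interleaved_states,
                  bitwShiftL(as.integer(block$interleaved_cgap), 4L))
  W <- block$W
  nh <- head_sites * W; nt <- tail_sites * W
  nm <- length(elems) - nh - nt
  head_e <- elems[seq_len(nh)]
  mid_e <- elems[nh + seq_len(nm)]
  tail_e <- elems[nh + nm + seq_len(nt)]
  pack6 <- function(e) {
    if (!length(e)) return(integer(0))
    pad <- (6L - length(e) %% 6L) %% 6L
    mat <- matrix(c(e, integer(pad)), nrow = 6L)
    as.integer(colSums(mat * 2^(5 * (0:5))))
  }
  head_w <- pad_to_32_words(head_e)
  mid_w <- pad_to_32_words(pack6(mid_e))
  tail_w <- pad_to_32_words(tail_e)
  structure(list(
    words = c(head_w, mid_w, tail_w),
    elements_per_word = 6L, bits_per_element = 5L,
    head_words = length(head_w), mid_words = length(mid_w),
    tail_words = length(tail_w),
    head_elems = nh, mid_elems = nm, tail_elems = nt,
    W = W, n_max = block$n_max,
    valid_mask = block$valid_mask, lane_lengths = block$lane_lengths,
    edge_ids = block$edge_ids),
    class = "papara_packed")
}

#' Unpack a 5-bit packed reference stream
#'
#' Exact inverse of [pack_references()] on the covered sites.
#'
#' @param stream A `papara_packed`.
#' @return The reconstructed `papara_block`.
#' @export
unpack_references <- function(stream) {
  stopifnot(inherits(stream, "papara_packed"))
  with(stream, {
    if (length(words) != head_words + mid_words + tail_words)
      stop("malformed stream: segment lengths do not sum to the word count")
    if (head_words %% 32L || mid_words %% 32L || tail_words %% 32L)
      stop("malformed stream: segments must be multiples of 32 words")
    head_e <- words[seq_len(head_words)][seq_len(head_elems)]
    midw <- words[head_words + seq_len(mid_words)]
    mid_all <- as.integer(bitwAnd(
      bitwShiftR(rep(midw, each = 6L), 5L * rep(0:5, length(midw))), 31L))
    mid_e <- mid_all[seq_len(mid_elems)]
    tail_e <- words[head_words + mid_words + seq_len(tail_words)][seq_len(tail_elems)]
    elems <- c(head_e, mid_e, tail_e)
    if (length(elems) != n_max * W)
      stop("malformed stream: covered elements do not match the block size")
    structure(list(
      W = W, n_max = n_max,
      interleaved_states = bitwAnd(elems, 15L),
      interleaved_cgap = bitwAnd(elems, 16L) != 0L,
      valid_mask = valid_mask, lane_lengths = lane_lengths,
      edge_ids = edge_ids),
      class = "papara_block")
  })
}

#' Write a packed stream as little-endian 32-bit words
#'
#' Binary dump for cross-implementation testing: an 8-word header
#' (magic `0x50615061`, W, n_max, head/mid/tail word counts, head/tail
#' site counts) followed by the word vector.
#'
#' @param stream A `papara_packed`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_packed_stream <- function(stream, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(0x50615061L, stream$W, stream$n_max, stream$head_words,
           stream$mid_words, stream$tail_words,
           stream$head_elems %/% stream$W, stream$tail_elems %/% stream$W)
  writeBin(c(hdr, stream$words), con, size = 4L, endian = "little")
  invisible(path)
}

#' Plan the blocked column schedule
#'
#' Splits the reference columns into a square head computed in the plain
#' buffer, fixed-width rectangular blocks, and a square tail, so that the
#' rectangular blocks never need boundary conditionals.  The rectangular
#' width is `floor(buffer_budget_bytes / (group_count * bytes_per_cell))`;
#' with the published configuration (15360 bytes, 320 references, 4-byte
#' cells) this yields 12 columns per block.
#'
#' @param n Number of reference columns.
#' @param buffer_budget_bytes Fast-buffer budget in bytes.
#' @param group_count Number of references sharing the buffer.
#' @param bytes_per_cell Bytes per DP cell (score width / 8).
#' @return Object of class `papara_schedule`: `square_head`,
#'   `rect_blocks` (list of 0-based half-open column ranges),
#'   `square_tail`, `cols_per_block`, `n`.  The ranges partition `[0, n)`.
#' @export
plan_blocks <- function(n, buffer_budget_bytes, group_count, bytes_per_cell) {
  n <- as.integer(n)
  stopifnot(n >= 1L, buffer_budget_bytes >= 1, group_count >= 1L,
            bytes_per_cell >= 1L)
  cols <- as.integer(buffer_budget_bytes %/% (group_count * bytes_per_cell))
  if (cols < 1L)
    stop("buffer budget too small: zero columns per block")
  head <- min(n, cols)
  rest <- n - head
  k <- rest %/% cols
  tail <- rest - k * cols
  rect <- lapply(seq_len(k) - 1L, function(b) c(head + b * cols, head + (b + 1L) * cols))
  structure(list(square_head = c(0L, head), rect_blocks = rect,
                 square_tail = c(n - tail, n), cols_per_block = cols, n = n),
            class = "papara_schedule")
}

# All non-empty column ranges of a schedule, in left-to-right order.
schedule_ranges <- function(schedule) {
  rng <- c(list(schedule$square_head), schedule$rect_blocks,
           list(schedule$square_tail))
  rng <- Filter(function(r) r[2] > r[1], rng)
  do.call(rbind, rng)
}

batch_call <- function(block, query, params, ranges, score_width) {
  q <- as_query_states(query)
  if (length(q) < 1L) stop("empty query")
  stopifnot(score_width %in% c(16L, 32L))
  res <- cpp_batch_score(block$interleaved_states, block$interleaved_cgap,
                         block$W, block$n_max, block$lane_lengths,
                         block$valid_mask, q,
                         params$mismatch, params$cgap_penalty,
                         params$gap_open_extend[1], params$gap_open_extend[2],
                         params$gap_open_extend_cgap[1],
                         params$gap_open_extend_cgap[2],
                         params$insertion_cost,
                         as.integer(ranges[, 1]), as.integer(ranges[, 2]),
                         as.integer(score_width))
  if (score_width == 16L && any(res$overflow)) {
    # detect-and-promote: lanes that touched the 16-bit sentinel are
    # recomputed at 32 bits
    res32 <- cpp_batch_score(block$interleaved_states, block$interleaved_cgap,
                             block$W, block$n_max, block$lane_lengths,
                             block$valid_mask, q,
                             params$mismatch, params$cgap_penalty,
                             params$gap_open_extend[1], params$gap_open_extend[2],
                             params$gap_open_extend_cgap[1],
                             params$gap_open_extend_cgap[2],
                             params$insertion_cost,
                             as.integer(ranges[, 1]), as.integer(ranges[, 2]),
                             32L)
    res$scores[res$overflow] <- res32$scores[res$overflow]
    res$sentinel <- res32$sentinel
    res$scores[!block$valid_mask] <- res32$sentinel
  }
  structure(list(scores = res$scores, overflow = res$overflow,
                 score_width = as.integer(score_width),
                 sentinel = res$sentinel, edge_ids = block$edge_ids,
                 valid_mask = block$valid_mask),
            class = "papara_batch_scores")
}

#' Score one query against all lanes of an inter-reference block
#'
#' Evaluates the recurrence across all W lanes simultaneously with
#' single-row, W-strided storage; per-lane results equal
#' [score_alignment()] bit-exactly.  In 16-bit mode a lane whose values
#' reach the 16-bit sentinel is flagged and transparently recomputed at
#' 32 bits.  Masked padding lanes report the infinity sentinel.
#'
#' @param block A `papara_block`.
#' @param query A `papara_query` or integer state vector.
#' @param params A `papara_params`.
#' @param score_width 16 or 32 (bits per DP cell).
#' @return Object of class `papara_batch_scores`: `scores` (length W),
#'   `overflow`, `score_width`, `sentinel`, `edge_ids`, `valid_mask`.
#' @export
batch_score <- function(block, query, params = scoring_params(),
                        score_width = 32L) {
  stopifnot(inherits(block, "papara_block"))
  batch_call(block, query, params,
             ranges = matrix(c(0L, block$n_max), nrow = 1), score_width)
}

#' Blocked evaluation of a batch score
#'
#' Computes the matrix block-by-block in left-to-right schedule order,
#' carrying the boundary columns between blocks; results are bit-exactly
#' identical to [batch_score()] for every schedule.
#'
#' @inheritParams batch_score
#' @param schedule A `papara_schedule` covering the block's columns.
#' @return A `papara_batch_scores`.
#' @export
blocked_batch_score <- function(block, query, params = scoring_params(),
                                schedule, score_width = 32L) {
  stopifnot(inherits(block, "papara_block"), inherits(schedule, "papara_schedule"))
  if (schedule$n != block$n_max)
    stop("schedule covers ", schedule$n, " columns but the block has ",
         block$n_max)
  batch_call(block, query, params, ranges = schedule_ranges(schedule),
             score_width)
}
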