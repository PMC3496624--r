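# Sequential alignment kernel: semi-global scoring of a read against a
# per-edge ancestral profile, with site-calibrated gap penalties driven by
# the CGAP flag.  Lower scores are better.
#
# Boundary convention (semi-global / "glocal"): the query is consumed in
# full, both reference flanks are free — S[i,0] = 0 for every i and the
# final score is the minimum over the last row.  This is the natural
# convention for placing short reads on long reference profiles.

INF32 <- .Machine$integer.max %/% 2L

as_query_states <- function(query) {
  if (inherits(query, "papara_query")) return(query$states)
  if (is.numeric(query)) return(as.integer(query))
  stop("query must be a papara_query or an integer state vector")
}

as_profile <- function(ref) {
  if (inherits(ref, "papara_profile")) return(ref)
  if (is.numeric(ref)) return(parsimony_state_vector(ref))
  stop("ref must be a papara_profile or an integer state vector")
}

site_penalties <- function(ref, params) {
  cg <- ref$cgap
  list(go = ifelse(cg, params$gap_open_extend_cgap[1], params$gap_open_extend[1]),
       ge = ifelse(cg, params$gap_open_extend_cgap[2], params$gap_open_extend[2]),
       cgi = ifelse(cg, params$cgap_penalty, 0L))
}

#' Score one query against one ancestral state profile
#'
#' Row-by-row evaluation of the site-calibrated recurrence with a single
#' retained row.  At site `i`: `CG_i = cgap_penalty` if the CGAP flag is
#' set, else 0; the gap open/extend pair is swapped for the CGAP pair at
#' flagged sites; a diagonal move costs `M_{i,j} + CG_i` where `M` is 0
#' when the state sets intersect (bitwise AND non-zero) and `mismatch`
#' otherwise; an insertion (query character consumed, reference held)
#' costs `insertion_cost`, linear.
#'
#' @param ref A `papara_profile` (or integer state vector).
#' @param query A `papara_query` (or integer state vector).
#' @param params A `papara_params`.
#' @return Integer alignment score (lower is better).
#' @export
score_alignment <- function(ref, query, params = scoring_params()) {
  ref <- as_profile(ref)
  q <- as_query_states(query)
  if (length(ref$states) < 1L || length(q) < 1L)
    stop("reference and query must be non-empty")
  cpp_score_alignment(ref$states, ref$cgap, q,
                      params$mismatch, params$cgap_penalty,
                      params$gap_open_extend[1], params$gap_open_extend[2],
                      params$gap_open_extend_cgap[1], params$gap_open_extend_cgap[2],
                      params$insertion_cost)
}

#' Fill the full scoring matrices
#'
#' Retains all (n+1) x (m+1) cells of `S` and `D` for traceback; the
#' minimum of the last row equals [score_alignment()].  This is a
#' deliberately independent pure-R evaluation of the same recurrence, so
#' it also serves as a cross-check of the row-wise kernel.
#'
#' @inheritParams score_alignment
#' @return List with integer matrices `S` and `D` (rows = reference
#'   columns 0..n, cols = query positions 0..m) and `score`.
#' @export
fill_matrix <- function(ref, query, params = scoring_params()) {
  ref <- as_profile(ref)
  q <- as_query_states(query)
  n <- length(ref$states); m <- length(q)
  if (n < 1L || m < 1L) stop("reference and query must be non-empty")
  pen <- site_penalties(ref, params)
  mm <- params$mismatch; ins <- params$insertion_cost
  S <- matrix(0L, n + 1L, m + 1L)   # S[i+1, j+1] = S^{i,j}
  D <- matrix(INF32, n + 1L, m + 1L)
  S[1, ] <- (0:m) * ins
  S[, 1] <- 0L
  for (j in seq_len(m)) {
    qs <- q[j]
    for (i in seq_len(n)) {
      d <- min(S[i, j + 1L] + pen$go[i], D[i, j + 1L] + pen$ge[i], INF32)
      match <- if (bitwAnd(ref$states[i], qs) != 0L) 0L else mm
      s <- min(S[i, j] + match + pen$cgi[i], d, S[i + 1L, j] + ins)
      D[i + 1L, j + 1L] <- d
      S[i + 1L, j + 1L] <- s
    }
  }
  list(S = S, D = D, score = min(S[-1, m + 1L]))
}

#' Backtrack the best semi-global alignment
#'
#' Starts at the minimizing cell of the last row (leftmost on ties) and
#' walks moves whose local recomputation reproduces the stored value;
#' tie-break order is diagonal, then reference gap (D), then insertion
#' (I).  The emitted path cost always equals the DP score (asserted).
#'
#' @param mats Matrices from [fill_matrix()].
#' @inheritParams score_alignment
#' @param keep_insertions Keep query characters consumed by insertion
#'   moves in the gapped query, as lowercase (default); otherwise drop
#'   them.
#' @return Object of class `papara_alignment`: `score`, `path` (character
#'   vector over `diag`/`del`/`ins`, left to right), `gapped_query`,
#'   `ref_span` (0-based half-open reference interval spanned),
#'   `end_column` (half-open end of that interval).
#' @export
traceback <- function(mats, ref, query, params = scoring_params(),
                      keep_insertions = TRUE) {
  ref <- as_profile(ref)
  q <- as_query_states(query)
  raw <- if (inherits(query, "papara_query")) query$raw else
    paste(decode_state(q), collapse = "")
  qchars <- strsplit(raw, "", fixed = TRUE)[[1]]
  S <- mats$S; D <- mats$D
  n <- length(ref$states); m <- length(q)
  pen <- site_penalties(ref, params)
  mm <- params$mismatch; ins <- params$insertion_cost

  i <- which.min(S[-1, m + 1L])  # leftmost minimum of the last row
  score <- S[i + 1L, m + 1L]
  j <- m
  path <- character(0); chars <- character(0)
  mode <- "S"
  end_column <- i
  while (j > 0L || mode == "D") {
    if (mode == "S") {
      match <- if (i >= 1L && bitwAnd(ref$states[i], q[j]) != 0L) 0L else mm
      if (i >= 1L && S[i + 1L, j + 1L] == S[i, j] + match + pen$cgi[i]) {
        path <- c(path, "diag"); chars <- c(chars, toupper(qchars[j]))
        i <- i - 1L; j <- j - 1L
      } else if (S[i + 1L, j + 1L] == D[i + 1L, j + 1L]) {
        mode <- "D"
      } else if (S[i + 1L, j + 1L] == S[i + 1L, j] + ins) {
        path <- c(path, "ins")
        chars <- c(chars, if (keep_insertions) tolower(qchars[j]) else NULL)
        j <- j - 1L
      } else stop("internal: inconsistent matrices at S cell (", i, ",", j, ")")
    } else {
      if (D[i + 1L, j + 1L] == S[i, j + 1L] + pen$go[i]) {
        path <- c(path, "del"); chars <- c(chars, "-")
        i <- i - 1L; mode <- "S"
      } else if (D[i + 1L, j + 1L] == D[i, j + 1L] + pen$ge[i]) {
        path <- c(path, "del"); chars <- c(chars, "-")
        i <- i - 1L
      } else stop("internal: inconsistent matrices at D cell (", i, ",", j, ")")
    }
  }
  path <- rev(path); chars <- rev(chars)

  # verify: the walked path must cost exactly the DP score
  stopifnot(alignment_path_cost(path, ref, q, params, start_col = i) == score)

  structure(list(score = score, path = path,
                 gapped_query = paste(chars, collapse = ""),
                 ref_span = c(start = i, end = end_column),
                 end_column = end_column),
            class = "papara_alignment")
}

# Cost of an explicit move path starting at 0-based reference column
# start_col; used as the traceback consistency assertion and in tests.
alignment_path_cost <- function(path, ref, qstates, params, start_col = 0L) {
  ref <- as_profile(ref)
  pen <- site_penalties(ref, params)
  i <- start_col; j <- 0L
  cost <- 0L; in_gap <- FALSE
  for (mv in path) {
    if (mv == "diag") {
      i <- i + 1L; j <- j + 1L
      match <- if (bitwAnd(ref$states[i], qstates[j]) != 0L) 0L else params$mismatch
      cost <- cost + match + pen$cgi[i]
      in_gap <- FALSE
    } else if (mv == "del") {
      i <- i + 1L
      cost <- cost + if (in_gap) pen$ge[i] else pen$go[i]
      in_gap <- TRUE
    } else if (mv == "ins") {
      j <- j + 1L
      cost <- cost + params$insertion_cost
      in_gap <- FALSE
    } else stop("unknown move: ", mv)
  }
  cost
}

#' Exhaustive oracle for the semi-global score
#'
#' Enumerates every alignment of the move set directly, without the DP
#' recurrence: choose which query positions are matched diagonally and to
#' which strictly increasing reference columns; all other query positions
#' are insertions; each maximal block of skipped reference columns between
#' consecutive matches is one gap run costing `GPOE` at its first site
#' plus `GPE` at each further site.  Because `GPOE_i >= GPE_i` at every
#' site, splitting a run is never cheaper, so this family contains an
#' optimal path.  Exponential in problem size; guarded to tiny inputs.
#'
#' @inheritParams score_alignment
#' @param max_cells Guard: `n * m` must not exceed this.
#' @return Integer minimum alignment cost.
#' @export
brute_force_score <- function(ref, query, params = scoring_params(),
                              max_cells = 150L) {
  ref <- as_profile(ref)
  q <- as_query_states(query)
  n <- length(ref$states); m <- length(q)
  if (n < 1L || m < 1L) stop("reference and query must be non-empty")
  if (n * m > max_cells)
    stop("brute_force_score is exponential; n*m = ", n * m,
         " exceeds the guard of ", max_cells)
  pen <- site_penalties(ref, params)
  mm <- params$mismatch; ins <- params$insertion_cost
  # diagonal cost of pairing reference column i with query position j
  inter <- outer(ref$states, q, bitwAnd) != 0L
  diagc <- ifelse(inter, 0L, mm) + pen$cgi
  cumge <- cumsum(pen$ge)
  gap_run <- function(c1, c2) {  # cost of skipping columns c1+1 .. c2-1
    w <- c2 - c1 - 1L
    ifelse(w <= 0L, 0L, pen$go[c1 + 1L] + cumge[c2 - 1L] - cumge[c1 + 1L])
  }
  best <- m * ins  # no matches: all insertions
  for (k in seq_len(min(n, m))) {
    qsets <- utils::combn(m, k)
    csets <- utils::combn(n, k)
    nc <- ncol(csets)
    gapsum <- if (k >= 2L) {
      colSums(matrix(gap_run(csets[-k, , drop = FALSE], csets[-1, , drop = FALSE]),
                     nrow = k - 1L))
    } else rep(0L, nc)
    for (qi in seq_len(ncol(qsets))) {
      js <- qsets[, qi]
      dsum <- colSums(matrix(diagc[cbind(as.vector(csets), rep(js, nc))],
                             nrow = k))
      tot <- (m - k) * ins + dsum + gapsum
      best <- min(best, tot)
    }
  }
  as.integer(best)
}
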