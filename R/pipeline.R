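# Two-phase placement pipeline.
#
# Scoring phase: all R*Q pairwise DPs, executed over a work queue of
# W-sized reference blocks; only the per-query best (lowest) score and its
# edge are retained.  Alignment phase: exactly Q full-matrix fills plus
# tracebacks, one per query, for the winning pairs only.  Results are
# provably independent of W, of queue consumption order and of how many
# workers would consume the queue (exactly-once delivery, order-free min
# reduction with a deterministic tie-break on the lowest edge id).

#' Scoring phase: best edge per query over a W-block work queue
#'
#' @param vectors List of `papara_profile`, one per reference tree edge.
#' @param queries List of `papara_query`.
#' @param params A `papara_params`.
#' @param W Work-group width (references per block).
#' @param score_width 16 or 32 bit DP cells (16-bit lanes that overflow
#'   are transparently promoted).
#' @param blocked Use the blocked column schedule (default) or a single
#'   full-width block.
#' @param block_budget Fast-buffer budget in bytes handed to
#'   [plan_blocks()].
#' @param queue_order Optional permutation of the block queue, to exercise
#'   order independence; results are identical for any permutation.
#' @return A data.frame of class `papara_placements` with columns
#'   `query_name`, `best_edge`, `best_score`.
#' @export
scoring_phase <- function(vectors, queries, params = scoring_params(),
                          W = 8L, score_width = 16L, blocked = TRUE,
                          block_budget = 15360L, queue_order = NULL) {
  R <- length(vectors); Q <- length(queries)
  if (R < 1L || Q < 1L) stop("need at least one reference vector and one query")
  W <- as.integer(W)
  block_ids <- split(seq_len(R), ceiling(seq_len(R) / W))
  nb <- length(block_ids)
  queue <- if (is.null(queue_order)) seq_len(nb) else as.integer(queue_order)
  if (!identical(sort(queue), seq_len(nb)))
    stop("queue_order must be a permutation of the ", nb, " blocks")

  best_score <- rep(INF32, Q)
  best_edge <- rep(NA_integer_, Q)
  for (b in queue) {
    idx <- block_ids[[b]]
    block <- build_inter_reference(vectors[idx], W)
    schedule <- if (blocked) {
      plan_blocks(block$n_max, block_budget, W, score_width %/% 8L)
    } else NULL
    for (qi in seq_len(Q)) {
      bs <- if (blocked) {
        blocked_batch_score(block, queries[[qi]], params, schedule, score_width)
      } else {
        batch_score(block, queries[[qi]], params, score_width)
      }
      count_score_dp(sum(block$valid_mask))
      for (k in which(block$valid_mask)) {
        s <- bs$scores[k]; e <- block$edge_ids[k]
        if (s < best_score[qi] ||
            (s == best_score[qi] && !is.na(best_edge[qi]) && e < best_edge[qi])) {
          best_score[qi] <- s
          best_edge[qi] <- e
        }
      }
    }
  }
  structure(data.frame(
    query_name = vapply(queries, function(q) q$name, character(1)),
    best_edge = best_edge, best_score = best_score,
    stringsAsFactors = FALSE),
    class = c("papara_placements", "data.frame"))
}

#' Alignment phase: backtrack the winning pair of each query
#'
#' Recomputes the full matrix for each query's best edge only (Q DPs in
#' total), asserts the recomputed score matches the scoring phase, and
#' backtracks the alignment.
#'
#' @param records Output of [scoring_phase()].
#' @param vectors,queries,params As in [scoring_phase()].
#' @param keep_insertions Passed to [traceback()].
#' @return The `records` data.frame with a list-column `alignment` of
#'   `papara_alignment` objects.
#' @export
alignment_phase <- function(records, vectors, queries,
                            params = scoring_params(),
                            keep_insertions = TRUE) {
  stopifnot(inherits(records, "papara_placements"))
  alns <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    ref <- vectors[[records$best_edge[r]]]
    query <- queries[[r]]
    mats <- fill_matrix(ref, query, params)
    count_traceback()
    if (mats$score != records$best_score[r])
      stop("internal: alignment-phase score ", mats$score,
           " disagrees with scoring phase ", records$best_score[r],
           " for query ", records$query_name[r])
    alns[[r]] <- traceback(mats, ref, query, params,
                           keep_insertions = keep_insertions)
  }
  records$alignment <- alns
  records
}

#' Place reads on a reference tree (both phases)
#'
#' @param msa A `papara_msa`.
#' @param tree The matching `papara_tree`.
#' @param queries List of `papara_query`.
#' @param params A `papara_params`.
#' @param cgap_rule CGAP rule, see [ancestral_states_for_edge()].
#' @param ... Passed to [scoring_phase()].
#' @return A `papara_placements` data.frame with alignments attached.
#' @export
place_reads <- function(msa, tree, queries, params = scoring_params(),
                        cgap_rule = "parsimonious", ...) {
  vectors <- all_edge_state_vectors(tree, msa, params, cgap_rule = cgap_rule)
  records <- scoring_phase(vectors, queries, params, ...)
  alignment_phase(records, vectors, queries, params)
}

cli_usage <- paste(
  "usage: papara --ref-msa FILE --ref-tree FILE --queries FILE [--fastq]",
  "              [--W INT=8] [--score-width 16|32=16] [--blocked|--no-blocked]",
  "              [--block-budget BYTES=15360] [--seed INT] [--out PREFIX=papara]",
  sep = "\n")

parse_cli_args <- function(args) {
  opt <- list(ref_msa = NULL, ref_tree = NULL, queries = NULL,
              fastq = FALSE, W = 8L, score_width = 16L, blocked = TRUE,
              block_budget = 15360L, seed = NULL, out = "papara")
  i <- 1L
  need <- function() {
    if (i + 1L > length(args)) stop("missing value for ", args[i])
    args[i + 1L]
  }
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--ref-msa") { opt$ref_msa <- need(); i <- i + 2L }
    else if (a == "--ref-tree") { opt$ref_tree <- need(); i <- i + 2L }
    else if (a == "--queries") { opt$queries <- need(); i <- i + 2L }
    else if (a == "--fastq") { opt$fastq <- TRUE; i <- i + 1L }
    else if (a == "--W") { opt$W <- as.integer(need()); i <- i + 2L }
    else if (a == "--score-width") { opt$score_width <- as.integer(need()); i <- i + 2L }
    else if (a == "--blocked") { opt$blocked <- TRUE; i <- i + 1L }
    else if (a == "--no-blocked") { opt$blocked <- FALSE; i <- i + 1L }
    else if (a == "--block-budget") { opt$block_budget <- as.integer(need()); i <- i + 2L }
    else if (a == "--seed") { opt$seed <- as.integer(need()); i <- i + 2L }
    else if (a == "--out") { opt$out <- need(); i <- i + 2L }
    else stop("unknown argument: ", a, "\n", cli_usage)
  }
  for (f in c("ref_msa", "ref_tree", "queries"))
    if (is.null(opt[[f]])) stop("missing required --", gsub("_", "-", f),
                                "\n", cli_usage)
  if (!opt$score_width %in% c(16L, 32L)) stop("--score-width must be 16 or 32")
  opt
}

#' Command-line entry point
#'
#' Reads the reference alignment, tree and queries, runs both phases and
#' writes `PREFIX.placements.tsv` (query, edge_id, score) and
#' `PREFIX.alignment.fasta` (gapped queries, insertions lowercase).  A
#' run log (R, Q, W, cell count, elapsed time) goes to stderr.  The
#' placements are independent of `--W`, of the queue order and of the
#' seed; `--seed` shuffles the block queue to exercise exactly that
#' order-independence, so outputs are byte-identical across seeds.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 on success, 1 on any input error
#'   (message on stderr).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  t0 <- proc.time()[["elapsed"]]
  status <- tryCatch({
    opt <- parse_cli_args(args)
    inputs <- read_reference_inputs(opt$ref_msa, opt$ref_tree)
    queries <- read_queries(opt$queries,
                            format = if (opt$fastq) "fastq" else "fasta")
    vectors <- all_edge_state_vectors(inputs$tree, inputs$msa)
    R <- length(vectors); Q <- length(queries)
    queue_order <- NULL
    if (!is.null(opt$seed)) {
      nb <- ceiling(R / opt$W)
      queue_order <- with_seed(opt$seed, sample.int(nb))
    }
    records <- scoring_phase(vectors, queries, W = opt$W,
                             score_width = opt$score_width,
                             blocked = opt$blocked,
                             block_budget = opt$block_budget,
                             queue_order = queue_order)
    records <- alignment_phase(records, vectors, queries)

    tsv <- data.frame(query = records$query_name,
                      edge_id = records$best_edge,
                      score = records$best_score)
    utils::write.table(tsv, paste0(opt$out, ".placements.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gq <- lapply(records$alignment, function(a) a$gapped_query)
    names(gq) <- records$query_name
    write_fasta(gq, paste0(opt$out, ".alignment.fasta"))

    n <- inputs$msa$n
    cells <- sum(vapply(queries, function(q) length(q$states), integer(1))) * R * n
    message(sprintf(
      "papara: R=%d edges, Q=%d reads, W=%d, n=%d sites, %.3g DP cells, %.2fs",
      R, Q, opt$W, n, cells, proc.time()[["elapsed"]] - t0))
    0L
  }, error = function(e) {
    message("papara: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
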