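# Synthetic inputs: random reference trees, alignments with
# phylogenetically structured gap blocks (so the CGAP signal is
# exercised), and error-bearing reads with a truth table.  Everything is
# deterministic under the configured seed; the only random number
# generator used is R's, explicitly seeded and restored.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Shapes and rates of the synthetic study inputs.  The defaults are a
#' desk-scale rendition of the kind of data the method targets (hundreds
#' of reference sites over tens of taxa, reads of about a hundred bases):
#' 16 taxa, 400 alignment columns, 20 reads of length 100, 5%
#' per-site-per-edge substitution rate, 1% read indel rate, 10% of
#' columns touched by clade-structured gap blocks.
#'
#' @param taxa Number of reference taxa (>= 4).
#' @param n_sites Alignment columns before gap events.
#' @param n_reads Number of query reads.
#' @param read_length Read length in bases (drawn from ungapped rows).
#' @param substitution_rate Per-site probability of substitution (per
#'   edge when evolving the reference; per base when mutating reads, with
#'   the replacement drawn uniformly from all four bases).
#' @param indel_rate Per-base probability of a short (1-2 nt) insertion
#'   or deletion in a read.
#' @param gap_column_fraction Target fraction of alignment columns
#'   covered by clade-wide gap blocks.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return Object of class `papara_simconfig`.
#' @export
simulation_config <- function(taxa = 16L, n_sites = 400L, n_reads = 20L,
                              read_length = 100L, substitution_rate = 0.05,
                              indel_rate = 0.01, gap_column_fraction = 0.1,
                              seed = 1L) {
  cfg <- list(taxa = as.integer(taxa), n_sites = as.integer(n_sites),
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              substitution_rate = substitution_rate,
              indel_rate = indel_rate,
              gap_column_fraction = gap_column_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$taxa >= 4L, cfg$n_sites >= 1L, cfg$n_reads >= 1L,
            cfg$read_length >= 1L,
            cfg$substitution_rate >= 0, cfg$substitution_rate <= 1,
            cfg$indel_rate >= 0, cfg$indel_rate <= 1,
            cfg$gap_column_fraction >= 0, cfg$gap_column_fraction <= 1)
  structure(cfg, class = "papara_simconfig")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a reference alignment and tree
#'
#' A random unrooted binary topology over `taxa` tips; a random root
#' sequence is evolved down the tree, substituting each site with
#' probability `substitution_rate` per edge (to a different base).
#' Gap blocks of 1-4 columns are then cleared in random clades until
#' about `gap_column_fraction` of the columns are touched, creating
#' phylogenetically structured indels.
#'
#' @param config A `papara_simconfig`.
#' @return List with `msa` (a `papara_msa`) and `tree` (a `papara_tree`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "papara_simconfig"))
  with_seed(config$seed, {
    phy <- ape::rtree(config$taxa, rooted = FALSE,
                      tip.label = paste0("t", seq_len(config$taxa)))
    tree <- reference_tree(phy)
    n <- config$n_sites
    ntip <- config$taxa
    nn <- ntip + phy$Nnode
    seqs <- vector("list", nn)
    root <- ntip + 1L
    seqs[[root]] <- sample(BASES, n, replace = TRUE)
    # preorder over ape's edge matrix: parents precede children
    ord <- ape::reorder.phylo(phy, "cladewise")$edge
    for (r in seq_len(nrow(ord))) {
      par <- ord[r, 1]; child <- ord[r, 2]
      s <- seqs[[par]]
      mut <- runif(n) < config$substitution_rate
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(BASES, b), 1L),
                         character(1))
      }
      seqs[[child]] <- s
    }
    tips <- do.call(rbind, seqs[seq_len(ntip)])

    # clade-structured gap blocks: tips below each edge, child side
    if (config$gap_column_fraction > 0) {
      tips_below <- lapply(seq_len(tree$n_edges), function(e) {
        child <- phy$edge[e, 2]
        if (child <= ntip) child
        else match(ape::extract.clade(phy, child)$tip.label, phy$tip.label)
      })
      target <- config$gap_column_fraction * n
      covered <- logical(n)
      guard <- 0L
      # events cover disjoint column blocks: one clade event per column, so
      # the gapped taxa at any column form a single connected clade
      while (sum(covered) < target && guard < 10L * n) {
        guard <- guard + 1L
        e <- sample.int(tree$n_edges, 1L)
        len <- min(sample(1:4, 1L), n)
        start <- sample.int(n - len + 1L, 1L)
        cols <- start:(start + len - 1L)
        if (any(covered[cols])) next
        tips[tips_below[[e]], cols] <- "-"
        covered[cols] <- TRUE
      }
    }
    rows <- apply(tips, 1, paste, collapse = "")
    msa <- reference_alignment(phy$tip.label, rows)
    list(msa = msa, tree = tree)
  })
}

#' Simulate reads from a reference alignment
#'
#' Reads are ungapped substrings of random alignment rows, then mutated:
#' each base substituted with probability `substitution_rate` (replacement
#' uniform over all four bases, so the expected per-site mismatch
#' fraction at rate 1 is 3/4), and short 1-2 nt insertions/deletions
#' applied at `indel_rate` per base.  A truth table records the source
#' row and ungapped interval of every read.
#'
#' @param msa A `papara_msa`.
#' @param config A `papara_simconfig` (its `seed + 1` seeds the read
#'   stream so reads are independent of the reference draw).
#' @return List with `queries` (list of `papara_query`) and `truth`
#'   (data.frame: name, source_taxon, start, end — 1-based inclusive
#'   ungapped coordinates).
#' @export
simulate_reads <- function(msa, config) {
  stopifnot(inherits(msa, "papara_msa"), inherits(config, "papara_simconfig"))
  ungapped <- gsub("-", "", msa$rows, fixed = TRUE)
  long_enough <- which(nchar(ungapped) >= config$read_length)
  if (!length(long_enough))
    stop("read_length ", config$read_length,
         " exceeds every ungapped row length (max ",
         max(nchar(ungapped)), ")")
  with_seed(config$seed + 1L, {
    queries <- vector("list", config$n_reads)
    truth <- data.frame(name = character(config$n_reads),
                        source_taxon = character(config$n_reads),
                        start = integer(config$n_reads),
                        end = integer(config$n_reads),
                        stringsAsFactors = FALSE)
    for (r in seq_len(config$n_reads)) {
      row <- sample(long_enough, 1L)
      src <- ungapped[[row]]
      start <- sample.int(nchar(src) - config$read_length + 1L, 1L)
      s <- strsplit(substr(src, start, start + config$read_length - 1L),
                    "", fixed = TRUE)[[1]]
      mut <- runif(length(s)) < config$substitution_rate
      if (any(mut)) s[mut] <- sample(BASES, sum(mut), replace = TRUE)
      if (config$indel_rate > 0) {
        out <- character(0)
        for (b in s) {
          if (runif(1) < config$indel_rate) {
            if (runif(1) < 0.5) {
              next                       # deletion: drop this base
            } else {
              out <- c(out, sample(BASES, sample(1:2, 1L), replace = TRUE), b)
            }
          } else out <- c(out, b)
        }
        if (!length(out)) out <- sample(BASES, 1L)
        s <- out
      }
      nm <- sprintf("read%03d", r)
      queries[[r]] <- encoded_query(nm, paste(s, collapse = ""))
      truth$name[r] <- nm
      truth$source_taxon[r] <- msa$taxon_names[row]
      truth$start[r] <- start
      truth$end[r] <- start + config$read_length - 1L
    }
    list(queries = queries, truth = truth)
  })
}

#' Write a simulated dataset as standard files
#'
#' Writes the alignment (FASTA), tree (Newick) and reads (FASTA or
#' FASTQ, constant quality) so fixtures double as end-to-end CLI tests.
#'
#' @param sim Output of [simulate_reference()].
#' @param reads Output of [simulate_reads()].
#' @param dir Output directory.
#' @param fastq Write reads as FASTQ instead of FASTA.
#' @return Named list of the three file paths.
#' @export
write_simulated_dataset <- function(sim, reads, dir, fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msa_path <- file.path(dir, "reference.fasta")
  tree_path <- file.path(dir, "reference.nwk")
  reads_path <- file.path(dir, if (fastq) "reads.fastq" else "reads.fasta")
  write_fasta(as.list(sim$msa$rows), msa_path)
  ape::write.tree(sim$tree$phylo, tree_path)
  rs <- lapply(reads$queries, function(q) q$raw)
  names(rs) <- vapply(reads$queries, function(q) q$name, character(1))
  if (fastq) write_fastq(rs, reads_path) else write_fasta(rs, reads_path)
  list(msa = msa_path, tree = tree_path, reads = reads_path)
}

#' Fixed tiny worked example
#'
#' A hand-written 4-taxon fixture (12 alignment columns, one clade-wide
#' gap block, 3 reads) used throughout the documentation and as a golden
#' test case.  The expected placements were computed once with the
#' exhaustive path-enumeration oracle and are frozen here.
#'
#' @return List with `msa`, `tree`, `newick`, `queries`, and `expected`
#'   (data.frame of per-read best score; plus the per-site Fitch
#'   mutation counts of the alignment).
#' @export
make_worked_example <- function() {
  newick <- "((t1:1,t2:1):1,(t3:1,t4:1):1);"
  rows <- c(t1 = "ACGTACGTACGT",
            t2 = "ACGTACGAACGT",
            t3 = "ACGTAC--ACGT",
            t4 = "ACGTAT--ACGT")
  msa <- reference_alignment(names(rows), unname(rows))
  tree <- reference_tree(ape::read.tree(text = newick))
  queries <- list(encoded_query("r1", "ACGTACGT"),
                  encoded_query("r2", "ACGTACACGT"),
                  encoded_query("r3", "AGGTACGT"))
  # frozen from brute_force_score over all 5 edges (see tests); r1 pays the
  # CGAP diagonal penalty at site 8 even though it is an exact substring of
  # t1, because t2 substitutes at that gap-adjacent site
  expected <- data.frame(query = c("r1", "r2", "r3"),
                         best_score = c(2L, 0L, 5L))
  fitch_per_site <- c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 2L, 0L, 0L, 0L, 0L)
  list(msa = msa, tree = tree, newick = newick, queries = queries,
       expected = expected, fitch_per_site = fitch_per_site)
}
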