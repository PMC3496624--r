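# Test helpers: independent oracles and random fixture builders.
# Oracles deliberately avoid the code paths they check.

with_seed <- papara:::with_seed

# Exhaustive parsimony oracle: minimum mutation count for one site over all
# assignments of single symbols (A,C,G,T,gap) to the internal nodes.  Tips
# may hold ambiguity sets; a tip edge is free iff the neighbouring internal
# state is a member of the tip set.  Exponential (5^internal), so only for
# trees with <= 6 tips.
exhaustive_fitch_site <- function(tree, tip_sets) {
  phy <- tree$phylo
  ntip <- tree$n_tips
  nint <- phy$Nnode
  stopifnot(ntip <= 6L)
  syms <- c(1L, 2L, 4L, 8L, 16L)
  combos <- as.matrix(expand.grid(rep(list(syms), nint)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(rep(NA_integer_, ntip), combos[r, ])
    cost <- 0L
    for (e in seq_len(nrow(phy$edge))) {
      a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
      sa <- lab[a]
      sb <- if (b <= ntip) tip_sets[b] else lab[b]
      cost <- cost + as.integer(bitwAnd(sa, sb) == 0L)
    }
    if (cost < best) best <- cost
  }
  as.integer(best)
}

# random unrooted binary tree over `taxa` tips, labels t1..tN
rand_tree <- function(taxa) {
  reference_tree(ape::rtree(taxa, rooted = FALSE,
                            tip.label = paste0("t", seq_len(taxa))))
}

# random alignment rows over ACGT + gaps + occasional ambiguity codes
rand_msa_rows <- function(taxa, n, gap_prob = 0.15, ambig_prob = 0.05) {
  pool <- c("A", "C", "G", "T")
  ambig <- c("R", "Y", "S", "W", "K", "M", "N")
  rows <- vapply(seq_len(taxa), function(i) {
    ch <- sample(pool, n, replace = TRUE)
    amask <- runif(n) < ambig_prob
    ch[amask] <- sample(ambig, sum(amask), replace = TRUE)
    ch[runif(n) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  reference_alignment(paste0("t", seq_len(taxa)), rows)
}

rand_profile <- function(n, cgap_prob = 0.3, ambig = TRUE) {
  states <- if (ambig) sample(1:15, n, replace = TRUE)
            else sample(c(1L, 2L, 4L, 8L), n, replace = TRUE)
  parsimony_state_vector(states, cgap = runif(n) < cgap_prob)
}

rand_query <- function(m, n_prob = 0.05) {
  st <- sample(c(1L, 2L, 4L, 8L), m, replace = TRUE)
  st[runif(m) < n_prob] <- 15L
  structure(list(name = "q", states = st,
                 raw = paste(decode_state(st), collapse = ""), qualities = NULL),
            class = "papara_query")
}
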