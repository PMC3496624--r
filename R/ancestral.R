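# Parsimony ancestral state vectors at per-edge virtual roots.
#
# State sets live over a 5-symbol alphabet {A,C,G,T,gap} encoded as bits
# (gap = 16).  Unit-cost Fitch passes (the state-set form of unit-cost
# Sankoff) run once over the unrooted tree; for every edge the two
# directional messages meeting there are combined at a "virtual root",
# giving the 4-bit DNA profile plus the per-site CGAP flag.  The traversal
# anchor is arbitrary and results are anchor-independent.

GAP_BIT <- 16L

# Fitch combine: intersection if nonempty, else union (one mutation).
# Vectorized over sites; returns set and a logical mask of union events.
fitch_combine <- function(x, y) {
  inter <- bitwAnd(x, y)
  un <- inter == 0L
  set <- inter
  set[un] <- bitwOr(x[un], y[un])
  list(set = set, union = un)
}

# 5-bit tip codes for one alignment row ('-' -> gap bit).
tip_codes <- function(row, what) {
  enc <- encode_sequence(row, allow_gap = TRUE, what = what)
  codes <- enc$states
  codes[enc$gap] <- GAP_BIT
  codes
}

# Adjacency of the unrooted tree: per node, incident (neighbor, edge_id).
tree_adjacency <- function(tree) {
  nn <- tree$n_tips + tree$phylo$Nnode
  adj <- vector("list", nn)
  e <- tree$edges
  for (i in seq_len(nrow(e))) {
    a <- e$node_a[i]; b <- e$node_b[i]
    adj[[a]] <- rbind(adj[[a]], c(b, e$edge_id[i]))
    adj[[b]] <- rbind(adj[[b]], c(a, e$edge_id[i]))
  }
  adj
}

#' Directional Fitch state-set passes over the reference tree
#'
#' Computes, for every edge, the state-set message from each of its two
#' sides: a postorder (tipward-to-anchor) pass and a preorder pass back
#' out.  Internal nodes are binary when the traversal is anchored at a
#' tip, so every combine is a well-defined two-set Fitch combine and the
#' per-edge results do not depend on the anchor.
#'
#' @param tree A `papara_tree`.
#' @param msa The matching `papara_msa`.
#' @param anchor Tip index (1..T) used as traversal anchor; the default is
#'   tip 1.  Any choice yields identical per-edge messages and site costs.
#' @return Object of class `papara_fitch`: matrices `down` and `up`
#'   (edges x sites; the message from the tipward and anchorward side of
#'   each edge, respectively), integer vector `site_cost` (per-site Fitch
#'   mutation counts, i.e. the parsimony score of each column), and the
#'   `tree`.
#' @export
fitch_passes <- function(tree, msa, anchor = 1L) {
  stopifnot(inherits(tree, "papara_tree"), inherits(msa, "papara_msa"))
  if (!setequal(tree$phylo$tip.label, msa$taxon_names))
    stop("tree and alignment cover different taxa")
  ntip <- tree$n_tips
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > ntip) stop("anchor must be a tip index in 1..", ntip)
  n <- msa$n
  tips <- matrix(0L, nrow = ntip, ncol = n)
  for (t in seq_len(ntip)) {
    lab <- tree$phylo$tip.label[t]
    tips[t, ] <- tip_codes(msa$rows[[lab]], what = sprintf("row '%s'", lab))
  }

  adj <- tree_adjacency(tree)
  nn <- ntip + tree$phylo$Nnode
  parent_node <- integer(nn); parent_edge <- integer(nn)
  preorder <- integer(0)
  visited <- logical(nn)
  stack <- anchor; parent_node[anchor] <- 0L; parent_edge[anchor] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    visited[v] <- TRUE
    preorder <- c(preorder, v)
    nb <- adj[[v]]
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (!visited[w] && w != parent_node[v]) {
        parent_node[w] <- v
        parent_edge[w] <- nb[r, 2]
        stack <- c(stack, w)
      }
    }
  }

  child_of_edge <- integer(tree$n_edges)
  child_of_edge[parent_edge[preorder[-1]]] <- preorder[-1]

  down <- matrix(0L, nrow = tree$n_edges, ncol = n)
  up <- matrix(0L, nrow = tree$n_edges, ncol = n)
  site_cost <- integer(n)

  # postorder: messages toward the anchor
  for (v in rev(preorder[-1])) {
    e <- parent_edge[v]
    if (v <= ntip) {
      down[e, ] <- tips[v, ]
    } else {
      ce <- setdiff(adj[[v]][, 2], e)   # exactly two child edges
      cmb <- fitch_combine(down[ce[1], ], down[ce[2], ])
      down[e, ] <- cmb$set
      site_cost <- site_cost + cmb$union
    }
  }
  # the anchor tip closes the score: root the count on its pendant edge
  root_edge <- parent_edge[adj[[anchor]][1, 1]]
  site_cost <- site_cost +
    fitch_combine(tips[anchor, ], down[root_edge, ])$union

  # preorder: messages away from the anchor
  up[root_edge, ] <- tips[anchor, ]
  for (v in preorder[-1]) {
    if (v <= ntip) next
    e <- parent_edge[v]
    ce <- setdiff(adj[[v]][, 2], e)
    up[ce[1], ] <- fitch_combine(up[e, ], down[ce[2], ])$set
    up[ce[2], ] <- fitch_combine(up[e, ], down[ce[1], ])$set
  }

  structure(list(down = down, up = up, site_cost = site_cost,
                 anchor = anchor, tree = tree),
            class = "papara_fitch")
}

#' Ancestral state vector and CGAP signal at one edge's virtual root
#'
#' Combines the two directional messages meeting at the edge with the
#' Fitch rule, projects out the gap symbol to obtain the 4-bit DNA state
#' (a set that is gap-only becomes the full set 15), and derives the
#' per-site CGAP flag.
#'
#' The CGAP rule is a documented stand-in: the published account derives
#' the flag from prior work without restating the rule.  The default,
#' `"parsimonious"`, sets CGAP where the gap symbol is a member of the
#' combined virtual-root set — i.e. where a gap is among the states
#' attaining minimal parsimony cost at that point.  Alternatives:
#' `"strict"` (gap survives a nonempty intersection) and `"gap_only"`
#' (the combined set is exactly the gap symbol).
#'
#' @param edge_id Integer edge identifier.
#' @param sets A `papara_fitch` from [fitch_passes()].
#' @param params A `papara_params` (unused by the default rules; kept so
#'   alternative rules may consult penalties).
#' @param cgap_rule One of `"parsimonious"`, `"strict"`, `"gap_only"`.
#' @return A `papara_profile` with `edge_id`, 4-bit `states`, and `cgap`.
#' @export
ancestral_states_for_edge <- function(edge_id, sets,
                                      params = scoring_params(),
                                      cgap_rule = c("parsimonious", "strict",
                                                    "gap_only")) {
  cgap_rule <- match.arg(cgap_rule)
  stopifnot(inherits(sets, "papara_fitch"))
  edge_id <- as.integer(edge_id)
  if (edge_id < 1L || edge_id > nrow(sets$down)) stop("unknown edge_id: ", edge_id)
  d <- sets$down[edge_id, ]; u <- sets$up[edge_id, ]
  inter <- bitwAnd(d, u)
  un <- inter == 0L
  set <- inter
  set[un] <- bitwOr(d[un], u[un])
  cgap <- switch(cgap_rule,
    parsimonious = bitwAnd(set, GAP_BIT) != 0L,
    strict = !un & bitwAnd(inter, GAP_BIT) != 0L,
    gap_only = set == GAP_BIT)
  states <- bitwAnd(set, 15L)
  states[states == 0L] <- 15L
  parsimony_state_vector(states, cgap = cgap, edge_id = edge_id)
}

#' Ancestral state vectors for every edge of the reference tree
#'
#' Runs the Fitch passes once and evaluates the virtual root of each of
#' the 2T-3 edges statelessly (no shared traversal data is mutated, so
#' edge order is irrelevant).
#'
#' @inheritParams fitch_passes
#' @inheritParams ancestral_states_for_edge
#' @return List of `papara_profile`, one per edge, in edge-id order.
#' @export
all_edge_state_vectors <- function(tree, msa, params = scoring_params(),
                                   cgap_rule = "parsimonious") {
  sets <- fitch_passes(tree, msa)
  lapply(seq_len(tree$n_edges), ancestral_states_for_edge, sets = sets,
         params = params, cgap_rule = cgap_rule)
}
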