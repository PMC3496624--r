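# Input plumbing: FASTA reference alignment, Newick reference tree,
# FASTA/FASTQ query reads.  Parsing goes through Biostrings and ape;
# validation and encoding are done here so errors name the offending
# record and position.

#' Read and cross-validate a reference alignment and tree
#'
#' The reference alignment (FASTA, DNA, may contain `-`) and the reference
#' tree (Newick) must cover exactly the same taxa.  The tree is unrooted if
#' necessary; an unrooted binary tree over T tips has 2T-3 edges, each of
#' which receives a stable integer identifier (its row in the `ape` edge
#' matrix, which is deterministic for a given Newick string).
#'
#' @param msa_path Path to the FASTA alignment.
#' @param tree_path Path to the Newick tree.  Branch lengths and internal
#'   node labels are accepted and ignored.
#' @return List with components `msa` (a `papara_msa`: fields
#'   `taxon_names`, `rows`, `n`) and `tree` (a `papara_tree`: fields
#'   `phylo`, `edges`, `n_tips`, `n_edges`).
#' @export
read_reference_inputs <- function(msa_path, tree_path) {
  if (!file.exists(msa_path)) stop("alignment file not found: ", msa_path)
  if (!file.exists(tree_path)) stop("tree file not found: ", tree_path)
  seqs <- Biostrings::readBStringSet(msa_path)
  if (length(seqs) == 0L) stop("empty alignment file: ", msa_path)
  msa <- reference_alignment(names(seqs), as.character(seqs))
  phy <- tryCatch(ape::read.tree(tree_path),
                  error = function(e) stop("malformed Newick in ", tree_path,
                                           ": ", conditionMessage(e), call. = FALSE),
                  warning = function(w) stop("malformed Newick in ", tree_path,
                                             ": ", conditionMessage(w), call. = FALSE))
  if (is.null(phy)) stop("malformed Newick in ", tree_path)
  tree <- reference_tree(phy)
  missing_in_msa <- setdiff(tree$phylo$tip.label, msa$taxon_names)
  missing_in_tree <- setdiff(msa$taxon_names, tree$phylo$tip.label)
  if (length(missing_in_msa))
    stop("tree tips absent from the alignment: ",
         paste(missing_in_msa, collapse = ", "))
  if (length(missing_in_tree))
    stop("alignment taxa absent from the tree: ",
         paste(missing_in_tree, collapse = ", "))
  list(msa = msa, tree = tree)
}

#' Construct a validated reference alignment object
#'
#' @param taxon_names Character vector of unique taxon names.
#' @param rows Character vector of aligned sequences (equal length, IUPAC
#'   DNA plus `-`).
#' @return A `papara_msa` with fields `taxon_names`, `rows` (named by
#'   taxon) and `n` (number of alignment columns).
#' @export
reference_alignment <- function(taxon_names, rows) {
  stopifnot(length(taxon_names) == length(rows), length(rows) >= 1L)
  if (anyDuplicated(taxon_names))
    stop("duplicated taxon names: ",
         paste(unique(taxon_names[duplicated(taxon_names)]), collapse = ", "))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("alignment row '%s' has length %d, expected %d",
                 taxon_names[bad], widths[bad], widths[1]))
  }
  # validate alphabet (raises with symbol and position)
  for (i in seq_along(rows))
    encode_sequence(rows[i], allow_gap = TRUE, what = sprintf("row '%s'", taxon_names[i]))
  rows <- toupper(rows)
  names(rows) <- taxon_names
  structure(list(taxon_names = unname(taxon_names), rows = rows,
                 n = unname(widths[1])),
            class = "papara_msa")
}

#' Wrap an ape tree as a reference tree with stable edge identifiers
#'
#' Rooted binary input trees are unrooted first.  All internal nodes must
#' then have degree 3 (tips degree 1).
#'
#' @param phy An `ape::phylo` object.
#' @return A `papara_tree`: `phylo`, `edges` (data.frame edge_id, node_a,
#'   node_b), `n_tips`, `n_edges`.
#' @export
reference_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  if (ntip < 3L) stop("reference tree needs at least 3 tips")
  deg <- tabulate(c(phy$edge), nbins = ntip + phy$Nnode)
  if (any(deg[seq_len(ntip)] != 1L))
    stop("tips must have degree 1")
  if (any(deg[(ntip + 1L):(ntip + phy$Nnode)] != 3L))
    stop("reference tree must be binary (every internal node of degree 3)")
  n_edges <- nrow(phy$edge)
  stopifnot(n_edges == 2L * ntip - 3L)
  edges <- data.frame(edge_id = seq_len(n_edges),
                      node_a = phy$edge[, 1], node_b = phy$edge[, 2])
  structure(list(phylo = phy, edges = edges, n_tips = ntip, n_edges = n_edges),
            class = "papara_tree")
}

#' Read query reads and encode them as state-set vectors
#'
#' Reads are encoded via [encode_sequence()]; gaps are not permitted in
#' queries.  FASTQ base qualities (Sanger offset 33) are parsed and
#' attached but ignored by all scoring.
#'
#' @param path FASTA or FASTQ file of reads.
#' @param format `"fasta"` or `"fastq"`.
#' @return List of encoded queries; each element has fields `name`,
#'   `states` (integer codes), `raw` (original string) and, for FASTQ,
#'   `qualities` (integer Phred scores).
#' @export
read_queries <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("query file not found: ", path)
  seqs <- Biostrings::readBStringSet(path, format = format,
                                     with.qualities = (format == "fastq"))
  if (length(seqs) == 0L) stop("no reads in ", path)
  quals <- NULL
  if (format == "fastq") {
    q <- S4Vectors::mcols(seqs)$qualities
    quals <- lapply(as.character(q), function(s) utf8ToInt(s) - 33L)
  }
  nm <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    raw <- as.character(seqs[[i]])
    enc <- encode_sequence(raw, allow_gap = FALSE,
                           what = sprintf("read '%s'", nm[i]))
    out[[i]] <- structure(list(name = nm[i], states = enc$states,
                               raw = toupper(raw),
                               qualities = if (is.null(quals)) NULL else quals[[i]]),
                          class = "papara_query")
  }
  out
}

#' Encode an in-memory read
#'
#' @param name Read name.
#' @param seq Gap-free IUPAC DNA string.
#' @return A `papara_query`.
#' @export
encoded_query <- function(name, seq) {
  enc <- encode_sequence(seq, allow_gap = FALSE, what = sprintf("read '%s'", name))
  structure(list(name = name, states = enc$states, raw = toupper(seq),
                 qualities = NULL),
            class = "papara_query")
}

# Minimal FASTA writer used by the synthetic module and the CLI output.
write_fasta <- function(named_seqs, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(named_seqs)) {
    writeLines(paste0(">", nm), con)
    s <- named_seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

write_fastq <- function(named_seqs, path, qual_char = "I") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(named_seqs)) {
    s <- named_seqs[[nm]]
    writeLines(c(paste0("@", nm), s, "+",
                 strrep(qual_char, nchar(s))), con)
  }
  invisible(path)
}

#' Dump per-edge state vectors as a tab-separated table
#'
#' Debug aid: one line per (edge, site) with the state as an IUPAC
#' character and the CGAP flag.  Sites are reported 1-based.
#'
#' @param vectors List of `papara_profile` objects.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
dump_edge_vectors <- function(vectors, path) {
  rows <- do.call(rbind, lapply(vectors, function(v) {
    data.frame(edge_id = v$edge_id, site = seq_along(v$states),
               state = decode_state(v$states), cgap = v$cgap)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
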