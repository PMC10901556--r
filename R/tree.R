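#' Parse a Newick string or file into a time tree
#'
#' Trees are `ape::phylo` objects throughout the package; chronograms carry
#' branch lengths in million years (My) with all tips at age 0.
#'
#' @param text A Newick string, or `NULL` when `path` is given.
#' @param path Path to a Newick file.
#' @return A rooted `phylo` tree with branch lengths.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort("malformed Newick input")
  }
  if (anyDuplicated(tr$tip.label)) abort("duplicate leaf labels in tree")
  if (is.null(tr$edge.length)) abort("tree must have branch lengths")
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` tree.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @param digits Branch-length precision.
#' @return The Newick string (invisibly when writing to a file).
#' @export
serialize_newick <- function(tree, path = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Node ages of a chronogram
#'
#' Ages are measured backwards from the present: tips of an ultrametric tree
#' have age 0 and the root has age equal to the tree height.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Numeric vector of ages indexed by ape node number
#'   (tips `1..n`, internals `n+1..n+Nnode`).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Is a tree ultrametric (a chronogram)?
#'
#' @param tree A `phylo` tree.
#' @param tol Absolute tolerance on root-to-tip path differences (My).
#' @return Logical.
#' @export
is_chronogram <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  tips <- seq_len(length(tree$tip.label))
  diff(range(depth[tips])) <= tol
}

# Resolve a node reference: ape node number, node label, or tip label.
resolve_node <- function(tree, node) {
  n <- length(tree$tip.label)
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1 || node > n + tree$Nnode) abort("node id out of range")
    return(node)
  }
  i <- match(node, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(node, tree$node.label)
    if (!is.na(j)) return(n + j)
  }
  abort(paste0("unknown node: ", node))
}

#' Remove leaves from a tree
#'
#' Drops the named leaves and suppresses the resulting unary nodes, summing
#' their branch lengths, so pairwise path lengths between remaining leaves
#' are unchanged.
#'
#' @param tree A `phylo` tree.
#' @param names Leaf labels to remove (may be empty).
#' @return The pruned tree.
#' @export
prune_taxa <- function(tree, names) {
  if (length(names) == 0) return(tree)
  unknown <- setdiff(names, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("unknown leaf label(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(setdiff(tree$tip.label, names)) < 1) {
    abort("cannot prune away every leaf")
  }
  ape::drop.tip(tree, names)
}

#' Graft a new leaf onto a chronogram at a given divergence age
#'
#' Attaches a new present-day leaf to the edge above `attach_node`, creating
#' a bifurcation at `divergence_age` (My). The age must lie strictly inside
#' the age span of that edge, so the tree stays ultrametric and all existing
#' pairwise distances are unchanged.
#'
#' @param tree An ultrametric `phylo` tree.
#' @param attach_node The child end of the edge to graft onto: an ape node
#'   number, a tip label, or a node label.
#' @param divergence_age Age (My) of the new bifurcation.
#' @param new_label Label of the new leaf.
#' @return The enlarged chronogram.
#' @export
graft_leaf <- function(tree, attach_node, divergence_age, new_label) {
  if (!is_chronogram(tree)) abort("graft_leaf requires a chronogram")
  if (new_label %in% tree$tip.label) abort("new_label already present")
  node <- resolve_node(tree, attach_node)
  ages <- node_ages(tree)
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(parent) != 1) abort("attach_node has no parent edge (root?)")
  lo <- ages[node]
  hi <- ages[parent]
  if (!(divergence_age > lo && divergence_age < hi)) {
    abort(sprintf(
      "divergence_age %.4g outside the open age span (%.4g, %.4g) of the edge",
      divergence_age, lo, hi))
  }
  tip <- structure(
    list(edge = matrix(c(2L, 1L), 1, 2), tip.label = new_label,
         edge.length = divergence_age, Nnode = 1L),
    class = "phylo")
  out <- ape::bind.tree(tree, tip, where = node,
                        position = divergence_age - lo)
  ape::reorder.phylo(out, "cladewise")
}

#' Duplicate a clade at a whole-genome-duplication age
#'
#' Replaces a clade by a new bifurcation at `split_age` (My) whose two
#' children are two copies of the clade, with paralog suffixes appended to
#' the copied leaf labels. This is the operation used to represent the
#' teleost whole-genome duplication (in the source analysis, at 303 My) on a
#' species chronogram. The edge above the clade root must span `split_age`.
#'
#' @param tree An ultrametric `phylo` tree.
#' @param clade_root Root node of the clade: ape node number, node label, or
#'   a vector of >= 2 tip labels whose MRCA is taken.
#' @param split_age Age (My) of the duplication bifurcation; must satisfy
#'   `age(clade_root) <= split_age <= age(parent)`.
#' @param suffixes Two label suffixes for the paralog copies.
#' @param node_label Optional label for the new duplication node.
#' @return The enlarged chronogram, with every clade leaf present twice.
#' @export
duplicate_clade <- function(tree, clade_root, split_age,
                            suffixes = c("_P1", "_P2"), node_label = NULL) {
  if (!is_chronogram(tree)) abort("duplicate_clade requires a chronogram")
  if (length(suffixes) != 2 || suffixes[1] == suffixes[2]) {
    abort("suffixes must be two distinct labels")
  }
  node <- if (is.character(clade_root) && length(clade_root) > 1) {
    ape::getMRCA(tree, clade_root)
  } else {
    resolve_node(tree, clade_root)
  }
  n <- length(tree$tip.label)
  if (node <= n) abort("clade_root must be an internal node")
  ages <- node_ages(tree)
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(parent) != 1) {
    abort("clade_root has no parent edge; cannot place the duplication")
  }
  if (split_age < ages[node] - 1e-9 || split_age > ages[parent] + 1e-9) {
    abort(sprintf(
      "split_age %.4g outside the age span [%.4g, %.4g] of the stem edge",
      split_age, ages[node], ages[parent]))
  }
  clade <- ape::extract.clade(tree, node)
  stem <- split_age - ages[node]
  sub_newick <- function(cl, suffix) {
    cl$tip.label <- paste0(cl$tip.label, suffix)
    sub(";$", "", ape::write.tree(cl, digits = 12))
  }
  joined_text <- paste0(
    "(", sub_newick(clade, suffixes[1]), ":", format(stem, digits = 12),
    ",", sub_newick(clade, suffixes[2]), ":", format(stem, digits = 12),
    ")", if (!is.null(node_label)) node_label else "", ";")
  joined <- ape::read.tree(text = joined_text)
  joined$root.edge <- 0

  # Reduce the original clade to a placeholder tip, then splice the
  # duplicated pair onto its terminal edge at split_age.
  keep_tip <- clade$tip.label[1]
  placeholder <- ape::drop.tip(tree, setdiff(clade$tip.label, keep_tip))
  out <- ape::bind.tree(placeholder, joined,
                        where = match(keep_tip, placeholder$tip.label),
                        position = split_age)
  out <- ape::drop.tip(out, keep_tip)
  ape::reorder.phylo(out, "cladewise")
}

#' Classify a p53 paralog from its gene neighborhood
#'
#' Applies the synteny rule distinguishing the two teleost p53 paralog
#' classes: Class II (paralog 2) copies are flanked upstream by *gps2* in the
#' sense direction and downstream by an antisense E3 ubiquitin-ligase gene
#' followed by a *capga* homolog; Class I (paralog 1) copies are flanked
#' upstream by *slc2a4* in the antisense direction. Anything else — including
#' neighborhoods carrying evidence for both classes — is `unknown`.
#'
#' @param nbhd A data frame with columns `gene`, `side`
#'   (`upstream`/`downstream`, in positional order within each side) and
#'   `strand` (`sense`/`antisense`).
#' @param e3_pattern Regular expression identifying E3 ubiquitin-ligase gene
#'   symbols.
#' @return A one-row tibble with columns `class` (`"ClassI"`, `"ClassII"` or
#'   `"unknown"`) and `conflict` (logical).
#' @export
classify_paralog <- function(nbhd, e3_pattern = "e3|ligase|rnf|ube|trim|mkrn") {
  if (nrow(nbhd) == 0) {
    return(tibble(class = "unknown", conflict = FALSE))
  }
  stopifnot(all(c("gene", "side", "strand") %in% names(nbhd)))
  if (!all(nbhd$side %in% c("upstream", "downstream")) ||
      !all(nbhd$strand %in% c("sense", "antisense"))) {
    abort("side must be upstream/downstream and strand sense/antisense")
  }
  g <- tolower(nbhd$gene)
  up <- nbhd$side == "upstream"
  down <- which(nbhd$side == "downstream")

  class2_up <- any(up & nbhd$strand == "sense" & grepl("^gps2", g))
  e3_at <- down[grepl(e3_pattern, g[down]) & nbhd$strand[down] == "antisense"]
  class2_down <- length(e3_at) > 0 &&
    any(vapply(e3_at, function(i) {
      later <- down[down > i]
      any(grepl("^capg", g[later]))
    }, logical(1)))
  is2 <- class2_up && class2_down
  is1 <- any(up & nbhd$strand == "antisense" & grepl("^slc2a4", g))

  if (is1 && is2) {
    tibble(class = "unknown", conflict = TRUE)
  } else if (is2) {
    tibble(class = "ClassII", conflict = FALSE)
  } else if (is1) {
    tibble(class = "ClassI", conflict = FALSE)
  } else {
    tibble(class = "unknown", conflict = FALSE)
  }
}
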