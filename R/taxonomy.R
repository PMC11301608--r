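#' Parse a taxonomy for a genome collection
#'
#' Reads either a Newick tree (via [ape::read.tree()]) or a two-column
#' child/parent TSV and checks that every genome name appears as a leaf.
#'
#' @param path Path to the taxonomy file, or a Newick string.
#' @param format `"newick"` or `"tsv"`. TSV rows are `child<TAB>parent`;
#'   the root may be given as a self-loop or omitted on the child side.
#' @param genome_names Character vector of genome identifiers (FASTA order);
#'   each must be a leaf of the tree.
#' @return A `taxonomy_tree`: `nodes`, `parent` (named character; the root
#'   maps to itself), `depth` (root = 0), `root`, `leaf_of_doc` (leaf node
#'   per 0-based genome index, in `genome_names` order).
#' @export
parse_taxonomy <- function(path, format = c("newick", "tsv"), genome_names) {
  format <- match.arg(format)
  if (format == "newick") {
    phy <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
    if (is.null(phy)) stop("could not parse Newick input")
    taxonomy_from_phylo(phy, genome_names)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("child", "parent"),
                             colClasses = "character")
    parent <- stats::setNames(tab$parent, tab$child)
    roots <- unique(tab$parent[!(tab$parent %in% tab$child) | tab$parent == tab$child])
    roots <- unique(c(roots, tab$child[tab$child == tab$parent]))
    for (r in roots) parent[r] <- r
    taxonomy_tree(parent, genome_names)
  }
}

#' Convert an ape phylogeny to a taxonomy_tree
#'
#' @param phy An [ape] `phylo` object whose tip labels include all genome
#'   names.
#' @param genome_names Genome identifiers in collection order.
#' @return A `taxonomy_tree`.
#' @export
taxonomy_from_phylo <- function(phy, genome_names) {
  ntip <- length(phy$tip.label)
  labs <- c(phy$tip.label,
            if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
              phy$node.label else paste0(".node", seq_len(phy$Nnode)))
  if (anyDuplicated(labs)) labs <- make.unique(labs, sep = "_")
  parent <- stats::setNames(labs, labs)  # root self-loop by default
  parent[labs[phy$edge[, 2]]] <- labs[phy$edge[, 1]]
  taxonomy_tree(parent, genome_names)
}

#' Construct a taxonomy_tree from a parent map
#'
#' @param parent Named character vector mapping each node to its parent;
#'   the root maps to itself.
#' @param genome_names Genome identifiers (must be leaves).
#' @return A `taxonomy_tree`.
#' @export
taxonomy_tree <- function(parent, genome_names) {
  nodes <- union(names(parent), parent)
  parent <- stats::setNames(ifelse(nodes %in% names(parent), parent[nodes], nodes), nodes)
  roots <- nodes[parent[nodes] == nodes]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  root <- roots
  # depths by repeated lifting; also detects cycles
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    kids <- nodes[parent[nodes] %in% frontier & is.na(depth[nodes]) & nodes != root]
    depth[kids] <- depth[parent[kids]] + 1L
    frontier <- kids
  }
  if (anyNA(depth)) stop("taxonomy contains a cycle or disconnected node(s): ",
                         paste(nodes[is.na(depth)], collapse = ", "))
  missing <- setdiff(genome_names, nodes)
  if (length(missing))
    stop("genome name(s) absent from taxonomy: ", paste(missing, collapse = ", "))
  is_leaf <- !(nodes %in% parent[nodes != parent])
  not_leaf <- setdiff(genome_names, nodes[is_leaf])
  if (length(not_leaf))
    stop("genome name(s) are internal taxonomy nodes, not leaves: ",
         paste(not_leaf, collapse = ", "))
  structure(list(nodes = nodes, parent = parent, depth = depth, root = root,
                 leaf_of_doc = genome_names),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree: ", length(x$nodes), " nodes, root '", x$root,
      "', ", length(x$leaf_of_doc), " genome leaves\n", sep = "")
  invisible(x)
}

#' Lowest common ancestor of two taxonomy nodes
#'
#' Depth-aligned pointer walk; adequate for the tree sizes this package
#' targets (an Euler-tour/RMQ structure could stand behind the same
#' contract for very large taxonomies).
#'
#' @param tree A `taxonomy_tree`.
#' @param a,b Node identifiers.
#' @return The identifier of the deepest node ancestral to both.
#' @export
lca <- function(tree, a, b) {
  if (!(a %in% tree$nodes) || !(b %in% tree$nodes))
    stop("unknown node(s): ", paste(setdiff(c(a, b), tree$nodes), collapse = ", "))
  while (tree$depth[a] > tree$depth[b]) a <- tree$parent[[a]]
  while (tree$depth[b] > tree$depth[a]) b <- tree$parent[[b]]
  while (a != b) { a <- tree$parent[[a]]; b <- tree$parent[[b]] }
  unname(a)
}

#' Taxonomy subtree reported for a MEM's document range
#'
#' The LCA of the leaves of the first and last genome of occurrence; with a
#' single genome this is that genome's leaf.
#'
#' @param tree A `taxonomy_tree`.
#' @param first_doc,last_doc 0-based genome indices.
#' @return Node identifier of the subtree root.
#' @export
subtree_for_mem <- function(tree, first_doc, last_doc) {
  nd <- length(tree$leaf_of_doc)
  if (first_doc < 0 || last_doc >= nd || first_doc > last_doc)
    stop("invalid document range [", first_doc, ", ", last_doc, "]")
  lca(tree, tree$leaf_of_doc[first_doc + 1L], tree$leaf_of_doc[last_doc + 1L])
}

#' Classify a MEM's [first, last] genome range against its source genome
#'
#' A range is a true positive (TP) when it is exactly the source genome,
#' a false positive (FP) when it is non-empty but excludes the source,
#' a vague positive (VP) when it contains the source together with at
#' least one other genome, and a false negative (FN) when it is empty
#' (no occurrence at all, possible only in digest-based modes).
#'
#' @param first_doc,last_doc 0-based genome indices, or `NA` for an empty
#'   range.
#' @param source_doc 0-based index of the genome the read was drawn from.
#' @return One of `"TP"`, `"FP"`, `"VP"`, `"FN"`.
#' @export
classify_range <- function(first_doc, last_doc, source_doc) {
  if (is.na(first_doc) || is.na(last_doc)) return("FN")
  if (first_doc > last_doc) stop("first_doc > last_doc")
  if (first_doc == last_doc && first_doc == source_doc) return("TP")
  if (source_doc >= first_doc && source_doc <= last_doc) return("VP")
  "FP"
}

#' Read-level verdict from a MEM table
#'
#' A read is a true positive when its longest MEM — or all of its longest
#' MEMs, in case of a tie — classifies as TP against the source genome.
#' An empty MEM table is a read-level false negative.
#'
#' @param mem_tab A MEM table as returned by [mem_table()] (a data frame
#'   with columns `length`, `first_doc`, `last_doc`), possibly empty.
#' @param source_doc 0-based source genome index.
#' @return A list with `is_true_positive`, `longest_mem_length`,
#'   `n_longest`, `longest_verdicts` (character vector) and
#'   `aggregate_label` (`"FN"` for an empty table, else `"TP"` when all
#'   longest MEMs are TP, otherwise the majority verdict among the longest
#'   MEMs, ties broken in the order TP, VP, FP, FN).
#' @export
classify_read <- function(mem_tab, source_doc) {
  if (is.null(mem_tab) || nrow(mem_tab) == 0L) {
    return(list(is_true_positive = FALSE, longest_mem_length = 0L,
                n_longest = 0L, longest_verdicts = character(),
                aggregate_label = "FN"))
  }
  L <- max(mem_tab$length)
  longest <- mem_tab[mem_tab$length == L, , drop = FALSE]
  verdicts <- mapply(classify_range, longest$first_doc, longest$last_doc,
                     MoreArgs = list(source_doc = source_doc))
  tp <- all(verdicts == "TP")
  agg <- if (tp) "TP" else {
    counts <- table(factor(verdicts, levels = c("TP", "VP", "FP", "FN")))
    names(counts)[which.max(counts)]
  }
  list(is_true_positive = tp, longest_mem_length = L,
       n_longest = nrow(longest), longest_verdicts = unname(verdicts),
       aggregate_label = agg)
}
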