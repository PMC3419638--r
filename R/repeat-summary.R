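# Hierarchical repeat ledger: annotations are aggregated up a repeat
# taxonomy (element counts and base sums per node), with percentages of
# total read bases and of total repeat bases. Internal nodes may carry
# bases not attributed to any leaf (members classified only at family
# level), so children are never forced to sum to their parent.

#' Default repeat taxonomy
#'
#' The hierarchy used by grass repeat surveys: a root "Total" over
#' Transposable Element (RNA transposon with LTR and non-LTR
#' retrotransposons; DNA transposon), Integrated Virus and Simple Repeat.
#' SINE2/tRNA nests under SINE: its members are a SINE subtype and are
#' counted within the SINE total, not alongside it.
#'
#' @return data.frame of edges (parent, child).
#' @export
default_repeat_taxonomy <- function() {
  edges <- rbind(
    c("Total", "Transposable Element"),
    c("Transposable Element", "RNA transposon"),
    c("RNA transposon", "LTR Retrotransposon"),
    c("LTR Retrotransposon", "Copia"),
    c("LTR Retrotransposon", "Gypsy"),
    c("RNA transposon", "Non-LTR Retrotransposon"),
    c("Non-LTR Retrotransposon", "L1"),
    c("Non-LTR Retrotransposon", "RTE"),
    c("Non-LTR Retrotransposon", "SINE"),
    c("SINE", "SINE2/tRNA"),
    c("Transposable Element", "DNA transposon"),
    c("DNA transposon", "EnSpm"),
    c("DNA transposon", "Harbinger"),
    c("DNA transposon", "Helitron"),
    c("DNA transposon", "MuDr"),
    c("DNA transposon", "hAT"),
    c("Total", "Integrated Virus"),
    c("Integrated Virus", "Caulimoviridae"),
    c("Total", "Simple Repeat"),
    c("Simple Repeat", "Satellite"))
  data.frame(parent = edges[, 1], child = edges[, 2], stringsAsFactors = FALSE)
}

#' Read a repeat taxonomy from an edge-list TSV
#'
#' @param path TSV with columns `parent` and `child`.
#' @return validated edge data.frame.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path)
  if (!all(c("parent", "child") %in% names(df))) {
    stopf("taxonomy file %s needs parent and child columns", path)
  }
  validate_taxonomy(df)
}

validate_taxonomy <- function(edges) {
  if (anyDuplicated(edges$child)) {
    stopf("taxonomy label %s has two parents",
          edges$child[duplicated(edges$child)][1])
  }
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1L) {
    stopf("taxonomy must have exactly one root (found: %s)",
          paste(roots, collapse = ", "))
  }
  edges
}

taxonomy_root <- function(edges) setdiff(edges$parent, edges$child)

#' Lineage of a taxonomy node
#'
#' @param edges taxonomy edge data.frame.
#' @param label node label.
#' @return character vector of labels from the root down to `label`.
#' @export
taxonomy_lineage <- function(edges, label) {
  parent <- setNames(edges$parent, edges$child)
  if (!(label %in% c(edges$child, edges$parent))) {
    stopf("unknown repeat family: %s", label)
  }
  path <- label
  while (path[1] %in% names(parent)) path <- c(parent[[path[1]]], path)
  path
}

# All nodes of the taxonomy in a parent-before-child order.
taxonomy_nodes <- function(edges) {
  root <- taxonomy_root(edges)
  out <- root
  frontier <- root
  while (length(frontier)) {
    kids <- edges$child[edges$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Summarise repeat annotations into a hierarchical ledger
#'
#' Element counts and base sums are accumulated at each annotation's own
#' label and rolled up the taxonomy. Percent of total bases uses the
#' supplied post-trimming read base total (the denominator is not
#' derivable from the annotations); percent of repeat bases uses the root
#' total.
#'
#' @param annotations data.frame with `family`, `start`, `end` (and
#'   `read_id`); intervals are assumed non-overlapping per read.
#' @param total_read_bases total bases in the analysed reads.
#' @param taxonomy edge data.frame (default [default_repeat_taxonomy()]).
#' @return a `repeat_ledger` data.frame: node, n_elements, length_bp,
#'   percent_of_total_bases, percent_of_repeat_bases, with attributes
#'   total_read_bases and total_repeat_bases.
#' @export
summarize_repeats <- function(annotations, total_read_bases,
                              taxonomy = default_repeat_taxonomy()) {
  validate_taxonomy(taxonomy)
  nodes <- taxonomy_nodes(taxonomy)
  known <- nodes
  if (nrow(annotations)) {
    bad <- setdiff(unique(annotations$family), known)
    if (length(bad)) stopf("unknown repeat family: %s", bad[1])
  }
  direct_n <- setNames(numeric(length(nodes)), nodes)
  direct_bp <- direct_n
  if (nrow(annotations)) {
    tn <- table(annotations$family)
    direct_n[names(tn)] <- as.numeric(tn)
    tb <- tapply(annotations$end - annotations$start, annotations$family, sum)
    direct_bp[names(tb)] <- as.numeric(tb)
  }
  # roll up children into parents (children listed after parents in
  # `nodes`, so walk in reverse)
  total_n <- direct_n; total_bp <- direct_bp
  parent <- setNames(taxonomy$parent, taxonomy$child)
  for (node in rev(nodes)) {
    if (node %in% names(parent)) {
      p <- parent[[node]]
      total_n[p] <- total_n[p] + total_n[node]
      total_bp[p] <- total_bp[p] + total_bp[node]
    }
  }
  root <- taxonomy_root(taxonomy)
  build_ledger(nodes, total_n, total_bp, total_read_bases,
               total_repeat_bases = total_bp[[root]])
}

build_ledger <- function(nodes, n_elements, length_bp, total_read_bases,
                         total_repeat_bases) {
  ledger <- data.frame(
    node = nodes,
    n_elements = as.numeric(n_elements[nodes]),
    length_bp = as.numeric(length_bp[nodes]),
    percent_of_total_bases = if (is.null(total_read_bases)) NA_real_ else
      round(100 * as.numeric(length_bp[nodes]) / total_read_bases, 2),
    percent_of_repeat_bases = if (total_repeat_bases > 0) {
      round(100 * as.numeric(length_bp[nodes]) / total_repeat_bases, 1)
    } else NA_real_,
    stringsAsFactors = FALSE)
  attr(ledger, "total_read_bases") <- total_read_bases
  attr(ledger, "total_repeat_bases") <- total_repeat_bases
  class(ledger) <- c("repeat_ledger", "data.frame")
  ledger
}

#' Rebuild a ledger from a published per-node table
#'
#' Takes a table that already lists each node's aggregate element count
#' and base sum (internal nodes may carry bases unattributed to any leaf)
#' and wraps it as a ledger, validating that no parent holds fewer bases
#' than its children's sum.
#'
#' @param node_table data.frame with columns `node`, `n_elements`,
#'   `length_bp` (nodes must match the taxonomy).
#' @param taxonomy edge data.frame.
#' @param total_read_bases optional total read bases for the
#'   percent-of-total column.
#' @return a `repeat_ledger`.
#' @export
ledger_from_table <- function(node_table, taxonomy = default_repeat_taxonomy(),
                              total_read_bases = NULL) {
  validate_taxonomy(taxonomy)
  nodes <- taxonomy_nodes(taxonomy)
  bad <- setdiff(node_table$node, nodes)
  if (length(bad)) stopf("unknown repeat family: %s", bad[1])
  n <- setNames(rep(0, length(nodes)), nodes)
  bp <- n
  n[node_table$node] <- node_table$n_elements
  bp[node_table$node] <- node_table$length_bp
  for (p in unique(taxonomy$parent)) {
    kids <- taxonomy$child[taxonomy$parent == p]
    if (bp[[p]] > 0 && sum(bp[kids]) > bp[[p]]) {
      stopf("children of %s sum to more bases than the node itself", p)
    }
  }
  root <- taxonomy_root(taxonomy)
  build_ledger(nodes, n, bp, total_read_bases, total_repeat_bases = bp[[root]])
}

#' Fraction of one taxonomy node within an ancestor
#'
#' 100 * child bases / parent bases, one decimal. The child must be a
#' descendant of (or equal to) the parent.
#'
#' @param ledger a `repeat_ledger`.
#' @param child,parent node labels.
#' @param taxonomy edge data.frame the ledger was built with.
#' @return percent, one decimal.
#' @export
fraction_of <- function(ledger, child, parent,
                        taxonomy = default_repeat_taxonomy()) {
  lin <- taxonomy_lineage(taxonomy, child)
  if (!(parent %in% lin)) {
    stopf("%s is not a descendant of %s", child, parent)
  }
  bp <- setNames(ledger$length_bp, ledger$node)
  if (!(child %in% names(bp)) || !(parent %in% names(bp))) {
    stopf("node missing from ledger")
  }
  if (bp[[parent]] <= 0) stopf("zero parent length for %s", parent)
  round(100 * bp[[child]] / bp[[parent]], 1)
}
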