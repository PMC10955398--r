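#' Geo-referenced time-calibrated phylogenies
#'
#' A `geophylo` object couples an [ape::phylo] topology with a node table
#' giving, for every node (tips and ancestors alike), its age in thousands of
#' years before present (ky BP), its geographic location (decimal degrees),
#' and optionally one or more trait values.  Ages decrease from the root
#' towards the present; the node table is authoritative for ages and branch
#' lengths are the age differences along each edge.
#'
#' @param phy an [ape::phylo] tree with tip labels and node labels.
#' @param nodes a data frame with one row per node and columns `id`,
#'   `parent` (`NA` for the root), `age`, `lat`, `lon`; any further numeric
#'   columns are treated as traits.  `id` values must match the tree labels.
#' @param tol tolerance for the age/branch-length consistency check.
#' @return an object of class `geophylo`: a list with elements `phy`
#'   (branch lengths recomputed from ages) and `nodes` (rows ordered by the
#'   internal node index, with columns `node`, `id`, `parent`, `length`,
#'   `age`, `lat`, `lon`, `is_leaf`, then traits).
#' @seealso [load_geophylo()], [cophenetic_matrix()], [greatcircle_matrix()],
#'   [lineages_at_time()]
#' @export
geophylo <- function(phy, nodes, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$node.label) || any(phy$node.label == ""))
    stop("all interior nodes must be labelled")
  labels <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labels))
    stop("duplicated node labels: ", paste(labels[duplicated(labels)], collapse = ", "))
  req <- c("id", "parent", "age", "lat", "lon")
  if (!all(req %in% names(nodes)))
    stop("node table must have columns: ", paste(req, collapse = ", "))
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  missing_ids <- setdiff(labels, nodes$id)
  extra_ids <- setdiff(nodes$id, labels)
  if (length(missing_ids) || length(extra_ids))
    stop("node-table ids do not match tree labels; missing: [",
         paste(missing_ids, collapse = ","), "] extra: [",
         paste(extra_ids, collapse = ","), "]")

  n_tip <- length(phy$tip.label)
  nodes <- nodes[match(labels, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$node <- seq_len(nrow(nodes))
  nodes$is_leaf <- nodes$node <= n_tip

  # derive parent from topology; cross-check against the table where given
  parent_idx <- rep(NA_integer_, nrow(nodes))
  parent_idx[phy$edge[, 2]] <- phy$edge[, 1]
  topo_parent <- ifelse(is.na(parent_idx), NA_character_, labels[parent_idx])
  has_par <- !is.na(nodes$parent) & nodes$parent != ""
  bad <- which(has_par & nodes$parent != topo_parent)
  if (length(bad))
    stop("parent mismatch between table and topology for node(s): ",
         paste(nodes$id[bad], collapse = ", "))
  nodes$parent <- topo_parent

  if (any(!is.finite(nodes$age))) stop("non-finite ages")
  if (any(nodes$lat < -90 | nodes$lat > 90, na.rm = TRUE)) stop("lat outside [-90, 90]")
  if (any(nodes$lon < -180 | nodes$lon > 180, na.rm = TRUE)) stop("lon outside [-180, 180]")

  # branch lengths from ages (table authoritative); validate direction
  B <- rep(NA_real_, nrow(nodes))
  child <- phy$edge[, 2]
  B[child] <- nodes$age[phy$edge[, 1]] - nodes$age[child]
  neg <- which(B < -tol)
  if (length(neg))
    stop("age(child) > age(parent) for node(s): ", paste(nodes$id[neg], collapse = ", "))
  B[!is.na(B) & B < 0] <- 0
  if (!is.null(phy$edge.length)) {
    dev <- abs(phy$edge.length - B[child])
    off <- which(dev > max(tol, 1e-9))
    if (length(off))
      stop("branch lengths inconsistent with ages (> tol) at node(s): ",
           paste(labels[child[off]], collapse = ", "))
  }
  phy$edge.length <- B[child]
  nodes$length <- B

  trait_cols <- setdiff(names(nodes),
                        c("node", "id", "parent", "length", "age", "lat", "lon", "is_leaf"))
  nodes <- nodes[, c("node", "id", "parent", "length", "age", "lat", "lon",
                     "is_leaf", trait_cols), drop = FALSE]
  structure(list(phy = phy, nodes = nodes),
            traits = trait_cols, class = "geophylo")
}

#' Load a geo-phylogeny from Newick text plus a node table
#'
#' @param newick a Newick string, or path to a file containing one.  Interior
#'   nodes must be labelled; branch lengths, if present, are checked against
#'   the table's ages (the table is authoritative).
#' @param node_table a data frame, or path to a CSV file, with columns
#'   `id`, `parent`, `age`, `lat`, `lon` and optional trait columns.
#' @inheritParams geophylo
#' @return a [geophylo] object.
#' @export
load_geophylo <- function(newick, node_table, tol = 1e-6) {
  phy <- if (length(newick) == 1 && file.exists(newick)) ape::read.tree(newick)
         else ape::read.tree(text = newick)
  if (is.null(phy)) stop("could not parse Newick input")
  if (is.character(node_table))
    node_table <- utils::read.csv(node_table, stringsAsFactors = FALSE)
  geophylo(phy, node_table, tol = tol)
}

#' Write a geo-phylogeny as Newick + CSV node table
#'
#' @param tree a [geophylo] object.
#' @param newick_path,table_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_geophylo <- function(tree, newick_path, table_path) {
  stopifnot(inherits(tree, "geophylo"))
  ape::write.tree(tree$phy, file = newick_path)
  nd <- tree$nodes
  nd <- nd[, setdiff(names(nd), c("node", "is_leaf", "length")), drop = FALSE]
  utils::write.csv(nd, table_path, row.names = FALSE)
  invisible(c(newick_path, table_path))
}

#' @export
print.geophylo <- function(x, ...) {
  n_tip <- length(x$phy$tip.label)
  cat("geophylo tree:", n_tip, "tips,", x$phy$Nnode, "interior nodes\n")
  cat("  root age:", format(max(x$nodes$age)), "ky BP\n")
  tr <- attr(x, "traits")
  if (length(tr)) cat("  traits:", paste(tr, collapse = ", "), "\n")
  invisible(x)
}

# edge table: one row per edge, ancestor/descendant indices and ids, ages, B
gp_edges <- function(tree) {
  e <- tree$phy$edge
  nd <- tree$nodes
  data.frame(anc = e[, 1], desc = e[, 2],
             anc_id = nd$id[e[, 1]], desc_id = nd$id[e[, 2]],
             age_anc = nd$age[e[, 1]], age_desc = nd$age[e[, 2]],
             length = nd$length[e[, 2]],
             stringsAsFactors = FALSE)
}

# named trait vector (by node id) for all nodes, or leaves only
gp_trait <- function(tree, name, leaves_only = FALSE) {
  nd <- tree$nodes
  if (!name %in% names(nd)) stop("no trait column '", name, "'")
  v <- stats::setNames(nd[[name]], nd$id)
  if (leaves_only) v[nd$is_leaf] else v
}

gp_set_trait <- function(tree, name, values) {
  # values: named by node id (possibly partial)
  nd <- tree$nodes
  if (!name %in% names(nd)) nd[[name]] <- NA_real_
  idx <- match(names(values), nd$id)
  if (anyNA(idx)) stop("unknown node ids in trait values")
  nd[[name]][idx] <- unname(values)
  tree$nodes <- nd
  attr(tree, "traits") <- union(attr(tree, "traits"), name)
  tree
}

#' Cophenetic (path-length) distances between all nodes
#'
#' Sum of branch lengths along the tree path between every pair of nodes,
#' interior nodes included — interior nodes take part in the phylogenetic
#' neighbourhoods used by the diachronic models, so distances among them are
#' needed, not only tip-to-tip distances.
#'
#' @param tree a [geophylo] object.
#' @return a symmetric matrix with node ids as dimnames and attribute
#'   `kind = "cophenetic"`; units are the tree's branch-length units (ky).
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "geophylo"))
  d <- ape::dist.nodes(tree$phy)
  dimnames(d) <- list(tree$nodes$id, tree$nodes$id)
  attr(d, "kind") <- "cophenetic"
  d
}

#' Great-circle distances between all node locations
#'
#' Haversine great-circle distance with Earth radius 6371 km.
#'
#' @param tree a [geophylo] object; every node must carry `lat`/`lon`.
#' @return a symmetric matrix (km) with node ids as dimnames and attribute
#'   `kind = "geographic"`.
#' @export
greatcircle_matrix <- function(tree) {
  stopifnot(inherits(tree, "geophylo"))
  nd <- tree$nodes
  if (any(is.na(nd$lat) | is.na(nd$lon)))
    stop("missing coordinates for node(s): ",
         paste(nd$id[is.na(nd$lat) | is.na(nd$lon)], collapse = ", "))
  d <- geosphere::distm(cbind(nd$lon, nd$lat),
                        fun = function(a, b) geosphere::distHaversine(a, b, r = 6371))
  dimnames(d) <- list(nd$id, nd$id)
  attr(d, "kind") <- "geographic"
  d
}

#' Lineages alive at a time point
#'
#' Returns every edge whose ancestor is older than `t` and whose descendant
#' is at or younger than `t`, together with the proportional position `p` of
#' `t` along the edge (`p = 0` at the ancestor, `p = 1` at the descendant).
#' Trait values or locations of a lineage at that moment are obtained by
#' linear interpolation with `p` (see [interpolate_lineage_value()]).
#'
#' @param tree a [geophylo] object.
#' @param t age in ky BP, within `[0, root age]`.
#' @return data frame with columns `anc_id`, `desc_id`, `p`.
#' @export
lineages_at_time <- function(tree, t) {
  stopifnot(inherits(tree, "geophylo"))
  ed <- gp_edges(tree)
  root_age <- max(tree$nodes$age)
  min_age <- min(tree$nodes$age)
  if (t > root_age || t < min_age)
    stop("t = ", t, " outside tree span [", min_age, ", ", root_age, "]")
  keep <- ed$age_anc > t & ed$age_desc <= t
  ed <- ed[keep, , drop = FALSE]
  p <- ifelse(ed$age_anc == ed$age_desc, 1,
              (ed$age_anc - t) / (ed$age_anc - ed$age_desc))
  data.frame(anc_id = ed$anc_id, desc_id = ed$desc_id, p = p,
             stringsAsFactors = FALSE)
}
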