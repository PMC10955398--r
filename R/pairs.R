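#' Linear interpolation of a lineage value at a proportional time point
#'
#' A lineage alive between an ancestor and a descendant node has its trait
#' (or coordinate) at proportional position `p` along the edge interpolated
#' linearly: `v_anc + p * (v_desc - v_anc)` (`p = 0` at the ancestor,
#' `p = 1` at the descendant).
#'
#' @param p proportional position(s) in `[0, 1]`.
#' @param v_anc,v_desc values at the ancestor and descendant nodes.
#' @return interpolated value(s).
#' @export
interpolate_lineage_value <- function(p, v_anc, v_desc) {
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]")
  v_anc + p * (v_desc - v_anc)
}

#' Build the ancestor-descendant node-pair table
#'
#' One row per positive-length edge of the tree, carrying everything the
#' diachronic causal models condition on: the trait at both ends (observed
#' at leaves, reconstructed with a standard error at interior nodes), the
#' temporal distance `dA` (ky), the mean humidity `H` of the two endpoint
#' locations, and the mean/SD of the trait in the edge's geographic and
#' phylogenetic neighbourhoods:
#' * `Gt_MEAN`/`Gt_SD`: over lineages alive at the reference time (the
#'   descendant node's age by default) whose interpolated location lies
#'   within `geo_radius_km` of the descendant node; lineage trait values and
#'   locations are linearly interpolated along their edge.  The edge's own
#'   lineage is excluded.
#' * `Pt_MEAN`/`Pt_SD`: over all nodes (not filtered for contemporaneity)
#'   within `phylo_radius` cophenetic distance of the descendant node,
#'   excluding the descendant itself and its own ancestor.
#' The covariate columns `H`, `Gt_MEAN`/`Gt_SD`, `Pt_MEAN`/`Pt_SD` are
#' z-scaled by dividing by the sample SD of the column (no centring); the
#' divisors are stored so raw values are recoverable.  Empty neighbourhoods
#' yield a 0/0 (scaled-scale) entry and a flag, so the corresponding
#' model term contributes nothing for that row.
#'
#' @param tree a [geophylo] object.
#' @param reconstruction optional [asr_brownian()] result supplying interior
#'   `T_REC`/`T_SE`; if `NULL`, the tree's own trait column is used at every
#'   node with `T_SE = 0` (appropriate for synthetic data with known
#'   histories).
#' @param trait,humidity column names on the tree.
#' @param geo_radius_km geographic neighbourhood radius (km).
#' @param phylo_radius cophenetic neighbourhood radius; interpreted in the
#'   tree's native branch-length units (`phylo_radius_mode = "native"`) or
#'   as a fraction of the root age (`"fraction_depth"`).
#' @param phylo_radius_mode see above.
#' @param gt_at reference time point for the geographic neighbourhood:
#'   the `"descendant"` node's age (default) or the edge `"midpoint"`.
#' @return a data frame of class `node_pair_table`; attributes `scales`
#'   (named divisors), `dropped` (ids of zero-length edges skipped),
#'   `geo_radius_km`, `phylo_radius` (native units).
#' @export
build_node_pair_table <- function(tree, reconstruction = NULL,
                                  trait = "trait", humidity = "humidity",
                                  geo_radius_km = 500, phylo_radius = 0.02,
                                  phylo_radius_mode = c("native",
                                                        "fraction_depth"),
                                  gt_at = c("descendant", "midpoint")) {
  phylo_radius_mode <- match.arg(phylo_radius_mode)
  gt_at <- match.arg(gt_at)
  stopifnot(inherits(tree, "geophylo"))
  nd <- tree$nodes
  h <- nd[[humidity]]
  if (is.null(h) || anyNA(h)) stop("humidity required for all nodes")

  if (is.null(reconstruction)) {
    tv <- nd[[trait]]
    if (is.null(tv) || anyNA(tv))
      stop("trait required at all nodes when no reconstruction is given")
    tse <- rep(0, nrow(nd))
  } else {
    stopifnot(inherits(reconstruction, "node_reconstruction"))
    idx <- match(nd$id, reconstruction$id)
    if (anyNA(idx)) stop("reconstruction does not cover all nodes")
    tv <- reconstruction$T_REC[idx]
    tse <- reconstruction$T_SE[idx]
  }

  if (phylo_radius_mode == "fraction_depth")
    phylo_radius <- phylo_radius * max(nd$age)
  coph <- cophenetic_matrix(tree)
  ed <- gp_edges(tree)
  dA <- pmax(ed$length, 0)
  keep <- which(dA > 0)
  dropped <- ed$desc_id[dA <= 0]
  parent_of <- stats::setNames(nd$parent, nd$id)

  rows <- lapply(keep, function(k) {
    t_ref <- if (gt_at == "descendant") ed$age_desc[k]
             else (ed$age_anc[k] + ed$age_desc[k]) / 2
    # geographic neighbourhood over contemporaneous lineages
    cross <- which(ed$age_anc > t_ref & ed$age_desc <= t_ref)
    cross <- setdiff(cross, k)
    gt_vals <- numeric(0)
    if (length(cross)) {
      p <- ifelse(ed$age_anc[cross] == ed$age_desc[cross], 1,
                  (ed$age_anc[cross] - t_ref) /
                    (ed$age_anc[cross] - ed$age_desc[cross]))
      lat_i <- interpolate_lineage_value(p, nd$lat[ed$anc[cross]],
                                         nd$lat[ed$desc[cross]])
      lon_i <- interpolate_lineage_value(p, nd$lon[ed$anc[cross]],
                                         nd$lon[ed$desc[cross]])
      dist <- geosphere::distHaversine(
        cbind(lon_i, lat_i),
        cbind(nd$lon[ed$desc[k]], nd$lat[ed$desc[k]]), r = 6371)
      sel <- which(dist <= geo_radius_km)
      if (length(sel))
        gt_vals <- interpolate_lineage_value(p[sel],
                                             tv[ed$anc[cross[sel]]],
                                             tv[ed$desc[cross[sel]]])
    }
    # phylogenetic neighbourhood over nodes (no contemporaneity filter)
    nb <- which(coph[ed$desc[k], ] < phylo_radius)
    nb <- setdiff(nb, c(ed$desc[k], ed$anc[k]))
    pt_vals <- tv[nb]
    data.frame(anc_id = ed$anc_id[k], desc_id = ed$desc_id[k],
               T_anc = tv[ed$anc[k]], T_desc = tv[ed$desc[k]],
               T_anc_se = tse[ed$anc[k]], T_desc_se = tse[ed$desc[k]],
               dA = dA[k],
               H = (h[ed$anc[k]] + h[ed$desc[k]]) / 2,
               Gt_MEAN = if (length(gt_vals)) mean(gt_vals) else 0,
               Gt_SD = if (length(gt_vals) > 1) stats::sd(gt_vals) else 0,
               Pt_MEAN = if (length(pt_vals)) mean(pt_vals) else 0,
               Pt_SD = if (length(pt_vals) > 1) stats::sd(pt_vals) else 0,
               gt_n = length(gt_vals), pt_n = length(pt_vals),
               gt_empty = length(gt_vals) == 0,
               pt_empty = length(pt_vals) == 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  # z-scale (divide by sample SD, no centring); empty rows stay pinned at 0
  scale_of <- function(v, mask = rep(TRUE, length(v))) {
    s <- stats::sd(v[mask])
    if (!isTRUE(s > 0)) 1 else s
  }
  sH <- scale_of(tab$H)
  sG <- scale_of(tab$Gt_MEAN, !tab$gt_empty)
  sP <- scale_of(tab$Pt_MEAN, !tab$pt_empty)
  tab$H <- tab$H / sH
  tab$Gt_MEAN <- tab$Gt_MEAN / sG; tab$Gt_SD <- tab$Gt_SD / sG
  tab$Pt_MEAN <- tab$Pt_MEAN / sP; tab$Pt_SD <- tab$Pt_SD / sP

  structure(tab, scales = c(H = sH, Gt = sG, Pt = sP),
            dropped = dropped, geo_radius_km = geo_radius_km,
            phylo_radius = phylo_radius,
            class = c("node_pair_table", "data.frame"))
}
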