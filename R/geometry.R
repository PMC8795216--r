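#' Binary vessel mask container
#'
#' @param data logical 3D array (TRUE = vessel).
#' @param spacing voxel spacing in mm.
#' @param origin world coordinates of voxel (1, 1, 1).
#' @return An object of class `vessel_mask` (also a `volume3d`).
#' @export
vessel_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3D array")
  storage.mode(data) <- "logical"
  v <- volume3d(data, spacing, origin)
  class(v) <- c("vessel_mask", class(v))
  v
}

#' Segment vessels on the temporal MIP
#'
#' Thresholds the t-MIP at an absolute HU cutoff or an intensity percentile
#' and removes small connected components, or passes a supplied mask through
#' after grid-compatibility checks. Thresholding stands in for learned
#' segmentation: on contrast-enhanced t-MIP data vessels are the brightest
#' structures, and the downstream flow quantification only needs a mask that
#' covers the branches of interest.
#'
#' @param tmip a [volume3d()] temporal MIP.
#' @param method `"threshold"` or `"supplied"`.
#' @param threshold absolute HU cutoff (used when `method = "threshold"`).
#' @param percentile alternative to `threshold`: keep voxels above this
#'   intensity quantile (in `(0, 1)`).
#' @param mask a [vessel_mask()] (used when `method = "supplied"`).
#' @param min_voxels connected components smaller than this are dropped.
#' @return A [vessel_mask()].
#' @export
segment_vessels <- function(tmip, method = c("threshold", "supplied"),
                            threshold = NULL, percentile = NULL,
                            mask = NULL, min_voxels = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(tmip, "volume3d"))
  if (method == "supplied") {
    if (is.null(mask) || !inherits(mask, "vessel_mask"))
      stop("method = 'supplied' requires a vessel_mask in 'mask'")
    if (!identical(dim(mask$data), dim(tmip$data)))
      stop("supplied mask grid does not match the t-MIP grid")
    return(mask)
  }
  if (is.null(threshold)) {
    if (is.null(percentile) || percentile <= 0 || percentile >= 1)
      stop("give an absolute 'threshold' (HU) or a 'percentile' in (0,1)")
    threshold <- stats::quantile(tmip$data, percentile, names = FALSE)
  }
  m <- tmip$data > threshold
  if (!any(m)) stop("empty mask: no voxel exceeds the threshold")
  m <- drop_small_components(m, min_voxels)
  if (!any(m)) stop("empty mask: all components below the size floor")
  vessel_mask(m, tmip$spacing, tmip$origin)
}

## label 26-connected components and drop those below a voxel-count floor
drop_small_components <- function(m, min_voxels) {
  if (min_voxels <= 1L) return(m)
  g <- voxel_graph_internal(m, spacing = c(1, 1, 1))
  if (!length(g$lin)) return(m)
  comp <- igraph::components(g$graph)
  keep_comp <- which(comp$csize >= min_voxels)
  keep <- g$lin[comp$membership %in% keep_comp]
  out <- array(FALSE, dim(m))
  out[keep] <- TRUE
  out
}

#' Restrict a vessel mask to a region of interest
#'
#' Voxelwise AND between the mask and an ROI that delimits the downstream
#' territory of the occluded vessel.
#'
#' @param mask a [vessel_mask()].
#' @param roi logical 3D array or [vessel_mask()] on the same grid.
#' @return A [vessel_mask()].
#' @export
restrict_to_roi <- function(mask, roi) {
  stopifnot(inherits(mask, "vessel_mask"))
  r <- if (inherits(roi, "volume3d")) roi$data else roi
  if (!identical(dim(r), dim(mask$data)))
    stop("ROI grid does not match the mask grid")
  out <- mask$data & (r != 0)
  if (!any(out)) warning("mask is empty after ROI restriction")
  vessel_mask(out, mask$spacing, mask$origin)
}

## build a 26-connectivity voxel graph over the TRUE voxels of a 3D array;
## vertices are named by their linear index, edges carry mm lengths
voxel_graph_internal <- function(arr, spacing) {
  d <- dim(arr)
  lin <- which(arr)
  ijk <- arrayInd(lin, d)
  id <- array(0L, d)
  id[lin] <- seq_along(lin)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] != 0 | offs[, 2] != 0 | offs[, 3] != 0, , drop = FALSE]
  ## half the offsets suffice (each edge found once)
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
               (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- sweep(ijk, 2L, o, "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nid <- id[nb[ok, , drop = FALSE]]
    hit <- nid > 0L
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, nid[hit])
    len <- c(len, rep(sqrt(sum((o * spacing)^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  igraph::V(g)$name <- as.character(lin)
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
    igraph::E(g)$length_mm <- len
  }
  list(graph = g, lin = lin, ijk = ijk, dim = d, spacing = spacing)
}

#' Build a voxel adjacency graph
#'
#' Connects every pair of 26-adjacent TRUE voxels with an edge whose length
#' is the Euclidean distance in mm under the (possibly anisotropic) voxel
#' spacing. Used on skeletons to obtain the centerline graph, and usable on
#' any voxel set.
#'
#' @param mask a [vessel_mask()] or logical 3D array.
#' @param spacing voxel spacing (taken from the mask if it is a
#'   `vessel_mask`).
#' @return An object of class `skeleton_graph`: the igraph graph (vertices
#'   named by linear voxel index, edges weighted by `length_mm`), the voxel
#'   index table, grid dimensions and spacing.
#' @export
voxel_graph <- function(mask, spacing = NULL) {
  if (inherits(mask, "vessel_mask")) {
    spacing <- mask$spacing
    arr <- mask$data
  } else {
    arr <- mask
    if (is.null(spacing)) stop("'spacing' required for a bare array")
  }
  g <- voxel_graph_internal(arr, spacing)
  structure(list(graph = g$graph, lin = g$lin, ijk = g$ijk, dim = g$dim,
                 spacing = spacing, mask = arr),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  deg <- igraph::degree(x$graph)
  cat(sprintf("<skeleton_graph> %d voxels, %d edges; %d endpoints, %d branch nodes\n",
              length(x$lin), igraph::ecount(x$graph),
              sum(deg == 1), sum(deg >= 3)))
  invisible(x)
}

#' Skeletonize a vessel mask
#'
#' Reduces the binary mask to a one-voxel-wide centerline by iterative
#' morphological thinning: border voxels are removed in increasing
#' distance-transform order whenever removal preserves the 26-connected
#' foreground / 6-connected background topology and the voxel is not a curve
#' endpoint. The thinning therefore preserves the number of connected
#' components exactly. Short side twigs created by surface irregularities
#' (spurs) are pruned afterwards.
#'
#' @param mask a [vessel_mask()].
#' @param spur_mm skeleton branches shorter than this with a free endpoint
#'   are pruned (set to 0 to disable).
#' @return A [voxel_graph()] over the skeleton voxels (class
#'   `skeleton_graph`); the source mask is kept in `$mask_full` for path-cost
#'   normalization.
#' @export
skeletonize <- function(mask, spur_mm = 3) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (!any(mask$data)) stop("cannot skeletonize an empty mask")
  skel <- cpp_thin3d(as.logical(mask$data), dim(mask$data))
  dim(skel) <- dim(mask$data)
  g <- voxel_graph(vessel_mask(skel, mask$spacing, mask$origin))
  if (spur_mm > 0) g <- prune_spurs(g, spur_mm)
  g$mask_full <- mask$data
  g
}

## remove skeleton twigs: chains from a free endpoint to the first branch
## node, shorter than spur_mm; whole isolated chains are never removed
prune_spurs <- function(sg, spur_mm) {
  g <- sg$graph
  repeat {
    deg <- igraph::degree(g)
    eps <- which(deg == 1)
    drop <- integer(0)
    for (e in eps) {
      chain <- e
      cur <- e
      prev <- -1L
      len <- 0
      repeat {
        nbs <- as.integer(igraph::neighbors(g, cur))
        nxt <- setdiff(nbs, prev)
        if (length(nxt) != 1L) { cur <- NA_integer_; break }  # isolated chain end
        eid <- igraph::get_edge_ids(g, c(cur, nxt[1]))
        len <- len + igraph::E(g)$length_mm[eid]
        prev <- cur
        cur <- nxt[1]
        if (deg[cur] >= 3L) break           # reached a junction
        if (deg[cur] == 1L) { cur <- NA_integer_; break }  # other endpoint
        chain <- c(chain, cur)
        if (len >= spur_mm) { cur <- NA_integer_; break }
      }
      if (!is.na(cur) && len < spur_mm) drop <- union(drop, chain)
    }
    if (!length(drop)) break
    g <- igraph::delete_vertices(g, drop)
  }
  keep_lin <- as.integer(igraph::V(g)$name)
  sel <- match(keep_lin, sg$lin)
  sg$graph <- g
  sg$lin <- sg$lin[sel]
  sg$ijk <- sg$ijk[sel, , drop = FALSE]
  arr <- array(FALSE, sg$dim)
  arr[sg$lin] <- TRUE
  sg$mask <- arr
  sg
}

## map a voxel (ijk 1-based or linear index) to a graph vertex id, or NA
node_of <- function(sg, voxel) {
  lin <- if (length(voxel) == 3L)
    voxel[1] + dim_offset(sg$dim, voxel) else as.integer(voxel)
  match(lin, sg$lin)
}

dim_offset <- function(d, ijk) {
  (ijk[2] - 1L) * d[1] + (ijk[3] - 1L) * d[1] * d[2]
}

## per-edge intensity-weighted cost on the t-MIP:
## length_mm * (I_max - mean(I_u, I_v) + eps)
edge_costs <- function(tmip, sg, eps = 1) {
  I <- tmip$data[sg$lin]
  over <- if (!is.null(sg$mask_full)) sg$mask_full else sg$mask
  I_max <- max(tmip$data[over])
  ends <- igraph::ends(sg$graph, igraph::E(sg$graph), names = FALSE)
  igraph::E(sg$graph)$length_mm *
    (I_max - (I[ends[, 1]] + I[ends[, 2]]) / 2 + eps)
}

#' Minimum-cost centerline path
#'
#' Finds the path through the skeleton graph minimizing the total
#' intensity-weighted cost, where each edge costs
#' `length_mm * (I_max - mean(I_u, I_v) + eps)` with intensities `I` taken
#' from the t-MIP and `I_max` its maximum over the vessel mask. High
#' t-MIP intensity (well-enhanced lumen) therefore attracts the path, while
#' the length factor penalizes detours. Ties between equal-cost routes are
#' broken deterministically toward the lexicographically smallest voxel
#' index at each step.
#'
#' @param tmip a [volume3d()] temporal MIP.
#' @param graph a [skeleton_graph()].
#' @param src,dst voxel coordinates (1-based `c(i, j, k)`) or linear indices;
#'   must be graph nodes.
#' @param eps positive cost guard (HU) keeping all edge costs > 0.
#' @return A data.frame of class `centerline_path` with columns `ordinal`,
#'   `i`, `j`, `k`, `arclength_mm`; total cost in `attr(, "cost")`.
#' @export
min_cost_path <- function(tmip, graph, src, dst, eps = 1) {
  stopifnot(inherits(graph, "skeleton_graph"), inherits(tmip, "volume3d"))
  vs <- node_of(graph, src)
  vd <- node_of(graph, dst)
  if (is.na(vs)) stop("'src' is not a graph node")
  if (is.na(vd)) stop("'dst' is not a graph node")
  w <- edge_costs(tmip, graph, eps)
  g <- graph$graph
  d_src <- as.numeric(igraph::distances(g, v = vs, weights = w))
  total <- d_src[vd]
  if (!is.finite(total))
    stop("no path: source and destination are in different components")
  d_dst <- as.numeric(igraph::distances(g, v = vd, weights = w))
  tol <- 1e-9 * max(1, total)
  ## greedy reconstruction along cost-optimal successors, smallest voxel
  ## index first (deterministic tie-break)
  path <- vs
  cur <- vs
  guard <- length(graph$lin) + 1L
  while (cur != vd) {
    nbs <- as.integer(igraph::neighbors(g, cur))
    eid <- igraph::get_edge_ids(g, rbind(cur, nbs))
    ok <- abs(d_src[cur] + w[eid] - d_src[nbs]) <= tol &
          abs(d_src[nbs] + d_dst[nbs] - total) <= tol
    cand <- nbs[ok]
    if (!length(cand)) stop("internal error: path reconstruction failed")
    cur <- cand[which.min(graph$lin[cand])]
    path <- c(path, cur)
    if (length(path) > guard) stop("internal error: path reconstruction cycled")
    }
  ijk <- graph$ijk[path, , drop = FALSE]
  steps <- sqrt(rowSums((sweep(diff(ijk), 2L, graph$spacing, "*"))^2))
  out <- data.frame(ordinal = seq_along(path), i = ijk[, 1], j = ijk[, 2],
                    k = ijk[, 3], arclength_mm = c(0, cumsum(steps)))
  class(out) <- c("centerline_path", "data.frame")
  attr(out, "cost") <- total
  attr(out, "nodes") <- graph$lin[path]
  attr(out, "spacing") <- graph$spacing
  out
}

#' Marker set
#'
#' Reference markers naming the proximal branch, the thrombus, and one or
#' more distal branches of interest. Coordinates are 1-based voxel indices
#' at the R level; marker JSON files on disk use 0-based indices
#' (see [read_markers()]).
#'
#' @param proximal,thrombus voxel `c(i, j, k)`.
#' @param distal list of voxel coordinates, one per distal branch.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(proximal, thrombus, distal) {
  if (!is.list(distal)) distal <- list(distal)
  if (!length(distal)) stop("at least one distal marker is required")
  chk <- function(p, nm) {
    if (length(p) != 3L || any(p < 1))
      stop(sprintf("marker '%s' must be a 1-based voxel index triple", nm))
    as.integer(p)
  }
  structure(list(proximal = chk(proximal, "proximal"),
                 thrombus = chk(thrombus, "thrombus"),
                 distal = lapply(seq_along(distal), function(i)
                   chk(distal[[i]], paste0("distal[", i, "]")))),
            class = "marker_set")
}

## snap a marker to the nearest skeleton node within `radius` voxels
## (Euclidean distance compared in mm); tie -> lowest linear index
snap_marker <- function(sg, voxel, radius, name) {
  dv <- sweep(sg$ijk, 2L, as.integer(voxel), "-")
  cheb <- pmax(abs(dv[, 1]), abs(dv[, 2]), abs(dv[, 3]))
  cand <- which(cheb <= radius)
  if (!length(cand))
    stop(sprintf("marker '%s' at (%s) has no skeleton node within %d voxels",
                 name, paste(voxel, collapse = ","), radius))
  dmm <- sqrt(rowSums(sweep(dv[cand, , drop = FALSE], 2L, sg$spacing, "*")^2))
  best <- cand[dmm <= min(dmm) + 1e-12]
  best[which.min(sg$lin[best])]
}

#' Assemble marker-guided centerline paths
#'
#' Builds one path per distal marker, routed proximal -> thrombus -> distal
#' through minimum-cost tracing, labels each voxel by leg (proximal /
#' thrombus / distal) and partitions the distal legs into mother and
#' daughter segments at the branch nodes where the paths diverge. With a
#' single distal path and no bifurcation the whole distal leg forms one
#' daughter segment.
#'
#' @param tmip a [volume3d()] temporal MIP.
#' @param graph a [skeleton_graph()] from [skeletonize()].
#' @param markers a [marker_set()].
#' @param snap_radius marker snap radius in voxels.
#' @param eps cost guard passed to [min_cost_path()].
#' @return A list of `centerline_path` data.frames (columns `path_id`,
#'   `ordinal`, `i`, `j`, `k`, `arclength_mm`, `label`, `segment_id`).
#' @export
assemble_paths <- function(tmip, graph, markers, snap_radius = 3L, eps = 1) {
  stopifnot(inherits(markers, "marker_set"))
  vprox <- snap_marker(graph, markers$proximal, snap_radius, "proximal")
  vthr <- snap_marker(graph, markers$thrombus, snap_radius, "thrombus")
  vdist <- lapply(seq_along(markers$distal), function(i)
    snap_marker(graph, markers$distal[[i]], snap_radius,
                paste0("distal[", i, "]")))
  leg1 <- min_cost_path(tmip, graph, graph$lin[vprox], graph$lin[vthr], eps)
  leg1_nodes <- attr(leg1, "nodes")
  legs2 <- lapply(seq_along(vdist), function(i) {
    p <- min_cost_path(tmip, graph, graph$lin[vthr], graph$lin[vdist[[i]]], eps)
    nd <- attr(p, "nodes")
    if (nd[length(nd)] %in% leg1_nodes[-length(leg1_nodes)])
      stop(sprintf("distal marker %d lies proximal to the thrombus marker", i))
    p
  })
  segids <- partition_daughters(lapply(legs2, attr, "nodes"))
  paths <- vector("list", length(legs2))
  for (p in seq_along(legs2)) {
    l1 <- leg1; l2 <- legs2[[p]]
    n1 <- nrow(l1); n2 <- nrow(l2)
    lab <- c(rep("proximal", n1 - 1L), "thrombus", rep("distal", n2 - 1L))
    seg <- c(rep("proximal", n1 - 1L), "thrombus", segids[[p]][-1L])
    ijk <- rbind(as.matrix(l1[, c("i", "j", "k")]),
                 as.matrix(l2[-1L, c("i", "j", "k")]))
    steps <- sqrt(rowSums((sweep(diff(ijk), 2L, graph$spacing, "*"))^2))
    df <- data.frame(path_id = p, ordinal = seq_len(nrow(ijk)),
                     i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                     arclength_mm = c(0, cumsum(steps)),
                     label = lab, segment_id = seg,
                     stringsAsFactors = FALSE)
    class(df) <- c("centerline_path", "data.frame")
    attr(df, "nodes") <- c(leg1_nodes, attr(l2, "nodes")[-1L])
    attr(df, "spacing") <- graph$spacing
    paths[[p]] <- df
  }
  paths
}

## Partition the distal legs (node-index sequences, all starting at the
## thrombus node) into shared/divergent runs. The run shared by all paths is
## "mother"; every other run is "daughterN" in order of first appearance.
## A single path yields one "daughter1" run.
partition_daughters <- function(node_seqs) {
  np <- length(node_seqs)
  out <- lapply(node_seqs, function(s) rep(NA_character_, length(s)))
  counter <- new.env()
  counter$n <- 0L
  next_daughter <- function() {
    counter$n <- counter$n + 1L
    paste0("daughter", counter$n)
  }
  recurse <- function(idx, start) {
    ## longest common run from `start` among paths idx
    lens <- vapply(node_seqs[idx], length, 1L)
    t <- start
    while (TRUE) {
      if (any(lens < t)) break
      v <- vapply(idx, function(p) node_seqs[[p]][t], 1)
      if (length(unique(v)) != 1L) break
      t <- t + 1L
    }
    stop_t <- t - 1L
    name <- if (length(idx) == np && np > 1L) "mother" else next_daughter()
    if (stop_t >= start)
      for (p in idx) out[[p]][start:stop_t] <<- name
    ## split by the next node
    alive <- idx[vapply(idx, function(p) length(node_seqs[[p]]) >= t, TRUE)]
    if (!length(alive)) return(invisible())
    nxt <- vapply(alive, function(p) node_seqs[[p]][t], 1)
    for (v in sort(unique(nxt)))
      recurse(alive[nxt == v], t)
    invisible()
  }
  recurse(seq_len(np), 1L)
  ## the thrombus node itself heads every leg; keep its run label
  out
}
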