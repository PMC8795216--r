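test_that("threshold segmentation recovers the phantom mask", {
  spec <- straight_tube_spec(5, noise_sigma = 0)
  r <- rasterize_tree(spec)
  tm <- compute_tmip(render_dynamic(spec, r))
  m <- segment_vessels(tm, threshold = 40 + 200)  # background + half amplitude
  truth <- r$mask$data
  ## covers at least 95% of the true mask
  expect_gte(sum(m$data & truth) / sum(truth), 0.95)
  ## contained in the truth dilated by one voxel
  dil <- truth
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    sh <- flowtrace:::shift_array3(truth, o); sh[is.na(sh)] <- FALSE
    dil <- dil | (sh > 0)
  }
  expect_true(all(dil[m$data]))
  ## a threshold above the global maximum is an explicit failure
  expect_error(segment_vessels(tm, threshold = max(tm$data) + 1), "empty mask")
  ## supplied masks pass through unchanged after grid checks
  expect_identical(segment_vessels(tm, "supplied", mask = r$mask), r$mask)
  wrong <- vessel_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  expect_error(segment_vessels(tm, "supplied", mask = wrong), "grid")
})

test_that("ROI restriction is a voxelwise AND", {
  spec <- y_tree_spec()
  r <- rasterize_tree(spec)
  expect_identical(restrict_to_roi(r$mask, array(TRUE, dim(r$mask$data)))$data,
                   r$mask$data)
  expect_warning(out <- restrict_to_roi(r$mask, array(FALSE, dim(r$mask$data))),
                 "empty")
  expect_false(any(out$data))
  ## half-space ROI keeps exactly the centerline points inside it
  roi <- array(FALSE, dim(r$mask$data)); roi[1:20, , ] <- TRUE  # x < 20 voxels
  cut <- restrict_to_roi(r$mask, roi)
  cl <- r$centerline
  inside <- cl$x_mm <= 18  # one voxel margin off the cut plane
  ijk <- cbind(round(cl$x_mm) + 1L, round(cl$y_mm) + 1L, round(cl$z_mm) + 1L)
  expect_true(all(cut$data[ijk[inside, , drop = FALSE]]))
  outside <- cl$x_mm >= 20
  expect_false(any(cut$data[ijk[outside, , drop = FALSE]]))
})

test_that("skeleton of a straight tube is a centered chain", {
  seg <- vessel_segment(c(5, 6, 6), c(45, 6, 6), radius_mm = 2,
                        velocity_mm_s = 5)
  spec <- phantom_spec(c(50, 13, 13), segments = list(seg), noise_sigma = 0)
  r <- rasterize_tree(spec)
  g <- skeletonize(r$mask)
  deg <- igraph::degree(g$graph)
  expect_true(all(deg <= 2))
  expect_equal(sum(deg == 1), 2L)
  ## endpoints within 3 voxels of the tube ends
  eps <- g$ijk[deg == 1, , drop = FALSE]
  ends <- rbind(c(6, 7, 7), c(46, 7, 7))
  for (r_i in 1:2)
    expect_lte(min(sqrt(rowSums(sweep(eps, 2, ends[r_i, ])^2))), 3)
  ## every skeleton voxel within 1.5 voxels of the true axis
  off_axis <- sqrt((g$ijk[, 2] - 7)^2 + (g$ijk[, 3] - 7)^2)
  expect_lte(max(off_axis), 1.5)
})

test_that("skeletonization handles degenerate and branching masks", {
  ## single isolated voxel survives
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  g1 <- skeletonize(vessel_mask(m1, c(1, 1, 1)))
  expect_equal(g1$ijk, matrix(c(3L, 3L, 3L), 1))
  ## Y-tree: 3 endpoints and a single degree-3 branch node after pruning
  gy <- skeletonize(rasterize_tree(y_tree_spec())$mask)
  degy <- igraph::degree(gy$graph)
  expect_equal(sum(degy == 1), 3L)
  expect_equal(sum(degy >= 3), 1L)
  ## connected-component count is preserved on random blobs
  for (s in 1:5) {
    set.seed(s)
    m <- array(FALSE, c(14, 14, 14))
    for (b in 1:3) {
      c0 <- sample(3:12, 3)
      m[(c0[1]-2):(c0[1]+2), (c0[2]-2):(c0[2]+2), (c0[3]-1):(c0[3]+1)] <- TRUE
    }
    vm <- vessel_mask(m, c(1, 1, 1))
    n_before <- igraph::components(voxel_graph(vm)$graph)$no
    n_after <- igraph::components(skeletonize(vm, spur_mm = 0)$graph)$no
    expect_equal(n_after, n_before)
  }
})

test_that("minimum-cost paths follow bright voxels and match a Dijkstra oracle", {
  ## uniform-intensity straight chain: the path is the chain itself
  m <- array(FALSE, c(20, 3, 3)); m[2:19, 2, 2] <- TRUE
  g <- voxel_graph(m, spacing = c(1, 1, 1))
  tm <- volume3d(array(100, c(20, 3, 3)), c(1, 1, 1))
  p <- min_cost_path(tm, g, c(2, 2, 2), c(19, 2, 2))
  expect_equal(nrow(p), 18L)
  expect_equal(max(p$arclength_mm), 17)
  ## bright S-curve on a planar grid: path follows the curve exactly
  d <- c(20, 20, 1)
  arr <- array(TRUE, d)
  intens <- array(50, d)
  scurve <- rbind(cbind(2:16, 3), cbind(16, 4:9), cbind(16:4, 10),
                  cbind(4, 11:16), cbind(4:19, 17))
  intens[cbind(scurve, 1)] <- 400
  gg <- voxel_graph(arr, spacing = c(1, 1, 1))
  tmip2 <- volume3d(intens, c(1, 1, 1))
  pp <- min_cost_path(tmip2, gg, c(2, 3, 1), c(19, 17, 1))
  on_curve <- paste(pp$i, pp$j) %in% paste(scurve[, 1], scurve[, 2])
  expect_true(all(on_curve))
  ## total cost agrees with the independent Bellman-Ford oracle
  w <- flowtrace:::edge_costs(tmip2, gg)
  ends <- igraph::ends(gg$graph, igraph::E(gg$graph), names = FALSE)
  src <- which(gg$lin == pp$i[1] + (pp$j[1] - 1) * 20)
  dst <- which(gg$lin == pp$i[nrow(pp)] + (pp$j[nrow(pp)] - 1) * 20)
  dist <- oracle_shortest_dist(ends[, 1], ends[, 2], w, length(gg$lin), src)
  expect_equal(attr(pp, "cost"), dist[dst], tolerance = 1e-10)
  ## disconnected endpoints fail loudly
  m2 <- array(FALSE, c(10, 3, 3)); m2[2:4, 2, 2] <- TRUE; m2[7:9, 2, 2] <- TRUE
  g2 <- voxel_graph(m2, spacing = c(1, 1, 1))
  tm2 <- volume3d(array(100, c(10, 3, 3)), c(1, 1, 1))
  expect_error(min_cost_path(tm2, g2, c(2, 2, 2), c(9, 2, 2)), "no path")
})

test_that("path costs equal the oracle on many random instances", {
  for (s in 1:100) {
    inst <- random_voxel_instance(s)
    g <- inst$graph
    if (length(g$lin) < 2L || !igraph::ecount(g$graph)) next
    comp <- igraph::components(g$graph)
    big <- which.max(comp$csize)
    nodes <- which(comp$membership == big)
    if (length(nodes) < 2L) next
    src <- nodes[1]; dst <- nodes[length(nodes)]
    p <- min_cost_path(inst$tmip, g, g$lin[src], g$lin[dst])
    w <- flowtrace:::edge_costs(inst$tmip, g)
    ends <- igraph::ends(g$graph, igraph::E(g$graph), names = FALSE)
    dist <- oracle_shortest_dist(ends[, 1], ends[, 2], w, length(g$lin), src)
    expect_equal(attr(p, "cost"), dist[dst], tolerance = 1e-9)
  }
})

test_that("equal-cost routes break ties deterministically", {
  ## a 2x2 planar loop has two equal-cost routes between opposite corners
  m <- array(FALSE, c(4, 4, 1)); m[2:3, 2:3, 1] <- TRUE
  g <- voxel_graph(m, spacing = c(1, 1, 1))
  tm <- volume3d(array(100, c(4, 4, 1)), c(1, 1, 1))
  p1 <- min_cost_path(tm, g, c(2, 2, 1), c(3, 3, 1))
  p2 <- min_cost_path(tm, g, c(2, 2, 1), c(3, 3, 1))
  expect_identical(p1, p2)
  ## the diagonal is shorter here; force the tie with a 4-neighbour detour
  expect_equal(nrow(p1), 2L)
})

test_that("marker-guided paths partition into mother and daughters", {
  spec <- y_tree_spec()
  r <- rasterize_tree(spec)
  dyn <- render_dynamic(spec, r)
  tm <- compute_tmip(dyn)
  g <- skeletonize(segment_vessels(tm, threshold = 120))
  paths <- assemble_paths(tm, g, y_tree_markers())
  expect_length(paths, 2L)
  for (p in paths) {
    expect_true(all(diff(p$arclength_mm) > 0))
    expect_equal(sum(p$label == "thrombus"), 1L)
    expect_true(all(c("proximal", "distal") %in% p$label))
  }
  ## the two paths share the mother prefix and diverge at the branch node
  n1 <- attr(paths[[1]], "nodes"); n2 <- attr(paths[[2]], "nodes")
  shared <- sum(cumprod(n1[seq_len(min(length(n1), length(n2)))] ==
                        n2[seq_len(min(length(n1), length(n2)))]))
  div_node <- n1[shared]
  deg <- igraph::degree(g$graph)
  expect_gte(deg[which(g$lin == div_node)], 3)
  expect_true(all(c("mother", "daughter1") %in% paths[[1]]$segment_id |
                  c("mother", "daughter2") %in% paths[[1]]$segment_id))
  ## single distal marker: whole distal leg is one daughter segment
  single <- assemble_paths(tm, g, marker_set(c(6, 21, 9), c(15, 21, 9),
                                             list(c(32, 29, 9))))
  expect_length(single, 1L)
  segs <- unique(single[[1]]$segment_id)
  expect_true("daughter1" %in% segs)
  expect_false("mother" %in% segs)
  ## a distal marker proximal to the thrombus is a validation error
  expect_error(assemble_paths(tm, g, marker_set(c(6, 21, 9), c(15, 21, 9),
                                                list(c(8, 21, 9)))),
               "proximal to the thrombus")
  ## markers far from any skeleton voxel fail, naming the marker
  expect_error(assemble_paths(tm, g, marker_set(c(6, 21, 9), c(15, 21, 9),
                                                list(c(38, 38, 16)))),
               "distal\\[1\\]")
})

test_that("paths depend only on the t-MIP, not the frame order", {
  spec <- y_tree_spec(noise_sigma = 5, seed = 2)
  dyn <- render_dynamic(spec)
  perm <- sample(seq_len(dim(dyn$data)[4]))
  dyn2 <- dynamic_cta(dyn$data[, , , perm], dyn$spacing, dyn$dt)
  tm1 <- compute_tmip(dyn); tm2 <- compute_tmip(dyn2)
  g1 <- skeletonize(segment_vessels(tm1, threshold = 120))
  g2 <- skeletonize(segment_vessels(tm2, threshold = 120))
  p1 <- assemble_paths(tm1, g1, y_tree_markers())
  p2 <- assemble_paths(tm2, g2, y_tree_markers())
  expect_identical(lapply(p1, as.data.frame), lapply(p2, as.data.frame))
})

test_that("arc-length of straight-tube paths approximates segment length", {
  spec <- straight_tube_spec(5, noise_sigma = 0)
  r <- rasterize_tree(spec)
  tm <- compute_tmip(render_dynamic(spec, r))
  g <- skeletonize(r$mask)
  deg <- igraph::degree(g$graph)
  ep <- which(deg == 1)
  p <- min_cost_path(tm, g, g$lin[ep[1]], g$lin[ep[2]])
  expect_lt(abs(max(p$arclength_mm) - 50) / 50, 0.15)
})
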