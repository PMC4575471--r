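# Automated bleeder detection & localization (D&L) from compounded
# power-Doppler volumes: segmentation -> skeleton centerlines ->
# bifurcations -> spectral-Doppler gates -> resistive index -> classification.

# Otsu's threshold on a numeric vector (maximizes between-class variance).
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (!length(x)) return(Inf)
  if (diff(range(x)) == 0) return(x[1] / 2)   # constant foreground vs zero
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(w); w2 <- 1 - w1
  mu <- cumsum(w * mids)
  muT <- mu[length(mu)]
  sb <- (muT * w1 - mu)^2 / (w1 * w2)
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Segment vessels from a power-Doppler volume
#'
#' Thresholds the volume (Otsu's method on the nonzero intensities by
#' default, or a fixed threshold) and removes connected components smaller
#' than `min_component_voxels` (26-connectivity). An empty volume yields an
#' empty mask, not an error.
#'
#' @param vol a `doppler_volume`.
#' @param threshold_mode "otsu" or "fixed".
#' @param threshold fixed threshold (intensity units) when
#'   `threshold_mode = "fixed"`.
#' @param min_component_voxels speckle-rejection size (voxels).
#' @param close_radius_vox morphological closing radius (voxels) applied
#'   before component filtering; fills noise-induced pinholes and tunnels
#'   that would otherwise become spurious skeleton cycles. 0 disables.
#' @return logical 3D array (same dims as the volume) with attributes
#'   `voxel_size` and `origin`.
#' @export
segment_vessels <- function(vol, threshold_mode = c("otsu", "fixed"),
                            threshold = NULL, min_component_voxels = 20,
                            close_radius_vox = 1) {
  threshold_mode <- match.arg(threshold_mode)
  g <- vol$grid
  thr <- if (threshold_mode == "fixed") threshold
         else otsu_threshold(g[g > 0])
  mask <- array(g > thr, dim(g))
  if (any(mask) && close_radius_vox > 0) {
    d <- dim(mask)
    dil <- cpp_chamfer_dt(!as.logical(mask), d[1], d[2], d[3]) <= close_radius_vox
    mask <- array(cpp_chamfer_dt(dil, d[1], d[2], d[3]) > close_radius_vox, d)
  }
  if (any(mask) && min_component_voxels > 1) {
    d <- dim(mask)
    lab <- cpp_label3d(as.logical(mask), d[1], d[2], d[3])
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component_voxels)
    mask <- array(lab %in% keep, d)
  }
  attr(mask, "voxel_size") <- vol$voxel_size
  attr(mask, "origin") <- vol$origin
  mask
}

#' Extract vessel centerlines from a binary mask
#'
#' 3D topological thinning (ordered by the chamfer distance transform,
#' endpoint-preserving) reduces the lumen mask to a curve skeleton, which
#' is converted to a graph of polyline edges between junction and endpoint
#' nodes. Spurs shorter than `spur_mm` are pruned and junction voxels
#' within `merge_mm` are merged into single bifurcation nodes. Edge radii
#' are estimated from the distance transform along the polyline.
#'
#' @param mask logical array from [segment_vessels()] (carries voxel size
#'   and origin attributes), or any logical array if `voxel_size`/`origin`
#'   are given.
#' @param voxel_size_mm,origin_mm grid geometry overrides.
#' @param spur_mm prune terminal spurs shorter than this.
#' @param merge_mm merge junction nodes within this radius.
#' @return object of class `centerline_graph`: `nodes` (n x 3 mm),
#'   `degree`, `edges` (list with `from`, `to`, `points`, `length_mm`,
#'   `radius_mm`).
#' @export
extract_centerlines <- function(mask, voxel_size_mm = NULL, origin_mm = NULL,
                                spur_mm = 2, merge_mm = 1.5) {
  vs <- if (is.null(voxel_size_mm)) attr(mask, "voxel_size") else voxel_size_mm
  org <- if (is.null(origin_mm)) attr(mask, "origin") else origin_mm
  if (is.null(vs) || is.null(org)) stop("mask lacks voxel_size/origin")
  if (!any(mask)) stop("empty mask: no vessels to trace")
  d <- dim(mask)
  dt <- cpp_chamfer_dt(as.logical(mask), d[1], d[2], d[3])
  skel <- array(cpp_skeletonize3d(as.logical(mask), dt, d[1], d[2], d[3]), d)
  dt <- array(dt, d)

  repeat {
    g <- skeleton_graph(skel, d)
    if (is.null(g)) stop("skeletonization produced no voxels")
    # prune short terminal spur chains, then re-derive
    chains <- chain_decomposition(g)
    spur <- vapply(chains, function(ch) {
      free_end <- any(!ch$junction_ends)
      free_end && ch$length_vox * vs < spur_mm && length(chains) > 1
    }, TRUE)
    if (!any(spur)) break
    for (ch in chains[spur]) {
      drop <- setdiff(ch$vox, g$junction_vox)
      skel[g$idx[drop]] <- FALSE
    }
  }

  build_centerline_graph(g, chains, dt, vs, org, merge_mm)
}

# Build voxel-level skeleton adjacency. Returns list(idx = linear indices,
# coords, adj = igraph, deg, junction_vox = vertex ids with degree >= 3).
skeleton_graph <- function(skel, d) {
  idx <- which(skel)
  if (!length(idx)) return(NULL)
  coords <- arrayInd(idx, d)
  key <- integer(prod(d))
  key[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ed <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[r, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
          nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    lin <- rep(0L, nrow(coords))
    lin[ok] <- nb[ok, 1] + d[1] * ((nb[ok, 2] - 1) + d[2] * (nb[ok, 3] - 1))
    tgt <- ifelse(ok & lin > 0, key[pmax(lin, 1)], 0L)
    hit <- which(tgt > 0 & tgt > seq_along(idx))  # i < j once
    if (length(hit)) ed[[length(ed) + 1]] <- cbind(hit, tgt[hit])
  }
  em <- if (length(ed)) do.call(rbind, ed) else matrix(0L, 0, 2)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  deg <- igraph::degree(g)
  list(idx = idx, coords = coords, g = g, deg = deg,
       junction_vox = which(deg >= 3))
}

# Decompose the skeleton into chains (maximal paths of degree <= 2 voxels),
# each annotated with its attached junction voxels.
chain_decomposition <- function(sg) {
  g <- sg$g; deg <- sg$deg
  nonj <- which(deg < 3)
  sub <- igraph::induced_subgraph(g, nonj)
  comp <- igraph::components(sub)
  chains <- list()
  for (ci in seq_len(comp$no)) {
    vs_sub <- which(comp$membership == ci)
    vox <- nonj[vs_sub]
    # order along the path
    if (length(vox) == 1) {
      path <- vox
    } else {
      s2 <- igraph::induced_subgraph(g, vox)
      dsub <- igraph::degree(s2)
      ends <- which(dsub <= 1)
      if (length(ends) < 2) { # cycle: break arbitrarily
        path <- vox[as.integer(igraph::dfs(s2, root = 1)$order)]
      } else {
        p <- igraph::shortest_paths(s2, from = ends[1], to = ends[2])$vpath[[1]]
        path <- vox[as.integer(p)]
      }
    }
    # junction attachments at both ends
    jstart <- intersect(as.integer(igraph::neighbors(g, path[1])), sg$junction_vox)
    jend <- intersect(as.integer(igraph::neighbors(g, path[length(path)])),
                      sg$junction_vox)
    chains[[length(chains) + 1]] <- list(
      vox = path,
      j_start = if (length(jstart)) jstart[1] else NA_integer_,
      j_end = if (length(jend)) jend[1] else NA_integer_,
      junction_ends = c(length(jstart) > 0, length(jend) > 0),
      length_vox = length(path))
  }
  chains
}

build_centerline_graph <- function(sg, chains, dt, vs, org, merge_mm) {
  pos <- sweep((sg$coords - 0.5) * vs, 2, org, `+`)
  # cluster junction voxels within merge_mm (single linkage via graph)
  jv <- sg$junction_vox
  jcluster <- integer(0)
  jcenters <- matrix(0, 0, 3)
  if (length(jv) > 5000)
    stop(sprintf("implausible skeleton: %d junction voxels (noise-dominated mask?)",
                 length(jv)))
  if (length(jv)) {
    jp <- pos[jv, , drop = FALSE]
    dm <- as.matrix(stats::dist(jp))
    adj <- dm <= max(merge_mm, vs * 1.8)
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              diag = FALSE)
    cl <- igraph::components(gg)$membership
    jcluster <- cl
    jcenters <- t(vapply(seq_len(max(cl)), function(k)
      colMeans(jp[cl == k, , drop = FALSE]), numeric(3)))
  }
  node_of_jvox <- function(v) match(v, jv)  # -> cluster via jcluster

  nodes <- jcenters
  node_kind <- rep("junction", nrow(jcenters))
  edges <- list()
  for (ch in chains) {
    pts <- pos[ch$vox, , drop = FALSE]
    from <- NA_integer_; to <- NA_integer_
    if (!is.na(ch$j_start)) {
      from <- jcluster[node_of_jvox(ch$j_start)]
      pts <- rbind(nodes[from, ], pts)
    } else {
      nodes <- rbind(nodes, pts[1, ]); node_kind <- c(node_kind, "end")
      from <- nrow(nodes)
    }
    if (!is.na(ch$j_end)) {
      to <- jcluster[node_of_jvox(ch$j_end)]
      pts <- rbind(pts, nodes[to, ])
    } else {
      nodes <- rbind(nodes, pts[nrow(pts), ]); node_kind <- c(node_kind, "end")
      to <- nrow(nodes)
    }
    L <- polyline_length(pts)
    if (from == to && L < 2 * max(merge_mm, vs)) next  # degenerate loop
    rad <- mean(dt[sg$idx[ch$vox]]) * vs
    # thin self-loop handles are segmentation-noise tunnels, not vessels
    if (from == to && rad < 1.6 * vs) next
    if (L == 0) next
    rad <- mean(dt[sg$idx[ch$vox]]) * vs
    edges[[length(edges) + 1]] <- list(from = from, to = to, points = pts,
                                       length_mm = L, radius_mm = rad)
  }
  g <- simplify_centerline_graph(nodes, edges, vs, merge_mm)
  structure(c(g, list(voxel_size = vs)), class = "centerline_graph")
}

# Graph-level cleanup of skeletonization artefacts:
#   (1) contract edges between junction nodes shorter than merge_mm and
#       short parallel double-edges (loops the thinning leaves around
#       thick junctions);
#   (2) dissolve degree-2 nodes by merging their edge pair;
#   (3) prune terminal edges that are below the spur length or are much
#       thinner than the vessel they attach to (noise whiskers), while
#       keeping genuine thin long branches.
simplify_centerline_graph <- function(nodes, edges, vs, merge_mm,
                                      spur_mm = 2, loop_mm = 10) {
  contract <- function(keep, drop) {
    nodes[keep, ] <<- colMeans(nodes[c(keep, drop), , drop = FALSE])
    edges <<- lapply(edges, function(ed) {
      if (ed$from == drop) ed$from <- keep
      if (ed$to == drop) ed$to <- keep
      ed
    })
  }
  degree_of <- function() tabulate(unlist(lapply(edges, function(e)
    c(e$from, e$to))), nbins = nrow(nodes))
  for (pass in 1:12) {
    changed <- FALSE
    # (1a) short junction-junction edges
    deg <- degree_of()
    short <- which(vapply(edges, function(e)
      e$from != e$to && e$length_mm < merge_mm &&
        deg[e$from] >= 3 && deg[e$to] >= 3, TRUE))
    if (length(short)) {
      e <- edges[[short[1]]]
      edges[[short[1]]] <- NULL
      contract(min(e$from, e$to), max(e$from, e$to))
      changed <- TRUE
    }
    # (1b) parallel double edges forming a short loop
    if (!changed) {
      keyp <- vapply(edges, function(e)
        paste(sort(c(e$from, e$to)), collapse = "-"), "")
      dup <- keyp[duplicated(keyp)]
      for (k in dup) {
        ei <- which(keyp == k)
        lens <- vapply(edges[ei], `[[`, 0, "length_mm")
        if (min(lens) < loop_mm) {
          e <- edges[[ei[which.min(lens)]]]
          edges[[ei[which.min(lens)]]] <- NULL
          if (e$from != e$to) contract(min(e$from, e$to), max(e$from, e$to))
          changed <- TRUE
          break
        }
      }
    }
    # drop self-loops created by contraction
    selfs <- which(vapply(edges, function(e) e$from == e$to &&
                            e$length_mm < 2 * loop_mm, TRUE))
    if (length(selfs)) { edges[selfs] <- NULL; changed <- TRUE }
    # (2) dissolve degree-2 nodes
    deg <- degree_of()
    d2 <- which(deg == 2)
    for (nd in d2) {
      ei <- which(vapply(edges, function(e)
        e$from == nd || e$to == nd, TRUE))
      if (length(ei) != 2) next
      e1 <- edges[[ei[1]]]; e2 <- edges[[ei[2]]]
      if (e1$from == e1$to || e2$from == e2$to) next
      p1 <- if (e1$to == nd) e1$points else e1$points[nrow(e1$points):1, ]
      p2 <- if (e2$from == nd) e2$points else e2$points[nrow(e2$points):1, ]
      merged <- list(from = if (e1$to == nd) e1$from else e1$to,
                     to = if (e2$from == nd) e2$to else e2$from,
                     points = rbind(p1, p2[-1, , drop = FALSE]),
                     length_mm = e1$length_mm + e2$length_mm,
                     radius_mm = stats::weighted.mean(
                       c(e1$radius_mm, e2$radius_mm),
                       c(e1$length_mm, e2$length_mm)))
      edges[[ei[1]]] <- merged
      edges[[ei[2]]] <- NULL
      changed <- TRUE
      break
    }
    # (3) spur pruning at graph level
    deg <- degree_of()
    term <- which(vapply(edges, function(e)
      xor(deg[e$from] == 1, deg[e$to] == 1), TRUE))
    for (ei in term) {
      e <- edges[[ei]]
      jn <- if (deg[e$from] == 1) e$to else e$from
      inc <- vapply(edges, function(x)
        (x$from == jn || x$to == jn), TRUE)
      rmax <- max(vapply(edges[inc], `[[`, 0, "radius_mm"))
      whisker <- e$radius_mm < 0.55 * rmax && e$length_mm < 4 * spur_mm
      if ((e$length_mm < spur_mm || whisker) && sum(inc) > 1) {
        edges[[ei]] <- NULL
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  list(nodes = nodes, degree = degree_of(), edges = edges)
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat(sprintf("<centerline_graph> %d nodes, %d edges, %d bifurcations\n",
              nrow(x$nodes), length(x$edges), sum(x$degree >= 3)))
  invisible(x)
}

#' Detect vascular bifurcations in a centerline graph
#'
#' Bifurcations are graph nodes of degree >= 3; nearby duplicates (within
#' `merge_mm`) are merged during graph construction.
#' @param graph a `centerline_graph`.
#' @return matrix (k x 3) of bifurcation coordinates (mm); 0 rows if none.
#' @export
detect_bifurcations <- function(graph) {
  graph$nodes[graph$degree >= 3, , drop = FALSE]
}

#' Place the three spectral-Doppler gates at a bifurcation
#'
#' One gate per incident branch, at arclength `gate_distance_mm` from the
#' junction (branch midpoint, flagged, if the branch is shorter). Roles are
#' assigned from the flow direction: the upstream branch is `proximal`; the
#' downstream branches are `distal` until classification promotes one to
#' `in-the-bleeder`. Flow direction comes from the generating tree when
#' supplied (the simulation's stand-in for the imager's directional Doppler).
#'
#' @param bifurcation 3D point (mm) -- must be a degree >= 3 node of `graph`.
#' @param graph a `centerline_graph`.
#' @param gate_distance_mm arclength from junction to gate (default 5 mm).
#' @param tree optional `vessel_tree` supplying true flow directions.
#' @return list of gates: `location`, `role`, `edge`, `flagged_short`.
#' @export
place_sd_gates <- function(bifurcation, graph, gate_distance_mm = 5,
                           tree = NULL) {
  dn <- sqrt(rowSums(sweep(graph$nodes, 2, bifurcation)^2))
  node <- which.min(dn)
  if (graph$degree[node] < 3)
    stop("bifurcation point does not match a degree >= 3 node")
  inc <- which(vapply(graph$edges, function(e)
    e$from == node || e$to == node, TRUE))
  gates <- list()
  for (ei in inc) {
    e <- graph$edges[[ei]]
    pts <- e$points
    if (e$to == node && e$from != node) pts <- pts[nrow(pts):1, , drop = FALSE]
    flagged <- e$length_mm < gate_distance_mm
    s <- if (flagged) e$length_mm / 2 else gate_distance_mm
    loc <- polyline_point_at(pts, s)
    role <- "distal"
    if (!is.null(tree)) {
      # true downstream tangent at the nearest tree point; flow INTO the
      # junction marks the proximal branch
      nb <- nearest_tree_branch(tree, loc)
      if (!is.na(nb$branch)) {
        tang <- polyline_dir_at(tree$branches[[nb$branch]]$points, nb$arclength)
        to_junction <- unitv(bifurcation - loc)
        if (sum(tang * to_junction) > 0) role <- "proximal"
      }
    }
    gates[[length(gates) + 1]] <- list(location = loc, role = role, edge = ei,
                                       flagged_short = flagged,
                                       arclength_mm = s)
  }
  # exactly one proximal: if flow info gave none/multiple, fall back to the
  # largest-radius branch as proximal
  np <- sum(vapply(gates, function(g) g$role == "proximal", TRUE))
  if (np != 1) {
    for (i in seq_along(gates)) gates[[i]]$role <- "distal"
    radii <- vapply(inc, function(ei) graph$edges[[ei]]$radius_mm, 0)
    gates[[which.max(radii)]]$role <- "proximal"
  }
  gates
}

# nearest branch of a vessel_tree to a point; returns branch id, distance,
# and arclength along the branch
nearest_tree_branch <- function(tree, p) {
  best <- list(branch = NA_integer_, dist = Inf, arclength = 0)
  for (b in seq_along(tree$branches)) {
    pts <- tree$branches[[b]]$points
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    cs <- c(0, cumsum(seg))
    for (s in seq_len(nrow(pts) - 1)) {
      d <- point_segment_dist(p, pts[s, ], pts[s + 1, ])
      if (d$dist < best$dist)
        best <- list(branch = b, dist = d$dist,
                     arclength = cs[s] + d$t * seg[s])
    }
  }
  best
}

#' Resistive index of a flow waveform
#'
#' RI = (V_systole - V_diastole) / V_systole. Defined only for positive
#' systolic velocity; otherwise returns NA (the branch is unclassifiable).
#' @param w a `flow_waveform`.
#' @return RI (dimensionless, <= 1), or NA if V_systole <= 0.
#' @export
compute_ri <- function(w) {
  if (is_no_signal(w)) return(NA_real_)
  if (w$V_systole <= 0) return(NA_real_)
  (w$V_systole - w$V_diastole) / w$V_systole
}

#' Classify a branch as bleeder or normal from its resistive index
#'
#' A vented bleeder lowers distal resistance, depressing the resistive
#' index; the classification rule is RI < threshold (strict), threshold
#' 0.75. An undefined RI yields "unclassifiable".
#' @param ri resistive index.
#' @param threshold classification threshold (default 0.75).
#' @return "bleeder", "normal" or "unclassifiable".
#' @export
classify_branch <- function(ri, threshold = dbac_requirements()$ri_threshold) {
  if (is.na(ri)) return("unclassifiable")
  if (ri < threshold) "bleeder" else "normal"
}

#' Run the full detection & localization chain
#'
#' Renders the compounded power-Doppler volume, segments vessels, extracts
#' centerlines, detects bifurcations, places spectral gates, computes the
#' resistive index on each sampled waveform and classifies branches. Phase
#' wall-clock durations are recorded. Target coordinates for each detected
#' bleeder are the in-the-bleeder gate location.
#'
#' @param phantom a `limb_phantom`.
#' @param cuff a `cuff_geometry`.
#' @param seed base RNG seed for rendering and spectral sampling.
#' @param voxel_size_mm rendering resolution.
#' @param noise_sd rendering noise SD.
#' @param sd_noise_sd spectral-Doppler multiplicative noise SD.
#' @param gate_distance_mm gate placement arclength.
#' @param ri_threshold bleeder classification threshold.
#' @param vol optional pre-rendered `doppler_volume` (skips rendering).
#' @return object of class `dl_report`.
#' @export
run_dl <- function(phantom, cuff, seed = 1, voxel_size_mm = 0.3,
                   noise_sd = 5, sd_noise_sd = 0.05, gate_distance_mm = 5,
                   ri_threshold = dbac_requirements()$ri_threshold,
                   vol = NULL) {
  tree <- phantom$vessel_tree
  t0 <- proc.time()[["elapsed"]]
  if (is.null(vol))
    vol <- render_power_doppler(phantom, cuff, voxel_size_mm,
                                noise_seed = seed, noise_sd = noise_sd)
  t_acq <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  bleeders <- list(); graph <- NULL; bifs <- matrix(0, 0, 3)
  errors <- character(0)
  mask <- segment_vessels(vol)
  if (any(mask)) {
    graph <- tryCatch(extract_centerlines(mask), error = function(e) {
      errors <<- c(errors, conditionMessage(e)); NULL
    })
  }
  if (!is.null(graph)) {
    bifs <- detect_bifurcations(graph)
    for (bi in seq_len(nrow(bifs))) {
      res <- tryCatch({
        gates <- place_sd_gates(bifs[bi, ], graph, gate_distance_mm, tree)
        for (gi in seq_along(gates)) {
          g <- gates[[gi]]
          if (g$role == "proximal") next
          w <- sample_spectral_doppler(g$location, tree,
                                       noise_seed = seed + 31 * bi + gi,
                                       noise_sd = sd_noise_sd)
          ri <- compute_ri(w)
          cls <- classify_branch(ri, ri_threshold)
          if (identical(cls, "bleeder")) {
            bleeders[[length(bleeders) + 1]] <- list(
              bifurcation = bifs[bi, ],
              branch = if (is_no_signal(w)) NA_integer_ else attr(w, "branch"),
              RI = ri, classification = cls,
              target_coordinate = g$location)
          }
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) errors <- c(errors, res)
    }
  }
  t_char <- proc.time()[["elapsed"]] - t1

  structure(list(
    n_bifurcations = nrow(bifs),
    bleeders = bleeders,
    n_bleeders = length(bleeders),
    graph = graph,
    volume_dims = dim(vol$grid),
    timings = list(acquisition_s = t_acq, characterization_s = t_char,
                   total_s = t_acq + t_char),
    errors = errors),
    class = "dl_report")
}

#' @export
print.dl_report <- function(x, ...) {
  cat(sprintf("<dl_report> %d bifurcations, %d bleeders  (acq %.1fs + char %.1fs = %.1fs)\n",
              x$n_bifurcations, x$n_bleeders, x$timings$acquisition_s,
              x$timings$characterization_s, x$timings$total_s))
  for (b in x$bleeders)
    cat(sprintf("  bleeder: branch %s RI=%.3f target (%.1f, %.1f, %.1f) mm\n",
                b$branch, b$RI, b$target_coordinate[1], b$target_coordinate[2],
                b$target_coordinate[3]))
  invisible(x)
}

#' Persist a D&L report as JSON
#' @param report a `dl_report`.
#' @param path output path.
#' @export
write_dl_report_json <- function(report, path) {
  x <- list(n_bifurcations = report$n_bifurcations,
            n_bleeders = report$n_bleeders,
            bleeders = lapply(report$bleeders, function(b)
              list(bifurcation = b$bifurcation, branch = b$branch, RI = b$RI,
                   target_coordinate = b$target_coordinate)),
            timings = report$timings, errors = report$errors)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
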