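# PC-MRA angiogram, lumen segmentation, centerline extraction and
# label/trim — the geometry side of the pipeline.

#' Compute the PC-MRA angiogram
#'
#' The standard phase-contrast angiogram product: time-averaged signal
#' magnitude times the Euclidean norm of the velocity vector, per voxel.
#'
#' @param vol a preprocessed \linkS4class{VelocityVolume}.
#' @return an \linkS4class{Angiogram}.
#' @export
computePCMRA <- function(vol) {
  new("Angiogram",
    intensity = vol@magnitude * velocityNorm(vol@velocity),
    voxelSize = vol@voxelSize,
    provenance = "magnitude * |v|"
  )
}

# Noise-floor scale of a chi-distributed (3 d.f.) background angiogram,
# estimated from the image median (vessels are assumed a small minority of
# voxels): median(chi_3) = sqrt(qchisq(0.5, 3)) sigma.
estimateAngioNoise <- function(intensity) {
  median(intensity) / sqrt(qchisq(0.5, 3))
}

#' Segment the vessel lumen
#'
#' Thresholds the angiogram and removes connected components smaller than
#' \code{minSize} voxels (26-connectivity). Threshold methods:
#' \describe{
#'   \item{otsu}{Otsu's between-class criterion (256 bins).}
#'   \item{background}{\code{value} times the chi-distribution noise floor
#'     estimated from the image median (default multiplier 3); on noise-free
#'     data this reduces to any positive intensity. Preferred for flow
#'     quantification: it keeps the slow near-wall flow that a bimodal
#'     criterion truncates.}
#'   \item{percentile}{intensity quantile \code{value}.}
#'   \item{fixed}{absolute threshold \code{value}.}
#'   \item{relmax}{\code{value} times the maximum intensity (default
#'     0.02); the noise-free analogue of \code{background}, placing the
#'     cut just above the partial-volume wall intensity.}
#' }
#'
#' @param angio an \linkS4class{Angiogram}.
#' @param method threshold method (default "otsu").
#' @param value method parameter (multiplier, quantile or absolute value).
#' @param minSize minimum connected-component size in voxels (default 27).
#' @return logical array mask with attribute \code{threshold}.
#' @export
segmentVessels <- function(angio,
                           method = c("otsu", "background", "percentile", "fixed", "relmax"),
                           value = NULL, minSize = 27L) {
  method <- match.arg(method)
  I <- angio@intensity
  mx <- max(I)
  if (mx <= 0) stop("angiogram is all zero; nothing to segment")
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(I / mx), range = c(0, 1)) * mx,
    background = {
      if (is.null(value)) value <- 3
      value * estimateAngioNoise(I)
    },
    percentile = {
      if (is.null(value)) stop("percentile method needs a value in (0,1)")
      quantile(I, value)
    },
    fixed = {
      if (is.null(value)) stop("fixed method needs an absolute threshold")
      value
    },
    relmax = {
      if (is.null(value)) value <- 0.02
      value * mx
    }
  )
  mask <- I > thr
  if (!any(mask)) stop("segmentation mask is empty at threshold ", signif(thr, 4))
  d <- dim(I)
  lab <- array(.ccLabel3d(as.logical(mask), d, 26L), d)
  keep <- which(tabulate(lab[lab > 0]) >= minSize)
  mask <- array(lab %in% keep, d)
  if (!any(mask)) {
    stop("segmentation mask is empty after small-component removal")
  }
  attr(mask, "threshold") <- unname(thr)
  mask
}

# 26-neighbor adjacency among a set of voxels. Returns a two-column matrix
# of indices into `k` (each pair once) and the Euclidean step length.
voxelAdjacency <- function(k, d) {
  n <- nrow(k)
  nodeId <- array(0L, d)
  nodeId[k] <- seq_len(n)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  e1 <- integer(0)
  e2 <- integer(0)
  len <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    ii <- k[, 1] + offs[r, 1]
    jj <- k[, 2] + offs[r, 2]
    kk <- k[, 3] + offs[r, 3]
    ok <- ii >= 1 & jj >= 1 & kk >= 1 & ii <= d[1] & jj <= d[2] & kk <= d[3]
    nb <- integer(n)
    nb[ok] <- nodeId[cbind(ii[ok], jj[ok], kk[ok])]
    hit <- which(nb > seq_len(n)) # each pair once
    e1 <- c(e1, hit)
    e2 <- c(e2, nb[hit])
    len <- c(len, rep(sqrt(sum(offs[r, ]^2)), length(hit)))
  }
  list(edges = cbind(e1, e2), length = len)
}

# Centerline paths of one connected component by medialness-weighted
# geodesics: Dijkstra paths whose edge cost is the step length divided by
# the squared distance-transform value pull the path onto the lumen axis.
# Tips are found as geodesically farthest voxels; additional branch paths
# are added while some voxel lies much farther from the current centerline
# than its own local radius. Returns a list of ordered voxel-index paths
# (indices into `k`); branch paths end on a voxel of an earlier path.
componentCenterline <- function(k, edt, d) {
  adj <- voxelAdjacency(k, d)
  if (nrow(adj$edges) == 0) return(NULL)
  medial <- 1 / (edt + 0.5)^2
  w <- adj$length * (medial[adj$edges[, 1]] + medial[adj$edges[, 2]]) / 2
  g <- igraph::graph_from_edgelist(adj$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(k) - igraph::vcount(g)))
  hopDist <- function(from) {
    suppressWarnings(igraph::distances(g, v = from)[1, ])
  }
  # tip 1: farthest (hop metric) from the most interior voxel
  d0 <- hopDist(which.max(edt))
  d0[!is.finite(d0)] <- -1
  tip1 <- which.max(d0)
  d1 <- hopDist(tip1)
  d1[!is.finite(d1)] <- -1
  tip2 <- which.max(d1)
  centerPath <- function(from, to) {
    as.integer(igraph::shortest_paths(
      g,
      from = from, to = to, weights = w
    )$vpath[[1]])
  }
  paths <- list(centerPath(tip1, tip2))
  skel <- paths[[1]]
  for (iter in 1:8) {
    ds <- suppressWarnings(igraph::distances(g, v = skel))
    near <- max.col(-t(ds), ties.method = "first")
    dmin <- ds[cbind(near, seq_len(ncol(ds)))]
    dmin[!is.finite(dmin)] <- -1
    # a voxel warrants a new branch when it lies much farther from the
    # centerline than the lumen radius there can explain; the margin is
    # deliberately generous so that attached noise blobs do not spawn
    # branches (a false branch cuts the through-vessel at a false junction)
    score <- dmin - (2 * edt[skel[near]] + 8)
    cand <- which.max(score)
    if (score[cand] <= 0) break
    target <- skel[near[cand]]
    branch <- centerPath(cand, target)
    # truncate at the first voxel already on the centerline
    hit <- which(branch %in% skel)[1]
    branch <- branch[seq_len(hit)]
    # a genuine side branch is at least a couple of radii long; short
    # stubs are attached noise blobs, and accepting one would cut the
    # through-vessel at a false junction
    if (length(branch) < 10) break
    paths[[length(paths) + 1L]] <- branch
    skel <- union(skel, branch)
  }
  paths
}

#' Extract vessel centerlines
#'
#' Reduces the lumen mask to a one-voxel centerline skeleton by
#' medialness-weighted geodesics: within each connected component, Dijkstra
#' paths between automatically detected tips are traced with an edge cost
#' that is inversely proportional to the squared Euclidean distance
#' transform, which pins the path to the lumen axis; additional branch
#' paths are added while any lumen voxel lies much farther from the
#' centerline than its own local radius. Skeleton voxels become tree nodes
#' (26-neighbor edges); nodes with three or more neighbors are flagged
#' junctions and nodes with one neighbor endpoints. The local radius is the
#' distance-transform value at the node; provisional tangents are central
#' differences of neighboring nodes (re-estimated along the smoothed
#' labeled path by \code{\link{labelAndTrim}}).
#'
#' @param mask logical 3-D array from \code{\link{segmentVessels}}.
#' @param voxelSize cm.
#' @param minComponentVoxels components smaller than this are ignored
#'   (default 27).
#' @return a \linkS4class{VesselTree}.
#' @export
extractCenterlines <- function(mask, voxelSize, minComponentVoxels = 27L) {
  if (!any(mask)) stop("mask is empty")
  d <- dim(mask)
  lab <- array(.ccLabel3d(as.logical(mask), d, 26L), d)
  edtFull <- array(.edt3d(as.logical(mask), d), d)
  allPaths <- list()
  for (comp in seq_len(max(lab))) {
    vox <- which(lab == comp)
    if (length(vox) < minComponentVoxels) next
    kc <- arrayInd(vox, d)
    paths <- componentCenterline(kc, edtFull[vox], d)
    for (pp in paths) {
      # trim path ends that run through near-zero-radius mask (tails of
      # above-threshold noise attached to a vessel end)
      e <- edtFull[vox[pp]]
      cut <- max(1.5, 0.4 * median(e))
      good <- e >= cut
      if (!any(good)) next
      pp <- pp[min(which(good)):max(which(good))]
      if (length(pp) >= 2) allPaths[[length(allPaths) + 1L]] <- vox[pp]
    }
  }
  if (length(allPaths) == 0) {
    stop("mask has no tubular structure (empty skeleton)")
  }
  idx <- sort(unique(unlist(allPaths)))
  k <- arrayInd(idx, d)
  n <- nrow(k)
  # edges connect consecutive path voxels only (paths, not blobs)
  e1 <- integer(0)
  e2 <- integer(0)
  for (pp in allPaths) {
    nid <- match(pp, idx)
    a <- nid[-length(nid)]
    b <- nid[-1]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    e1 <- c(e1, lo)
    e2 <- c(e2, hi)
  }
  keepE <- !duplicated(paste(e1, e2))
  e1 <- e1[keepE]
  e2 <- e2[keepE]
  deg <- tabulate(c(e1, e2), nbins = n)
  if (all(deg == 0)) {
    stop("mask has no tubular structure (isolated skeleton voxels only)")
  }
  edt <- edtFull
  flag <- ifelse(deg >= 3, "junction", ifelse(deg == 1, "endpoint", "interior"))
  # provisional tangents from neighbor positions
  tx <- ty <- tz <- rep(NA_real_, n)
  adj <- vector("list", n)
  for (t in seq_along(e1)) {
    adj[[e1[t]]] <- c(adj[[e1[t]]], e2[t])
    adj[[e2[t]]] <- c(adj[[e2[t]]], e1[t])
  }
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (length(nb) == 0) next
    if (length(nb) >= 2) {
      dvec <- k[nb[2], ] - k[nb[1], ]
    } else {
      dvec <- k[i, ] - k[nb[1], ]
    }
    nrm <- sqrt(sum(dvec^2))
    if (nrm > 0) {
      tx[i] <- dvec[1] / nrm
      ty[i] <- dvec[2] / nrm
      tz[i] <- dvec[3] / nrm
    }
  }
  nodes <- data.frame(
    id = seq_len(n), i = k[, 1], j = k[, 2], k = k[, 3],
    x = (k[, 1] - 1) * voxelSize,
    y = (k[, 2] - 1) * voxelSize,
    z = (k[, 3] - 1) * voxelSize,
    degree = deg, flag = flag, radius = edt[idx] * voxelSize,
    tx = tx, ty = ty, tz = tz,
    label = "unlabeled", measurement = FALSE, ord = NA_integer_,
    stringsAsFactors = FALSE
  )
  new("VesselTree",
    nodes = nodes, edges = cbind(e1, e2),
    voxelSize = voxelSize, dims = as.integer(d)
  )
}

#' Label vessels from seed points and trim junctions/endpoints
#'
#' Each label is assigned to the skeleton branch (the connected component
#' after cutting at junction nodes) containing the node nearest its seed
#' point. Branch nodes are ordered along the path starting from the branch
#' end nearest the seed, tangents are re-estimated as central differences of
#' the moving-average-smoothed (window 5) node path, and the measurement set
#' excludes nodes within \code{k} graph steps of any junction and \code{m}
#' steps of any endpoint.
#'
#' @param tree a \linkS4class{VesselTree}.
#' @param seeds named list of world-cm points, one per label.
#' @param k junction trim margin in nodes (default 2).
#' @param m endpoint trim margin in nodes (default 3).
#' @param maxSeedDistance maximum seed-to-node distance, cm (default 0.5).
#' @param tangentWindow smoothing window (nodes) for tangent estimation.
#' @param radiusFraction nodes whose local (distance-transform) radius falls
#'   below this fraction of their vessel's median radius are also excluded
#'   from measurement — such nodes sit where the lumen is truncated (vessel
#'   ends, mask tails), not in open tube (default 0.75).
#' @return the labeled and trimmed \linkS4class{VesselTree}.
#' @export
labelAndTrim <- function(tree, seeds, k = 2L, m = 3L,
                         maxSeedDistance = 0.5, tangentWindow = 5L,
                         radiusFraction = 0.75) {
  nd <- tree@nodes
  g <- igraph::graph_from_edgelist(tree@edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(nd) - igraph::vcount(g)))
  junctions <- which(nd$flag == "junction")
  endpoints <- which(nd$flag == "endpoint")
  gCut <- igraph::delete_vertices(g, junctions)
  cutMembership <- rep(NA_integer_, nrow(nd))
  cutMembership[setdiff(seq_len(nrow(nd)), junctions)] <-
    igraph::components(gCut)$membership

  usedBranch <- c()
  for (lab in names(seeds)) {
    p <- seeds[[lab]]
    d2 <- (nd$x - p[1])^2 + (nd$y - p[2])^2 + (nd$z - p[3])^2
    nearest <- which.min(d2)
    if (sqrt(d2[nearest]) > maxSeedDistance) {
      stop("seed for label ", lab, " matches no centerline node")
    }
    if (nd$flag[nearest] == "junction") {
      # snap to the nearest non-junction node
      cand <- which(nd$flag != "junction")
      nearest <- cand[which.min(d2[cand])]
    }
    br <- cutMembership[nearest]
    if (br %in% usedBranch) {
      stop("two seeds resolve to the same branch (label ", lab, ")")
    }
    usedBranch <- c(usedBranch, br)
    members <- which(cutMembership == br)

    # order along the branch from the end nearest the seed
    sub <- igraph::induced_subgraph(g, members)
    subDeg <- igraph::degree(sub)
    ends <- members[subDeg <= 1]
    if (length(ends) == 0) ends <- members[1] # cycle; arbitrary start
    endD2 <- (nd$x[ends] - p[1])^2 + (nd$y[ends] - p[2])^2 +
      (nd$z[ends] - p[3])^2
    start <- ends[which.min(endD2)]
    ordv <- as.integer(igraph::dfs(
      sub,
      root = which(members == start)
    )$order)
    ordered <- members[ordv]
    nd$label[ordered] <- lab
    nd$ord[ordered] <- seq_along(ordered)

    # smoothed path tangents, oriented along increasing order
    if (length(ordered) >= 2) {
      sx <- movingAverage(nd$x[ordered], tangentWindow)
      sy <- movingAverage(nd$y[ordered], tangentWindow)
      sz <- movingAverage(nd$z[ordered], tangentWindow)
      np <- length(ordered)
      ip <- pmin(seq_len(np) + 1L, np)
      im <- pmax(seq_len(np) - 1L, 1L)
      dx <- sx[ip] - sx[im]
      dy <- sy[ip] - sy[im]
      dz <- sz[ip] - sz[im]
      nrm <- sqrt(dx^2 + dy^2 + dz^2)
      nrm[nrm == 0] <- 1
      nd$tx[ordered] <- dx / nrm
      nd$ty[ordered] <- dy / nrm
      nd$tz[ordered] <- dz / nrm

      # a path that folds back on itself (runs off the vessel end over an
      # attached noise blob and returns) has nodes whose tangent opposes
      # the path's mean direction; keep only the longest agreeing run
      if (np >= 3) {
        meanDir <- c(sum(dx), sum(dy), sum(dz))
        meanDir <- meanDir / sqrt(sum(meanDir^2))
        agree <- (dx * meanDir[1] + dy * meanDir[2] + dz * meanDir[3]) /
          nrm > 0.2
        if (!all(agree)) {
          r <- rle(agree)
          ends <- cumsum(r$lengths)
          good <- which(r$values)
          best <- good[which.max(r$lengths[good])]
          keepIdx <- (ends[best] - r$lengths[best] + 1):ends[best]
          drop <- ordered[-keepIdx]
          nd$label[drop] <- "unlabeled"
          nd$ord[drop] <- NA_integer_
        }
      }
    }
  }

  # trim: exclude nodes within k steps of a junction, m steps of an endpoint
  distTo <- function(targets) {
    if (length(targets) == 0)

      return(rep(Inf, nrow(nd)))
    dm <- igraph::distances(g, v = targets)
    apply(dm, 2, min)
  }
  dJ <- distTo(junctions)
  dE <- distTo(endpoints)
  nd$measurement <- nd$label != "unlabeled" & dJ >= k & dE >= m &
    nd$flag == "interior"
  for (lab in names(seeds)) {
    sel <- nd$label == lab
    if (any(sel)) {
      cut <- radiusFraction * median(nd$radius[sel])
      nd$measurement[sel & nd$radius < cut] <- FALSE
    }
  }
  out <- tree
  out@nodes <- nd
  validObject(out)
  out
}
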