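# Flow and cross-sectional area on planes perpendicular to the centerline,
# averaged along each labeled vessel; global flow = ICA_L + ICA_R + BA.

#' Sample one cross-section
#'
#' Interpolates (trilinear) the velocity field and the lumen mask onto a
#' square plane through a centerline node, perpendicular to its tangent
#' (side length 4 x local radius, pixel size half a voxel). Lumen pixels are
#' those with interpolated mask >= 0.5; flux is the lumen sum of the normal
#' velocity component times pixel area, converted to mL/min; CSA is lumen
#' pixel count times pixel area.
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param mask logical lumen mask on the same grid.
#' @param node one-row node data.frame (from \code{treeNodes}).
#' @param otherMask optional logical array of other labeled vessels; a plane
#'   touching it is skipped (prevents double counting near junctions).
#' @param sideFactor plane side length as a multiple of the local radius.
#' @param pixelFraction plane pixel size as a fraction of the voxel size.
#' @return list(flux, csa, nPixels, origin, normal), or NULL when the plane
#'   leaves the grid, contains no lumen pixel, or touches \code{otherMask}.
#' @export
sampleCrossSection <- function(vol, mask, node, otherMask = NULL,
                               sideFactor = 4, pixelFraction = 0.5) {
  normal <- c(node$tx, node$ty, node$tz)
  if (anyNA(normal)) return(NULL)
  origin <- c(node$x, node$y, node$z)
  h <- vol@voxelSize
  px <- h * pixelFraction
  side <- sideFactor * node$radius
  npix <- max(3L, ceiling(side / px))
  u <- (seq_len(npix) - (npix + 1) / 2) * px
  b <- planeBasis(normal)
  uu <- rep(u, times = npix)
  vv <- rep(u, each = npix)
  pts <- cbind(
    origin[1] + uu * b$e1[1] + vv * b$e2[1],
    origin[2] + uu * b$e1[2] + vv * b$e2[2],
    origin[3] + uu * b$e1[3] + vv * b$e2[3]
  )
  mnum <- trilinear(mask + 0, pts, h)
  if (anyNA(mnum)) return(NULL) # plane exits the grid
  lum <- mnum >= 0.5
  if (!any(lum)) return(NULL)
  if (!is.null(otherMask)) {
    onum <- trilinear(otherMask + 0, pts, h)
    if (any(onum >= 0.5, na.rm = TRUE)) return(NULL)
  }
  vdot <- numeric(sum(lum))
  lpts <- pts[lum, , drop = FALSE]
  for (c in 1:3) {
    vdot <- vdot + normal[c] * trilinear(vol@velocity[, , , c], lpts, h)
  }
  pixArea <- px * px
  list(
    flux = sum(vdot) * pixArea * 60, # cm^3/s -> mL/min
    csa = sum(lum) * pixArea,
    nPixels = sum(lum),
    origin = origin, normal = normal
  )
}

# Partition mask voxels among labels: each lumen voxel goes to the label of
# the nearest labeled centerline node. Used for the other-vessel overlap
# test.
labeledMaskPartition <- function(mask, tree) {
  nd <- tree@nodes
  labs <- setdiff(unique(nd$label), "unlabeled")
  d <- dim(mask)
  out <- array(0L, d)
  if (length(labs) == 0) return(list(partition = out, labels = labs))
  idx <- which(mask)
  kk <- arrayInd(idx, d)
  h <- tree@voxelSize
  wx <- (kk[, 1] - 1) * h
  wy <- (kk[, 2] - 1) * h
  wz <- (kk[, 3] - 1) * h
  best <- rep(Inf, length(idx))
  assign <- integer(length(idx))
  for (li in seq_along(labs)) {
    nn <- nd[nd$label == labs[li], , drop = FALSE]
    dmin <- rep(Inf, length(idx))
    for (r in seq_len(nrow(nn))) {
      d2 <- (wx - nn$x[r])^2 + (wy - nn$y[r])^2 + (wz - nn$z[r])^2
      dmin <- pmin(dmin, d2)
    }
    upd <- dmin < best
    best[upd] <- dmin[upd]
    assign[upd] <- li
  }
  out[idx] <- assign
  list(partition = out, labels = labs)
}

#' Measure one vessel
#'
#' Unweighted mean of per-section flux and CSA over all non-skipped
#' measurement nodes of a label. Flux sign is positive along increasing node
#' order from the labeled seed.
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param mask logical lumen mask.
#' @param tree a labeled \linkS4class{VesselTree}.
#' @param label vessel label to measure.
#' @param partition optional precomputed \code{labeledMaskPartition} result.
#' @param condition optional condition string carried into the output.
#' @param ... passed to \code{\link{sampleCrossSection}}.
#' @return one-row data.frame: vessel, condition, flow_ml_min, csa_cm2,
#'   n_sections.
#' @export
measureVessel <- function(vol, mask, tree, label, partition = NULL,
                          condition = NA_character_, ...) {
  nd <- tree@nodes
  sel <- nd$label == label & nd$measurement
  if (!any(sel)) stop("label ", label, " has no measurement nodes")
  nodes <- nd[sel, , drop = FALSE]
  nodes <- nodes[order(nodes$ord), , drop = FALSE]
  if (is.null(partition)) partition <- labeledMaskPartition(mask, tree)
  li <- match(label, partition$labels)
  otherMask <- if (length(partition$labels) > 1) {
    partition$partition != li & partition$partition != 0L
  } else {
    NULL
  }
  flux <- numeric(0)
  csa <- numeric(0)
  for (r in seq_len(nrow(nodes))) {
    cs <- sampleCrossSection(vol, mask, nodes[r, ], otherMask = otherMask, ...)
    if (is.null(cs)) next
    flux <- c(flux, cs$flux)
    csa <- c(csa, cs$csa)
  }
  if (length(flux) == 0) stop("no valid cross-sections for label ", label)
  data.frame(
    vessel = label, condition = condition,
    flow_ml_min = mean(flux), csa_cm2 = mean(csa),
    n_sections = length(flux), stringsAsFactors = FALSE
  )
}

#' Measure all labeled vessels
#'
#' @inheritParams measureVessel
#' @return data.frame with one row per label.
#' @export
measureAllVessels <- function(vol, mask, tree,
                              condition = NA_character_, ...) {
  partition <- labeledMaskPartition(mask, tree)
  do.call(rbind, lapply(partition$labels, function(lab) {
    measureVessel(vol, mask, tree, lab,
      partition = partition,
      condition = condition, ...
    )
  }))
}

#' Global cerebral blood flow
#'
#' Sum of the left and right internal carotid and basilar artery flows.
#'
#' @param measurements data.frame with columns vessel and flow_ml_min (one
#'   condition), or a named numeric vector of flows.
#' @return global flow, mL/min.
#' @examples
#' globalFlow(c(ICA_L = 250, ICA_R = 240, BA = 150))
#' @export
globalFlow <- function(measurements) {
  flows <- if (is.data.frame(measurements)) {
    setNames(measurements$flow_ml_min, measurements$vessel)
  } else {
    measurements
  }
  need <- c("ICA_L", "ICA_R", "BA")
  missing <- setdiff(need, names(flows))
  if (length(missing)) {
    stop("global flow needs ", paste(missing, collapse = ", "))
  }
  unname(sum(flows[need]))
}
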