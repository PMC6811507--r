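# Shared fixtures: small phantoms and a synthetic centerline tree built in
# code (no stored data).

# Tiny noise-free straight tube measured through the standard chain.
measureTube <- function(bundle, params = list(), label = "V") {
  p <- utils::modifyList(
    list(
      thresholdMethod = "relmax", thresholdValue = 0.02,
      trimEndpoint = 6L
    ),
    params
  )
  q <- quantifyVolume(bundle$volume, bundle$seeds,
    params = p,
    preprocess = FALSE
  )
  q$measurements[q$measurements$vessel == label, ]
}

# Hand-built straight-path VesselTree (n nodes along z), for label/trim
# arithmetic independent of any image.
syntheticPathTree <- function(n = 50, voxelSize = 0.03, radius = 0.15) {
  nodes <- data.frame(
    id = seq_len(n), i = 5L, j = 5L, k = seq_len(n),
    x = 4 * voxelSize, y = 4 * voxelSize, z = (seq_len(n) - 1) * voxelSize,
    degree = c(1L, rep(2L, n - 2), 1L),
    flag = c("endpoint", rep("interior", n - 2), "endpoint"),
    radius = radius, tx = 0, ty = 0, tz = 1,
    label = "unlabeled", measurement = FALSE, ord = NA_integer_,
    stringsAsFactors = FALSE
  )
  edges <- cbind(seq_len(n - 1), 2:n)
  new("VesselTree",
    nodes = nodes, edges = edges,
    voxelSize = voxelSize, dims = c(10L, 10L, as.integer(n + 2))
  )
}

# Y-shaped synthetic tree: a junction node with three straight arms.
syntheticYTree <- function(armLength = 12, voxelSize = 0.03) {
  h <- voxelSize
  n <- 3 * armLength + 1
  pos <- rbind(
    cbind(20, 20, 20 - (armLength:1)), # arm A (parent, below junction)
    c(20, 20, 20), # junction
    cbind(20 + (1:armLength), 20, 20 + (1:armLength)), # arm B
    cbind(20 - (1:armLength), 20, 20 + (1:armLength)) # arm C
  )
  jn <- armLength + 1L
  deg <- rep(2L, n)
  deg[jn] <- 3L
  tips <- c(1L, jn + armLength, n)
  deg[tips] <- 1L
  flag <- rep("interior", n)
  flag[jn] <- "junction"
  flag[tips] <- "endpoint"
  nodes <- data.frame(
    id = seq_len(n), i = pos[, 1], j = pos[, 2], k = pos[, 3],
    x = (pos[, 1] - 1) * h, y = (pos[, 2] - 1) * h, z = (pos[, 3] - 1) * h,
    degree = deg, flag = flag, radius = 0.12,
    tx = NA_real_, ty = NA_real_, tz = NA_real_,
    label = "unlabeled", measurement = FALSE, ord = NA_integer_,
    stringsAsFactors = FALSE
  )
  edges <- rbind(
    cbind(1:(jn - 1), 2:jn), # along arm A into junction
    cbind(c(jn, (jn + 1):(jn + armLength - 1)), (jn + 1):(jn + armLength)),
    cbind(
      c(jn, (jn + armLength + 1):(n - 1)),
      (jn + armLength + 1):n
    )
  )
  new("VesselTree",
    nodes = nodes, edges = edges,
    voxelSize = h, dims = c(45L, 45L, 45L)
  )
}
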