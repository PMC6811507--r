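# Dataset I/O: one NIfTI file per velocity component and magnitude per
# condition (<cond>_<axis|mag>.nii.gz), a JSON sidecar per condition
# carrying Venc and voxel size (portable across viewers, unlike header
# extensions), a condition CSV and a truth/seeds JSON.

axisFiles <- function(condition) {
  paste0(condition, "_", c("vx", "vy", "vz", "mag"), ".nii.gz")
}

writeNiftiVolume <- function(arr, path, voxelSize) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxelSize, 3)
  RNifti::writeNifti(img, path)
}

#' Write a simulated study to a dataset directory
#'
#' Emits per condition the three decoded velocity-component volumes and the
#' magnitude volume as NIfTI, a JSON sidecar with Venc and voxel size, plus
#' \code{conditions.csv} (condition, etco2_mmHg, map_mmHg, hr_bpm,
#' spo2_pct), \code{seeds.json} (world-cm vessel seed points) and
#' \code{truth.json} (the analytic ground-truth ledger).
#'
#' @param study a \linkS4class{PhantomStudy}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(study@volumes)) {
    vol <- study@volumes[[cond]]
    files <- axisFiles(cond)
    for (c in 1:3) {
      writeNiftiVolume(
        vol@velocity[, , , c], file.path(dir, files[c]), vol@voxelSize
      )
    }
    writeNiftiVolume(vol@magnitude, file.path(dir, files[4]), vol@voxelSize)
    jsonlite::write_json(
      list(
        condition = cond, venc_cm_s = vol@venc,
        voxel_size_cm = vol@voxelSize
      ),
      file.path(dir, paste0(cond, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  cond <- study@conditions
  write.csv(
    data.frame(
      condition = cond$condition, etco2_mmHg = cond$etco2,
      map_mmHg = cond$map, hr_bpm = cond$hr, spo2_pct = cond$spo2
    ),
    file.path(dir, "conditions.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    study@seeds, file.path(dir, "seeds.json"),
    digits = NA
  )
  tr <- study@truth
  jsonlite::write_json(
    list(
      measurements = tr@measurements, global_flow = tr@globalFlow,
      slopes = tr@slopes
    ),
    file.path(dir, "truth.json"),
    digits = NA, dataframe = "rows"
  )
  invisible(dir)
}

#' Read one condition's velocity dataset
#'
#' @param dir dataset directory.
#' @param condition condition label (file prefix).
#' @return a \linkS4class{VelocityVolume}.
#' @export
readVelocityDataset <- function(dir, condition) {
  files <- file.path(dir, axisFiles(condition))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing dataset file(s): ", paste(basename(missing), collapse = ", "))
  }
  sidecar <- file.path(dir, paste0(condition, ".json"))
  if (!file.exists(sidecar)) {
    stop("missing sidecar metadata: ", basename(sidecar))
  }
  meta <- jsonlite::read_json(sidecar)
  if (is.null(meta$venc_cm_s)) {
    stop("sidecar ", basename(sidecar), " does not state Venc")
  }
  arrs <- lapply(files, function(f) {
    a <- RNifti::readNifti(f)
    array(as.numeric(a), dim(a))
  })
  dims <- lapply(arrs, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("velocity/magnitude volumes have mismatched shapes")
  }
  h <- meta$voxel_size_cm
  if (is.null(h)) {
    h <- RNifti::pixdim(RNifti::readNifti(files[1]))[1]
  }
  vel <- array(0, c(dims[[1]], 3L))
  for (c in 1:3) vel[, , , c] <- arrs[[c]]
  new("VelocityVolume",
    velocity = vel, magnitude = arrs[[4]],
    voxelSize = as.numeric(h), venc = as.numeric(meta$venc_cm_s)
  )
}

#' Read a dataset's condition table
#'
#' @param dir dataset directory.
#' @return data.frame: condition, etco2, map, hr, spo2.
#' @export
readConditionTable <- function(dir) {
  f <- file.path(dir, "conditions.csv")
  if (!file.exists(f)) stop("missing conditions.csv in ", dir)
  x <- read.csv(f, stringsAsFactors = FALSE)
  data.frame(
    condition = x$condition, etco2 = x$etco2_mmHg, map = x$map_mmHg,
    hr = x$hr_bpm, spo2 = x$spo2_pct
  )
}

#' Read vessel seed points
#'
#' @param dir dataset directory (expects \code{seeds.json}: label to world
#'   cm point).
#' @return named list of numeric length-3 points.
#' @export
readSeeds <- function(dir) {
  f <- file.path(dir, "seeds.json")
  if (!file.exists(f)) stop("missing seeds.json in ", dir)
  lapply(jsonlite::read_json(f), function(p) as.numeric(unlist(p)))
}
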