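VESSEL_LABELS <- c("ICA_L", "ICA_R", "MCA_L", "MCA_R", "BA")

#' VelocityVolume: decoded three-component velocity field
#'
#' Time-averaged three-component velocity field (cm/s) on a regular isotropic
#' 3-D grid together with the signal magnitude image, voxel spacing and the
#' velocity-encoding parameter Venc.
#'
#' @slot velocity numeric array \code{(nx, ny, nz, 3)}, cm/s.
#' @slot magnitude numeric array \code{(nx, ny, nz)}, arbitrary units.
#' @slot voxelSize isotropic voxel edge length, cm.
#' @slot venc velocity-encoding parameter, cm/s.
#' @slot metadata list of processing annotations (e.g. unwrap corrections).
#' @exportClass VelocityVolume
setClass("VelocityVolume",
  representation(
    velocity = "array", magnitude = "array",
    voxelSize = "numeric", venc = "numeric", metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("VelocityVolume", function(object) {
  dv <- dim(object@velocity)
  dm <- dim(object@magnitude)
  if (length(dv) != 4 || dv[4] != 3) {
    return("velocity must be an (nx, ny, nz, 3) array")
  }
  if (length(dm) != 3 || any(dm != dv[1:3])) {
    return("magnitude grid must match the velocity grid")
  }
  if (any(!is.finite(object@velocity))) return("velocity must be finite")
  if (length(object@voxelSize) != 1 || object@voxelSize <= 0) {
    return("voxelSize must be a single positive number (cm)")
  }
  if (length(object@venc) != 1 || object@venc <= 0) {
    return("venc must be a single positive number (cm/s)")
  }
  TRUE
})

#' EncodedVolume: phase-encoded velocity signal
#'
#' Per-axis encoded phase (radians, wrapped into \code{[-pi, pi)}) and
#' per-axis signal magnitude, the acquisition-side representation from which
#' velocities are decoded as \code{v = venc * phase / pi}.
#'
#' @slot phase numeric array \code{(nx, ny, nz, 3)}, radians.
#' @slot magnitude numeric array \code{(nx, ny, nz, 3)}.
#' @slot voxelSize cm.
#' @slot venc cm/s.
#' @exportClass EncodedVolume
setClass("EncodedVolume",
  representation(
    phase = "array", magnitude = "array",
    voxelSize = "numeric", venc = "numeric"
  )
)

setValidity("EncodedVolume", function(object) {
  dp <- dim(object@phase)
  if (length(dp) != 4 || dp[4] != 3) {
    return("phase must be an (nx, ny, nz, 3) array")
  }
  if (!identical(dim(object@magnitude), dp)) {
    return("magnitude must match the phase array dimensions")
  }
  if (object@venc <= 0) return("venc must be positive")
  TRUE
})

#' Angiogram: PC-MRA intensity volume
#'
#' Scalar vessel-enhancing intensity volume (time-averaged magnitude times
#' velocity norm) used for lumen segmentation.
#'
#' @slot intensity non-negative 3-D array.
#' @slot voxelSize cm.
#' @slot provenance character description of the formula used.
#' @exportClass Angiogram
setClass("Angiogram",
  representation(
    intensity = "array", voxelSize = "numeric", provenance = "character"
  )
)

setValidity("Angiogram", function(object) {
  if (length(dim(object@intensity)) != 3) return("intensity must be 3-D")
  if (any(object@intensity < 0)) return("intensity must be non-negative")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

#' VesselTree: labeled centerline graph
#'
#' Centerline skeleton of the segmented vasculature: nodes carry voxel and
#' world coordinates, a unit tangent, a local radius estimate (distance
#' transform), a topological flag (junction / endpoint / interior), a vessel
#' label and a measurement flag; edges are 26-neighbor connections.
#'
#' @slot nodes data.frame with columns id, i, j, k (1-based voxel index),
#'   x, y, z (world cm), degree, flag, radius, tx, ty, tz, label,
#'   measurement, ord.
#' @slot edges two-column integer matrix of node ids.
#' @slot voxelSize cm.
#' @slot dims integer grid dimensions of the source mask.
#' @exportClass VesselTree
setClass("VesselTree",
  representation(
    nodes = "data.frame", edges = "matrix",
    voxelSize = "numeric", dims = "integer"
  )
)

setValidity("VesselTree", function(object) {
  need <- c(
    "id", "i", "j", "k", "x", "y", "z", "degree", "flag", "radius",
    "tx", "ty", "tz", "label", "measurement", "ord"
  )
  if (!all(need %in% names(object@nodes))) {
    return("nodes is missing required columns")
  }
  tn <- sqrt(object@nodes$tx^2 + object@nodes$ty^2 + object@nodes$tz^2)
  if (any(is.finite(tn) & abs(tn - 1) > 1e-6)) {
    return("tangents must be unit-norm")
  }
  TRUE
})

#' BackgroundModel: fitted background/eddy-current phase-offset model
#'
#' Low-order polynomial (per velocity axis, in decoded-velocity units cm/s)
#' fitted to static-tissue voxels by least squares.
#'
#' @slot coefficients matrix (terms x 3 axes), cm/s per unit of each term.
#' @slot terms character names of the polynomial terms.
#' @slot residualRMS per-axis residual RMS over the static mask, cm/s.
#' @slot nMask number of static-tissue voxels used in the fit.
#' @slot order polynomial order (1 or 2).
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  representation(
    coefficients = "matrix", terms = "character", residualRMS = "numeric",
    nMask = "integer", order = "integer"
  )
)

#' VesselSpec: synthetic vessel description
#'
#' One tube of the synthetic phantom: a labeled parametric centerline
#' (polyline, cm) with radius and cross-section mean velocity. Voxels inside
#' the tube carry the Poiseuille profile
#' \eqn{v(r) = 2 \bar v (1 - (r/R)^2)} along the local tangent.
#'
#' @slot label one of ICA_L, ICA_R, MCA_L, MCA_R, BA (or a custom label).
#' @slot centerline n x 3 matrix of control points, world cm.
#' @slot radius lumen radius, cm.
#' @slot meanVelocity cross-section mean velocity, cm/s (scalar for steady
#'   flow, or one value per cardiac phase).
#' @exportClass VesselSpec
setClass("VesselSpec",
  representation(
    label = "character", centerline = "matrix",
    radius = "numeric", meanVelocity = "numeric"
  )
)

setValidity("VesselSpec", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  cl <- object@centerline
  if (ncol(cl) != 3 || nrow(cl) < 2) {
    return("centerline needs at least 2 points (n x 3 matrix)")
  }
  if (max(dist(cl)) <= 0) return("centerline points must be distinct")
  if (any(object@meanVelocity < 0)) return("meanVelocity values must be >= 0")
  TRUE
})

#' AcquisitionSpec: phantom acquisition model
#'
#' Image-space acquisition parameters of the synthetic phantom: grid,
#' velocity encoding, cardiac phases, noise level, background phase offsets
#' and partial-volume supersampling.
#'
#' @slot voxelSize isotropic voxel size, cm.
#' @slot gridShape integer triple.
#' @slot venc velocity encoding, cm/s.
#' @slot nCardiacPhases integer >= 1.
#' @slot snr signal magnitude over complex-noise standard deviation
#'   (Inf = noise-free), defined on the vessel magnitude (= 1).
#' @slot backgroundPhaseCoeffs 4 x 3 matrix; per velocity axis (columns) the
#'   constant and three linear background phase terms (radians; linear terms
#'   radians/cm of world coordinate).
#' @slot supersampling subsamples per voxel edge for partial-volume
#'   rendering.
#' @slot tissueMagnitude signal magnitude of static tissue (vessel = 1).
#' @slot pulsatility amplitude of the optional sinusoidal cardiac modulation
#'   of the mean velocity (fraction; time-average stays at the specified
#'   mean).
#' @exportClass AcquisitionSpec
setClass("AcquisitionSpec",
  representation(
    voxelSize = "numeric", gridShape = "integer", venc = "numeric",
    nCardiacPhases = "integer", snr = "numeric",
    backgroundPhaseCoeffs = "matrix", supersampling = "integer",
    tissueMagnitude = "numeric", pulsatility = "numeric"
  )
)

setValidity("AcquisitionSpec", function(object) {
  if (object@venc <= 0) return("venc must be positive")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (!(object@snr > 0)) return("snr must be positive (or Inf for noise-free)")
  if (object@nCardiacPhases < 1) return("nCardiacPhases must be >= 1")
  if (object@supersampling < 1) return("supersampling must be >= 1")
  if (!all(dim(object@backgroundPhaseCoeffs) == c(4, 3))) {
    return("backgroundPhaseCoeffs must be a 4 x 3 matrix")
  }
  if (any(!is.finite(object@backgroundPhaseCoeffs))) {
    return("backgroundPhaseCoeffs must be finite")
  }
  TRUE
})

#' StudySpec: hypercapnia study design with known reactivity
#'
#' Three-condition (normocapnia / 4\% CO2 / 6\% CO2) study description with a
#' programmed true CVR slope: per-condition vessel flows are set so that the
#' true global conductance CVC = flow / MAP x 100 lies exactly on the
#' specified line against ETCO2, and each vessel carries a fixed fraction of
#' global flow (so per-vessel CVC lines are exact too). The MCA radius is
#' dilated at the highest-CO2 condition.
#'
#' @slot conditions data.frame with columns condition, etco2 (mmHg),
#'   map (mmHg), hr (bpm), spo2 (percent).
#' @slot trueSlope programmed global CVR slope, CVC-units per mmHg ETCO2.
#' @slot globalFlowNormo normocapnic global flow (ICA_L + ICA_R + BA),
#'   mL/min; fixes the intercept of the CVC line.
#' @slot flowFractions named fractions of global flow per vessel
#'   (ICA_L + ICA_R + BA must sum to 1).
#' @slot mcaDilationFraction relative MCA CSA increase at the top condition.
#' @slot brainVolume brain volume (GM + WM), liters.
#' @slot subjects number of subjects simulated.
#' @slot seed base random seed.
#' @exportClass StudySpec
setClass("StudySpec",
  representation(
    conditions = "data.frame", trueSlope = "numeric",
    globalFlowNormo = "numeric", flowFractions = "numeric",
    mcaDilationFraction = "numeric", brainVolume = "numeric",
    subjects = "integer", seed = "integer"
  )
)

setValidity("StudySpec", function(object) {
  cond <- object@conditions
  if (nrow(cond) < 2) return("need >= 2 conditions")
  if (anyDuplicated(cond$etco2)) return("conditions must have distinct etco2")
  if (any(cond$map <= 0)) return("map must be positive")
  fr <- object@flowFractions
  if (!all(c("ICA_L", "ICA_R", "BA") %in% names(fr))) {
    return("flowFractions must name ICA_L, ICA_R and BA")
  }
  if (abs(sum(fr[c("ICA_L", "ICA_R", "BA")]) - 1) > 1e-8) {
    return("ICA_L + ICA_R + BA flow fractions must sum to 1")
  }
  if (object@brainVolume <= 0) return("brainVolume must be positive")
  TRUE
})

#' PhantomTruth: analytic ground-truth ledger
#'
#' Per vessel and condition the analytic flow (mean velocity x lumen area x
#' 60) and CSA, global flow per condition, and the programmed CVC-vs-ETCO2
#' line per scope.
#'
#' @slot measurements data.frame: vessel, condition, flow_ml_min, csa_cm2,
#'   mean_velocity_cm_s, radius_cm.
#' @slot globalFlow data.frame: condition, flow_ml_min.
#' @slot slopes data.frame: scope, slope, intercept.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(
    measurements = "data.frame", globalFlow = "data.frame",
    slopes = "data.frame"
  )
)

#' PhantomStudy: one simulated subject's study
#'
#' Per-condition measured (decoded, artifact-bearing) velocity volumes, the
#' physiological condition table, vessel seed points and the analytic truth
#' ledger.
#'
#' @slot volumes named list of \linkS4class{VelocityVolume}, one per
#'   condition.
#' @slot conditions data.frame of condition records (etco2, map, hr, spo2).
#' @slot seeds named list of world-cm seed points per vessel label.
#' @slot truth \linkS4class{PhantomTruth}.
#' @slot acquisition \linkS4class{AcquisitionSpec}.
#' @slot study \linkS4class{StudySpec}.
#' @exportClass PhantomStudy
setClass("PhantomStudy",
  representation(
    volumes = "list", conditions = "data.frame", seeds = "list",
    truth = "PhantomTruth", acquisition = "AcquisitionSpec",
    study = "StudySpec"
  )
)

#' CVRFit: fitted conductance-reactivity line
#'
#' Ordinary least-squares line of CVC against ETCO2 for one scope (a vessel,
#' global, or brain-volume-corrected global).
#'
#' @slot scope character scope label.
#' @slot slope CVC-units per mmHg.
#' @slot intercept CVC-units.
#' @slot nPoints number of conditions used.
#' @slot conditionsUsed character vector.
#' @slot mode "all_conditions" or "hypercapnic_only".
#' @exportClass CVRFit
setClass("CVRFit",
  representation(
    scope = "character", slope = "numeric", intercept = "numeric",
    nPoints = "integer", conditionsUsed = "character", mode = "character"
  )
)

setValidity("CVRFit", function(object) {
  if (object@nPoints < 2) return("nPoints must be >= 2")
  if (!is.finite(object@slope)) return("slope must be finite")
  TRUE
})
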