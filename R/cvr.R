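# Cerebrovascular conductance and reactivity: CVC = flow / MAP x 100, CVR =
# OLS slope of CVC against end-tidal CO2 across conditions; brain-volume
# correction and MCA cross-sectional-area change.

#' Cerebrovascular conductance
#'
#' \code{CVC = flow / MAP x 100}, accounting for perfusion-pressure changes
#' during hypercapnia. Units are kept exactly as the formula states,
#' (mL/min/mmHg) x 100.
#'
#' @param flow blood flow, mL/min.
#' @param map mean arterial pressure, mmHg (> 0).
#' @return CVC units.
#' @examples
#' computeCVC(300, 100) # 300
#' @export
computeCVC <- function(flow, map) {
  if (any(map <= 0)) stop("MAP must be positive")
  flow / map * 100
}

#' Fit the CVC-versus-ETCO2 line (CVR)
#'
#' Ordinary least-squares slope and intercept of CVC on ETCO2 over the
#' selected conditions; with exactly two points this is the two-point
#' difference quotient. \code{mode = "hypercapnic_only"} drops the
#' lowest-ETCO2 (normocapnic) condition.
#'
#' @param points data.frame with columns \code{etco2} and \code{cvc}, and
#'   optionally \code{condition}.
#' @param mode "all_conditions" (default) or "hypercapnic_only".
#' @param scope scope label carried into the result.
#' @return a \linkS4class{CVRFit}.
#' @examples
#' fitCVR(data.frame(etco2 = c(46, 48), cvc = c(200, 210))) # slope 5
#' @export
fitCVR <- function(points, mode = c("all_conditions", "hypercapnic_only"),
                   scope = "global") {
  mode <- match.arg(mode)
  pts <- points
  if (mode == "hypercapnic_only" && nrow(pts) > 2) {
    pts <- pts[-which.min(pts$etco2), , drop = FALSE]
  }
  if (nrow(pts) < 2) stop("need at least 2 points to fit CVR")
  if (anyDuplicated(pts$etco2)) {
    stop("ETCO2 values must be distinct to fit CVR")
  }
  fit <- lm(cvc ~ etco2, data = pts)
  condUsed <- if ("condition" %in% names(pts)) {
    as.character(pts$condition)
  } else {
    paste0("etco2=", pts$etco2)
  }
  new("CVRFit",
    scope = scope, slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]), nPoints = nrow(pts),
    conditionsUsed = condUsed, mode = mode
  )
}

#' Brain-volume-corrected global flow
#'
#' @param flow global flow, mL/min.
#' @param gm gray-matter volume, liters.
#' @param wm white-matter volume, liters.
#' @return flow / (gm + wm), mL/min per liter of brain.
#' @examples
#' correctGlobalFlow(640, 0.7, 0.5) # 533.3
#' @export
correctGlobalFlow <- function(flow, gm, wm) {
  bv <- gm + wm
  if (any(bv <= 0) || any(gm <= 0) || any(wm <= 0)) {
    stop("brain volume (GM + WM) must be positive")
  }
  flow / bv
}

#' MCA cross-sectional-area change
#'
#' @param normo normocapnic CSA, cm^2 (> 0).
#' @param hyper hypercapnic CSA, cm^2.
#' @return list(delta, percent): absolute change (cm^2) and percent change.
#' @examples
#' csaChange(0.069, 0.072) # +0.003 cm^2, +4.35 %
#' @export
csaChange <- function(normo, hyper) {
  if (any(normo <= 0)) stop("normocapnic CSA must be positive")
  delta <- hyper - normo
  list(delta = delta, percent = delta / normo * 100)
}

#' Summarize a physiological time series over a scan window
#'
#' Arithmetic mean of each channel (ETCO2, MAP, HR, SpO2) within the scan
#' window.
#'
#' @param timeseries data.frame with a \code{time} column and physiological
#'   channels.
#' @param window numeric length-2 window (start, end), same units as
#'   \code{time}.
#' @param channels channels to average.
#' @return one-row data.frame of channel means.
#' @export
summarizeCondition <- function(timeseries, window,
                               channels = c("etco2", "map", "hr", "spo2")) {
  sel <- timeseries$time >= window[1] & timeseries$time <= window[2]
  if (!any(sel)) stop("scan window contains no samples")
  channels <- intersect(channels, names(timeseries))
  as.data.frame(lapply(
    setNames(channels, channels),
    function(ch) mean(timeseries[[ch]][sel])
  ))
}

#' Per-vessel and global CVR from measurements
#'
#' Joins per-condition vessel measurements with the physiological condition
#' table, computes CVC per vessel and globally (ICA_L + ICA_R + BA), fits
#' the CVC-versus-ETCO2 line for every scope and, when brain volumes are
#' given, for brain-volume-corrected global flow.
#'
#' @param measurements data.frame: vessel, condition, flow_ml_min, csa_cm2.
#' @param conditions data.frame: condition, etco2, map.
#' @param mode fit mode, see \code{\link{fitCVR}}.
#' @param gm,wm optional gray/white-matter volumes, liters.
#' @param subject optional subject id carried into the output.
#' @return data.frame: subject, scope, slope, intercept, n_points, mode.
#' @export
cvrTable <- function(measurements, conditions,
                     mode = c("all_conditions", "hypercapnic_only"),
                     gm = NULL, wm = NULL, subject = NA_character_) {
  mode <- match.arg(mode)
  m <- merge(measurements, conditions, by = "condition")
  rows <- list()
  for (lab in unique(m$vessel)) {
    sub <- m[m$vessel == lab, ]
    fit <- fitCVR(
      data.frame(
        etco2 = sub$etco2, cvc = computeCVC(sub$flow_ml_min, sub$map),
        condition = sub$condition
      ),
      mode = mode, scope = lab
    )
    rows[[length(rows) + 1L]] <- fit
  }
  gflow <- vapply(conditions$condition, function(cc) {
    globalFlow(m[m$condition == cc, c("vessel", "flow_ml_min")])
  }, numeric(1))
  rows[[length(rows) + 1L]] <- fitCVR(
    data.frame(
      etco2 = conditions$etco2,
      cvc = computeCVC(gflow, conditions$map),
      condition = conditions$condition
    ),
    mode = mode, scope = "global"
  )
  if (!is.null(gm) && !is.null(wm)) {
    rows[[length(rows) + 1L]] <- fitCVR(
      data.frame(
        etco2 = conditions$etco2,
        cvc = computeCVC(correctGlobalFlow(gflow, gm, wm), conditions$map),
        condition = conditions$condition
      ),
      mode = mode, scope = "global_bv_corrected"
    )
  }
  do.call(rbind, lapply(rows, function(f) {
    data.frame(
      subject = subject, scope = f@scope, slope = f@slope,
      intercept = f@intercept, n_points = f@nPoints, mode = f@mode,
      stringsAsFactors = FALSE
    )
  }))
}
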