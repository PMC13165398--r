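# Per-frame pose features from 6-keypoint tracks: kinematics, dispersion,
# geometry, body angles, reversal scoring, behavioral sleep, the assembled
# 57-dimensional feature vector, and its principal-component reduction.

# Base features (39) and which of them also get a rolling SD column (18);
# together with the rolling means this yields the 57-column feature vector.
BASE_FEATURES <- c(
  as.vector(rbind(paste0("x_", COORD_KEYPOINTS), paste0("y_", COORD_KEYPOINTS))),
  paste0(COORD_KEYPOINTS, "_velocity"),
  "snout_acceleration", "disp", "bounding_area", "body_length_norm",
  "tail_fan_prop",
  paste0("count_", KEYPOINTS),
  "dist_snout", "heading_direction",
  "alpha1", "alpha2", "alpha3", "alpha_all",
  "theta1", "theta2", "theta3",
  "dot_product", "reversal", "reversal_binary",
  "sleep"
)

SD_FEATURES <- c(
  paste0(COORD_KEYPOINTS, "_velocity"),
  "snout_acceleration", "disp", "bounding_area", "body_length_norm",
  "tail_fan_prop",
  "alpha1", "alpha2", "alpha3", "alpha_all",
  "theta1", "theta2", "theta3",
  "dot_product"
)

#' @keywords internal
trailingMinMax <- function(x, w) {
  n <- length(x)
  mx <- rep(-Inf, n); mn <- rep(Inf, n)
  xz <- x
  for (k in 0:(w - 1L)) {
    if (k >= n) break
    sh <- c(rep(NA_real_, k), xz[seq_len(n - k)])
    mx <- pmax(mx, sh, na.rm = TRUE)
    mn <- pmin(mn, sh, na.rm = TRUE)
  }
  mx[!is.finite(mx)] <- NA_real_
  mn[!is.finite(mn)] <- NA_real_
  list(min = mn, max = mx)
}

#' Per-frame kinematics: keypoint velocities, snout acceleration, heading
#'
#' Coordinates are first passed through the causal FIR jitter filter
#' (`config$filterB`), then differentiated against the frame timestamps, so
#' velocities are in pixels/second and robust to dropped frames. Heading is
#' the unit vector from midbody to snout. Frames whose required keypoints
#' are invisible yield missing values.
#'
#' @param track a [KeypointTrack-class].
#' @param config a [poseConfig()].
#' @return list with `velocity` (frames x 5 speeds, px/s),
#'   `velocityVec` (list of frames x 2 velocity vectors per keypoint),
#'   `acceleration` (snout, px/s^2), `heading` (frames x 2 unit vectors).
#' @export
computeKinematics <- function(track, config = poseConfig()) {
  n <- nFrames(track)
  ts <- timestamps(track)
  vel <- matrix(NA_real_, n, length(COORD_KEYPOINTS),
                dimnames = list(NULL, paste0(COORD_KEYPOINTS, "_velocity")))
  velVec <- stats::setNames(vector("list", length(COORD_KEYPOINTS)),
                            COORD_KEYPOINTS)
  if (n < 2L) {
    warning("kinematics undefined for single-frame input; returning missing")
    return(list(velocity = vel, velocityVec = velVec,
                acceleration = rep(NA_real_, n),
                heading = matrix(NA_real_, n, 2)))
  }
  dt <- c(NA_real_, diff(ts))
  filt <- function(x) lfilterFIR(x, config$filterB)
  for (kp in COORD_KEYPOINTS) {
    xy <- keypointCoords(track, kp)
    fx <- filt(xy[, 1]); fy <- filt(xy[, 2])
    vx <- c(NA_real_, diff(fx)) / dt
    vy <- c(NA_real_, diff(fy)) / dt
    velVec[[kp]] <- cbind(vx, vy)
    vel[, paste0(kp, "_velocity")] <- sqrt(vx^2 + vy^2)
  }
  sv <- velVec[["snout"]]
  acc <- sqrt((c(NA_real_, diff(sv[, 1])) / dt)^2 +
              (c(NA_real_, diff(sv[, 2])) / dt)^2)
  sn <- keypointCoords(track, "snout")
  mb <- keypointCoords(track, "midbody")
  hx <- sn[, 1] - mb[, 1]; hy <- sn[, 2] - mb[, 2]
  hn <- sqrt(hx^2 + hy^2)
  heading <- cbind(hx / hn, hy / hn)
  heading[!is.finite(heading)] <- NA_real_
  list(velocity = vel, velocityVec = velVec, acceleration = acc,
       heading = heading)
}

#' Snout dispersion area over a trailing window
#'
#' Area of the circle whose diameter is the diagonal of the axis-aligned
#' bounding box of snout positions in the trailing `dispersionWindow`-frame
#' window (40 frames = 2 s by default):
#' area = pi * ((dx^2 + dy^2) / 4). Windows at the start of the recording
#' are truncated; all-missing windows give a missing value.
#'
#' @param snout frames x 2 matrix of snout coordinates.
#' @param config a [poseConfig()].
#' @return numeric vector of per-frame areas (px^2).
#' @export
computeDispersion <- function(snout, config = poseConfig()) {
  w <- config$dispersionWindow
  rx <- trailingMinMax(snout[, 1], w)
  ry <- trailingMinMax(snout[, 2], w)
  dx <- rx$max - rx$min
  dy <- ry$max - ry$min
  pi * (dx^2 + dy^2) / 4
}

#' Whole-body geometry features
#'
#' Bounding area applies the dispersion circle rule to all visible keypoints
#' over the trailing window, then is centered and normalized by its mean
#' within each calendar recording day. Body length sums the four body
#' segments and is day-normalized the same way; the tail-fan proportion is
#' that segment's share of body length.
#'
#' @param track a [KeypointTrack-class].
#' @param config a [poseConfig()].
#' @return list with `bounding_area` (day-normalized), `body_length` (raw px),
#'   `body_length_norm`, `tail_fan_prop`, `counts` (frames x 6, 0/1),
#'   `dist_snout` (px to nearest tank edge), and `flags` (days whose
#'   normalization was skipped as degenerate).
#' @export
computeGeometry <- function(track, config = poseConfig()) {
  n <- nFrames(track)
  ts <- timestamps(track)
  w <- config$dispersionWindow
  vis <- keypointVisible(track)
  xs <- track@coords[, paste0("x_", KEYPOINTS), drop = FALSE]
  ys <- track@coords[, paste0("y_", KEYPOINTS), drop = FALSE]
  xs[!vis] <- NA_real_; ys[!vis] <- NA_real_
  fx_min <- suppressWarnings(apply(xs, 1, min, na.rm = TRUE))
  fx_max <- suppressWarnings(apply(xs, 1, max, na.rm = TRUE))
  fy_min <- suppressWarnings(apply(ys, 1, min, na.rm = TRUE))
  fy_max <- suppressWarnings(apply(ys, 1, max, na.rm = TRUE))
  fx_min[!is.finite(fx_min)] <- NA; fx_max[!is.finite(fx_max)] <- NA
  fy_min[!is.finite(fy_min)] <- NA; fy_max[!is.finite(fy_max)] <- NA
  lo_x <- trailingMinMax(fx_min, w)$min; hi_x <- trailingMinMax(fx_max, w)$max
  lo_y <- trailingMinMax(fy_min, w)$min; hi_y <- trailingMinMax(fy_max, w)$max
  areaRaw <- pi * ((hi_x - lo_x)^2 + (hi_y - lo_y)^2) / 4
  seg <- function(a, b) {
    pa <- keypointCoords(track, a); pb <- keypointCoords(track, b)
    sqrt((pa[, 1] - pb[, 1])^2 + (pa[, 2] - pb[, 2])^2)
  }
  tailFan <- seg("tail", "fan")
  bodyLen <- seg("snout", "midbody") + seg("midbody", "endbody") +
    seg("endbody", "tail") + tailFan
  day <- floor(ts / 86400)
  normByDay <- function(x) {
    out <- rep(NA_real_, n)
    flagged <- numeric(0)
    for (d in unique(day)) {
      sel <- day == d
      m <- mean(x[sel], na.rm = TRUE)
      if (!is.finite(m) || m == 0) {
        out[sel] <- x[sel]            # degenerate day: normalization skipped
        flagged <- c(flagged, d)
      } else out[sel] <- (x[sel] - m) / m
    }
    list(x = out, flagged = flagged)
  }
  areaN <- normByDay(areaRaw)
  lenN <- normByDay(bodyLen)
  sn <- keypointCoords(track, "snout")
  tank <- track@tankSize
  distSnout <- pmin(sn[, 1], tank[1] - sn[, 1], sn[, 2], tank[2] - sn[, 2])
  list(
    bounding_area = areaN$x, bounding_area_raw = areaRaw,
    body_length = bodyLen, body_length_norm = lenN$x,
    tail_fan_prop = tailFan / bodyLen,
    counts = matrix(as.numeric(vis), n, length(KEYPOINTS),
                    dimnames = list(NULL, paste0("count_", KEYPOINTS))),
    dist_snout = distSnout,
    flags = list(bounding_area_days = areaN$flagged,
                 body_length_days = lenN$flagged)
  )
}

#' Body connectivity and curvature angles
#'
#' `alpha1..3` are the interior angles (radians, in [0, pi]) at the middle
#' keypoint of the consecutive triples snout-midbody-endbody,
#' midbody-endbody-tail, endbody-tail-fan; `alpha_all` is their sum.
#' `theta1..3` are the signed angles of the local body tangent at midbody,
#' endbody, and tail relative to heading; the tangent at a keypoint is the
#' direction from its posterior to its anterior neighbour, and angles are
#' positive when the tangent points toward the animal's left
#' (counterclockwise from heading in tank coordinates).
#'
#' @param track a [KeypointTrack-class].
#' @return list with `alpha1..3`, `alpha_all`, `theta1..3`.
#' @export
computeAngles <- function(track) {
  P <- lapply(c("snout", "midbody", "endbody", "tail", "fan"),
              function(k) keypointCoords(track, k))
  names(P) <- c("snout", "midbody", "endbody", "tail", "fan")
  ang3 <- function(a, b, c) {
    u <- a - b; v <- c - b
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cosang <- rowSums(u * v) / (nu * nv)
    out <- acos(pmin(1, pmax(-1, cosang)))
    out[nu == 0 | nv == 0] <- NA_real_   # coincident keypoints: undefined
    out
  }
  alpha1 <- ang3(P$snout, P$midbody, P$endbody)
  alpha2 <- ang3(P$midbody, P$endbody, P$tail)
  alpha3 <- ang3(P$endbody, P$tail, P$fan)
  h <- P$snout - P$midbody
  hn <- sqrt(rowSums(h^2)); h <- h / hn
  signedAngle <- function(t) {
    tn <- sqrt(rowSums(t^2))
    t <- t / tn
    out <- atan2(h[, 1] * t[, 2] - h[, 2] * t[, 1], rowSums(h * t))
    out[tn == 0 | hn == 0] <- NA_real_
    out
  }
  list(
    alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
    alpha_all = alpha1 + alpha2 + alpha3,
    theta1 = signedAngle(P$snout - P$endbody),
    theta2 = signedAngle(P$midbody - P$tail),
    theta3 = signedAngle(P$endbody - P$fan)
  )
}

#' Reversal scoring
#'
#' Keypoint coordinates are pre-smoothed by a trailing rolling mean over
#' `config$rollingWindow` frames; the dot product of the unit heading with
#' the snout velocity vector is negative when the animal moves backward.
#' Zero-velocity frames score 0 and are not reversals.
#'
#' @param track a [KeypointTrack-class].
#' @param config a [poseConfig()].
#' @return list with `dot_product`, `reversal` (backward speed magnitude),
#'   `reversal_binary` (0/1).
#' @export
detectReversal <- function(track, config = poseConfig()) {
  w <- config$rollingWindow
  ts <- timestamps(track)
  dt <- c(NA_real_, diff(ts))
  sm <- function(xy) cbind(rollMean(xy[, 1], w), rollMean(xy[, 2], w))
  sn <- sm(keypointCoords(track, "snout"))
  mb <- sm(keypointCoords(track, "midbody"))
  h <- sn - mb
  hn <- sqrt(rowSums(h^2))
  h <- h / hn
  v <- cbind(c(NA_real_, diff(sn[, 1])) / dt, c(NA_real_, diff(sn[, 2])) / dt)
  dp <- rowSums(h * v)
  speed <- sqrt(rowSums(v^2))
  dp[!is.na(speed) & speed == 0] <- 0
  list(dot_product = dp,
       reversal = pmax(-dp, 0),
       reversal_binary = as.numeric(!is.na(dp) & dp < 0))
}

#' Behavioral sleep scoring from the dispersion series
#'
#' Frames whose dispersion area is below the threshold are inactive; maximal
#' runs of consecutive inactive frames lasting at least `sleepMinDuration`
#' seconds (1 min by default, i.e. `fps * 60` frames) are labeled sleep in
#' their entirety. Missing dispersion breaks a run.
#'
#' @param dispersion per-frame dispersion areas.
#' @param config a [poseConfig()].
#' @param fps frames per second of the recording.
#' @return logical vector, one value per frame.
#' @export
scoreSleep <- function(dispersion, config = poseConfig(), fps = 20) {
  inactive <- !is.na(dispersion) & dispersion < config$sleepDispersionThreshold
  minFrames <- round(config$sleepMinDuration * fps)
  r <- rle(inactive)
  sleepRun <- r$values & r$lengths >= minFrames
  inverse.rle(list(values = sleepRun, lengths = r$lengths))
}

#' Assemble the 57-dimensional pose feature matrix
#'
#' Computes all base features on the shared frame index and expands them by
#' trailing rolling statistics over `config$rollingWindow` frames: a rolling
#' mean of every base feature plus a rolling standard deviation of the
#' kinematic and shape features, for 57 named columns in a fixed, documented
#' order (`mean_*` then `std_*`).
#'
#' @param track a [KeypointTrack-class].
#' @param config a [poseConfig()].
#' @return a [PoseFeatures-class] with the feature matrix filled in (PC
#'   slots are empty until [reduceToPCs()] is called).
#' @export
assembleFeatures <- function(track, config = poseConfig()) {
  n <- nFrames(track)
  kin <- computeKinematics(track, config)
  sn <- keypointCoords(track, "snout")
  disp <- computeDispersion(sn, config)
  geo <- computeGeometry(track, config)
  ang <- computeAngles(track)
  rev <- detectReversal(track, config)
  sleep <- scoreSleep(disp, config, fps = track@fps)
  base <- matrix(NA_real_, n, length(BASE_FEATURES),
                 dimnames = list(NULL, BASE_FEATURES))
  for (kp in COORD_KEYPOINTS) {
    xy <- keypointCoords(track, kp)
    base[, paste0("x_", kp)] <- xy[, 1]
    base[, paste0("y_", kp)] <- xy[, 2]
    base[, paste0(kp, "_velocity")] <- kin$velocity[, paste0(kp, "_velocity")]
  }
  base[, "snout_acceleration"] <- kin$acceleration
  base[, "disp"] <- disp
  base[, "bounding_area"] <- geo$bounding_area
  base[, "body_length_norm"] <- geo$body_length_norm
  base[, "tail_fan_prop"] <- geo$tail_fan_prop
  base[, colnames(geo$counts)] <- geo$counts
  base[, "dist_snout"] <- geo$dist_snout
  base[, "heading_direction"] <- atan2(kin$heading[, 2], kin$heading[, 1])
  for (nm in c("alpha1", "alpha2", "alpha3", "alpha_all",
               "theta1", "theta2", "theta3"))
    base[, nm] <- ang[[nm]]
  base[, "dot_product"] <- rev$dot_product
  base[, "reversal"] <- rev$reversal
  base[, "reversal_binary"] <- rev$reversal_binary
  base[, "sleep"] <- as.numeric(sleep)
  w <- config$rollingWindow
  means <- apply(base, 2, rollMean, w = w)
  colnames(means) <- paste0("mean_", BASE_FEATURES)
  sds <- apply(base[, SD_FEATURES, drop = FALSE], 2, rollSd, w = w)
  colnames(sds) <- paste0("std_", SD_FEATURES)
  features <- cbind(means, sds)
  if (ncol(features) != 57L)
    stop("feature allocation does not sum to 57 columns (got ",
         ncol(features), "); check BASE_FEATURES/SD_FEATURES")
  methods::new("PoseFeatures",
    features = features,
    pcs = matrix(numeric(0), 0, 0), loadings = matrix(numeric(0), 0, 0),
    center = numeric(0), scale = numeric(0), explainedVar = numeric(0),
    dropped = character(0)
  )
}

#' Reduce pose features to smoothed principal components
#'
#' Features are z-scored (constant columns dropped with a warning and
#' recorded in the model), projected onto the top `nPcs` principal
#' components, and the scores smoothed with a trailing moving average over
#' `config$smoothWindow` frames. Rows with missing features get missing
#' scores; the PCA itself is fit on complete rows.
#'
#' @param x a [PoseFeatures-class] or a numeric feature matrix.
#' @param nPcs number of components to retain (default 15).
#' @param config a [poseConfig()].
#' @return a [PoseFeatures-class] with `pcs`, `loadings`, `center`, `scale`,
#'   `explainedVar`, and `dropped` filled in.
#' @export
reduceToPCs <- function(x, nPcs = 15L, config = poseConfig()) {
  feats <- if (is(x, "PoseFeatures")) featureMatrix(x) else as.matrix(x)
  sds <- apply(feats, 2, stats::sd, na.rm = TRUE)
  constant <- is.na(sds) | sds == 0
  dropped <- colnames(feats)[constant]
  if (length(dropped))
    warning("dropping constant feature columns: ",
            paste(dropped, collapse = ", "))
  keep <- feats[, !constant, drop = FALSE]
  nPcs <- min(nPcs, ncol(keep))
  if (ncol(keep) < 1L) stop("no non-degenerate feature columns")
  z <- zscoreCols(keep)
  complete <- stats::complete.cases(z)
  if (sum(complete) <= nPcs) stop("too few complete frames for PCA")
  pc <- stats::prcomp(z[complete, , drop = FALSE], center = FALSE,
                      scale. = FALSE)
  loadings <- pc$rotation[, seq_len(nPcs), drop = FALSE]
  scores <- matrix(NA_real_, nrow(z), nPcs,
                   dimnames = list(NULL, colnames(loadings)))
  scores[complete, ] <- z[complete, , drop = FALSE] %*% loadings
  smoothed <- apply(scores, 2, rollMean, w = config$smoothWindow)
  if (!is.matrix(smoothed)) smoothed <- matrix(smoothed, ncol = nPcs)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  out <- if (is(x, "PoseFeatures")) x else
    methods::new("PoseFeatures", features = feats,
                 pcs = matrix(numeric(0), 0, 0),
                 loadings = matrix(numeric(0), 0, 0),
                 center = numeric(0), scale = numeric(0),
                 explainedVar = numeric(0), dropped = character(0))
  out@pcs <- smoothed
  out@loadings <- loadings
  out@center <- attr(z, "center")
  out@scale <- attr(z, "scale")
  out@explainedVar <- ev[seq_len(nPcs)]
  out@dropped <- dropped
  methods::validObject(out)
  out
}

#' Linear separability of two frame classes in PC space
#'
#' Mean stratified k-fold cross-validated accuracy of a linear max-margin
#' classifier on the top `nPcs` principal components; 0.5 means the classes
#' are not linearly separable, 1 means perfectly separable.
#'
#' @param scores frames x PCs score matrix.
#' @param labels binary per-frame labels (two classes).
#' @param nPcs number of leading PCs to use (default 5).
#' @param nFolds cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @return mean held-out accuracy in [0, 1].
#' @export
linearSeparability <- function(scores, labels, nPcs = 5L, nFolds = 5L,
                               seed = 1L) {
  scores <- as.matrix(scores)
  keep <- stats::complete.cases(scores) & !is.na(labels)
  scores <- scores[keep, seq_len(min(nPcs, ncol(scores))), drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("need exactly two label classes")
  y <- ifelse(labels == classes[2], 1, -1)
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in c(-1, 1)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep(seq_len(nFolds), length.out = length(idx)))
    }
    accs <- vapply(seq_len(nFolds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      m <- svmLinearFit(scores[tr, , drop = FALSE], y[tr])
      mean(svmLinearPredict(m, scores[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  })
}
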