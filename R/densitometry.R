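# Lane densitometry: background subtraction, band location, and the
# di-/tri-nucleosome spacing index.

#' Construct a lane profile
#'
#' A `lane_profile` is a 1-D densitometry trace: intensity as a function of
#' a strictly increasing migration coordinate (pixels or mm). An optional
#' semi-log calibration (`intercept`, `slope` of migration vs log10 length)
#' links migration to fragment length. Smaller migration coordinates
#' correspond to larger (slower) fragments.
#'
#' @param position Strictly increasing migration coordinates.
#' @param intensity Intensities, same length as `position`.
#' @param calibration Optional named vector `c(intercept=, slope=)` with
#'   `slope < 0`.
#' @param lane_id Label.
#' @param background_subtracted Has background already been removed?
#' @return An object of class `lane_profile`.
#' @export
lane_profile <- function(position, intensity, calibration = NULL,
                         lane_id = "lane", background_subtracted = FALSE) {
  position <- as.numeric(position); intensity <- as.numeric(intensity)
  if (length(position) != length(intensity))
    stop("position and intensity must have equal length")
  if (length(position) < 2L) stop("a profile needs at least two points")
  if (any(diff(position) <= 0)) stop("position must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (!is.null(calibration)) {
    if (!all(c("intercept", "slope") %in% names(calibration)))
      stop("calibration must carry named 'intercept' and 'slope'")
    if (calibration[["slope"]] >= 0)
      stop("calibration slope must be negative (monotone mobility)")
  }
  structure(list(position = position, intensity = intensity,
                 calibration = calibration, lane_id = lane_id,
                 background_subtracted = isTRUE(background_subtracted)),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("<lane_profile> '%s': %d points, migration %g..%g%s%s\n",
              x$lane_id, length(x$position), min(x$position), max(x$position),
              if (x$background_subtracted) ", background-subtracted" else "",
              if (!is.null(x$calibration)) ", calibrated" else ""))
  invisible(x)
}

# Running extremum with a centred window of `k` points (k odd enforced).
running_extremum <- function(y, k, fun) {
  n <- length(y)
  k <- min(k, n)
  if (k %% 2 == 0) k <- k + 1
  h <- (k - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- fun(y[max(1, i - h):min(n, i + h)])
  out
}

# Morphological opening (erosion then dilation): the standard rolling
# baseline. Never exceeds the signal, flattens features narrower than the
# window, and is exactly idempotent.
rolling_baseline <- function(y, k)
  running_extremum(running_extremum(y, k, min), k, max)

#' Subtract background staining from a lane profile
#'
#' `rolling_minimum` estimates the baseline by morphological opening (a
#' running minimum followed by a running maximum over the same window, in
#' migration units) and subtracts it; `linear_anchors` fits a straight line
#' between the minimum of the first and last window-width stretch. Results
#' are floored at zero. Opening is idempotent, so re-applying
#' `rolling_minimum` to an already-subtracted noiseless profile changes
#' nothing; the window must be wider than the widest feature to preserve
#' (for band ladders, wider than the band spacing, or the inter-band
#' valleys are absorbed into the baseline).
#'
#' @param profile A [lane_profile()].
#' @param method `"rolling_minimum"` (default) or `"linear_anchors"`.
#' @param window Baseline window in migration units; defaults to 3x a
#'   nominal 10-unit band width.
#' @return The background-subtracted [lane_profile()] (flag set).
#' @export
subtract_background <- function(profile,
                                method = c("rolling_minimum", "linear_anchors"),
                                window = 30) {
  stopifnot(inherits(profile, "lane_profile"))
  method <- match.arg(method)
  span <- diff(range(profile$position))
  if (window > span) stop("background window exceeds the profile span")
  step <- mean(diff(profile$position))
  y <- profile$intensity
  if (method == "rolling_minimum") {
    k <- max(3L, round(window / step))
    baseline <- rolling_baseline(y, k)
  } else {
    n <- length(y)
    k <- max(1L, round(window / step))
    i1 <- which.min(y[seq_len(min(k, n))])
    i2 <- n - min(k, n) + which.min(y[seq(n - min(k, n) + 1L, n)])
    x1 <- profile$position[i1]; x2 <- profile$position[i2]
    if (x2 == x1) baseline <- rep(y[i1], n)
    else baseline <- y[i1] + (y[i2] - y[i1]) * (profile$position - x1) / (x2 - x1)
  }
  lane_profile(profile$position, pmax(y - baseline, 0),
               calibration = profile$calibration, lane_id = profile$lane_id,
               background_subtracted = TRUE)
}

#' Define di-/tri-nucleosome band windows
#'
#' Band windows delimit the migration intervals in which the dinucleosome
#' and trinucleosome bands are sought. They can be given explicitly or
#' derived from a mobility calibration and the expected nucleosomal repeat:
#' the expected di/tri fragment lengths are `k * repeat - linker` for
#' k = 2, 3 (an MNase-trimmed fragment of k nucleosomes spans k footprints
#' and k - 1 linkers), and each window extends `window_frac` of the di-tri
#' band spacing either side of the expected position.
#'
#' @param di,tri Explicit `c(lo, hi)` migration windows (di at larger
#'   migration than tri, since dinucleosomes run faster).
#' @param calibration Named `c(intercept=, slope=)` mobility map, used when
#'   windows are not explicit.
#' @param repeat_bp Nucleosomal repeat, bp.
#' @param footprint Core-particle footprint, bp (linker = repeat - footprint).
#' @param window_frac Half-width as a fraction of the di-tri spacing.
#' @return An object of class `band_windows` with elements `di` and `tri`.
#' @export
band_windows <- function(di = NULL, tri = NULL, calibration = NULL,
                         repeat_bp = 200, footprint = 147,
                         window_frac = 0.2) {
  if (is.null(di) || is.null(tri)) {
    if (is.null(calibration))
      stop("supply explicit di/tri windows or a calibration")
    linker <- repeat_bp - footprint
    m <- function(len) calibration[["intercept"]] + calibration[["slope"]] * log10(len)
    c2 <- m(2 * repeat_bp - linker)
    c3 <- m(3 * repeat_bp - linker)
    half <- window_frac * abs(c2 - c3)
    di <- sort(c(c2 - half, c2 + half))
    tri <- sort(c(c3 - half, c3 + half))
  }
  di <- sort(as.numeric(di)); tri <- sort(as.numeric(tri))
  if (max(tri) > min(di))
    stop("band windows must be disjoint with tri at smaller migration than di")
  structure(list(di = di, tri = tri), class = "band_windows")
}

# Brute-force windowed extrema. Returns index or NA when the window misses
# the profile support.
window_extremum <- function(profile, window, what = c("max", "min"),
                            exclusive = FALSE) {
  what <- match.arg(what)
  p <- profile$position
  inside <- if (exclusive) p > window[1] & p < window[2]
            else p >= window[1] & p <= window[2]
  idx <- which(inside)
  if (length(idx) == 0) return(NA_integer_)
  y <- profile$intensity[idx]
  idx[if (what == "max") which.max(y) else which.min(y)]
}

#' Locate di- and tri-nucleosome bands and the inter-peak valley
#'
#' Within each band window, finds the intensity maximum and its migration
#' position; strictly between the two peak positions, finds the minimum
#' (the valley). Ties in the valley are broken toward the midpoint of the
#' two peaks. A peak sitting on a window edge is flagged as not a local
#' extremum.
#'
#' @param profile A background-subtracted [lane_profile()].
#' @param windows A [band_windows()].
#' @return List with `p2`, `p3`, `v` (each `list(position, height)`),
#'   and logical flags `p2_local`, `p3_local`.
#' @export
locate_bands <- function(profile, windows) {
  stopifnot(inherits(profile, "lane_profile"), inherits(windows, "band_windows"))
  if (!profile$background_subtracted)
    warning("profile is not flagged as background-subtracted")
  i2 <- window_extremum(profile, windows$di, "max")
  i3 <- window_extremum(profile, windows$tri, "max")
  if (is.na(i2)) stop("band not found: di window misses the profile support")
  if (is.na(i3)) stop("band not found: tri window misses the profile support")
  p <- profile$position; y <- profile$intensity
  lo <- min(p[i2], p[i3]); hi <- max(p[i2], p[i3])
  between <- which(p > lo & p < hi)
  if (length(between) == 0)
    stop("degenerate profile: di and tri peaks are coincident or adjacent")
  ymin <- min(y[between])
  cand <- between[y[between] <= ymin]
  mid <- (lo + hi) / 2
  iv <- cand[which.min(abs(p[cand] - mid))]
  local_flag <- function(i, w) p[i] > w[1] && p[i] < w[2] ||
    (i > 1 && i < length(p) && y[i] >= y[i - 1] && y[i] >= y[i + 1])
  list(p2 = list(position = p[i2], height = y[i2]),
       p3 = list(position = p[i3], height = y[i3]),
       v = list(position = p[iv], height = y[iv]),
       p2_local = local_flag(i2, windows$di),
       p3_local = local_flag(i3, windows$tri))
}

#' Compute the nucleosome spacing index of a lane
#'
#' The spacing index summarizes how periodic a partial MNase digestion
#' ladder is: with P2 the dinucleosome peak height, P3 the trinucleosome
#' peak height, and V the minimum of the valley between them,
#'
#'   index = 0.5 * (P2 + P3) - V.
#'
#' Well-separated di- and tri-nucleosome bands (periodic chromatin) give a
#' large index; a smear (random nucleosome positions) gives an index near
#' zero. The index is invariant under additive intensity shifts and scales
#' linearly with intensity, so it is only comparable across lanes run and
#' imaged under identical conditions.
#'
#' @param profile A background-subtracted [lane_profile()].
#' @param windows A [band_windows()]; if `NULL`, derived from the profile's
#'   calibration with [band_windows()] defaults.
#' @return An object of class `spacing_index_result` with fields `P2`,
#'   `P3`, `V`, `index`, `p2_pos`, `p3_pos`, `v_pos`, `lane_id`.
#' @export
compute_spacing_index <- function(profile, windows = NULL) {
  stopifnot(inherits(profile, "lane_profile"))
  if (is.null(windows)) {
    if (is.null(profile$calibration))
      stop("no windows supplied and profile carries no calibration")
    windows <- band_windows(calibration = profile$calibration)
  }
  b <- locate_bands(profile, windows)
  res <- structure(
    list(P2 = b$p2$height, P3 = b$p3$height, V = b$v$height,
         index = 0.5 * (b$p2$height + b$p3$height) - b$v$height,
         p2_pos = b$p2$position, p3_pos = b$p3$position, v_pos = b$v$position,
         p2_local = b$p2_local, p3_local = b$p3_local,
         lane_id = profile$lane_id),
    class = "spacing_index_result")
  res
}

#' @export
print.spacing_index_result <- function(x, ...) {
  cat(sprintf("<spacing_index_result> '%s': P2=%.3g (at %.4g), P3=%.3g (at %.4g), V=%.3g (at %.4g)\n  spacing index = %.4g\n",
              x$lane_id, x$P2, x$p2_pos, x$P3, x$p3_pos, x$V, x$v_pos, x$index))
  invisible(x)
}

#' Extract lane profiles from a grayscale gel image
#'
#' Averages pixel columns within each lane boundary to produce one
#' densitometry trace per lane. By default wells are at the top and
#' migration increases downward, i.e. the migration coordinate is the row
#' index.
#'
#' @param image Numeric matrix (rows = migration, columns = lateral
#'   position), e.g. from [read_pgm()].
#' @param lanes List of `c(first_col, last_col)` pixel intervals, one per
#'   lane; must be non-overlapping and within the image.
#' @param lane_ids Optional labels.
#' @return List of [lane_profile()] objects.
#' @export
extract_lane_profiles <- function(image, lanes, lane_ids = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (!is.list(lanes) || length(lanes) == 0)
    stop("lanes must be a non-empty list of column intervals")
  iv <- t(vapply(lanes, function(l) sort(as.integer(l)), integer(2)))
  if (any(iv[, 1] < 1L) || any(iv[, 2] > ncol(image)))
    stop("lane boundaries fall outside the image")
  if (nrow(iv) > 1) {
    o <- order(iv[, 1])
    if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)]))
      stop("lane intervals overlap")
  }
  if (is.null(lane_ids)) lane_ids <- paste0("lane", seq_len(nrow(iv)))
  out <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    cols <- iv[i, 1]:iv[i, 2]
    out[[i]] <- lane_profile(seq_len(nrow(image)) - 1,
                             rowMeans(image[, cols, drop = FALSE]),
                             lane_id = lane_ids[i])
  }
  out
}
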