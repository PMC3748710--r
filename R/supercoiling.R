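# Percent-supercoiling quantification of DNA supercoiling assay lanes.
#
# Convention: percent supercoiling = 100 * SC / (SC + Rel + N). Nicked DNA
# is counted in the total but never in the supercoiled amount, because the
# fraction of nicked molecules packaged into chromatin cannot be determined
# from the gel; percent supercoiling therefore reflects only closed-circular
# plasmid packaged into chromatin.

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Quantify a supercoiling assay lane
#'
#' Integrates (trapezoidal rule) the background-subtracted lane profile over
#' three disjoint migration windows — supercoiled (SC), relaxed topoisomer
#' cluster (Rel), and nicked open circular (N) — and computes percent
#' supercoiling as `100 * SC / (SC + Rel + N)`.
#'
#' @param profile A background-subtracted [lane_profile()].
#' @param windows Named list with `sc`, `relaxed`, `nicked` windows, each
#'   `c(lo, hi)` in migration units (see [supercoiling_windows()]); windows
#'   must not overlap.
#' @return An object of class `supercoiling_result` with integrated
#'   intensities and `percent_supercoiling`.
#' @export
quantify_supercoiling <- function(profile, windows = supercoiling_windows()) {
  stopifnot(inherits(profile, "lane_profile"))
  need <- c("sc", "relaxed", "nicked")
  if (!all(need %in% names(windows)))
    stop("windows must name 'sc', 'relaxed', and 'nicked' intervals")
  w <- lapply(windows[need], function(x) sort(as.numeric(x)))
  o <- order(vapply(w, `[`, numeric(1), 1))
  ws <- w[o]
  for (i in seq_len(length(ws) - 1))
    if (ws[[i + 1]][1] < ws[[i]][2])
      stop("species windows overlap: ", names(ws)[i], " and ", names(ws)[i + 1])
  integrate_window <- function(win) {
    sel <- profile$position >= win[1] & profile$position <= win[2]
    if (sum(sel) < 2) return(0)
    trapezoid(profile$position[sel], profile$intensity[sel])
  }
  sc <- integrate_window(w$sc)
  rel <- integrate_window(w$relaxed)
  nk <- integrate_window(w$nicked)
  total <- sc + rel + nk
  if (total <= 0)
    stop("undefined result: zero total signal in the species windows")
  structure(list(sc_intensity = sc, relaxed_intensity = rel,
                 nicked_intensity = nk,
                 percent_supercoiling = 100 * sc / total,
                 windows = w, lane_id = profile$lane_id,
                 reference_lane_id = NULL, delta_percent = NULL),
            class = "supercoiling_result")
}

#' @export
print.supercoiling_result <- function(x, ...) {
  cat(sprintf("<supercoiling_result> '%s': SC=%.4g Rel=%.4g N=%.4g -> %.2f%% supercoiling\n",
              x$lane_id, x$sc_intensity, x$relaxed_intensity,
              x$nicked_intensity, x$percent_supercoiling))
  if (!is.null(x$delta_percent))
    cat(sprintf("  delta vs '%s': %+.2f points\n", x$reference_lane_id, x$delta_percent))
  invisible(x)
}

#' Change in percent supercoiling relative to a reference lane
#'
#' The reference is typically the matched AMP-PNP (non-hydrolyzable analog)
#' lane or the zero-time lane of the same series; both lanes must have been
#' quantified under identical species windows. Negative values are allowed
#' (net loss of supercoiling).
#'
#' @param sample,reference `supercoiling_result` objects quantified with the
#'   same windows.
#' @return The `sample` result with `delta_percent` and
#'   `reference_lane_id` filled in.
#' @export
delta_supercoiling <- function(sample, reference) {
  stopifnot(inherits(sample, "supercoiling_result"),
            inherits(reference, "supercoiling_result"))
  same <- all(vapply(names(sample$windows), function(nm)
    isTRUE(all.equal(sample$windows[[nm]], reference$windows[[nm]])), logical(1)))
  if (!same)
    stop("comparability error: sample and reference were quantified with different windows")
  sample$reference_lane_id <- reference$lane_id
  sample$delta_percent <- sample$percent_supercoiling - reference$percent_supercoiling
  sample
}
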