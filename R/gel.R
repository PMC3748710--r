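# Electrophoretic mobility model and lane rendering.
#
# Migration follows the standard semi-log mobility law: migration distance
# is linear in log10(fragment length) with negative slope, so larger
# fragments sit nearer the well (smaller migration coordinate).

#' Construct a gel model
#'
#' Defines the mobility calibration and rendering parameters of a simulated
#' agarose gel lane. Migration in "pixels" is `intercept + slope *
#' log10(length_bp)` with `slope < 0`, so migration is strictly decreasing
#' in fragment length.
#'
#' @param intercept,slope Coefficients of the log-length to migration map.
#'   The defaults map the calibrated range `length_range` onto roughly
#'   pixels 50-950 of a 1000-point axis.
#' @param band_width Gaussian sigma of a band, migration units (pixels).
#' @param axis_length Number of sample points along the lane (>= 100).
#' @param noise_sd Additive Gaussian intensity noise per sample point.
#' @param baseline_drift Total linear baseline rise across the lane,
#'   intensity units.
#' @param length_range Calibrated fragment-length range, bp.
#' @param staining Intensity per (bp x molecule): intercalating-dye staining
#'   is proportional to mass, i.e. band area = staining * count * length.
#' @return An object of class `gel_model`.
#' @export
gel_model <- function(intercept = NULL, slope = NULL, band_width = 10,
                      axis_length = 1000L, noise_sd = 5, baseline_drift = 20,
                      length_range = c(50, 5000), staining = 1) {
  if (axis_length < 100L) stop("axis_length must be >= 100")
  if (band_width <= 0) stop("band_width must be positive")
  lr <- sort(as.numeric(length_range))
  if (is.null(slope))
    slope <- -(0.9 * axis_length) / (log10(lr[2]) - log10(lr[1]))
  if (slope >= 0) stop("slope must be negative (larger fragments migrate less)")
  if (is.null(intercept))
    intercept <- 0.05 * axis_length - slope * log10(lr[2])
  structure(list(intercept = intercept, slope = slope,
                 band_width = band_width, axis_length = as.integer(axis_length),
                 noise_sd = noise_sd, baseline_drift = baseline_drift,
                 length_range = lr, staining = staining),
            class = "gel_model")
}

#' @export
print.gel_model <- function(x, ...) {
  cat(sprintf("<gel_model> migration = %.1f %+.1f*log10(bp); axis %d px, band sigma %g px\n",
              x$intercept, x$slope, x$axis_length, x$band_width))
  invisible(x)
}

#' Map fragment length to migration coordinate (and back)
#'
#' @param gel A [gel_model()].
#' @param length_bp Fragment length(s), bp.
#' @return Migration coordinate(s) in pixels.
#' @export
migration_of_length <- function(gel, length_bp) {
  if (any(length_bp < gel$length_range[1] - 1e-9) ||
      any(length_bp > gel$length_range[2] + 1e-9))
    stop("fragment length outside the gel's calibrated range [",
         gel$length_range[1], ", ", gel$length_range[2], "] bp")
  gel$intercept + gel$slope * log10(length_bp)
}

#' @rdname migration_of_length
#' @param migration Migration coordinate(s), pixels.
#' @export
length_of_migration <- function(gel, migration) {
  10^((migration - gel$intercept) / gel$slope)
}

#' Render a fragment sample as a densitometry lane profile
#'
#' Each distinct fragment length contributes a Gaussian band centred at its
#' migration coordinate with area `staining * count * length`
#' (mass-proportional intercalating-dye staining). Additive Gaussian noise
#' and a linear baseline drift are then applied.
#'
#' @param fragments A non-empty [fragment_sample()].
#' @param gel A [gel_model()].
#' @param seed Optional integer seed for the noise.
#' @param lane_id Label carried on the returned profile.
#' @return A [lane_profile()] with calibration attached.
#' @export
render_gel_profile <- function(fragments, gel = gel_model(), seed = NULL,
                               lane_id = "lane") {
  if (!inherits(fragments, "fragment_sample")) stop("fragments must be a fragment_sample")
  if (length(fragments$lengths) == 0) stop("cannot render an empty fragment sample")
  if (!is.null(seed)) set.seed(seed)
  x <- seq_len(gel$axis_length) - 1
  centers <- migration_of_length(gel, fragments$lengths)
  areas <- gel$staining * fragments$counts * fragments$lengths
  y <- rep(0, gel$axis_length)
  s <- gel$band_width
  for (i in seq_along(centers))
    y <- y + areas[i] * stats::dnorm(x, centers[i], s)
  if (gel$baseline_drift != 0)
    y <- y + gel$baseline_drift * x / (gel$axis_length - 1)
  if (gel$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, gel$noise_sd)
  lane_profile(x, y, calibration = c(intercept = gel$intercept, slope = gel$slope),
               lane_id = lane_id)
}

#' Simulate a partial MNase digestion lane
#'
#' Convenience ensemble simulator: generates `n_molecules` independent
#' nucleosome arrays (all random or all regularly spaced), digests each with
#' [digest_mnase()], pools the fragments, and renders one lane. This is the
#' synthetic analogue of running a chromatin assembly or spacing reaction
#' and loading the deproteinized partial digest on an agarose gel.
#'
#' @param kind `"spaced"` or `"random"` array ensemble.
#' @param n_molecules Number of template molecules in the reaction.
#' @param template_length,footprint,repeat_length,jitter_sd Array parameters
#'   (see [generate_random_array()], [generate_spaced_array()]); for
#'   `kind = "random"` the nucleosome count is
#'   `floor(template_length / repeat_length)` so both kinds carry equal
#'   nucleosome numbers.
#' @param cut_probability_per_linker,trimming Digestion parameters.
#' @param gel A [gel_model()].
#' @param seed Integer seed controlling arrays, digestion, and noise.
#' @param lane_id Lane label.
#' @return A [lane_profile()]; the pooled [fragment_sample()] is attached as
#'   attribute `"fragments"`.
#' @export
simulate_mnase_lane <- function(kind = c("spaced", "random"),
                                n_molecules = 60, template_length = 3000,
                                footprint = 147, repeat_length = 200,
                                jitter_sd = 5,
                                cut_probability_per_linker = 0.5,
                                trimming = TRUE, gel = gel_model(),
                                seed = NULL, lane_id = kind[1]) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n_nuc <- floor(template_length / repeat_length)
  digests <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    arr <- if (kind == "spaced")
      generate_spaced_array(template_length, repeat_length, jitter_sd,
                            footprint, circular = TRUE)
    else
      generate_random_array(template_length, n_nuc, footprint, circular = TRUE)
    digests[[i]] <- digest_mnase(arr, cut_probability_per_linker, trimming)
  }
  pooled <- pool_fragments(digests)
  if (length(pooled$lengths) == 0) stop("digestion produced no fragments")
  # Guard against the occasional uncut-but-trimmed span exceeding the
  # calibrated range (whole-template fragments); clip to range.
  keep <- pooled$lengths >= gel$length_range[1] & pooled$lengths <= gel$length_range[2]
  pooled <- fragment_sample(pooled$lengths[keep], pooled$counts[keep],
                            provenance = pooled$provenance)
  prof <- render_gel_profile(pooled, gel, lane_id = lane_id)
  attr(prof, "fragments") <- pooled
  prof
}

#' Simulate a DNA supercoiling assay lane
#'
#' In the supercoiling assay, nucleosome formation on relaxed closed-circular
#' DNA in the presence of topoisomerase I changes the linking number by about
#' -1 per nucleosome; deproteinized products run as a fast supercoiled band,
#' while unassembled closed circles run as a cluster of relaxed topoisomers
#' and nicked molecules run as slow open circles regardless of assembly.
#'
#' Each of `n_molecules` plasmids is independently nicked with probability
#' `nick_fraction` and assembled with probability `fraction_assembled`;
#' assembled closed circles carry a binomially sampled nucleosome count
#' around `n_nucleosomes` (small position spread of the supercoiled band),
#' unassembled closed circles are spread over relaxed topoisomers with
#' linking-number difference 0 or +/-1.
#'
#' @param fraction_assembled Probability a molecule is chromatinized.
#' @param n_nucleosomes Mean nucleosome count per assembled molecule.
#' @param nick_fraction Probability a molecule is nicked (independent of
#'   assembly).
#' @param gel A [gel_model()]; only axis/band/noise fields are used.
#' @param n_molecules Plasmids per lane.
#' @param positions Migration coordinates (pixels) of the nicked, relaxed,
#'   and supercoiled species, in increasing-mobility order.
#' @param topo_spacing Pixel spacing between adjacent relaxed topoisomer
#'   bands.
#' @param intensity_per_molecule Stain intensity (band area units) each
#'   plasmid contributes; all molecules carry the same plasmid so staining
#'   per molecule is constant.
#' @param seed Integer seed.
#' @param lane_id Lane label.
#' @return A [lane_profile()] with attribute `"truth"`: a list with the
#'   exact sampled species fractions (`sc`, `relaxed`, `nicked`) and the
#'   implied `percent_supercoiling`.
#' @export
simulate_supercoiling_lane <- function(fraction_assembled, n_nucleosomes = 25,
                                       nick_fraction = 0.1, gel = gel_model(),
                                       n_molecules = 1000,
                                       positions = c(nicked = 200, relaxed = 320,
                                                     supercoiled = 650),
                                       topo_spacing = 12,
                                       intensity_per_molecule = 100,
                                       seed = NULL, lane_id = "lane") {
  for (p in c(fraction_assembled, nick_fraction))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("fraction_assembled and nick_fraction must be probabilities in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_nick <- stats::rbinom(1, n_molecules, nick_fraction)
  n_closed <- n_molecules - n_nick
  n_sc <- stats::rbinom(1, n_closed, fraction_assembled)
  n_rel <- n_closed - n_sc
  x <- seq_len(gel$axis_length) - 1
  y <- rep(0, gel$axis_length)
  s <- gel$band_width
  add_band <- function(y, center, weight)
    y + intensity_per_molecule * weight * stats::dnorm(x, center, s)
  if (n_nick > 0) y <- add_band(y, positions[["nicked"]], n_nick)
  if (n_rel > 0) {
    # Relaxed topoisomer cluster: delta-Lk 0 and +/-1 around the relaxed
    # position, Poisson-ish weights 0.5/0.25/0.25.
    split <- stats::rmultinom(1, n_rel, c(0.25, 0.5, 0.25))[, 1]
    for (j in 1:3)
      if (split[j] > 0)
        y <- add_band(y, positions[["relaxed"]] + (j - 2) * topo_spacing, split[j])
  }
  if (n_sc > 0) {
    # Binomial nucleosome counts; molecules missing turns run marginally
    # slower than the fully supercoiled position.
    m <- stats::rbinom(n_sc, size = n_nucleosomes, prob = 0.9)
    tab <- table(m)
    for (j in seq_along(tab)) {
      miss <- n_nucleosomes - as.integer(names(tab)[j])
      y <- add_band(y, positions[["supercoiled"]] - 1.5 * miss, as.integer(tab[j]))
    }
  }
  if (gel$baseline_drift != 0)
    y <- y + gel$baseline_drift * x / (gel$axis_length - 1)
  if (gel$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, gel$noise_sd)
  prof <- lane_profile(x, y, lane_id = lane_id)
  attr(prof, "truth") <- list(
    sc = n_sc / n_molecules, relaxed = n_rel / n_molecules,
    nicked = n_nick / n_molecules,
    percent_supercoiling = 100 * n_sc / n_molecules)
  prof
}

#' Default species windows for simulated supercoiling lanes
#'
#' Migration windows for the nicked, relaxed-topoisomer, and supercoiled
#' species matching the defaults of [simulate_supercoiling_lane()].
#'
#' @param positions,topo_spacing,band_width As in
#'   [simulate_supercoiling_lane()] / [gel_model()].
#' @return Named list of `c(lo, hi)` windows (`nicked`, `relaxed`, `sc`).
#' @export
supercoiling_windows <- function(positions = c(nicked = 200, relaxed = 320,
                                               supercoiled = 650),
                                 topo_spacing = 12, band_width = 10) {
  half <- 4 * band_width + topo_spacing
  list(nicked = c(positions[["nicked"]] - half, positions[["nicked"]] + half),
       relaxed = c(positions[["relaxed"]] - half, positions[["relaxed"]] + half),
       sc = c(positions[["supercoiled"]] - 2 * half, positions[["supercoiled"]] + half))
}
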