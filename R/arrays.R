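# Nucleosome array construction: hard-core placement of dyads on a
# (usually circular) DNA template.

#' Construct a nucleosome array object
#'
#' A `nucleosome_array` records the dyad positions of non-overlapping
#' nucleosomes on a linear or circular DNA template. Each nucleosome
#' protects `footprint` base pairs centred on its dyad; the hard-core
#' constraint is that every pair of dyads is at least `footprint` bp apart
#' (minimal arc distance when circular), so footprints never overlap.
#'
#' @param template_length Template size in base pairs.
#' @param dyads Numeric vector of dyad positions, each in `[0, template_length)`.
#' @param footprint Protected length per nucleosome in bp (canonical core
#'   particle: 147 bp).
#' @param circular Is the template a closed circle?
#' @param provenance Optional character tag describing how the array was made.
#' @return An object of class `nucleosome_array`.
#' @export
nucleosome_array <- function(template_length, dyads = numeric(0),
                             footprint = 147, circular = TRUE,
                             provenance = NA_character_) {
  stopifnot(is.numeric(template_length), length(template_length) == 1L,
            template_length > 0, is.numeric(footprint), footprint > 0)
  dyads <- as.numeric(dyads)
  if (length(dyads) > 0 && (any(dyads < 0) || any(dyads >= template_length)))
    stop("dyad positions must lie in [0, template_length)")
  if (length(dyads) * footprint > template_length)
    stop("n_nucleosomes * footprint exceeds template_length")
  obj <- structure(
    list(template_length = as.numeric(template_length),
         circular = isTRUE(circular),
         dyads = sort(dyads),
         footprint = as.numeric(footprint),
         provenance = provenance),
    class = "nucleosome_array")
  bad <- which(dyad_distances(obj) < footprint - 1e-9)
  if (length(bad) > 0)
    stop("footprint exclusion violated: dyads closer than ", footprint, " bp")
  obj
}

#' @export
print.nucleosome_array <- function(x, ...) {
  cat(sprintf("<nucleosome_array> %d nucleosomes on %s %g bp template (footprint %g bp)\n",
              length(x$dyads), if (x$circular) "circular" else "linear",
              x$template_length, x$footprint))
  invisible(x)
}

#' @export
length.nucleosome_array <- function(x) length(x$dyads)

# Pairwise successive dyad distances (including the wrap-around gap on a
# circle); empty arrays and singletons on a line have no constrained pair.
dyad_distances <- function(array) {
  d <- array$dyads
  n <- length(d)
  if (n < 2L) {
    if (n == 1L || !array$circular) return(numeric(0))
    return(numeric(0))
  }
  gaps <- diff(d)
  if (array$circular) gaps <- c(gaps, array$template_length - d[n] + d[1])
  gaps
}

#' Generate a randomly positioned nucleosome array
#'
#' Draws dyads uniformly at random subject to the hard-core exclusion: the
#' result is an exact sample from the uniform distribution over all integer
#' dyad configurations in which every pair of dyads is at least `footprint`
#' bp apart. Sampling is constructive (gap decomposition), not sequential
#' insertion, so the measure is the true equilibrium hard-core measure
#' rather than the random-sequential-adsorption one.
#'
#' Emulates salt-dialysis reconstitution, which deposits nucleosomes without
#' regular spacing.
#'
#' @param template_length Template size, bp.
#' @param n_nucleosomes Number of nucleosomes to place.
#' @param footprint Protected length per nucleosome, bp.
#' @param circular Is the template circular?
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A [nucleosome_array()].
#' @examples
#' a <- generate_random_array(3000, 10, seed = 7)
#' min(diff(a$dyads)) >= 147
#' @export
generate_random_array <- function(template_length, n_nucleosomes,
                                  footprint = 147, circular = TRUE,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(round(template_length))
  n <- as.integer(n_nucleosomes)
  f <- as.integer(round(footprint))
  if (n < 0) stop("n_nucleosomes must be >= 0")
  if (n * f > L)
    stop("packing failure: cannot place ", n, " nucleosomes of ", f,
         " bp on a ", L, " bp template")
  if (n == 0L)
    return(nucleosome_array(L, numeric(0), f, circular, "random"))
  if (circular) {
    # Gap decomposition on a circle: circular gaps g_i >= f summing to L.
    # A uniform composition of the slack M = L - n*f into n parts plus a
    # uniform rotation yields every valid configuration equiprobably.
    M <- L - n * f
    excess <- if (n == 1L) M else {
      bars <- sort(sample.int(M + n - 1L, n - 1L))
      diff(c(0L, bars, M + n)) - 1L
    }
    gaps <- f + excess
    start <- sample.int(L, 1L) - 1L
    dyads <- (start + cumsum(c(0L, gaps[-n]))) %% L
  } else {
    # Linear template: subtract (f-1) per preceding nucleosome so that the
    # constrained draw becomes a plain sorted sample without replacement.
    m <- L - (n - 1L) * (f - 1L)
    if (m < n)
      stop("packing failure: cannot place ", n, " nucleosomes of ", f,
           " bp on a ", L, " bp linear template")
    x <- sort(sample.int(m, n)) - 1L
    dyads <- x + (seq_len(n) - 1L) * (f - 1L)
  }
  nucleosome_array(L, sort(dyads), f, circular, "random")
}

#' Generate a regularly spaced nucleosome array
#'
#' Places dyads at `phase + i * repeat_length` with optional Gaussian
#' positional jitter; jittered dyads are clamped so the footprint exclusion
#' still holds. The number of nucleosomes is `floor(template_length /
#' repeat_length)`. Emulates the periodic arrays produced by an
#' ATP-dependent spacing (remodeling) activity.
#'
#' @param template_length Template size, bp.
#' @param repeat_length Nucleosomal repeat, bp; must exceed `footprint`.
#' @param jitter_sd Standard deviation of the per-dyad Gaussian positional
#'   jitter, bp. Zero gives perfectly periodic dyads.
#' @param footprint Protected length per nucleosome, bp.
#' @param circular Is the template circular?
#' @param phase Position of the first dyad before jitter; `NULL` draws it
#'   uniformly.
#' @param seed Optional integer seed.
#' @return A [nucleosome_array()].
#' @examples
#' a <- generate_spaced_array(3000, 200, jitter_sd = 0, seed = 3)
#' unique(diff(a$dyads))
#' @export
generate_spaced_array <- function(template_length, repeat_length,
                                  jitter_sd = 0, footprint = 147,
                                  circular = TRUE, phase = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (repeat_length <= footprint)
    stop("repeat_length must exceed the nucleosome footprint")
  L <- as.numeric(template_length)
  n <- floor(L / repeat_length)
  if (n < 1) stop("template too short for one nucleosomal repeat")
  if (is.null(phase)) phase <- stats::runif(1, 0, repeat_length)
  base <- phase + (seq_len(n) - 1) * repeat_length
  # Clamp jitter to half the slack per repeat: two neighbours displaced to
  # opposite extremes are then still exactly `footprint` apart.
  slack <- (repeat_length - footprint) / 2
  jitter <- if (jitter_sd > 0) stats::rnorm(n, 0, jitter_sd) else numeric(n)
  jitter <- pmin(pmax(jitter, -slack), slack)
  dyads <- (base + jitter) %% L
  if (!circular) dyads <- pmin(pmax(dyads, 0), L - 1e-9)
  nucleosome_array(L, sort(dyads), footprint, circular, "spaced")
}
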