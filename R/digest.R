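# MNase digestion model: linker-only cutting with optional exonucleolytic
# trimming back to the outermost protected boundaries.

#' Construct a fragment sample
#'
#' A `fragment_sample` is a multiset of linear DNA fragment lengths, the
#' material that is loaded on a gel after deproteinization. Lengths are
#' integer base pairs; equal lengths are aggregated with counts.
#'
#' @param lengths Integer fragment lengths, bp (all >= 1).
#' @param counts Multiplicity of each length (defaults to 1 each).
#' @param provenance Character tag identifying the generating array and
#'   digestion parameters.
#' @return An object of class `fragment_sample`.
#' @export
fragment_sample <- function(lengths = integer(0), counts = NULL,
                            provenance = NA_character_) {
  lengths <- as.integer(round(lengths))
  if (is.null(counts)) counts <- rep(1L, length(lengths))
  counts <- as.integer(counts)
  stopifnot(length(lengths) == length(counts))
  if (length(lengths) > 0 && (any(lengths < 1L) || any(counts < 1L)))
    stop("fragment lengths and counts must be >= 1")
  if (length(lengths) > 0) {
    agg <- tapply(counts, lengths, sum)
    lengths <- as.integer(names(agg))
    counts <- as.integer(agg)
    o <- order(lengths)
    lengths <- lengths[o]; counts <- counts[o]
  }
  structure(list(lengths = lengths, counts = counts, provenance = provenance),
            class = "fragment_sample")
}

#' @export
print.fragment_sample <- function(x, ...) {
  cat(sprintf("<fragment_sample> %d fragments, %d distinct lengths\n",
              sum(x$counts), length(x$lengths)))
  invisible(x)
}

#' Combine fragment samples
#'
#' Pools several digests (e.g., the molecules of one reaction) into the
#' material of a single gel lane.
#'
#' @param ... `fragment_sample` objects.
#' @return A pooled `fragment_sample`.
#' @export
pool_fragments <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "fragment_sample"))
    xs <- xs[[1]]
  fragment_sample(unlist(lapply(xs, `[[`, "lengths")),
                  unlist(lapply(xs, `[[`, "counts")),
                  provenance = "pooled")
}

# Maximal linker (unprotected) intervals of an array, as a two-column
# matrix of [start, end) coordinates. On a circle an interval may wrap;
# it is then reported with end > template_length.
linker_intervals <- function(array) {
  L <- array$template_length
  f <- array$footprint
  d <- array$dyads
  n <- length(d)
  if (n == 0L) {
    if (array$circular) return(matrix(numeric(0), ncol = 2))
    return(matrix(c(0, L), ncol = 2))
  }
  starts <- d - f / 2
  ends <- d + f / 2
  if (array$circular) {
    # Linker i runs from the end of footprint i to the start of footprint
    # i+1 (wrapping for the last one).
    ls <- ends
    le <- c(starts[-1], starts[1] + L)
    keep <- le - ls > 1e-9
    cbind(ls, le)[keep, , drop = FALSE]
  } else {
    ls <- c(0, ends)
    le <- c(starts, L)
    keep <- le - ls > 1e-9
    cbind(ls, le)[keep, , drop = FALSE]
  }
}

#' Digest a nucleosome array with MNase
#'
#' Models partial micrococcal nuclease digestion of a single chromatinized
#' template. MNase cuts only in linker DNA: each nucleosome-free stretch
#' independently receives at most one cut, with probability
#' `cut_probability_per_linker`, at a uniformly chosen position within the
#' linker. Fragments are the intervals between successive cuts (plus the
#' template ends on a linear molecule). With `trimming = TRUE`, fragments
#' that contain at least one nucleosome are trimmed back to the outermost
#' protected footprint boundaries they contain (exonucleolytic nibbling of
#' exposed linker ends) and protein-free fragments are degraded entirely;
#' `cut_probability_per_linker = 1` with trimming then reproduces the
#' extensive-digestion limit in which every fragment is a core-particle
#' footprint.
#'
#' @param array A [nucleosome_array()].
#' @param cut_probability_per_linker Probability in `[0, 1]` that a given
#'   linker is cut.
#' @param trimming Trim cut fragments to footprint boundaries?
#' @param seed Optional integer seed.
#' @return A [fragment_sample()]. Empty when a circular template receives
#'   no cuts.
#' @examples
#' a <- generate_spaced_array(3000, 200, seed = 1)
#' digest_mnase(a, cut_probability_per_linker = 1, trimming = TRUE, seed = 1)
#' @export
digest_mnase <- function(array, cut_probability_per_linker = 0.5,
                         trimming = TRUE, seed = NULL) {
  if (!inherits(array, "nucleosome_array")) stop("array must be a nucleosome_array")
  p <- cut_probability_per_linker
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("cut_probability_per_linker must be a probability in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  L <- array$template_length
  f <- array$footprint
  lk <- linker_intervals(array)
  cuts <- numeric(0)
  if (nrow(lk) > 0) {
    hit <- stats::runif(nrow(lk)) < p
    if (any(hit)) {
      w <- lk[hit, , drop = FALSE]
      cuts <- (w[, 1] + stats::runif(nrow(w)) * (w[, 2] - w[, 1])) %% L
    }
  }
  prov <- sprintf("digest(p=%g,trim=%s)", p, trimming)
  # Footprint intervals in template coordinates (may wrap on a circle).
  fp <- if (length(array$dyads) > 0)
    cbind(array$dyads - f / 2, array$dyads + f / 2) else matrix(numeric(0), ncol = 2)

  frag_ends <- NULL
  if (array$circular) {
    if (length(cuts) == 0) return(fragment_sample(provenance = prov))
    cuts <- sort(cuts)
    starts <- cuts
    ends <- c(cuts[-1], cuts[1] + L)
    frag_ends <- cbind(starts, ends)
  } else {
    bounds <- sort(unique(c(0, cuts, L)))
    frag_ends <- cbind(bounds[-length(bounds)], bounds[-1])
  }

  if (!trimming) {
    lens <- frag_ends[, 2] - frag_ends[, 1]
    return(fragment_sample(round(lens[lens >= 0.5]), provenance = prov))
  }

  # Trim each fragment to the span of the footprints it fully contains.
  lens <- numeric(0)
  for (i in seq_len(nrow(frag_ends))) {
    a <- frag_ends[i, 1]; b <- frag_ends[i, 2]
    if (nrow(fp) == 0) next
    # Unwrap footprints into the fragment's coordinate frame: on a circle a
    # footprint (or the fragment itself) may wrap, so test shifted copies.
    shifts <- if (array$circular) c(-L, 0, L) else 0
    smin <- Inf; emax <- -Inf; found <- FALSE
    for (k in shifts) {
      s <- fp[, 1] + k; e <- fp[, 2] + k
      inside <- s >= a - 1e-9 & e <= b + 1e-9
      if (any(inside)) {
        found <- TRUE
        smin <- min(smin, s[inside]); emax <- max(emax, e[inside])
      }
    }
    if (!found) next
    lens <- c(lens, emax - smin)
  }
  fragment_sample(round(lens), provenance = prov)
}
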