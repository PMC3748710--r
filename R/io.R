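# Readers and writers. All tabular formats are comma-separated UTF-8 with
# '#'-prefixed metadata header lines, so outputs are diff-able and
# self-describing.

write_with_metadata <- function(df, path, metadata = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (m in metadata) writeLines(paste0("# ", m), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_skip_metadata <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines)
  body <- if (length(meta)) lines[-meta] else lines
  if (length(body) < 1) stop("no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "metadata") <- sub("^#\\s*", "", lines[meta])
  df
}

metadata_field <- function(meta, key) {
  hit <- grep(paste0("^", key, "="), meta, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Write / read a lane profile as CSV
#'
#' Two columns (`migration_px`, `intensity`) preceded by `#` metadata lines
#' carrying the lane id, background flag, and any mobility calibration.
#' Write-then-read round-trips to the same profile within floating-point
#' output precision.
#'
#' @param profile A [lane_profile()].
#' @param path Output file.
#' @return `write_lane_profile`: the path, invisibly. `read_lane_profile`:
#'   a [lane_profile()].
#' @export
write_lane_profile <- function(profile, path) {
  stopifnot(inherits(profile, "lane_profile"))
  meta <- c(paste0("lane_id=", profile$lane_id),
            paste0("background_subtracted=", profile$background_subtracted))
  if (!is.null(profile$calibration))
    meta <- c(meta, sprintf("calibration=%.12g,%.12g",
                            profile$calibration[["intercept"]],
                            profile$calibration[["slope"]]))
  write_with_metadata(
    data.frame(migration_px = profile$position, intensity = profile$intensity),
    path, meta)
  invisible(path)
}

#' @rdname write_lane_profile
#' @export
read_lane_profile <- function(path) {
  df <- read_skip_metadata(path)
  need <- c("migration_px", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), " in header")
  meta <- attr(df, "metadata")
  calib <- NULL
  cs <- metadata_field(meta, "calibration")
  if (!is.na(cs)) {
    v <- as.numeric(strsplit(cs, ",")[[1]])
    calib <- c(intercept = v[1], slope = v[2])
  }
  lane_profile(df$migration_px, df$intensity, calibration = calib,
               lane_id = {
                 id <- metadata_field(meta, "lane_id")
                 if (is.na(id)) "lane" else id
               },
               background_subtracted =
                 identical(metadata_field(meta, "background_subtracted"), "TRUE"))
}

#' Write / read a fragment sample as CSV
#'
#' Columns `length_bp`, `count`.
#'
#' @param fragments A [fragment_sample()].
#' @param path File path.
#' @export
write_fragment_sample <- function(fragments, path) {
  stopifnot(inherits(fragments, "fragment_sample"))
  write_with_metadata(
    data.frame(length_bp = fragments$lengths, count = fragments$counts),
    path, paste0("provenance=", fragments$provenance))
  invisible(path)
}

#' @rdname write_fragment_sample
#' @export
read_fragment_sample <- function(path) {
  df <- read_skip_metadata(path)
  if (!all(c("length_bp", "count") %in% names(df)))
    stop("parse error in ", path, ": expected columns length_bp, count")
  prov <- metadata_field(attr(df, "metadata"), "provenance")
  fragment_sample(df$length_bp, df$count, provenance = prov)
}

#' Export a nucleosome array as BED-like intervals
#'
#' 0-based half-open intervals, one per nucleosome footprint:
#' `chrom = template id`, `start = dyad - footprint/2`,
#' `end = dyad + footprint/2` (clipped/wrapped coordinates are clipped to
#' the template on linear molecules; on circular templates intervals that
#' wrap are split is NOT done — the raw span is written and may extend
#' beyond the template boundary by up to half a footprint).
#'
#' @param array A [nucleosome_array()].
#' @param path Output BED file.
#' @param chrom Template identifier for column 1.
#' @export
write_array_bed <- function(array, path, chrom = "template") {
  stopifnot(inherits(array, "nucleosome_array"))
  start <- round(array$dyads - array$footprint / 2)
  end <- round(array$dyads + array$footprint / 2)
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end),
                   name = paste0("nuc", seq_along(array$dyads)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write spacing index results as CSV
#'
#' One row per lane: `lane_id, P2, P3, V, index, p2_pos, p3_pos, v_pos`.
#'
#' @param results A `spacing_index_result` or list of them.
#' @param path Output file.
#' @param metadata Extra `#` header lines.
#' @export
write_spacing_results <- function(results, path, metadata = character(0)) {
  if (inherits(results, "spacing_index_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(lane_id = r$lane_id, P2 = r$P2, P3 = r$P3, V = r$V,
               index = r$index, p2_pos = r$p2_pos, p3_pos = r$p3_pos,
               v_pos = r$v_pos)))
  write_with_metadata(df, path, metadata)
  invisible(path)
}

#' Write supercoiling results as CSV
#'
#' One row per lane: `lane_id, sc, rel, n, percent, delta_vs_reference`.
#'
#' @param results A `supercoiling_result` or list of them.
#' @param path Output file.
#' @param metadata Extra `#` header lines.
#' @export
write_supercoiling_results <- function(results, path, metadata = character(0)) {
  if (inherits(results, "supercoiling_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(lane_id = r$lane_id, sc = r$sc_intensity,
               rel = r$relaxed_intensity, n = r$nicked_intensity,
               percent = r$percent_supercoiling,
               delta_vs_reference = if (is.null(r$delta_percent)) NA_real_
                                    else r$delta_percent)))
  write_with_metadata(df, path, metadata)
  invisible(path)
}

#' Read a kinetic time course from CSV
#'
#' Expects columns `time_min` and `value`, optionally `protein_nM`.
#'
#' @param path CSV file (with optional `#` metadata lines).
#' @param observable Label for the observable.
#' @return A [time_course()].
#' @export
read_time_course <- function(path, observable = "signal") {
  df <- read_skip_metadata(path)
  if (!all(c("time_min", "value") %in% names(df)))
    stop("parse error in ", path, ": expected columns time_min, value")
  time_course(df$time_min, df$value, observable = observable,
              protein_nM = if ("protein_nM" %in% names(df))
                df$protein_nM[1] else NA_real_)
}

#' Write a kinetic time course to CSV
#'
#' @param tc A [time_course()].
#' @param path Output file.
#' @export
write_time_course <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  df <- data.frame(time_min = tc$times, value = tc$values)
  if (!is.na(tc$protein_nM)) df$protein_nM <- tc$protein_nM
  write_with_metadata(df, path, paste0("observable=", tc$observable))
  invisible(path)
}

#' Read a substrate-saturation table from CSV
#'
#' Expects columns `substrate_nM` and `kobs_per_min`.
#'
#' @param path CSV file.
#' @return Data frame with the two columns.
#' @export
read_saturation_table <- function(path) {
  df <- read_skip_metadata(path)
  if (!all(c("substrate_nM", "kobs_per_min") %in% names(df)))
    stop("parse error in ", path, ": expected columns substrate_nM, kobs_per_min")
  df[c("substrate_nM", "kobs_per_min")]
}

#' Read an ASCII PGM (P2) grayscale image
#'
#' Plain-text portable graymap support for gel images: returns a numeric
#' matrix (rows = image rows, i.e. the migration axis when wells are at the
#' top). Binary TIFF/PNG are not supported; convert externally (e.g.
#' ImageMagick `convert gel.tif -compress none gel.pgm`).
#'
#' @param path PGM (P2, ASCII) file.
#' @return Numeric matrix of pixel values.
#' @export
read_pgm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE,
                 comment.char = "#")
  if (length(tokens) < 4 || tokens[1] != "P2")
    stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != w * h)
    stop("PGM pixel count mismatch in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write an ASCII PGM (P2) grayscale image
#'
#' @param image Numeric matrix of nonnegative values.
#' @param path Output file.
#' @param maxval Stated maximum gray value (pixels are rounded and clipped).
#' @export
write_pgm <- function(image, path, maxval = 65535) {
  stopifnot(is.matrix(image))
  px <- pmin(pmax(round(image), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxval)), con)
  apply(px, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
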