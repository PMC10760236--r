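# Single-mRNA translation calling from two-channel data: mRNA smFISH
# spots plus nascent-peptide (SunTag-type reporter) IF spots.

#' Estimate the unit single-peptide intensity
#'
#' The intensity scale of one fully synthesized protein, estimated as the
#' median integrated intensity of free peptide spots — spots farther than
#' the pairing threshold from any mRNA, i.e. mature proteins that have
#' diffused away from their mRNA. The median is robust to bright
#' aggregates among the free spots.
#'
#' @param peptide_spots peptide-channel \code{spot_table}.
#' @param mrna_spots mRNA-channel \code{spot_table} (same cell).
#' @param threshold distance beyond which a peptide is considered free, nm.
#' @param min_free minimum number of free spots required (default 20).
#' @return List with \code{value} (AU), \code{method}, \code{n_spots}.
#' @export
estimate_unit_intensity <- function(peptide_spots, mrna_spots,
                                    threshold = 200, min_free = 20) {
  if (nrow(mrna_spots) == 0L) {
    free <- rep(TRUE, nrow(peptide_spots))
  } else {
    d <- .cross_dist(.xyz(peptide_spots), .xyz(mrna_spots))
    free <- apply(d, 1, min) > threshold
  }
  if (sum(free) < min_free)
    stop(sprintf("calibration error: only %d free peptide spots (>= %d required); supply the unit intensity explicitly",
                 sum(free), min_free))
  list(value = stats::median(peptide_spots$intensity[free]),
       method = "median of free peptide spots", n_spots = sum(free))
}

#' Nascent peptide (ribosome) count of a translation site
#'
#' Integrated peptide intensity divided by the unit single-peptide
#' intensity, rounded to the nearest integer and floored at 1: a peptide
#' signal kept at an mRNA implies at least one nascent chain.
#'
#' @param intensity peptide spot intensities (vectorized).
#' @param unit unit single-peptide intensity (scalar > 0, or the list
#'   returned by \code{\link{estimate_unit_intensity}}).
#' @return Integer nascent peptide counts.
#' @export
nascent_count <- function(intensity, unit) {
  if (is.list(unit)) unit <- unit$value
  stopifnot(isTRUE(unit > 0))
  pmax(1L, as.integer(round(intensity / unit)))
}

#' Pair peptide spots with mRNAs and call translating mRNAs
#'
#' Implements the closest-mRNA pairing rule: peptide coordinates are first
#' corrected by the mean chromatic offset between the channels; each
#' peptide is provisionally assigned to its nearest mRNA (3D Euclidean);
#' the assignment is kept only if the distance is within
#' \code{base_threshold} plus the magnitude of the residual chromatic
#' aberration. Where several peptides remain on one mRNA, the brightest is
#' kept, ties broken by the smaller distance (then the lower peptide id,
#' for determinism). An mRNA with a kept peptide is translating.
#'
#' @param mrnas mRNA-channel \code{spot_table}.
#' @param peptides peptide-channel \code{spot_table}.
#' @param base_threshold base pairing distance, nm (default 200).
#' @param chromatic_offset length-3 nm vector subtracted from peptide
#'   coordinates (the measured mean inter-channel offset).
#' @param chromatic_residual scalar nm added to the threshold (residual
#'   registration error after offset correction).
#' @param unit optional unit single-peptide intensity; when supplied (or
#'   estimable via \code{\link{estimate_unit_intensity}}) each kept pair
#'   gets a nascent peptide count.
#' @return An object of class \code{translation_calls}: \code{pairs}
#'   (mrna_id, peptide_id, distance_nm, peptide_intensity, n_peptides),
#'   \code{mrnas} (per-mRNA translating flag), \code{free_peptides}, and
#'   the effective threshold.
#' @export
assign_peptides <- function(mrnas, peptides, base_threshold = 200,
                            chromatic_offset = c(0, 0, 0),
                            chromatic_residual = 0, unit = NULL) {
  if (base_threshold < 0) stop("config error: negative threshold")
  thr <- base_threshold + sqrt(sum(chromatic_residual^2))
  pep <- as.data.frame(peptides)
  if (nrow(pep)) {
    pep$x <- pep$x - chromatic_offset[1]
    pep$y <- pep$y - chromatic_offset[2]
    pep$z <- pep$z - chromatic_offset[3]
  }
  if (nrow(mrnas) == 0L || nrow(pep) == 0L) {
    pairs <- data.frame(mrna_id = integer(0), peptide_id = integer(0),
                        distance_nm = numeric(0), peptide_intensity = numeric(0))
  } else {
    d <- .cross_dist(.xyz(pep), .xyz(mrnas))
    nearest <- apply(d, 1, which.min)
    dist <- d[cbind(seq_len(nrow(pep)), nearest)]
    keep <- dist <= thr
    cand <- data.frame(mrna_id = mrnas$id[nearest[keep]],
                       peptide_id = pep$id[keep],
                       distance_nm = dist[keep],
                       peptide_intensity = pep$intensity[keep])
    # dedupe per mRNA: brightest peptide, then closest, then lowest id
    cand <- cand[order(cand$mrna_id, -cand$peptide_intensity,
                       cand$distance_nm, cand$peptide_id), , drop = FALSE]
    pairs <- cand[!duplicated(cand$mrna_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  if (!is.null(unit)) {
    if (is.list(unit)) unit <- unit$value
    pairs$n_peptides <- if (nrow(pairs)) nascent_count(pairs$peptide_intensity, unit) else integer(0)
  }
  mrna_df <- data.frame(mrna_id = mrnas$id,
                        translating = mrnas$id %in% pairs$mrna_id)
  structure(list(pairs = pairs, mrnas = mrna_df,
                 free_peptides = setdiff(pep$id, pairs$peptide_id),
                 threshold_nm = thr, unit = unit),
            class = "translation_calls")
}

#' @export
print.translation_calls <- function(x, ...) {
  cat(sprintf("Translation calls: %d/%d mRNAs translating (threshold %g nm)\n",
              sum(x$mrnas$translating), nrow(x$mrnas), x$threshold_nm))
  if (!is.null(x$pairs$n_peptides) && nrow(x$pairs)) {
    cat("  nascent peptide counts: ")
    print(table(x$pairs$n_peptides))
  }
  invisible(x)
}

#' @export
as_result_table.translation_calls <- function(x, ...) {
  m <- x$mrnas
  idx <- match(m$mrna_id, x$pairs$mrna_id)
  data.frame(mrna_id = m$mrna_id,
             translating = m$translating,
             peptide_id = x$pairs$peptide_id[idx],
             distance_nm = x$pairs$distance_nm[idx],
             n_peptides = if (!is.null(x$pairs$n_peptides))
               x$pairs$n_peptides[idx] else NA_integer_)
}

#' Percent of mRNAs translating
#'
#' 100 x translating / total, per cell or per dendrite branch (the latter
#' needs the mRNA channel's \code{binned_assignment} to know each mRNA's
#' branch). A scope with no mRNAs is reported as NA.
#'
#' @param calls a \code{translation_calls}.
#' @param scope \code{"cell"} or \code{"dendrite"}.
#' @param assignment \code{binned_assignment} of the mRNA channel
#'   (required for dendrite scope).
#' @return For cell scope a single percentage; for dendrite scope a data
#'   frame with one row per branch.
#' @export
percent_translating <- function(calls, scope = c("cell", "dendrite"),
                                assignment = NULL) {
  scope <- match.arg(scope)
  if (scope == "cell") {
    n <- nrow(calls$mrnas)
    return(if (n == 0L) NA_real_ else 100 * sum(calls$mrnas$translating) / n)
  }
  if (is.null(assignment)) stop("dendrite scope requires the mRNA binned_assignment")
  dend <- assignment[assignment$compartment == "dendrite", , drop = FALSE]
  tr <- calls$mrnas$translating[match(dend$id, calls$mrnas$mrna_id)]
  out <- do.call(rbind, lapply(split(tr, dend$branch), function(v)
    data.frame(n_mrna = length(v), percent = 100 * mean(v))))
  out$branch <- as.integer(rownames(out))
  rownames(out) <- NULL
  out[, c("branch", "n_mrna", "percent")]
}

#' Ribosome-load histogram of translating mRNAs
#'
#' @param calls a \code{translation_calls} with nascent counts.
#' @return Table of nascent peptide counts over kept pairs (monosomes at
#'   1, polysomes above).
#' @export
ribosome_histogram <- function(calls) {
  if (is.null(calls$pairs$n_peptides))
    stop("no nascent counts: supply a unit intensity to assign_peptides")
  table(factor(calls$pairs$n_peptides,
               levels = seq_len(max(1, calls$pairs$n_peptides))))
}
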