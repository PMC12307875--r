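#' Detect puncta in the red channel of a tandem reporter image
#'
#' Puncta are 8-connected components of the thresholded red channel passing
#' the minimum-size rule; the mean intensity of both channels is recorded
#' per punctum for downstream acid/neutral classification.
#'
#' @param red,green Same-shape intensity matrices.
#' @param threshold Red-channel threshold in \[0, 1\]; `NULL` uses Otsu on
#'   the red channel.
#' @param min_size Minimum punctum area in pixels.
#' @return Data frame: `punctum_id`, `row`, `col` (centroid), `area_px`,
#'   `mean_red`, `mean_green`, plus a `pixels` list-column of linear pixel
#'   indices.
#' @export
detect_puncta <- function(red, green, threshold = NULL, min_size = 10) {
  check_matrix(red); check_matrix(green)
  if (!identical(dim(red), dim(green)))
    stop_param("channels must share one shape")
  if (is.null(threshold)) threshold <- batch_otsu(list(red))
  lm <- binarize_and_filter(red, threshold, min_size)
  n <- lm$n_objects
  if (n == 0)
    return(data.frame(punctum_id = integer(0), row = numeric(0),
                      col = numeric(0), area_px = integer(0),
                      mean_red = numeric(0), mean_green = numeric(0)))
  nr <- nrow(red)
  rows <- lapply(seq_len(n), function(k) {
    px <- which(lm$labels == k)
    data.frame(punctum_id = k,
               row = mean(((px - 1L) %% nr) + 1L),
               col = mean(((px - 1L) %/% nr) + 1L),
               area_px = length(px),
               mean_red = mean(red[px]),
               mean_green = mean(green[px]))
  })
  out <- do.call(rbind, rows)
  out$pixels <- I(lapply(seq_len(n), function(k) which(lm$labels == k)))
  attr(out, "mask") <- lm$mask
  out
}

#' Classify puncta as red-only (acidic) or dual-positive
#'
#' A punctum is red-only when its mean green intensity does not exceed the
#' green background level, estimated robustly from the pixels outside all
#' puncta as `median + k * MAD`. Red-only puncta mark acidic vesicles in
#' which the green fluorophore is quenched.
#'
#' @param puncta [detect_puncta()] output (must carry the `pixels` column).
#' @param green Green-channel intensity matrix.
#' @param k Robust-threshold multiplier (default 3).
#' @return `puncta` with `classification` (`red_only` or `dual`) and the
#'   `green_cutoff` used, recorded as an attribute.
#' @export
classify_puncta <- function(puncta, green, k = 3) {
  check_matrix(green)
  if (nrow(puncta) == 0) {
    puncta$classification <- character(0)
    return(puncta)
  }
  if (is.null(puncta$pixels))
    stop_param("puncta must carry the pixels column from detect_puncta()")
  fg <- unlist(puncta$pixels, use.names = FALSE)
  bgpx <- green[-fg]
  cutoff <- median(bgpx) + k * mad(bgpx)
  puncta$classification <- ifelse(puncta$mean_green <= cutoff,
                                  "red_only", "dual")
  attr(puncta, "green_cutoff") <- cutoff
  puncta
}

#' Percentage of red-only puncta in a cell
#'
#' The tandem-reporter flux readout: `100 * red puncta / total puncta`.
#' With zero puncta the percentage is undefined and `NA` is returned with a
#' warning.
#'
#' @param puncta Classified puncta ([classify_puncta()] output) or a
#'   character vector of classifications.
#' @return Percentage in \[0, 100\], or `NA`.
#' @export
red_puncta_percentage <- function(puncta) {
  cls <- if (is.data.frame(puncta)) puncta$classification else puncta
  if (length(cls) == 0) {
    warning("no puncta: red-puncta percentage undefined")
    return(NA_real_)
  }
  100 * sum(cls == "red_only") / length(cls)
}

#' Red signal as a percentage of total fluorescence
#'
#' Mitophagy readout for mito-targeted tandem reporters:
#' `100 * sum(red) / (sum(red) + sum(green))` over a region of interest.
#' Invariant to multiplying both channels by a common positive factor.
#'
#' @param red,green Same-shape intensity matrices.
#' @param roi Optional logical matrix restricting the sums (default whole
#'   image).
#' @return Percentage in \[0, 100\]; `NA` with a warning when the total
#'   fluorescence is zero.
#' @export
red_only_intensity_percentage <- function(red, green, roi = NULL) {
  check_matrix(red); check_matrix(green)
  if (!identical(dim(red), dim(green)))
    stop_param("channels must share one shape")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(red), ncol(red))
  roi <- as_binary_matrix(roi)
  if (sum(roi) == 0) stop_param("ROI is empty")
  tot <- sum(red[roi]) + sum(green[roi])
  if (tot <= 0) {
    warning("total fluorescence is zero: percentage undefined")
    return(NA_real_)
  }
  100 * sum(red[roi]) / tot
}

#' Count marker puncta that also contain mitochondria
#'
#' Counts puncta (e.g. LC3 or CD63 vesicles) whose pixel footprint overlaps
#' the mitochondrial foreground by at least `min_overlap_frac` of the
#' punctum area (default: any overlap, i.e. >= 1 pixel) -- an explicit
#' software surrogate for manually scoring vesicles engulfing mitochondria.
#'
#' @param puncta [detect_puncta()] output with the `pixels` column.
#' @param mito_mask Logical matrix or [labeled_mask] of the mitochondrial
#'   channel.
#' @param min_overlap_frac Required overlapping fraction of each punctum's
#'   area; 0 means any overlap.
#' @return Integer count.
#' @export
copositive_puncta_count <- function(puncta, mito_mask,
                                    min_overlap_frac = 0) {
  mito <- as_binary_matrix(mito_mask)
  if (nrow(puncta) == 0) return(0L)
  if (is.null(puncta$pixels))
    stop_param("puncta must carry the pixels column from detect_puncta()")
  hits <- vapply(seq_len(nrow(puncta)), function(i) {
    px <- puncta$pixels[[i]]
    ov <- sum(mito[px])
    need <- max(1, ceiling(min_overlap_frac * length(px)))
    ov >= need
  }, logical(1))
  sum(hits)
}
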