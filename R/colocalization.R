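#' Contrast-stretch (and optionally sharpen) one image channel
#'
#' Linearly rescales intensities between two percentile bounds and clips to
#' \[0, 1\]; optionally applies unsharp masking afterwards. For a grouped
#' comparison the same parameters must be applied to every image -- use
#' [preprocess_batch()], which enforces this.
#'
#' @param channel Numeric intensity matrix.
#' @param stretch Percentile bounds `c(low, high)` with
#'   `0 <= low < high <= 100`.
#' @param sharpen If `TRUE`, apply unsharp masking (fixed `sigma` and
#'   `amount`, recorded in the result's `provenance` attribute).
#' @param sigma,amount Unsharp-mask Gaussian radius (px) and strength.
#' @return Matrix in \[0, 1\] with a `provenance` attribute recording the
#'   parameters.
#' @export
preprocess_channel <- function(channel, stretch = c(0, 100),
                               sharpen = FALSE, sigma = 2, amount = 1) {
  check_matrix(channel)
  if (length(stretch) != 2 || stretch[1] < 0 || stretch[2] > 100 ||
      stretch[1] >= stretch[2])
    stop_param("stretch must be percentiles c(low, high) with 0 <= low < high <= 100")
  q <- quantile(channel, probs = stretch / 100, names = FALSE)
  out <- if (q[2] > q[1]) (channel - q[1]) / (q[2] - q[1]) else channel * 0
  out <- pmin(pmax(out, 0), 1)
  if (sharpen) {
    blur <- EBImage::gblur(out, sigma = sigma)
    out <- pmin(pmax(out + amount * (out - blur), 0), 1)
  }
  out <- matrix(out, nrow(channel), ncol(channel))
  attr(out, "provenance") <- list(stretch = stretch, sharpen = sharpen,
                                  sigma = if (sharpen) sigma else NA,
                                  amount = if (sharpen) amount else NA)
  out
}

#' Uniformly preprocess one channel across a batch of images
#'
#' Applies [preprocess_channel()] with a single parameter set to the named
#' channel of every image, guaranteeing that all images in a comparison are
#' adjusted identically. Per-image parameters are refused.
#'
#' @param images List of [multichannel_image] objects.
#' @param channel Channel name present in every image.
#' @inheritParams preprocess_channel
#' @return List of preprocessed channel matrices (one per image), named by
#'   sample id.
#' @export
preprocess_batch <- function(images, channel, stretch = c(0, 100),
                             sharpen = FALSE, sigma = 2, amount = 1) {
  if (!is.list(images) || length(images) == 0)
    stop_param("images must be a non-empty list of multichannel_image")
  if (is.list(stretch) || length(stretch) != 2)
    stop_param("a single stretch = c(low, high) must be applied uniformly ",
               "to every image in the batch; per-image parameters are not ",
               "allowed")
  out <- lapply(images, function(img) {
    if (!inherits(img, "multichannel_image"))
      stop_param("every element of images must be a multichannel_image")
    if (!channel %in% names(img$channels))
      stop_param("channel '", channel, "' missing in sample '",
                 img$sample_id, "'")
    preprocess_channel(img$channels[[channel]], stretch, sharpen, sigma,
                       amount)
  })
  names(out) <- vapply(images, function(i) i$sample_id, character(1))
  out
}

#' Pooled Otsu threshold for a batch of adjusted channels
#'
#' Computes one global Otsu threshold from the pooled pixel histogram of a
#' set of preprocessed channels (typically the control batch) so that a
#' single threshold is applied uniformly to every image in a comparison.
#'
#' @param channels List of matrices with values in \[0, 1\].
#' @return Threshold in \[0, 1\].
#' @export
batch_otsu <- function(channels) {
  px <- unlist(lapply(channels, as.numeric), use.names = FALSE)
  if (length(px) == 0) stop_param("no pixels supplied")
  EBImage::otsu(EBImage::Image(matrix(px, ncol = 1)), range = c(0, 1))
}

#' Binarize a channel and remove very small puncta
#'
#' Pixels at or above the threshold become foreground; 8-connected
#' components with fewer than `min_size` pixels are then removed (a
#' component of exactly `min_size` pixels survives -- the strictly-less
#' removal rule).
#'
#' @param channel Matrix with values in \[0, 1\].
#' @param threshold Threshold in \[0, 1\] (e.g. from [batch_otsu()]).
#' @param min_size Minimum surviving component area in pixels.
#' @return A [labeled_mask] whose provenance records the threshold,
#'   `min_size` and connectivity.
#' @export
binarize_and_filter <- function(channel, threshold, min_size = 10) {
  check_matrix(channel)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop_param("threshold must be a single value in [0, 1]")
  mask <- channel >= threshold
  labels <- label_components(mask, connectivity = 8)
  if (max(labels) > 0) {
    sizes <- tabulate(labels)
    drop <- which(sizes < min_size)
    if (length(drop)) {
      mask[labels %in% drop] <- FALSE
      labels <- label_components(mask, connectivity = 8)
    }
  }
  prov <- c(attr(channel, "provenance"),
            list(threshold = threshold, min_size = min_size,
                 connectivity = 8))
  labeled_mask(mask, labels, prov)
}

#' Count pixels shared by two binary masks
#'
#' The pixel-intersection measurement behind the overlap index: foreground
#' pixel counts of each mask and the number of coordinates foreground in
#' both.
#'
#' @param mask_a,mask_b [labeled_mask] objects or logical matrices of the
#'   same shape.
#' @param sample_id,group Annotation carried into the result row.
#' @return One-row data frame: `sample_id`, `group`, `pixels_a`, `pixels_b`,
#'   `overlap_pixels`.
#' @export
overlap_pixels <- function(mask_a, mask_b, sample_id = "sample",
                           group = "control") {
  a <- as_binary_matrix(mask_a)
  b <- as_binary_matrix(mask_b)
  if (!identical(dim(a), dim(b)))
    stop_param("masks must share one shape")
  data.frame(sample_id = sample_id, group = group,
             pixels_a = sum(a), pixels_b = sum(b),
             overlap_pixels = sum(a & b), stringsAsFactors = FALSE)
}

#' Count pixels shared by three binary masks
#'
#' Three-way coordinate intersection (e.g. ER, mitochondria and a protein
#' channel): the number of pixels foreground in all three masks.
#'
#' @param mask_er,mask_mito,mask_protein Same-shape masks or
#'   [labeled_mask]s.
#' @inheritParams overlap_pixels
#' @return One-row data frame: `sample_id`, `group`, `pixels_er`,
#'   `pixels_mito`, `pixels_protein`, `overlap_pixels`.
#' @export
triple_overlap <- function(mask_er, mask_mito, mask_protein,
                           sample_id = "sample", group = "control") {
  er <- as_binary_matrix(mask_er)
  mito <- as_binary_matrix(mask_mito)
  prot <- as_binary_matrix(mask_protein)
  if (!identical(dim(er), dim(mito)) || !identical(dim(er), dim(prot)))
    stop_param("masks must share one shape")
  data.frame(sample_id = sample_id, group = group,
             pixels_er = sum(er), pixels_mito = sum(mito),
             pixels_protein = sum(prot),
             overlap_pixels = sum(er & mito & prot),
             stringsAsFactors = FALSE)
}

#' Overlap index: fold change of overlapping pixels vs the control mean
#'
#' Each sample's overlapping-pixel count is divided by the mean count of the
#' control group, so the control-group mean index is 1 by construction.
#' Group summaries are reported as mean +/- SEM.
#'
#' @param measurements Data frame with columns `sample_id`, `group`,
#'   `overlap_pixels` (rows from [overlap_pixels()] or [triple_overlap()]).
#' @param control_group Label of the normalizing group.
#' @return A list with `per_sample` (measurements plus `overlap_index`) and
#'   `summary` (per group: `n`, `mean_index`, `sem_index`; SEM is `NA` for a
#'   singleton group).
#' @export
overlap_index <- function(measurements, control_group = "control") {
  need <- c("sample_id", "group", "overlap_pixels")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop_param("measurements lacks column(s): ", paste(miss, collapse = ", "))
  ctrl <- measurements$overlap_pixels[measurements$group == control_group]
  if (length(ctrl) == 0)
    stop_param("control group '", control_group, "' is empty")
  denom <- mean(ctrl)
  if (denom <= 0)
    stop_param("control-group mean overlap is zero; the fold change ",
               "(overlap index) is undefined")
  per_sample <- measurements
  per_sample$overlap_index <- measurements$overlap_pixels / denom
  groups <- unique(per_sample$group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    v <- per_sample$overlap_index[per_sample$group == g]
    data.frame(group = g, n = length(v), mean_index = mean(v),
               sem_index = sem(v), stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, summary = summary,
       control_group = control_group, control_mean_overlap = denom)
}

#' Pearson colocalization coefficient of two channels
#'
#' Standard Pearson product-moment correlation of the raw (unbinarized)
#' intensities of two channels over an optional region of interest. The
#' coefficient is undefined when either channel has zero variance over the
#' ROI; `NA` is returned with a warning giving the reason.
#'
#' @param channel_a,channel_b Same-shape intensity matrices.
#' @param roi Optional logical matrix selecting the pixels to correlate
#'   (default: whole image). At least 2 pixels are required.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
pearson_colocalization <- function(channel_a, channel_b, roi = NULL) {
  check_matrix(channel_a); check_matrix(channel_b)
  if (!identical(dim(channel_a), dim(channel_b)))
    stop_param("channels must share one shape")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  roi <- as_binary_matrix(roi)
  if (!identical(dim(roi), dim(channel_a)))
    stop_param("roi must share the channel shape")
  a <- channel_a[roi]; b <- channel_b[roi]
  if (length(a) < 2) stop_param("ROI must contain at least 2 pixels")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("Pearson coefficient undefined: zero variance in ",
            if (sd(a) == 0) "channel_a" else "channel_b", " over the ROI")
    return(NA_real_)
  }
  cor(a, b)
}
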