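#' Label connected components of a binary mask
#'
#' 8-connected (default) or 4-connected component labeling. Components are
#' numbered in raster (column-major) order of first appearance, so labeling is
#' deterministic.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 8 (diagonal neighbours touch, the common default for
#'   fluorescence puncta) or 4.
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_binary_matrix(mask)
  if (!connectivity %in% c(4, 8)) stop_param("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok]
    hit <- mask[nb]
    edges <- c(edges, rbind(vid[src[hit]], vid[nb[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber components by first appearance in raster order
  first <- !duplicated(memb)
  remap <- integer(max(memb))
  remap[memb[first]] <- seq_len(sum(first))
  labels[idx] <- remap[memb]
  labels
}

#' Morphological dilation of a binary mask
#'
#' Dilates with a square (box) structuring element of half-width `radius`,
#' matching the 8-connected neighbourhood convention used throughout the
#' package. `radius = 0` returns the mask unchanged.
#'
#' @param mask Logical matrix.
#' @param radius Half-width of the structuring element in pixels (>= 0).
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, radius = 1) {
  mask <- as_binary_matrix(mask)
  if (radius < 0) stop_param("radius must be >= 0")
  radius <- as.integer(radius)
  if (radius == 0) return(mask)
  brush <- matrix(1L, 2 * radius + 1, 2 * radius + 1)
  out <- EBImage::dilate(mask * 1L, brush)
  matrix(as.logical(out > 0), nrow(mask), ncol(mask))
}
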