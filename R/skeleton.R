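# Binary skeletonization and geodesic path length.
#
# Zhang-Suen iterative thinning on logical matrices, vectorized with shifted
# neighbour matrices. The thinning conditions never remove endpoint pixels
# (neighbour count >= 2 is required), which keeps stroke ends in place -- the
# property length measurement relies on.

nb_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ri <- seq_len(nr) + dr; ci <- seq_len(nc) + dc
  okr <- ri >= 1 & ri <= nr; okc <- ci >= 1 & ci <= nc
  out[okr, okc] <- m[ri[okr], ci[okc], drop = FALSE]
  out
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until every object is reduced to a
#' one-pixel-wide, 8-connected skeleton. Topology and stroke endpoints are
#' preserved.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  m <- as_binary_matrix(mask) * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north (row - 1)
      p2 <- nb_shift(m, -1, 0); p3 <- nb_shift(m, -1, 1)
      p4 <- nb_shift(m, 0, 1);  p5 <- nb_shift(m, 1, 1)
      p6 <- nb_shift(m, 1, 0);  p7 <- nb_shift(m, 1, -1)
      p8 <- nb_shift(m, 0, -1); p9 <- nb_shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1L & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# weighted 8-neighbour graph over the foreground pixels of a mask;
# returns the graph, the linear pixel indices (vertex order) and edge data
pixel_graph <- function(mask, w_orth = 1, w_diag = sqrt(2)) {
  idx <- which(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  vid <- integer(nr * nc); vid[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L, w_orth), c(0L, 1L, w_orth),
               c(1L, 1L, w_diag), c(-1L, 1L, w_diag))
  edges <- integer(0); w <- numeric(0)
  for (o in offs) {
    r2 <- row + o[1]; c2 <- col + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok]
    hit <- mask[nb]
    if (any(hit)) {
      edges <- c(edges, rbind(vid[src[hit]], vid[nb[hit]]))
      w <- c(w, rep(o[3], sum(hit)))
    }
  }
  list(g = igraph::make_graph(edges, n = length(idx), directed = FALSE),
       idx = idx, weights = w)
}

#' Longest geodesic path length through a skeleton
#'
#' Treats skeleton pixels as graph vertices joined to their 8-neighbours
#' (orthogonal steps weight 1, diagonal steps weight sqrt(2)) and returns the
#' largest shortest-path distance between any two pixels -- the end-to-end
#' length of a (possibly branched) skeleton, in pixels. A single-pixel
#' skeleton has length 0. Disconnected skeletons return the maximum over
#' components.
#'
#' @param skeleton Logical matrix, e.g. from [thin_mask()].
#' @return Length in pixel units (numeric scalar).
#' @export
longest_geodesic <- function(skeleton) {
  skel <- as_binary_matrix(skeleton)
  if (sum(skel) <= 1) return(0)
  pg <- pixel_graph(skel)
  d <- igraph::distances(pg$g, weights = pg$weights)
  max(d[is.finite(d)])
}

# Length of a single object mask: longest skeleton geodesic with Kulpa
# step-weight correction (0.948 orthogonal, 1.340 diagonal -- the unbiased
# digital line-length estimator), extended at each end by how far the object
# reaches beyond the path endpoint in excess of the local half-width
# (Euclidean distance transform), compensating the end erosion of thinning.
object_length_px <- function(sub) {
  skel <- thin_mask(sub)
  n_skel <- sum(skel)
  if (n_skel == 0) return(0)
  pg <- pixel_graph(skel)
  if (n_skel == 1) {
    path <- pg$idx
    path_len <- 0
  } else {
    d <- igraph::distances(pg$g, weights = pg$weights)
    d[!is.finite(d)] <- -1
    far <- arrayInd(which.max(d), dim(d))
    sp <- igraph::shortest_paths(pg$g, from = far[1], to = far[2],
                                 weights = pg$weights)$vpath[[1]]
    path <- pg$idx[as.integer(sp)]
    nr <- nrow(sub)
    pr <- ((path - 1L) %% nr) + 1L
    pc <- ((path - 1L) %/% nr) + 1L
    diag_step <- abs(diff(pr)) + abs(diff(pc)) == 2
    path_len <- 0.948 * sum(!diag_step) + 1.340 * sum(diag_step)
  }
  # per-end extension: among mask pixels whose nearest path vertex is the
  # path endpoint, how far does the object reach beyond it, less the local
  # half-width (so a perfectly recovered medial axis gets no extension)
  dmap <- EBImage::distmap(sub * 1)
  mg <- pixel_graph(sub)
  vids <- match(path, mg$idx)
  dm <- igraph::distances(mg$g, v = vids, weights = mg$weights)
  dm[!is.finite(dm)] <- Inf
  nearest <- max.col(-t(dm), ties.method = "first")
  ext <- 0
  for (e in c(1L, length(path))) {
    own <- nearest == e
    reach <- if (any(own)) max(dm[e, own]) else 0
    ext <- ext + max(0, reach - dmap[path[e]])
  }
  path_len + ext
}
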