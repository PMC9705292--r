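#' Segment vessels from a fundus image
#'
#' Thresholding-based segmentation for vessel-contrast images: vessels are
#' the darker phase (light-absorbing in the red channel). The threshold is
#' chosen by Otsu's method. With seed points given, only connected
#' components (8-connectivity) touching a seed are retained -- the
#' semi-automatic, operator-in-the-loop mode.
#'
#' @param image Numeric [y, x] matrix in [0, 1], or a [y, x, channel] array
#'   of which the first (red) channel is used.
#' @param seeds Optional per-vessel click points: a two-column (x, y) matrix
#'   or data.frame with columns \code{x}, \code{y} (1-based px).
#' @param dark_vessels Are vessels darker than the background? Default TRUE.
#' @return Logical [y, x] matrix; TRUE for vessel pixels. A blank
#'   (constant) image yields an all-FALSE map.
#' @export
segment_vessels <- function(image, seeds = NULL, dark_vessels = TRUE) {
  if (length(dim(image)) == 3) image <- image[, , 1]
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (diff(range(image)) < 1e-6)
    return(matrix(FALSE, nrow(image), ncol(image)))
  thr <- EBImage::otsu(EBImage::Image(image))
  bw <- if (dark_vessels) image < thr else image > thr
  if (!is.null(seeds) && nrow(seeds) > 0) {
    has_names <- !is.null(colnames(seeds)) && all(c("x", "y") %in% colnames(seeds))
    sx <- round(as.numeric(if (has_names) seeds[, "x"] else seeds[, 1]))
    sy <- round(as.numeric(if (has_names) seeds[, "y"] else seeds[, 2]))
    lab <- label8(bw)
    hit <- lab[cbind(sy, sx)]
    if (any(hit == 0))
      warning(sprintf("%d seed(s) not on any segmented component; skipped",
                      sum(hit == 0)))
    keep <- unique(hit[hit > 0])
    bw <- matrix(lab %in% keep, nrow(bw), ncol(bw))
  }
  bw
}

#' 8-connected component labelling
#'
#' Built on EBImage's 4-connected flood fill, with labels merged across
#' diagonal adjacencies via union-find.
#'
#' @param bw Logical matrix.
#' @param cut_diag Optional logical matrix: diagonal adjacencies between
#'   two pixels that are both marked TRUE are not merged. Used when
#'   splitting skeletons at junctions, where branches otherwise remain
#'   diagonally connected around a removed junction pixel.
#' @return Integer matrix of component labels (0 = background), relabelled
#'   1..n in first-encounter order.
#' @export
label8 <- function(bw, cut_diag = NULL) {
  lab <- EBImage::bwlabel(bw * 1)
  lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # Diagonal neighbour pairs (down-right and down-left).
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  if (!is.null(cut_diag)) {
    c1a <- cut_diag[-nr, -nc]; c1b <- cut_diag[-1, -1]
    c2a <- cut_diag[-nr, -1];  c2b <- cut_diag[-1, -nc]
    sel1 <- sel1 & !(c1a & c1b)
    sel2 <- sel2 & !(c2a & c2b)
  }
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # Relabel roots compactly in order of first appearance.
  new_id <- integer(n)
  uroots <- unique(root)
  new_id[uroots] <- seq_along(uroots)
  out <- lab
  out[lab > 0] <- new_id[root[lab[lab > 0]]]
  out
}
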