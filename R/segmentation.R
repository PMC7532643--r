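#' Otsu threshold of an intensity image
#'
#' Computes the histogram threshold that maximizes the between-class variance
#' (equivalently, minimizes the pooled within-class variance) over a 256-bin
#' histogram spanning the observed intensity range. Candidate thresholds are
#' the 255 interior bin edges; ties are broken toward the lowest edge so that
#' the result is deterministic. The foreground mask is `values > threshold`.
#'
#' @param img A [channel_image] or numeric matrix with at least two distinct
#'   values.
#' @return A list with `mask` (logical matrix) and `threshold` (numeric).
#' @examples
#' img <- matrix(c(rep(0, 32), rep(100, 32)), 8, 8)
#' ot <- otsu_threshold(img)
#' ot$threshold
#' @export
otsu_threshold <- function(img) {
  v <- .chan_values(img, "img")
  rng <- range(v)
  if (!(rng[2] > rng[1])) {
    stop("degenerate input: constant image has no Otsu threshold", call. = FALSE)
  }
  nb <- 256L
  width <- (rng[2] - rng[1]) / nb
  bin <- pmin(floor((as.numeric(v) - rng[1]) / width) + 1L, nb)
  cnt <- as.numeric(tabulate(bin, nbins = nb))
  mids <- rng[1] + (seq_len(nb) - 0.5) * width
  csum <- cumsum(cnt)
  msum <- cumsum(cnt * mids)
  n_tot <- csum[nb]
  m_tot <- msum[nb]
  t <- seq_len(nb - 1L)
  w0 <- csum[t]
  w1 <- n_tot - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- msum[t] / w0
  mu1 <- (m_tot - msum[t]) / w1
  sb <- w0 * w1 * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  t_best <- which.max(sb)  # first (lowest) maximizer
  threshold <- rng[1] + t_best * width
  list(mask = matrix(v > threshold, nrow(v), ncol(v)), threshold = threshold)
}

#' Remove isolated foreground pixels from a binary mask
#'
#' A true pixel with no true neighbor among its 8-connected neighborhood is
#' set to false; all other pixels are unchanged. This is the noise-rejection
#' step applied to the thresholded nuclear stain before dilation.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same shape.
#' @export
remove_isolated_pixels <- function(mask) {
  mask <- .as_binary_matrix(mask)
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  nb <- matrix(0L, h, w)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- nb + p[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    }
  }
  mask & (nb > 0L)
}

# Exact Euclidean distance (in pixels) of every pixel to the nearest true
# pixel of `mask`; Inf everywhere if the mask is empty.
.dist_px <- function(mask) {
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(1 - mask, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Build the vessel "inside" and agglomeration masks by micron dilation
#'
#' Dilates the noise-filtered nuclei mask with Euclidean disks calibrated in
#' micrometres: a first dilation (default 8 um) defines the "inside" of each
#' vessel, and a second dilation (default 25 um) groups nearby nucleus
#' agglomerations into one continuous vessel. Dilation by a disk of radius r
#' is computed exactly as thresholding the Euclidean distance transform at r
#' pixels, with `r = round(radius_um / pixel_size_um)`.
#'
#' @param nuclei_mask Logical matrix, the noise-filtered nuclear-stain mask.
#' @param pixel_size_um Positive pixel size in um/px.
#' @param inside_um Radius of the first dilation (um), default 8.
#' @param agglomeration_um Radius of the second dilation (um), default 25.
#' @param mode `"successive"` (default) applies the second dilation to the
#'   already-dilated inside mask, so the agglomeration boundary lies
#'   `inside_um + agglomeration_um` from the nuclei; `"from_nuclei"` measures
#'   the second dilation from the nuclei themselves (sensitivity analysis).
#' @return List with logical matrices `inside` and `agglomeration`
#'   (`inside` is always a subset of `agglomeration`).
#' @export
build_vessel_masks <- function(nuclei_mask, pixel_size_um,
                               inside_um = 8, agglomeration_um = 25,
                               mode = c("successive", "from_nuclei")) {
  mode <- match.arg(mode)
  mask <- .as_binary_matrix(nuclei_mask, "nuclei_mask")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (!any(mask)) {
    empty <- matrix(FALSE, nrow(mask), ncol(mask))
    return(list(inside = empty, agglomeration = empty))
  }
  r1 <- round(inside_um / pixel_size_um)
  r2 <- round(agglomeration_um / pixel_size_um)
  d_nuclei <- .dist_px(mask)
  inside <- d_nuclei <= r1
  agglomeration <- if (mode == "successive") {
    .dist_px(inside) <= r2
  } else {
    inside | (d_nuclei <= r2)
  }
  list(inside = inside, agglomeration = agglomeration)
}

# 8-connected component labeling; labels are 1..K in order of the smallest
# column-major linear index in each component (deterministic).
.label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(out)
  pos <- integer(h * w)
  pos[idx] <- seq_len(n)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  edge_from <- integer(0)
  edge_to <- integer(0)
  offs <- list(c(1L, 1L, 0L),        # down
               c(h, 0L, 1L),         # right
               c(h + 1L, 1L, 1L),    # down-right
               c(h - 1L, -1L, 1L))   # up-right
  for (o in offs) {
    ok <- rep(TRUE, n)
    if (o[2] == 1L) ok <- ok & rows < h
    if (o[2] == -1L) ok <- ok & rows > 1L
    if (o[3] == 1L) ok <- ok & cols < w
    nb <- idx[ok] + o[1]
    hit <- pos[nb] > 0L
    edge_from <- c(edge_from, pos[idx[ok]][hit])
    edge_to <- c(edge_to, pos[nb][hit])
  }
  g <- igraph::make_graph(as.vector(rbind(edge_from, edge_to)), n = n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # idx is ascending, so first appearance order = order of minimum linear index
  relabel <- match(memb, unique(memb))
  out[idx] <- as.integer(relabel)
  out
}

#' Partition the field into per-vessel influence zones
#'
#' Treats each 8-connected component of the agglomeration mask as one vessel
#' seed and computes the watershed of the negated Euclidean
#' distance-to-nearest-seed surface: every pixel of the field receives the
#' label of its nearest seed component (exact Euclidean distance), so the
#' zones partition the entire image. Pixels exactly equidistant from two
#' seeds are assigned to the lowest label, and seeds are numbered 1..K by the
#' position of their first pixel in column-major order, making the output
#' deterministic.
#'
#' @param agglomeration_mask Logical matrix with at least one true pixel.
#' @return Integer matrix of labels in `1..K` covering every pixel.
#' @export
watershed_influence <- function(agglomeration_mask) {
  mask <- .as_binary_matrix(agglomeration_mask, "agglomeration_mask")
  comps <- .label_components(mask)
  k <- max(comps)
  if (k == 0L) stop("no vessels: agglomeration mask is empty", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(1L, h, w)
  if (k == 1L) return(labels)
  best <- .dist_px(comps == 1L)
  for (j in 2:k) {
    dj <- .dist_px(comps == j)
    upd <- dj < best  # strict: ties keep the lower label
    labels[upd] <- j
    best[upd] <- dj[upd]
  }
  labels
}

#' Segment vessels from the nuclear-stain channel
#'
#' Full segmentation chain: Otsu threshold of the blue channel, removal of
#' isolated pixels, the two successive micron dilations, and the watershed
#' partition into influence zones.
#'
#' @param blue [channel_image] of the nuclear/vascular stain.
#' @param inside_um,agglomeration_um,dilation_mode Passed to
#'   [build_vessel_masks()].
#' @return An object of class `vessel_segmentation`: list with `nuclei_mask`,
#'   `inside_mask`, `agglomeration_mask`, `labels`, `n_vessels` and
#'   `pixel_size_um`.
#' @examples
#' field <- generate_field(simulation_config(
#'   image_height_px = 256, image_width_px = 256, n_vessels = 2,
#'   min_separation_um = 80, background_sigma = 0, seed = 3))
#' seg <- segment_vessels(field$blue)
#' seg$n_vessels
#' @export
segment_vessels <- function(blue, inside_um = 8, agglomeration_um = 25,
                            dilation_mode = c("successive", "from_nuclei")) {
  dilation_mode <- match.arg(dilation_mode)
  ps <- .chan_pixel_size(blue)
  ot <- otsu_threshold(blue)
  nuclei <- remove_isolated_pixels(ot$mask)
  masks <- build_vessel_masks(nuclei, ps, inside_um, agglomeration_um,
                              mode = dilation_mode)
  if (!any(masks$agglomeration)) {
    stop("no vessels found: empty agglomeration mask", call. = FALSE)
  }
  labels <- watershed_influence(masks$agglomeration)
  structure(list(nuclei_mask = nuclei,
                 inside_mask = masks$inside,
                 agglomeration_mask = masks$agglomeration,
                 labels = labels,
                 n_vessels = max(labels),
                 pixel_size_um = ps,
                 threshold = ot$threshold),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf(
    "<vessel_segmentation> %d vessels, inside %d px, agglomeration %d px (%.3g um/px)\n",
    x$n_vessels, sum(x$inside_mask), sum(x$agglomeration_mask),
    x$pixel_size_um))
  invisible(x)
}
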