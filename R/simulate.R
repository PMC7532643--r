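#' Configuration for the synthetic two-channel field generator
#'
#' Defines the geometry, intensities and noise of a simulated confocal field
#' of a thin (cryosection-like) tumor slice: straight vessel segments whose
#' walls are lined with nuclei (the "blue" perfusion-stain channel), and an
#' antibody fluorophore (the "red" channel) that is intravascular everywhere
#' and, for leaky vessels, additionally forms a perivascular halo decaying
#' exponentially with distance from the lumen.
#'
#' Defaults emulate a 20x confocal field of a treated tumor section: a ~1.15 mm
#' square field at 1 um/px, capillary-scale lumens (3.5 um radius) lined by
#' endothelial nuclei (2.5 um radius, ~4 um apart along the wall), a bright
#' intravascular pool, and for leaky vessels a halo whose amplitude exceeds the
#' intravascular level (blood is flushed at perfusion fixation while
#' extravasated antibody is retained) decaying over `decay_length_um = 30` um.
#'
#' @param image_height_px,image_width_px Field size in pixels.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param n_vessels Number of vessels to place (rejection-sampled so that
#'   centerlines keep at least `min_separation_um` apart; lumens never overlap).
#' @param vessel_length_um Length of each straight vessel segment, um.
#' @param lumen_radius_um Lumen radius, um.
#' @param nucleus_radius_um Radius of the wall nuclei, um.
#' @param nucleus_spacing_um Mean gap between neighboring nuclei along the
#'   vessel wall, um.
#' @param nucleus_intensity Blue-channel intensity of a nucleus (a.u.).
#' @param intravascular_intensity Red-channel intensity inside the lumen (a.u.).
#' @param leaky_fraction Fraction of vessels that are leaky, in `[0, 1]`; the
#'   number of leaky vessels is `round(leaky_fraction * n_vessels)`, assigned
#'   to a random subset.
#' @param halo_amplitude Red halo intensity at the lumen wall of a leaky
#'   vessel (a.u.).
#' @param decay_length_um Exponential decay length (lambda) of the
#'   perivascular halo, um: the halo at distance `d` from the lumen surface is
#'   `halo_amplitude * exp(-d / lambda)`.
#' @param background_sigma Standard deviation of additive Gaussian noise
#'   applied to both channels (clipped at zero).
#' @param min_separation_um Minimum distance between vessel centerline
#'   segments, um.
#' @param border_margin_um Minimum distance of segment endpoints from the
#'   field border, um.
#' @param seed Integer seed; identical configurations reproduce identical
#'   fields bit for bit.
#'
#' @return An object of class `simulation_config`.
#' @seealso [generate_field()]
#' @export
simulation_config <- function(image_height_px = 1152L,
                              image_width_px = 1152L,
                              pixel_size_um = 1,
                              n_vessels = 20L,
                              vessel_length_um = 60,
                              lumen_radius_um = 3.5,
                              nucleus_radius_um = 2.5,
                              nucleus_spacing_um = 4,
                              nucleus_intensity = 255,
                              intravascular_intensity = 150,
                              leaky_fraction = 0.5,
                              halo_amplitude = 200,
                              decay_length_um = 30,
                              background_sigma = 5,
                              min_separation_um = 140,
                              border_margin_um = 45,
                              seed = 1L) {
  cfg <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = as.numeric(pixel_size_um),
    n_vessels = as.integer(n_vessels),
    vessel_length_um = as.numeric(vessel_length_um),
    lumen_radius_um = as.numeric(lumen_radius_um),
    nucleus_radius_um = as.numeric(nucleus_radius_um),
    nucleus_spacing_um = as.numeric(nucleus_spacing_um),
    nucleus_intensity = as.numeric(nucleus_intensity),
    intravascular_intensity = as.numeric(intravascular_intensity),
    leaky_fraction = as.numeric(leaky_fraction),
    halo_amplitude = as.numeric(halo_amplitude),
    decay_length_um = as.numeric(decay_length_um),
    background_sigma = as.numeric(background_sigma),
    min_separation_um = as.numeric(min_separation_um),
    border_margin_um = as.numeric(border_margin_um),
    seed = as.integer(seed)
  )
  lengths_pos <- c("pixel_size_um", "vessel_length_um", "lumen_radius_um",
                   "nucleus_radius_um", "nucleus_spacing_um", "decay_length_um")
  for (f in lengths_pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("`%s` must be strictly positive", f), call. = FALSE)
    }
  }
  if (cfg$image_height_px < 1L || cfg$image_width_px < 1L) {
    stop("image dimensions must be at least 1 px", call. = FALSE)
  }
  if (cfg$n_vessels < 0L) stop("`n_vessels` must be >= 0", call. = FALSE)
  if (cfg$leaky_fraction < 0 || cfg$leaky_fraction > 1) {
    stop("`leaky_fraction` must be in [0, 1]", call. = FALSE)
  }
  for (f in c("nucleus_intensity", "intravascular_intensity", "halo_amplitude",
              "background_sigma", "min_separation_um", "border_margin_um")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("`%s` must be nonnegative", f), call. = FALSE)
    }
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_config> %d x %d px @ %.3g um/px, %d vessels ",
    "(L=%g um, lumen r=%g um), leaky fraction %.2f, lambda=%g um, ",
    "sigma=%g, seed=%d\n"),
    x$image_height_px, x$image_width_px, x$pixel_size_um, x$n_vessels,
    x$vessel_length_um, x$lumen_radius_um, x$leaky_fraction,
    x$decay_length_um, x$background_sigma, x$seed))
  invisible(x)
}

# Distance between two segments p1-p2 and q1-q2 (each c(y, x)), in um.
.seg_seg_dist <- function(p1, p2, q1, q2) {
  if (.seg_intersect(p1, p2, q1, q2)) return(0)
  min(.point_seg_dist(q1[1], q1[2], p1, p2),
      .point_seg_dist(q2[1], q2[2], p1, p2),
      .point_seg_dist(p1[1], p1[2], q1, q2),
      .point_seg_dist(p2[1], p2[2], q1, q2))
}

.point_seg_dist <- function(y, x, a, b) {
  vy <- b[1] - a[1]; vx <- b[2] - a[2]
  l2 <- vy * vy + vx * vx
  t <- if (l2 == 0) 0 else pmin(pmax(((y - a[1]) * vy + (x - a[2]) * vx) / l2, 0), 1)
  sqrt((y - (a[1] + t * vy))^2 + (x - (a[2] + t * vx))^2)
}

.seg_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    sign((b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2]))
  }
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 != o2 && o3 != o4)
}

# Rejection-sample n straight segments with pairwise separation and a border
# margin; errors out after a bounded number of attempts.
.place_vessels <- function(cfg) {
  n <- cfg$n_vessels
  if (n == 0L) {
    return(data.frame(vessel_id = integer(), y1_um = numeric(),
                      x1_um = numeric(), y2_um = numeric(), x2_um = numeric()))
  }
  h_um <- cfg$image_height_px * cfg$pixel_size_um
  w_um <- cfg$image_width_px * cfg$pixel_size_um
  m <- cfg$border_margin_um
  L <- cfg$vessel_length_um
  if (h_um - 2 * m <= 0 || w_um - 2 * m <= 0) {
    stop("field too small to place vessels: border margin exceeds field size",
         call. = FALSE)
  }
  segs <- vector("list", n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- max(5000L, 1000L * n)
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "failed to place %d vessels after %d attempts; field too small for the requested separation",
        n, max_attempts), call. = FALSE)
    }
    theta <- stats::runif(1, 0, pi)
    cy <- stats::runif(1, m, h_um - m)
    cx <- stats::runif(1, m, w_um - m)
    dy <- sin(theta) * L / 2
    dx <- cos(theta) * L / 2
    p1 <- c(cy - dy, cx - dx)
    p2 <- c(cy + dy, cx + dx)
    if (min(p1, p2) < m || p1[1] > h_um - m || p2[1] > h_um - m ||
        p1[2] > w_um - m || p2[2] > w_um - m) next
    ok <- TRUE
    if (placed > 0L) {
      for (j in seq_len(placed)) {
        s <- segs[[j]]
        if (.seg_seg_dist(p1, p2, c(s[1], s[2]), c(s[3], s[4])) <
            cfg$min_separation_um) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) next
    placed <- placed + 1L
    segs[[placed]] <- c(p1, p2)
  }
  out <- do.call(rbind, segs)
  data.frame(vessel_id = seq_len(n), y1_um = out[, 1], x1_um = out[, 2],
             y2_um = out[, 3], x2_um = out[, 4])
}

# Field of distances (um) from every pixel center to a segment.
.segment_distance_field <- function(Y, X, y1, x1, y2, x2) {
  vy <- y2 - y1; vx <- x2 - x1
  l2 <- vy * vy + vx * vx
  if (l2 == 0) return(sqrt((Y - y1)^2 + (X - x1)^2))
  t <- ((Y - y1) * vy + (X - x1) * vx) / l2
  t[t < 0] <- 0
  t[t > 1] <- 1
  sqrt((Y - (y1 + t * vy))^2 + (X - (x1 + t * vx))^2)
}

# Stamp a disk of the given intensity into `img` (matrix, modified copy
# returned); center in um, radius in um. Pixel centers at (i - 0.5) * ps.
.stamp_disk <- function(img, cy, cx, r, value, ps) {
  h <- nrow(img); w <- ncol(img)
  r0 <- max(1L, floor((cy - r) / ps + 0.5))
  r1 <- min(h, ceiling((cy + r) / ps + 0.5))
  c0 <- max(1L, floor((cx - r) / ps + 0.5))
  c1 <- min(w, ceiling((cx + r) / ps + 0.5))
  if (r0 > r1 || c0 > c1) return(img)
  yy <- (r0:r1 - 0.5) * ps
  xx <- (c0:c1 - 0.5) * ps
  d2 <- outer(yy - cy, xx - cx, function(a, b) a * a + b * b)
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  sub[d2 <= r * r] <- pmax(sub[d2 <= r * r], value)
  img[r0:r1, c0:c1] <- sub
  img
}

#' Generate a synthetic two-channel field with known ground truth
#'
#' Places straight, non-overlapping vessel segments, lines each lumen wall
#' with nucleus disks (blue channel), fills each lumen with intravascular
#' antibody signal and adds, for leaky vessels, a perivascular halo
#' `halo_amplitude * exp(-d / decay_length_um)` where `d` is the distance of a
#' pixel center from the lumen surface (red channel). Additive Gaussian noise
#' of standard deviation `background_sigma` is applied to both channels and
#' clipped at zero. The same configuration (including `seed`) reproduces the
#' same field bit for bit.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#' \describe{
#'   \item{blue}{[channel_image] of the nuclear/vascular stain.}
#'   \item{red}{[channel_image] of the antibody fluorophore.}
#'   \item{truth}{`synthetic_truth` object: `vessels` (data frame with
#'     per-vessel centerline endpoints in um, `leaky` flag and
#'     `decay_length_um`, `NA` for tight vessels), `lumen_labels` (integer
#'     matrix, vessel id on lumen pixels, 0 elsewhere), `n_vessels`, and the
#'     generating `config`.}
#' }
#' @examples
#' cfg <- simulation_config(image_height_px = 192, image_width_px = 192,
#'                          n_vessels = 2, min_separation_um = 60,
#'                          vessel_length_um = 30, seed = 7)
#' field <- generate_field(cfg)
#' field$blue
#' field$truth$vessels
#' @export
generate_field <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("`config` must be a simulation_config", call. = FALSE)
  }
  set.seed(config$seed)
  h <- config$image_height_px
  w <- config$image_width_px
  ps <- config$pixel_size_um
  segs <- .place_vessels(config)
  n <- nrow(segs)

  leaky <- rep(FALSE, n)
  if (n > 0L) {
    n_leaky <- round(config$leaky_fraction * n)
    if (n_leaky > 0L) leaky[sample.int(n, n_leaky)] <- TRUE
  }

  blue <- matrix(0, h, w)
  red <- matrix(0, h, w)
  lumen_labels <- matrix(0L, h, w)

  if (n > 0L) {
    Y <- matrix((seq_len(h) - 0.5) * ps, h, w)
    X <- matrix((seq_len(w) - 0.5) * ps, h, w, byrow = TRUE)
    for (k in seq_len(n)) {
      d <- .segment_distance_field(Y, X, segs$y1_um[k], segs$x1_um[k],
                                   segs$y2_um[k], segs$x2_um[k])
      lum <- d <= config$lumen_radius_um
      red[lum] <- red[lum] + config$intravascular_intensity
      lumen_labels[lum] <- k
      if (leaky[k]) {
        halo <- config$halo_amplitude *
          exp(-(d - config$lumen_radius_um) / config$decay_length_um)
        red[!lum] <- red[!lum] + halo[!lum]
      }
      blue <- .line_nuclei(blue, segs[k, ], config)
    }
  }

  if (config$background_sigma > 0) {
    blue <- pmax(blue + stats::rnorm(h * w, 0, config$background_sigma), 0)
    red <- pmax(red + stats::rnorm(h * w, 0, config$background_sigma), 0)
  }

  vessels <- segs
  vessels$leaky <- leaky
  vessels$decay_length_um <- ifelse(leaky, config$decay_length_um, NA_real_)

  truth <- structure(list(vessels = vessels, lumen_labels = lumen_labels,
                          n_vessels = n, config = config),
                     class = "synthetic_truth")
  list(blue = channel_image(blue, ps), red = channel_image(red, ps),
       truth = truth)
}

# Place nucleus disks along both walls of one segment.
.line_nuclei <- function(blue, seg, cfg) {
  L <- sqrt((seg$y2_um - seg$y1_um)^2 + (seg$x2_um - seg$x1_um)^2)
  uy <- (seg$y2_um - seg$y1_um) / L
  ux <- (seg$x2_um - seg$x1_um) / L
  ny <- -ux; nx <- uy  # unit normal
  step_mean <- 2 * cfg$nucleus_radius_um + cfg$nucleus_spacing_um
  for (side in c(-1, 1)) {
    pos <- stats::runif(1, 0, step_mean)
    while (pos <= L) {
      cy <- seg$y1_um + pos * uy + side * cfg$lumen_radius_um * ny
      cx <- seg$x1_um + pos * ux + side * cfg$lumen_radius_um * nx
      blue <- .stamp_disk(blue, cy, cx, cfg$nucleus_radius_um,
                          cfg$nucleus_intensity, cfg$pixel_size_um)
      pos <- pos + 2 * cfg$nucleus_radius_um +
        cfg$nucleus_spacing_um * stats::runif(1, 0.5, 1.5)
    }
  }
  blue
}

#' Match ground-truth vessels to segmentation labels
#'
#' Associates each simulated vessel with the influence-zone label that covers
#' the majority of its lumen pixels, for parameter-recovery validation.
#'
#' @param seg A `vessel_segmentation` of the generated blue channel.
#' @param truth The `synthetic_truth` of the same field.
#' @return Integer vector of length `truth$n_vessels`: the segmentation label
#'   of each ground-truth vessel.
#' @export
match_ground_truth <- function(seg, truth) {
  vapply(seq_len(truth$n_vessels), function(k) {
    lb <- seg$labels[truth$lumen_labels == k]
    as.integer(names(sort(table(lb), decreasing = TRUE))[1])
  }, integer(1))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d vessels (%d leaky), lumen area %d px\n",
              x$n_vessels, sum(x$vessels$leaky), sum(x$lumen_labels > 0)))
  invisible(x)
}
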