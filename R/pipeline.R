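#' Pipeline configuration
#'
#' Collects the tunable parameters of the extravasation quantification chain.
#' The defaults reproduce the standard analysis: an 8 um inside dilation
#' followed by a further 25 um agglomeration dilation (identical for all
#' images), distance bands one pixel wide, Type III ANOVA partitioning and a
#' two-sided Fisher test.
#'
#' @param pixel_size_um Pixel size override in um/px; when `NULL` the pixel
#'   size must be resolvable from the image file (TIFF resolution tags or a
#'   JSON sidecar written by [write_field()]). A non-`NULL` value always wins.
#' @param channel_blue,channel_red 1-based channel indices in the TIFF.
#' @param dilation_inside_um,dilation_agglomeration_um Dilation radii in um.
#' @param dilation_mode `"successive"` or `"from_nuclei"`; see
#'   [build_vessel_masks()].
#' @param band_preset `"fine"` (bands one pixel wide) or `"figure36um"`
#'   (36 um bands, the coarse spacing used for display-style distance masks).
#' @param band_width_um Explicit band width in um, overriding the preset.
#' @param anova_ss_type `"III"` or `"I"`.
#' @param log_level `"info"` prints per-stage counts, `"quiet"` does not.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = NULL,
                            channel_blue = 1L,
                            channel_red = 2L,
                            dilation_inside_um = 8,
                            dilation_agglomeration_um = 25,
                            dilation_mode = c("successive", "from_nuclei"),
                            band_preset = c("fine", "figure36um"),
                            band_width_um = NULL,
                            anova_ss_type = c("III", "I"),
                            log_level = c("info", "quiet")) {
  dilation_mode <- match.arg(dilation_mode)
  band_preset <- match.arg(band_preset)
  anova_ss_type <- match.arg(anova_ss_type)
  log_level <- match.arg(log_level)
  if (!is.null(pixel_size_um) &&
      (!is.numeric(pixel_size_um) || pixel_size_um <= 0)) {
    stop("`pixel_size_um` must be NULL or a positive number", call. = FALSE)
  }
  if (dilation_inside_um <= 0 || dilation_agglomeration_um <= 0) {
    stop("dilation radii must be positive", call. = FALSE)
  }
  structure(list(pixel_size_um = pixel_size_um,
                 channel_blue = as.integer(channel_blue),
                 channel_red = as.integer(channel_red),
                 dilation_inside_um = dilation_inside_um,
                 dilation_agglomeration_um = dilation_agglomeration_um,
                 dilation_mode = dilation_mode,
                 band_preset = band_preset,
                 band_width_um = band_width_um,
                 anova_ss_type = anova_ss_type,
                 log_level = log_level),
            class = "pipeline_config")
}

.log_info <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) message(sprintf(fmt, ...))
  invisible(NULL)
}

.band_width <- function(config, pixel_size_um) {
  if (!is.null(config$band_width_um)) return(config$band_width_um)
  if (config$band_preset == "figure36um") return(36)
  pixel_size_um
}

#' Write a two-channel field to TIFF with a JSON sidecar
#'
#' Stores the blue and red channels as a two-page 32-bit float TIFF (channel
#' order: blue, red). Because baseline TIFF stores float32 in `[0, 1]`,
#' intensities are divided by a power-of-two scale recorded, together with
#' `pixel_size_um` and any ground truth, in a JSON sidecar `<path>.json`
#' (replacing the `.tif` extension). The round trip is exact to float32
#' precision (about 1e-7 relative).
#'
#' @param blue,red [channel_image]s sharing shape and pixel size.
#' @param path Output TIFF path.
#' @param truth Optional `synthetic_truth`; its per-vessel records are stored
#'   in the sidecar.
#' @return `path`, invisibly.
#' @export
write_field <- function(blue, red, path, truth = NULL) {
  bv <- .chan_values(blue, "blue")
  rv <- .chan_values(red, "red")
  if (!identical(dim(bv), dim(rv))) {
    stop("blue and red channels must share the same shape", call. = FALSE)
  }
  ps <- .chan_pixel_size(blue)
  top <- max(bv, rv, 1)
  scale <- 2^ceiling(log2(top))
  tiff::writeTIFF(list(bv / scale, rv / scale), path, bits.per.sample = 32L)
  sidecar <- list(pixel_size_um = ps, intensity_scale = scale,
                  channels = c("blue", "red"))
  if (!is.null(truth)) {
    sidecar$vessels <- truth$vessels
  }
  jsonlite::write_json(sidecar, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a two-channel field from a multi-channel TIFF
#'
#' Channels are mapped by the configured indices (default: page 1 = blue,
#' page 2 = red; a single page with a third array dimension is also
#' accepted). The pixel size is resolved, in order of precedence, from the
#' configuration override, the TIFF resolution tags, or a JSON sidecar
#' written by [write_field()]; if none is available an error is raised.
#' Intensities are clipped at zero and rescaled by the sidecar's intensity
#' scale when present.
#'
#' @param path Path to the TIFF file.
#' @param config A [pipeline_config()].
#' @return List with [channel_image]s `blue` and `red`.
#' @export
read_field <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop(sprintf("cannot read `%s`", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
    a <- pages[[1]]
    pages <- lapply(seq_len(dim(a)[3]), function(k) {
      out <- a[, , k]
      attributes(out) <- c(attributes(out),
                           attributes(a)[c("x.resolution", "resolution.unit")])
      out
    })
  }
  need <- max(config$channel_blue, config$channel_red)
  if (length(pages) < need) {
    stop(sprintf("`%s` has %d channel(s); %d required by the channel mapping",
                 path, length(pages), need), call. = FALSE)
  }
  sidecar <- NULL
  sp <- .sidecar_path(path)
  if (file.exists(sp)) sidecar <- jsonlite::read_json(sp, simplifyVector = TRUE)

  ps <- config$pixel_size_um
  if (is.null(ps)) ps <- .resolution_to_um(attributes(pages[[1]]))
  if (is.null(ps) && !is.null(sidecar$pixel_size_um)) {
    ps <- sidecar$pixel_size_um
  }
  if (is.null(ps)) {
    stop(sprintf(
      "`%s`: no pixel size in TIFF tags or sidecar and no config override",
      path), call. = FALSE)
  }
  scale <- if (!is.null(sidecar$intensity_scale)) sidecar$intensity_scale else 1
  grab <- function(k) {
    v <- pages[[k]]
    if (length(dim(v)) == 3L) v <- v[, , 1L]
    channel_image(pmax(matrix(as.numeric(v), nrow(v), ncol(v)), 0) * scale, ps)
  }
  list(blue = grab(config$channel_blue), red = grab(config$channel_red))
}

.resolution_to_um <- function(att) {
  xres <- att[["x.resolution"]]
  if (is.null(xres) || !is.numeric(xres) || xres <= 0) return(NULL)
  unit <- att[["resolution.unit"]]
  per_unit_um <- switch(as.character(unit %||% "inch"),
                        inch = 25400, cm = 10000, NULL)
  if (is.null(per_unit_um)) return(NULL)
  per_unit_um / xres
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One image -> segmentation + per-vessel profiles. `field` is a list with
# channel_images `blue` and `red`.
.process_field <- function(field, config, image_id) {
  seg <- segment_vessels(field$blue,
                         inside_um = config$dilation_inside_um,
                         agglomeration_um = config$dilation_agglomeration_um,
                         dilation_mode = config$dilation_mode)
  noise_mask <- antibody_noise_mask(field$red)
  .log_info(config, "[%s] %d vessels, inside %d px, red mask %d px",
            image_id, seg$n_vessels, sum(seg$inside_mask), sum(noise_mask))
  bw <- .band_width(config, seg$pixel_size_um)
  profiles <- profile_all(seg, field$red, band_width_um = bw,
                          noise_mask = noise_mask)
  tab <- profiles_table(profiles)
  tab$image <- image_id
  list(seg = seg, profiles = profiles, table = tab)
}

.load_side <- function(inputs, config, side) {
  if (is.character(inputs)) {
    fields <- lapply(inputs, read_field, config = config)
    names(fields) <- paste0(side, "_", basename(inputs))
  } else if (is.list(inputs)) {
    if (!is.null(inputs$blue)) inputs <- list(inputs)
    fields <- inputs
    names(fields) <- paste0(side, "_field", seq_along(fields))
  } else {
    stop("inputs must be file paths or lists of fields", call. = FALSE)
  }
  fields
}

#' Run the full extravasation quantification pipeline
#'
#' For every image of each side: segment vessels from the blue channel,
#' compute per-vessel cumulative differential antibody profiles, then pool
#' vessels per side into the contingency table, Fisher's exact test and the
#' side-level summary metrics. Given identical inputs and configuration the
#' output (including written CSVs) is byte-identical between runs.
#'
#' @param control,treated Either character vectors of TIFF paths, or lists of
#'   in-memory fields (each a list with [channel_image]s `blue` and `red`,
#'   e.g. from [generate_field()]); at least one image per side.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, writes `vessels.csv`
#'   (one row per vessel), `contingency.csv` (counts, percentages and the
#'   Fisher p-value), `group_metrics.csv` (per-side mean, sd, sem and n of
#'   `[DeltaAb]_max` and extravasation range), `per_image.csv` (subtotals)
#'   and `manifest.json` (configuration, input identities, package version).
#' @return List with `vessels` (data frame), `contingency`
#'   (`contingency_table`), `fisher_p`, `group_metrics`, `per_image` and
#'   `manifest`.
#' @export
run_pipeline <- function(control, treated, config = pipeline_config(),
                         output_dir = NULL) {
  fields_c <- .load_side(control, config, "control")
  fields_t <- .load_side(treated, config, "treated")
  if (length(fields_c) < 1L || length(fields_t) < 1L) {
    stop("need at least one image per side", call. = FALSE)
  }
  run_one <- function(fields, side) {
    res <- Map(function(f, id) .process_field(f, config, id),
               fields, names(fields))
    tab <- do.call(rbind, lapply(res, `[[`, "table"))
    tab$side <- side
    rownames(tab) <- NULL
    tab
  }
  vc <- run_one(fields_c, "control")
  vt <- run_one(fields_t, "treated")
  vessels <- rbind(vc, vt)
  vessels <- vessels[, c("image", "side", "vessel_id", "delta_ab_max",
                         "extravasation_range_um", "extravasated")]

  tab <- tabulate_extravasation(vc$extravasated, vt$extravasated)
  p <- fisher_exact_2x2(tab)
  pct <- percent_extravasated(tab)
  contingency <- data.frame(
    side = c("control", "treated"),
    n_extravasated = c(tab$control_exv, tab$treated_exv),
    n_not_extravasated = c(tab$control_not, tab$treated_not),
    pct_extravasated = as.integer(pct),
    fisher_p = p)

  metric_rows <- function(d, side) {
    do.call(rbind, lapply(
      c(delta_ab_max = "delta_ab_max",
        extravasation_range_um = "extravasation_range_um"),
      function(col) {
        v <- d[[col]]
        data.frame(side = side, metric = col, n = length(v), mean = mean(v),
                   sd = stats::sd(v), sem = stats::sd(v) / sqrt(length(v)))
      }))
  }
  group_metrics <- rbind(metric_rows(vc, "control"), metric_rows(vt, "treated"))
  rownames(group_metrics) <- NULL

  per_image <- do.call(rbind, lapply(split(vessels, vessels$image),
                                     function(d) {
    data.frame(image = d$image[1], side = d$side[1], n_vessels = nrow(d),
               n_extravasated = sum(d$extravasated))
  }))
  rownames(per_image) <- NULL

  manifest <- list(
    package = "vesselex",
    version = as.character(utils::packageVersion("vesselex")),
    config = unclass(config),
    inputs = list(
      control = if (is.character(control)) {
        list(paths = control, md5 = unname(tools::md5sum(control)))
      } else sprintf("%d in-memory field(s)", length(fields_c)),
      treated = if (is.character(treated)) {
        list(paths = treated, md5 = unname(tools::md5sum(treated)))
      } else sprintf("%d in-memory field(s)", length(fields_t))
    )
  )

  result <- list(vessels = vessels, contingency = tab, fisher_p = p,
                 contingency_table = contingency,
                 group_metrics = group_metrics, per_image = per_image,
                 manifest = manifest)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) utils::write.csv(
      d, file.path(output_dir, f), row.names = FALSE)
    wr(vessels, "vessels.csv")
    wr(contingency, "contingency.csv")
    wr(group_metrics, "group_metrics.csv")
    wr(per_image, "per_image.csv")
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
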