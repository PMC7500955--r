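#' Load a named simulation preset
#'
#' Presets bundle the geometry and phenotype parameters of a study condition
#' (wall radius, tubulin length distribution, per-protein radial offsets and
#' coverage distributions, break prevalence, ellipticity range). They ship
#' with the package as YAML files under `extdata/presets`.
#'
#' @param name One of `"cr-wildtype"`, `"hs-control"`, `"hs-siwdr90"`,
#'   `"wdr90-decoration"`, or a path to a custom YAML file.
#' @return A named list of preset parameters (class `centriole_preset`).
#' @examples
#' p <- centriole_preset("hs-control")
#' names(p$channels)
#' @export
centriole_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(tolower(name), ".yaml"),
                package = "centriomorph")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown preset: ", name)
  }
  p <- yaml::read_yaml(path)
  class(p) <- c("centriole_preset", "list")
  p
}

preset_channel <- function(preset, channel) {
  if (is.null(channel)) channel <- names(preset$channels)[1]
  ch <- preset$channels[[channel]]
  if (is.null(ch)) {
    stop("preset '", preset$name, "' has no channel '", channel, "'")
  }
  ch$name <- channel
  ch
}

#' Simulate a batch of centrioles from a preset
#'
#' Draws `n` centrioles from a condition preset and renders them in the
#' requested view. Per-image parameters (length, coverage, ellipticity,
#' break assignment, orientation) are drawn from the preset distributions
#' under deterministic per-image substreams of `seed`; the number of broken
#' centrioles is exactly `round(break_prevalence * n)`, assigned to a random
#' subset.
#'
#' @param preset A [centriole_preset()] or preset name.
#' @param n Number of centrioles.
#' @param view `"top"` or `"lateral"`.
#' @param channel Protein channel name from the preset (default: first).
#' @param seed Integer base seed.
#' @param imaging Optional [imaging_spec()] used as a template (its seed is
#'   replaced per image).
#' @return A list with `images` (list of `centriole_image`) and `manifest`
#'   (data frame of per-image ground truths, one row per image, including
#'   `image_id`, `channel` and every drawn parameter).
#' @export
simulate_centrioles <- function(preset, n, view = c("top", "lateral"),
                                channel = NULL, seed = 1L,
                                imaging = imaging_spec()) {
  if (is.character(preset)) preset <- centriole_preset(preset)
  view <- match.arg(view)
  ch <- preset_channel(preset, channel)
  set.seed(seed)
  n_broken <- round((preset$phenotype$break_prevalence %||% 0) * n)
  broken_ids <- if (n_broken > 0) sample.int(n, n_broken) else integer(0)
  er_range <- preset$phenotype$ellipse_ratio %||% c(1, 1)
  if (length(er_range) == 1L) er_range <- rep(er_range, 2)
  orient <- stats::runif(n, 0, 360)
  break_start <- stats::runif(n, 0, 360)
  ellipse <- stats::runif(n, er_range[[1]], er_range[[2]])
  cov_spec <- ch$coverage_pct
  pos_frac <- if (identical(preset$position, "proximal")) {
    preset$position_frac %||% 0.15
  } else NA_real_

  images <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- centriole_spec(
      view = view,
      wall_radius_nm = preset$wall_radius_nm,
      n_triplets = preset$n_triplets %||% 9L,
      tubulin_length_nm = c(preset$tubulin_length_nm$mean,
                            preset$tubulin_length_nm$sd),
      protein_offset_nm = ch$offset_nm,
      protein_coverage_frac = c(cov_spec$mean / 100, cov_spec$sd / 100),
      protein_position_frac = pos_frac,
      ellipse_ratio = ellipse[i],
      break_arc_deg = if (i %in% broken_ids) preset$phenotype$break_arc_deg else 0,
      break_start_deg = break_start[i],
      orientation_deg = orient[i])
    im <- imaging
    im$seed <- substream_seed(seed, i)
    out <- if (view == "top") generate_top_view(spec, im)
           else generate_lateral_view(spec, im)
    images[[i]] <- out$image
    row <- out$truth
    row$image_id <- i
    row$channel <- ch$name
    row$preset <- preset$name
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  manifest <- manifest[, c("image_id", "preset", "channel",
                           setdiff(names(manifest),
                                   c("image_id", "preset", "channel")))]
  list(images = images, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
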