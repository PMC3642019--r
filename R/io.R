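# File formats: multi-page 32-bit TIFF for image stacks with a JSON sidecar
# carrying geometry and the affine scale used to map data into the TIFF's
# [0,1] sample range (restored on read, so round-trips are exact to float32
# precision). Tables go to CSV, configuration to YAML.

scale_to_unit <- function(stack) {
  vmin <- min(vapply(stack, min, numeric(1)))
  vmax <- max(vapply(stack, max, numeric(1)))
  span <- if (vmax > vmin) vmax - vmin else 1
  list(images = lapply(stack, function(m) (m - vmin) / span),
       vmin = vmin, vmax = vmax)
}

write_stack_tiff <- function(stack, path) {
  sc <- scale_to_unit(stack)
  tiff::writeTIFF(sc$images, path, bits.per.sample = 32L, reduce = FALSE)
  list(vmin = sc$vmin, vmax = sc$vmax)
}

read_stack_tiff <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  span <- if (scale$vmax > scale$vmin) scale$vmax - scale$vmin else 1
  lapply(pages, function(m) m * span + scale$vmin)
}

#' Write a projection set to disk
#'
#' Writes `<name>.tif` (one page per angle), `<name>_background.tif` (pre
#' and post frames) and the JSON sidecar `<name>.json` holding angles,
#' pixel pitch, contrast mode, group id, seed and the intensity scales.
#'
#' @param pset A `projection_set`.
#' @param dir Output directory (created if needed).
#' @param name Basename (default `"projections"`).
#' @return Invisibly, the sidecar path.
#' @export
write_projections <- function(pset, dir, name = "projections") {
  stopifnot(inherits(pset, "projection_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".tif"))
  bg_path <- file.path(dir, paste0(name, "_background.tif"))
  s_img <- write_stack_tiff(pset$images, img_path)
  s_bg <- write_stack_tiff(pset$background, bg_path)
  sidecar <- list(format = "vesselct_projections", angles_deg = pset$angles_deg,
                  pixel_pitch_um = pset$pixel_pitch_um, mode = pset$mode,
                  group_id = pset$group_id, lambda = pset$lambda,
                  seed = pset$seed, domain = pset$domain,
                  scale = s_img, background_scale = s_bg)
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(json_path)
}

#' Read a projection set written by [write_projections()]
#' @param dir Directory holding the files.
#' @param name Basename (default `"projections"`).
#' @export
read_projections <- function(dir, name = "projections") {
  json_path <- file.path(dir, paste0(name, ".json"))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  required <- c("angles_deg", "pixel_pitch_um", "mode", "scale",
                "background_scale")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("malformed sidecar ", json_path, ": missing key(s) ",
         paste(missing, collapse = ", "))
  images <- read_stack_tiff(file.path(dir, paste0(name, ".tif")), meta$scale)
  bg <- read_stack_tiff(file.path(dir, paste0(name, "_background.tif")),
                        meta$background_scale)
  structure(list(images = images, angles_deg = meta$angles_deg,
                 background = list(pre = bg[[1]], post = bg[[2]]),
                 pixel_pitch_um = meta$pixel_pitch_um, mode = meta$mode,
                 group_id = meta$group_id, lambda = meta$lambda,
                 seed = meta$seed, domain = meta$domain %||% "intensity"),
            class = "projection_set")
}

#' Write a slice volume (multi-page float TIFF + sidecar)
#' @param vol A `slice_volume`.
#' @param dir Output directory.
#' @param name Basename (default `"slices"`).
#' @export
write_slices <- function(vol, dir, name = "slices") {
  stopifnot(inherits(vol, "slice_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- write_stack_tiff(lapply(vol$slices, function(s) {
    attributes(s)[c("background_gray", "background_mode")] <- NULL
    s
  }), file.path(dir, paste0(name, ".tif")))
  sidecar <- list(format = "vesselct_slices", rows = vol$rows,
                  voxel_size_um = vol$voxel_size_um,
                  axis_offset = vol$axis_offset, filter = vol$filter,
                  background_gray = vol$background_gray,
                  provenance = vol$provenance, scale = sc)
  jsonlite::write_json(sidecar, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, paste0(name, ".json")))
}

#' Read a slice volume written by [write_slices()]
#' @param dir Directory holding the files.
#' @param name Basename (default `"slices"`).
#' @export
read_slices <- function(dir, name = "slices") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  slices <- read_stack_tiff(file.path(dir, paste0(name, ".tif")), meta$scale)
  structure(list(slices = slices, rows = meta$rows,
                 voxel_size_um = meta$voxel_size_um,
                 axis_offset = meta$axis_offset, filter = meta$filter,
                 background_gray = meta$background_gray,
                 provenance = meta$provenance,
                 timings_s = rep(NA_real_, length(slices))),
            class = "slice_volume")
}

#' Write a binary mask as an 8-bit image (0/255)
#' @param mask A `binary_mask` or 0/1 matrix.
#' @param path Output path (`.png` or `.tif` by extension).
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  img <- matrix(as.numeric(m), nrow(m), ncol(m))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Export a vessel tree as JSON
#' @param tree A `vessel_tree`.
#' @param path Output path.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(list(format = "vesselct_tree",
                            contrast_per_um = tree$contrast_per_um,
                            segments = tree$segments),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vessel tree written by [write_tree_json()]
#' @param path JSON path.
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree <- structure(list(segments = as.data.frame(x$segments),
                         contrast_per_um = x$contrast_per_um),
                    class = "vessel_tree")
  validate_vessel_tree(tree)
}

#' Write a score table as CSV
#'
#' Columns: `group`, `angle_deg`, `film_idx`, `area_idx`, `roi_row`,
#' `roi_col`, `score` — one row per scored ROI.
#' @param scores Data frame of scored placements (with a `group` column).
#' @param path Output CSV path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores_csv()]
#' @param path CSV path.
#' @export
read_scores_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
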