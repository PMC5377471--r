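# Readers and writers for profile images (TIFF/PNG), voxel volumes
# (multi-page TIFF + plain-text sidecar) and pipeline configuration.

#' Write a profile image to PNG or TIFF
#'
#' @param image a \code{\link{profile_image}}.
#' @param path output path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
write_profile_image <- function(image, path) {
  stopifnot(inherits(image, "profile_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: .", ext, " (use .png or .tif)")
  }
  invisible(path)
}

#' Read a profile image from PNG or TIFF
#'
#' JPEG composites must be converted to PNG or TIFF first (no JPEG reader
#' is available to this package).
#'
#' @param path image file (.png/.tif/.tiff).
#' @param pixel_size physical pixel size in cm (default 56 um).
#' @param aquarium_id,face_id labels for the returned object.
#' @return A \code{\link{profile_image}}.
#' @export
read_profile_image <- function(path, pixel_size = 0.0056,
                               aquarium_id = NULL, face_id = "composite") {
  ext <- tolower(tools::file_ext(path))
  if (is.null(aquarium_id)) {
    aquarium_id <- tools::file_path_sans_ext(basename(path))
  }
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    stop("JPEG input is not supported in this build; convert to PNG or TIFF")
  } else {
    stop("unsupported image format: .", ext)
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  profile_image(px, pixel_size, aquarium_id, face_id)
}

#' Write a voxel volume as a multi-page TIFF with a sidecar metadata file
#'
#' One grayscale page per z slice; a plain \code{key: value} sidecar
#' (\code{<path>.meta}) records the voxel size, up axis, dimensions and
#' aquarium id so the volume round-trips losslessly.
#'
#' @param volume a \code{\link{voxel_volume}}.
#' @param path output path ending in .tif/.tiff.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$voxels)
  pages <- lapply(seq_len(d[3]), function(k) {
    matrix(volume$voxels[, , k] / 255, d[1], d[2])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- c(paste("voxel_size_cm:", format(volume$voxel_size, digits = 12)),
            paste("up_axis:", volume$up_axis),
            paste("aquarium_id:", volume$aquarium_id),
            paste("dims:", paste(d, collapse = " ")))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a voxel volume written by \code{\link{write_volume}}
#'
#' @param path multi-page TIFF path; the sidecar \code{<path>.meta} must
#'   exist.
#' @return A \code{\link{voxel_volume}}.
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
  kv <- read_key_values(meta_path)
  d1 <- dim(pages[[1]])
  vox <- array(0, c(d1[1], d1[2], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- round(pages[[k]] * 255)
  voxel_volume(vox, as.numeric(kv[["voxel_size_cm"]]), kv[["up_axis"]],
               kv[["aquarium_id"]])
}

read_key_values <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  setNames(as.list(vals), trimws(keys))
}

#' Pipeline configuration
#'
#' Validated bundle of the settings a full synthetic-through-inference run
#' needs.  Serialises losslessly through \code{\link{write_config}} /
#' \code{\link{read_config}} (plain-text YAML).  The configuration hash
#' stamped on every output table is computed from the serialised content,
#' so outputs from different configurations are distinguishable.
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param output_dir directory for stage outputs.
#' @param pixel_size profile-image pixel size (cm).
#' @param voxel_size CT voxel size (cm).
#' @param image_px c(height, width) of generated profile images.
#' @param volume_dims c(nx, ny, nz) of generated CT volumes.
#' @param n_particles tracer particles per profile image.
#' @param noise_sd CT gray noise sd.
#' @param replicates replicates per treatment x shape cell.
#' @param alpha retention level for backward selection.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(seed = 1L, output_dir = tempfile("bioturb_run_"),
                            pixel_size = 0.025, voxel_size = 0.07,
                            image_px = c(440L, 240L),
                            volume_dims = c(72L, 72L, 160L),
                            n_particles = 3000L, noise_sd = 8,
                            replicates = 5L, alpha = 0.05) {
  stopifnot(pixel_size > 0, voxel_size > 0, all(image_px >= 8),
            all(volume_dims >= 8), n_particles >= 1, noise_sd >= 0,
            replicates >= 2, alpha > 0, alpha < 1)
  cfg <- list(seed = as.integer(seed), output_dir = output_dir,
              pixel_size = pixel_size, voxel_size = voxel_size,
              image_px = as.integer(image_px),
              volume_dims = as.integer(volume_dims),
              n_particles = as.integer(n_particles), noise_sd = noise_sd,
              replicates = as.integer(replicates), alpha = alpha)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  cfg$hash <- NULL; cfg$output_dir <- NULL
  fnv1a32(yaml::as.yaml(cfg))
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = raw$seed, output_dir = raw$output_dir,
                         pixel_size = raw$pixel_size,
                         voxel_size = raw$voxel_size,
                         image_px = raw$image_px,
                         volume_dims = raw$volume_dims,
                         n_particles = raw$n_particles,
                         noise_sd = raw$noise_sd,
                         replicates = raw$replicates, alpha = raw$alpha)
  cfg
}
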