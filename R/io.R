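## Persistence: binary masks as 1-bit-content PNG with a JSON sidecar,
## synthetic slides as multi-page TIFF pyramids with a metadata sidecar,
## per-slide tile archives, cohort manifests (CSV) and provenance records
## (JSON).

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a tissue mask (PNG + JSON sidecar)
#'
#' The raster goes to a binary PNG; slide id, resolution, provenance method
#' and the failure flag go to `<path>.json`. A mask round-trips
#' bit-identically. A sidecar missing a required field raises an integrity
#' error naming the field.
#'
#' @param mask a [tissue_mask()].
#' @param path PNG file path.
#' @param params optional parameter list stored in the sidecar for
#'   provenance.
#' @return `read_mask` returns the `tissue_mask`.
#' @export
write_mask <- function(mask, path, params = NULL) {
  stopifnot(inherits(mask, "tissue_mask"))
  png::writePNG(mask$raster * 1, path)
  meta <- list(slide_id = mask$slide_id, mpp = mask$mpp, method = mask$method,
               failure = mask$failure,
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(params)) meta$params <- params
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) td_stop("mask_integrity", "missing sidecar %s", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (field in c("slide_id", "mpp", "method")) {
    if (is.null(meta[[field]]))
      td_stop("mask_integrity", "sidecar missing required field '%s'", field)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  tissue_mask(img > 0.5, as.numeric(meta$mpp), meta$method, meta$slide_id,
              failure = isTRUE(meta$failure) || !any(img > 0.5))
}

#' Write / read a slide pyramid (multi-page TIFF + JSON sidecar)
#'
#' One TIFF page per pyramid level, finest first; per-level resolutions and
#' the slide/patient ids go to `<path>.json`.
#'
#' @param slide a `slide_pyramid`.
#' @param path TIFF file path.
#' @return `read_slide_tiff` returns the `slide_pyramid`.
#' @export
write_slide_tiff <- function(slide, path) {
  stopifnot(inherits(slide, "slide_pyramid"))
  tiff::writeTIFF(lapply(slide$levels, `[[`, "raster"), path,
                  bits.per.sample = 8L, compression = "LZW")
  jsonlite::write_json(list(slide_id = slide$slide_id,
                            patient_id = slide$patient_id,
                            mpp = vapply(slide$levels, `[[`, numeric(1), "mpp")),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_slide_tiff
#' @export
read_slide_tiff <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) td_stop("slide_integrity", "missing sidecar %s", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  structure(list(slide_id = meta$slide_id, patient_id = meta$patient_id,
                 levels = lapply(seq_along(pages), function(i)
                   list(mpp = meta$mpp[i], raster = pages[[i]]))),
            class = "slide_pyramid")
}

#' Archive / load a slide's tiles
#'
#' One container file per slide: a coordinate index, the tiling
#' configuration and the (losslessly stored) tile rasters. Duplicate
#' coordinates in the index are refused. The container is R serialization
#' of a documented `list(slide_id, index, config, rasters)` structure.
#'
#' @param tileset a `tile_set`.
#' @param path archive file path.
#' @param slide optional `slide_pyramid`; when given, tile rasters are
#'   extracted and stored.
#' @param rasters optional precomputed raster list aligned with the index.
#' @return `load_tiles` returns the archive structure.
#' @export
archive_tiles <- function(tileset, path, slide = NULL, rasters = NULL) {
  stopifnot(inherits(tileset, "tile_set"))
  key <- paste(tileset$tiles$x, tileset$tiles$y)
  if (anyDuplicated(key))
    td_stop("duplicate_coordinates", "duplicate tile coordinates in index")
  if (is.null(rasters) && !is.null(slide)) {
    rasters <- lapply(seq_len(nrow(tileset$tiles)), function(i)
      extract_tile(slide, c(tileset$tiles$x[i], tileset$tiles$y[i]),
                   tileset$config))
  }
  saveRDS(list(slide_id = tileset$slide_id, index = tileset$tiles,
               config = tileset$config, rasters = rasters), path)
  invisible(path)
}

#' @rdname archive_tiles
#' @export
load_tiles <- function(path) {
  arc <- readRDS(path)
  key <- paste(arc$index$x, arc$index$y)
  if (anyDuplicated(key))
    td_stop("duplicate_coordinates", "duplicate tile coordinates in archive")
  arc
}

#' Write / read a cohort manifest (CSV)
#'
#' One row per slide: identifiers, reference grade, rendering profile,
#' artifact flags, role in the study and the slide seed.
#'
#' @param manifest data.frame as built by [standard_cohort_manifest()].
#' @param path CSV path.
#' @return `read_cohort_manifest` returns the data.frame.
#' @export
write_cohort_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_manifest
#' @export
read_cohort_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(man$artifacts)) man$artifacts[is.na(man$artifacts)] <- ""
  man
}

#' Write a machine-readable provenance record
#'
#' Records the package version, R version, timestamp and the configuration
#' and seeds of a run, sufficient to re-execute it bit-identically.
#'
#' @param path JSON path.
#' @param config named list of run configuration.
#' @param seed master seed of the run.
#' @export
write_provenance <- function(path, config = list(), seed = NA) {
  jsonlite::write_json(list(
    package = "tissuedetect",
    version = as.character(utils::packageVersion("tissuedetect")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, config = config
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
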