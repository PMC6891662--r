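# Raster and table I/O, configuration, run manifests.

#' Assay configuration
#'
#' Central container for the tunable parameters of the pipeline. All
#' thresholds are on the `[0, 1]` intensity scale and sit between the
#' rendering intensity bands (see the package help page); they apply
#' equally to real grayscale micrographs after rescaling to `[0, 1]`.
#'
#' @param pixel_size Calibration in um per pixel (default 1; the coverage
#'   fraction, thickness ratio, grades and index are scale-invariant, so
#'   calibration only changes reported absolute areas).
#' @param bead_threshold Intensity above which a pixel is bead (default
#'   0.7).
#' @param capsule_low Lower edge of the capsule intensity band; the capsule
#'   band is `(capsule_low, bead_threshold]` (default 0.25).
#' @param cell_threshold Cell-body mask threshold (default 0.3).
#' @param nucleus_threshold Nuclei-seed mask threshold (default 0.5).
#' @param spot_threshold Bacteria-spot mask threshold (default 0.6).
#' @param circularity_max Circularity below which a cell is called spread
#'   (default 0.6).
#' @param defects_min Convexity-defect (arm) count at or above which a cell
#'   is called spread (default 3).
#' @param temperature Absolute temperature for energy/Ki conversion, K
#'   (default 298.15).
#' @param seed Default seed recorded in run manifests.
#' @return An object of class `assay_config` (a validated named list).
#' @export
assay_config <- function(pixel_size = 1, bead_threshold = 0.7,
                         capsule_low = 0.25, cell_threshold = 0.3,
                         nucleus_threshold = 0.5, spot_threshold = 0.6,
                         circularity_max = 0.6, defects_min = 3,
                         temperature = 298.15, seed = 1L) {
  cfg <- list(pixel_size = pixel_size, bead_threshold = bead_threshold,
              capsule_low = capsule_low, cell_threshold = cell_threshold,
              nucleus_threshold = nucleus_threshold,
              spot_threshold = spot_threshold,
              circularity_max = circularity_max,
              defects_min = as.integer(defects_min),
              temperature = temperature, seed = as.integer(seed))
  thr <- c("bead_threshold", "capsule_low", "cell_threshold",
           "nucleus_threshold", "spot_threshold", "circularity_max")
  for (nm in thr)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(nm, " must lie in [0, 1]")
  if (cfg$capsule_low >= cfg$bead_threshold)
    stop("capsule_low must be below bead_threshold")
  if (cfg$pixel_size <= 0) stop("pixel_size must be positive")
  if (cfg$temperature <= 0) stop("temperature must be positive")
  if (cfg$defects_min < 1) stop("defects_min must be >= 1")
  structure(cfg, class = "assay_config")
}

#' Write / read an assay configuration
#'
#' Configurations round-trip losslessly through a flat YAML document.
#'
#' @param config An [assay_config()].
#' @param path File path.
#' @return `read_config` returns a validated [assay_config()];
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "assay_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(assay_config, yaml::read_yaml(path))
}

#' Read a grayscale raster image
#'
#' Reads single- or multi-page TIFF or PNG, 8- or 16-bit grayscale, as
#' numeric matrices scaled to `[0, 1]`. Colour images and other formats are
#' rejected with an error naming the offender.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return A list of numeric matrices, one per page, in page order, with
#'   attributes `n_pages` and (when the file records it) `bits_per_sample`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pages <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, all = TRUE, info = TRUE),
    png = list(png::readPNG(path, info = TRUE)),
    stop("unsupported image format '.", ext, "' (", basename(path),
         "): only grayscale TIFF or PNG are read")
  )
  bits <- attr(pages[[1]], "bits.per.sample")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      if (dim(p)[3] == 1) p <- p[, , 1] else
        stop("colour image not supported (", basename(path),
             "): grayscale only")
    }
    p <- unclass(as.matrix(p))
    attributes(p) <- list(dim = dim(p))
    p
  })
  attr(pages, "n_pages") <- length(pages)
  if (!is.null(bits)) attr(pages, "bits_per_sample") <- bits
  pages
}

#' Write a grayscale raster image
#'
#' @param image Numeric matrix with values in `[0, 1]`, or a list of such
#'   matrices (written as a multi-page TIFF; PNG accepts one page only).
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param bits Bit depth for TIFF output (8 or 16; default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = bits)
  } else if (ext == "png") {
    if (is.list(image)) {
      if (length(image) > 1) stop("PNG supports a single page")
      image <- image[[1]]
    }
    png::writePNG(image, path)
  } else {
    stop("unsupported image format '.", ext, "'")
  }
  invisible(path)
}

.schemas <- list(
  grades = list(cols = c("bead_id", "area_grade", "thickness_grade"),
                numeric = c("area_grade", "thickness_grade")),
  cells = list(cols = c("cell_id", "type", "circularity", "defects",
                        "spread", "engulfed_count"),
               numeric = c("circularity", "defects", "engulfed_count")),
  factin = list(cols = c("group", "intensity"), numeric = "intensity"),
  poses = list(cols = c("ligand", "conformer", "binding_energy_kcal_mol"),
               numeric = c("conformer", "binding_energy_kcal_mol"))
)

#' Read and validate a delimited assay table
#'
#' Reads a comma-separated (`.csv`) or tab-separated (`.tsv`) table with a
#' header row and validates it against one of the named schemas:
#' `"grades"` (`bead_id, area_grade, thickness_grade`; grades must be
#' integers in 0-4 / 0-6), `"cells"` (per-cell morphology records),
#' `"factin"` (`group, intensity`) or `"poses"`
#' (`ligand, conformer, binding_energy_kcal_mol`, energies finite).
#'
#' @param path File path.
#' @param schema One of `"grades"`, `"cells"`, `"factin"`, `"poses"`.
#' @return The validated data frame.
#' @export
read_assay_table <- function(path, schema = c("grades", "cells",
                                              "factin", "poses")) {
  schema <- match.arg(schema)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  sc <- .schemas[[schema]]
  missing <- setdiff(sc$cols, names(tab))
  if (length(missing) > 0)
    stop("schema '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in sc$numeric) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad) > 0)
      stop("schema '", schema, "': non-numeric values in '", col,
           "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    tab[[col]] <- v
  }
  if (schema == "grades") {
    if (any(tab$area_grade != round(tab$area_grade)) ||
        any(tab$area_grade < 0 | tab$area_grade > 4))
      stop("area_grade values must be integers in 0-4")
    if (any(tab$thickness_grade != round(tab$thickness_grade)) ||
        any(tab$thickness_grade < 0 | tab$thickness_grade > 6))
      stop("thickness_grade values must be integers in 0-6")
  }
  if (schema == "poses" && any(!is.finite(tab$binding_energy_kcal_mol)))
    stop("binding energies must be finite")
  tab
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed, package version and input-file hashes
#' alongside an analysis output, sufficient to reproduce deterministic
#' stages byte-identically.
#'
#' @param path Output JSON path.
#' @param config An [assay_config()].
#' @param inputs Character vector of input file paths to hash (optional).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = assay_config(),
                               inputs = character(0)) {
  hashes <- vapply(inputs, function(f)
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_,
    character(1))
  manifest <- list(
    package = "hemoquant",
    version = as.character(utils::packageVersion("hemoquant")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    inputs = if (length(inputs) > 0)
      data.frame(path = inputs, md5 = unname(hashes)) else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
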