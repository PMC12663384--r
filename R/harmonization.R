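# Legend harmonization: map each product's native land-cover classes into
# the common scheme so transitions are comparable across datasets. The
# built-in tables are shipped as editable CSV files under
# inst/extdata/harmonization/ because native code lists differ by product
# version; each file names the product legend it was built against.

supported_datasets <- function() {
  c("globeland30", "glcluc", "glc_fcs30d", "synthetic")
}

#' Built-in legend harmonization table for a land-cover product
#'
#' Returns the mapping from a product's native class codes to the
#' harmonized scheme of [harmonized_classes()]. The mappings encode the
#' study's class correspondence rules:
#' * GlobeLand30: cultivated land includes cultivated grassland (pastures)
#'   and excludes tree crops; the entire wetland class maps to non-forested
#'   wetland and is never counted as forest; tundra maps to `OTHER`.
#' * GLCLUC: classes split by tree height — tree cover of at least 5 m
#'   (including forested wetlands) is forest; short vegetation and trees
#'   under 5 m map to grassland & shrubland (terra firma stratum) or
#'   non-forested wetland (wetland stratum, together with seasonally open
#'   surface water).
#' * GLC_FCS30D: cropland includes tree crops; swamp and mangrove (woody
#'   wetlands) map to forest, the remaining wetland subclasses (marsh, salt
#'   marsh, flooded flat, tidal flat, saline) to non-forested wetland;
#'   tundra/lichen-moss maps to `OTHER`.
#' * synthetic: identity mapping over the harmonized codes.
#'
#' Native codes not assigned to any of the four analysis classes (water,
#' ice, bare, impervious, tundra, sparse vegetation) map to `OTHER`.
#'
#' @param dataset_id One of `"globeland30"`, `"glcluc"`, `"glc_fcs30d"`,
#'   `"synthetic"`.
#' @return A `harmonization_table`: data.frame with columns `dataset_id`,
#'   `native_code`, `native_label`, `harmonized_code`, `note`.
#' @export
#' @examples
#' tab <- builtin_table("glc_fcs30d")
#' subset(tab, native_label %in% c("Swamp", "Mangrove"))
builtin_table <- function(dataset_id) {
  if (!dataset_id %in% supported_datasets())
    stop(sprintf("unknown dataset_id '%s'; supported: %s", dataset_id,
                 paste(supported_datasets(), collapse = ", ")))
  path <- system.file("extdata", "harmonization",
                      paste0(dataset_id, ".csv"), package = "landconvert")
  read_harmonization_table(path)
}

#' Read a harmonization table from CSV
#'
#' @param path CSV file with columns `dataset_id`, `native_code`,
#'   `native_label`, `harmonized_code`, `note`.
#' @return A `harmonization_table` data.frame.
#' @export
read_harmonization_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(native_code = "integer"))
  required <- c("dataset_id", "native_code", "native_label",
                "harmonized_code", "note")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("harmonization table missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(tab$harmonized_code, names(harmonized_classes()))
  if (length(bad))
    stop("unknown harmonized code(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$native_code))
    stop("native codes must map to exactly one harmonized class")
  class(tab) <- c("harmonization_table", "data.frame")
  tab
}

#' Harmonize an epoch raster with a legend table
#'
#' Remaps every native class code to its harmonized code. Geometry is
#' unchanged, nodata cells stay nodata, and the non-nodata cell count is
#' preserved, so total land area is conserved and each harmonized class
#' area equals the summed areas of its native source classes.
#'
#' @param raster An [epoch_raster()] holding native class codes.
#' @param table A `harmonization_table` for the raster's dataset (see
#'   [builtin_table()]).
#' @return An [epoch_raster()] of harmonized codes (`harmonized = TRUE`).
#' @export
harmonize <- function(raster, table) {
  stopifnot(inherits(raster, "epoch_raster"),
            inherits(table, "harmonization_table"))
  if (!raster$dataset_id %in% table$dataset_id)
    stop(sprintf("table is for dataset '%s' but raster is '%s'",
                 table$dataset_id[1], raster$dataset_id))
  v <- raster$values
  present <- sort(unique(v[!is.na(v)]))
  unmapped <- setdiff(present, table$native_code)
  if (length(unmapped)) {
    counts <- vapply(unmapped, function(code) sum(v == code, na.rm = TRUE),
                     integer(1))
    stop("unmapped native code(s): ",
         paste(sprintf("%d (%d cells)", unmapped, counts), collapse = ", "))
  }
  lut <- rep(NA_integer_, max(table$native_code) + 1L)
  lut[table$native_code + 1L] <- harmonized_classes()[table$harmonized_code]
  out <- raster
  out$values <- matrix(lut[v + 1L], nrow(v), ncol(v))
  out$harmonized <- TRUE
  out
}
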