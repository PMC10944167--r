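# aggregation of level-4 land-cover codes to the summary classes used for
# gap/trend statistics, keyed by the conventional five-letter abbreviations
LC_AGG <- local({
  map <- c(
    "10" = "CRPRF", "11" = "CRPRF", "12" = "CRPRF",
    "20" = "CRPIF",
    "30" = "MCRNV", "40" = "MCRNV",
    "50" = "TREBE",
    "60" = "TREBD", "61" = "TREBD", "62" = "TREBD",
    "70" = "TRENE", "71" = "TRENE", "72" = "TRENE",
    "80" = "TREND", "81" = "TREND", "82" = "TREND",
    "90" = "TREMX",
    "100" = "MTSHH", "110" = "MTSHH",
    "120" = "SHRUB", "121" = "SHRUB", "122" = "SHRUB",
    "130" = "GRASS",
    "140" = "LICMO",
    "150" = "SPARV", "151" = "SPARV", "152" = "SPARV",
    "160" = "TREFL", "170" = "TREFL",
    "180" = "SHHFL",
    "190" = "URBAN",
    "200" = "BAREA", "201" = "BAREA", "202" = "BAREA",
    "210" = "WATER",
    "220" = "SNOIC"
  )
  map
})

LC_AGG_LABELS <- c(
  CRPRF = "Cropland rainfed",
  CRPIF = "Cropland, irrigated or post-flooding",
  MCRNV = "Mosaic cropland-natural vegetation",
  TREBE = "Tree cover broadleaved evergreen",
  TREBD = "Tree cover broadleaved deciduous",
  TRENE = "Tree cover needleleaved evergreen",
  TREND = "Tree cover needleleaved deciduous",
  TREMX = "Tree cover mixed leaf type",
  MTSHH = "Mosaic tree and shrub-herbaceous cover",
  SHRUB = "Shrubland",
  GRASS = "Grassland",
  LICMO = "Lichens and mosses",
  SPARV = "Sparse vegetation",
  TREFL = "Tree cover flooded",
  SHHFL = "Shrub or herbaceous cover flooded",
  URBAN = "Urban areas",
  BAREA = "Bare areas",
  WATER = "Water bodies",
  SNOIC = "Permanent snow and ice"
)

#' Aggregate level-4 land-cover codes
#'
#' @param codes Integer vector or matrix of level-4 codes.
#' @return Character vector/matrix of aggregated class abbreviations (e.g.
#'   `"CRPRF"` for rainfed cropland, `"URBAN"` for urban areas); see
#'   [lc_class_labels()] for the full names.
#' @export
lc_aggregate <- function(codes) {
  key <- as.character(codes)
  unknown <- setdiff(unique(key[!is.na(codes)]), names(LC_AGG))
  if (length(unknown) > 0)
    stop("unknown land-cover code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- unname(LC_AGG[key])
  if (is.matrix(codes)) out <- matrix(out, nrow(codes), ncol(codes))
  out
}

#' Full names of the aggregated land-cover classes
#' @return Named character vector, abbreviation -> descriptive label.
#' @export
lc_class_labels <- function() LC_AGG_LABELS

#' Land-cover change classes between two epochs
#'
#' Aggregates both maps with [lc_aggregate()] and labels each pixel with the
#' pair `"A-B"` of first- and last-epoch classes, or simply `"A"` where the
#' aggregated class is stable.
#'
#' @param lc_first,lc_last Integer matrices of level-4 codes on the same
#'   grid.
#' @return Character matrix of change-class labels.
#' @export
lc_change_classes <- function(lc_first, lc_last) {
  if (!all(dim(lc_first) == dim(lc_last)))
    stop("land-cover maps must share the grid", call. = FALSE)
  a <- lc_aggregate(lc_first)
  b <- lc_aggregate(lc_last)
  out <- ifelse(a == b, a, paste0(a, "-", b))
  matrix(out, nrow(lc_first), ncol(lc_first))
}

# code sets used by the sampling stratification: "forest/wetland" and
# "grassland/cropland" groups for the land-cover-change categories
LC_FOREST_WETLAND <- c(CCI_GROUPS$forest, 180L)
LC_GRASS_CROP <- c(CCI_GROUPS$grassland, CCI_GROUPS$cropland)
LC_WATER_ICE <- c(210L, 220L)
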