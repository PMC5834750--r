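#' Load the packaged 90-region parcellation table
#'
#' Returns the automated-anatomical-labelling style table of 90 cortical and
#' subcortical regions (45 per hemisphere) shipped with the package. Each
#' region carries a 1-based index, a name whose `_L`/`_R` suffix encodes the
#' hemisphere, and one of six lobe groups (frontal, temporal, parietal,
#' medial temporal, occipital, subcortical) used for block structure in the
#' synthetic cohort and for connection-type reporting.
#'
#' @param path Optional path to a user-supplied region table with columns
#'   `index`, `name`, `hemisphere`, `lobe`. Defaults to the packaged table.
#' @return A data.frame with columns `index`, `name`, `hemisphere`, `lobe`.
#' @export
#' @examples
#' head(aal_regions())
aal_regions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal90_regions.csv", package = "sivdnet")
  }
  regions <- read.csv(path, stringsAsFactors = FALSE)
  validate_region_table(regions)
  regions
}

validate_region_table <- function(regions) {
  need <- c("index", "name", "hemisphere", "lobe")
  if (!all(need %in% names(regions))) {
    stop_sivd("region table must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(regions$index) || anyDuplicated(regions$name)) {
    stop_sivd("region table indices and names must be unique")
  }
  if (!all(regions$hemisphere %in% c("L", "R"))) {
    stop_sivd("hemisphere labels must be 'L' or 'R'")
  }
  if (any(is.na(regions$lobe)) || any(!nzchar(regions$lobe))) {
    stop_sivd("every region needs a lobe label")
  }
  invisible(regions)
}

#' Classify a connection by the hemispheres of its endpoints
#'
#' Edges of the significant-difference network are reported as left
#' intrahemispheric, right intrahemispheric, or interhemispheric, based on
#' the hemisphere labels of the two regions.
#'
#' @param region_a,region_b Region names (character vectors of equal length).
#' @param regions Region table as from [aal_regions()].
#' @return Character vector with values `"left_intra"`, `"right_intra"`,
#'   or `"inter"`.
#' @export
#' @examples
#' classify_connection("Precentral_L", "Precuneus_L", aal_regions())
classify_connection <- function(region_a, region_b, regions = aal_regions()) {
  hemi <- setNames(regions$hemisphere, regions$name)
  unknown <- setdiff(c(region_a, region_b), names(hemi))
  if (length(unknown) > 0) {
    stop_sivd("unknown region(s): ", paste(unique(unknown), collapse = ", "))
  }
  ha <- hemi[region_a]
  hb <- hemi[region_b]
  out <- ifelse(ha != hb, "inter",
                ifelse(ha == "L", "left_intra", "right_intra"))
  unname(out)
}
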