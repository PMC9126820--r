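#' Desikan-Killiany cortical regions
#'
#' The 34 cortical regions of the Desikan-Killiany parcellation, one set per
#' hemisphere, in the fixed canonical order used throughout the package.
#' Left index i and right index i always denote homotopic regions, so
#' hemispheric differences can be formed by index alignment.
#'
#' @return Character vector of 34 region base names.
#' @export
#' @examples
#' dk_regions()[1:5]
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' Canonical thickness column names
#'
#' Region base names suffixed `_L` / `_R`; left hemisphere first.
#'
#' @param hemisphere `"both"` (default), `"L"` or `"R"`.
#' @return Character vector of column names (68 for `"both"`).
#' @export
region_columns <- function(hemisphere = c("both", "L", "R")) {
  hemisphere <- match.arg(hemisphere)
  switch(hemisphere,
    L = paste0(dk_regions(), "_L"),
    R = paste0(dk_regions(), "_R"),
    both = c(paste0(dk_regions(), "_L"), paste0(dk_regions(), "_R"))
  )
}

# number of nodes per hemispheric network and distinct node pairs
N_REGIONS <- 34L
N_PAIRS <- 561L  # choose(34, 2)
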