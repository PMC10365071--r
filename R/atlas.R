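#' Left-hemisphere Desikan-Killiany cortical parcellation
#'
#' The 34 left-hemisphere cortical regions of the Desikan-Killiany atlas,
#' in the conventional FreeSurfer `aparc` order. These are the regions over
#' which per-ROI neurodegeneration biomarkers are computed, so a
#' biomarker vector built in atlas mode always has exactly 34 entries.
#'
#' @return character vector of 34 ROI names
#' @examples
#' length(dk_lh_atlas()) # 34
#' @export
dk_lh_atlas <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
    "cuneus", "entorhinal", "fusiform", "inferiorparietal",
    "inferiortemporal", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula")
}
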