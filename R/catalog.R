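#' Hindpaw bone catalog
#'
#' Enumerates the bones of the mouse hindpaw as segmented by this package:
#' 7 tarsal entities in the unfused variant (calcaneus, talus, tibiale,
#' cuboid, medial cuneiform, the consistently fused navicular + lateral
#' cuneiform "NAVLAT", and a separate intermediate cuneiform) or 6 in the
#' fused variant (intermediate cuneiform fused into "NAVLATINT"), plus 5
#' metatarsals, 5 proximal phalanges, 4 distal phalanges (digits 2-5), and
#' 10 sesamoids. Digit-associated bones are numbered in increasing order
#' from medial to lateral.
#'
#' Because the cuneiform fusion is sporadic (it can differ between the two
#' limbs of one animal), the navicular / lateral cuneiform / intermediate
#' cuneiform volumes are always *reported* combined as the single analysis
#' unit "NAVLATINT" (`report_unit` column), so every limb contributes 30
#' analysis units regardless of variant.
#'
#' @param fusion_variant `"unfused"` (31 bones) or `"fused"` (30 bones).
#' @return data.frame with columns `label` (1..30/31, the atlas label),
#'   `bone` (shorthand code), `compartment`, `report_unit`, `digit`
#'   (NA for tarsals).
#' @examples
#' nrow(bone_catalog("unfused"))  # 31
#' nrow(bone_catalog("fused"))    # 30
#' length(unique(bone_catalog("unfused")$report_unit))  # 30 analysis units
#' @export
bone_catalog <- function(fusion_variant = c("unfused", "fused")) {
  fusion_variant <- match.arg(fusion_variant)
  tars <- if (fusion_variant == "unfused") {
    data.frame(bone = c("Calc", "Tal", "Tib", "Cub", "Med", "NAVLAT", "IntCun"),
               report_unit = c("Calc", "Tal", "Tib", "Cub", "Med",
                               "NAVLATINT", "NAVLATINT"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(bone = c("Calc", "Tal", "Tib", "Cub", "Med", "NAVLATINT"),
               report_unit = c("Calc", "Tal", "Tib", "Cub", "Med",
                               "NAVLATINT"),
               stringsAsFactors = FALSE)
  }
  tars$compartment <- "tarsals"
  tars$digit <- NA_integer_
  dig <- function(prefix, digits, compartment) {
    data.frame(bone = paste0(prefix, digits),
               report_unit = paste0(prefix, digits),
               compartment = compartment, digit = digits,
               stringsAsFactors = FALSE)
  }
  ses <- data.frame(bone = paste0("S", 1:10),
                    report_unit = paste0("S", 1:10),
                    compartment = "sesamoids",
                    digit = rep(1:5, each = 2),
                    stringsAsFactors = FALSE)
  cat <- rbind(tars,
               dig("Met", 1:5, "metatarsals"),
               dig("PP", 1:5, "proximal_phalanges"),
               dig("DP", 2:5, "distal_phalanges"),
               ses)
  cat <- cbind(label = seq_len(nrow(cat)), cat)
  rownames(cat) <- NULL
  cat
}

#' Compartment names in reporting order
#' @return character vector of the five hindpaw compartments.
#' @export
compartment_names <- function() {
  c("tarsals", "metatarsals", "proximal_phalanges", "distal_phalanges",
    "sesamoids")
}
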