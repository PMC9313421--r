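#' Build a grey-scale feature record for EU TIRADS categorisation
#'
#' @param composition `"pure_cyst"`, `"spongiform"`, `"solid"` or `"mixed"`.
#' @param echogenicity `"hyperechoic"`, `"isoechoic"`, `"mildly_hypoechoic"`,
#'   `"markedly_hypoechoic"` or `"anechoic"`. A pure cyst must be anechoic.
#' @param margins `"smooth"` or `"irregular"`.
#' @param taller_than_wide,microcalcifications,shape_oval logicals.
#' @return A one-row data frame of class `grey_scale_features`; rows of such
#'   frames (or any data frame with these columns) feed
#'   [eu_tirads_category()].
#' @export
grey_scale_features <- function(composition = "solid",
                                echogenicity = "isoechoic",
                                margins = "smooth",
                                taller_than_wide = FALSE,
                                microcalcifications = FALSE,
                                shape_oval = TRUE) {
  composition <- match.arg(composition,
    c("pure_cyst", "spongiform", "solid", "mixed"))
  echogenicity <- match.arg(echogenicity,
    c("hyperechoic", "isoechoic", "mildly_hypoechoic", "markedly_hypoechoic",
      "anechoic"))
  margins <- match.arg(margins, c("smooth", "irregular"))
  stop_if_not_flag(taller_than_wide, "taller_than_wide")
  stop_if_not_flag(microcalcifications, "microcalcifications")
  stop_if_not_flag(shape_oval, "shape_oval")
  if (composition == "pure_cyst" && echogenicity != "anechoic")
    stop("a pure cyst must be anechoic")
  structure(
    data.frame(composition = composition, echogenicity = echogenicity,
               margins = margins, taller_than_wide = taller_than_wide,
               microcalcifications = microcalcifications,
               shape_oval = shape_oval, stringsAsFactors = FALSE),
    class = c("grey_scale_features", "data.frame")
  )
}

#' EU TIRADS malignancy-risk category from grey-scale features
#'
#' Rule-based categorisation: category 5 (high risk) if any high-risk feature
#' is present — irregular margins, marked hypoechogenicity in a solid or
#' mixed nodule, taller-than-wide shape, or microcalcifications; otherwise
#' category 4 (intermediate) for a mildly hypoechoic nodule; category 2
#' (benign) for a pure cyst or a spongiform nodule; category 3 (low risk)
#' otherwise. Mixed cystic-solid nodules are categorised by their solid
#' component's features, the standard convention. Category 1 (no nodule) is
#' unreachable because inputs are nodules.
#'
#' @param features a data frame with the columns of [grey_scale_features()];
#'   one nodule per row.
#' @return Integer vector of categories in `{2, 3, 4, 5}`.
#' @examples
#' eu_tirads_category(grey_scale_features("solid", "isoechoic"))       # 3
#' eu_tirads_category(grey_scale_features(microcalcifications = TRUE)) # 5
#' @export
eu_tirads_category <- function(features) {
  need <- c("composition", "echogenicity", "margins", "taller_than_wide",
            "microcalcifications")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  high_risk <- features$margins == "irregular" |
    (features$echogenicity == "markedly_hypoechoic" &
       features$composition %in% c("solid", "mixed")) |
    features$taller_than_wide | features$microcalcifications
  cat <- ifelse(high_risk, 5L,
    ifelse(features$echogenicity == "mildly_hypoechoic", 4L,
      ifelse(features$composition %in% c("pure_cyst", "spongiform"), 2L, 3L)))
  as.integer(cat)
}

#' Classify a TIRADS category at a malignancy cut-off
#'
#' The study uses category >= 5 as the cut-off for the sole grey-scale
#' assessment and category >= 4 for the combined assessment with Doppler
#' vascularity.
#'
#' @param category integer vector over `{2, 3, 4, 5}`.
#' @param cutoff `"sole_ge5"` or `"combined_ge4"`.
#' @return Logical vector: `TRUE` = test-positive for malignancy.
#' @export
classify_tirads <- function(category, cutoff = c("sole_ge5", "combined_ge4")) {
  cutoff <- match.arg(cutoff)
  if (any(!category %in% 2:5)) stop("TIRADS category must be in {2, 3, 4, 5}")
  category >= if (cutoff == "sole_ge5") 5L else 4L
}

#' Combine TIRADS and vascularity assessments
#'
#' A nodule is predicted malignant iff it is TIRADS-positive at the chosen
#' cut-off AND the vascularity assessment is suspicious for malignancy (the
#' conjunction rule). The AND can only remove false positives, so combined
#' specificity is at least each component's and combined sensitivity at most
#' each component's.
#'
#' @param tirads_positive logical vector from [classify_tirads()].
#' @param vascular_suspicion character vector over
#'   `c("benign_suspicious", "malignant_suspicious")`; `"non_vascular"`
#'   records must be excluded upstream and are an error here.
#' @return Character vector of predictions, `"malignant"` or `"benign"`.
#' @export
combine_assessments <- function(tirads_positive, vascular_suspicion) {
  if (any(vascular_suspicion == "non_vascular"))
    stop("non_vascular records must be excluded before combination")
  bad <- !vascular_suspicion %in% c("benign_suspicious", "malignant_suspicious")
  if (any(bad)) stop("invalid vascular suspicion label(s)")
  ifelse(tirads_positive & vascular_suspicion == "malignant_suspicious",
         "malignant", "benign")
}
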