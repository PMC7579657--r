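# Fixed universe of analysis items: 4 emotion groups + 43 factor groups.

EMOTION_GROUPS <- c("HG", "FAO", "SDLG", "AD")

EMOTION_LABELS <- c(
  HG   = "Hope/Gratitude",
  FAO  = "Fear/Anxiety/Overwhelmed",
  SDLG = "Sadness/Depression/Loneliness/Guilt",
  AD   = "Anger/Denial"
)

# Nine ontology emotion classes -> four analysis groups.
EMOTION_CLASS_MAP <- c(
  hope = "HG", gratitude = "HG",
  anxiety = "FAO", overwhelmed = "FAO",
  depression = "SDLG", loneliness = "SDLG", guilt = "SDLG",
  anger = "AD", denial = "AD"
)

FACTOR_CATEGORIES <- list(
  gender = c("male", "female"),
  age = c("age_under_10", "age_10s", "age_20s", "age_30s", "age_40s",
          "age_50s", "age_60s", "age_70s", "age_over_80"),
  cancer_type = c("breast_cancer", "colon_cancer", "gastric_cancer",
                  "leukemia", "lung_cancer", "cervical_cancer",
                  "liver_cancer", "brain_cancer", "pancreatic_cancer",
                  "ovarian_cancer", "prostatic_cancer", "gallbladder_cancer",
                  "kidney_cancer", "thyroid_cancer"),
  stage = c("early_stage", "middle_stage", "terminal_stage"),
  treatment = c("surgery", "chemotherapy", "radiation_therapy",
                "immunotherapy", "cam", "transplantation"),
  survival_stage = c("acute_survival", "extended_survival",
                     "permanent_survival"),
  symptom = c("fatigue_pain_fever", "gastrointestinal_problems",
              "hair_loss_skin_problems", "poor_circulation",
              "thrombocytopenia", "infection")
)

# Role markers are not analysis items: they drive inclusion/exclusion.
ROLE_MARKERS <- c("cancer_keyword", "stop_keyword", "ad_keyword")

CHANNELS <- c("blog", "cafe", "twitter", "board")
LONGFORM_CHANNELS <- c("blog", "cafe", "board")

#' Catalog of the 47 analysis items
#'
#' The analysis universe consists of 4 multi-label emotion groups
#' (hope/gratitude, fear/anxiety/overwhelmed,
#' sadness/depression/loneliness/guilt, anger/denial — aggregating nine
#' ontology emotion classes) and 43 emotion-related factor groups:
#' gender (2), age bands (9), cancer types (14), cancer stages (3),
#' treatments (6), survival stages (3), and symptom clusters (6).
#'
#' @return An object of class `item_catalog`: a list with elements
#'   `emotion_groups` (length 4), `factor_groups` (length 43),
#'   `factor_category` (named character mapping each factor item to its
#'   category), `emotion_class_map` (the 9-class to 4-group map),
#'   `all_items` (the 47 item identifiers, emotions first), `labels`
#'   (display labels for the emotion groups), and `role_markers`.
#' @examples
#' cat47 <- item_catalog()
#' length(cat47$factor_groups)  # 43
#' @export
item_catalog <- function() {
  factor_groups <- unlist(FACTOR_CATEGORIES, use.names = FALSE)
  sizes <- lengths(FACTOR_CATEGORIES)
  stopifnot(
    length(EMOTION_GROUPS) == 4L,
    length(factor_groups) == 43L,
    identical(unname(sizes[c("gender", "age", "cancer_type", "stage",
                             "treatment", "survival_stage", "symptom")]),
              c(2L, 9L, 14L, 3L, 6L, 3L, 6L)),
    anyDuplicated(factor_groups) == 0L,
    setequal(names(EMOTION_CLASS_MAP),
             c("denial", "anger", "overwhelmed", "anxiety", "depression",
               "loneliness", "guilt", "hope", "gratitude")),
    all(EMOTION_CLASS_MAP %in% EMOTION_GROUPS)
  )
  factor_category <- rep(names(FACTOR_CATEGORIES), sizes)
  names(factor_category) <- factor_groups
  structure(
    list(
      emotion_groups = EMOTION_GROUPS,
      factor_groups = factor_groups,
      factor_category = factor_category,
      emotion_class_map = EMOTION_CLASS_MAP,
      all_items = c(EMOTION_GROUPS, factor_groups),
      labels = EMOTION_LABELS,
      role_markers = ROLE_MARKERS
    ),
    class = "item_catalog"
  )
}

#' @export
print.item_catalog <- function(x, ...) {
  cat("Item catalog: 4 emotion groups + 43 factor groups\n")
  cat("  emotions:", paste(x$emotion_groups, collapse = ", "), "\n")
  tab <- table(factor(x$factor_category, levels = unique(x$factor_category)))
  cat("  factors: ",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
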