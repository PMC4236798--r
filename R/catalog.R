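#' Assessment-item domains
#'
#' The nine domains into which the analytic items of a comprehensive home-care
#' assessment are partitioned.
#'
#' @export
ITEM_DOMAINS <- c(
  "clinical_complication", "disease", "treatment",
  "cognition_communication", "mood_behavior", "social_supports",
  "function", "environment", "services"
)

# Default number of analytic items per domain (sums to 123).
DOMAIN_COUNTS <- c(
  clinical_complication = 28L, disease = 19L, treatment = 15L,
  cognition_communication = 6L, mood_behavior = 12L, social_supports = 4L,
  "function" = 11L, environment = 10L, services = 18L
)

#' Construct an item catalog
#'
#' An item catalog lists the dichotomous assessment items available to the
#' pipeline, the domain each belongs to, and the planted truth used by the
#' synthetic-cohort generator: the item's true log-odds effect on the
#' follow-up hospital/ED outcome and its marginal prevalence.
#'
#' @param items Data frame with columns `item_id` (unique strings), `domain`
#'   (one of [ITEM_DOMAINS]), `true_beta` (finite log-odds), and `prevalence`
#'   (strictly between 0 and 1).
#' @return The validated catalog, a data frame of class `hedri_catalog`.
#' @seealso [default_catalog()] for the planted-truth profile shipped with
#'   the package.
#' @export
item_catalog <- function(items) {
  required <- c("item_id", "domain", "true_beta", "prevalence")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    stop_config(paste0(
      "catalog is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  items <- as.data.frame(items)[required]
  items$item_id <- as.character(items$item_id)
  items$domain <- as.character(items$domain)
  if (anyDuplicated(items$item_id)) {
    stop_config(paste0(
      "duplicated item_id(s): ",
      paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", ")
    ))
  }
  bad_domain <- setdiff(unique(items$domain), ITEM_DOMAINS)
  if (length(bad_domain) > 0) {
    stop_config(paste0("unknown domain(s): ", paste(bad_domain, collapse = ", ")))
  }
  if (!all(is.finite(items$true_beta))) {
    stop_config("true_beta must be finite for every item")
  }
  if (!all(items$prevalence > 0 & items$prevalence < 1)) {
    stop_config("prevalence must lie strictly between 0 and 1 for every item")
  }
  rownames(items) <- NULL
  class(items) <- c("hedri_catalog", "data.frame")
  items
}

# Cycle of prevalences assigned to null items, in catalog order.
NULL_PREVALENCES <- c(0.05, 0.08, 0.12, 0.15, 0.20, 0.25, 0.30, 0.40)

#' Default planted-truth item catalog
#'
#' The 123-item profile used throughout the package: 28 clinical
#' complications, 19 disease diagnoses, 15 specialized treatments, 6
#' cognition/communication, 12 mood/behavior, 4 social supports, 11
#' functional, 10 environmental, and 18 service items. Sixteen items carry a
#' planted elevated risk (true odds ratios spread over 1.5-2.0, matching the
#' composition of the canonical index: seven clinical complications, three
#' diseases, six treatments), two carry a protective effect (an Alzheimer's
#' disease diagnosis, OR 0.60, and day-care participation, OR 0.65), and the
#' remaining 105 are null.
#'
#' `risk_ors` / `protective_ors` override the planted effect sizes while
#' keeping the item structure. A single value is recycled to all items of
#' that role. The moderate profile `default_catalog(risk_ors = 1.15)`
#' emulates *adjusted* (multivariate) per-item effects of the magnitude
#' implied by the published category gradient, and is the profile used for
#' the prior-use crossing evaluation; the default strong profile matches the
#' univariate screening magnitudes.
#'
#' @param risk_ors Optional odds ratio(s) for the 16 elevated-risk items.
#' @param protective_ors Optional odds ratio(s) for the 2 protective items.
#' @return A `hedri_catalog` data frame with 123 rows.
#' @export
default_catalog <- function(risk_ors = NULL, protective_ors = NULL) {
  risk <- data.frame(
    item_id = c(
      # clinical complications (7)
      "pneumonia", "urinary_tract_infection", "stasis_ulcer",
      "unintended_weight_loss", "status_decline_90d", "falls", "fever",
      # diseases (3)
      "renal_failure", "emphysema", "cancer",
      # treatments (6)
      "wound_care", "iv_infusion", "injection_medication",
      "daily_nurse_monitoring", "unscheduled_md_visit", "nine_plus_medications"
    ),
    domain = rep(c("clinical_complication", "disease", "treatment"), c(7L, 3L, 6L)),
    true_or = c(
      1.95, 1.75, 1.85, 1.60, 1.65, 1.50, 1.70,
      1.55, 1.50, 1.65,
      1.90, 2.00, 1.70, 1.55, 1.60, 1.50
    ),
    prevalence = c(
      0.04, 0.12, 0.03, 0.10, 0.12, 0.30, 0.04,
      0.05, 0.10, 0.12,
      0.10, 0.03, 0.08, 0.12, 0.15, 0.35
    ),
    stringsAsFactors = FALSE
  )
  if (!is.null(risk_ors)) {
    risk$true_or <- rep_len(risk_ors, nrow(risk))
  }
  # conditional ORs chosen so the *marginal* univariate ORs (attenuated by
  # non-collapsibility over the other planted effects) land near the
  # published day-care screening value of ~0.66
  protective <- data.frame(
    item_id = c("alzheimers", "day_care"),
    domain = c("disease", "services"),
    true_or = c(0.60, 0.65),
    prevalence = c(0.12, 0.08),
    stringsAsFactors = FALSE
  )
  if (!is.null(protective_ors)) {
    protective$true_or <- rep_len(protective_ors, nrow(protective))
  }
  null_ids <- list(
    clinical_complication = c(
      "chest_pain", "diarrhea", "vomiting", "dizziness", "edema", "skin_tear",
      "pressure_ulcer", "poor_self_rated_health", "daily_pain", "unsteady_gait",
      "hallucinations", "delusions", "swallowing_problem",
      "bladder_incontinence", "bowel_incontinence", "dehydration",
      "shortness_of_breath", "chewing_problem", "dysphasia", "skin_abrasion",
      "surgical_wound"
    ),
    disease = c(
      "congestive_heart_failure", "coronary_artery_disease", "hypertension",
      "diabetes", "arthritis", "parkinsons", "stroke", "hemiplegia",
      "osteoporosis", "hip_fracture", "cataract", "glaucoma",
      "thyroid_disease", "peripheral_vascular_disease", "head_trauma"
    ),
    treatment = c(
      "oxygen_therapy", "dialysis", "radiation", "chemotherapy",
      "blood_transfusion", "catheter_care", "ostomy_care",
      "tracheostomy_care", "ventilator"
    ),
    cognition_communication = c(
      "short_term_memory_problem", "decision_making_impairment",
      "making_self_understood", "understanding_others", "delirium_signs",
      "communication_decline"
    ),
    mood_behavior = c(
      "depressed_mood", "anxiety", "withdrawal", "reduced_interest",
      "anger_outbursts", "wandering", "verbal_abuse", "physical_abuse",
      "socially_inappropriate", "resists_care", "sleep_problem",
      "sad_expression"
    ),
    social_supports = c(
      "lives_alone", "caregiver_distress", "reduced_social_interaction",
      "no_informal_helper"
    ),
    "function" = c(
      "adl_impairment", "iadl_impairment", "poor_exercise_tolerance",
      "stairs_difficulty", "bed_mobility_problem", "transfer_problem",
      "locomotion_problem", "dressing_problem", "eating_problem",
      "toileting_problem", "bathing_problem"
    ),
    environment = c(
      "home_clutter", "inadequate_heating", "unsafe_neighborhood",
      "no_smoke_detector", "poor_lighting", "bathroom_hazard", "stair_hazard",
      "inaccessible_entrance", "inadequate_finances", "housing_instability"
    ),
    services = c(
      "home_health_aide", "homemaker", "meals_on_wheels", "visiting_nurse",
      "physical_therapy", "occupational_therapy", "speech_therapy",
      "medical_oversight", "respite_care", "transportation_service",
      "social_worker", "hospice", "emergency_response_system",
      "volunteer_visits", "case_management", "mental_health_service",
      "nutrition_counseling"
    )
  )
  nulls <- data.frame(
    item_id = unlist(null_ids, use.names = FALSE),
    domain = rep(names(null_ids), lengths(null_ids)),
    true_or = 1,
    prevalence = NA_real_,
    stringsAsFactors = FALSE
  )
  nulls$prevalence <- NULL_PREVALENCES[(seq_len(nrow(nulls)) - 1L) %% length(NULL_PREVALENCES) + 1L]

  all_items <- rbind(risk, protective, nulls)
  # order by domain for readability, stable within blocks
  all_items <- all_items[order(match(all_items$domain, ITEM_DOMAINS)), ]
  cat <- item_catalog(data.frame(
    item_id = all_items$item_id,
    domain = all_items$domain,
    true_beta = log(all_items$true_or),
    prevalence = all_items$prevalence,
    stringsAsFactors = FALSE
  ))
  stopifnot(nrow(cat) == 123L)
  cat
}

#' @export
print.hedri_catalog <- function(x, ...) {
  counts <- table(factor(x$domain, levels = ITEM_DOMAINS))
  n_risk <- sum(x$true_beta > 0)
  n_prot <- sum(x$true_beta < 0)
  cat(sprintf(
    "Item catalog: %d items (%d elevated-risk, %d protective, %d null)\n",
    nrow(x), n_risk, n_prot, nrow(x) - n_risk - n_prot
  ))
  cat("Items per domain:\n")
  print(counts)
  invisible(x)
}
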