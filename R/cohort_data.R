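#' Follow-up data of a 20-patient bone-tumor resection cohort
#'
#' Vital status and follow-up duration (months since surgery) of 20 patients
#' who underwent computer-assisted bone tumor resection with safe-margin
#' planning, together with the prescribed safe margin (10/15/20 mm per the
#' Enneking staging of each tumor). Two patients died of pulmonary
#' metastases, at 17 and 50 months; all others are censored at their last
#' follow-up. Used as the worked example for [kaplan_meier()].
#'
#' @return A data.frame with columns `id`, `safe_margin_mm`,
#'   `follow_up_months` and `died`.
#' @export
resection_cohort <- function() {
  data.frame(
    id = 1:20,
    safe_margin_mm = c(15, 20, 10, 20, 10, 20, 20, 20, 20, 10,
                       10, 20, 20, 20, 20, 20, 20, 20, 15, 10),
    follow_up_months = c(86, 17, 65, 62, 62, 61, 58, 54, 50, 47,
                         43, 35, 31, 31, 28, 26, 25, 25, 20, 20),
    died = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
             FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
             FALSE, FALSE)
  )
}

#' Reported per-patient maximum absolute geometric errors of three methods
#'
#' Maximum absolute geometric errors (mm) of the patient-specific safe-margin
#' volumes generated for the same 20-patient cohort by three methods:
#' voxel-unit morphological dilation, the coarse-only anisotropic distance
#' transform, and the fused coarse-plus-ring method. Used as the worked
#' example for [compare_methods()].
#'
#' @return A data.frame with columns `id`, `dilation`, `coarse_adt`, `fused`.
#' @export
method_max_abs_errors <- function() {
  data.frame(
    id = 1:20,
    dilation = c(1.2445, 1.5455, 0.7533, 0.9155, 0.7331, 1.3451, 2.5997,
                 0.8972, 1.4217, 0.8553, 13.2932, 0.5356, 1.2072, 0.6052,
                 2.5455, 1.1414, 0.7435, 10.0286, 20.6174, 8.4768),
    coarse_adt = c(1.1513, 1.5259, 1.2342, 1.1702, 1.6167, 1.3451, 1.4409,
                   1.0667, 1.2657, 1.2658, 0.8781, 1.2321, 1.2072, 1.1911,
                   1.4968, 1.5379, 1.5801, 2.2835, 1.5924, 2.0593),
    fused = c(0.1776, 0.1957, 0.1835, 0.1837, 0.1819, 0.1777, 0.1777,
              0.1831, 0.1963, 0.1871, 0.1766, 0.1776, 0.1768, 0.1513,
              0.1818, 0.1846, 0.1888, 0.1761, 0.1778, 0.2000)
  )
}
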