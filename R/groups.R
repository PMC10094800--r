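# Study-group vocabulary and serostatus assignment.

#' Study group labels
#'
#' The four cohort arms, in fixed order: healthy controls without and with
#' serological evidence of prior SARS-CoV-2 infection, and acute myocardial
#' infarction (AMI) patients without and with such evidence.
#'
#' @return Character vector of the four group labels.
#' @export
cohort_groups <- function() {
  c("control", "control_post_covid", "ami_control", "ami_post_covid")
}

#' Assign a subject to a serostatus group
#'
#' Prior SARS-CoV-2 infection is inferred from the anti-nucleocapsid (anti-N)
#' IgG index: subjects with anti-N IgG below `threshold` form the control
#' (seronegative) arm of their cohort, subjects at or above it the post-COVID
#' arm. The AMI flag selects between the healthy-volunteer and the AMI
#' cohort. The boundary value itself is classified post-COVID because the
#' control arm is defined by values strictly below the threshold.
#'
#' @param anti_n_igg Nonnegative anti-N IgG index value(s) (assay units).
#' @param ami_flag Logical: `TRUE` for AMI patients, `FALSE` for healthy
#'   volunteers. Recycled against `anti_n_igg`.
#' @param threshold Seropositivity cutoff on the index scale (default 1.4).
#' @return Factor with levels [cohort_groups()], same length as the inputs.
#' @examples
#' assign_serostatus_group(1.0, ami_flag = TRUE)   # ami_control
#' assign_serostatus_group(2.5, ami_flag = FALSE)  # control_post_covid
#' @export
assign_serostatus_group <- function(anti_n_igg, ami_flag, threshold = 1.4) {
  if (any(!is.na(anti_n_igg) & anti_n_igg < 0)) {
    stop("anti_n_igg must be nonnegative")
  }
  ami_flag <- rep_len(as.logical(ami_flag), length(anti_n_igg))
  post <- anti_n_igg >= threshold
  lab <- ifelse(ami_flag,
    ifelse(post, "ami_post_covid", "ami_control"),
    ifelse(post, "control_post_covid", "control")
  )
  factor(lab, levels = cohort_groups())
}
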