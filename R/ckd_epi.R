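#' CKD-EPI (2009) creatinine equation parameters
#'
#' Constants of the Chronic Kidney Disease Epidemiology Collaboration (CKD-EPI)
#' 2009 serum-creatinine equation: sex-specific kappa (mg/dL) and alpha
#' exponents, the shared exponent applied above kappa, the base rate of
#' 141 mL/min/1.73 m^2, the per-year age factor, and the female and Black
#' race multipliers.  Individual constants can be overridden, e.g. to drop
#' the race coefficient.
#'
#' @param ... named overrides of individual constants.
#' @return A named list of equation constants.
#' @examples
#' ckd_epi_params()
#' ckd_epi_params(black_factor = 1)
#' @export
ckd_epi_params <- function(...) {
  params <- list(
    kappa_female  = 0.7,
    kappa_male    = 0.9,
    alpha_female  = -0.329,
    alpha_male    = -0.411,
    max_exponent  = -1.209,
    base          = 141,
    age_factor    = 0.993,
    female_factor = 1.018,
    black_factor  = 1.159
  )
  override <- list(...)
  bad <- setdiff(names(override), names(params))
  if (length(bad)) stopf("unknown CKD-EPI parameter(s): %s", paste(bad, collapse = ", "))
  params[names(override)] <- override
  params
}

#' Estimated glomerular filtration rate from serum creatinine (CKD-EPI 2009)
#'
#' Computes eGFR in mL/min/1.73 m^2 as
#' \deqn{141 \cdot \min(\mathrm{Scr}/\kappa, 1)^{\alpha} \cdot
#'       \max(\mathrm{Scr}/\kappa, 1)^{-1.209} \cdot 0.993^{\mathrm{age}}
#'       \cdot 1.018[\mathrm{female}] \cdot 1.159[\mathrm{Black}]}
#' with sex-specific \eqn{\kappa} and \eqn{\alpha}.  Vectorised over all
#' arguments; eGFR is strictly decreasing in creatinine and in age.
#'
#' @param scr serum creatinine, mg/dL; must be positive.
#' @param age age in years; must be positive.
#' @param is_female logical, female sex.
#' @param is_black logical, self-identified Black race (the 2009 equation's
#'   race coefficient; retained because the cohorts modelled here used it).
#' @param params constants from [ckd_epi_params()].
#' @return numeric vector of eGFR values.
#' @examples
#' compute_ckd_epi_egfr(0.9, 50, is_female = FALSE, is_black = FALSE)
#' compute_ckd_epi_egfr(0.7, 50, is_female = TRUE, is_black = TRUE)
#' @export
compute_ckd_epi_egfr <- function(scr, age, is_female, is_black,
                                 params = ckd_epi_params()) {
  if (any(!is.finite(scr)) || any(scr <= 0)) stopf("scr must be positive and finite")
  if (any(!is.finite(age)) || any(age <= 0)) stopf("age must be positive and finite")
  n <- max(length(scr), length(age), length(is_female), length(is_black))
  scr <- rep_len(scr, n); age <- rep_len(age, n)
  is_female <- rep_len(as.logical(is_female), n)
  is_black <- rep_len(as.logical(is_black), n)

  kappa <- ifelse(is_female, params$kappa_female, params$kappa_male)
  alpha <- ifelse(is_female, params$alpha_female, params$alpha_male)
  ratio <- scr / kappa
  egfr <- params$base *
    pmin(ratio, 1)^alpha *
    pmax(ratio, 1)^params$max_exponent *
    params$age_factor^age
  egfr <- egfr * ifelse(is_female, params$female_factor, 1)
  egfr * ifelse(is_black, params$black_factor, 1)
}
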