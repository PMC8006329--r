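#' The 35-analyte Luminex cytokine/chemokine panel
#'
#' Returns the fixed, ordered labels of the Comprehensive Human Cytokine
#' 35-Plex panel measured in serum pre- and post-antivenom: growth factors
#' (EGF, FGF-basic, HGF, VEGF), colony-stimulating factors, interferons,
#' interleukins, and CXC/CC chemokines.
#'
#' @return character vector of length 35, no duplicates, fixed order.
#' @examples
#' length(panelAnalytes())
#' "HGF" %in% panelAnalytes()
#' @export
panelAnalytes <- function() {
  c("EGF", "Eotaxin", "FGF-basic", "G-CSF", "GM-CSF", "HGF",
    "IFN-alpha", "IFN-gamma", "IL-1 beta", "IL-1 alpha", "IL-1RA",
    "IL-2", "IL-2R", "IL-3", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8",
    "IL-9", "IL-10", "IL-12", "IL-13", "IL-15", "IL-17A", "IL-17F",
    "IL-22", "CXCL10", "CCL2", "CXCL9", "CCL3", "CCL4", "CCL5",
    "TNF-alpha", "VEGF")
}

#' Clinical variables emulated by the cohort generator
#'
#' Static variables (age, sex, comorbidity flag) plus dynamic ones
#' (antihistamine use, white blood cell count, respiratory rate, serum
#' CO2/bicarbonate), mirroring a standard emergency-department assessment.
#'
#' @return character vector of supported clinical variable names.
#' @export
clinicalVariables <- function() {
  c("age", "sex", "comorbidity", "antihistamines", "WBC", "resp_rate", "CO2")
}

# Baseline natural-log concentration per analyte.  The named entries are
# anchored near published log medians (e.g. HGF ~ 6.2, CCL5 ~ 7.3 on the
# natural-log pg/mL scale); the rest get a deterministic spread over 1-6.
.analyte_baselines <- function() {
  base <- rep(seq(1.5, 5.5, by = 1), length.out = 35L)
  names(base) <- panelAnalytes()
  anchor <- c("EGF" = 3.6, "Eotaxin" = 4.2, "FGF-basic" = 2.3, "HGF" = 6.2,
              "IL-1RA" = 3.9, "IL-2R" = 3.8, "IL-10" = 1.7, "IL-12" = 4.3,
              "CXCL10" = 1.6, "CCL2" = 5.9, "CCL4" = 4.0, "CCL5" = 7.3,
              "VEGF" = 0.6)
  base[names(anchor)] <- anchor
  base
}

# Severity-coupling coefficients on the log scale (per SD of latent
# severity, at severity_effect = 1).  Signs follow the direction of the
# observed good/poor contrasts: HGF, Eotaxin, IL-10, IL-12, CCL2 rise with
# severity; CXCL10, CCL4, VEGF fall.  All other analytes are uncoupled.
.analyte_couplings <- function() {
  cp <- stats::setNames(numeric(35L), panelAnalytes())
  cp[c("HGF", "Eotaxin", "IL-10", "IL-12", "CCL2")] <-
    c(0.55, 0.25, 0.30, 0.25, 0.25)
  cp[c("CXCL10", "CCL4", "VEGF")] <- c(-0.30, -0.45, -0.40)
  cp
}

# Mean shift between pre- and post-antivenom draws (post minus pre, log
# scale), mirroring the observed direction of treatment changes.
.analyte_post_shifts <- function() {
  sh <- stats::setNames(numeric(35L), panelAnalytes())
  sh[c("FGF-basic", "IL-2R", "CCL5", "HGF")] <- c(1.2, 1.5, 0.13, -0.4)
  sh
}
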