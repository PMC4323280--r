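#' Z-transform a numeric vector over complete cases
#'
#' Standardizes `(x - mean) / sd` with the mean and SD computed from the
#' non-missing values of the standardization cohort; missing values
#' propagate. The default SD convention is the sample SD (n - 1 divisor),
#' matching common statistics-package defaults; a population (n divisor)
#' switch is provided since either convention yields identical composites
#' up to a constant factor per component.
#'
#' @param x Numeric vector, possibly with `NA`.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Numeric vector of z-scores with attributes `mean`, `sd` and
#'   `n_complete` recording the standardization constants.
#' @export
#' @examples
#' z_transform(c(1, 2, 3))        # -1 0 1
z_transform <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) {
    stop("z_transform needs at least 2 complete values (got ", n, ")",
         call. = FALSE)
  }
  mu <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0) {
    stop("z_transform: zero spread (constant variable over the ", n,
         " complete cases)", call. = FALSE)
  }
  z <- (x - mu) / s
  attr(z, "mean") <- mu
  attr(z, "sd") <- s
  attr(z, "n_complete") <- n
  z
}

#' @keywords internal
#' @noRd
z_sum <- function(..., sd_type = "sample") {
  parts <- list(...)
  zs <- lapply(parts, z_transform, sd_type = sd_type)
  Reduce(`+`, lapply(zs, as.numeric))
}

#' Global stress composite
#'
#' Sum of the z-transformed PSS-14 total and the z-transformed ESI total.
#' Missing whenever either component is missing.
#'
#' @param pss14_total,esi_total Numeric vectors over the same cohort.
#' @param sd_type SD convention, see [z_transform()].
#' @return Numeric vector.
#' @export
global_stress <- function(pss14_total, esi_total, sd_type = "sample") {
  z_sum(pss14_total, esi_total, sd_type = sd_type)
}

#' Global psychopathology composite
#'
#' Sum of the z-transformed SCL-90-R somatization total, the z-transformed
#' combined HSCL-25 total (anxiety plus depression, standardized as one
#' score) and the z-transformed PDS symptom severity.
#'
#' @param scl_somatization,hscl_total,pds_severity Numeric vectors over the
#'   same cohort.
#' @inheritParams global_stress
#' @return Numeric vector; missing whenever any component is missing.
#' @export
global_psychopathology <- function(scl_somatization, hscl_total, pds_severity,
                                   sd_type = "sample") {
  z_sum(scl_somatization, hscl_total, pds_severity, sd_type = sd_type)
}

#' Global trauma load composite
#'
#' Sum of the z-transformed PDS traumatic-event count and the z-transformed
#' CFV family-violence total.
#'
#' @param pds_events,cfv_total Numeric vectors over the same cohort.
#' @inheritParams global_stress
#' @return Numeric vector; missing whenever any component is missing.
#' @export
global_trauma_load <- function(pds_events, cfv_total, sd_type = "sample") {
  z_sum(pds_events, cfv_total, sd_type = sd_type)
}

#' All three global criterion composites for a scored cohort
#'
#' Builds the z-based global stress, global psychopathology and global
#' trauma load scores from a battery score table (see [score_battery()]).
#' Standardization is cohort-relative: means and SDs come from the complete
#' cases of the supplied table, and each composite is missing exactly for
#' respondents missing any of its components.
#'
#' @param scores Tibble from [score_battery()].
#' @inheritParams global_stress
#' @return Tibble `respondent_id`, `global_stress`, `global_psychopathology`,
#'   `global_trauma_load`, with attribute `standardization` (tibble of
#'   component, mean, sd, n_complete used for each z-transform).
#' @export
compute_composites <- function(scores, sd_type = "sample") {
  comp_map <- list(
    pss14_total = scores$pss14_total,
    esi_total = scores$esi_total,
    scl_somatization = scores$scl_somatization,
    hscl_total = scores$hscl_total,
    pds_severity = scores$pds_severity,
    pds_events = scores$pds_events,
    cfv_total = scores$cfv_total)
  zs <- lapply(comp_map, z_transform, sd_type = sd_type)
  standardization <- tibble::tibble(
    component = names(zs),
    mean = unname(vapply(zs, attr, numeric(1), "mean")),
    sd = unname(vapply(zs, attr, numeric(1), "sd")),
    n_complete = unname(vapply(zs, attr, numeric(1), "n_complete")))
  out <- tibble::tibble(
    respondent_id = scores$respondent_id,
    global_stress = as.numeric(zs$pss14_total) + as.numeric(zs$esi_total),
    global_psychopathology = as.numeric(zs$scl_somatization) +
      as.numeric(zs$hscl_total) + as.numeric(zs$pds_severity),
    global_trauma_load = as.numeric(zs$pds_events) + as.numeric(zs$cfv_total))
  attr(out, "standardization") <- standardization
  out
}
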