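#' Classify birth size from the birthweight percentile
#'
#' Below the 10th percentile for gestational age is small for gestational age
#' (SGA), above the 90th is large (LGA), everything else is appropriate (AGA).
#' Inequalities are strict, so a subject at exactly the 10th or 90th percentile
#' is AGA.
#'
#' @param birthweightPercentile numeric vector of percentiles in (0, 100).
#' @return factor with levels `SGA`, `AGA`, `LGA`.
#' @examples
#' classifyBirthSize(c(5, 50, 95))
#' @export
classifyBirthSize <- function(birthweightPercentile) {
  p <- birthweightPercentile
  bad <- !is.na(p) & (p <= 0 | p >= 100)
  if (any(bad))
    stop("birthweight percentile out of (0, 100): ",
         paste(utils::head(p[bad]), collapse = ", "))
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < 10, "SGA", ifelse(p > 90, "LGA", "AGA")))
  factor(out, levels = c("SGA", "AGA", "LGA"))
}

#' Classify catch-up / catch-down status at age 7
#'
#' An SGA-born child whose height has returned above the 10th percentile by
#' age 7 has caught up (`CU-SGA`); an LGA-born child whose height has dropped
#' below the 90th has caught down (`LGA-CD`). AGA children keep their label. A
#' missing height percentile for an SGA/LGA child yields `unclassifiable`,
#' never a silent AGA.
#'
#' @param birth factor from [classifyBirthSize()].
#' @param heightPercentileAge7 numeric vector of height percentiles at age 7,
#'   in (0, 100); may be `NA` for AGA subjects.
#' @return factor with levels `CU-SGA`, `SGA-noCU`, `AGA`, `LGA-CD`,
#'   `LGA-noCD`, `unclassifiable`.
#' @examples
#' classifyPostnatal(classifyBirthSize(c(5, 5, 50)), c(25, 5, NA))
#' @export
classifyPostnatal <- function(birth, heightPercentileAge7) {
  h <- heightPercentileAge7
  if (length(h) != length(birth))
    stop("'birth' and 'heightPercentileAge7' lengths differ")
  bad <- !is.na(h) & (h <= 0 | h >= 100)
  if (any(bad)) stop("height percentile out of (0, 100)")
  b <- as.character(birth)
  out <- vapply(seq_along(b), function(i) {
    if (is.na(b[i])) return(NA_character_)
    if (b[i] == "AGA") return("AGA")
    if (is.na(h[i])) return("unclassifiable")
    if (b[i] == "SGA") {
      if (h[i] > 10) "CU-SGA" else "SGA-noCU"
    } else {
      if (h[i] < 90) "LGA-CD" else "LGA-noCD"
    }
  }, character(1))
  factor(out, levels = c("CU-SGA", "SGA-noCU", "AGA", "LGA-CD", "LGA-noCD",
                         "unclassifiable"))
}

#' Fetal weight-trajectory statistic (percentile points per day)
#'
#' Birthweight percentile minus the 23-week estimated-fetal-weight percentile,
#' divided by the number of days between the two measurements.
#'
#' @param birthweightPercentile,efw23Percentile percentiles in (0, 100).
#' @param daysBetween positive number of days between the 23-week scan and
#'   birth.
#' @return numeric, percentile points per day.
#' @examples
#' deltaFetalWt(50, 30, 140)   # 1/7
#' @export
deltaFetalWt <- function(birthweightPercentile, efw23Percentile, daysBetween) {
  if (any(daysBetween <= 0, na.rm = TRUE))
    stop("'daysBetween' must be positive")
  (birthweightPercentile - efw23Percentile) / daysBetween
}

#' Childhood weight-trajectory statistic (SDS per year)
#'
#' Weight SDS at the childhood visit minus birthweight SDS, divided by the
#' years between birth and the visit.
#'
#' @param childWeightSDS,birthweightSDS standard-deviation scores.
#' @param years positive number of years.
#' @return numeric, SDS per year.
#' @examples
#' deltaChildWt(0.5, -1.5, 5)  # 0.4
#' @export
deltaChildWt <- function(childWeightSDS, birthweightSDS, years) {
  if (any(years <= 0, na.rm = TRUE)) stop("'years' must be positive")
  (childWeightSDS - birthweightSDS) / years
}

#' Hadlock estimated fetal weight
#'
#' Evaluates the Hadlock log10 polynomial for estimated fetal weight from
#' ultrasound biometry. The default four-parameter variant uses biparietal
#' diameter (BPD), head circumference (HC), abdominal circumference (AC) and
#' femur length (FL):
#'
#' \deqn{\log_{10} EFW = 1.3596 + 0.0064\,HC + 0.0424\,AC + 0.174\,FL +
#'   0.00061\,BPD\cdot AC - 0.00386\,AC\cdot FL}
#'
#' The three-parameter variant (HC, AC, FL) is
#' \eqn{1.326 - 0.00326\,AC\cdot FL + 0.0107\,HC + 0.0438\,AC + 0.158\,FL}.
#'
#' @param hc,ac,fl,bpd biometry in centimetres; `bpd` is only required for the
#'   four-parameter variant.
#' @param variant `"four"` (default) or `"three"` parameter equation.
#' @return estimated fetal weight in grams.
#' @examples
#' hadlockEFW(hc = 20, ac = 18, fl = 3.5, bpd = 5.5)
#' @export
hadlockEFW <- function(hc, ac, fl, bpd = NULL,
                       variant = c("four", "three")) {
  variant <- match.arg(variant)
  if (any(c(hc, ac, fl) <= 0, na.rm = TRUE))
    stop("biometry must be positive")
  if (variant == "four") {
    if (is.null(bpd)) stop("'bpd' is required for the four-parameter variant")
    if (any(bpd <= 0, na.rm = TRUE)) stop("biometry must be positive")
    lg <- 1.3596 + 0.0064 * hc + 0.0424 * ac + 0.174 * fl +
      0.00061 * bpd * ac - 0.00386 * ac * fl
  } else {
    lg <- 1.326 - 0.00326 * ac * fl + 0.0107 * hc + 0.0438 * ac + 0.158 * fl
  }
  10^lg
}

#' Percentile of an estimated fetal weight for gestational age
#'
#' Converts an EFW in grams to a percentile against a pluggable
#' gestational-age reference (columns `ga_weeks`, `mean_g`, `sd_g`), linearly
#' interpolating the mean and SD across gestational age and assuming a normal
#' weight distribution at each age. A synthetic reference chart ships with the
#' package for testing (`inst/extdata/efw_reference_synthetic.csv`).
#'
#' @param efw estimated fetal weight, grams.
#' @param gaWeeks gestational age in weeks.
#' @param reference data.frame reference chart; default loads the synthetic
#'   chart.
#' @return percentile in (0, 100).
#' @export
efwPercentile <- function(efw, gaWeeks, reference = efwReference()) {
  rng <- range(reference$ga_weeks)
  if (any(gaWeeks < rng[1] | gaWeeks > rng[2]))
    stop(sprintf("gestational age outside reference coverage [%g, %g] weeks",
                 rng[1], rng[2]))
  m <- stats::approx(reference$ga_weeks, reference$mean_g, xout = gaWeeks)$y
  s <- stats::approx(reference$ga_weeks, reference$sd_g, xout = gaWeeks)$y
  100 * stats::pnorm((efw - m) / s)
}

#' @rdname efwPercentile
#' @export
efwReference <- function() {
  utils::read.csv(system.file("extdata", "efw_reference_synthetic.csv",
                              package = "hypergrowth"))
}

#' Cohort-relative quartile labels
#'
#' Assigns `Q1`..`Q4` by empirical quartile within the supplied vector. Values
#' are ranked with ties taking the lowest rank of their group, and ranks are
#' split at n/4, n/2 and 3n/4, so a tie group spanning a cut falls entirely in
#' the lower quartile (a constant vector is all `Q1`). Missing values stay
#' unlabeled.
#'
#' @param values numeric vector with at least 4 non-missing entries.
#' @return factor with levels `Q1`..`Q4`.
#' @examples
#' assignQuartiles(c(1, 2, 3, 4))
#' @export
assignQuartiles <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 4) stop("need at least 4 non-missing values")
  r <- rank(values[ok], ties.method = "min")
  q <- cut(r, breaks = c(0, n / 4, n / 2, 3 * n / 4, n),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  out <- factor(rep(NA_character_, length(values)),
                levels = c("Q1", "Q2", "Q3", "Q4"))
  out[ok] <- q
  out
}

#' Per-subject trajectory summary
#'
#' Computes both trajectory statistics, cohort-relative quartiles and
#' birth/postnatal classes from a growth table with the column dictionary of
#' [simulateCohort()].
#'
#' @param growth data.frame with columns `subject_id`,
#'   `birthweight_percentile`, `efw23_percentile`, `days_between`,
#'   `height_percentile_age7`, `child_weight_sds`, `birthweight_sds`,
#'   `visit_age`.
#' @return data.frame with classes, `delta_fetal_wt`, `delta_child_wt` and
#'   their quartiles.
#' @export
summarizeTrajectories <- function(growth) {
  birth <- classifyBirthSize(growth$birthweight_percentile)
  post <- classifyPostnatal(birth, growth$height_percentile_age7)
  dfw <- deltaFetalWt(growth$birthweight_percentile, growth$efw23_percentile,
                      growth$days_between)
  dcw <- deltaChildWt(growth$child_weight_sds, growth$birthweight_sds,
                      growth$visit_age)
  data.frame(subject_id = growth$subject_id,
             birth_class = birth,
             postnatal_class = post,
             delta_fetal_wt = dfw,
             delta_child_wt = dcw,
             fetal_quartile = assignQuartiles(dfw),
             child_quartile = assignQuartiles(dcw),
             stringsAsFactors = FALSE)
}

#' Read a growth table
#'
#' One row per subject; see [summarizeTrajectories()] for the column
#' dictionary.
#' @param path CSV file.
#' @return data.frame.
#' @export
readGrowthTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
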