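#' NHLBI-style prehypertension thresholds
#'
#' The phenotype is called when ANY active criterion is met, evaluated in
#' `evaluationOrder` (the order determines the primary driver only, never the
#' flag). Defaults follow NHLBI 2011 pediatric guidance: SBP/DBP at or above
#' the 90th percentile for age/sex/height when a blood-pressure reference
#' table is supplied, or at or above the absolute 120/80 mmHg cut-offs
#' (adolescents), HDL below 1.03 mmol/L, LDL at or above 3.36 mmol/L. All
#' values are configurable and are recorded in the output of
#' [callPrehypertension()].
#'
#' @param sbpAbs,dbpAbs absolute mmHg cut-offs (value at or above flags).
#' @param bpPercentileCut BP percentile cut-off used when a reference table is
#'   supplied (at or above flags).
#' @param hdlLow HDL below this flags.
#' @param ldlHigh LDL at or above this flags.
#' @param units `"mmol/L"` or `"mg/dL"` for the lipid cut-offs; the mg/dL
#'   defaults are 40 and 130.
#' @param evaluationOrder permutation of `c("SBP", "HDL", "LDL", "DBP")`.
#' @return a list of class `NHLBIThresholds`.
#' @export
nhlbiThresholds <- function(sbpAbs = 120, dbpAbs = 80, bpPercentileCut = 90,
                            hdlLow = NULL, ldlHigh = NULL,
                            units = c("mmol/L", "mg/dL"),
                            evaluationOrder = c("SBP", "HDL", "LDL", "DBP")) {
  units <- match.arg(units)
  if (is.null(hdlLow)) hdlLow <- if (units == "mmol/L") 1.03 else 40
  if (is.null(ldlHigh)) ldlHigh <- if (units == "mmol/L") 3.36 else 130
  if (!setequal(evaluationOrder, c("SBP", "HDL", "LDL", "DBP")) ||
      length(evaluationOrder) != 4L)
    stop("'evaluationOrder' must be a permutation of SBP, HDL, LDL, DBP")
  structure(list(sbpAbs = sbpAbs, dbpAbs = dbpAbs,
                 bpPercentileCut = bpPercentileCut,
                 hdlLow = hdlLow, ldlHigh = ldlHigh, units = units,
                 evaluationOrder = evaluationOrder),
            class = "NHLBIThresholds")
}

#' Call the prehypertensive phenotype
#'
#' Applies the any-criterion rule: a subject is flagged when any one of high
#' SBP, low HDL, high LDL, or high DBP is present. Criteria are evaluated in
#' the threshold object's order; the first criterion met is reported as the
#' primary driver. A missing marker makes that criterion evaluate false (and
#' is counted in `n_missing`); a subject with all four markers missing is
#' uncallable (`prehypertensive = NA`), never a false negative.
#'
#' @param pheno data.frame with columns `subject_id`, `sbp`, `dbp`, `hdl`,
#'   `ldl` and optionally `age`, `sex`, `height_percentile`.
#' @param thresholds an [nhlbiThresholds()] object.
#' @param bpReference optional blood-pressure reference table (see
#'   [bpPercentile()]); when supplied, the SBP/DBP criteria use the
#'   percentile-for-age/sex/height rule instead of the absolute cut-offs.
#' @return data.frame with `subject_id`, `prehypertensive`, `criteria_hit`
#'   (comma-separated, in evaluation order), `primary_driver`, `n_missing`;
#'   the thresholds used are attached as attribute `"thresholds"`.
#' @examples
#' ph <- data.frame(subject_id = c("a", "b"), sbp = c(128, 105),
#'                  dbp = c(70, 64), hdl = c(1.3, 1.4), ldl = c(2.4, 2.2))
#' callPrehypertension(ph)
#' @export
callPrehypertension <- function(pheno, thresholds = nhlbiThresholds(),
                                bpReference = NULL) {
  thr <- thresholds
  n <- nrow(pheno)
  getcol <- function(nm) if (nm %in% names(pheno)) pheno[[nm]] else
    rep(NA_real_, n)
  sbp <- getcol("sbp"); dbp <- getcol("dbp")
  hdl <- getcol("hdl"); ldl <- getcol("ldl")

  bpHit <- function(bp, absCut, measure) {
    if (!is.null(bpReference)) {
      pct <- bpPercentile(bp, getcol("age"), pheno$sex,
                          getcol("height_percentile"), bpReference,
                          measure = measure)
      pct >= thr$bpPercentileCut
    } else bp >= absCut
  }
  crit <- list(SBP = bpHit(sbp, thr$sbpAbs, "sbp"),
               DBP = bpHit(dbp, thr$dbpAbs, "dbp"),
               HDL = hdl < thr$hdlLow,
               LDL = ldl >= thr$ldlHigh)
  crit <- crit[thr$evaluationOrder]
  hitmat <- do.call(cbind, crit)           # n x 4, NA where marker missing
  nMissing <- rowSums(is.na(hitmat))
  hits <- hitmat
  hits[is.na(hits)] <- FALSE               # missing marker => criterion false
  flag <- rowSums(hits) > 0
  flag[nMissing == 4L] <- NA               # uncallable
  criteria <- apply(hits, 1L, function(z)
    paste(thr$evaluationOrder[z], collapse = ","))
  driver <- apply(hits, 1L, function(z)
    if (any(z)) thr$evaluationOrder[which(z)[1]] else NA_character_)
  out <- data.frame(subject_id = pheno$subject_id,
                    prehypertensive = flag,
                    criteria_hit = criteria,
                    primary_driver = driver,
                    n_missing = nMissing,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thr
  out
}

#' Blood-pressure percentile for age, sex and height
#'
#' Interpolates a pluggable reference table with columns `measure`
#' (`"sbp"`/`"dbp"`), `sex`, `age`, `height_percentile`, `bp_percentile`,
#' `bp_mmHg`. For each tabulated percentile curve the mmHg value is bilinearly
#' interpolated over age and height percentile, then the subject's pressure is
#' located on the (monotone) percentile-vs-pressure curve. Pressures outside
#' the tabulated curves clamp to the extreme tabulated percentile with a
#' warning. A synthetic reference ships with the package
#' (`inst/extdata/bp_reference_synthetic.csv`).
#'
#' @param bp pressure(s), mmHg.
#' @param age years; ages outside the table's coverage raise an error naming
#'   the gap.
#' @param sex `"M"`/`"F"` (must match the table's coding).
#' @param heightPercentile height percentile (clamped to the tabulated range).
#' @param reference reference table; default loads the synthetic chart.
#' @param measure `"sbp"` or `"dbp"`.
#' @return percentile(s).
#' @export
bpPercentile <- function(bp, age, sex, heightPercentile,
                         reference = bpReference(), measure = c("sbp", "dbp")) {
  measure <- match.arg(measure)
  ref <- reference[reference$measure == measure, , drop = FALSE]
  rng <- range(ref$age)
  vapply(seq_along(bp), function(i) {
    if (is.na(bp[i])) return(NA_real_)
    if (is.na(age[i]) || age[i] < rng[1] || age[i] > rng[2])
      stop(sprintf("age %s outside reference coverage [%g, %g] years",
                   format(age[i]), rng[1], rng[2]))
    ri <- ref[ref$sex == sex[i], , drop = FALSE]
    if (!nrow(ri)) stop("sex '", sex[i], "' not covered by the reference")
    h <- heightPercentile[i]
    hTab <- sort(unique(ri$height_percentile))
    if (is.na(h)) h <- 50
    h <- min(max(h, min(hTab)), max(hTab))
    pcts <- sort(unique(ri$bp_percentile))
    vals <- vapply(pcts, function(p) {
      rp <- ri[ri$bp_percentile == p, , drop = FALSE]
      # bilinear: interpolate over height within each age, then over age
      ages <- sort(unique(rp$age))
      byAge <- vapply(ages, function(a) {
        ra <- rp[rp$age == a, , drop = FALSE]
        stats::approx(ra$height_percentile, ra$bp_mmHg, xout = h,
                      rule = 2)$y
      }, numeric(1))
      stats::approx(ages, byAge, xout = age[i])$y
    }, numeric(1))
    if (bp[i] <= vals[1]) {
      warning(sprintf("pressure %g below the tabulated %gth percentile; clamped",
                      bp[i], pcts[1]))
      return(pcts[1])
    }
    if (bp[i] >= vals[length(vals)]) {
      if (bp[i] > vals[length(vals)])
        warning(sprintf("pressure %g above the tabulated %gth percentile; clamped",
                        bp[i], pcts[length(pcts)]))
      return(pcts[length(pcts)])
    }
    stats::approx(vals, pcts, xout = bp[i], ties = "ordered")$y
  }, numeric(1))
}

#' @rdname bpPercentile
#' @export
bpReference <- function() {
  utils::read.csv(system.file("extdata", "bp_reference_synthetic.csv",
                              package = "hypergrowth"))
}

#' Prevalence by group with a relative-frequency ratio
#'
#' Tabulates, per postnatal class, how many subjects carry the phenotype flag,
#' and reports the relative frequency of the focus class against everyone
#' else: `ratio = prevalence(focus) / prevalence(others)`, with a chi-square
#' test (without continuity correction) on the 2x2 table. When the input
#' contains no non-focus subjects the ratio and p-value are `NA`.
#'
#' @param flagged logical vector of phenotype calls (`NA` = uncallable,
#'   excluded).
#' @param classes vector of group labels aligned with `flagged`.
#' @param focus the class of interest (default `"CU-SGA"`).
#' @param test `"chisq"` or `"fisher"`.
#' @return list with elements `table` (class, n, n_flagged, prevalence_pct),
#'   `focus`, `focus_prevalence_pct`, `ratio`, `p_value`, `test`.
#' @examples
#' # the two-cohort worked example: 155 flagged of 611 in the focus class
#' gp <- groupPrevalence(rep(c(TRUE, FALSE), c(155, 456)),
#'                       rep("CU-SGA", 611))
#' round(gp$focus_prevalence_pct)  # 25
#' @export
groupPrevalence <- function(flagged, classes, focus = "CU-SGA",
                            test = c("chisq", "fisher")) {
  test <- match.arg(test)
  keep <- !is.na(flagged)
  flagged <- flagged[keep]
  classes <- as.character(classes)[keep]
  if (!any(classes == focus))
    stop("focus class '", focus, "' is empty")
  tab <- do.call(rbind, lapply(split(flagged, classes), function(z)
    data.frame(n = length(z), n_flagged = sum(z))))
  tab <- data.frame(class = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  tab$prevalence_pct <- 100 * tab$n_flagged / tab$n
  inFocus <- classes == focus
  kF <- sum(flagged[inFocus]); nF <- sum(inFocus)
  kO <- sum(flagged[!inFocus]); nO <- sum(!inFocus)
  if (nO > 0) {
    ratio <- (kF / nF) / (kO / nO)
    m <- matrix(c(kF, nF - kF, kO, nO - kO), 2, byrow = TRUE)
    p <- if (test == "chisq")
      stats::chisq.test(m, correct = FALSE)$p.value
    else stats::fisher.test(m)$p.value
  } else {
    ratio <- NA_real_; p <- NA_real_
  }
  list(table = tab, focus = focus,
       focus_prevalence_pct = 100 * kF / nF,
       ratio = ratio, p_value = p, test = test)
}

#' Read a phenotype table
#' @param path CSV file with the columns described in [callPrehypertension()].
#' @return data.frame.
#' @export
readPhenotypeTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
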