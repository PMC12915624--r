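#' Gene-level miRNA expression of one sample
#'
#' Total RPM over both arms and all included read types (exclusive,
#' nontemplate-flagged and mutated reads; ambiguous reads are excluded),
#' with the log2(RPM + 1) transform used for cohort comparisons.
#'
#' @param records isomiR records of one sample x gene
#' @return list with \code{rpm} and \code{log2_level}
#' @export
geneLevel <- function(records) {
  keep <- records$source %in% c("exclusive", "snps")
  rpm <- sum(records$rpm[keep], na.rm = TRUE)
  list(rpm = rpm, log2_level = log2(rpm + 1))
}

#' Compare a single mutated sample against a wild-type cohort
#'
#' The shared engine of the cross-sample experiments: a one-sample t test
#' of the wild-type values against the hypothesized mean equal to the
#' mutated sample's value (two-sided, df = n - 1), a z-score of the mutated
#' value under the cohort's mean and standard deviation (two-sided normal
#' p), and the Tukey outlier rule (beyond 1.5 IQR below Q1 or above Q3).
#'
#' @param wt_values numeric vector of cohort values (n >= 3)
#' @param mut_value the mutated sample's value
#' @return one-row data.frame: \code{mut_value, n_wt, t_p, z, z_p, outlier,
#'   flag} (\code{flag} is \code{"ok"}, \code{"cohort_too_small"} or
#'   \code{"degenerate_cohort"}; in the degenerate cases the statistics are
#'   NA and downstream calls must be \code{ns}).
#' @export
cohortCompare <- function(wt_values, mut_value) {
  n <- length(wt_values)
  na <- data.frame(mut_value = mut_value, n_wt = n, t_p = NA_real_,
                   z = NA_real_, z_p = NA_real_, outlier = NA)
  if (n < 3L) return(cbind(na, flag = "cohort_too_small"))
  s <- stats::sd(wt_values)
  if (s == 0) return(cbind(na, flag = "degenerate_cohort"))
  t_p <- stats::t.test(wt_values, mu = mut_value)$p.value
  z <- (mut_value - mean(wt_values)) / s
  z_p <- 2 * stats::pnorm(-abs(z))
  q <- stats::quantile(wt_values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  outlier <- mut_value < q[1] - 1.5 * iqr | mut_value > q[2] + 1.5 * iqr
  data.frame(mut_value = mut_value, n_wt = n, t_p = t_p, z = z, z_p = z_p,
             outlier = outlier, flag = "ok")
}

.bonf <- function(p, m) pmin(1, p * m)

#' Cohort miRNA-level calls (Experiment 3 style)
#'
#' Each case compares the log2(RPM + 1) miRNA level of one mutated sample
#' with the wild-type cohort of the same cancer type. The fold change is
#' computed on the log scale: \code{log2fc = log2(mut RPM + 1) - mean of
#' log2(WT RPM + 1)}. A call requires all four of: Bonferroni-corrected
#' one-sample t p < alpha, z-score p < alpha, |log2FC| > min_abs_log2fc,
#' and the mutated value being an IQR outlier. The Bonferroni denominator
#' is the number of cases in the run.
#'
#' @param cases list; each element a list with \code{wt_rpm} (vector) and
#'   \code{mut_rpm} (scalar), both on the normalized RPM scale
#' @param alpha significance level for both t and z criteria
#' @param min_abs_log2fc fold-change threshold
#' @return data.frame, one row per case: cohort statistics, \code{log2fc},
#'   \code{call} in \code{increase}/\code{decrease}/\code{ns}
#' @export
runExp3 <- function(cases, alpha = 0.05, min_abs_log2fc = 1) {
  m <- length(cases)
  res <- do.call(rbind, lapply(cases, function(cs) {
    cc <- cohortCompare(log2(cs$wt_rpm + 1), log2(cs$mut_rpm + 1))
    cc$log2fc <- log2(cs$mut_rpm + 1) - mean(log2(cs$wt_rpm + 1))
    cc
  }))
  res$t_p_bonf <- .bonf(res$t_p, m)
  sig <- res$flag == "ok" & res$t_p_bonf < alpha & res$z_p < alpha &
    abs(res$log2fc) > min_abs_log2fc & res$outlier
  sig[is.na(sig)] <- FALSE
  res$call <- ifelse(sig & res$log2fc > 0, "increase",
                     ifelse(sig, "decrease", "ns"))
  rownames(res) <- NULL
  res
}

#' L1 distance between two isomiR class profiles
#'
#' Sum over classes of the absolute fraction differences; ranges from 0
#' (identical profiles) to 2 (completely disjoint class support).
#'
#' @param p,q \code{ClassProfile} objects or named fraction vectors over
#'   the same label set
#' @return numeric distance in [0, 2]
#' @export
profileDistance <- function(p, q) {
  pv <- if (is(p, "ClassProfile")) fractions(p) else p
  qv <- if (is(q, "ClassProfile")) fractions(q) else q
  if (!setequal(names(pv), names(qv)))
    stop("profiles are over different class label sets")
  sum(abs(pv - qv[names(pv)]))
}

#' Cohort isomiR-profile distance calls (Experiment 4 style)
#'
#' For each case (one mutation x arm), the reference profile is the
#' arithmetic per-class mean of the wild-type samples' profiles; the
#' mutated sample's distance to that reference is compared (same t/z
#' engine) with each wild-type sample's distance to the same reference.
#' A call requires Bonferroni-corrected t p < alpha, z p < alpha, and a
#' mutated-sample distance > min_distance.
#'
#' @param cases list; each element a list with \code{wt_profiles} (matrix,
#'   samples x classes, rows summing to 1) and \code{mut_profile} (fraction
#'   vector over the same classes, ten-class scheme)
#' @param alpha significance level
#' @param min_distance distance threshold (default 0.2)
#' @return data.frame: cohort statistics, \code{distance}, logical
#'   \code{call}
#' @export
runExp4 <- function(cases, alpha = 0.05, min_distance = 0.2) {
  m <- length(cases)
  res <- do.call(rbind, lapply(cases, function(cs) {
    ref <- colMeans(cs$wt_profiles)
    wt_d <- apply(cs$wt_profiles, 1L, function(r) sum(abs(r - ref)))
    mut_d <- sum(abs(cs$mut_profile - ref))
    cc <- cohortCompare(wt_d, mut_d)
    cc$distance <- mut_d
    cc
  }))
  res$t_p_bonf <- .bonf(res$t_p, m)
  call <- res$flag == "ok" & res$t_p_bonf < alpha & res$z_p < alpha &
    res$distance > min_distance
  call[is.na(call)] <- FALSE
  res$call <- call
  rownames(res) <- NULL
  res
}

#' 5p/3p strand balance
#'
#' \code{B = log2((c5p + 1) / (c3p + 1))} on raw counts (exclusive,
#' nontemplate and mutated reads). Antisymmetric under swapping the arms.
#'
#' @param c5p,c3p raw read counts of the 5p and 3p arms
#' @return numeric balance
#' @export
strandBalance <- function(c5p, c3p) {
  stopifnot(all(c5p >= 0), all(c3p >= 0))
  log2((c5p + 1) / (c3p + 1))
}

#' Cohort strand-balance calls (Experiment 5 style)
#'
#' Compares the mutated sample's strand balance with the wild-type cohort
#' (same t/z engine). Wild-type samples with fewer than \code{min_reads}
#' total reads for the gene are dropped from the cohort. The effect size is
#' the change in 5p fraction in percentage points:
#' \code{delta_f5p = 100 * (f5p_mut - mean(f5p_wt))}. A call requires
#' Bonferroni-corrected t p < alpha, z p < alpha, |delta_f5p| >
#' min_delta_points, and the IQR outlier rule.
#'
#' @param cases list; each element a list with \code{wt_counts} (matrix,
#'   samples x 2 columns c5p, c3p) and \code{mut_counts} (length-2 vector)
#' @param alpha significance level
#' @param min_delta_points strand-fraction change threshold (points)
#' @param min_reads cohort inclusion minimum (total reads per sample)
#' @return data.frame: cohort statistics on B, \code{f5p_mut},
#'   \code{delta_f5p}, logical \code{call}
#' @export
runExp5 <- function(cases, alpha = 0.05, min_delta_points = 10,
                    min_reads = 50) {
  m <- length(cases)
  res <- do.call(rbind, lapply(cases, function(cs) {
    wt <- cs$wt_counts[rowSums(cs$wt_counts) >= min_reads, , drop = FALSE]
    b_wt <- strandBalance(wt[, 1], wt[, 2])
    b_mut <- strandBalance(cs$mut_counts[1], cs$mut_counts[2])
    cc <- cohortCompare(b_wt, b_mut)
    f5p_wt <- wt[, 1] / rowSums(wt)
    f5p_mut <- cs$mut_counts[1] / sum(cs$mut_counts)
    cc$f5p_mut <- f5p_mut
    cc$delta_f5p <- 100 * (f5p_mut - mean(f5p_wt))
    cc
  }))
  res$t_p_bonf <- .bonf(res$t_p, m)
  call <- res$flag == "ok" & res$t_p_bonf < alpha & res$z_p < alpha &
    abs(res$delta_f5p) > min_delta_points & res$outlier
  call[is.na(call)] <- FALSE
  res$call <- call
  rownames(res) <- NULL
  res
}

#' Roll up per-experiment results into functional-mutation calls
#'
#' A mutation is functional when it is called significant in at least one
#' experiment.
#'
#' @param calls named list of data.frames, each with columns
#'   \code{mutation_id} and \code{call} (logical, or the
#'   increase/decrease/ns factor of the level experiments)
#' @return data.frame with one row per mutation: per-experiment logicals
#'   and the combined \code{functional} flag
#' @export
functionalCalls <- function(calls) {
  asLogical <- function(x) if (is.logical(x)) x else x != "ns"
  ids <- sort(unique(unlist(lapply(calls, `[[`, "mutation_id"))))
  out <- data.frame(mutation_id = ids, stringsAsFactors = FALSE)
  for (nm in names(calls)) {
    v <- rep(NA, length(ids))
    df <- calls[[nm]]
    hit <- tapply(asLogical(df$call), df$mutation_id, any)
    v[match(names(hit), ids)] <- as.logical(hit)
    out[[nm]] <- v
  }
  out$functional <- apply(out[, names(calls), drop = FALSE], 1L,
                          function(r) any(r, na.rm = TRUE))
  out
}
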