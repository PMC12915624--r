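#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric probabilities not exceeding that of
#' the observed table (the common two-sided convention). Degenerate tables
#' (any margin zero) return p = 1.
#'
#' @param a,b,c,d nonnegative integer cells, row-wise:
#'   \code{rbind(c(a, b), c(c, d))}
#' @return list with \code{p} and \code{odds_ratio} (conditional MLE)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), sum(cells) > 0)
  tab <- matrix(round(cells), 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, odds_ratio = NA_real_))
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Adjust p-values for multiple testing
#'
#' @param ps numeric vector of p-values in [0, 1]
#' @param method \code{"BH"} (step-up false discovery rate) or
#'   \code{"bonferroni"}
#' @return adjusted p-values, same length
#' @export
adjustPvalues <- function(ps, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!length(ps)) return(numeric(0))
  stopifnot(all(ps >= 0 & ps <= 1, na.rm = TRUE))
  stats::p.adjust(ps, method = method)
}

#' Allelic-fraction test of miRNA level (within-sample, Experiment 1 style)
#'
#' Compares the mutant-allele fraction among miRNA reads with the
#' mutant-allele fraction among DNA reads by Fisher's exact test. The fold
#' change is the ratio of the two mutant fractions (RNA over DNA), reported
#' as log2; when any cell is zero a Haldane-style 0.5 correction is applied
#' to all cells for the fold-change estimate only -- the exact test always
#' uses the raw counts.
#'
#' @param mut_rna,wt_rna miRNA read counts from the mutant / wild-type allele
#' @param mut_dna,wt_dna DNA read counts of the two alleles
#' @return one-row data.frame: \code{frac_dna, frac_rna, log2fc, p};
#'   \code{undefined_fc} flags a fold change that is degenerate even after
#'   correction.
#' @export
exp1Test <- function(mut_rna, wt_rna, mut_dna, wt_dna) {
  stopifnot(mut_dna + wt_dna > 0, mut_rna + wt_rna > 0)
  frac_rna <- mut_rna / (mut_rna + wt_rna)
  frac_dna <- mut_dna / (mut_dna + wt_dna)
  cells <- c(mut_rna, wt_rna, mut_dna, wt_dna)
  if (any(cells == 0)) {
    cr <- cells + 0.5
    fr <- cr[1] / (cr[1] + cr[2])
    fd <- cr[3] / (cr[3] + cr[4])
  } else {
    fr <- frac_rna
    fd <- frac_dna
  }
  undefined <- fd == 0
  log2fc <- if (undefined) NA_real_ else log2(fr / fd)
  p <- fisherExact2x2(mut_rna, wt_rna, mut_dna, wt_dna)$p
  data.frame(frac_dna = frac_dna, frac_rna = frac_rna, log2fc = log2fc,
             p = p, undefined_fc = undefined)
}

#' Batch Experiment-1 calls with multiple-testing adjustment
#'
#' @param tests data.frame with columns \code{mut_rna, wt_rna, mut_dna,
#'   wt_dna} (one row per mutation; any id columns are carried through)
#' @param alpha adjusted-p threshold for a call
#' @param min_abs_log2fc minimum |log2 fold change| for a call
#' @param method multiple-testing adjustment
#' @return input with \code{frac_dna, frac_rna, log2fc, p, p_adj, call}
#'   appended; \code{call} is \code{increase}, \code{decrease} or \code{ns}.
#' @export
runExp1 <- function(tests, alpha = 0.05, min_abs_log2fc = 1,
                    method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  res <- do.call(rbind, lapply(seq_len(nrow(tests)), function(i)
    exp1Test(tests$mut_rna[i], tests$wt_rna[i],
             tests$mut_dna[i], tests$wt_dna[i])))
  res$p_adj <- adjustPvalues(res$p, method)
  sig <- !is.na(res$log2fc) & res$p_adj < alpha &
    abs(res$log2fc) >= min_abs_log2fc
  res$call <- ifelse(sig & res$log2fc > 0, "increase",
                     ifelse(sig & res$log2fc < 0, "decrease", "ns"))
  cbind(tests, res)
}

#' Cramer's V effect size from a chi-square statistic
#'
#' \code{sqrt(chi2 / (N * min(r - 1, c - 1)))}; for the 2 x k allele-by-class
#' tables used here \code{min(r - 1, c - 1) = 1}.
#'
#' @param chi2 chi-square statistic
#' @param n grand total of the table the statistic was computed on
#' @param r,c table dimensions
#' @return V in [0, 1]
#' @export
cramersV <- function(chi2, n, r = 2L, c = 2L) {
  sqrt(chi2 / (n * min(r - 1L, c - 1L)))
}

.vStrength <- function(v) {
  cut(v, breaks = c(-Inf, 0.1, 0.2, 0.4, Inf),
      labels = c("none", "small", "medium", "large"), right = TRUE)
}

#' Allele-resolved isomiR-profile test (within-sample, Experiment 2 style)
#'
#' Pearson's chi-square independence test on the 2 x 9 allele-by-class
#' count table, with a pseudocount added to every cell, plus Cramer's V as
#' the effect size (computed on the same pseudocounted table). V strength
#' bins: none < 0.1, small 0.1-0.2, medium 0.2-0.4, large > 0.4.
#'
#' @param wt_counts,mut_counts per-class read counts of the two alleles
#'   (nine-class scheme, same ordering)
#' @param pseudocount added to each cell before testing (default 5)
#' @return one-row data.frame: \code{chi2, p, cramers_v, strength}
#' @export
exp2Test <- function(wt_counts, mut_counts, pseudocount = 5) {
  stopifnot(length(wt_counts) == length(mut_counts))
  tab <- rbind(wt_counts, mut_counts) + pseudocount
  chi2 <- unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE))$statistic)
  v <- cramersV(chi2, sum(tab), nrow(tab), ncol(tab))
  data.frame(chi2 = chi2,
             p = stats::pchisq(chi2, df = ncol(tab) - 1L, lower.tail = FALSE),
             cramers_v = v, strength = as.character(.vStrength(v)))
}

#' Batch Experiment-2 calls with multiple-testing adjustment
#'
#' A mutation is called when the adjusted chi-square p falls below
#' \code{alpha} (default 1e-11) and Cramer's V exceeds \code{min_v}
#' (default 0.2).
#'
#' @param count_pairs list of lists with elements \code{wt} and \code{mut}
#'   (per-class count vectors)
#' @param alpha adjusted-p threshold
#' @param min_v Cramer's V threshold
#' @param pseudocount see \code{\link{exp2Test}}
#' @param method multiple-testing adjustment
#' @return data.frame with \code{chi2, p, p_adj, cramers_v, strength, call}
#' @export
runExp2 <- function(count_pairs, alpha = 1e-11, min_v = 0.2,
                    pseudocount = 5, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  res <- do.call(rbind, lapply(count_pairs, function(p)
    exp2Test(p$wt, p$mut, pseudocount)))
  res$p_adj <- adjustPvalues(res$p, method)
  res$call <- res$p_adj < alpha & res$cramers_v > min_v
  rownames(res) <- NULL
  res
}

#' Pairwise Cramer's V between same-allele profiles across samples
#'
#' For validating that the V threshold separates mutation effects from
#' inter-sample noise: computes V for every pair of count vectors in the
#' group (same allele of the same miRNA in different samples), using the
#' same pseudocounted chi-square machinery as the allele comparison.
#'
#' @param count_list list of per-class count vectors (one per sample)
#' @param pseudocount see \code{\link{exp2Test}}
#' @return numeric vector of V values, empty for singleton groups
#' @export
pairwiseProfileV <- function(count_list, pseudocount = 5) {
  k <- length(count_list)
  if (k < 2L) return(numeric(0))
  idx <- utils::combn(k, 2L)
  apply(idx, 2L, function(ij)
    exp2Test(count_list[[ij[1]]], count_list[[ij[2]]],
             pseudocount)$cramers_v)
}
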