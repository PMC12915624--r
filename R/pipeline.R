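#' Run configuration
#'
#' All pipeline thresholds in one serializable object. Defaults are the
#' significance and effect-size rules of the five experiments: adjusted
#' p < 0.05 and |log2FC| >= 1 (allelic level test); adjusted chi-square
#' p < 1e-11 and Cramer's V > 0.2 (allelic isomiR test); Bonferroni t
#' p < 0.05, z p < 0.05, |log2FC| > 1 plus the IQR outlier rule (cohort
#' level test); distance > 0.2 (cohort isomiR test); > 10 percentage points
#' of 5p-fraction change plus the outlier rule (strand balance); read
#' minima 50 / 50-per-allele / 10 RPM / 20 RPM-per-arm / 50.
#'
#' @param alpha significance level shared by the t/z/Fisher criteria
#' @param e2_alpha adjusted-p threshold of the allelic isomiR test
#' @param min_v Cramer's V threshold
#' @param min_distance isomiR-profile distance threshold
#' @param min_abs_log2fc fold-change threshold (log2)
#' @param min_delta_points strand-fraction change threshold (points)
#' @param pseudocount chi-square pseudocount per class
#' @param adjust_method multiple-testing method for the within-sample tests
#' @param experiments which experiments to run
#' @param eligibility read/RPM minima (\code{\link{eligibilityThresholds}})
#' @param ambig_max_frac see \code{\link{datasetExclusions}}
#' @return classed list (\code{"RunConfig"})
#' @export
runConfig <- function(alpha = 0.05, e2_alpha = 1e-11, min_v = 0.2,
                      min_distance = 0.2, min_abs_log2fc = 1,
                      min_delta_points = 10, pseudocount = 5,
                      adjust_method = c("BH", "bonferroni"),
                      experiments = c("E1", "E2", "E3", "E4", "E5"),
                      eligibility = eligibilityThresholds(),
                      ambig_max_frac = 0.5) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(alpha > 0, e2_alpha > 0, min_v > 0, min_distance > 0,
            min_abs_log2fc > 0, min_delta_points > 0,
            all(experiments %in% c("E1", "E2", "E3", "E4", "E5")))
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the full mutation-effect pipeline
#'
#' Eligibility screening, the five per-mutation experiments, and the
#' functional-mutation roll-up, on either a simulated cohort
#' (\code{\link{simulateCohort}}) or equivalent loaded inputs.
#'
#' @param annotations a \code{MirnaGeneSet}
#' @param isomirs isomiR records (native schema, with \code{rpm})
#' @param expression genes x samples RPM matrix; when NULL it is computed
#'   from the records
#' @param mutations mutation table (\code{\link{readMutationTable}} schema)
#' @param catalog_flags optional named logical (\code{\link{datasetExclusions}})
#' @param config a \code{RunConfig}
#' @return classed list (\code{"MirnaPipelineResult"}): \code{eligibility},
#'   per-experiment result data.frames (\code{exp1}..\code{exp5}),
#'   \code{functional} roll-up, and a \code{manifest}
#' @export
runPipeline <- function(annotations, isomirs, expression = NULL, mutations,
                        catalog_flags = NULL, config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  mut <- parseMutations(mutations, annotations)
  elig <- datasetExclusions(mut, annotations, isomirs, catalog_flags,
                            ambig_max_frac = config$ambig_max_frac)
  ok <- mut[elig$verdict == "eligible", , drop = FALSE]

  if (is.null(expression)) expression <- .rpmMatrix(isomirs)
  th <- config$eligibility
  use <- isomirs$source %in% c("exclusive", "snps")

  e1_cases <- e2_cases <- e3_cases <- e4_cases <- e5_cases <- list()
  e4_meta <- list()
  for (i in seq_len(nrow(ok))) {
    m <- ok[i, ]
    g <- m$gene_id
    s <- m$sample_id
    grec <- isomirs[use & isomirs$gene_id == g, , drop = FALSE]
    srec <- grec[grec$sample_id == s, , drop = FALSE]
    arm_mut <- matureArmOf(annotations, g, m$start)
    cohort <- .cohortSamples(expression, mutations, g, s, m$cancer_type)

    # within-sample: exclusive/mutated reads, no nontemplate, no ambiguous
    al <- srec[!srec$nontemplate & srec$allele %in% c("WT", "MUT"), ,
               drop = FALSE]
    mut_rna <- sum(al$count[al$allele == "MUT"])
    wt_rna <- sum(al$count[al$allele == "WT"])
    if ("E1" %in% config$experiments &&
        experimentFilter("E1", list(in_mature = !is.na(arm_mut),
                                    total_reads = mut_rna + wt_rna),
                         th)$selected)
      e1_cases[[m$mutation_id]] <- data.frame(
        mutation_id = m$mutation_id, mut_rna = mut_rna, wt_rna = wt_rna,
        mut_dna = m$dna_alt_reads, wt_dna = m$dna_ref_reads)
    if ("E2" %in% config$experiments && !is.na(arm_mut) &&
        experimentFilter("E2", list(in_mature = TRUE,
                                    wt_reads = sum(al$count[al$allele ==
                                      "WT" & al$arm == arm_mut]),
                                    mut_reads = sum(al$count[al$allele ==
                                      "MUT" & al$arm == arm_mut])),
                         th)$selected) {
      aa <- al[al$arm == arm_mut, , drop = FALSE]
      e2_cases[[m$mutation_id]] <- list(
        wt = .classCountVec(aa[aa$allele == "WT", , drop = FALSE]),
        mut = .classCountVec(aa[aa$allele == "MUT", , drop = FALSE]))
    }

    if (length(cohort) >= 3L) {
      mut_rpm <- expression[g, s]
      wt_rpm <- expression[g, cohort]
      if ("E3" %in% config$experiments &&
          experimentFilter("E3", list(mut_rpm = mut_rpm,
                                      wt_mean_rpm = mean(wt_rpm)),
                           th)$selected)
        e3_cases[[m$mutation_id]] <- list(wt_rpm = wt_rpm,
                                          mut_rpm = mut_rpm)

      arm_rpm <- function(rec, a) sum(rec$rpm[rec$arm == a], na.rm = TRUE)
      crec <- grec[grec$sample_id %in% cohort, , drop = FALSE]
      wt_arm_mean <- function(a) {
        v <- tapply(crec$rpm[crec$arm == a], crec$sample_id[crec$arm == a],
                    sum)
        sum(v, na.rm = TRUE) / length(cohort)
      }
      if ("E4" %in% config$experiments) {
        f4 <- experimentFilter("E4", list(
          mut_rpm_5p = arm_rpm(srec, "5p"),
          wt_mean_rpm_5p = wt_arm_mean("5p"),
          mut_rpm_3p = arm_rpm(srec, "3p"),
          wt_mean_rpm_3p = wt_arm_mean("3p")), th)
        if (f4$selected) for (a in f4$arms) {
          key <- paste(m$mutation_id, a, sep = ".")
          prof <- .armProfiles(grec, c(cohort, s), a)
          if (!is.null(prof) && s %in% rownames(prof) &&
              sum(rownames(prof) != s) >= 3L) {
            e4_cases[[key]] <- list(
              wt_profiles = prof[rownames(prof) != s, , drop = FALSE],
              mut_profile = prof[s, ])
            e4_meta[[key]] <- data.frame(mutation_id = m$mutation_id,
                                         arm = a)
          }
        }
      }
      if ("E5" %in% config$experiments &&
          experimentFilter("E5", list(total_reads = sum(srec$count)),
                           th)$selected) {
        wt_counts <- t(vapply(cohort, function(cs) {
          r <- grec[grec$sample_id == cs, , drop = FALSE]
          c(sum(r$count[r$arm == "5p"]), sum(r$count[r$arm == "3p"]))
        }, numeric(2)))
        e5_cases[[m$mutation_id]] <- list(
          wt_counts = wt_counts,
          mut_counts = c(sum(srec$count[srec$arm == "5p"]),
                         sum(srec$count[srec$arm == "3p"])))
      }
    }
  }

  res <- list()
  if (length(e1_cases))
    res$exp1 <- runExp1(do.call(rbind, e1_cases), alpha = config$alpha,
                        min_abs_log2fc = config$min_abs_log2fc,
                        method = config$adjust_method)
  if (length(e2_cases)) {
    r2 <- runExp2(e2_cases, alpha = config$e2_alpha, min_v = config$min_v,
                  pseudocount = config$pseudocount,
                  method = config$adjust_method)
    res$exp2 <- cbind(data.frame(mutation_id = names(e2_cases)), r2)
  }
  if (length(e3_cases))
    res$exp3 <- cbind(data.frame(mutation_id = names(e3_cases)),
                      runExp3(e3_cases, alpha = config$alpha,
                              min_abs_log2fc = config$min_abs_log2fc))
  if (length(e4_cases))
    res$exp4 <- cbind(do.call(rbind, e4_meta),
                      runExp4(e4_cases, alpha = config$alpha,
                              min_distance = config$min_distance))
  if (length(e5_cases))
    res$exp5 <- cbind(data.frame(mutation_id = names(e5_cases)),
                      runExp5(e5_cases, alpha = config$alpha,
                              min_delta_points = config$min_delta_points,
                              min_reads = th$E5_min_reads))
  for (nm in names(res)) rownames(res[[nm]]) <- NULL

  functional <- if (length(res)) functionalCalls(res) else NULL
  manifest <- list(
    package = as.character(utils::packageVersion("mirMutImpact")),
    config_hash = configHash(config),
    n_mutations = nrow(mutations),
    n_eligible = nrow(ok),
    n_samples = ncol(expression))
  structure(c(list(eligibility = elig), res,
              list(functional = functional, manifest = manifest,
                   config = config)),
            class = "MirnaPipelineResult")
}

.rpmMatrix <- function(isomirs) {
  keep <- isomirs$source %in% c("exclusive", "snps")
  agg <- tapply(isomirs$rpm[keep],
                list(isomirs$gene_id[keep], isomirs$sample_id[keep]), sum)
  agg[is.na(agg)] <- 0
  agg
}

# wild-type cohort: same cancer type, no mutation in the gene, not the
# mutated sample itself
.cohortSamples <- function(expression, mutations, gene, sample,
                           cancer_type) {
  all_s <- colnames(expression)
  mut_s <- mutations$sample_id[mutations$gene_id == gene]
  same_type <- if ("cancer_type" %in% names(mutations)) {
    type_of <- stats::setNames(mutations$cancer_type, mutations$sample_id)
    known <- all_s %in% names(type_of)
    all_s[!known | type_of[all_s] == cancer_type]
  } else all_s
  setdiff(same_type, c(mut_s, sample))
}

.classCountVec <- function(rec) {
  labs <- classLabels("nine")
  cls <- isomirClass(rec$shift5, rec$shift3, rec$nontemplate, "nine")
  vapply(labs, function(l) sum(rec$count[cls == l]), 0)
}

# per-sample ten-class RPM-weighted profiles of one arm; rows = samples
.armProfiles <- function(grec, samples, arm) {
  labs <- classLabels("ten")
  rec <- grec[grec$arm == arm & grec$sample_id %in% samples, , drop = FALSE]
  if (!nrow(rec)) return(NULL)
  cls <- isomirClass(rec$shift5, rec$shift3, rec$nontemplate, "ten")
  agg <- tapply(rec$rpm, list(rec$sample_id, factor(cls, levels = labs)),
                sum)
  agg[is.na(agg)] <- 0
  tot <- rowSums(agg)
  agg <- agg[tot > 0, , drop = FALSE] / tot[tot > 0]
  agg[, labs, drop = FALSE]
}

#' Stable hash of a run configuration
#'
#' @param config a \code{RunConfig}
#' @return md5 string of the deparsed configuration
#' @export
configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Enrichment of functional mutations among homozygous mutations
#'
#' Compares the proportion of functional mutations between homozygous and
#' nonhomozygous groups: fold enrichment is the ratio of the two
#' proportions, significance a two-sided Fisher's exact test on the
#' implied 2x2 table.
#'
#' @param n_func_hom functional mutations among homozygous ones
#' @param n_hom total homozygous mutations
#' @param n_func_other functional mutations among the rest
#' @param n_other total nonhomozygous mutations
#' @return list: \code{prop_hom}, \code{prop_other} (percent),
#'   \code{fold_enrichment}, \code{fisher_p}, \code{odds_ratio}
#' @export
functionalEnrichment <- function(n_func_hom, n_hom, n_func_other, n_other) {
  stopifnot(n_func_hom <= n_hom, n_func_other <= n_other)
  if (n_hom == 0 || n_other == 0)
    return(list(prop_hom = NA_real_, prop_other = NA_real_,
                fold_enrichment = NA_real_, fisher_p = NA_real_,
                odds_ratio = NA_real_, note = "zero denominator"))
  ft <- fisherExact2x2(n_func_hom, n_hom - n_func_hom,
                       n_func_other, n_other - n_func_other)
  p_hom <- n_func_hom / n_hom
  p_other <- n_func_other / n_other
  list(prop_hom = 100 * p_hom, prop_other = 100 * p_other,
       fold_enrichment = p_hom / p_other, fisher_p = ft$p,
       odds_ratio = ft$odds_ratio)
}

#' @export
print.MirnaPipelineResult <- function(x, ...) {
  cat("MirnaPipelineResult\n")
  cat(sprintf("  mutations: %d input, %d eligible\n",
              x$manifest$n_mutations, x$manifest$n_eligible))
  for (e in c("exp1", "exp2", "exp3", "exp4", "exp5")) {
    if (is.null(x[[e]])) next
    cl <- x[[e]]$call
    hits <- if (is.logical(cl)) sum(cl) else sum(cl != "ns")
    cat(sprintf("  %s: %d tested, %d called\n", e, nrow(x[[e]]), hits))
  }
  if (!is.null(x$functional))
    cat(sprintf("  functional mutations: %d\n", sum(x$functional$functional)))
  invisible(x)
}

#' Serialize a pipeline result bundle to TSV files
#'
#' Deterministic plain-text output: eligibility report, one TSV per
#' experiment, the functional roll-up, and the manifest as key-value
#' pairs.
#'
#' @param result a \code{MirnaPipelineResult}
#' @param dir output directory
#' @return invisibly, the files written
#' @export
writeResultBundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(result$eligibility, "eligibility.tsv")
  for (e in c("exp1", "exp2", "exp3", "exp4", "exp5"))
    if (!is.null(result[[e]])) wr(result[[e]], paste0(e, ".tsv"))
  if (!is.null(result$functional)) wr(result$functional, "functional.tsv")
  mf <- result$manifest
  wr(data.frame(key = names(mf), value = unlist(lapply(mf, as.character))),
     "manifest.tsv")
  invisible(files)
}
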