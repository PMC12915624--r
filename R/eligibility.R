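#' Dataset-level exclusion screening
#'
#' Applies the nine dataset-level exclusion criteria to every input
#' mutation and produces one auditable report row per mutation (reporting,
#' never silently failing). Criteria: (i) redundant (multicopy) miRNA
#' genes; (ii) more than one mutation in the same gene and sample;
#' (iii) indels longer than 4 nt; (iv) samples with no small-RNA data;
#' (v) genes with an undefined mature arm; (vi) samples with multiple
#' small-RNA datasets; (vii) no reads mapped to the gene in the mutated
#' sample; (viii) an excessive share of ambiguous reads in the gene
#' (default > 50\% of the gene's reads in that sample, configurable);
#' (ix) mutations in or within 2 nt of a mature miRNA that are absent from
#' the external variant catalog (supplied as a flag, since such reads
#' cannot be allele-resolved by the mapper).
#'
#' @param mutations parsed mutation table (\code{\link{parseMutations}})
#' @param annotations a \code{MirnaGeneSet}
#' @param reads isomiR records for all samples
#' @param catalog_flags named logical vector by \code{mutation_id}; TRUE
#'   when the mutation is annotated in the external catalog. Missing names
#'   default to TRUE.
#' @param datasets_per_sample optional named integer: number of small-RNA
#'   datasets per sample. When NULL, every sample present in \code{reads}
#'   is assumed to have exactly one.
#' @param ambig_max_frac threshold for criterion (viii)
#' @return data.frame: \code{mutation_id}, \code{verdict}
#'   (eligible/excluded), \code{reasons} (semicolon-joined codes)
#' @export
datasetExclusions <- function(mutations, annotations, reads,
                              catalog_flags = NULL,
                              datasets_per_sample = NULL,
                              ambig_max_frac = 0.5) {
  n <- nrow(mutations)
  reasons <- vector("list", n)
  add <- function(i, code) reasons[[i]] <<- c(reasons[[i]], code)

  rej <- rejectedGenes(annotations)
  dup <- duplicated(mutations[, c("gene_id", "sample_id")]) |
    duplicated(mutations[, c("gene_id", "sample_id")], fromLast = TRUE)

  gene_sample_tot <- tapply(reads$count,
                            paste(reads$gene_id, reads$sample_id), sum)
  amb <- reads$source == "ambiguous"
  gene_sample_amb <- tapply(reads$count[amb],
    paste(reads$gene_id[amb], reads$sample_id[amb]), sum)
  samples_with_data <- unique(reads$sample_id)

  for (i in seq_len(n)) {
    g <- mutations$gene_id[i]
    s <- mutations$sample_id[i]
    mid <- mutations$mutation_id[i]
    if (g %in% geneIds(annotations)) {
      if (!is.na(annotations@anno$redundant_group[.geneRow(annotations, g)]))
        add(i, "redundant_gene")
    } else {
      rr <- rej$reason[match(g, rej$gene_id)]
      add(i, if (!is.na(rr)) rr else "gene_unknown")
    }
    if (dup[i]) add(i, "multi_mutation_same_gene_sample")
    pe <- mutations$parse_error[i]
    if (!is.na(pe)) add(i, pe)
    if (!is.null(datasets_per_sample)) {
      k <- datasets_per_sample[s]
      if (is.na(k) || k == 0) add(i, "no_srna_data")
      else if (k > 1) add(i, "multiple_srna_datasets")
    } else if (!s %in% samples_with_data) {
      add(i, "no_srna_data")
    }
    key <- paste(g, s)
    tot <- gene_sample_tot[key]
    if (is.na(tot) || tot == 0) {
      if (s %in% samples_with_data) add(i, "no_reads_in_gene")
    } else {
      a <- gene_sample_amb[key]
      if (!is.na(a) && a / tot > ambig_max_frac) add(i, "many_ambiguous_reads")
    }
    in_cat <- if (is.null(catalog_flags)) TRUE
              else { v <- catalog_flags[mid]; is.na(v) || isTRUE(unname(v)) }
    if (!in_cat && isTRUE(.nearMature(annotations, g, mutations$start[i])))
      add(i, "not_in_catalog")
  }
  data.frame(
    mutation_id = mutations$mutation_id,
    verdict = ifelse(lengths(reasons) > 0, "excluded", "eligible"),
    reasons = vapply(reasons, function(r)
      paste(unique(r), collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

# inside a mature miRNA or within 2 nt of its ends (the DROSHA/DICER1
# cleavage sites); NA when the gene or position is unavailable
.nearMature <- function(annotations, gene_id, position) {
  if (is.na(position) || !gene_id %in% geneIds(annotations)) return(NA)
  m5 <- matureSpan(annotations, gene_id, "5p")
  m3 <- matureSpan(annotations, gene_id, "3p")
  (position >= m5[1] - 2 & position <= m5[2] + 2) ||
    (position >= m3[1] - 2 & position <= m3[2] + 2)
}

#' Is a position inside a canonical mature miRNA span?
#'
#' @param annotations a \code{MirnaGeneSet}
#' @param gene_id gene id
#' @param position n. coordinate
#' @return \code{"5p"}, \code{"3p"} or NA when outside both arms
#' @export
matureArmOf <- function(annotations, gene_id, position) {
  if (is.na(position)) return(NA_character_)
  m5 <- matureSpan(annotations, gene_id, "5p")
  m3 <- matureSpan(annotations, gene_id, "3p")
  if (position >= m5[1] && position <= m5[2]) "5p"
  else if (position >= m3[1] && position <= m3[2]) "3p"
  else NA_character_
}

#' Default per-experiment inclusion thresholds
#'
#' Read-depth and expression minima applied before each experiment:
#' 50 total reads (level, within-sample), 50 reads per allele (isomiR,
#' within-sample), 10 RPM (level, cross-sample), 20 RPM per strand
#' (isomiR, cross-sample), 50 total reads (strand balance).
#'
#' @return named list of thresholds
#' @export
eligibilityThresholds <- function() {
  list(E1_min_reads = 50, E2_min_allele_reads = 50, E3_min_rpm = 10,
       E4_min_arm_rpm = 20, E5_min_reads = 50)
}

#' Per-experiment inclusion filter
#'
#' Decides whether an (eligible) mutation enters a given experiment, from
#' summary statistics of its read support. The within-sample experiments
#' additionally require the mutation to lie inside a mature miRNA span.
#'
#' @param experiment one of \code{"E1"}..\code{"E5"}
#' @param stats list of the statistics the experiment's filter consumes:
#'   E1: \code{in_mature}, \code{total_reads}; E2: \code{in_mature},
#'   \code{wt_reads}, \code{mut_reads}; E3: \code{mut_rpm},
#'   \code{wt_mean_rpm}; E4: \code{mut_rpm_5p}, \code{wt_mean_rpm_5p},
#'   \code{mut_rpm_3p}, \code{wt_mean_rpm_3p}; E5: \code{total_reads}.
#' @param thresholds see \code{\link{eligibilityThresholds}}
#' @return list with \code{selected} (logical), \code{reason} (NA when
#'   selected) and, for E4, \code{arms} (character vector of strands
#'   passing the per-arm filter)
#' @export
experimentFilter <- function(experiment = c("E1", "E2", "E3", "E4", "E5"),
                             stats, thresholds = eligibilityThresholds()) {
  experiment <- match.arg(experiment)
  sel <- function(ok, reason) list(selected = ok,
                                   reason = if (ok) NA_character_ else reason)
  switch(experiment,
    E1 = {
      if (!isTRUE(stats$in_mature)) return(sel(FALSE, "not_in_mature"))
      sel(stats$total_reads >= thresholds$E1_min_reads, "min_reads_50")
    },
    E2 = {
      if (!isTRUE(stats$in_mature)) return(sel(FALSE, "not_in_mature"))
      sel(min(stats$wt_reads, stats$mut_reads) >=
            thresholds$E2_min_allele_reads, "min_allele_reads_50")
    },
    E3 = sel(min(stats$mut_rpm, stats$wt_mean_rpm) >= thresholds$E3_min_rpm,
             "min_rpm_10"),
    E4 = {
      arms <- c("5p", "3p")[c(
        min(stats$mut_rpm_5p, stats$wt_mean_rpm_5p) >=
          thresholds$E4_min_arm_rpm,
        min(stats$mut_rpm_3p, stats$wt_mean_rpm_3p) >=
          thresholds$E4_min_arm_rpm)]
      out <- sel(length(arms) > 0, "min_arm_rpm_20")
      out$arms <- arms
      out
    },
    E5 = sel(stats$total_reads >= thresholds$E5_min_reads, "min_reads_50"))
}
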