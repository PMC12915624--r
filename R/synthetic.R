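#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model behind \code{\link{simulateCohort}}: a
#' per-cancer-type cohort of wild-type samples with log-normal gene
#' expression, Beta-distributed 5p/3p arm balance, and
#' Dirichlet-multinomial isomiR class counts (the overdispersion knob is
#' the Dirichlet concentration). These distributions are the simulator's
#' stated model of sample-to-sample variability, chosen to emulate the
#' statistical structure the cohort experiments assume.
#'
#' @param n_wt_samples wild-type cohort size (default 50)
#' @param n_genes number of simulated miRNA genes
#' @param library_size sequencing depth, reads per sample
#' @param expr_meanlog,expr_sdlog_gene log-normal baseline RPM across genes
#' @param expr_sdlog_sample log-normal sample-to-sample expression noise
#' @param class_template length-10 fraction vector over the isomiR classes
#'   (ten-class order of \code{classLabels("ten")}); the Dirichlet mean
#' @param class_concentration Dirichlet concentration (larger = less
#'   overdispersion)
#' @param f5p_mean,f5p_concentration Beta model of the per-sample 5p arm
#'   fraction
#' @param dna_depth DNA sequencing depth at mutation loci
#' @param ambiguous_rate expected share of ambiguous-source reads
#' @param hairpin_length L of the synthetic precursors
#' @return classed list (\code{"SimulationConfig"})
#' @export
simulationConfig <- function(n_wt_samples = 50L, n_genes = 1L,
                             library_size = 2e6,
                             expr_meanlog = log(1000),
                             expr_sdlog_gene = 1,
                             expr_sdlog_sample = 0.5,
                             class_template = c(0.45, 0.12, 0.10, 0.08,
                                                0.06, 0.05, 0.04, 0.03,
                                                0.03, 0.04),
                             class_concentration = 300,
                             f5p_mean = 0.8, f5p_concentration = 200,
                             dna_depth = 100L, ambiguous_rate = 0.01,
                             hairpin_length = 80L) {
  stopifnot(n_wt_samples > 0, n_genes > 0, library_size > 0,
            length(class_template) == 10L, all(class_template > 0),
            abs(sum(class_template) - 1) < 1e-8,
            class_concentration > 0, f5p_mean > 0, f5p_mean < 1,
            f5p_concentration > 0, dna_depth > 0, ambiguous_rate >= 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Injected effect of one simulated mutation
#'
#' Effect kinds mirror the pipeline's three endpoints: a level multiplier
#' acting on the mutant allele's output, a class shift moving probability
#' mass between isomiR classes of the mutant allele, and a strand shift
#' setting the mutant allele's 5p fraction. \code{level_multiplier = 1}
#' with no shifts is the null effect.
#'
#' @param mutation_id,gene_id,sample_id identifiers; the sample is created
#'   as an extra (mutated) sample of the cohort
#' @param vaf_dna DNA variant allele fraction in [0, 1]
#' @param level_multiplier lambda >= 0 scaling the mutant allele's output
#' @param class_shift NULL or list(from =, to =, mass =): class labels and
#'   the fraction mass moved from one to the other
#' @param strand_shift NA or the mutant allele's target 5p fraction
#' @param homozygous flag carried into the mutation table
#' @param hgvs_n variant token for the emitted mutation table; the default
#'   places a substitution inside the synthetic 3p mature span
#' @return classed list (\code{"EffectSpec"})
#' @export
effectSpec <- function(mutation_id, gene_id, sample_id, vaf_dna = 0.5,
                       level_multiplier = 1, class_shift = NULL,
                       strand_shift = NA_real_, homozygous = FALSE,
                       hgvs_n = NULL) {
  stopifnot(vaf_dna >= 0, vaf_dna <= 1, level_multiplier >= 0)
  if (!is.null(class_shift)) {
    stopifnot(all(c("from", "to", "mass") %in% names(class_shift)),
              class_shift$mass >= 0, class_shift$mass <= 1,
              all(c(class_shift$from, class_shift$to) %in%
                    classLabels("ten")))
  }
  if (!is.na(strand_shift))
    stopifnot(strand_shift > 0, strand_shift < 1)
  structure(as.list(environment()), class = "EffectSpec")
}

.CLASS_SHIFTS <- data.frame(
  class = c("0|0", "0|-", "0|+", "+|0", "-|0", "+|-", "-|+", "+|+", "-|-",
            "(nt)"),
  shift5 = c(0L, 0L, 0L, 1L, -1L, 1L, -1L, 1L, -1L, 0L),
  shift3 = c(0L, -1L, 1L, 0L, 0L, -1L, 1L, 1L, -1L, 0L),
  nontemplate = c(rep(FALSE, 9L), TRUE),
  stringsAsFactors = FALSE)

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

.applyClassShift <- function(frac, shift) {
  i <- match(shift$from, colnames(frac))
  j <- match(shift$to, colnames(frac))
  moved <- pmin(frac[, i], shift$mass)
  frac[, i] <- frac[, i] - moved
  frac[, j] <- frac[, j] + moved
  frac
}

#' Synthetic miRNA gene annotations
#'
#' Random-sequence precursors with fixed-layout mature spans, used as the
#' coordinate frame of simulated cohorts (gene ids \code{SIMG001}, ...).
#' Sequences are drawn from the active RNG.
#'
#' @param n_genes number of genes
#' @param L hairpin length (>= 60)
#' @return a \code{MirnaGeneSet}; mature spans are 5p 6..27 and 3p
#'   L-29..L-8
#' @export
syntheticAnnotation <- function(n_genes, L = 80L) {
  stopifnot(L >= 60L)
  ids <- sprintf("SIMG%03d", seq_len(n_genes))
  rand <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                   replace = TRUE), collapse = "")
  anno <- data.frame(gene_id = ids, precursor_id = tolower(ids), L = L,
                     m5_start = 6L, m5_end = 27L,
                     m3_start = L - 29L, m3_end = L - 8L,
                     redundant_group = NA_character_,
                     stringsAsFactors = FALSE)
  precursor <- vapply(ids, function(g) rand(L), "")
  flank5 <- vapply(ids, function(g) rand(25L), "")
  flank3 <- vapply(ids, function(g) rand(25L), "")
  MirnaGeneSet(anno, precursor, flank5, flank3)
}

#' RNA-level mutant fraction implied by DNA VAF and a level multiplier
#'
#' The mutant allele contributes \code{vaf * lambda} of the gene's output
#' and the wild-type allele \code{1 - vaf}, so the expected mutant read
#' fraction is \code{vaf * lambda / (1 - vaf + vaf * lambda)}.
#'
#' @param vaf_dna DNA variant allele fraction
#' @param lambda mutant-allele level multiplier
#' @return expected mutant fraction at the RNA level
#' @export
rnaMutantFraction <- function(vaf_dna, lambda) {
  denom <- 1 - vaf_dna + vaf_dna * lambda
  ifelse(denom == 0, 0, vaf_dna * lambda / denom)
}

#' Simulate an allele-resolved isomiR cohort with known injected effects
#'
#' Draws a cohort of wild-type samples i.i.d. from the generative model of
#' \code{\link{simulationConfig}} plus one extra sample per mutated sample
#' id named in the effects, applies each effect to the mutant allele of its
#' gene, and emits the native schemas: an isomiR record table (exclusive /
#' snps / ambiguous sources, classes mapped to representative end shifts),
#' an RPM expression matrix, a mutation table (with binomially drawn DNA
#' allele counts at the configured depth), and a truth table. Fully
#' reproducible for a fixed seed.
#'
#' @param config a \code{SimulationConfig}
#' @param effects list of \code{EffectSpec}s (possibly empty)
#' @param seed integer seed
#' @return classed list (\code{"MirnaCohortSim"}) with elements
#'   \code{annotations}, \code{isomirs}, \code{expression} (genes x
#'   samples), \code{mutations}, \code{truth}, \code{config}, \code{seed}
#' @export
simulateCohort <- function(config, effects = list(), seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(as.integer(seed))
  genes <- sprintf("SIMG%03d", seq_len(config$n_genes))
  bad <- vapply(effects, function(e) !e$gene_id %in% genes, TRUE)
  if (any(bad)) stop("effect references unknown gene")
  annotations <- syntheticAnnotation(config$n_genes, config$hairpin_length)

  wt_samples <- sprintf("WT%03d", seq_len(config$n_wt_samples))
  mut_samples <- unique(vapply(effects, `[[`, "", "sample_id"))
  samples <- c(wt_samples, mut_samples)
  nS <- length(samples)
  labs <- classLabels("ten")

  baseline <- stats::rlnorm(config$n_genes, config$expr_meanlog,
                            config$expr_sdlog_gene)
  names(baseline) <- genes
  f5p_gene <- stats::rbeta(config$n_genes,
                           config$f5p_mean * config$f5p_concentration,
                           (1 - config$f5p_mean) * config$f5p_concentration)
  names(f5p_gene) <- genes
  alpha <- config$class_template * config$class_concentration

  eff_gene <- vapply(effects, `[[`, "", "gene_id")
  eff_sample <- vapply(effects, `[[`, "", "sample_id")

  recs <- vector("list", config$n_genes)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    mu <- baseline[[g]] *
      stats::rlnorm(nS, 0, config$expr_sdlog_sample)
    v_rna <- numeric(nS)
    e_idx <- rep(NA_integer_, nS)
    for (k in which(eff_gene == g)) {
      si <- match(eff_sample[k], samples)
      e <- effects[[k]]
      mu[si] <- mu[si] * (1 - e$vaf_dna + e$vaf_dna * e$level_multiplier)
      v_rna[si] <- rnaMutantFraction(e$vaf_dna, e$level_multiplier)
      e_idx[si] <- k
    }
    tot <- stats::rpois(nS, mu / 1e6 * config$library_size)
    mut_tot <- stats::rbinom(nS, tot, v_rna)
    wt_tot <- tot - mut_tot
    f5p_s <- stats::rbeta(nS, f5p_gene[[g]] * config$f5p_concentration,
                          (1 - f5p_gene[[g]]) * config$f5p_concentration)
    frac5 <- .rdirichlet(nS, alpha)
    frac3 <- .rdirichlet(nS, alpha)
    colnames(frac5) <- colnames(frac3) <- labs

    c5_wt <- stats::rbinom(nS, wt_tot, f5p_s)
    c3_wt <- wt_tot - c5_wt
    cls_wt5 <- .classCounts(c5_wt, frac5)
    cls_wt3 <- .classCounts(c3_wt, frac3)
    out <- list(
      .armRecords(samples, g, "5p", cls_wt5, "WT", "exclusive"),
      .armRecords(samples, g, "3p", cls_wt3, "WT", "exclusive"))

    mut_rows <- which(mut_tot > 0)
    if (length(mut_rows)) {
      f5p_m <- f5p_s
      frac5m <- frac5
      frac3m <- frac3
      for (si in mut_rows) {
        e <- effects[[e_idx[si]]]
        if (!is.na(e$strand_shift)) f5p_m[si] <- e$strand_shift
        if (!is.null(e$class_shift)) {
          frac5m[si, ] <- .applyClassShift(frac5[si, , drop = FALSE],
                                           e$class_shift)
          frac3m[si, ] <- .applyClassShift(frac3[si, , drop = FALSE],
                                           e$class_shift)
        }
      }
      c5_mut <- stats::rbinom(nS, mut_tot, f5p_m)
      c3_mut <- mut_tot - c5_mut
      out <- c(out, list(
        .armRecords(samples, g, "5p", .classCounts(c5_mut, frac5m),
                    "MUT", "snps"),
        .armRecords(samples, g, "3p", .classCounts(c3_mut, frac3m),
                    "MUT", "snps")))
    }
    if (config$ambiguous_rate > 0) {
      amb <- stats::rpois(nS, config$ambiguous_rate * mu / 1e6 *
                            config$library_size)
      keep <- amb > 0
      if (any(keep))
        out <- c(out, list(data.frame(
          sample_id = samples[keep], gene_id = g, arm = "5p",
          shift5 = 0L, shift3 = 0L, nontemplate = FALSE, allele = "AMBIG",
          source = "ambiguous", count = as.numeric(amb[keep]),
          stringsAsFactors = FALSE)))
    }
    recs[[gi]] <- do.call(rbind, out)
  }
  isomirs <- do.call(rbind, recs)
  isomirs$rpm <- isomirs$count / config$library_size * 1e6
  rownames(isomirs) <- NULL

  keep <- isomirs$source %in% c("exclusive", "snps")
  expression <- matrix(0, config$n_genes, nS,
                       dimnames = list(genes, samples))
  agg <- tapply(isomirs$rpm[keep],
                list(isomirs$gene_id[keep], isomirs$sample_id[keep]), sum)
  expression[rownames(agg), colnames(agg)] <-
    ifelse(is.na(agg), 0, agg)

  mutations <- do.call(rbind, lapply(effects, function(e) {
    alt <- stats::rbinom(1L, config$dna_depth, e$vaf_dna)
    hg <- e$hgvs_n
    if (is.null(hg)) {
      pos <- config$hairpin_length - 25L  # inside the synthetic 3p arm
      ref <- substr(extendedSequence(annotations, e$gene_id),
                    nToIndex(pos, config$hairpin_length),
                    nToIndex(pos, config$hairpin_length))
      alt_base <- setdiff(c("A", "C", "G", "U"), ref)[1L]
      hg <- sprintf("n.%d%s>%s", pos, ref, alt_base)
    }
    data.frame(mutation_id = e$mutation_id, gene_id = e$gene_id,
               sample_id = e$sample_id, cancer_type = "SIM", hgvs_n = hg,
               dna_ref_reads = config$dna_depth - alt, dna_alt_reads = alt,
               homozygous = e$homozygous, stringsAsFactors = FALSE)
  }))

  truth <- do.call(rbind, lapply(effects, function(e) data.frame(
    mutation_id = e$mutation_id, gene_id = e$gene_id,
    sample_id = e$sample_id, vaf_dna = e$vaf_dna,
    level_multiplier = e$level_multiplier,
    class_shift_mass = if (is.null(e$class_shift)) 0 else e$class_shift$mass,
    strand_shift = e$strand_shift,
    affects_level = e$level_multiplier != 1,
    affects_isomir = !is.null(e$class_shift),
    affects_strand = !is.na(e$strand_shift),
    stringsAsFactors = FALSE)))

  structure(list(annotations = annotations, isomirs = isomirs,
                 expression = expression, mutations = mutations,
                 truth = truth, config = config, seed = as.integer(seed)),
            class = "MirnaCohortSim")
}

.classCounts <- function(n_per_sample, frac) {
  k <- ncol(frac)
  out <- matrix(0L, length(n_per_sample), k)
  for (i in which(n_per_sample > 0))
    out[i, ] <- stats::rmultinom(1L, n_per_sample[i], frac[i, ])[, 1L]
  out
}

.armRecords <- function(samples, gene, arm, counts, allele, source) {
  labs <- classLabels("ten")
  nz <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(nz)) return(NULL)
  sh <- .CLASS_SHIFTS[match(labs[nz[, 2L]], .CLASS_SHIFTS$class), ]
  data.frame(sample_id = samples[nz[, 1L]], gene_id = gene, arm = arm,
             shift5 = sh$shift5, shift3 = sh$shift3,
             nontemplate = sh$nontemplate, allele = allele, source = source,
             count = as.numeric(counts[nz]), stringsAsFactors = FALSE)
}

#' @export
print.MirnaCohortSim <- function(x, ...) {
  cat(sprintf(paste0("MirnaCohortSim: %d genes x %d samples, ",
                     "%d mutation(s), %d isomiR records (seed %d)\n"),
              x$config$n_genes, ncol(x$expression),
              if (is.null(x$mutations)) 0L else nrow(x$mutations),
              nrow(x$isomirs), x$seed))
  invisible(x)
}

#' Write a simulated cohort to the native TSV schemas
#'
#' @param sim a \code{MirnaCohortSim}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("isomirs.tsv", "expression.tsv", "mutations.tsv",
                        "truth.tsv"))
  writeIsomirTable(sim$isomirs, p[1])
  utils::write.table(data.frame(gene_id = rownames(sim$expression),
                                sim$expression, check.names = FALSE),
                     p[2], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$mutations))
    utils::write.table(sim$mutations, p[3], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(sim$truth))
    utils::write.table(sim$truth, p[4], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(p)
}
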