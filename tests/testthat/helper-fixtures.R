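# Shared fixtures and independent oracles, built in code.

# deterministic two-gene annotation set: L = 60, arms 5..26 / 34..55
toyGeneSet <- function() {
  pre <- strrep("ACGU", 15L)              # 60 nt
  f5 <- strrep("G", 25L)
  f3 <- strrep("C", 25L)
  anno <- data.frame(
    gene_id = c("GENE1", "GENE2"),
    precursor_id = c("gene1", "gene2"),
    L = 60L, m5_start = 5L, m5_end = 26L, m3_start = 34L, m3_end = 55L,
    redundant_group = NA_character_, stringsAsFactors = FALSE)
  MirnaGeneSet(anno,
               precursor = c(GENE1 = pre, GENE2 = pre),
               flank5 = c(GENE1 = f5, GENE2 = f5),
               flank3 = c(GENE1 = f3, GENE2 = f3))
}

toyRecords <- function(sample = "S1", gene = "GENE1", arm = "3p",
                       counts, alleles = "WT") {
  # counts: named vector class label -> count (ten-class labels)
  sh <- mirMutImpact:::.CLASS_SHIFTS
  i <- match(names(counts), sh$class)
  stopifnot(!anyNA(i))
  data.frame(sample_id = sample, gene_id = gene, arm = arm,
             shift5 = sh$shift5[i], shift3 = sh$shift3[i],
             nontemplate = sh$nontemplate[i], allele = alleles,
             source = ifelse(alleles == "MUT", "snps", "exclusive"),
             count = as.numeric(counts), rpm = as.numeric(counts),
             stringsAsFactors = FALSE)
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher test
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  c2 <- b + d
  if (r1 == 0 || c + d == 0 || c1 == 0 || c2 == 0) return(1)
  k <- max(0, r1 - c2):min(r1, c1)
  probs <- dhyper(k, c1, c2, r1)
  p_obs <- dhyper(a, c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force chi-square statistic, Sum (O - E)^2 / E
chisqOracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

randomProfile <- function(k = 10L) {
  v <- rgamma(k, 1)
  v <- v / sum(v)
  names(v) <- classLabels("ten")
  v
}
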