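test_that("annotation FASTA + TSV round trip, arm rejection and redundancy", {
  dir <- withr::local_tempdir()
  pre <- strrep("AUGC", 15L)
  ext <- paste0(strrep("G", 25L), pre, strrep("C", 25L))
  writeLines(c(">GENE1", ext, ">GENE2", ext, ">GENE3", ext,
               ">GENE4", pre), file.path(dir, "ref.fa"))
  tsv <- file.path(dir, "coords.tsv")
  writeLines(c(
    "gene_id\tprecursor_id\tL\tmature5p_span\tmature3p_span\tredundant_group",
    "GENE1\tgene1\t60\t5-26\t34-55\t",
    "GENE2\tgene2\t60\t5-26\t34-55\tMIRX",
    "GENE3\tgene3\t60\t5-26\t\t",       # no 3p arm
    "GENE4\tgene4\t60\t5-26\t34-55\tMIRX"), tsv)
  gs <- readMirnaAnnotations(file.path(dir, "ref.fa"), tsv)

  expect_equal(length(gs), 2L)
  expect_equal(precursorLength(gs, "GENE1"), 60L)
  expect_equal(extendedSequence(gs, "GENE1"), ext)
  expect_equal(matureSpan(gs, "GENE1", "5p"), c(5L, 26L))
  rej <- rejectedGenes(gs)
  expect_equal(rej$reason[rej$gene_id == "GENE3"], "arm_undefined")
  expect_equal(rej$reason[rej$gene_id == "GENE4"], "bad_flank")
  # multicopy genes are loaded and flagged, not dropped
  expect_equal(gs@anno$redundant_group[gs@anno$gene_id == "GENE2"], "MIRX")
})

test_that("miRBase-style GFF3 coordinates convert to precursor frame", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "mir.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1\t.\tmiRNA_primary_transcript\t1000\t1059\t.\t+\t.",
          "ID=MI001;Name=mir-1", sep = "\t"),
    paste("chr1\t.\tmiRNA\t1004\t1025\t.\t+\t.",
          "ID=MIMAT1;Name=miR-1-5p;Derives_from=MI001", sep = "\t"),
    paste("chr1\t.\tmiRNA\t1033\t1054\t.\t+\t.",
          "ID=MIMAT2;Name=miR-1-3p;Derives_from=MI001", sep = "\t"),
    # minus-strand gene: relative coordinates must flip
    paste("chr2\t.\tmiRNA_primary_transcript\t2000\t2059\t.\t-\t.",
          "ID=MI002;Name=mir-2", sep = "\t"),
    paste("chr2\t.\tmiRNA\t2034\t2055\t.\t-\t.",
          "ID=MIMAT3;Name=miR-2-5p;Derives_from=MI002", sep = "\t"),
    paste("chr2\t.\tmiRNA\t2005\t2026\t.\t-\t.",
          "ID=MIMAT4;Name=miR-2-3p;Derives_from=MI002", sep = "\t")), gff)
  ext <- paste0(strrep("G", 25L), strrep("AUGC", 15L), strrep("C", 25L))
  writeLines(c(">MIR-1", ext, ">MIR-2", ext), file.path(dir, "ref.fa"))
  gs <- readMirnaAnnotations(file.path(dir, "ref.fa"), gff, dialect = "gff3")
  expect_equal(matureSpan(gs, "MIR-1", "5p"), c(5L, 26L))
  expect_equal(matureSpan(gs, "MIR-1", "3p"), c(34L, 55L))
  expect_equal(matureSpan(gs, "MIR-2", "5p"), c(5L, 26L))
  expect_equal(matureSpan(gs, "MIR-2", "3p"), c(34L, 55L))
})

test_that("n.-style variant tokens parse, validate and format back", {
  v <- parseNVariant("n.35C>T", L = 87)
  expect_equal(v[c("kind", "start", "ref", "alt")],
               list(kind = "substitution", start = 35, ref = "C", alt = "T"))
  v <- parseNVariant("n.-6C>G", L = 72)
  expect_equal(v$start, -6)
  v <- parseNVariant("n.5-7delAGC", L = 85)
  expect_equal(v[c("kind", "start", "end", "ref")],
               list(kind = "deletion", start = 5, end = 7, ref = "AGC"))
  v <- parseNVariant("n.97_98dupGG", L = 110)
  expect_equal(v[c("kind", "alt")], list(kind = "duplication", alt = "GGGG"))

  expect_error(parseNVariant("n.5_10delAAAAAA", 60), class = "long_indel")
  expect_error(parseNVariant("n.0A>C", 60), class = "out_of_range")
  expect_error(parseNVariant("n.90A>C", 60), class = "out_of_range")
  expect_error(parseNVariant("rubbish", 60), class = "bad_token")

  # parse and format are mutually inverse on in-range tokens
  toks <- c("n.35C>T", "n.-6C>G", "n.5_7delAGC", "n.97_98dupGG",
            "n.10_11insAC", "n.12delA", "n.-2_1delGGA")
  for (tk in toks)
    expect_equal(formatNVariant(parseNVariant(tk, 110)), tk)
})

test_that("reference-allele check distinguishes match from mismatch", {
  gs <- toyGeneSet()
  # precursor is ACGUACGU...; n.1 = A, n.2 = C
  expect_true(checkRefAllele(gs, "GENE1", parseNVariant("n.2C>G", 60)))
  expect_error(checkRefAllele(gs, "GENE1", parseNVariant("n.2A>G", 60)),
               class = "ref_mismatch")
  # flank5 is all G
  expect_true(checkRefAllele(gs, "GENE1", parseNVariant("n.-6G>A", 60)))
})

test_that("subregion labels partition the whole coordinate range", {
  gs <- toyGeneSet()
  pos <- seq_n(-25, 85)
  lab <- subregion(gs, "GENE1", pos)
  expect_false(any(lab == ""))  # total
  expect_equal(subregion(gs, "GENE1", c(-6, 1, 5, 6, 13, 30, 34, 35, 56, 85)),
               c("flank5", "flank5", "duplex5p", "seed5p", "duplex5p",
                 "loop", "duplex3p", "seed3p", "flank3", "flank3"))
  # seed is mature positions 2-8 of each arm
  expect_equal(sum(lab == "seed5p"), 7L)
  expect_equal(sum(lab == "seed3p"), 7L)
  expect_error(subregion(gs, "GENE1", 0), class = "out_of_range")
})

test_that("native isomiR tables round-trip byte-identically", {
  rec <- data.frame(
    sample_id = c("S1", "S1", "S2"), gene_id = "GENE1",
    arm = c("5p", "3p", "5p"), shift5 = c(0L, 1L, -2L),
    shift3 = c(0L, -1L, 2L), nontemplate = c(FALSE, TRUE, FALSE),
    allele = c("WT", "MUT", "WT"),
    source = c("exclusive", "snps", "exclusive"),
    count = c(10, 5, 3), rpm = c(100, 50, 30), stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  writeIsomirTable(rec, f1)
  back <- readIsomirTable(f1)
  writeIsomirTable(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(back$count, rec$count)
})

test_that("native dialect rejects malformed input hard", {
  f <- withr::local_tempfile()
  writeLines(c("sample_id\tgene_id\tarm\tshift5\tshift3\tnontemplate\tallele\tsource\tcount\tbogus",
               "S1\tG1\t5p\t0\t0\tFALSE\tWT\texclusive\t5\tx"), f)
  expect_error(readIsomirTable(f), "unknown columns")
  writeLines(c("sample_id\tgene_id\tarm\tshift5\tshift3\tnontemplate\tallele\tsource\tcount",
               "S1\tG1\t5p\t0\t0\tFALSE\tWT\texclusive\t-5"), f)
  expect_error(readIsomirTable(f), "negative")
})

test_that("out-of-range end shifts are rejected with a reason, not dropped", {
  f <- withr::local_tempfile()
  writeLines(c("sample_id\tgene_id\tarm\tshift5\tshift3\tnontemplate\tallele\tsource\tcount",
               "S1\tG1\t5p\t12\t0\tFALSE\tWT\texclusive\t5",
               "S1\tG1\t5p\t1\t0\tFALSE\tWT\texclusive\t7"), f)
  rec <- readIsomirTable(f)
  expect_equal(nrow(rec), 1L)
  rej <- attr(rec, "rejected")
  expect_equal(rej$reason, "shift_out_of_range")
  expect_equal(rej$shift5, 12L)
})

test_that("isomirmap dialect maps the documented column subset", {
  f <- withr::local_tempfile()
  writeLines(c("hairpin\tmature\tshift_5p\tshift_3p\tnt_additions\treads\textra",
               "mir-21\tmiR-21-5p\t0\t1\t\t120\tz",
               "mir-21\tmiR-21-3p\t-1\t0\tUU\t30\tz"), f)
  expect_warning(rec <- readIsomirTable(f, dialect = "isomirmap",
                                        sample_id = "S9",
                                        source = "exclusive"),
                 "ignoring")
  expect_equal(rec$gene_id, c("MIR-21", "MIR-21"))
  expect_equal(rec$arm, c("5p", "3p"))
  expect_equal(rec$nontemplate, c(FALSE, TRUE))
  expect_equal(rec$allele, c("WT", "WT"))
  # snps files produce mutant-allele records
  writeLines(c("hairpin\tmature\tshift_5p\tshift_3p\tnt_additions\treads",
               "mir-21\tmiR-21-5p\t0\t0\t\t44"), f)
  rec <- readIsomirTable(f, dialect = "isomirmap", sample_id = "S9",
                         source = "snps")
  expect_equal(rec$allele, "MUT")
  expect_equal(rec$source, "snps")
})

test_that("mutation tables parse against the annotation frame", {
  gs <- toyGeneSet()
  f <- withr::local_tempfile()
  writeLines(c(
    "mutation_id\tgene_id\tsample_id\tcancer_type\thgvs_n\tdna_ref_reads\tdna_alt_reads\thomozygous",
    "M1\tGENE1\tS1\tLUAD\tn.2C>G\t60\t40\tFALSE",
    "M2\tGENE1\tS2\tLUAD\tn.5_10delACGUAC\t50\t50\tFALSE",
    "M3\tNOPE\tS3\tLUAD\tn.2C>G\t50\t50\tTRUE"), f)
  mut <- parseMutations(readMutationTable(f), gs)
  expect_equal(mut$parse_error, c(NA, "long_indel", "gene_unknown"))
  expect_equal(mut$subregion[1], "flank5")  # n.2 precedes the 5p mature start
  expect_equal(mut$kind[1], "substitution")
})
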