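.ISOMIR_COLS <- c("sample_id", "gene_id", "arm", "shift5", "shift3",
                  "nontemplate", "allele", "source", "count", "rpm")

#' Read an isomiR-resolved read table
#'
#' Loads per-sample isomiR observations into the native schema: one row per
#' (sample, gene, arm, 5p-shift, 3p-shift, nontemplate-flag, allele) with a
#' raw count and optional RPM. Two dialects are supported:
#'
#' \describe{
#'   \item{\code{native}}{TSV with header \code{sample_id, gene_id, arm,
#'     shift5, shift3, nontemplate, allele, source, count[, rpm]}. Unknown
#'     columns are a hard error; negative counts are a hard error.}
#'   \item{\code{isomirmap}}{minimal column subset of isoMiRmap output files
#'     (one file per sample and read type): \code{hairpin} (gene),
#'     \code{mature} (name ending -5p/-3p), \code{shift_5p}, \code{shift_3p},
#'     \code{nt_additions} (empty when templated), \code{reads}, and for
#'     "snps" files \code{allele}. Any other column is ignored with a
#'     warning. \code{sample_id} and \code{source} (exclusive / ambiguous /
#'     snps) are supplied by the caller since they are encoded in the file
#'     name, not the table.}
#' }
#'
#' Rows whose end shifts exceed 10 nt in absolute value are rejected (reason
#' \code{shift_out_of_range}) and returned in the \code{"rejected"}
#' attribute rather than silently dropped.
#'
#' @param path TSV file
#' @param dialect \code{"native"} or \code{"isomirmap"}
#' @param sample_id,source required for the isomirmap dialect
#' @return data.frame in the native schema; attribute \code{"rejected"}
#'   holds refused rows with a \code{reason} column.
#' @export
readIsomirTable <- function(path, dialect = c("native", "isomirmap"),
                            sample_id = NULL,
                            source = c("exclusive", "ambiguous", "snps")) {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (dialect == "native") {
    unknown <- setdiff(names(tab), .ISOMIR_COLS)
    if (length(unknown))
      stop("unknown columns in native isomiR table: ",
           paste(unknown, collapse = ", "))
    missing <- setdiff(setdiff(.ISOMIR_COLS, "rpm"), names(tab))
    if (length(missing))
      stop("native isomiR table lacks columns: ",
           paste(missing, collapse = ", "))
    if (is.null(tab$rpm)) tab$rpm <- NA_real_
    rec <- tab
  } else {
    source <- match.arg(source)
    if (is.null(sample_id))
      stop("sample_id is required for the isomirmap dialect")
    need <- c("hairpin", "mature", "shift_5p", "shift_3p", "nt_additions",
              "reads")
    missing <- setdiff(need, names(tab))
    if (length(missing))
      stop("isomirmap table lacks columns: ", paste(missing, collapse = ", "))
    extra <- setdiff(names(tab), c(need, "allele"))
    if (length(extra))
      warning("ignoring isomirmap columns: ", paste(extra, collapse = ", "))
    arm <- ifelse(grepl("-5p$", tab$mature), "5p",
                  ifelse(grepl("-3p$", tab$mature), "3p", NA))
    if (anyNA(arm)) stop("mature names must end in -5p or -3p")
    rec <- data.frame(
      sample_id = sample_id, gene_id = toupper(tab$hairpin), arm = arm,
      shift5 = as.integer(tab$shift_5p), shift3 = as.integer(tab$shift_3p),
      nontemplate = !is.na(tab$nt_additions) & nzchar(tab$nt_additions),
      allele = if (source == "snps" && !is.null(tab$allele)) tab$allele
               else if (source == "snps") "MUT"
               else if (source == "ambiguous") "AMBIG" else "WT",
      source = source, count = as.integer(tab$reads), rpm = NA_real_,
      stringsAsFactors = FALSE)
  }
  validateIsomirRecords(rec)
}

#' Validate isomiR records against the schema invariants
#'
#' @param rec data.frame in the native schema
#' @return the records with types normalized; out-of-range shifts are moved
#'   to the \code{"rejected"} attribute. Negative counts are a hard error.
#' @export
validateIsomirRecords <- function(rec) {
  rec$shift5 <- as.integer(rec$shift5)
  rec$shift3 <- as.integer(rec$shift3)
  rec$count <- as.numeric(rec$count)
  rec$nontemplate <- as.logical(rec$nontemplate)
  if (any(rec$count < 0, na.rm = TRUE)) stop("negative counts")
  if (!all(rec$arm %in% c("5p", "3p"))) stop("arm must be 5p or 3p")
  if (!all(rec$allele %in% c("WT", "MUT", "AMBIG", "NA")))
    stop("allele must be WT, MUT, AMBIG or NA")
  if (!all(rec$source %in% c("exclusive", "ambiguous", "snps")))
    stop("source must be exclusive, ambiguous or snps")
  bad <- abs(rec$shift5) > 10L | abs(rec$shift3) > 10L
  rejected <- rec[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "shift_out_of_range"
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, rejected = rejected)
}

#' Write isomiR records in the native TSV dialect
#'
#' Deterministic formatting so that read/write round trips are
#' byte-identical.
#'
#' @param rec records in the native schema
#' @param path output file
#' @export
writeIsomirTable <- function(rec, path) {
  out <- rec[, intersect(.ISOMIR_COLS, names(rec)), drop = FALSE]
  out$nontemplate <- ifelse(out$nontemplate, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a somatic mutation table
#'
#' TSV with header \code{mutation_id, gene_id, sample_id, cancer_type,
#' hgvs_n, dna_ref_reads, dna_alt_reads, homozygous}.
#'
#' @param path TSV file
#' @return data.frame with typed columns
#' @export
readMutationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mutation_id", "gene_id", "sample_id", "cancer_type", "hgvs_n",
            "dna_ref_reads", "dna_alt_reads", "homozygous")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("mutation table lacks columns: ", paste(missing, collapse = ", "))
  tab$dna_ref_reads <- as.integer(tab$dna_ref_reads)
  tab$dna_alt_reads <- as.integer(tab$dna_alt_reads)
  tab$homozygous <- as.logical(tab$homozygous)
  if (any(tab$dna_ref_reads < 0 | tab$dna_alt_reads < 0, na.rm = TRUE))
    stop("negative DNA read counts")
  tab
}

#' Parse and annotate a mutation table against the reference frame
#'
#' Adds parsed variant fields (\code{kind}, \code{start}, \code{end},
#' \code{ref}, \code{alt}), the subregion label, and a \code{parse_error}
#' column holding the error code (\code{long_indel}, \code{out_of_range},
#' \code{ref_mismatch}, \code{bad_token}, \code{gene_unknown}) for rows
#' that fail -- parsing problems are recorded, not thrown, so that
#' eligibility reporting can account for every input mutation.
#'
#' @param mutations data.frame from \code{\link{readMutationTable}}
#' @param annotations a \code{MirnaGeneSet}
#' @return the mutation table with parsed columns appended
#' @export
parseMutations <- function(mutations, annotations) {
  n <- nrow(mutations)
  mutations$kind <- mutations$ref <- mutations$alt <- NA_character_
  mutations$start <- mutations$end <- NA_integer_
  mutations$subregion <- NA_character_
  mutations$parse_error <- NA_character_
  for (i in seq_len(n)) {
    g <- mutations$gene_id[i]
    if (!g %in% geneIds(annotations)) {
      mutations$parse_error[i] <- "gene_unknown"
      next
    }
    L <- precursorLength(annotations, g)
    v <- tryCatch(parseNVariant(mutations$hgvs_n[i], L),
                  mirMutImpactError = function(e) conditionClass1(e))
    if (is.character(v)) {
      mutations$parse_error[i] <- v
      next
    }
    err <- tryCatch({checkRefAllele(annotations, g, v); NA_character_},
                    mirMutImpactError = function(e) conditionClass1(e))
    mutations$kind[i] <- v$kind
    mutations$start[i] <- v$start
    mutations$end[i] <- v$end
    mutations$ref[i] <- v$ref
    mutations$alt[i] <- v$alt
    mutations$subregion[i] <- subregion(annotations, g, v$start)
    mutations$parse_error[i] <- err
  }
  mutations
}

conditionClass1 <- function(e) class(e)[1L]
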