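#' @import methods
NULL

#' Set of miRNA gene annotations
#'
#' Container for the reference frame every position in the pipeline is
#' measured against: one row per miRNA gene, holding the precursor (hairpin)
#' sequence, the two 25-nt flanking sequences, and the coordinates of the
#' canonical 5p and 3p mature miRNAs in precursor (n.) coordinates.
#'
#' Coordinate frame: n.1 is the first nucleotide of the pre-miRNA hairpin;
#' the 5' flank is numbered -25..-1 (there is no position 0) and the 3'
#' flank L+1..L+25, where L is the hairpin length.
#'
#' Genes failing the annotation invariants (an undefined mature arm, a flank
#' that is not exactly 25 nt) are not silently dropped: they are recorded in
#' the \code{rejected} slot with a reason code.
#'
#' @slot anno data.frame with columns \code{gene_id}, \code{precursor_id},
#'   \code{L}, \code{m5_start}, \code{m5_end}, \code{m3_start},
#'   \code{m3_end}, \code{redundant_group} (NA when the gene is single-copy).
#' @slot precursor named character vector of hairpin sequences (length L).
#' @slot flank5,flank3 named character vectors of 25-nt flanking sequences.
#' @slot rejected data.frame with columns \code{gene_id}, \code{reason};
#'   reason codes are \code{"arm_undefined"} and \code{"bad_flank"}.
#' @export
setClass("MirnaGeneSet",
  representation(
    anno = "data.frame",
    precursor = "character",
    flank5 = "character",
    flank3 = "character",
    rejected = "data.frame"
  )
)

setValidity("MirnaGeneSet", function(object) {
  a <- object@anno
  need <- c("gene_id", "precursor_id", "L", "m5_start", "m5_end",
            "m3_start", "m3_end", "redundant_group")
  if (!all(need %in% names(a)))
    return(paste("anno lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (anyDuplicated(a$gene_id)) return("duplicated gene_id")
  ids <- a$gene_id
  for (sl in c("precursor", "flank5", "flank3")) {
    v <- slot(object, sl)
    if (!identical(sort(names(v)), sort(ids)))
      return(sprintf("names of @%s do not match gene ids", sl))
  }
  if (nrow(a) == 0L) return(TRUE)
  if (any(nchar(object@precursor[ids]) != a$L))
    return("precursor length disagrees with L")
  if (any(nchar(object@flank5) != 25L) || any(nchar(object@flank3) != 25L))
    return("flanks must be exactly 25 nt")
  bad <- a$m5_start < 1 | a$m5_end > a$L | a$m3_start < 1 | a$m3_end > a$L |
    a$m5_start > a$m5_end | a$m3_start > a$m3_end | a$m5_end >= a$m3_start
  if (any(bad))
    return(paste("invalid mature spans for:",
                 paste(a$gene_id[bad], collapse = ", ")))
  TRUE
})

#' @describeIn MirnaGeneSet-class number of annotated genes
#' @param x,object a \code{MirnaGeneSet}
#' @export
setMethod("length", "MirnaGeneSet", function(x) nrow(x@anno))

setMethod("show", "MirnaGeneSet", function(object) {
  cat(sprintf("MirnaGeneSet with %d gene(s), %d rejected\n",
              length(object), nrow(object@rejected)))
  if (length(object) > 0) {
    n <- min(5L, length(object))
    print(object@anno[seq_len(n), , drop = FALSE], row.names = FALSE)
    if (length(object) > n) cat("  ...\n")
  }
})

#' @describeIn MirnaGeneSet-class ids of the accepted genes
#' @export
geneIds <- function(x) x@anno$gene_id

#' @describeIn MirnaGeneSet-class genes rejected at load time, with reasons
#' @export
rejectedGenes <- function(x) x@rejected

#' Accessors for a single gene's annotation
#'
#' @param x a \code{MirnaGeneSet}
#' @param gene_id a single gene id present in \code{x}
#' @param arm \code{"5p"} or \code{"3p"}
#' @return \code{precursorLength}: integer hairpin length L.
#'   \code{matureSpan}: integer vector \code{c(start, end)} in n. coordinates.
#' @export
precursorLength <- function(x, gene_id) {
  i <- .geneRow(x, gene_id)
  x@anno$L[i]
}

#' @rdname precursorLength
#' @export
matureSpan <- function(x, gene_id, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  i <- .geneRow(x, gene_id)
  if (arm == "5p") c(x@anno$m5_start[i], x@anno$m5_end[i])
  else c(x@anno$m3_start[i], x@anno$m3_end[i])
}

.geneRow <- function(x, gene_id) {
  stopifnot(length(gene_id) == 1L)
  i <- match(gene_id, x@anno$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  i
}

#' Normalized isomiR class profile
#'
#' Fraction vector over the isomiR classes for one (sample, gene, arm,
#' allele) combination, together with the total weight (raw reads or RPM)
#' behind it. Fractions always sum to 1.
#'
#' @slot labels ordered character vector of class labels
#' @slot fractions nonnegative numeric of the same length, summing to 1
#' @slot n total weight (reads or RPM) the profile was built from
#' @export
setClass("ClassProfile",
  representation(labels = "character", fractions = "numeric", n = "numeric"))

setValidity("ClassProfile", function(object) {
  if (length(object@labels) != length(object@fractions))
    return("labels and fractions differ in length")
  if (any(object@fractions < 0)) return("negative fraction")
  if (abs(sum(object@fractions) - 1) > 1e-9)
    return("fractions must sum to 1")
  if (length(object@n) != 1L || object@n <= 0) return("n must be positive")
  TRUE
})

setMethod("show", "ClassProfile", function(object) {
  cat(sprintf("ClassProfile (n = %g)\n", object@n))
  v <- round(object@fractions, 4)
  names(v) <- object@labels
  print(v)
})

#' @describeIn ClassProfile-class fractions as a named numeric vector
#' @param object a \code{ClassProfile}
#' @export
fractions <- function(object) {
  v <- object@fractions
  names(v) <- object@labels
  v
}
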