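.mirError <- function(code, msg) {
  stop(errorCondition(msg, class = c(code, "mirMutImpactError",
                                     "error", "condition")))
}

# number of n. positions in [start, end] -- position 0 does not exist
.spanLength <- function(start, end) {
  if (start < 0 && end > 0) end - start else end - start + 1L
}

#' Parse an n.-style variant token
#'
#' Parses the HGVS-like grammar used for noncoding miRNA gene variants:
#' substitutions \code{n.35C>T} (including flank positions, \code{n.-6C>G}),
#' deletions \code{n.5-7delAGC} / \code{n.5_7delAGC}, duplications
#' \code{n.97_98dupGG}, and insertions \code{n.10_11insA}. Positions are in
#' precursor coordinates (1 = first hairpin nucleotide, 5' flank -25..-1,
#' 3' flank L+1..L+25; no position 0).
#'
#' @param token variant string, e.g. \code{"n.-6C>G"}
#' @param L hairpin length of the gene the token refers to
#' @return list with \code{kind} (substitution/deletion/duplication/
#'   insertion), \code{start}, \code{end}, \code{ref}, \code{alt}
#' @section Errors: condition class \code{"long_indel"} for indel spans
#'   longer than 4 nt, \code{"out_of_range"} for positions outside
#'   [-25, L+25] or zero, \code{"bad_token"} for unparseable input.
#' @export
parseNVariant <- function(token, L) {
  stopifnot(length(token) == 1L)
  m <- regmatches(token,
    regexec("^n\\.(-?\\d+)([ACGTU])>([ACGTU])$", token))[[1]]
  if (length(m) == 4L) {
    pos <- as.integer(m[2])
    nToIndex(pos, L)
    return(list(kind = "substitution", start = pos, end = pos,
                ref = m[3], alt = m[4]))
  }
  m <- regmatches(token,
    regexec("^n\\.(-?\\d+)(?:_(-?\\d+)|-(\\d+))?(del|dup|ins)([ACGTU]*)$",
            token))[[1]]
  if (length(m) != 6L) .mirError("bad_token", paste("unparseable:", token))
  start <- as.integer(m[2])
  end <- if (nzchar(m[3])) as.integer(m[3])
         else if (nzchar(m[4])) as.integer(m[4]) else start
  op <- m[5]
  seq <- m[6]
  nToIndex(c(start, end), L)
  if (end < start) .mirError("bad_token", paste("reversed span:", token))
  span <- .spanLength(start, end)
  if (op == "ins") {
    if (!nzchar(seq)) .mirError("bad_token", "insertion without sequence")
    if (span != 2L)
      .mirError("bad_token", "insertion span must be two adjacent positions")
    if (nchar(seq) > 4L) .mirError("long_indel", paste("indel > 4 nt:", token))
    return(list(kind = "insertion", start = start, end = end,
                ref = "", alt = seq))
  }
  if (span > 4L) .mirError("long_indel", paste("indel > 4 nt:", token))
  if (nzchar(seq) && nchar(seq) != span)
    .mirError("bad_token", "stated sequence length disagrees with span")
  if (op == "del")
    list(kind = "deletion", start = start, end = end, ref = seq, alt = "")
  else
    list(kind = "duplication", start = start, end = end, ref = seq,
         alt = paste0(seq, seq))
}

#' Format a parsed variant back to its n.-style token
#'
#' Inverse of \code{\link{parseNVariant}} (canonical form: underscore range
#' separator, explicit sequences).
#'
#' @param v list as returned by \code{parseNVariant}
#' @return character token
#' @export
formatNVariant <- function(v) {
  switch(v$kind,
    substitution = sprintf("n.%d%s>%s", v$start, v$ref, v$alt),
    deletion = if (v$start == v$end) sprintf("n.%ddel%s", v$start, v$ref)
               else sprintf("n.%d_%ddel%s", v$start, v$end, v$ref),
    duplication = if (v$start == v$end) sprintf("n.%ddup%s", v$start, v$ref)
                  else sprintf("n.%d_%ddup%s", v$start, v$end, v$ref),
    insertion = sprintf("n.%d_%dins%s", v$start, v$end, v$alt),
    stop("unknown kind: ", v$kind))
}

#' Check a variant's stated reference allele against the annotation
#'
#' @param x a \code{MirnaGeneSet}
#' @param gene_id gene the variant lies in
#' @param v parsed variant (\code{\link{parseNVariant}})
#' @return invisibly TRUE; signals condition class \code{"ref_mismatch"}
#'   when the stated reference bases disagree with the annotated sequence.
#' @export
checkRefAllele <- function(x, gene_id, v) {
  if (!nzchar(v$ref)) return(invisible(TRUE))
  L <- precursorLength(x, gene_id)
  ext <- extendedSequence(x, gene_id)
  idx <- nToIndex(seq_n(v$start, v$end), L)
  have <- paste(strsplit(ext, "")[[1]][idx], collapse = "")
  # DNA/RNA alphabet equivalence
  norm <- function(s) chartr("U", "T", toupper(s))
  if (norm(have) != norm(v$ref))
    .mirError("ref_mismatch",
              sprintf("%s: annotation has %s at n.%d..%d, token states %s",
                      gene_id, have, v$start, v$end, v$ref))
  invisible(TRUE)
}

#' Sequence of n. coordinates between two positions (skipping zero)
#' @param from,to n. coordinates, \code{from <= to}
#' @return integer vector
#' @export
seq_n <- function(from, to) setdiff(seq.int(from, to), 0L)
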