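#' IsomiR class labels
#'
#' The nine basic end-shift classes in their canonical order (reference
#' class first), optionally extended with the "(nt)" class collecting reads
#' with nontemplated 3' additions.
#'
#' @param scheme \code{"nine"} or \code{"ten"}
#' @return character vector of labels
#' @export
classLabels <- function(scheme = c("nine", "ten")) {
  scheme <- match.arg(scheme)
  base <- c("0|0", "0|-", "0|+", "+|0", "-|0", "+|-", "-|+", "+|+", "-|-")
  if (scheme == "ten") c(base, "(nt)") else base
}

#' End shifts of a read against the canonical mature span
#'
#' Shifts are signed offsets of the read's ends against the annotated
#' mature ends, positive meaning a downstream (3'-ward) shift of that end:
#' \code{shift5 = read_start - span_start}, \code{shift3 = read_end -
#' span_end}. A read shifted +1 at the 5p end is 1 nt shorter at that end.
#'
#' @param read_start,read_end read boundaries in n. coordinates
#' @param span_start,span_end canonical mature span
#' @return list with \code{shift5}, \code{shift3} (vectorized)
#' @export
endShifts <- function(read_start, read_end, span_start, span_end) {
  stopifnot(all(read_start <= read_end))
  list(shift5 = as.integer(read_start - span_start),
       shift3 = as.integer(read_end - span_end))
}

#' Basic isomiR class of an end-shift pair
#'
#' Maps the signs of the 5p and 3p end shifts to one of the nine basic
#' labels (5p|3p notation; "0|0" is the canonical isomiR). Under the
#' ten-class scheme any read with a nontemplated 3' modification is routed
#' to the "(nt)" class regardless of its shifts.
#'
#' @param shift5,shift3 integer shifts
#' @param nontemplate logical flag(s)
#' @param scheme \code{"nine"} or \code{"ten"}
#' @return character vector of class labels
#' @export
isomirClass <- function(shift5, shift3, nontemplate = FALSE,
                        scheme = c("nine", "ten")) {
  scheme <- match.arg(scheme)
  sgn <- function(x) c("-", "0", "+")[sign(x) + 2L]
  lab <- paste0(sgn(shift5), "|", sgn(shift3))
  if (scheme == "ten") {
    nontemplate <- rep_len(as.logical(nontemplate), length(lab))
    lab[nontemplate] <- "(nt)"
  }
  lab
}

#' Build a class profile from isomiR records
#'
#' Sums the chosen weight (raw counts or RPM) of the records within each
#' isomiR class and normalizes to fractions. Records are expected to come
#' from a single (sample, gene, arm, allele) combination; the function does
#' not check this so that callers can deliberately pool.
#'
#' @param records data.frame in the native isomiR schema
#' @param scheme \code{"nine"} or \code{"ten"}
#' @param weight \code{"count"} or \code{"rpm"}
#' @return a \code{\linkS4class{ClassProfile}}
#' @section Errors: condition class \code{"empty_profile"} when the total
#'   weight is zero.
#' @export
buildProfile <- function(records, scheme = c("nine", "ten"),
                         weight = c("count", "rpm")) {
  scheme <- match.arg(scheme)
  weight <- match.arg(weight)
  labs <- classLabels(scheme)
  w <- records[[weight]]
  if (is.null(w) || sum(w, na.rm = TRUE) <= 0)
    .mirError("empty_profile", "no positive weight in records")
  cls <- isomirClass(records$shift5, records$shift3, records$nontemplate,
                     scheme)
  agg <- vapply(labs, function(l) sum(w[cls == l], na.rm = TRUE), 0)
  new("ClassProfile", labels = labs, fractions = unname(agg) / sum(agg),
      n = sum(agg))
}

#' Profile over 5p-end shifts only (5p-isomiRs)
#'
#' Coarsens the isomiR classification to the exact 5p-end shift, ignoring
#' the 3p end: labels are \code{"s|n"} with s the signed shift (e.g.
#' \code{"+1|n"}, \code{"0|n"}, \code{"-2|n"}).
#'
#' @inheritParams buildProfile
#' @return named numeric vector of fractions with attribute \code{"n"}
#'   (total weight), ordered by increasing shift
#' @export
fivepProfile <- function(records, weight = c("count", "rpm")) {
  weight <- match.arg(weight)
  w <- records[[weight]]
  if (is.null(w) || sum(w, na.rm = TRUE) <= 0)
    .mirError("empty_profile", "no positive weight in records")
  tot <- tapply(w, records$shift5, sum)
  sh <- sort(as.integer(names(tot)))
  v <- as.numeric(tot[as.character(sh)]) / sum(tot)
  names(v) <- paste0(ifelse(sh > 0, "+", ""), sh, "|n")
  attr(v, "n") <- sum(tot)
  v
}

#' Serialize class profiles to the profile TSV schema
#'
#' One row per class: \code{sample_id, gene_id, arm, allele, class,
#' fraction, n_reads}.
#'
#' @param profile a \code{ClassProfile}
#' @param sample_id,gene_id,arm,allele identifying labels
#' @return data.frame
#' @export
profileToTable <- function(profile, sample_id, gene_id, arm, allele) {
  data.frame(sample_id = sample_id, gene_id = gene_id, arm = arm,
             allele = allele, class = profile@labels,
             fraction = profile@fractions, n_reads = profile@n,
             stringsAsFactors = FALSE)
}
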