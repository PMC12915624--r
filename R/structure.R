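#' Apply a parsed variant to an extended precursor sequence
#'
#' Substitutions replace in place; deletions remove the span; duplications
#' insert a second copy of the span immediately after it; insertions place
#' the new bases between the two flanking positions. Coordinates are n.
#' positions interpreted against the gene's hairpin length \code{L}; the
#' sequence is the extended (flank + hairpin + flank) string.
#'
#' @param extended_seq character string of length L + 50
#' @param v parsed variant (\code{\link{parseNVariant}})
#' @param L hairpin length
#' @return mutant sequence (length changes by the indel size)
#' @section Errors: condition class \code{"ref_mismatch"} when the variant's
#'   stated reference disagrees with the sequence.
#' @export
mutateSequence <- function(extended_seq, v, L) {
  stopifnot(nchar(extended_seq) == L + 50L)
  norm <- function(s) chartr("U", "T", toupper(s))
  chars <- strsplit(extended_seq, "")[[1]]
  idx <- nToIndex(seq_n(v$start, v$end), L)
  have <- paste(chars[idx], collapse = "")
  if (nzchar(v$ref) && norm(have) != norm(v$ref))
    .mirError("ref_mismatch",
              sprintf("sequence has %s at n.%d..%d, variant states %s",
                      have, v$start, v$end, v$ref))
  alphaU <- grepl("U", extended_seq, fixed = TRUE)
  fix <- function(s) if (alphaU) chartr("T", "U", toupper(s)) else norm(s)
  out <- switch(v$kind,
    substitution = {
      chars[idx] <- strsplit(fix(v$alt), "")[[1]]
      paste(chars, collapse = "")
    },
    deletion = paste(chars[-idx], collapse = ""),
    duplication = paste0(substr(extended_seq, 1L, max(idx)), fix(have),
                         substring(extended_seq, max(idx) + 1L)),
    insertion = paste0(substr(extended_seq, 1L, min(idx)), fix(v$alt),
                       substring(extended_seq, min(idx) + 1L)),
    stop("unknown kind: ", v$kind))
  out
}

#' Deterministic hairpin-ladder folding stub
#'
#' A synthetic stability proxy used when no thermodynamic folding engine is
#' wanted: the sequence is paired against its own reverse (first half with
#' second half) and each complementary pair contributes a fixed bonus
#' (G:C 3, A:U/A:T 2, G:U 1 arbitrary units, negated). It is deterministic,
#' platform-independent and sensitive to mutations, but its values are NOT
#' free energies; use \code{\link{viennaFoldBackend}} for real
#' minimum-free-energy estimates.
#'
#' @return a fold backend: list with \code{fold(sequence) -> dG} and
#'   \code{name}
#' @export
ladderFoldBackend <- function() {
  list(
    name = "ladder-stub",
    fold = function(sequence) {
      s <- chartr("T", "U", toupper(sequence))
      ch <- strsplit(s, "")[[1]]
      n <- length(ch)
      k <- n %/% 2L
      left <- ch[seq_len(k)]
      right <- rev(ch)[seq_len(k)]
      pair <- paste0(left, right)
      -sum(c("GC" = 3, "CG" = 3, "AU" = 2, "UA" = 2, "GU" = 1,
             "UG" = 1)[pair], na.rm = TRUE)
    })
}

#' ViennaRNA (RNAfold) folding backend
#'
#' Minimum-free-energy folding via the \code{RNAfold} executable, when
#' available on the PATH. Optional: no pipeline result depends on it.
#'
#' @param exe path to the RNAfold binary
#' @return a fold backend (see \code{\link{ladderFoldBackend}})
#' @export
viennaFoldBackend <- function(exe = Sys.which("RNAfold")) {
  if (!nzchar(exe)) stop("RNAfold not found on PATH")
  list(
    name = "RNAfold",
    fold = function(sequence) {
      out <- system2(exe, "--noPS", input = chartr("T", "U",
                                                   toupper(sequence)),
                     stdout = TRUE)
      m <- regmatches(out[2], regexec("\\((\\s*-?[0-9.]+)\\)$", out[2]))[[1]]
      as.numeric(m[2])
    })
}

#' Fold a sequence with a backend
#'
#' @param sequence nucleotide string
#' @param backend a fold backend
#' @return dG estimate (kcal/mol for thermodynamic backends)
#' @export
foldSequence <- function(sequence, backend = ladderFoldBackend()) {
  dg <- backend$fold(sequence)
  stopifnot(is.finite(dg))
  dg
}

#' Precursor stability change of a mutation
#'
#' \code{ddg = dg_mut - dg_wt}; positive values destabilize the mutant
#' hairpin.
#'
#' @param dg_wt,dg_mut folding energies of the wild-type and mutant
#'   extended precursors
#' @param mutation_id optional identifier
#' @param backend_name name of the backend the energies came from
#' @return one-row data.frame (\code{mutation_id, dg_wt, dg_mut, ddg,
#'   backend})
#' @export
ddg <- function(dg_wt, dg_mut, mutation_id = NA_character_,
                backend_name = NA_character_) {
  stopifnot(is.finite(dg_wt), is.finite(dg_mut))
  data.frame(mutation_id = mutation_id, dg_wt = dg_wt, dg_mut = dg_mut,
             ddg = dg_mut - dg_wt, backend = backend_name,
             stringsAsFactors = FALSE)
}

#' Fold wild-type and mutant precursors for a batch of mutations
#'
#' @param annotations a \code{MirnaGeneSet}
#' @param mutations parsed mutation table (rows with parse errors are
#'   skipped)
#' @param backend fold backend
#' @return data.frame of stability records
#' @export
stabilityRecords <- function(annotations, mutations,
                             backend = ladderFoldBackend()) {
  keep <- is.na(mutations$parse_error)
  out <- lapply(which(keep), function(i) {
    g <- mutations$gene_id[i]
    L <- precursorLength(annotations, g)
    wt <- extendedSequence(annotations, g)
    v <- list(kind = mutations$kind[i], start = mutations$start[i],
              end = mutations$end[i], ref = mutations$ref[i],
              alt = mutations$alt[i])
    mut <- mutateSequence(wt, v, L)
    ddg(foldSequence(wt, backend), foldSequence(mut, backend),
        mutations$mutation_id[i], backend$name)
  })
  do.call(rbind, out)
}

#' Cohort-level stability statistics
#'
#' (1) Paired t test of mutant versus wild-type folding energies across all
#' mutations (is the average mutant precursor less stable?); (2) Welch
#' two-sample t test of ddG for functional versus remaining mutations
#' (Student's available via \code{var_equal}).
#'
#' @param records stability records (\code{\link{stabilityRecords}})
#' @param functional_flags logical vector aligned with \code{records},
#'   marking mutations called functional in at least one experiment
#' @param var_equal use the pooled-variance (Student) two-sample test
#' @return list: \code{mean_ddg}, \code{paired_t_p}, \code{group_t_p},
#'   \code{mean_ddg_functional}, \code{mean_ddg_rest}, \code{note}
#' @export
ddgCohortTests <- function(records, functional_flags, var_equal = FALSE) {
  stopifnot(nrow(records) >= 2L,
            length(functional_flags) == nrow(records))
  paired_p <- if (stats::sd(records$ddg) == 0) NA_real_
              else stats::t.test(records$dg_mut, records$dg_wt,
                                 paired = TRUE)$p.value
  out <- list(mean_ddg = mean(records$ddg), paired_t_p = paired_p,
              group_t_p = NA_real_,
              mean_ddg_functional = NA_real_, mean_ddg_rest = NA_real_,
              note = if (is.na(paired_p)) "paired test degenerate (all ddg equal); ns"
                     else NA_character_)
  f <- records$ddg[functional_flags]
  r <- records$ddg[!functional_flags]
  if (length(f) < 2L || length(r) < 2L) {
    out$note <- "group test skipped: fewer than 2 mutations in a group"
    return(out)
  }
  out$group_t_p <- stats::t.test(f, r, var.equal = var_equal)$p.value
  out$mean_ddg_functional <- mean(f)
  out$mean_ddg_rest <- mean(r)
  out
}
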