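#' Construct a MirnaGeneSet from in-memory components
#'
#' @param anno data.frame with columns \code{gene_id}, \code{precursor_id},
#'   \code{L}, \code{m5_start}, \code{m5_end}, \code{m3_start}, \code{m3_end}
#'   and optionally \code{redundant_group}.
#' @param precursor,flank5,flank3 named character vectors of sequences,
#'   names matching \code{anno$gene_id}.
#' @param rejected optional data.frame (\code{gene_id}, \code{reason}) of
#'   genes refused at load time.
#' @return a validated \code{\linkS4class{MirnaGeneSet}}
#' @export
MirnaGeneSet <- function(anno, precursor, flank5, flank3,
                         rejected = data.frame(gene_id = character(),
                                               reason = character())) {
  if (is.null(anno$redundant_group)) anno$redundant_group <- NA_character_
  anno$redundant_group <- as.character(anno$redundant_group)
  for (col in c("L", "m5_start", "m5_end", "m3_start", "m3_end"))
    anno[[col]] <- as.integer(anno[[col]])
  new("MirnaGeneSet",
      anno = as.data.frame(anno, stringsAsFactors = FALSE),
      precursor = toupper(precursor[anno$gene_id]),
      flank5 = toupper(flank5[anno$gene_id]),
      flank3 = toupper(flank3[anno$gene_id]),
      rejected = rejected)
}

#' Read miRNA gene annotations
#'
#' Loads the reference coordinate frame from a FASTA of extended precursor
#' sequences (25-nt 5' flank + hairpin + 25-nt 3' flank, so length L + 50)
#' and a coordinates table giving the canonical mature spans in precursor
#' (n.) coordinates. Genes with an undefined arm or a malformed flank are
#' rejected with a reason code (\code{rejectedGenes}), never silently
#' dropped.
#'
#' Two coordinate dialects are supported:
#' \describe{
#'   \item{\code{tsv}}{columns \code{gene_id}, \code{precursor_id},
#'     \code{L}, \code{mature5p_span}, \code{mature3p_span},
#'     \code{redundant_group}; spans are \code{"start-end"} strings in n.
#'     coordinates, empty/NA when the arm is not annotated.}
#'   \item{\code{gff3}}{miRBase-style GFF3 with
#'     \code{miRNA_primary_transcript} and \code{miRNA} features; mature
#'     arms are matched to hairpins via the \code{Derives_from} attribute
#'     and assigned to 5p/3p by the \code{-5p}/\code{-3p} name suffix.
#'     Genomic coordinates are converted to precursor-relative ones using
#'     the hairpin's strand.}
#' }
#'
#' @param path_fasta FASTA of extended sequences; ids must match
#'   \code{gene_id} (or \code{precursor_id}) in the coordinate table.
#' @param path_coords coordinates table (see Details).
#' @param dialect \code{"tsv"} or \code{"gff3"}.
#' @return a \code{\linkS4class{MirnaGeneSet}}
#' @export
readMirnaAnnotations <- function(path_fasta, path_coords,
                                 dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::readBStringSet(path_fasta)
  seqv <- toupper(as.character(seqs))
  names(seqv) <- sub("\\s.*$", "", names(seqv))

  coords <- if (dialect == "tsv") .coordsFromTsv(path_coords)
            else .coordsFromGff3(path_coords)

  rejected <- data.frame(gene_id = character(), reason = character())
  keep <- logical(nrow(coords))
  anno <- coords
  precursor <- flank5 <- flank3 <- character(0)
  for (i in seq_len(nrow(coords))) {
    g <- coords$gene_id[i]
    if (is.na(coords$m5_start[i]) || is.na(coords$m3_start[i])) {
      rejected <- rbind(rejected, data.frame(gene_id = g,
                                             reason = "arm_undefined"))
      next
    }
    key <- if (g %in% names(seqv)) g else coords$precursor_id[i]
    s <- seqv[[key]]
    if (is.null(s) || is.na(s) || nchar(s) != coords$L[i] + 50L) {
      rejected <- rbind(rejected, data.frame(gene_id = g,
                                             reason = "bad_flank"))
      next
    }
    keep[i] <- TRUE
    flank5[g] <- substr(s, 1L, 25L)
    precursor[g] <- substr(s, 26L, 25L + coords$L[i])
    flank3[g] <- substr(s, 26L + coords$L[i], 50L + coords$L[i])
  }
  MirnaGeneSet(anno[keep, , drop = FALSE], precursor, flank5, flank3,
               rejected = rejected)
}

.parseSpan <- function(sp) {
  if (is.na(sp) || !nzchar(sp)) return(c(NA_integer_, NA_integer_))
  m <- regmatches(sp, regexec("^(-?\\d+)-(-?\\d+)$", sp))[[1]]
  if (length(m) != 3L) stop("malformed span: ", sp)
  as.integer(m[2:3])
}

.coordsFromTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "precursor_id", "L", "mature5p_span", "mature3p_span")
  if (!all(need %in% names(tab)))
    stop("coordinate TSV lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  m5 <- t(vapply(tab$mature5p_span, .parseSpan, integer(2)))
  m3 <- t(vapply(tab$mature3p_span, .parseSpan, integer(2)))
  data.frame(gene_id = tab$gene_id, precursor_id = tab$precursor_id,
             L = as.integer(tab$L),
             m5_start = m5[, 1], m5_end = m5[, 2],
             m3_start = m3[, 1], m3_end = m3[, 2],
             redundant_group = if ("redundant_group" %in% names(tab))
               ifelse(nzchar(tab$redundant_group), tab$redundant_group, NA)
             else NA_character_,
             stringsAsFactors = FALSE)
}

.gffAttr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

.coordsFromGff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  gff <- data.frame(type = f[, 3], start = as.integer(f[, 4]),
                    end = as.integer(f[, 5]), strand = f[, 7],
                    attr = f[, 9], stringsAsFactors = FALSE)
  pre <- gff[gff$type == "miRNA_primary_transcript", ]
  mat <- gff[gff$type == "miRNA", ]
  pre$id <- .gffAttr(pre$attr, "ID")
  pre$name <- .gffAttr(pre$attr, "Name")
  mat$from <- .gffAttr(mat$attr, "Derives_from")
  mat$name <- .gffAttr(mat$attr, "Name")
  out <- lapply(seq_len(nrow(pre)), function(i) {
    p <- pre[i, ]
    m <- mat[mat$from == p$id, ]
    rel <- function(j) {
      if (p$strand == "-") c(p$end - m$end[j] + 1L, p$end - m$start[j] + 1L)
      else c(m$start[j] - p$start + 1L, m$end[j] - p$start + 1L)
    }
    m5 <- m3 <- c(NA_integer_, NA_integer_)
    for (j in seq_len(nrow(m))) {
      if (grepl("-5p$", m$name[j])) m5 <- rel(j)
      else if (grepl("-3p$", m$name[j])) m3 <- rel(j)
    }
    data.frame(gene_id = toupper(p$name), precursor_id = p$name,
               L = p$end - p$start + 1L,
               m5_start = m5[1], m5_end = m5[2],
               m3_start = m3[1], m3_end = m3[2],
               redundant_group = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map an n.-style coordinate to an index in the extended sequence
#'
#' Position 1 is the first hairpin nucleotide; the 5' flank runs -25..-1
#' (no zero) and the 3' flank L+1..L+25. The extended sequence is the
#' 25-nt 5' flank, the hairpin, then the 25-nt 3' flank.
#'
#' @param position integer vector of n. coordinates
#' @param L hairpin length
#' @return 1-based index into the extended (L + 50 nt) sequence
#' @export
nToIndex <- function(position, L) {
  bad <- position == 0 | position < -25 | position > L + 25
  if (any(bad))
    stop(errorCondition(paste("position out of [-25, L+25] or zero:",
                              paste(position[bad], collapse = ", ")),
                        class = c("out_of_range", "mirMutImpactError",
                                  "error", "condition")))
  ifelse(position < 0, position + 26L, position + 25L)
}

#' Extended precursor sequence (hairpin plus 25-nt flanks)
#'
#' @param x a \code{MirnaGeneSet}
#' @param gene_id single gene id
#' @return character string of length L + 50
#' @export
extendedSequence <- function(x, gene_id) {
  i <- .geneRow(x, gene_id)
  paste0(x@flank5[[gene_id]], x@precursor[[gene_id]], x@flank3[[gene_id]])
}

#' Subregion of a precursor position
#'
#' Partitions the coordinate range [-25, L+25] \\ {0} into seven labelled
#' subregions using the annotated mature spans: everything 5' of the 5p
#' mature start is \code{flank5}, everything 3' of the 3p mature end is
#' \code{flank3} (even when still inside the annotated hairpin), the region
#' between the arms is \code{loop}, and within each arm the seed (mature
#' positions 2-8) is distinguished from the rest of the duplex.
#'
#' @param x a \code{MirnaGeneSet}
#' @param gene_id single gene id
#' @param position integer vector of n. coordinates
#' @return character vector over \code{flank5, duplex5p, seed5p, loop,
#'   duplex3p, seed3p, flank3}
#' @export
subregion <- function(x, gene_id, position) {
  i <- .geneRow(x, gene_id)
  L <- x@anno$L[i]
  nToIndex(position, L)  # range check
  m5 <- c(x@anno$m5_start[i], x@anno$m5_end[i])
  m3 <- c(x@anno$m3_start[i], x@anno$m3_end[i])
  out <- character(length(position))
  out[position < m5[1]] <- "flank5"
  out[position > m3[2]] <- "flank3"
  out[position > m5[2] & position < m3[1]] <- "loop"
  in5 <- position >= m5[1] & position <= m5[2]
  out[in5] <- ifelse(position[in5] >= m5[1] + 1 & position[in5] <= m5[1] + 7,
                     "seed5p", "duplex5p")
  in3 <- position >= m3[1] & position <= m3[2]
  out[in3] <- ifelse(position[in3] >= m3[1] + 1 & position[in3] <= m3[1] + 7,
                     "seed3p", "duplex3p")
  out
}
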