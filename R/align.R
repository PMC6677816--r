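#' Alignment scoring parameters
#'
#' Affine-gap scoring scheme for global (Needleman-Wunsch) alignment. A gap
#' run of length L costs `gap_open + L * gap_extend` (both supplied as
#' negative numbers). Defaults are deliberately gentle on substitutions
#' relative to gaps: 16S rRNA parents in the 75-97% identity range differ
#' mostly by scattered substitutions, and over-eager gapping would shred the
#' shared stretches downstream analyses depend on.
#'
#' @param match Score for an identical column (positive).
#' @param mismatch Score for a substitution column (negative).
#' @param gap_open Cost for opening a gap run (negative).
#' @param gap_extend Cost per gapped column (negative).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

.substitution_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- params$match
  # N is a placeholder for an unread base: never rewarded
  m["N", ] <- params$mismatch
  m[, "N"] <- params$mismatch
  m
}

#' Optimal global pairwise alignment
#'
#' Globally aligns two nucleotide sequences under affine-gap scoring
#' (Needleman-Wunsch), via [Biostrings::pairwiseAlignment()]. The result is
#' deterministic for fixed inputs and parameters.
#'
#' @param a,b Sequences: strings or one-row record tibbles from [read_fasta()].
#' @param params An [align_params()] scoring scheme.
#' @return An object of class `pairwise_alignment`: gapped rows of equal
#'   length (named by sequence id), the optimal score, and the parameters.
#'   De-gapping either row reproduces its input exactly; no column is gap/gap.
#' @examples
#' aln <- global_align("ACGT", "AGT")
#' aln$rows
#' percent_identity(aln)
#' @export
global_align <- function(a, b, params = align_params()) {
  ra <- .as_seqrec(a, "seqA")
  rb <- .as_seqrec(b, "seqB")
  if (!nzchar(ra$residues) || !nzchar(rb$residues)) {
    abort("Cannot align empty sequences")
  }
  fit <- Biostrings::pairwiseAlignment(
    ra$residues, rb$residues,
    substitutionMatrix = .substitution_matrix(params),
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend,
    type = "global"
  )
  rows <- c(as.character(Biostrings::alignedPattern(fit)),
            as.character(Biostrings::alignedSubject(fit)))
  names(rows) <- c(ra$id, rb$id)
  structure(
    list(rows = rows, score = Biostrings::score(fit), params = params),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", paste(names(x$rows), collapse = " vs "),
      "\n  length ", nchar(x$rows[[1]]), ", score ", x$score,
      ", identity ", sprintf("%.1f%%", percent_identity(x)), "\n", sep = "")
  invisible(x)
}

#' @rdname global_align
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble(length = nchar(x$rows[[1]]), score = x$score,
         percent_identity = percent_identity(x))
}

.row_chars <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), ""))
}

# map each row's ungapped 1-based position to its alignment column
.pos_to_col <- function(row) which(strsplit(row, "")[[1]] != "-")

#' Percent identity of a pairwise alignment
#'
#' Identical columns divided by a denominator chosen by convention, times 100.
#' The denominator conventions cover the usual ways published identity values
#' are computed; which one a given publication used is rarely stated, so all three
#' are exposed:
#' * `"trim_ends"` (default): all columns except terminal gap overhangs, i.e.
#'   the span from the first to the last column where both rows have a residue.
#' * `"all"`: every alignment column.
#' * `"ungapped"`: only columns where neither row is gapped.
#'
#' @param aln A `pairwise_alignment` (or the two parent rows of a
#'   `triple_alignment`).
#' @param convention Denominator convention, see Details.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln,
                             convention = c("trim_ends", "all", "ungapped")) {
  convention <- match.arg(convention)
  ch <- if (inherits(aln, "triple_alignment")) {
    .row_chars(aln)[2:3, , drop = FALSE]
  } else {
    .row_chars(aln)
  }
  a <- ch[1, ]; b <- ch[2, ]
  ident <- a == b & a != "-"
  keep <- switch(convention,
    all = rep(TRUE, length(a)),
    ungapped = a != "-" & b != "-",
    trim_ends = {
      both <- which(a != "-" & b != "-")
      k <- rep(FALSE, length(a))
      if (length(both)) k[both[1]:both[length(both)]] <- TRUE
      k
    }
  )
  if (!any(keep)) abort("Zero-length identity denominator")
  100 * sum(ident & keep) / sum(keep)
}

#' Align a recombinant against two candidate parents
#'
#' Each parent is globally aligned to the recombinant and the two pairwise
#' alignments are merged on the recombinant's ungapped coordinates, giving
#' three rows in common columns (order: recombinant, parent A, parent B).
#' Columns where one parent carries an insertion relative to the recombinant
#' show a gap in the other two rows; parent-A insertions are emitted before
#' parent-B insertions at the same recombinant position, which fixes the
#' column order deterministically.
#'
#' @param recombinant,parent_a,parent_b Sequences (strings or one-row record
#'   tibbles). By convention parent A is the host gene.
#' @param params An [align_params()] scoring scheme.
#' @return An object of class `triple_alignment`: `rows` (three gapped
#'   strings, named), `ids`, and `maps` (per row, the alignment column of each
#'   ungapped position). De-gapping any row reproduces its input; no column is
#'   all-gap.
#' @export
align_triple <- function(recombinant, parent_a, parent_b,
                         params = align_params()) {
  rec <- .as_seqrec(recombinant, "recombinant")
  pa <- .as_seqrec(parent_a, "parentA")
  pb <- .as_seqrec(parent_b, "parentB")
  ids <- c(rec$id, pa$id, pb$id)
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
  }
  alnA <- global_align(rec, pa, params)
  alnB <- global_align(rec, pb, params)
  a <- strsplit(unname(alnA$rows), "")
  b <- strsplit(unname(alnB$rows), "")
  merged <- .merge_on_focal(a[[1]], a[[2]], b[[1]], b[[2]])
  rows <- setNames(vapply(merged, paste, "", collapse = ""), ids)
  structure(
    list(rows = rows, ids = ids,
         maps = lapply(rows, .pos_to_col), params = params),
    class = "triple_alignment"
  )
}

# merge two pairwise alignments sharing a focal (first) sequence into three
# rows on common columns; focal insertions from alignment A are emitted first
.merge_on_focal <- function(focA, othA, focB, othB) {
  i <- 1L; j <- 1L
  nA <- length(focA); nB <- length(focB)
  rec <- character(0); pa <- character(0); pb <- character(0)
  while (i <= nA || j <= nB) {
    if (i <= nA && focA[i] == "-") {
      rec <- c(rec, "-"); pa <- c(pa, othA[i]); pb <- c(pb, "-")
      i <- i + 1L
    } else if (j <= nB && focB[j] == "-") {
      rec <- c(rec, "-"); pa <- c(pa, "-"); pb <- c(pb, othB[j])
      j <- j + 1L
    } else {
      # both columns carry the same focal residue
      rec <- c(rec, focA[i]); pa <- c(pa, othA[i]); pb <- c(pb, othB[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  list(rec, pa, pb)
}

#' @export
print.triple_alignment <- function(x, ...) {
  cat("<triple_alignment> ", paste(x$ids, collapse = ", "),
      "\n  length ", nchar(x$rows[[1]]), " columns\n", sep = "")
  invisible(x)
}

#' Export an alignment as aligned FASTA
#'
#' @param aln A `pairwise_alignment` or `triple_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, c("pairwise_alignment", "triple_alignment")))
  set <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
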