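#' Classify the columns of a multiple alignment
#'
#' Partitions the columns of an aligned set of homologs into three classes:
#' `gapped` (any row gapped), `consensus` (gap-free and unanimous across
#' rows) and `discriminating` (gap-free, not unanimous). With
#' `mode = "pairwise_focal"` the discriminating/consensus split is instead
#' made per sequence against a focal reference: for each non-focal row, the
#' gap-free columns where it differs from the focal row; for the focal row
#' itself, the columns where any other row differs from it.
#'
#' @param msa An aligned set: a tibble with `id`/`residues` (equal-length
#'   gapped strings, as from [read_fasta()] of an aligned FASTA), or a named
#'   character vector.
#' @param mode `"unanimous"` (default) or `"pairwise_focal"`.
#' @param focal_id Sequence id of the focal reference (`pairwise_focal` only;
#'   defaults to the first sequence).
#' @return An object of class `column_class_profile`: `classes` (tibble
#'   `column`, `class`; for `pairwise_focal`, class refers to the per-sequence
#'   matrix in `per_seq`), counts `n_consensus`, `n_discriminating`,
#'   `n_gapped`, plus `ids`, `mode`, and the aligned matrix.
#' @export
classify_msa_columns <- function(msa, mode = c("unanimous", "pairwise_focal"),
                                 focal_id = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(msa)) {
    rows <- setNames(msa$residues, msa$id)
  } else if (is.character(msa)) {
    rows <- msa
    if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
  } else {
    abort("msa must be a record tibble or a named character vector")
  }
  if (length(rows) < 2) abort("Need at least two aligned sequences")
  if (length(unique(nchar(rows))) != 1) {
    abort("Aligned rows must all have the same length")
  }
  ch <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(ch) <- names(rows)
  gapped <- colSums(ch == "-") > 0
  unanimous <- apply(ch, 2, function(col) length(unique(col)) == 1)
  cls <- ifelse(gapped, "gapped",
                ifelse(unanimous, "consensus", "discriminating"))
  per_seq <- NULL
  if (mode == "pairwise_focal") {
    focal_id <- focal_id %||% names(rows)[1]
    if (!focal_id %in% names(rows)) abort("focal_id not found in msa")
    f <- ch[focal_id, ]
    per_seq <- t(apply(ch, 1, function(r) {
      ifelse(gapped, "gapped", ifelse(r == f, "consensus", "discriminating"))
    }))
    # the focal row discriminates wherever any other row departs from it
    others <- ch[setdiff(rownames(ch), focal_id), , drop = FALSE]
    any_diff <- colSums(sweep(others, 2, f, FUN = "!=")) > 0
    per_seq[focal_id, ] <- ifelse(gapped, "gapped",
                                  ifelse(any_diff, "discriminating",
                                         "consensus"))
  }
  structure(
    list(
      classes = tibble(column = seq_len(ncol(ch)), class = cls),
      n_consensus = sum(cls == "consensus"),
      n_discriminating = sum(cls == "discriminating"),
      n_gapped = sum(cls == "gapped"),
      ids = names(rows), mode = mode, focal_id = focal_id,
      matrix = ch, per_seq = per_seq
    ),
    class = "column_class_profile"
  )
}

#' @export
print.column_class_profile <- function(x, ...) {
  cat("<column_class_profile> ", length(x$ids), " sequences, ",
      ncol(x$matrix), " columns (", x$n_consensus, " consensus, ",
      x$n_discriminating, " discriminating, ", x$n_gapped, " gapped; mode ",
      x$mode, ")\n", sep = "")
  invisible(x)
}

#' GC content at discriminating vs consensus columns
#'
#' For each sequence, the GC percentage of its residues restricted to the
#' discriminating columns and to the consensus columns of the alignment.
#' Species-specific (discriminating) positions carry the thermal-adaptation
#' signal of rRNA, so their GC typically departs from the conserved consensus
#' background. A class with zero columns yields `NA` (undefined), never 0.
#'
#' @param msa The aligned set (as for [classify_msa_columns()]).
#' @param profile Optional profile from [classify_msa_columns()] on the same
#'   alignment; computed with defaults when omitted.
#' @return A tibble, one row per sequence: `seq_id`, `gc_discriminating`,
#'   `gc_consensus` (percent, `NA` when undefined), `n_discriminating`,
#'   `n_consensus`, `n_gapped`. Under the unanimous mode consensus columns are
#'   identical across rows, so `gc_consensus` is the same for every sequence
#'   (the per-representative and averaged readings coincide by construction).
#' @examples
#' msa <- tibble::tibble(id = c("a", "b"), residues = c("ACGT", "AGGT"))
#' gc_by_class(msa)
#' @export
gc_by_class <- function(msa, profile = NULL) {
  profile <- profile %||% classify_msa_columns(msa)
  ch <- profile$matrix
  gc_of <- function(bases) {
    if (length(bases) == 0) return(NA_real_)
    100 * sum(bases %in% c("G", "C")) / length(bases)
  }
  per_row <- function(id) {
    cls <- if (profile$mode == "pairwise_focal") {
      profile$per_seq[id, ]
    } else {
      profile$classes$class
    }
    tibble(
      seq_id = id,
      gc_discriminating = gc_of(ch[id, cls == "discriminating"]),
      gc_consensus = gc_of(ch[id, cls == "consensus"]),
      n_discriminating = sum(cls == "discriminating"),
      n_consensus = sum(cls == "consensus"),
      n_gapped = sum(cls == "gapped")
    )
  }
  dplyr::bind_rows(lapply(profile$ids, per_row))
}
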