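#' Load a structural segment / helix annotation
#'
#' Reads an annotation of reference coordinates into a validated tibble.
#' Two formats are auto-detected by extension:
#' * `.tsv` / `.txt`: tab-delimited with header columns `segment_id`,
#'   `age_rank`, `start`, `end`, `kind`, `label` (1-based inclusive
#'   coordinates; `kind` is `accretion_segment` or `helix`; an optional
#'   `reference_id` column names the coordinate system).
#' * `.bed`: BED (0-based half-open), converted on load; column 4 becomes
#'   `segment_id`, column 5 (score) `age_rank`, `kind` defaults to
#'   `accretion_segment`.
#'
#' Accretion-model segment ranges come from the published secondary-structure
#' work and are user-supplied, never baked in; the package's test fixtures use
#' an explicitly synthetic annotation.
#'
#' @param path Annotation file path.
#' @return A tibble (`segment_id`, `age_rank`, `start`, `end`, `kind`,
#'   `label`) with attribute `reference_id`. Records of the same kind may not
#'   overlap; `age_rank` must be unique across accretion segments.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("Annotation file not found: ", path))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           show_col_types = FALSE)
    if (ncol(raw) < 4) abort("BED annotation needs at least 4 columns")
    ann <- tibble(
      segment_id = as.character(raw[[4]]),
      age_rank = if (ncol(raw) >= 5) as.integer(raw[[5]]) else NA_integer_,
      start = as.integer(raw[[2]]) + 1L,  # 0-based half-open -> 1-based
      end = as.integer(raw[[3]]),
      kind = "accretion_segment",
      label = as.character(raw[[4]])
    )
    ref <- unique(as.character(raw[[1]]))
    if (length(ref) > 1) abort("BED annotation spans multiple reference ids")
    attr(ann, "reference_id") <- ref
  } else {
    ann <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    need <- c("segment_id", "age_rank", "start", "end", "kind")
    miss <- setdiff(need, names(ann))
    if (length(miss)) {
      abort(paste0("Annotation is missing column(s): ",
                   paste(miss, collapse = ", ")))
    }
    if (!"label" %in% names(ann)) ann$label <- ann$segment_id
    ref <- if ("reference_id" %in% names(ann)) unique(ann$reference_id) else NA
    suppressWarnings({
      ann$age_rank <- as.integer(ann$age_rank)
      ann$start <- as.integer(ann$start)
      ann$end <- as.integer(ann$end)
    })
    bad <- which(is.na(ann$start) | is.na(ann$end) | !nzchar(ann$segment_id))
    if (length(bad)) {
      abort(paste0("Malformed annotation row at line ", bad[1] + 1L,
                   " of ", path))
    }
    ann <- ann[, c("segment_id", "age_rank", "start", "end", "kind", "label")]
    attr(ann, "reference_id") <- ref
  }
  validate_annotation(ann)
}

#' @rdname load_annotation
#' @param ann An annotation tibble to validate (returned invisibly unchanged).
#' @export
validate_annotation <- function(ann) {
  if (any(ann$start > ann$end)) {
    abort(paste0("Annotation record '",
                 ann$segment_id[which(ann$start > ann$end)[1]],
                 "' has start > end"))
  }
  acc <- ann[ann$kind == "accretion_segment", ]
  if (anyDuplicated(acc$age_rank[!is.na(acc$age_rank)])) {
    abort("age_rank must be unique across accretion segments")
  }
  for (k in unique(ann$kind)) {
    a <- ann[ann$kind == k, ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) {
      ov <- which(a$start[-1] <= a$end[-nrow(a)])
      if (length(ov)) {
        abort(paste0("Overlapping ", k, " records: '",
                     a$segment_id[ov[1]], "' and '", a$segment_id[ov[1] + 1],
                     "'"))
      }
    }
  }
  ann
}

#' Write an annotation back to TSV
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  out <- ann
  ref <- attr(ann, "reference_id")
  if (!is.null(ref) && !is.na(ref)) out$reference_id <- ref
  readr::write_tsv(out, path)
  invisible(path)
}

#' Transfer positions to reference coordinates
#'
#' Maps 1-based ungapped positions on a query (e.g. a recombinant gene) to a
#' reference coordinate system through a global alignment of the two. Where
#' the reference is gapped at the matched column, the nearest reference
#' position on the 5' side is returned and flagged inexact (0 becomes `NA` if
#' the gap precedes the whole reference).
#'
#' @param pos Integer vector of 1-based positions on the query.
#' @param aln A `pairwise_alignment` with the query as first row and the
#'   reference as second.
#' @return A tibble (`pos`, `ref_pos`, `exact`).
#' @export
transfer_to_reference <- function(pos, aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  qmap <- .pos_to_col(aln$rows[[1]])
  rmap <- .pos_to_col(aln$rows[[2]])
  if (any(pos < 1 | pos > length(qmap))) {
    abort(paste0("Position out of range 1..", length(qmap)))
  }
  cols <- qmap[pos]
  ref_pos <- match(cols, rmap)
  exact <- !is.na(ref_pos)
  # gap in the reference: nearest reference residue 5' of the column
  nearest <- findInterval(cols, rmap)
  ref_pos[!exact] <- ifelse(nearest[!exact] >= 1, nearest[!exact], NA_integer_)
  tibble(pos = as.integer(pos), ref_pos = as.integer(ref_pos), exact = exact)
}

#' Count boundary points per annotated segment
#'
#' Assigns each reference-coordinate boundary point to the annotation record
#' containing it (1-based inclusive; a point on a segment edge belongs to the
#' segment spanning that exact position) and tallies per segment. Helix
#' records are ignored here; counting is over accretion segments.
#'
#' @param points Integer vector of reference positions (may be empty).
#' @param ann Annotation tibble from [load_annotation()].
#' @return A tibble (`segment_id`, `age_rank`, `start`, `end`, `count`), one
#'   row per accretion segment, with attributes `unassigned` (points falling
#'   in no segment) and `n_points`.
#' @export
map_boundaries <- function(points, ann) {
  acc <- ann[ann$kind == "accretion_segment", ]
  if (nrow(acc) == 0) abort("Annotation contains no accretion segments")
  hit <- vapply(points, function(p) {
    i <- which(acc$start <= p & acc$end >= p)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  counts <- tabulate(hit[!is.na(hit)], nbins = nrow(acc))
  out <- tibble(
    segment_id = acc$segment_id,
    age_rank = acc$age_rank,
    start = acc$start,
    end = acc$end,
    count = as.integer(counts)
  )
  attr(out, "unassigned") <- sum(is.na(hit))
  attr(out, "n_points") <- length(points)
  out
}

#' Fraction of boundaries in the k oldest segments
#'
#' In the accretion model of ribosome evolution, segments are ranked by their
#' inferred order of addition (rank 1 = oldest). This summarizes how many
#' boundary points fall in the `k` oldest segments, out of all boundaries
#' (including any that map to no annotated segment).
#'
#' @param counts Count tibble from [map_boundaries()].
#' @param k Number of oldest segments (`age_rank <= k`), at least 1.
#' @return A tibble (`k`, `count_in_k_oldest`, `total`, `fraction`).
#' @export
oldest_fraction <- function(counts, k) {
  stopifnot(k >= 1)
  unassigned <- attr(counts, "unassigned") %||% 0L
  total <- sum(counts$count) + unassigned
  if (total == 0) abort("No boundary points to summarize")
  in_k <- sum(counts$count[!is.na(counts$age_rank) & counts$age_rank <= k])
  tibble(k = as.integer(k), count_in_k_oldest = as.integer(in_k),
         total = as.integer(total), fraction = in_k / total)
}

#' Length of a 1-based inclusive genomic interval
#'
#' Coordinate arithmetic helper matching the genomic-locus convention used
#' throughout the package (1-based, both ends included), e.g. for computing a
#' gene's length from its printed genome coordinates.
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return Integer length `end - start + 1`.
#' @export
locus_length <- function(start, end) {
  stopifnot(all(start <= end))
  as.integer(end - start + 1)
}
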