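#' Maximal identical shared stretches between two parents
#'
#' A shared stretch is a maximal run of alignment columns at which the two
#' parent sequences are identical and gap-free. These are the homology tracts
#' inside which a crossover can occur; a gap terminates a stretch, because
#' recombination needs contiguous identity.
#'
#' @param aln A `triple_alignment` (the two parent rows are used) or a
#'   `pairwise_alignment` of the two parents.
#' @return A tibble, one row per stretch sorted by start: `stretch`,
#'   `start_col`, `end_col` (alignment columns, inclusive), `length`, and the
#'   stretch's span on each parent's own ungapped coordinates (`start_a`,
#'   `end_a`, `start_b`, `end_b`).
#' @examples
#' aln <- global_align("AACCTT", "AAGCTT")
#' shared_stretches(aln)
#' @export
shared_stretches <- function(aln) {
  if (inherits(aln, "triple_alignment")) {
    ch <- .row_chars(aln)[2:3, , drop = FALSE]
    mapA <- aln$maps[[2]]; mapB <- aln$maps[[3]]
  } else if (inherits(aln, "pairwise_alignment")) {
    ch <- .row_chars(aln)
    mapA <- .pos_to_col(aln$rows[[1]]); mapB <- .pos_to_col(aln$rows[[2]])
  } else {
    abort("Expected a triple_alignment or pairwise_alignment")
  }
  ident <- ch[1, ] == ch[2, ] & ch[1, ] != "-"
  runs <- rle(ident)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]
  tibble(
    stretch = seq_along(starts),
    start_col = starts,
    end_col = ends,
    length = ends - starts + 1L,
    start_a = match(starts, mapA),
    end_a = match(ends, mapA),
    start_b = match(starts, mapB),
    end_b = match(ends, mapB)
  )
}

#' Homology tract spanning a breakpoint
#'
#' Attributes to a breakpoint the shared stretch lying strictly between its
#' two flanking discriminating sites -- the tract in which the crossover must
#' have occurred. Its length is the breakpoint's homology length: the full
#' identical tract, not merely the distance between the flanking sites,
#' because the crossover can sit anywhere inside the identity. If gap columns
#' split the inter-site span into several stretches, the longest is returned
#' and `n_candidates` reports how many there were. Adjacent discriminating
#' columns leave no room for a stretch; a zero-length sentinel row flagged
#' `zero_length = TRUE` is returned then.
#'
#' @param bp One breakpoint: a one-row slice of a `mosaic_path`'s
#'   `breakpoints` tibble (needs `left_col` and `right_col`).
#' @param stretches Stretch tibble from [shared_stretches()] on the same
#'   alignment.
#' @return A one-row tibble: the chosen stretch's columns plus
#'   `homology_length`, `between_sites` (columns strictly between the two
#'   flanking sites, the alternative tract-size convention), `n_candidates`
#'   and `zero_length`.
#' @export
stretch_at_breakpoint <- function(bp, stretches) {
  stopifnot(is.data.frame(bp), nrow(bp) == 1,
            all(c("left_col", "right_col") %in% names(bp)))
  between <- bp$right_col - bp$left_col - 1L
  cand <- dplyr::filter(stretches,
                        .data$start_col > bp$left_col,
                        .data$end_col < bp$right_col)
  if (nrow(cand) == 0) {
    return(tibble(
      stretch = NA_integer_, start_col = NA_integer_, end_col = NA_integer_,
      length = 0L, start_a = NA_integer_, end_a = NA_integer_,
      start_b = NA_integer_, end_b = NA_integer_,
      homology_length = 0L, between_sites = between,
      n_candidates = 0L, zero_length = TRUE
    ))
  }
  best <- cand[order(-cand$length, cand$start_col)[1], ]
  best$homology_length <- best$length
  best$between_sites <- between
  best$n_candidates <- nrow(cand)
  best$zero_length <- FALSE
  best
}

#' Homology lengths of all breakpoints of a mosaic
#'
#' Convenience wrapper applying [stretch_at_breakpoint()] to every breakpoint
#' of a mosaic path.
#'
#' @param path A `mosaic_path`.
#' @param stretches Stretch tibble from [shared_stretches()] on the same
#'   alignment.
#' @return The path's breakpoint tibble with the spanning stretch columns
#'   appended (one row per breakpoint; zero rows for a single-segment path).
#' @export
breakpoint_homology <- function(path, stretches) {
  stopifnot(inherits(path, "mosaic_path"))
  bp <- path$breakpoints
  if (nrow(bp) == 0) {
    return(dplyr::bind_cols(bp, stretch_at_breakpoint(
      tibble(left_col = 0L, right_col = 2L), stretches)[0, ]))
  }
  hits <- purrr::map(seq_len(nrow(bp)),
                     ~ stretch_at_breakpoint(bp[.x, ], stretches))
  dplyr::bind_cols(bp, dplyr::bind_rows(hits)[, c(
    "start_col", "end_col", "homology_length", "between_sites",
    "n_candidates", "zero_length")] |>
      dplyr::rename(stretch_start_col = "start_col",
                    stretch_end_col = "end_col"))
}

#' Length distribution of shared stretches
#'
#' @param stretches Non-empty stretch tibble from [shared_stretches()].
#' @return A tibble (`length`, `count`, `fraction_ge`): counts per observed
#'   length, and the fraction of stretches at least that long (supports the
#'   "how often is there enough homology for a crossover?" query).
#' @export
stretch_length_distribution <- function(stretches) {
  if (nrow(stretches) == 0) abort("Empty stretch list")
  stretches |>
    dplyr::count(.data$length, name = "count") |>
    arrange(.data$length) |>
    mutate(fraction_ge = rev(cumsum(rev(.data$count))) / sum(.data$count))
}

#' Plot the shared-stretch length distribution
#'
#' @param stretches Stretch tibble from [shared_stretches()].
#' @param l_min Optional minimum-homology threshold to mark (e.g. 9 bases).
#' @return A ggplot histogram of stretch lengths.
#' @export
plot_stretch_distribution <- function(stretches, l_min = NULL) {
  p <- ggplot2::ggplot(stretches, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey30") +
    ggplot2::labs(x = "Shared stretch length (bp)", y = "Count") +
    ggplot2::theme_minimal()
  if (!is.null(l_min)) {
    p <- p + ggplot2::geom_vline(xintercept = l_min, linetype = "dashed",
                                 colour = "red")
  }
  p
}
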