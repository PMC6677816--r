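#' Discriminating sites of a three-way alignment
#'
#' A discriminating site is a gap-free alignment column at which the two
#' parents differ, so the recombinant's base there can be attributed to one
#' parent (or to neither, pointing at a de novo mutation). Columns containing
#' a gap in any row are never called as sites -- insertion/deletion
#' differences contribute to identity but not to boundary calling -- and are
#' tallied separately.
#'
#' @param aln A `triple_alignment` from [align_triple()].
#' @return A tibble, one row per site in column order: `column` (alignment
#'   column, 1-based), `rec_pos` (recombinant ungapped position, 1-based),
#'   `parent_a`, `parent_b`, `recombinant` (bases), and `state` in
#'   `matches_A` / `matches_B` / `matches_neither`. The number of gapped
#'   columns is attached as attribute `n_gapped`.
#' @export
find_discriminating_sites <- function(aln) {
  stopifnot(inherits(aln, "triple_alignment"))
  ch <- .row_chars(aln)
  gapfree <- colSums(ch == "-") == 0
  is_site <- gapfree & ch[2, ] != ch[3, ]
  cols <- which(is_site)
  rec_pos <- match(cols, aln$maps[[1]])
  state <- dplyr::case_when(
    ch[1, cols] == ch[2, cols] ~ "matches_A",
    ch[1, cols] == ch[3, cols] ~ "matches_B",
    TRUE ~ "matches_neither"
  )
  out <- tibble(
    column = cols,
    rec_pos = rec_pos,
    parent_a = ch[2, cols],
    parent_b = ch[3, cols],
    recombinant = ch[1, cols],
    state = state
  )
  attr(out, "n_gapped") <- sum(!gapfree)
  out
}

#' Minimal-crossover parent-of-origin mosaic
#'
#' Assigns every discriminating site to parent A or B so as to minimize
#' `switch_cost * (number of label changes) + mismatch_cost * (number of
#' sites whose observed state contradicts their label)`. A `matches_neither`
#' site contradicts both labels equally. The optimum is found by dynamic
#' programming over sites x \{A, B\}; ties are broken deterministically by
#' preferring fewer segments, then a first segment labelled A (the host
#' parent, by convention).
#'
#' The defaults `switch_cost = 2`, `mismatch_cost = 1` make one de novo
#' mutation cheaper than two extra crossovers, so isolated non-parental or
#' lone opposite-parent bases are explained as mutations rather than as
#' micro-recombination. Set `mismatch_cost = Inf` for the pure
#' minimal-crossover path when mutations can be ruled out (labels then track
#' the site states exactly; requires no `matches_neither` site).
#'
#' Each breakpoint is reported both as the conventional point -- the first
#' discriminating nucleotide attributable to the new parent -- and as the
#' ambiguity interval between the flanking discriminating sites, inside which
#' the true crossover is unidentifiable.
#'
#' @param sites Site tibble from [find_discriminating_sites()].
#' @param switch_cost,mismatch_cost Positive costs; see Details.
#' @return An object of class `mosaic_path` with elements `segments` (tibble:
#'   `segment`, `parent`, first/last site column and recombinant position,
#'   `n_sites`), `breakpoints` (tibble: `left_col`, `right_col`,
#'   `boundary_col`, `left_pos`, `right_pos`, `boundary_pos`), `sites` (input
#'   plus assigned `label`), `n_mismatch`, `cost`.
#' @examples
#' sites <- tibble::tibble(
#'   column = c(10, 50, 90), rec_pos = c(10, 50, 90),
#'   parent_a = "A", parent_b = "G", recombinant = c("A", "G", "G"),
#'   state = c("matches_A", "matches_B", "matches_B")
#' )
#' infer_mosaic(sites)$breakpoints
#' @export
infer_mosaic <- function(sites, switch_cost = 2, mismatch_cost = 1) {
  stopifnot(is.data.frame(sites), switch_cost > 0, mismatch_cost > 0)
  n <- nrow(sites)
  if (n == 0) {
    abort(paste("No discriminating sites: the recombinant cannot be",
                "distinguished between these parents"))
  }
  if (is.infinite(mismatch_cost) && any(sites$state == "matches_neither")) {
    abort("mismatch_cost = Inf is incompatible with matches_neither sites")
  }
  # per-site cost of each label
  costA <- ifelse(sites$state == "matches_A", 0, mismatch_cost)
  costB <- ifelse(sites$state == "matches_B", 0, mismatch_cost)
  lab <- .mosaic_dp(costA, costB, switch_cost)
  sites$label <- lab

  runs <- rle(lab)
  seg_end <- cumsum(runs$lengths)
  seg_start <- seg_end - runs$lengths + 1L
  segments <- tibble(
    segment = seq_along(runs$values),
    parent = runs$values,
    first_col = sites$column[seg_start],
    last_col = sites$column[seg_end],
    first_pos = sites$rec_pos[seg_start],
    last_pos = sites$rec_pos[seg_end],
    n_sites = runs$lengths
  )
  k <- nrow(segments)
  breakpoints <- if (k > 1) {
    tibble(
      breakpoint = seq_len(k - 1),
      from_parent = segments$parent[-k],
      to_parent = segments$parent[-1],
      left_col = segments$last_col[-k],
      right_col = segments$first_col[-1],
      left_pos = segments$last_pos[-k],
      right_pos = segments$first_pos[-1]
    )
  } else {
    tibble(breakpoint = integer(), from_parent = character(),
           to_parent = character(), left_col = integer(),
           right_col = integer(), left_pos = integer(), right_pos = integer())
  }
  # boundary point convention: first discriminating nucleotide of the new parent
  breakpoints$boundary_col <- breakpoints$right_col
  breakpoints$boundary_pos <- breakpoints$right_pos
  n_mismatch <- sum(ifelse(lab == "A", costA, costB) > 0)
  cost <- switch_cost * (k - 1) +
    if (n_mismatch > 0) mismatch_cost * n_mismatch else 0
  structure(
    list(segments = segments, breakpoints = breakpoints, sites = sites,
         n_mismatch = n_mismatch, cost = cost,
         params = list(switch_cost = switch_cost,
                       mismatch_cost = mismatch_cost)),
    class = "mosaic_path"
  )
}

# DP over sites x {A,B}; objective tuples (cost, n_segments, first_label_rank)
# compared lexicographically, which realizes the documented tie-breaks.
.mosaic_dp <- function(costA, costB, switch_cost) {
  n <- length(costA)
  # best[label, ] = c(cost, nseg, first) for paths ending at current site
  best <- rbind(A = c(costA[1], 1, 0), B = c(costB[1], 1, 1))
  back <- matrix(NA_character_, nrow = n, ncol = 2,
                 dimnames = list(NULL, c("A", "B")))
  lex_less <- function(x, y) {
    d <- x - y
    i <- which(d != 0)
    length(i) > 0 && d[i[1]] < 0
  }
  if (n > 1) {
    for (j in 2:n) {
      nxt <- best
      for (L in c("A", "B")) {
        cj <- if (L == "A") costA[j] else costB[j]
        stay <- best[L, ] + c(cj, 0, 0)
        M <- if (L == "A") "B" else "A"
        move <- best[M, ] + c(cj + switch_cost, 1, 0)
        if (lex_less(move, stay)) {
          nxt[L, ] <- move; back[j, L] <- M
        } else {
          nxt[L, ] <- stay; back[j, L] <- L  # ties keep the same label
        }
      }
      best <- nxt
    }
  }
  last <- if (lex_less(best["B", ], best["A", ])) "B" else "A"
  lab <- character(n)
  lab[n] <- last
  if (n > 1) for (j in n:2) lab[j - 1] <- back[j, lab[j]]
  lab
}

#' Recombination boundary points of a mosaic
#'
#' The paper-style point location of each breakpoint: the first discriminating
#' nucleotide attributable to the new parent, in the recombinant's ungapped
#' 1-based coordinates.
#'
#' @param path A `mosaic_path`.
#' @return Integer vector (possibly empty) of boundary positions.
#' @export
boundary_points <- function(path) {
  stopifnot(inherits(path, "mosaic_path"))
  path$breakpoints$boundary_pos
}

#' Classify a recombinant as intact, chimeric, or a full replacement
#'
#' Under the gene-targeting readout, a clone whose gene matches the host at
#' every discriminating site is `intact`, one matching the donor everywhere is
#' a `full_replacement`, and anything else is a `chimera`. Parent A is taken
#' to be the host gene.
#'
#' @param path A `mosaic_path` (used for its site table unless `sites` given).
#' @param sites Optional site tibble overriding `path$sites`.
#' @return One of `"intact"`, `"full_replacement"`, `"chimera"`.
#' @export
call_chimera_class <- function(path, sites = NULL) {
  sites <- sites %||% path$sites
  if (all(sites$state == "matches_A")) return("intact")
  if (all(sites$state == "matches_B")) return("full_replacement")
  "chimera"
}

#' @export
print.mosaic_path <- function(x, ...) {
  cat("<mosaic_path> ", nrow(x$segments), " segment(s), ",
      nrow(x$breakpoints), " breakpoint(s), ", x$n_mismatch,
      " mismatching site(s), cost ", x$cost, "\n", sep = "")
  invisible(x)
}

#' @rdname infer_mosaic
#' @param x A `mosaic_path`.
#' @param ... Unused.
#' @export
tidy.mosaic_path <- function(x, ...) x$segments

#' @rdname infer_mosaic
#' @export
glance.mosaic_path <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    n_segments = nrow(x$segments),
    n_breakpoints = nrow(x$breakpoints),
    n_mismatch = x$n_mismatch,
    cost = x$cost,
    class = call_chimera_class(x)
  )
}

#' Plot a mosaic path
#'
#' Draws the recombinant as a bar segmented by parent of origin, with
#' discriminating sites as ticks and breakpoint ambiguity intervals shaded.
#'
#' @param object A `mosaic_path`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mosaic_path <- function(object, ...) {
  seg <- object$segments
  bp <- object$breakpoints
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$first_pos, xmax = .data$last_pos,
                   ymin = 0, ymax = 1, fill = .data$parent)
    ) +
    ggplot2::geom_segment(
      data = object$sites,
      ggplot2::aes(x = .data$rec_pos, xend = .data$rec_pos,
                   y = -0.15, yend = -0.05, colour = .data$state)
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(-0.2, 1.2)) +
    ggplot2::labs(x = "Position in recombinant (bp)", fill = "Parent",
                  colour = "Site state") +
    ggplot2::theme_minimal()
  if (nrow(bp)) {
    p <- p + ggplot2::geom_rect(
      data = bp,
      ggplot2::aes(xmin = .data$left_pos, xmax = .data$right_pos,
                   ymin = 0, ymax = 1),
      fill = "grey40", alpha = 0.35
    )
  }
  p
}
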