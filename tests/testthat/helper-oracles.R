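# Independent oracles used across the suite. These deliberately share no code
# with the package: enumeration and direct scans only.

rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Exhaustive optimal global alignment score under affine gaps.
# Convention (same as the package documents): a gap run of length L costs
# gap_open + L * gap_extend; no gap/gap columns. Enumerates every global
# alignment recursively -- only viable for lengths <= ~6.
brute_align_score <- function(a, b, match = 2, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  # state: position in a, position in b, previous move (0 none, 1 diag,
  # 2 gap-in-b, 3 gap-in-a)
  rec <- function(i, j, prev) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, 1L))
    }
    if (i <= length(av)) {
      s <- gap_extend + if (prev == 2L) 0 else gap_open
      best <- max(best, s + rec(i + 1, j, 2L))
    }
    if (j <= length(bv)) {
      s <- gap_extend + if (prev == 3L) 0 else gap_open
      best <- max(best, s + rec(i, j + 1, 3L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Exhaustive minimal-cost parent labeling over all 2^n assignments, with the
# same tie-break order the package documents: cost, then fewer segments, then
# first label A. Returns list(cost=, labels=).
brute_mosaic <- function(states, switch_cost, mismatch_cost) {
  n <- length(states)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    lab <- ifelse(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L, "B", "A")
    mis <- sum((lab == "A" & states != "matches_A") |
                 (lab == "B" & states != "matches_B"))
    nseg <- 1L + sum(lab[-1] != lab[-n])
    cost <- switch_cost * (nseg - 1L) + mismatch_cost * mis
    key <- c(cost, nseg, as.integer(lab[1] == "B"))
    if (is.null(best) || isTRUE(.lex_less(key, best$key))) {
      best <- list(cost = cost, labels = lab, key = key)
    }
  }
  best
}

.lex_less <- function(x, y) {
  d <- x - y
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

# Direct per-column scan of maximal identical gap-free runs between two
# gapped rows; returns a data.frame of start/end columns.
brute_stretches <- function(row1, row2) {
  a <- strsplit(row1, "")[[1]]
  b <- strsplit(row2, "")[[1]]
  out <- list()
  start <- NA
  for (i in seq_along(a)) {
    same <- a[i] == b[i] && a[i] != "-"
    if (same && is.na(start)) start <- i
    if (!same && !is.na(start)) {
      out[[length(out) + 1]] <- c(start, i - 1)
      start <- NA
    }
  }
  if (!is.na(start)) out[[length(out) + 1]] <- c(start, length(a))
  if (!length(out)) {
    return(data.frame(start_col = integer(), end_col = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(start_col = m[, 1], end_col = m[, 2])
}

# parse a truth table's comma-separated crossover field
parse_crossovers <- function(x) {
  if (!nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",")[[1]])
}

# inferred breakpoints of one simulated clone against its parents, using the
# package pipeline; mismatch_cost Inf is the mutation-free analysis mode
infer_clone <- function(residues, parents, mismatch_cost = Inf) {
  aln <- align_triple(list(id = "clone", residues = residues),
                      parents[1, ], parents[2, ])
  sites <- find_discriminating_sites(aln)
  list(aln = aln, sites = sites,
       path = infer_mosaic(sites, mismatch_cost = mismatch_cost))
}
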