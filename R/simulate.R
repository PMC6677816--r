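#' Simulation configuration
#'
#' Parameters of the polyploid recombination simulator. The defaults describe
#' the experimental system being emulated: a polyploid thermophile host
#' (several genome copies per cell) transformed with a targeting construct
#' carrying a donor 16S rRNA gene between host-identical homology flanks,
#' followed by rounds of copy-to-copy gene conversion, with crossovers
#' requiring a minimum of 9 bases of contiguous local identity, and a
#' 1/1000-dilution serial enrichment repeated five times.
#'
#' @param ploidy Genome copies per cell (>= 1; default 4 -- the host is
#'   polyploid with an unreported copy number).
#' @param l_min Minimum shared-stretch length for a crossover, in bases
#'   (default 9).
#' @param flank_len Length of each host-identical homology flank on the
#'   integrating construct, in bases (default 1000).
#' @param conversion_cycles Iterations of intragenomic (copy-to-copy)
#'   conversion after integration (default 3).
#' @param tract_model Conversion tract length distribution; only
#'   `"geometric"` is implemented.
#' @param tract_mean Mean conversion tract length in bases (default 300).
#' @param mutation_rate Per-base substitution probability applied to each
#'   clone's final sequence (default 0).
#' @param dilution Per-cycle bottleneck factor of the enrichment regime
#'   (default 1/1000).
#' @param n_cycles Number of enrichment cycles (default 5).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(ploidy = 4, l_min = 9, flank_len = 1000,
                       conversion_cycles = 3, tract_model = "geometric",
                       tract_mean = 300, mutation_rate = 0,
                       dilution = 1 / 1000, n_cycles = 5) {
  stopifnot(ploidy >= 1, l_min >= 1, flank_len >= 0, conversion_cycles >= 0,
            tract_mean > 0, mutation_rate >= 0, mutation_rate < 1,
            dilution > 0, dilution <= 1, n_cycles >= 0)
  tract_model <- match.arg(tract_model, "geometric")
  structure(
    list(ploidy = as.integer(ploidy), l_min = as.integer(l_min),
         flank_len = as.integer(flank_len),
         conversion_cycles = as.integer(conversion_cycles),
         tract_model = tract_model, tract_mean = tract_mean,
         mutation_rate = mutation_rate, dilution = dilution,
         n_cycles = as.integer(n_cycles)),
    class = "sim_config"
  )
}

.BASES <- c("A", "C", "G", "T")

.base_probs <- function(gc) {
  c(A = (100 - gc) / 200, C = gc / 200, G = gc / 200, T = (100 - gc) / 200)
}

#' Generate a parent pair at controlled divergence
#'
#' Builds a host sequence with the requested base composition, then derives a
#' donor by substituting a fixed number of positions so that the realized
#' ungapped identity lands within 0.5 points of the target (it is exact up to
#' rounding the substitution count). Replacement bases are drawn from the
#' same composition, restricted to the three non-original bases, so donor GC
#' stays close to the target composition.
#'
#' @param length Gene length in bases.
#' @param target_identity Target percent identity in `(0, 100]`.
#' @param gc Target GC percent in `[0, 100]`.
#' @param placement `"uniform"` scatters substitutions uniformly;
#'   `"clustered"` concentrates them around random foci (normal spread of
#'   20 bases), mimicking variability hot-spots.
#' @param seed Optional integer seed; identical seed and arguments give
#'   byte-identical output.
#' @return A two-row record tibble (`id` = `"host"`, `"donor"`) with a
#'   `description` noting the realized identity.
#' @export
make_parent_pair <- function(length, target_identity, gc = 50,
                             placement = c("uniform", "clustered"),
                             seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(length >= 1, gc >= 0, gc <= 100)
  if (target_identity <= 0 || target_identity > 100) {
    abort("target_identity must be in (0, 100]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_diff <- round(length * (1 - target_identity / 100))
  if (n_diff >= length) abort("Infeasible identity: every position differs")
  pr <- .base_probs(gc)
  host <- sample(.BASES, length, replace = TRUE, prob = pr)
  pos <- if (n_diff == 0) {
    integer(0)
  } else if (placement == "uniform") {
    sort(sample.int(length, n_diff))
  } else {
    centers <- sample.int(length, max(1L, ceiling(n_diff / 15)))
    acc <- integer(0)
    while (length(acc) < n_diff) {
      draw <- sample(centers, n_diff, replace = TRUE) +
        round(stats::rnorm(n_diff, 0, 20))
      acc <- unique(c(acc, pmin(pmax(draw, 1L), length)))
    }
    sort(acc[seq_len(n_diff)])
  }
  donor <- host
  for (p in pos) {
    alt <- setdiff(.BASES, host[p])
    donor[p] <- sample(alt, 1, prob = pr[alt] / sum(pr[alt]))
  }
  realized <- 100 * (length - n_diff) / length
  tibble(
    id = c("host", "donor"),
    residues = c(paste(host, collapse = ""), paste(donor, collapse = "")),
    description = sprintf("synthetic parent (realized identity %.2f%%)",
                          realized)
  )
}

# crossover-eligible boundary points on the locus (flank5 + gene + flank3):
# boundaries strictly inside identity runs of length >= l_min. Flanks are
# host-identical by construction and eligibility inside the gene is defined
# against the two parent genes, so it holds for any pair of genome copies.
.eligible_points <- function(host, donor, flank_len, l_min) {
  ident <- c(rep(TRUE, flank_len), host == donor, rep(TRUE, flank_len))
  runs <- rle(ident)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= l_min
  unlist(purrr::map2(starts[keep], ends[keep] - 1L, seq), use.names = FALSE)
}

.new_copy <- function(seq, label) list(seq = seq, labels = rep(label, length(seq)))

.state_heterozygous <- function(copies) {
  seqs <- vapply(copies, function(cp) paste(cp$seq, collapse = ""), "")
  length(unique(seqs)) > 1
}

#' Simulate double-crossover integration of a donor construct
#'
#' Event #1 of the chimerization mechanism: the targeting construct (5'
#' host-identical flank + donor gene + 3' host-identical flank) recombines
#' into one genome copy of a polyploid cell via two crossovers. Crossover
#' points are drawn uniformly over all eligible positions -- boundaries
#' inside shared stretches of length at least `config$l_min` (the flanks
#' count as shared) -- reflecting that no positional preference beyond local
#' homology is assumed. The other `ploidy - 1` copies remain pure host.
#'
#' @param host,donor The two parent genes: strings or one-row record tibbles
#'   of equal ungapped length (the simulator is substitution-only).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list with `state` (a `genome_state`: `copies` with per-base
#'   `host`/`donor` origin labels, `parents`, `heterozygous`) and `truth`
#'   (the [chimera_truth] of the integrated copy).
#' @export
simulate_integration <- function(host, donor, config = sim_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- strsplit(.as_seqrec(host, "host")$residues, "")[[1]]
  d <- strsplit(.as_seqrec(donor, "donor")$residues, "")[[1]]
  if (length(h) != length(d)) {
    abort("host and donor genes must have equal length (substitution-only model)")
  }
  f <- config$flank_len
  elig <- .eligible_points(h, d, f, config$l_min)
  if (length(elig) < 2) {
    abort(paste0("no homology >= l_min (", config$l_min,
                 ") to place two crossovers"))
  }
  cx <- sort(sample(elig, 2))
  copy <- .new_copy(h, "host")
  # positions strictly after cx[1] up to cx[2] come from the donor construct
  gene_pos <- seq_along(h)
  take <- gene_pos + f > cx[1] & gene_pos + f <= cx[2]
  copy$seq[take] <- d[take]
  copy$labels[take] <- "donor"
  copies <- c(list(copy),
              replicate(config$ploidy - 1, .new_copy(h, "host"),
                        simplify = FALSE))
  state <- structure(
    list(copies = copies, parents = list(host = h, donor = d),
         config = config, heterozygous = .state_heterozygous(copies)),
    class = "genome_state"
  )
  list(state = state, truth = .chimera_truth(copy, h, d))
}

#' @export
print.genome_state <- function(x, ...) {
  cat("<genome_state> ploidy ", length(x$copies), ", gene length ",
      length(x$parents$host), ", ",
      if (x$heterozygous) "heterozygous" else "homogeneous", "\n", sep = "")
  invisible(x)
}

#' Simulate iterative intragenomic gene conversion
#'
#' Event #2 of the mechanism: per cycle, a donor copy and a recipient copy
#' are sampled (uniformly, distinct) and a conversion tract bounded by
#' crossover-eligible points is copied from one to the other, overwriting
#' sequence and origin labels. Tract length is geometric with mean
#' `config$tract_mean`; the tract end snaps to the next eligible point. A
#' cycle is a no-op when the sampled copies are identical over the tract.
#'
#' @param state A `genome_state` (ploidy >= 2).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return The updated `genome_state`.
#' @export
simulate_conversion_cycles <- function(state, config = state$config,
                                       seed = NULL) {
  stopifnot(inherits(state, "genome_state"))
  if (!is.null(seed)) set.seed(seed)
  if (length(state$copies) < 2 || config$conversion_cycles == 0) {
    return(state)
  }
  f <- config$flank_len
  elig <- .eligible_points(state$parents$host, state$parents$donor,
                           f, config$l_min)
  n_gene <- length(state$parents$host)
  for (cyc in seq_len(config$conversion_cycles)) {
    pair <- sample(length(state$copies), 2)
    from <- state$copies[[pair[1]]]
    to <- state$copies[[pair[2]]]
    c1 <- sample(elig, 1)
    len <- stats::rgeom(1, 1 / (1 + config$tract_mean)) + 1L
    after <- elig[elig >= c1 + len]
    c2 <- if (length(after)) after[1] else max(elig)
    if (c2 <= c1) next
    gene_pos <- seq_len(n_gene)
    take <- gene_pos + f > c1 & gene_pos + f <= c2
    to$seq[take] <- from$seq[take]
    to$labels[take] <- from$labels[take]
    state$copies[[pair[2]]] <- to
  }
  state$heterozygous <- .state_heterozygous(state$copies)
  state
}

#' Resolve a heterozygous polyploid state to homogeneity
#'
#' Mixed (allopolyploid) states are transient: on outgrowth one copy's
#' sequence becomes fixed across all copies. `random_fix` picks a copy
#' uniformly; `majority_fix` fixes the most common copy sequence (ties broken
#' at random).
#'
#' @param state A `genome_state`.
#' @param mode `"random_fix"` or `"majority_fix"`.
#' @param seed Optional integer seed.
#' @return A `chimera_truth` object for the fixed copy: `final_sequence`,
#'   `outcome_class` (`intact` / `chimera` / `full_replacement`),
#'   `crossovers` (observable true crossover positions, 1-based, strictly
#'   increasing), per-base `labels`, and `labels_rle` (run-length encoding
#'   `label:length` joined by `,`).
#' @export
resolve_to_homogeneity <- function(state, mode = c("random_fix",
                                                   "majority_fix"),
                                   seed = NULL) {
  stopifnot(inherits(state, "genome_state"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(state$copies, function(cp) paste(cp$seq, collapse = ""), "")
  pick <- if (mode == "random_fix") {
    sample(length(seqs), 1)
  } else {
    tab <- table(seqs)
    winners <- names(tab)[tab == max(tab)]
    win <- if (length(winners) == 1) winners else sample(winners, 1)
    which(seqs == win)[1]
  }
  cp <- state$copies[[pick]]
  .chimera_truth(cp, state$parents$host, state$parents$donor)
}

# Ground truth for one resolved copy. Crossovers are the *observable* ones:
# label boundaries that flip the parent assignment between consecutive
# discriminating positions. A conversion tract containing no discriminating
# site changes no base and therefore no sequence-level crossover exists.
.chimera_truth <- function(copy, host, donor) {
  labels <- copy$labels
  n <- length(labels)
  disc <- which(host != donor)
  site_lab <- labels[disc]
  outcome <- if (length(disc) == 0 || all(site_lab == "host")) {
    "intact"
  } else if (all(site_lab == "donor")) {
    "full_replacement"
  } else {
    "chimera"
  }
  bounds <- which(labels[-n] != labels[-1])  # boundary after position i
  crossovers <- integer(0)
  if (length(disc) > 1) {
    flip <- which(site_lab[-length(site_lab)] != site_lab[-1])
    crossovers <- vapply(flip, function(j) {
      inb <- bounds[bounds >= disc[j] & bounds < disc[j + 1]]
      max(inb)  # the boundary actually carrying the transition
    }, integer(1))
  }
  rl <- rle(labels)
  structure(
    list(
      final_sequence = paste(copy$seq, collapse = ""),
      crossovers = crossovers,
      outcome_class = outcome,
      labels = labels,
      labels_rle = paste(paste0(rl$values, ":", rl$lengths), collapse = ",")
    ),
    class = "chimera_truth"
  )
}

#' @export
print.chimera_truth <- function(x, ...) {
  cat("<chimera_truth> ", x$outcome_class, ", ", length(x$crossovers),
      " observable crossover(s)",
      if (length(x$crossovers)) paste0(" at ",
                                       paste(x$crossovers, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

.apply_mutations <- function(seq_chr, rate) {
  if (rate <= 0) return(seq_chr)
  hit <- which(stats::runif(length(seq_chr)) < rate)
  for (p in hit) {
    seq_chr[p] <- sample(setdiff(.BASES, seq_chr[p]), 1)
  }
  seq_chr
}

#' Deterministic serial-dilution enrichment
#'
#' Exponential growth competition under a serial-dilution regime: each cycle,
#' every genotype grows as `exp(rate * t)` where the cycle time `t` is set by
#' growth back to fixed density (total growth factor `1 / dilution`), then
#' frequencies are renormalized. Fully deterministic: no drift, no mutation.
#'
#' @param rates Named positive growth rates (per hour) per genotype.
#' @param init_freq Initial frequencies, same names, summing to 1.
#' @param config A [sim_config()] (`dilution`, `n_cycles`).
#' @return A tibble of class `enrichment_trajectory` (`cycle`, `genotype`,
#'   `frequency`), cycles `0..n_cycles`; frequencies sum to 1 at every cycle.
#' @examples
#' simulate_enrichment(c(mut = 0.5, wt = 0.25), c(mut = 0.01, wt = 0.99),
#'                     sim_config())
#' @export
simulate_enrichment <- function(rates, init_freq, config = sim_config()) {
  stopifnot(length(rates) == length(init_freq), all(rates > 0),
            all(init_freq >= 0))
  if (abs(sum(init_freq) - 1) > 1e-8) abort("init_freq must sum to 1")
  if (is.null(names(rates))) names(rates) <- paste0("g", seq_along(rates))
  if (is.null(names(init_freq))) names(init_freq) <- names(rates)
  rates <- rates[names(init_freq)]
  target <- 1 / config$dilution
  f <- init_freq / sum(init_freq)
  traj <- list(tibble(cycle = 0L, genotype = names(f), frequency = unname(f)))
  for (cyc in seq_len(config$n_cycles)) {
    t <- .cycle_time(f, rates, target)
    grown <- f * exp(rates * t)
    f <- grown / sum(grown)
    traj[[cyc + 1]] <- tibble(cycle = cyc, genotype = names(f),
                              frequency = unname(f))
  }
  out <- dplyr::bind_rows(traj)
  class(out) <- c("enrichment_trajectory", class(out))
  out
}

# solve sum(f * exp(r t)) = target; g is convex increasing, so Newton
# overshoots once then converges monotonically from above
.cycle_time <- function(f, r, target) {
  t <- log(target) / max(r)
  for (i in 1:200) {
    g <- sum(f * exp(r * t))
    dg <- sum(f * r * exp(r * t))
    step <- (g - target) / dg
    t <- t - step
    if (abs(g - target) <= 1e-14 * target) break
  }
  t
}

#' @rdname simulate_enrichment
#' @param object An `enrichment_trajectory`.
#' @param ... Unused.
#' @export
autoplot.enrichment_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cycle, y = .data$frequency,
                                       colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Enrichment cycle", y = "Frequency") +
    ggplot2::theme_minimal()
}

#' Generate a ground-truth chimera benchmark
#'
#' Runs the full mechanism end to end for `n_clones` independent clones --
#' integration, conversion cycles, resolution to homogeneity, optional point
#' mutation -- and collects the final sequences with their per-clone ground
#' truth. Reproducible: identical `seed` and arguments give byte-identical
#' output (one RNG stream is threaded through all stages).
#'
#' @param config A [sim_config()].
#' @param n_clones Number of clones (0 gives empty tables with headers).
#' @param seed Optional integer seed.
#' @param parents Optional two-row parent record tibble (`host` first); by
#'   default a synthetic pair is generated with `length`, `identity`, `gc`.
#' @param length,identity,gc Parent-pair parameters used when `parents` is
#'   `NULL`. Defaults emulate the focal donor of the emulated system: a
#'   1521-base gene at 85.9% identity to the host, GC-rich as befits a
#'   thermophile.
#' @param dir Optional output directory; when given, writes
#'   `chimeras.fasta` and `truth.tsv` there.
#' @return A list of class `chimera_benchmark`: `sequences` (record tibble),
#'   `truth` (tibble `clone_id`, `class`, `n_crossovers`, `crossovers`
#'   comma-separated, `labels_rle`), `parents`, `config`.
#' @export
generate_benchmark <- function(config = sim_config(), n_clones, seed = NULL,
                               parents = NULL, length = 1521,
                               identity = 85.9, gc = 62, dir = NULL) {
  stopifnot(n_clones >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(parents)) {
    parents <- make_parent_pair(length, identity, gc)
  }
  host <- parents$residues[1]
  donor <- parents$residues[2]
  seqs <- vector("list", n_clones)
  truths <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    run <- simulate_integration(host, donor, config)
    st <- simulate_conversion_cycles(run$state, config)
    tr <- resolve_to_homogeneity(st, "random_fix")
    final <- .apply_mutations(strsplit(tr$final_sequence, "")[[1]],
                              config$mutation_rate)
    id <- sprintf("clone_%04d", i)
    seqs[[i]] <- tibble(id = id,
                        residues = paste(final, collapse = ""),
                        description = tr$outcome_class)
    truths[[i]] <- tibble(
      clone_id = id,
      class = tr$outcome_class,
      n_crossovers = length(tr$crossovers),
      crossovers = paste(tr$crossovers, collapse = ","),
      labels_rle = tr$labels_rle
    )
  }
  sequences <- if (n_clones) dplyr::bind_rows(seqs) else
    tibble(id = character(), residues = character(),
           description = character())
  truth <- if (n_clones) dplyr::bind_rows(truths) else
    tibble(clone_id = character(), class = character(),
           n_crossovers = integer(), crossovers = character(),
           labels_rle = character())
  out <- structure(
    list(sequences = sequences, truth = truth, parents = parents,
         config = config),
    class = "chimera_benchmark"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(sequences, file.path(dir, "chimeras.fasta"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  out
}

#' @export
print.chimera_benchmark <- function(x, ...) {
  cat("<chimera_benchmark> ", nrow(x$sequences), " clone(s)\n", sep = "")
  if (nrow(x$truth)) print(dplyr::count(x$truth, .data$class))
  invisible(x)
}
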