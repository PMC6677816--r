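test_that("parent pairs hit the requested divergence deterministically", {
  same <- make_parent_pair(200, 100, seed = 1)
  expect_identical(same$residues[1], same$residues[2])

  pp <- make_parent_pair(1500, 85.9, gc = 62, seed = 2)
  h <- strsplit(pp$residues[1], "")[[1]]
  d <- strsplit(pp$residues[2], "")[[1]]
  realized <- 100 * mean(h == d)
  expect_lt(abs(realized - 85.9), 0.5)
  gc_host <- 100 * mean(h %in% c("G", "C"))
  expect_lt(abs(gc_host - 62), 5)

  expect_identical(make_parent_pair(300, 90, seed = 7),
                   make_parent_pair(300, 90, seed = 7))
  expect_false(identical(make_parent_pair(300, 90, seed = 7)$residues,
                         make_parent_pair(300, 90, seed = 8)$residues))

  cl <- make_parent_pair(1500, 90, placement = "clustered", seed = 4)
  hc <- strsplit(cl$residues[1], "")[[1]]
  dc <- strsplit(cl$residues[2], "")[[1]]
  expect_lt(abs(100 * mean(hc == dc) - 90), 0.5)

  expect_error(make_parent_pair(100, 0), "target_identity")
})

test_that("integration recombines one copy with two eligible crossovers", {
  pp <- make_parent_pair(400, 85, seed = 10)
  cfg <- sim_config(flank_len = 300, conversion_cycles = 0)

  # donor identical to host: no discriminating site, intact-equivalent
  run0 <- simulate_integration(pp$residues[1], pp$residues[1], cfg, seed = 1)
  expect_equal(run0$truth$outcome_class, "intact")

  set.seed(2)
  classes <- character(60)
  for (i in 1:60) {
    run <- simulate_integration(pp$residues[1], pp$residues[2], cfg)
    classes[i] <- run$truth$outcome_class
    expect_length(run$state$copies, cfg$ploidy)
    # untouched copies stay pure host
    expect_true(all(run$state$copies[[2]]$labels == "host"))
    if (run$truth$outcome_class == "full_replacement") {
      expect_identical(run$truth$final_sequence, pp$residues[2])
    }
    # perfect mosaic: every base equals at least one parent at that position
    f <- strsplit(run$truth$final_sequence, "")[[1]]
    h <- strsplit(pp$residues[1], "")[[1]]
    d <- strsplit(pp$residues[2], "")[[1]]
    expect_true(all(f == h | f == d))
  }
  expect_true("full_replacement" %in% classes)  # flank-to-flank crossovers occur
})

test_that("crossovers in flanks only force donor or host genes exactly", {
  # parents too diverged for any in-gene homology: with l_min above every
  # in-gene stretch, both crossovers must fall in the flanks
  pp <- make_parent_pair(300, 55, seed = 12)
  cfg <- sim_config(flank_len = 200, l_min = 60, conversion_cycles = 0)
  set.seed(3)
  for (i in 1:20) {
    run <- simulate_integration(pp$residues[1], pp$residues[2], cfg)
    expect_true(run$truth$outcome_class %in% c("intact", "full_replacement"))
    if (run$truth$outcome_class == "full_replacement") {
      expect_identical(run$truth$final_sequence, pp$residues[2])
    } else {
      expect_identical(run$truth$final_sequence, pp$residues[1])
    }
  }
  expect_error(
    simulate_integration(pp$residues[1], pp$residues[2],
                         sim_config(flank_len = 0, l_min = 60)),
    "no homology")
})

test_that("conversion cycles splice tracts between copies and keep labels traceable", {
  pp <- make_parent_pair(500, 85, seed = 20)
  cfg <- sim_config(flank_len = 300, conversion_cycles = 5, ploidy = 3)
  run <- simulate_integration(pp$residues[1], pp$residues[2], cfg, seed = 21)
  st <- simulate_conversion_cycles(run$state, cfg)
  h <- strsplit(pp$residues[1], "")[[1]]
  d <- strsplit(pp$residues[2], "")[[1]]
  for (cp in st$copies) {
    # every base agrees with the parent its label claims
    expect_true(all(ifelse(cp$labels == "host", h, d) == cp$seq))
  }

  # homogeneous states are fixed points
  hom <- run$state
  hom$copies <- replicate(3, list(seq = h, labels = rep("host", length(h))),
                          simplify = FALSE)
  hom$heterozygous <- FALSE
  after <- simulate_conversion_cycles(hom, cfg, seed = 5)
  expect_identical(after$copies, hom$copies)
})

test_that("resolution fixes one copy with the documented frequencies", {
  pp <- make_parent_pair(200, 85, seed = 30)
  h <- strsplit(pp$residues[1], "")[[1]]
  d <- strsplit(pp$residues[2], "")[[1]]
  mk <- function(seq, lab) list(seq = seq, labels = rep(lab, length(seq)))
  state <- structure(
    list(copies = list(mk(h, "host"), mk(h, "host"), mk(h, "host"),
                       mk(d, "donor")),
         parents = list(host = h, donor = d),
         config = sim_config(), heterozygous = TRUE),
    class = "genome_state")

  expect_equal(resolve_to_homogeneity(state, "majority_fix",
                                      seed = 1)$outcome_class, "intact")

  set.seed(31)
  fixed <- replicate(400, resolve_to_homogeneity(state,
                                                 "random_fix")$outcome_class)
  p_host <- mean(fixed == "intact")
  se <- sqrt(0.75 * 0.25 / 400)
  expect_lt(abs(p_host - 0.75), 3 * se)
})

test_that("enrichment is a deterministic replicator on the simplex", {
  cfg <- sim_config(dilution = 1 / 1000, n_cycles = 5)
  eq <- simulate_enrichment(c(a = 0.4, b = 0.4), c(a = 0.3, b = 0.7), cfg)
  eq_w <- tidyr::pivot_wider(eq, names_from = "genotype",
                             values_from = "frequency")
  expect_equal(eq_w$a, rep(0.3, 6), tolerance = 1e-12)

  tr <- simulate_enrichment(c(slow = 0.25, fast = 0.5),
                            c(slow = 0.99, fast = 0.01), cfg)
  sums <- dplyr::summarise(dplyr::group_by(tr, .data$cycle),
                           s = sum(.data$frequency))$s
  expect_equal(sums, rep(1, 6), tolerance = 1e-12)
  final_fast <- tr$frequency[tr$cycle == 5 & tr$genotype == "fast"]
  expect_gt(final_fast, 0.5)  # the fast grower takes over
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("benchmark output is reproducible, truthful and homology-bounded", {
  cfg <- sim_config(flank_len = 300, conversion_cycles = 2)
  pp <- make_parent_pair(400, 86, seed = 40)

  empty <- generate_benchmark(cfg, 0, seed = 1, parents = pp)
  expect_equal(nrow(empty$sequences), 0)
  expect_named(empty$truth, c("clone_id", "class", "n_crossovers",
                              "crossovers", "labels_rle"))

  b1 <- generate_benchmark(cfg, 15, seed = 2, parents = pp)
  b2 <- generate_benchmark(cfg, 15, seed = 2, parents = pp)
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$truth, b2$truth)

  # every true crossover lies inside a parent-parent shared stretch >= l_min
  h <- strsplit(pp$residues[1], "")[[1]]
  d <- strsplit(pp$residues[2], "")[[1]]
  same <- h == d
  runs <- rle(same)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  ok_run <- runs$values & runs$lengths >= cfg$l_min
  for (i in seq_len(nrow(b1$truth))) {
    for (x in parse_crossovers(b1$truth$crossovers[i])) {
      in_ok <- any(ok_run & starts <= x & ends > x)
      expect_true(in_ok, info = paste("crossover", x))
    }
  }

  dir <- withr::local_tempdir()
  generate_benchmark(cfg, 3, seed = 5, parents = pp, dir = dir)
  expect_true(file.exists(file.path(dir, "chimeras.fasta")))
  expect_equal(nrow(read_fasta(file.path(dir, "chimeras.fasta"))), 3)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})

test_that("with mutation, inferred intervals still cover most true crossovers", {
  cfg <- sim_config(flank_len = 500, conversion_cycles = 3,
                    mutation_rate = 0.001)
  bm <- generate_benchmark(cfg, 60, seed = 60, length = 1521, identity = 85.9)
  covered <- 0; total <- 0
  for (i in seq_len(nrow(bm$truth))) {
    tr <- parse_crossovers(bm$truth$crossovers[i])
    if (!length(tr)) next
    # mutations are rare relative to crossovers per opportunity here, so the
    # likelihood-consistent analysis mode prices a mismatch well above a switch
    inf <- infer_clone(bm$sequences$residues[i], bm$parents,
                       mismatch_cost = 6)
    bp <- inf$path$breakpoints
    total <- total + length(tr)
    for (x in tr) {
      covered <- covered + any(bp$left_pos <= x & x < bp$right_pos)
    }
  }
  expect_gt(total, 20)
  expect_gte(covered / total, 0.95)
})
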