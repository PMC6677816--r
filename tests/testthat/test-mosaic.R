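make_sites <- function(states, columns = seq_along(states) * 10L) {
  tibble::tibble(
    column = columns, rec_pos = columns,
    parent_a = "A", parent_b = "G",
    recombinant = dplyr::case_when(states == "matches_A" ~ "A",
                                   states == "matches_B" ~ "G",
                                   TRUE ~ "T"),
    state = states
  )
}

test_that("discriminating sites are exactly the gap-free differing columns", {
  t0 <- align_triple("ACGT", "ACGT", "ACGT")
  expect_equal(nrow(find_discriminating_sites(t0)), 0)

  t1 <- align_triple("ACGT", "ACGT", "ATGT")
  s <- find_discriminating_sites(t1)
  expect_equal(s$column, 2)
  expect_equal(s$state, "matches_A")

  set.seed(5)
  for (i in 1:8) {
    r <- rand_seq(100); a <- rand_seq(100); b <- rand_seq(sample(95:105, 1))
    tr <- align_triple(r, a, b)
    s <- find_discriminating_sites(tr)
    # independent per-column scan
    ch <- do.call(rbind, strsplit(unname(tr$rows), ""))
    expected <- which(ch[1, ] != "-" & ch[2, ] != "-" & ch[3, ] != "-" &
                        ch[2, ] != ch[3, ])
    expect_equal(s$column, expected)
    expect_equal(attr(s, "n_gapped"), sum(colSums(ch == "-") > 0))
  }
})

test_that("single-parent site patterns give trivial mosaics", {
  p <- infer_mosaic(make_sites(rep("matches_A", 5)))
  expect_equal(nrow(p$segments), 1)
  expect_equal(p$segments$parent, "A")
  expect_equal(p$cost, 0)
  expect_equal(boundary_points(p), integer(0))
  expect_equal(call_chimera_class(p), "intact")
})

test_that("a single switch yields one breakpoint at the first new-parent site", {
  st <- c("matches_A", "matches_B", "matches_B")
  # with mutations ruled out, the mosaic must switch: one breakpoint whose
  # point location is the first new-parent site and whose ambiguity interval
  # spans the flanking sites (10, 50); matches exhaustive enumeration
  p <- infer_mosaic(make_sites(st, columns = c(10L, 50L, 90L)),
                    switch_cost = 2, mismatch_cost = 3)
  expect_equal(nrow(p$breakpoints), 1)
  expect_equal(p$breakpoints$left_pos, 10)
  expect_equal(p$breakpoints$boundary_pos, 50)
  expect_equal(boundary_points(p), 50)
  expect_equal(call_chimera_class(p), "chimera")
  oracle <- brute_mosaic(st, 2, 3)
  expect_equal(p$cost, oracle$cost)
  expect_equal(p$sites$label, oracle$labels)

  # under the default costs one crossover and two mutations tie at cost 2,
  # and the fewer-segments tie-break keeps a single host segment -- exactly
  # what the exhaustive oracle selects under the same ordering
  pd <- infer_mosaic(make_sites(st, columns = c(10L, 50L, 90L)))
  od <- brute_mosaic(st, 2, 1)
  expect_equal(pd$cost, od$cost)
  expect_equal(pd$sites$label, od$labels)
  expect_equal(nrow(pd$breakpoints), 0)
})

test_that("DP cost and labeling match exhaustive enumeration", {
  set.seed(23)
  states_pool <- c("matches_A", "matches_B", "matches_neither")
  for (i in 1:60) {
    n <- sample(1:12, 1)
    st <- sample(states_pool, n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
    sw <- sample(c(1, 2, 3.5), 1)
    mm <- sample(c(0.5, 1, 2), 1)
    p <- infer_mosaic(make_sites(st), switch_cost = sw, mismatch_cost = mm)
    oracle <- brute_mosaic(st, sw, mm)
    expect_equal(p$cost, oracle$cost, info = paste(st, collapse = ","))
    expect_equal(p$sites$label, oracle$labels,
                 info = paste(st, collapse = ","))
  }
})

test_that("infinite mismatch cost makes labels track site states exactly", {
  set.seed(31)
  for (i in 1:20) {
    st <- sample(c("matches_A", "matches_B"), sample(2:30, 1), replace = TRUE)
    p <- infer_mosaic(make_sites(st), mismatch_cost = Inf)
    expect_equal(p$sites$label, ifelse(st == "matches_A", "A", "B"))
    expect_equal(nrow(p$breakpoints), sum(st[-1] != st[-length(st)]))
  }
  expect_error(
    infer_mosaic(make_sites("matches_neither"), mismatch_cost = Inf),
    "matches_neither")
})

test_that("raising switch_cost never increases the number of segments", {
  set.seed(37)
  for (i in 1:30) {
    st <- sample(c("matches_A", "matches_B", "matches_neither"),
                 sample(2:11, 1), replace = TRUE)
    segs <- sapply(c(0.5, 1, 2, 4, 8), function(sw) {
      # verified against the exhaustive optimum at each cost
      p <- infer_mosaic(make_sites(st), switch_cost = sw)
      expect_equal(p$cost, brute_mosaic(st, sw, 1)$cost)
      nrow(p$segments)
    })
    expect_true(all(diff(segs) <= 0))
  }
})

test_that("empty site lists are rejected with guidance", {
  expect_error(infer_mosaic(make_sites(character(0))), "not be distinguished")
})

test_that("chimera classes cover intact, full replacement and chimera", {
  expect_equal(call_chimera_class(
    infer_mosaic(make_sites(rep("matches_B", 4)))), "full_replacement")
  expect_equal(call_chimera_class(
    infer_mosaic(make_sites(c("matches_A", "matches_B")))), "chimera")
})

test_that("tidy, glance and autoplot work on a mosaic path", {
  p <- infer_mosaic(make_sites(c("matches_A", "matches_B", "matches_B")),
                    mismatch_cost = 3)
  expect_equal(nrow(tidy(p)), 2)
  g <- glance(p)
  expect_equal(g$n_breakpoints, 1)
  expect_equal(g$class, "chimera")
  expect_s3_class(autoplot(p), "ggplot")
})
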