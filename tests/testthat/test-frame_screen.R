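test_that("site intersection matches set logic and a brute-force oracle", {
  disjoint <- make_site_table(c("p1", "p2"), c("S", "S"), c(1, 2),
                              A = c(1, NA), B = c(NA, 1))
  expect_equal(intersect_sites(disjoint, "A", "B")$n_sites, 0)

  same <- make_site_table(c("p1", "p2"), c("S", "S"), c(1, 2),
                          A = c(1, 2), B = c(3, 4))
  expect_equal(intersect_sites(same, "A", "B")$sites, same$site_key)

  expect_error(intersect_sites(same, "A", "nope"), "unknown condition")

  set.seed(5)
  for (i in 1:3) {
    n <- 200
    tab <- make_site_table(sprintf("p%02d", sample(1:20, n, TRUE)),
                           rep("S", n), seq_len(n) * 7,
                           A = ifelse(runif(n) < 0.4, NA, runif(n)),
                           B = ifelse(runif(n) < 0.4, NA, runif(n)))
    res <- intersect_sites(tab, "A", "B")
    expected <- oracle_intersect(tab, "A", "B")
    expect_setequal(res$sites, expected)
    expect_equal(res$n_proteins,
                 length(unique(tab$protein_id[tab$site_key %in% expected])))
  }
})

test_that("fold changes divide intersected cells and skip zero cells", {
  tab <- make_site_table(c("p1", "p2", "p3"), rep("S", 3), c(1, 2, 3),
                         SS = c(1.0, 2, 0), AAS = c(2.35, 2, 5))
  msg <- capture_messages(r <- compute_ratios(tab, "AAS", "SS"))
  expect_match(paste(msg, collapse = ""), "skipped 1")
  expect_equal(r$fc[r$site_key == "p1:S1"], 2.35)
  expect_equal(r$fc[r$site_key == "p2:S2"], 1.0)
  expect_false("p3:S3" %in% r$site_key)  # zero cell: excluded, not infinite
  ud <- updown_counts(r)
  expect_equal(ud, c(up = 1L, down = 0L))
})

test_that("reversing a contrast inverts fold changes and swaps counts", {
  set.seed(9)
  n <- 150
  tab <- make_site_table(sprintf("p%03d", 1:n), rep("S", n), 1:n * 3,
                         A = rlnorm(n), B = rlnorm(n))
  fwd <- compute_ratios(tab, "A", "B")
  rev <- compute_ratios(tab, "B", "A")
  expect_equal(fwd$fc, 1 / rev$fc[match(fwd$site_key, rev$site_key)])
  expect_equal(unname(updown_counts(fwd)), rev(unname(updown_counts(rev))))
})

test_that("frame rules classify the leucine screen example sites", {
  ratios <- screen_examples_to_ratios(leucine_screen_examples())
  asg <- assign_frames(ratios)
  expect_equal(asg$frame1, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(asg$frame2, c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(asg$frame3 | asg$frame4))
})

test_that("threshold boundaries are strict and frames may overlap", {
  ratios <- tibble::tibble(
    site_key = c("a", "b", "c"), protein_id = c("a", "b", "c"),
    residue = "S",
    fc_aas_ss = c(1.0, 2.0, 0.01),
    fc_leus_aas = c(0.06, 0.4, 6.11),
    fc_alls_aas = c(NA, NA, 23.49))
  asg <- assign_frames(ratios)
  expect_false(any(asg$frame1[1:2]))  # fc = 1 and fc = 2 both excluded
  # one site positively regulated by leucine AND by all amino acids
  expect_true(asg$frame2[3] && asg$frame4[3])

  expect_error(assign_frames(ratios, theta_up = 1), "theta_up")
  expect_error(assign_frames(ratios, theta_down = 1.2), "theta_down")
})

test_that("the ten-fold top tier retains the all-amino-acid examples", {
  asg <- assign_frames(screen_examples_to_ratios(all_aa_screen_examples()))
  expect_true(all(asg$frame4))
  top <- top_subset(asg, 4, log10_threshold = 1)
  expect_equal(nrow(top), 17)
  expect_equal(attr(top, "n_proteins"), 12)
  expect_true(all(top$top_flag))

  # a pair passing |log2 FC| > 1 but not the ten-fold rule is excluded
  weak <- tibble::tibble(site_key = "w", protein_id = "w", residue = "S",
                         fc_aas_ss = 0.5, fc_leus_aas = NA_real_,
                         fc_alls_aas = 2)
  expect_equal(nrow(top_subset(assign_frames(weak), 4)), 0)
})

test_that("top subset equals a brute-force filter and nests in its frame", {
  set.seed(21)
  for (i in 1:3) {
    n <- 300
    ratios <- tibble::tibble(
      site_key = sprintf("s%03d", 1:n),
      protein_id = sprintf("p%02d", sample(1:40, n, TRUE)),
      residue = "S",
      fc_aas_ss = exp(runif(n, -6, 6) * log(2)),
      fc_leus_aas = exp(runif(n, -6, 6) * log(2)),
      fc_alls_aas = exp(runif(n, -6, 6) * log(2)))
    asg <- assign_frames(ratios)
    top <- top_subset(asg, 4)
    expected <- oracle_top4(asg)
    expect_setequal(top$site_key, expected$site_key)
    expect_true(all(top$site_key %in% asg$site_key[asg$frame4]))
  }
})

test_that("frame sets nest inside their contrasts' up/down sets", {
  set.seed(33)
  n <- 400
  ratios <- tibble::tibble(
    site_key = sprintf("s%03d", 1:n), protein_id = sprintf("p%03d", 1:n),
    residue = "S",
    fc_aas_ss = exp(rnorm(n, 0, 1.5)),
    fc_leus_aas = exp(rnorm(n, 0, 1.5)),
    fc_alls_aas = exp(rnorm(n, 0, 1.5)))
  asg <- assign_frames(ratios)
  up <- function(col) sum(ratios[[col]] > 2)
  dn <- function(col) sum(ratios[[col]] < 0.5)
  expect_lte(sum(asg$frame1), min(up("fc_aas_ss"), dn("fc_leus_aas")))
  expect_lte(sum(asg$frame2), min(dn("fc_aas_ss"), up("fc_leus_aas")))
  expect_lte(sum(asg$frame3), min(up("fc_aas_ss"), dn("fc_alls_aas")))
  expect_lte(sum(asg$frame4), min(dn("fc_aas_ss"), up("fc_alls_aas")))
})

test_that("the whole screen runs from a hand-built five-condition table", {
  # two planted regulated sites and two stable sites
  tab <- make_site_table(
    c("pA", "pB", "pC", "pD"), rep("S", 4), c(10, 20, 30, 40),
    NT = c(1, 1, 1, 1), SS = c(1, 1, 1, 1),
    AAS = c(16, 1 / 16, 1, 1), LeuS = c(16, 1, 1, 1),
    AllS = c(16, 1, 1, 1))
  # pA: up under starvation, unchanged by restimulation -> no frame
  # pB: down under starvation, restored 16x by both stimuli -> frames 2 & 4
  ratios <- compute_frame_ratios(tab)
  asg <- assign_frames(ratios)
  expect_equal(asg$site_key[asg$frame2], "pB:S20")
  expect_equal(asg$site_key[asg$frame4], "pB:S20")
  expect_false(any(asg$frame1 | asg$frame3))
})
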