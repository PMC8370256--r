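test_that("reliability filtering respects threshold and missing policy", {
  rec <- make_records("NT", "chx:1", rep("S10", 10), 1:10,
                      c(0.1, 0.2, 0.5, 0.7, 0.8, 0.9, 0.95, 1, 0.76, 0.99))
  expect_identical(filter_reliable(rec, 0), rec)
  expect_equal(nrow(suppressMessages(filter_reliable(rec, 0.75))), 6)

  missing <- make_records("NT", "chx:1", rep("S10", 4), 1:4)
  expect_identical(filter_reliable(missing, 0.75, missing = "keep"), missing)
  expect_equal(nrow(suppressMessages(
    filter_reliable(missing, 0.75, missing = "drop"))), 0)
})

test_that("site merging is additive and attributes multi-site peptides fully", {
  rec <- make_records("NT", "chx:X", c("S10", "S10"), c(3, 5))
  tab <- merge_to_sites(rec)
  expect_equal(tab$NT[tab$site_key == "chx:X:S10"], 8)

  multi <- make_records("NT", "chx:X", "S10;T14", 4)
  tab2 <- merge_to_sites(multi)
  expect_equal(tab2$NT[tab2$site_key == "chx:X:S10"], 4)
  expect_equal(tab2$NT[tab2$site_key == "chx:X:T14"], 4)
})

test_that("exact duplicate records are collapsed before summing", {
  rec <- make_records("NT", "chx:X", c("S10", "S10"), c(3, 3))
  rec$peptide <- c("AAASK", "AAASK")  # identical in every field
  tab <- merge_to_sites(rec)
  expect_equal(tab$NT, 3)

  # same peptide, different abundance: both genuine observations
  rec2 <- make_records("NT", "chx:X", c("S10", "S10"), c(3, 4))
  rec2$peptide <- c("AAASK", "AAASK")
  expect_equal(merge_to_sites(rec2)$NT, 7)
})

test_that("conflicting residue letters at one site are rejected", {
  rec <- make_records("NT", "chx:X", c("S10", "T10"), c(1, 2))
  expect_error(merge_to_sites(rec), "chx:X:10")
})

test_that("merging equals a brute-force group-by-sum oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    rec <- random_records(120, n_proteins = 6,
                          conditions = c("NT", "SS", "AAS"))
    # plant a few exact duplicates the merge must collapse
    rec <- dplyr::bind_rows(rec, rec[sample(nrow(rec), 10), ])
    tab <- merge_to_sites(rec)
    expected <- oracle_merge(rec)
    for (i in seq_len(nrow(expected))) {
      key <- site_key(expected$protein_id[i], expected$residue[i],
                      expected$position[i])
      got <- tab[[expected$condition[i]]][tab$site_key == key]
      expect_equal(got, expected$abundance[i], tolerance = 1e-12)
    }
    # no extra observed cells beyond the oracle's
    long_n <- sum(!is.na(as.matrix(tab[, site_conditions(tab)])))
    expect_equal(long_n, nrow(expected))
  }
})

test_that("median normalisation matches its definition and invariances", {
  tab <- make_site_table(rep("p", 3), rep("S", 3), c(1, 2, 3) * 10,
                         A = c(2, 4, 8))
  norm <- normalize_sites(tab, "median")
  expect_equal(norm$A, c(0.5, 1, 2))
  expect_identical(normalize_sites(tab, "none"), tab)

  # a column that is a positive rescaling of another normalises identically
  tab2 <- make_site_table(rep("p", 4), rep("S", 4), (1:4) * 10,
                          A = c(1, 3, 5, 9), B = 2 * c(1, 3, 5, 9))
  n2 <- normalize_sites(tab2, "median")
  expect_equal(n2$A, n2$B)
  # idempotence
  expect_equal(normalize_sites(n2, "median"), n2)

  bad <- make_site_table("p", "S", 10, A = NA_real_)
  expect_error(normalize_sites(bad, "median"), "A")
})

test_that("total normalisation divides by the column sum", {
  tab <- make_site_table(rep("p", 3), rep("S", 3), (1:3) * 10,
                         A = c(1, 2, 7))
  expect_equal(normalize_sites(tab, "total")$A, c(0.1, 0.2, 0.7))
})

test_that("residue composition reproduces known count layouts", {
  # layout matching the untreated group of the screen: 1267 S, 135 T, 5 Y
  n <- c(S = 1267L, T = 135L, Y = 5L)
  tab <- make_site_table(sprintf("p%04d", seq_len(sum(n))),
                         rep(names(n), n), seq_len(sum(n)),
                         NT = rep(1, sum(n)))
  cs <- composition_summary(tab, "NT")
  expect_equal(cs$n_sites, 1407L)
  expect_equal(cs$counts$pct[cs$counts$residue == "S"], 90.05)
  expect_equal(cs$counts$pct[cs$counts$residue == "T"], 9.59)
  expect_equal(cs$counts$pct[cs$counts$residue == "Y"], 0.36)

  # amino-acid-starved layout: 242 S, 24 T, 3 Y
  n2 <- c(S = 242L, T = 24L, Y = 3L)
  tab2 <- make_site_table(sprintf("q%03d", seq_len(sum(n2))),
                          rep(names(n2), n2), seq_len(sum(n2)),
                          AAS = rep(1, sum(n2)))
  cs2 <- composition_summary(tab2, "AAS")
  expect_equal(cs2$n_sites, 269L)
  expect_equal(cs2$counts$pct[cs2$counts$residue == "Y"], 1.12)

  single <- make_site_table("p", "T", 5, NT = 3)
  expect_equal(composition_summary(single, "NT")$counts$pct,
               c(0, 100, 0))
})

test_that("composition percentages sum to 100 within rounding", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:500, 1)
    tab <- make_site_table(sprintf("p%03d", 1:n),
                           sample(c("S", "T", "Y"), n, TRUE,
                                  prob = c(0.7, 0.2, 0.1)),
                           1:n, X = runif(n, 0.5, 2))
    cs <- composition_summary(tab, "X")
    expect_lt(abs(sum(cs$counts$pct) - 100), 0.02 + 1e-9)
  }
})

test_that("site tables round-trip through the TSV serialisation", {
  tab <- make_site_table(c("chx:1", "chx:1", "chx:2"), c("S", "T", "Y"),
                         c(10, 20, 5), NT = c(1.5, NA, 2),
                         SS = c(NA, 3, 4.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path)
  back <- read_site_table(path)
  expect_equal(back$site_key, tab$site_key)
  expect_equal(back$protein_id, tab$protein_id)
  expect_equal(back$position, tab$position)
  expect_equal(back$NT, tab$NT)
  expect_equal(back$SS, tab$SS)
})
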