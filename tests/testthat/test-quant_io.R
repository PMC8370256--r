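test_that("site tokens parse in three-letter and one-letter spellings", {
  expect_equal(parse_site_token("Ser25"),
               tibble::tibble(residue = "S", position = 25L))
  expect_equal(parse_site_token("Thr688")$residue, "T")
  expect_equal(parse_site_token("Tyr187")$position, 187L)
  expect_equal(parse_site_token("Y1"),
               tibble::tibble(residue = "Y", position = 1L))
  expect_error(parse_site_token("His42"), "unsupported residue")
  expect_error(parse_site_token("S"), "malformed")
})

test_that("site key canonical form is a bijection on valid triples", {
  set.seed(11)
  for (i in 1:50) {
    pid <- paste0("chx:", sample(1e5:1e6, 1))
    res <- sample(c("S", "T", "Y"), 1)
    pos <- sample(1:5000, 1)
    key <- site_key(pid, res, pos)
    back <- parse_site_key(key)
    expect_equal(back$protein_id, pid)
    expect_equal(back$residue, res)
    expect_equal(back$position, pos)
    expect_equal(site_key(back$protein_id, back$residue, back$position), key)
  }
})

test_that("a well-formed peptide table reads row-for-row in order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tprotein_id\tmod_positions\tabundance\treliability",
               "AASPK\tchx:1\tS10;T14\t4\t0.9",
               "GGSR\tchx:1\tS25\t3\t",
               "TTYK\tchx:2\tY3\t5.5\t0.4"), path)
  rec <- read_peptide_table(path, condition = "NT")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$peptide, c("AASPK", "GGSR", "TTYK"))
  expect_equal(rec$mod_positions[[1]], c(10L, 14L))
  expect_equal(rec$residues[[1]], c("S", "T"))
  expect_true(is.na(rec$reliability[2]))
  expect_equal(rec$condition, rep("NT", 3))
})

test_that("malformed rows are skipped with line numbers, others returned", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tprotein_id\tmod_positions\tabundance",
               "AASPK\tchx:1\tS10\t4",
               "GGSR\tchx:1\tS25\tNA",
               "TTYK\tchx:2\tH3\t5"), path)
  expect_warning(rec <- read_peptide_table(path, condition = "SS"),
                 "line 3")
  expect_equal(nrow(rec), 1)
  skipped <- attr(rec, "skipped")
  expect_equal(skipped$line, c(3L, 4L))
})

test_that("a missing required column is a schema error naming the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tprotein_id\tabundance", "AASPK\tchx:1\t4"), path)
  expect_error(read_peptide_table(path, condition = "NT"), "mod_positions")
})

test_that("peptide records round-trip through write and read", {
  rec <- make_records("AllS", c("chx:1", "chx:2"),
                      c("S10;T14;Y20", "S5"), c(4.25, 1 / 3),
                      c(0.9, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(rec, path)
  back <- read_peptide_table(path)
  expect_equal(back$condition, rec$condition)
  expect_equal(back$peptide, rec$peptide)
  expect_equal(back$protein_id, rec$protein_id)
  expect_equal(back$mod_positions, rec$mod_positions)
  expect_equal(back$residues, rec$residues)
  expect_equal(back$abundance, rec$abundance)
  expect_equal(back$reliability, rec$reliability)
})

test_that("generated peptide tables read back with the bookkept totals", {
  sim <- simulate_phospho(sim_config(n_frame1 = 10, n_frame2 = 10,
                                     n_frame3 = 10, n_frame4 = 30,
                                     n_null = 60), seed = 404)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  for (cond in unname(sim$config$conditions)) {
    rec <- read_peptide_table(paths[[paste0("peptides_", cond)]])
    expect_gt(nrow(rec), 0)
    expect_equal(sum(rec$abundance), sim$record_totals[[cond]],
                 tolerance = 1e-10)
  }
})

test_that("FASTA reading concatenates wrapped lines and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "ACDEF", "GHIKL", "MNP",
               ">p2", "WYSTV"), path)
  seqs <- read_fasta(path)
  expect_equal(seqs, c(p1 = "ACDEFGHIKLMNP", p2 = "WYSTV"))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACD", ">p1", "EFG"), dup)
  expect_error(read_fasta(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(out <- read_fasta(empty), "no sequences")
  expect_length(out, 0)
})

test_that("FASTA writing round-trips through reading", {
  seqs <- c(a = "ACDEFGHIKLMNPQRSTVWY", b = strrep("SATP", 40))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})

test_that("GMT terms parse with hand-counted memberships", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("termA\tdesc a\tp1\tp2\tp3\tp4",
               "termB\tdesc b\tp2\tp5\tp6",
               "termC\tdesc c\tp7\tp8\tp9\tp10\tp1"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("termA", "termB", "termC"))
  expect_equal(lengths(sets), c(termA = 4L, termB = 3L, termC = 5L))
  expect_equal(attr(sets, "description")[["termB"]], "desc b")

  empty <- withr::local_tempfile(fileext = ".gmt")
  file.create(empty)
  expect_warning(out <- read_gmt(empty), "no terms")
  expect_length(out, 0)
})

test_that("edge lists collapse duplicates and orientations, drop self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tB", "B\tA", "C\tC", "B\tD"), path)
  edges <- read_edge_list(path)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$a, c("A", "B"))
  expect_equal(edges$b, c("B", "D"))

  scored <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t0.5", "B\tA\t0.9"), scored)
  e2 <- read_edge_list(scored)
  expect_equal(e2$score, 0.9)
})
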