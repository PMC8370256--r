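# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately naive (loops, base R) so they share no code path
# with the implementation they check.

# ---- record builders --------------------------------------------------------

# mods: character vector like c("S10;T14", "S25")
make_records <- function(condition, protein_id, mods, abundance,
                         reliability = NA_real_) {
  n <- length(abundance)
  parsed <- lapply(mods, function(m) {
    tok <- strsplit(m, ";", fixed = TRUE)[[1]]
    list(pos = as.integer(sub("^[A-Z]", "", tok)),
         res = substr(tok, 1, 1))
  })
  tibble::tibble(
    condition = rep_len(condition, n),
    peptide = replicate(n, paste(sample(LETTERS[1:20], 8, TRUE),
                                 collapse = "")),
    protein_id = rep_len(protein_id, n),
    mod_positions = lapply(parsed, `[[`, "pos"),
    residues = lapply(parsed, `[[`, "res"),
    abundance = abundance,
    reliability = rep_len(reliability, n)
  )
}

random_records <- function(n, n_proteins = 5, conditions = c("A", "B")) {
  # residue is a deterministic function of position (pos mod 3) so that no
  # two records ever disagree about the residue at one protein position
  mods <- vapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    pos <- sort(sample(1:80, k))
    res <- c("S", "T", "Y")[pos %% 3 + 1]
    paste0(res, pos, collapse = ";")
  }, character(1))
  make_records(sample(conditions, n, TRUE),
               sprintf("prot%02d", sample(n_proteins, n, TRUE)),
               mods, stats::runif(n, 1, 100),
               stats::runif(n, 0, 1))
}

# ---- site table builder -----------------------------------------------------

make_site_table <- function(protein_id, residue, position, ...) {
  cols <- list(...)
  tb <- tibble::tibble(
    site_key = phosphoscreen::site_key(protein_id, residue, position),
    protein_id = protein_id, residue = residue, position = position)
  for (nm in names(cols)) tb[[nm]] <- cols[[nm]]
  tb
}

# ---- brute-force oracles ----------------------------------------------------

# group-by-sum over (site, condition), with naive duplicate collapsing
oracle_merge <- function(records) {
  seen <- character(0)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(records))) {
    id <- paste(records$condition[i], records$peptide[i],
                records$protein_id[i],
                paste(records$residues[[i]], records$mod_positions[[i]],
                      collapse = "|"),
                sprintf("%.17g", records$abundance[i]), sep = "##")
    if (id %in% seen) next
    seen <- c(seen, id)
    for (j in seq_along(records$mod_positions[[i]])) {
      key <- paste(records$protein_id[i], records$residues[[i]][j],
                   records$mod_positions[[i]][j], records$condition[i],
                   sep = "##")
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        records$abundance[i]
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "##", fixed = TRUE)
  data.frame(
    protein_id = vapply(parts, `[`, "", 1),
    residue = vapply(parts, `[`, "", 2),
    position = as.integer(vapply(parts, `[`, "", 3)),
    condition = vapply(parts, `[`, "", 4),
    abundance = vapply(keys, function(k) acc[[k]], numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

oracle_intersect <- function(table, a, b) {
  out <- character(0)
  for (i in seq_len(nrow(table))) {
    va <- table[[a]][i]
    vb <- table[[b]][i]
    if (!is.na(va) && va > 0 && !is.na(vb) && vb > 0) {
      out <- c(out, table$site_key[i])
    }
  }
  out
}

oracle_updown <- function(fc, up, down) {
  n_up <- 0L
  n_down <- 0L
  for (x in fc) {
    if (is.na(x)) next
    if (x > up) n_up <- n_up + 1L
    if (x < down) n_down <- n_down + 1L
  }
  c(up = n_up, down = n_down)
}

oracle_top4 <- function(assignments, thr = 1) {
  keep <- logical(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    dn <- assignments$fc_aas_ss[i]
    up <- assignments$fc_alls_aas[i]
    keep[i] <- !is.na(dn) && !is.na(up) && dn < 10^(-thr) && up > 10^thr
  }
  assignments[keep, , drop = FALSE]
}

oracle_degree <- function(edges, proteins) {
  deg <- setNames(integer(length(proteins)), proteins)
  for (p in proteins) {
    nb <- character(0)
    for (i in seq_len(nrow(edges))) {
      a <- edges$a[i]
      b <- edges$b[i]
      if (a == p && b %in% proteins && b != p) nb <- c(nb, b)
      if (b == p && a %in% proteins && a != p) nb <- c(nb, a)
    }
    deg[p] <- length(unique(nb))
  }
  deg
}

oracle_multiplicity <- function(protein_id, site_key) {
  pair <- unique(paste(protein_id, site_key, sep = "##"))
  prot <- vapply(strsplit(pair, "##", fixed = TRUE), `[`, "", 1)
  k_per_protein <- table(prot)
  list(total_sites = length(pair),
       total_proteins = length(k_per_protein),
       hist = table(as.integer(k_per_protein)))
}

# Monte-Carlo estimate of the hypergeometric upper tail P[X >= k]
oracle_mc_hyper <- function(k, term, query_size, universe, reps = 20000) {
  hits <- replicate(reps, {
    draw <- sample(universe, query_size)
    sum(draw %in% term) >= k
  })
  c(p = mean(hits), se = stats::sd(hits) / sqrt(reps))
}

# ---- printed screening examples (used as inputs) ---------------------------

leucine_screen_examples <- function() {
  tibble::tibble(
    protein_name = c("EPB41L2", "SRRM1", "HSP90A", "CALD1"),
    protein_id = c("chx:102190693", "chx:102175909", "chx:100860851",
                   "chx:102188560"),
    site = c("Ser722", "Thr220", "Ser252", "Ser784"),
    fc_aas_ss = c(2.35, 2.26, 0.01, 0.22),
    fc_leus_aas = c(0.06, 0.11, 6.11, 2.33),
    fc_alls_aas = NA_real_
  )
}

all_aa_screen_examples <- function() {
  tibble::tibble(
    protein_name = c("AAK1", "AIM1", "MAP1", "MAP1", "BCLAF1", "CCDC6",
                     "CCDC6", "FLNA", "HSP90A", "HSP90A", "MAPK1", "MYH10",
                     "PDXDC1", "STMN1", "TGFB1I1", "TGFB1I1", "TGFB1I1"),
    protein_id = c("chx:102187599", "chx:102180395", "chx:102176074",
                   "chx:102176074", "chx:102180497", "chx:102172968",
                   "chx:102172968", "chx:102176601", "chx:100860851",
                   "chx:100860851", "chx:102186040", "chx:102177371",
                   "chx:102176932", "chx:102173139", "chx:100861032",
                   "chx:100861032", "chx:100861032"),
    site = c("Ser646", "Ser1499", "Ser1782", "Ser1779", "Ser512", "Ser246",
             "Ser242", "Ser969", "Ser252", "Ser231", "Tyr187", "Ser1987",
             "Thr688", "Ser25", "Ser173", "Ser167", "Ser171"),
    fc_aas_ss = c(0.02, 0.06, 0.02, 0.04, 0.02, 0.06, 0.06, 0.08, 0.01,
                  0.08, 0.06, 0.05, 0.02, 0.02, 0.04, 0.02, 0.02),
    fc_leus_aas = NA_real_,
    fc_alls_aas = c(41.89, 14.38, 33.16, 16.53, 26.17, 24.07, 14.31, 13.53,
                    23.49, 12.89, 12.80, 16.61, 44.23, 113.30, 147.26,
                    11.80, 10.71)
  )
}

screen_examples_to_ratios <- function(tab) {
  tok <- phosphoscreen::parse_site_token(tab$site)
  tibble::tibble(
    site_key = phosphoscreen::site_key(tab$protein_id, tok$residue,
                                       tok$position),
    protein_id = tab$protein_id,
    residue = tok$residue,
    fc_aas_ss = tab$fc_aas_ss,
    fc_leus_aas = tab$fc_leus_aas,
    fc_alls_aas = tab$fc_alls_aas
  )
}

# benchmark configuration: simulated conditions share one intensity scale,
# so no between-column normalisation is applied when scoring recovery
recovery_config <- function(...) {
  phosphoscreen::run_config(normalize = "none", ...)
}
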