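#' Configuration for the synthetic five-condition phosphoproteomics generator
#'
#' The defaults emulate the study design the pipeline targets: five pooled
#' samples (one per condition, no replicates), log-normal baseline site
#' abundances, multiplicative planted effects of 16-fold (so that both the
#' `|log2 FC| > 1` screen and the stricter `|log10 FC| > 1` tier are
#' exercised), 20% multiplicative noise, 1-3 redundant peptides per
#' observed site, a fraction of low-reliability junk records, exact
#' duplicate records, heavy dropout of unregulated sites in the
#' amino-acid-starved and leucine columns (their observed site counts are
#' small in this design), an S/T/Y residue mixture of roughly 90/9/1%, and
#' a motif mixture planting a proline-directed class (+1 P), a +3 glutamate
#' class and a +2 aspartate class around the serine sites that are
#' positively regulated by amino acids.
#'
#' @param n_frame1,n_frame2,n_frame3,n_frame4 Planted site counts per
#'   regulation class. Defaults 30, 30, 30, 200.
#' @param n_null Unregulated sites, default 310.
#' @param effect Planted fold effect (> 1); up-effects use `effect`,
#'   down-effects `1/effect`. Default 16.
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   noise, default 0.2; 0 gives noiseless data.
#' @param conditions Condition labels, see [default_conditions()].
#' @param residue_probs Probabilities of S/T/Y for each site.
#' @param motif_mixture Named numeric vector with elements
#'   `proline_directed`, `plus3_E`, `plus2_D` giving the fraction of
#'   frame-4 serine sites planted with each motif class (remainder `none`);
#'   must sum to at most 1.
#' @param dropout Named per-condition probability that an *unregulated*
#'   site is unobserved in that condition; planted sites are always
#'   observed.
#' @param peptides_per_site Integer vector of possible redundant peptide
#'   counts per observed (site, condition) cell, default `1:3`.
#' @param junk_frac Fraction of observed cells that additionally emit one
#'   low-reliability junk record (reliability < 0.75, abundance unrelated
#'   to the planted signal), default 0.1.
#' @param duplicate_frac Fraction of records re-emitted as exact
#'   duplicates, default 0.05.
#' @param protein_length Length of each synthetic protein, default 400.
#' @param sites_per_protein_probs Probabilities of a protein carrying
#'   1, 2, 3, 4 sites.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline site abundance (arbitrary intensity units).
#' @param n_terms Number of annotation terms to generate, default 6.
#' @param edge_factor Average edges per frame-4 protein in the synthetic
#'   interaction network, default 3.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_frame1 = 30, n_frame2 = 30, n_frame3 = 30,
                       n_frame4 = 200, n_null = 310,
                       effect = 16, cv = 0.2,
                       conditions = default_conditions(),
                       residue_probs = c(S = 0.90, T = 0.09, Y = 0.01),
                       motif_mixture = c(proline_directed = 0.45,
                                         plus3_E = 0.19, plus2_D = 0.16),
                       dropout = c(nt = 0.10, ss = 0.02, aas = 0.80,
                                   leus = 0.92, alls = 0.25),
                       peptides_per_site = 1:3,
                       junk_frac = 0.10, duplicate_frac = 0.05,
                       protein_length = 400,
                       sites_per_protein_probs = c(0.75, 0.15, 0.07, 0.03),
                       baseline_meanlog = log(1e6), baseline_sdlog = 1,
                       n_terms = 6, edge_factor = 3) {
  cfg <- list(n_frame1 = n_frame1, n_frame2 = n_frame2, n_frame3 = n_frame3,
              n_frame4 = n_frame4, n_null = n_null, effect = effect,
              cv = cv, conditions = conditions,
              residue_probs = residue_probs, motif_mixture = motif_mixture,
              dropout = dropout, peptides_per_site = peptides_per_site,
              junk_frac = junk_frac, duplicate_frac = duplicate_frac,
              protein_length = protein_length,
              sites_per_protein_probs = sites_per_protein_probs,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              n_terms = n_terms, edge_factor = edge_factor)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- unlist(cfg[c("n_frame1", "n_frame2", "n_frame3", "n_frame4",
                         "n_null")])
  if (any(counts < 0)) stop("site counts must be non-negative")
  if (sum(counts) == 0) stop("no sites to generate")
  if (cfg$effect <= 1) stop("`effect` must exceed 1")
  if (cfg$cv < 0) stop("`cv` must be non-negative")
  needed <- c("nt", "ss", "aas", "leus", "alls")
  if (!all(needed %in% names(cfg$conditions))) {
    stop("`conditions` must name ", paste(needed, collapse = ", "))
  }
  if (!all(needed %in% names(cfg$dropout)) ||
      any(cfg$dropout < 0 | cfg$dropout > 1)) {
    stop("`dropout` must give a probability in [0,1] per condition role")
  }
  if (abs(sum(cfg$residue_probs) - 1) > 1e-8 ||
      !identical(names(cfg$residue_probs), c("S", "T", "Y"))) {
    stop("`residue_probs` must be named S, T, Y and sum to 1")
  }
  mm <- cfg$motif_mixture
  if (!all(c("proline_directed", "plus3_E", "plus2_D") %in% names(mm))) {
    stop("`motif_mixture` must name proline_directed, plus3_E, plus2_D")
  }
  if (any(mm < 0) || sum(mm) > 1) {
    stop("`motif_mixture` entries must be non-negative and sum to at most 1")
  }
  if (any(cfg$junk_frac < 0, cfg$junk_frac > 1, cfg$duplicate_frac < 0,
          cfg$duplicate_frac > 1)) {
    stop("`junk_frac` and `duplicate_frac` must be probabilities")
  }
  invisible(cfg)
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# planted per-contrast multipliers by regulation class
class_effects <- function(class, effect) {
  e_aas <- ifelse(class %in% c("frame1", "frame3"), effect,
                  ifelse(class %in% c("frame2", "frame4"), 1 / effect, 1))
  e_leu <- ifelse(class == "frame1", 1 / effect,
                  ifelse(class == "frame2", effect, 1))
  e_all <- ifelse(class == "frame3", 1 / effect,
                  ifelse(class == "frame4", effect, 1))
  list(aas = e_aas, leu = e_leu, all = e_all)
}

motif_offsets <- list(proline_directed = c(offset = 1L, residue = "P"),
                      plus3_E = c(offset = 3L, residue = "E"),
                      plus2_D = c(offset = 2L, residue = "D"))

#' Generate a synthetic five-condition phosphoproteomics data set
#'
#' Produces peptide-level quantification records for the five conditions of
#' the starvation/restimulation design, a matching synthetic proteome, a
#' planted annotation set, a planted interaction edge list, and a ground
#' truth table recording every planted regulation class, effect and motif
#' class. The same seed and configuration always reproduce the identical
#' data set.
#'
#' Unregulated ("null") sites carry no planted effect; regulated sites are
#' multiplied by the class effects on top of a shared log-normal baseline,
#' then multiplicative noise with the configured CV is applied per (site,
#' condition) cell. Each observed cell is split over 1-3 redundant peptide
#' records whose abundances sum exactly to the cell value, so that
#' peptide-to-site aggregation by summing recovers the planted signal.
#' Low-reliability junk records and exact duplicates are laid on top and
#' must be removed by [filter_reliable()] and the redundancy collapsing of
#' [merge_to_sites()] for recovery to be exact in the noiseless case.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed controlling every random draw.
#' @return List of class `"phospho_sim"` with elements `peptides` (record
#'   tibble over all conditions), `proteome` (named character vector),
#'   `truth` (tibble: `site_key`, `protein_id`, `residue`, `position`,
#'   `class`, `motif_class`, `e_aas`, `e_leu`, `e_all`, `baseline`, one
#'   logical `obs_<condition>` column and one numeric `ab_<condition>`
#'   column per condition), `annotations` (GMT-style list), `edges`
#'   (tibble), `record_totals` (named per-condition abundance sums over all
#'   emitted records, for input bookkeeping checks), `config`, and `seed`.
#' @export
simulate_phospho <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"), is.numeric(seed))
  set.seed(as.integer(seed))
  cfg <- config
  conds <- cfg$conditions

  class <- rep(c("frame1", "frame2", "frame3", "frame4", "null"),
               times = c(cfg$n_frame1, cfg$n_frame2, cfg$n_frame3,
                         cfg$n_frame4, cfg$n_null))
  n_sites <- length(class)
  class <- sample(class)  # shuffle classes over site slots

  # ---- protein layout: sites per protein, spaced positions -----------------
  k_choices <- seq_along(cfg$sites_per_protein_probs)
  protein_id <- character(n_sites)
  position <- integer(n_sites)
  assigned <- 0L
  prot_i <- 0L
  protein_names <- character(0)
  grid <- seq(10L, cfg$protein_length - 10L, by = 13L)
  while (assigned < n_sites) {
    prot_i <- prot_i + 1L
    id <- sprintf("syn:%06d", prot_i)
    protein_names <- c(protein_names, id)
    k <- min(sample(k_choices, 1L, prob = cfg$sites_per_protein_probs),
             n_sites - assigned)
    idx <- assigned + seq_len(k)
    protein_id[idx] <- id
    position[idx] <- sort(sample(grid, k))
    assigned <- assigned + k
  }
  residue <- sample(names(cfg$residue_probs), n_sites, replace = TRUE,
                    prob = cfg$residue_probs)

  motif_class <- rep("none", n_sites)
  f4s <- which(class == "frame4" & residue == "S")
  if (length(f4s) > 0L) {
    mm <- cfg$motif_mixture
    motif_class[f4s] <- sample(
      c(names(mm), "none"), length(f4s), replace = TRUE,
      prob = c(unname(mm), max(0, 1 - sum(mm))))
  }

  # ---- proteome with planted residues --------------------------------------
  proteome <- vapply(protein_names, function(id) {
    paste(sample(AA_ALPHABET, cfg$protein_length, replace = TRUE),
          collapse = "")
  }, character(1))
  for (i in seq_len(n_sites)) {
    seq <- proteome[[protein_id[i]]]
    substr(seq, position[i], position[i]) <- residue[i]
    if (motif_class[i] != "none") {
      off <- motif_offsets[[motif_class[i]]]
      p <- position[i] + as.integer(off[["offset"]])
      substr(seq, p, p) <- off[["residue"]]
    }
    proteome[[protein_id[i]]] <- seq
  }

  # ---- planted abundances ---------------------------------------------------
  eff <- class_effects(class, cfg$effect)
  baseline <- stats::rlnorm(n_sites, cfg$baseline_meanlog, cfg$baseline_sdlog)
  expected <- cbind(nt = baseline,
                    ss = baseline,
                    aas = baseline * eff$aas,
                    leus = baseline * eff$aas * eff$leu,
                    alls = baseline * eff$aas * eff$all)
  roles <- colnames(expected)

  observed <- matrix(TRUE, n_sites, length(roles),
                     dimnames = list(NULL, roles))
  is_null <- class == "null"
  for (role in roles) {
    observed[is_null, role] <-
      stats::runif(sum(is_null)) >= cfg$dropout[[role]]
  }

  noisy <- expected
  for (role in roles) {
    noisy[, role] <- expected[, role] * lognormal_noise(n_sites, cfg$cv)
  }
  noisy[!observed] <- NA_real_

  # ---- peptide records ------------------------------------------------------
  peptide_seq <- function(i) {
    lo <- max(1L, position[i] - sample(5:10, 1L))
    hi <- min(cfg$protein_length, position[i] + sample(5:10, 1L))
    substr(proteome[[protein_id[i]]], lo, hi)
  }
  rec <- vector("list", n_sites * length(roles))
  ridx <- 0L
  for (i in seq_len(n_sites)) {
    for (role in roles) {
      if (!observed[i, role]) next
      total <- noisy[i, role]
      m <- sample(cfg$peptides_per_site, 1L)
      shares <- if (m == 1L) 1 else {
        u <- stats::runif(m)
        u / sum(u)
      }
      ridx <- ridx + 1L
      rec[[ridx]] <- tibble::tibble(
        condition = unname(conds[[role]]),
        peptide = vapply(seq_len(m), function(j) peptide_seq(i),
                         character(1)),
        protein_id = protein_id[i],
        mod_positions = rep(list(position[i]), m),
        residues = rep(list(residue[i]), m),
        abundance = total * shares,
        reliability = stats::runif(m, 0.8, 1)
      )
    }
  }
  peptides <- dplyr::bind_rows(rec[seq_len(ridx)])

  # junk records: low reliability, abundance unrelated to the planted signal
  n_junk <- round(cfg$junk_frac * nrow(peptides))
  if (n_junk > 0L) {
    j <- sample(nrow(peptides), n_junk, replace = FALSE)
    junk <- peptides[j, , drop = FALSE]
    junk$abundance <- stats::rlnorm(n_junk, cfg$baseline_meanlog,
                                    cfg$baseline_sdlog)
    junk$reliability <- stats::runif(n_junk, 0, 0.7)
    peptides <- dplyr::bind_rows(peptides, junk)
  }

  # exact duplicates (redundant records that aggregation must collapse)
  n_dup <- round(cfg$duplicate_frac * nrow(peptides))
  if (n_dup > 0L) {
    d <- sample(nrow(peptides), n_dup, replace = FALSE)
    peptides <- dplyr::bind_rows(peptides, peptides[d, , drop = FALSE])
  }
  peptides <- peptides[sample(nrow(peptides)), , drop = FALSE]

  truth <- tibble::tibble(
    site_key = site_key(protein_id, residue, position),
    protein_id = protein_id, residue = residue, position = position,
    class = class, motif_class = motif_class,
    e_aas = eff$aas, e_leu = eff$leu, e_all = eff$all,
    baseline = baseline
  )
  for (role in roles) {
    truth[[paste0("obs_", unname(conds[[role]]))]] <- observed[, role]
    truth[[paste0("ab_", unname(conds[[role]]))]] <- noisy[, role]
  }

  record_totals <- vapply(unname(conds), function(cl) {
    sum(peptides$abundance[peptides$condition == cl])
  }, numeric(1))
  names(record_totals) <- unname(conds)

  # planted annotations: one term enriched in frame-4 proteins + random terms
  f4_proteins <- unique(protein_id[class == "frame4"])
  other_proteins <- setdiff(protein_names, f4_proteins)
  sets <- list()
  if (length(f4_proteins) >= 2L) {
    sets$planted_aa_response <- unique(c(
      sample(f4_proteins, max(1L, round(0.6 * length(f4_proteins)))),
      sample(other_proteins, min(5L, length(other_proteins)))))
  }
  for (t in seq_len(max(0L, cfg$n_terms - 1L))) {
    sets[[sprintf("random_term_%02d", t)]] <-
      sample(protein_names, min(length(protein_names),
                                max(5L, round(length(protein_names) / 10))))
  }
  attr(sets, "description") <- setNames(
    ifelse(names(sets) == "planted_aa_response",
           "planted amino-acid-responsive set", "random set"),
    names(sets))

  # planted interaction network among frame-4 proteins
  if (length(f4_proteins) >= 2L) {
    n_edges <- max(1L, round(cfg$edge_factor * length(f4_proteins)))
    ea <- sample(f4_proteins, n_edges, replace = TRUE)
    eb <- sample(f4_proteins, n_edges, replace = TRUE)
    keep <- ea != eb
    lo <- pmin(ea[keep], eb[keep])
    hi <- pmax(ea[keep], eb[keep])
    edges <- tibble::tibble(a = lo, b = hi,
                            score = round(stats::runif(sum(keep), 0.4, 1), 3))
    edges <- edges[!duplicated(edges[, c("a", "b")]), , drop = FALSE]
  } else {
    edges <- tibble::tibble(a = character(0), b = character(0),
                            score = numeric(0))
  }

  structure(list(peptides = peptides, proteome = proteome, truth = truth,
                 annotations = sets, edges = edges,
                 record_totals = record_totals, config = cfg, seed = seed),
            class = "phospho_sim")
}

#' Write a simulated data set to disk
#'
#' Emits one peptide TSV per condition (`peptides_<condition>.tsv`), the
#' proteome FASTA, the annotation GMT, the edge list TSV and the truth
#' table TSV into a directory.
#'
#' @param sim A `"phospho_sim"` object from [simulate_phospho()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "phospho_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (cond in unname(sim$config$conditions)) {
    p <- file.path(dir, paste0("peptides_", cond, ".tsv"))
    write_peptide_table(
      sim$peptides[sim$peptides$condition == cond, , drop = FALSE], p)
    paths[paste0("peptides_", cond)] <- p
  }
  paths["fasta"] <- write_fasta(sim$proteome, file.path(dir, "proteome.fasta"))
  paths["gmt"] <- write_gmt(sim$annotations, file.path(dir, "annotations.gmt"))
  ep <- file.path(dir, "edges.tsv")
  utils::write.table(sim$edges, ep, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths["edges"] <- ep
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- tp
  invisible(paths)
}

#' Expected frame memberships of a simulation's ground truth
#'
#' @param truth Truth tibble from [simulate_phospho()].
#' @return Logical matrix (sites x frames 1-4) of planted memberships.
#' @export
truth_frame_matrix <- function(truth) {
  m <- sapply(paste0("frame", 1:4), function(f) truth$class == f)
  rownames(m) <- truth$site_key
  m
}

#' Sensitivity and specificity of frame recovery against the ground truth
#'
#' Each (site, frame) pair of the truth table is a binary classification
#' instance: planted membership versus recovered membership (a site absent
#' from the assignments is counted as recovered in no frame). Sensitivity is
#' the recovered fraction of planted memberships; specificity the fraction
#' of non-memberships not assigned.
#'
#' @param truth Truth tibble from [simulate_phospho()].
#' @param assignments Output of [assign_frames()].
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
evaluate_frame_recovery <- function(truth, assignments) {
  planted <- truth_frame_matrix(truth)
  recovered <- matrix(FALSE, nrow(planted), 4,
                      dimnames = dimnames(planted))
  idx <- match(assignments$site_key, rownames(recovered))
  for (f in 1:4) {
    hit <- assignments[[paste0("frame", f)]] & !is.na(idx)
    recovered[idx[hit], f] <- TRUE
  }
  tp <- sum(planted & recovered)
  fn <- sum(planted & !recovered)
  tn <- sum(!planted & !recovered)
  fp <- sum(!planted & recovered)
  c(sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}
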