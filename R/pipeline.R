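#' Pipeline run configuration
#'
#' Bundles every tunable of the screening pipeline, validated up front.
#' Defaults reproduce the screen's stated settings: `|log2 FC| > 1`
#' thresholds (fold change above 2 or below 0.5), the stricter
#' `|log10 FC| > 1` top tier, reliability filtering at 0.75 with missing
#' scores kept, median normalisation, sum aggregation of peptides to
#' sites, and motif discovery at binomial p `1e-6` with at least 20
#' occurrences over 13-residue windows.
#'
#' @param theta_up,theta_down Frame thresholds; `theta_up > 1`,
#'   `0 < theta_down < 1`.
#' @param top_log10 Threshold of the strict top tier, default 1.
#' @param min_reliability Reliability threshold, default 0.75.
#' @param missing_reliability `"keep"` or `"drop"` records without a score.
#' @param normalize Normalisation method: `"median"`, `"total"`, `"none"`.
#' @param merge_stat Site aggregation statistic: `"sum"` or `"mean"`.
#' @param motif_p,motif_min,motif_width Motif discovery parameters.
#' @param conditions Named condition labels, see [default_conditions()].
#' @param min_edge_score Edge confidence threshold for the network stage.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(theta_up = 2, theta_down = 0.5, top_log10 = 1,
                       min_reliability = 0.75,
                       missing_reliability = c("keep", "drop"),
                       normalize = c("median", "total", "none"),
                       merge_stat = c("sum", "mean"),
                       motif_p = 1e-6, motif_min = 20, motif_width = 13,
                       conditions = default_conditions(),
                       min_edge_score = 0.4) {
  missing_reliability <- match.arg(missing_reliability)
  normalize <- match.arg(normalize)
  merge_stat <- match.arg(merge_stat)
  if (!(theta_up > 1)) stop("`theta_up` must exceed 1")
  if (!(theta_down > 0 && theta_down < 1)) {
    stop("`theta_down` must lie in (0, 1)")
  }
  if (!(top_log10 > 0)) stop("`top_log10` must be positive")
  if (min_reliability < 0 || min_reliability > 1) {
    stop("`min_reliability` must lie in [0, 1]")
  }
  if (!(motif_p > 0 && motif_p < 1)) stop("`motif_p` must lie in (0, 1)")
  if (motif_min < 1) stop("`motif_min` must be at least 1")
  if (motif_width %% 2 != 1 || motif_width < 3) {
    stop("`motif_width` must be odd and at least 3")
  }
  needed <- c("nt", "ss", "aas", "leus", "alls")
  if (!all(needed %in% names(conditions))) {
    stop("`conditions` must name ", paste(needed, collapse = ", "))
  }
  structure(list(theta_up = theta_up, theta_down = theta_down,
                 top_log10 = top_log10, min_reliability = min_reliability,
                 missing_reliability = missing_reliability,
                 normalize = normalize, merge_stat = merge_stat,
                 motif_p = motif_p, motif_min = motif_min,
                 motif_width = motif_width, conditions = conditions,
                 min_edge_score = min_edge_score),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Chains assembly, frame screening, summaries, motif discovery and the
#' optional enrichment and network stages, writing one TSV per stage plus a
#' `manifest.json` recording package version, configuration and the MD5
#' checksum of every output for reproducibility. Any stage error aborts the
#' run naming the stage.
#'
#' @param input Either a `"phospho_sim"` object from [simulate_phospho()],
#'   or a list with elements `peptide_tables` (named character vector of
#'   TSV paths, names = condition labels), optional `fasta`, `gmt`, and
#'   `edges` paths.
#' @param out_dir Output directory, created if needed.
#' @param config A [run_config()].
#' @return Invisibly, a list with the principal in-memory results:
#'   `sites`, `ratios`, `assignments`, `top4`, `composition`, `updown`,
#'   `shared`, `multiplicity4`, `windows`, `motifs`, `enrichment`,
#'   `network`, and `manifest`.
#' @export
run_pipeline <- function(input, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- config$conditions

  # ---- load -----------------------------------------------------------------
  loaded <- run_stage("load", {
    if (inherits(input, "phospho_sim")) {
      list(records = input$peptides, proteome = input$proteome,
           gmt = input$annotations, edges = input$edges)
    } else {
      recs <- dplyr::bind_rows(lapply(names(input$peptide_tables), function(cond) {
        read_peptide_table(input$peptide_tables[[cond]], condition = cond)
      }))
      list(records = recs,
           proteome = if (!is.null(input$fasta)) read_fasta(input$fasta),
           gmt = if (!is.null(input$gmt)) read_gmt(input$gmt),
           edges = if (!is.null(input$edges)) read_edge_list(input$edges))
    }
  })

  # ---- assemble -------------------------------------------------------------
  sites <- run_stage("assemble", {
    recs <- filter_reliable(loaded$records, config$min_reliability,
                            config$missing_reliability)
    tab <- merge_to_sites(recs, stat = config$merge_stat)
    normalize_sites(tab, method = config$normalize)
  })
  write_site_table(sites, file.path(out_dir, "sites.tsv"))

  # ---- frames ---------------------------------------------------------------
  frames <- run_stage("frames", {
    ratios <- compute_frame_ratios(sites, conditions = conds)
    assignments <- assign_frames(ratios, config$theta_up, config$theta_down)
    top4 <- top_subset(assignments, 4, config$top_log10)
    list(ratios = ratios, assignments = assignments, top4 = top4)
  })
  write_frame_table(frames$assignments, file.path(out_dir, "frames.tsv"))
  write_frame_table(frames$top4, file.path(out_dir, "top_frame4.tsv"))

  # ---- summarise ------------------------------------------------------------
  summaries <- run_stage("summarize", {
    comp <- lapply(unname(conds), function(cond)
      composition_summary(sites, cond))
    names(comp) <- unname(conds)
    contrasts <- list(aas_vs_ss = c(conds[["aas"]], conds[["ss"]]),
                      leus_vs_aas = c(conds[["leus"]], conds[["aas"]]),
                      alls_vs_aas = c(conds[["alls"]], conds[["aas"]]))
    ud <- lapply(contrasts, function(cc) {
      updown_counts(compute_ratios(sites, cc[1], cc[2]),
                    config$theta_up, config$theta_down)
    })
    shared <- lapply(contrasts, function(cc) {
      intersect_sites(sites, cc[1], cc[2])$n_proteins
    })
    mult4 <- multiplicity(frame_sites(frames$assignments, 4))
    list(composition = comp, updown = ud, shared = shared,
         multiplicity4 = mult4)
  })
  run_stage("summarize", {
    comp_tab <- dplyr::bind_rows(lapply(summaries$composition, function(cs) {
      tibble::tibble(condition = cs$condition,
                     residue = cs$counts$residue, n = cs$counts$n,
                     pct = cs$counts$pct, n_sites = cs$n_sites,
                     n_proteins = cs$n_proteins)
    }))
    utils::write.table(comp_tab, file.path(out_dir, "composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ud_tab <- tibble::tibble(
      contrast = names(summaries$updown),
      up = vapply(summaries$updown, `[[`, numeric(1), "up"),
      down = vapply(summaries$updown, `[[`, numeric(1), "down"),
      shared_proteins = unlist(summaries$shared))
    utils::write.table(ud_tab, file.path(out_dir, "contrasts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summaries$multiplicity4$distribution,
                       file.path(out_dir, "multiplicity_frame4.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # ---- motifs ---------------------------------------------------------------
  motif_out <- run_stage("motifs", {
    if (is.null(loaded$proteome) || !any(frames$assignments$frame4)) {
      list(windows = NULL, motifs = NULL)
    } else {
      f4 <- frame_sites(frames$assignments, 4)
      site_info <- parse_site_key(f4$site_key)
      windows <- extract_windows(site_info, loaded$proteome,
                                 width = config$motif_width)
      bg <- unlist(lapply(intersect(PHOSPHO_RESIDUES,
                                    unique(windows$residue)),
                          function(r) background_windows(
                            loaded$proteome, r, config$motif_width)))
      motifs <- if (nrow(windows) == 0) NULL else
        discover_motifs(windows$window, bg, config$motif_p,
                        config$motif_min)
      list(windows = windows, motifs = motifs)
    }
  })
  if (!is.null(motif_out$windows)) {
    utils::write.table(motif_out$windows, file.path(out_dir, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(motif_out$motifs)) {
    utils::write.table(motif_out$motifs, file.path(out_dir, "motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- enrichment -----------------------------------------------------------
  enrich <- run_stage("enrich", {
    if (is.null(loaded$gmt) || length(loaded$gmt) == 0) NULL else {
      universe <- unique(sites$protein_id)
      query <- intersect(unique(frame_sites(frames$assignments,
                                            4)$protein_id), universe)
      if (length(query) == 0) NULL else
        hypergeom_ora(query, loaded$gmt, universe)
    }
  })
  if (!is.null(enrich)) {
    utils::write.table(enrich, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- network --------------------------------------------------------------
  network <- run_stage("network", {
    if (is.null(loaded$edges) || nrow(loaded$edges) == 0) NULL else {
      degree_rank(loaded$edges,
                  proteins = unique(frame_sites(frames$assignments,
                                                4)$protein_id),
                  min_score = config$min_edge_score)
    }
  })
  if (!is.null(network)) {
    utils::write.table(network, file.path(out_dir, "network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- manifest -------------------------------------------------------------
  manifest <- run_stage("manifest", {
    outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
    man <- list(
      package = "phosphoscreen",
      version = as.character(utils::packageVersion("phosphoscreen")),
      config = unclass(config),
      seed = if (inherits(input, "phospho_sim")) input$seed else NULL,
      outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                                 basename(outputs)))
    )
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  })

  invisible(list(sites = sites, ratios = frames$ratios,
                 assignments = frames$assignments, top4 = frames$top4,
                 composition = summaries$composition,
                 updown = summaries$updown, shared = summaries$shared,
                 multiplicity4 = summaries$multiplicity4,
                 windows = motif_out$windows, motifs = motif_out$motifs,
                 enrichment = enrich, network = network,
                 manifest = manifest))
}
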