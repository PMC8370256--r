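#' Drop unreliable peptide records
#'
#' Records whose reliability score falls below a threshold are removed before
#' site aggregation. Records lacking a score follow a configurable policy:
#' keep them (default) or drop them.
#'
#' @param records Peptide record tibble (see [read_peptide_table()]).
#' @param min_reliability Threshold in `[0, 1]`; records with
#'   `reliability < min_reliability` are removed. Default `0.75`.
#' @param missing Policy for records with `NA` reliability: `"keep"`
#'   (default) or `"drop"`.
#' @return Filtered record tibble. The number of removed records is reported
#'   via `message()`.
#' @export
filter_reliable <- function(records, min_reliability = 0.75,
                            missing = c("keep", "drop")) {
  missing <- match.arg(missing)
  stopifnot(min_reliability >= 0, min_reliability <= 1)
  rel <- records$reliability
  keep <- ifelse(is.na(rel), missing == "keep", rel >= min_reliability)
  removed <- sum(!keep)
  if (removed > 0L) {
    message("filter_reliable: removed ", removed, " of ", nrow(records),
            " record(s) below reliability ", min_reliability)
  }
  records[keep, , drop = FALSE]
}

record_identity <- function(records) {
  # identity of a record for redundancy collapsing: condition, peptide,
  # protein, exact modified positions and abundance
  mod <- vapply(seq_len(nrow(records)), function(i) {
    paste0(records$residues[[i]], records$mod_positions[[i]], collapse = ";")
  }, character(1))
  paste(records$condition, records$peptide, records$protein_id, mod,
        format(records$abundance, digits = 17), sep = "\r")
}

#' Collapse peptide records to residue-level phosphosite abundances
#'
#' Exact duplicate records (same condition, peptide, modified positions and
#' abundance) are first collapsed to one — the redundancy removal step. Each
#' remaining peptide then contributes its full abundance to every phosphosite
#' it covers, and abundances are aggregated per (site, condition) with the
#' chosen statistic (sum by default).
#'
#' @param records Peptide record tibble.
#' @param stat Aggregation statistic, `"sum"` (default) or `"mean"`.
#' @return A site quantification tibble with columns `site_key`,
#'   `protein_id`, `residue`, `position` and one abundance column per
#'   condition (in order of first appearance); `NA` marks a site not observed
#'   in a condition.
#' @export
merge_to_sites <- function(records, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  if (nrow(records) == 0L) stop("no records to merge")
  records <- records[!duplicated(record_identity(records)), , drop = FALSE]

  n_sites <- vapply(records$mod_positions, length, integer(1))
  long <- tibble::tibble(
    condition = rep(records$condition, n_sites),
    protein_id = rep(records$protein_id, n_sites),
    position = unlist(records$mod_positions),
    residue = unlist(records$residues),
    abundance = rep(records$abundance, n_sites)
  )

  conflict <- long |>
    dplyr::distinct(.data$protein_id, .data$position, .data$residue) |>
    dplyr::count(.data$protein_id, .data$position) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflict) > 0L) {
    stop("conflicting residue letters at site(s): ",
         paste0(conflict$protein_id, ":", conflict$position, collapse = ", "))
  }

  cond_levels <- unique(records$condition)
  agg <- long |>
    dplyr::group_by(.data$protein_id, .data$position, .data$residue,
                    .data$condition) |>
    dplyr::summarise(abundance = if (stat == "sum") sum(.data$abundance) else
      mean(.data$abundance), .groups = "drop")

  wide <- agg |>
    dplyr::mutate(condition = factor(.data$condition, levels = cond_levels)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "abundance",
                       names_expand = TRUE) |>
    dplyr::mutate(site_key = site_key(.data$protein_id, .data$residue,
                                      .data$position)) |>
    dplyr::relocate("site_key", "protein_id", "residue", "position") |>
    dplyr::arrange(.data$protein_id, .data$position)
  wide
}

site_meta_cols <- c("site_key", "protein_id", "residue", "position")

#' Condition columns of a site quantification table
#'
#' @param table Site quantification tibble from [merge_to_sites()].
#' @return Character vector of condition column names.
#' @export
site_conditions <- function(table) {
  setdiff(names(table), site_meta_cols)
}

#' Normalise a site quantification table across conditions
#'
#' `"median"` divides each condition column by the median of its positive
#' values (the column median becomes 1); `"total"` divides by the column sum;
#' `"none"` is the identity. Median scaling is the default because it is
#' robust to a handful of very abundant sites.
#'
#' @param table Site quantification tibble.
#' @param method `"median"` (default), `"total"` or `"none"`.
#' @return Normalised table of the same shape.
#' @export
normalize_sites <- function(table, method = c("median", "total", "none")) {
  method <- match.arg(method)
  if (method == "none") return(table)
  for (cond in site_conditions(table)) {
    vals <- table[[cond]]
    pos <- vals[!is.na(vals) & vals > 0]
    if (length(pos) == 0L) {
      stop("condition '", cond, "' has no positive abundances to normalise")
    }
    denom <- if (method == "median") stats::median(pos) else
      sum(vals, na.rm = TRUE)
    table[[cond]] <- vals / denom
  }
  table
}

present_in <- function(table, condition) {
  vals <- table[[condition]]
  !is.na(vals) & vals > 0
}

#' Residue composition of the phosphosites observed in one condition
#'
#' Counts Ser/Thr/Tyr phosphosites and distinct phosphoproteins among the
#' sites with a positive abundance in the given condition, with percentages
#' rounded half-up to two decimals (see [percent()]).
#'
#' @param table Site quantification tibble.
#' @param condition Condition column name.
#' @return List with `condition`, `counts` (tibble of `residue`, `n`, `pct`),
#'   `n_sites`, and `n_proteins`.
#' @export
composition_summary <- function(table, condition) {
  if (!condition %in% site_conditions(table)) {
    stop("unknown condition: ", condition)
  }
  obs <- table[present_in(table, condition), , drop = FALSE]
  n_total <- nrow(obs)
  counts <- tibble::tibble(
    residue = PHOSPHO_RESIDUES,
    n = vapply(PHOSPHO_RESIDUES, function(r) sum(obs$residue == r),
               integer(1), USE.NAMES = FALSE)
  )
  counts$pct <- if (n_total > 0) percent(counts$n, n_total) else
    rep(NA_real_, nrow(counts))
  list(condition = condition, counts = counts, n_sites = n_total,
       n_proteins = length(unique(obs$protein_id)))
}

#' Write / read a site quantification table as TSV
#'
#' Columns are `site_key`, `residue`, then one column per condition; absent
#' cells are blank. Protein accession and position are recovered from the
#' site key on reading.
#'
#' @param table Site quantification tibble.
#' @param path File path.
#' @return `path` (write) or the table (read).
#' @export
write_site_table <- function(table, path) {
  out <- table[, c("site_key", "residue", site_conditions(table))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("site_key", "residue") %in% names(raw))) {
    stop("site table must have columns site_key and residue")
  }
  parsed <- parse_site_key(raw$site_key)
  conds <- setdiff(names(raw), c("site_key", "residue"))
  out <- tibble::as_tibble(cbind(parsed,
                                 raw[, conds, drop = FALSE]))
  out[, c(site_meta_cols, conds)]
}
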