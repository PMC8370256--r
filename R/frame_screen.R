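#' Sites observed in both of two conditions
#'
#' A site counts as present in a condition when its cell is non-missing and
#' strictly positive. Also reports the number of distinct proteins carrying
#' at least one shared site (the protein-level Venn count).
#'
#' @param table Site quantification tibble.
#' @param cond_a,cond_b Condition column names.
#' @return List with `sites` (character vector of shared site keys),
#'   `n_sites`, `proteins`, and `n_proteins`.
#' @export
intersect_sites <- function(table, cond_a, cond_b) {
  conds <- site_conditions(table)
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% conds) stop("unknown condition: ", cond)
  }
  shared <- present_in(table, cond_a) & present_in(table, cond_b)
  list(sites = table$site_key[shared],
       n_sites = sum(shared),
       proteins = unique(table$protein_id[shared]),
       n_proteins = length(unique(table$protein_id[shared])))
}

#' Fold changes for one condition contrast
#'
#' For every site present (positive cell) in both conditions, the fold
#' change is `numerator cell / denominator cell`. Sites with a zero or
#' missing cell in either condition are excluded from the contrast (never
#' imputed, never an infinite fold change); the number of sites excluded for
#' a zero cell is reported via `message()`.
#'
#' @param table Site quantification tibble.
#' @param numerator,denominator Condition column names, e.g. `"AAS"` over
#'   `"SS"` for the starvation contrast.
#' @return Tibble with columns `site_key`, `protein_id`, `residue`, `fc`,
#'   carrying the contrast as the `"contrast"` attribute.
#' @export
compute_ratios <- function(table, numerator, denominator) {
  conds <- site_conditions(table)
  for (cond in c(numerator, denominator)) {
    if (!cond %in% conds) stop("unknown condition: ", cond)
  }
  num <- table[[numerator]]
  den <- table[[denominator]]
  both_obs <- !is.na(num) & !is.na(den)
  zero_cell <- both_obs & (num <= 0 | den <= 0)
  if (any(zero_cell)) {
    message("compute_ratios(", numerator, "/", denominator, "): skipped ",
            sum(zero_cell), " site(s) with a zero cell")
  }
  keep <- both_obs & !zero_cell
  out <- tibble::tibble(site_key = table$site_key[keep],
                        protein_id = table$protein_id[keep],
                        residue = table$residue[keep],
                        fc = num[keep] / den[keep])
  attr(out, "contrast") <- c(numerator = numerator, denominator = denominator)
  out
}

#' All three screening contrasts for one site table
#'
#' Builds the per-site fold changes for the starvation contrast (AAS vs SS),
#' the leucine restimulation contrast (LeuS vs AAS), and the all-amino-acid
#' restimulation contrast (AllS vs AAS), joined into one row per site. A
#' site appears when it is defined in at least one contrast; `NA` marks an
#' undefined contrast for that site.
#'
#' @param table Site quantification tibble.
#' @param conditions Named character vector mapping the design roles `ss`,
#'   `aas`, `leus`, `alls` to the table's condition labels; defaults to
#'   [default_conditions()].
#' @return Tibble with columns `site_key`, `protein_id`, `residue`,
#'   `fc_aas_ss`, `fc_leus_aas`, `fc_alls_aas`.
#' @export
compute_frame_ratios <- function(table, conditions = default_conditions()) {
  needed <- c("ss", "aas", "leus", "alls")
  if (!all(needed %in% names(conditions))) {
    stop("`conditions` must name ", paste(needed, collapse = ", "))
  }
  grab <- function(num, den, col) {
    r <- compute_ratios(table, conditions[[num]], conditions[[den]])
    names(r)[names(r) == "fc"] <- col
    r
  }
  r1 <- grab("aas", "ss", "fc_aas_ss")
  r2 <- grab("leus", "aas", "fc_leus_aas")
  r3 <- grab("alls", "aas", "fc_alls_aas")
  keys <- c("site_key", "protein_id", "residue")
  out <- r1 |>
    dplyr::full_join(r2, by = keys) |>
    dplyr::full_join(r3, by = keys)
  out
}

#' Classify sites into regulation frames
#'
#' Frames are fold-change rectangles over two contrasts, with strict
#' inequalities at the thresholds (default `theta_up = 2`,
#' `theta_down = 0.5`, i.e. `|log2 FC| > 1`):
#' \describe{
#'   \item{Frame 1}{up under amino acid starvation (`fc_aas_ss > theta_up`)
#'     and down under leucine restimulation (`fc_leus_aas < theta_down`):
#'     phosphorylation negatively regulated by leucine.}
#'   \item{Frame 2}{down under starvation and up under leucine:
#'     positively regulated by leucine.}
#'   \item{Frame 3}{up under starvation and down under all-amino-acid
#'     restimulation: negatively regulated by amino acids.}
#'   \item{Frame 4}{down under starvation and up under all-amino-acid
#'     restimulation: positively regulated by amino acids.}
#' }
#' Frames are not mutually exclusive: one site may satisfy several rules.
#' A site with an undefined (`NA`) contrast fails any rule using it.
#'
#' @param ratios Tibble with numeric columns `fc_aas_ss`, `fc_leus_aas`,
#'   `fc_alls_aas` (any of which may be `NA`), e.g. from
#'   [compute_frame_ratios()].
#' @param theta_up Up threshold, must exceed 1. Default 2.
#' @param theta_down Down threshold in (0, 1). Default 0.5.
#' @return The input with added logical columns `frame1` ... `frame4`.
#' @export
assign_frames <- function(ratios, theta_up = 2, theta_down = 0.5) {
  stopifnot(theta_up > 1, theta_down > 0, theta_down < 1)
  for (col in c("fc_aas_ss", "fc_leus_aas", "fc_alls_aas")) {
    if (!col %in% names(ratios)) {
      stop("`ratios` is missing column ", col)
    }
    if (any(ratios[[col]] <= 0, na.rm = TRUE)) {
      stop("fold changes must be positive (column ", col, ")")
    }
  }
  up <- function(fc) !is.na(fc) & fc > theta_up
  dn <- function(fc) !is.na(fc) & fc < theta_down
  ratios$frame1 <- up(ratios$fc_aas_ss) & dn(ratios$fc_leus_aas)
  ratios$frame2 <- dn(ratios$fc_aas_ss) & up(ratios$fc_leus_aas)
  ratios$frame3 <- up(ratios$fc_aas_ss) & dn(ratios$fc_alls_aas)
  ratios$frame4 <- dn(ratios$fc_aas_ss) & up(ratios$fc_alls_aas)
  attr(ratios, "theta") <- c(up = theta_up, down = theta_down)
  ratios
}

frame_contrasts <- list(
  `1` = c(up = "fc_aas_ss", down = "fc_leus_aas"),
  `2` = c(down = "fc_aas_ss", up = "fc_leus_aas"),
  `3` = c(up = "fc_aas_ss", down = "fc_alls_aas"),
  `4` = c(down = "fc_aas_ss", up = "fc_alls_aas")
)

#' Sites of one frame
#'
#' @param assignments Output of [assign_frames()].
#' @param frame Frame number 1-4.
#' @return Subset of `assignments` belonging to the frame.
#' @export
frame_sites <- function(assignments, frame) {
  stopifnot(frame %in% 1:4)
  assignments[assignments[[paste0("frame", frame)]], , drop = FALSE]
}

#' Stricter top subset of a frame (`|log10 FC|` rule)
#'
#' Within one frame, retains the sites whose defining contrasts pass the
#' ten-fold-per-decade rule: the up contrast exceeds `10^log10_threshold`
#' and the down contrast falls below `10^-log10_threshold` (default
#' threshold 1, i.e. `|log10 FC| > 1`). Since `10 > theta_up = 2`, the top
#' subset is always contained in the frame.
#'
#' @param assignments Output of [assign_frames()].
#' @param frame Frame number 1-4.
#' @param log10_threshold Positive threshold on `|log10 FC|`. Default 1.
#' @return The retained rows with a logical `top_flag` column set to `TRUE`;
#'   the number of distinct proteins is attached as attribute
#'   `"n_proteins"`.
#' @export
top_subset <- function(assignments, frame, log10_threshold = 1) {
  stopifnot(frame %in% 1:4, log10_threshold > 0)
  contr <- frame_contrasts[[as.character(frame)]]
  fc_up <- assignments[[contr[["up"]]]]
  fc_dn <- assignments[[contr[["down"]]]]
  pass <- !is.na(fc_up) & !is.na(fc_dn) &
    fc_up > 10^log10_threshold & fc_dn < 10^(-log10_threshold)
  out <- assignments[pass, , drop = FALSE]
  out$top_flag <- rep(TRUE, nrow(out))
  attr(out, "n_proteins") <- length(unique(out$protein_id))
  out
}

#' Write frame assignments as TSV
#'
#' Mirrors the screen's reporting layout: one row per site with the three
#' contrast fold changes and the frame membership flags.
#'
#' @param assignments Output of [assign_frames()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(assignments, path) {
  cols <- intersect(c("site_key", "protein_id", "residue", "fc_aas_ss",
                      "fc_leus_aas", "fc_alls_aas", paste0("frame", 1:4),
                      "top_flag"), names(assignments))
  utils::write.table(assignments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
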