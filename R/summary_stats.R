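#' Round half-up
#'
#' Base R's `round()` rounds half to even; the descriptive tables here use
#' conventional half-up rounding (0.005 -> 0.01 at two decimals).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.345, 2.335), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by one ulp so values like 2.345 stored just below the half survive
  floor(x * p + 0.5 + sign(x) * .Machine$double.eps * abs(x) * p) / p
}

#' Percentage with half-up rounding to two decimals
#'
#' @param numerator Count(s).
#' @param denominator Positive total(s).
#' @return `100 * numerator / denominator`, rounded half-up to 2 decimals.
#' @export
#' @examples
#' percent(2102, 3631)  # 57.89
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("percent(): denominator must be positive")
  round_half_up(100 * numerator / denominator, 2)
}

#' Per-protein phosphosite multiplicity distribution
#'
#' Tallies how many proteins carry 1, 2, 3, ... distinct phosphosites in a
#' set of site assignments, together with the implied totals
#' (`total_sites = sum k * n_k`, `total_proteins = sum n_k`).
#'
#' @param sites Data frame with columns `protein_id` and `site_key` (for
#'   example one frame of [assign_frames()] output).
#' @return List with `distribution` (tibble of `sites_per_protein`,
#'   `n_proteins`, sorted by decreasing multiplicity), `total_sites`, and
#'   `total_proteins`.
#' @export
multiplicity <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(distribution = tibble::tibble(sites_per_protein = integer(0),
                                              n_proteins = integer(0)),
                total_sites = 0L, total_proteins = 0L))
  }
  per_protein <- sites |>
    dplyr::distinct(.data$protein_id, .data$site_key) |>
    dplyr::count(.data$protein_id, name = "k")
  dist <- per_protein |>
    dplyr::count(.data$k, name = "n_proteins") |>
    dplyr::arrange(dplyr::desc(.data$k)) |>
    dplyr::rename(sites_per_protein = "k")
  list(distribution = dist,
       total_sites = sum(dist$sites_per_protein * dist$n_proteins),
       total_proteins = sum(dist$n_proteins))
}

#' Up/down counts for one contrast
#'
#' Counts fold changes above the up-regulation threshold and below the
#' down-regulation threshold (strict inequalities; fc equal to a threshold is
#' neither).
#'
#' @param ratios Tibble with a numeric `fc` column (see [compute_ratios()]).
#' @param theta_up Up threshold (> 1), default 2.
#' @param theta_down Down threshold in (0, 1), default 0.5.
#' @return Named integer vector `c(up = , down = )`.
#' @export
updown_counts <- function(ratios, theta_up = 2, theta_down = 0.5) {
  stopifnot(theta_up > 1, theta_down > 0, theta_down < 1)
  fc <- ratios$fc
  c(up = sum(fc > theta_up, na.rm = TRUE),
    down = sum(fc < theta_down, na.rm = TRUE))
}
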