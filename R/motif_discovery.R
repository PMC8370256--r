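#' Extract fixed-width sequence windows centered on phosphosites
#'
#' Builds the odd-width (default 13-residue) peptide context around each
#' site from the protein sequences, padding positions beyond the protein
#' termini with the pad symbol. Sites whose protein is missing from the
#' proteome, or whose annotated residue disagrees with the sequence at that
#' position, are skipped with a warning.
#'
#' @param sites Data frame with columns `protein_id`, `residue`, `position`
#'   (and optionally `site_key`).
#' @param proteome Named character vector of protein sequences (see
#'   [read_fasta()]).
#' @param width Odd window width, default 13.
#' @param pad Pad symbol for positions beyond the termini, default `"_"`.
#' @return Tibble with columns `site_key`, `residue`, `window`. Skipped
#'   sites are recorded in the `"skipped"` attribute (`site_key`, `reason`).
#' @export
extract_windows <- function(sites, proteome, width = 13, pad = "_") {
  stopifnot(width %% 2 == 1, width >= 3, nchar(pad) == 1)
  flank <- (width - 1L) / 2L
  n <- nrow(sites)
  key <- if ("site_key" %in% names(sites)) sites$site_key else
    site_key(sites$protein_id, sites$residue, sites$position)
  window <- character(n)
  reason <- character(n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    seq <- unname(proteome[sites$protein_id[i]])
    if (is.na(seq)) {
      ok[i] <- FALSE
      reason[i] <- "protein missing from proteome"
      next
    }
    pos <- sites$position[i]
    if (pos < 1L || pos > nchar(seq)) {
      ok[i] <- FALSE
      reason[i] <- "position outside protein"
      next
    }
    center <- substr(seq, pos, pos)
    if (center != sites$residue[i]) {
      ok[i] <- FALSE
      reason[i] <- paste0("residue mismatch: annotated ", sites$residue[i],
                          ", sequence has ", center)
      next
    }
    lo <- pos - flank
    hi <- pos + flank
    core <- substr(seq, max(lo, 1L), min(hi, nchar(seq)))
    window[i] <- paste0(strrep(pad, max(0L, 1L - lo)), core,
                        strrep(pad, max(0L, hi - nchar(seq))))
  }
  skipped <- tibble::tibble(site_key = key[!ok], reason = reason[!ok])
  if (nrow(skipped) > 0L) {
    warning("extract_windows: skipped ", nrow(skipped), " site(s): ",
            paste0(skipped$site_key, " (", skipped$reason, ")",
                   collapse = "; "),
            call. = FALSE)
  }
  out <- tibble::tibble(site_key = key[ok], residue = sites$residue[ok],
                        window = window[ok])
  attr(out, "skipped") <- skipped
  out
}

#' All windows around a residue class in a proteome
#'
#' Enumerates every occurrence of the given residue in every protein and
#' extracts its window; the standard background set for motif discovery.
#'
#' @param proteome Named character vector of sequences.
#' @param residue Center residue class, default `"S"`.
#' @param width Odd window width, default 13.
#' @param pad Pad symbol, default `"_"`.
#' @return Character vector of windows.
#' @export
background_windows <- function(proteome, residue = "S", width = 13,
                               pad = "_") {
  stopifnot(residue %in% PHOSPHO_RESIDUES)
  sites <- lapply(names(proteome), function(id) {
    pos <- gregexpr(residue, proteome[[id]], fixed = TRUE)[[1]]
    if (pos[1] == -1L) return(NULL)
    tibble::tibble(protein_id = id, residue = residue,
                   position = as.integer(pos))
  })
  sites <- dplyr::bind_rows(sites)
  if (nrow(sites) == 0L) return(character(0))
  extract_windows(sites, proteome, width = width, pad = pad)$window
}

window_matrix <- function(windows, width) {
  if (length(windows) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = width))
  }
  stopifnot(all(nchar(windows) == width))
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

# best (position, residue) candidate by binomial tail probability; windows
# padded at a position are excluded from both foreground and background
# counts at that position, and residues unseen in the background there are
# not candidates (no finite enrichment estimate)
best_fixed_pair <- function(fg, bg, open_positions, pad, p_threshold,
                            min_occurrences) {
  best <- NULL
  for (j in open_positions) {
    fg_col <- fg[, j]
    fg_col <- fg_col[fg_col != pad]
    bg_col <- bg[, j]
    bg_col <- bg_col[bg_col != pad]
    n <- length(fg_col)
    m <- length(bg_col)
    if (n == 0L || m == 0L) next
    fg_tab <- table(fg_col)
    bg_tab <- table(bg_col)
    for (res in names(fg_tab)) {
      k <- as.integer(fg_tab[[res]])
      if (k < min_occurrences) next
      b <- if (res %in% names(bg_tab)) as.integer(bg_tab[[res]]) else 0L
      if (b == 0L) next
      p0 <- b / m
      pval <- stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
      if (pval > p_threshold) next
      better <- is.null(best) || pval < best$pval ||
        (pval == best$pval && k > best$k) ||
        (pval == best$pval && k == best$k &&
           (j < best$position || (j == best$position && res < best$residue)))
      if (better) {
        best <- list(position = j, residue = res, k = k, n = n, p0 = p0,
                     pval = pval)
      }
    }
  }
  best
}

match_fixed <- function(mat, fixed) {
  # fixed: named character vector, names = column indices as character
  keep <- rep(TRUE, nrow(mat))
  for (j in names(fixed)) {
    keep <- keep & mat[, as.integer(j)] == fixed[[j]]
  }
  keep
}

render_motif <- function(fixed, center_residue, width) {
  center <- (width + 1L) / 2L
  chars <- rep("x", width)
  chars[center] <- center_residue
  for (j in names(fixed)) chars[as.integer(j)] <- fixed[[j]]
  full <- paste(chars, collapse = "")
  core_idx <- (center - 3L):(center + 3L)
  core_chars <- chars[core_idx]
  core <- paste0(paste(core_chars[1:3], collapse = ""), "_",
                 center_residue, "_",
                 paste(core_chars[5:7], collapse = ""))
  list(full = full, core = core)
}

#' Iterative binomial motif discovery (motif-x style)
#'
#' Greedy motif extraction over fixed-width windows sharing a center
#' residue class. At each step the (position, residue) pair with the
#' smallest binomial upper-tail probability — foreground occurrences tested
#' against the background frequency at that position — is fixed, and both
#' window sets are restricted to the matching windows; fixing stops when no
#' pair passes both the p-value threshold and the minimum occurrence count.
#' The matched foreground windows then form one motif class, are removed,
#' and the search restarts, so motif classes are disjoint and their
#' proportions sum to at most 100%.
#'
#' When foreground windows mix center residues (S/T/Y), each residue class
#' is analysed separately against the same-center subset of the background.
#'
#' @param foreground Character vector of foreground windows (equal odd
#'   width).
#' @param background Character vector of background windows; typically all
#'   same-residue windows of the proteome, and ideally a superset of the
#'   foreground.
#' @param p_threshold Binomial p-value threshold per fixed position,
#'   default `1e-6`.
#' @param min_occurrences Minimum foreground matches for a fixed position
#'   and for a reported motif, default 20.
#' @param pad Pad symbol, default `"_"`.
#' @return Tibble with one row per motif: `motif` (the `xxx_S_Pxx`-style
#'   +/-3 core), `pattern` (full-width pattern, `x` = wildcard), `center`,
#'   `fixed` (e.g. `"+1P"`, semicolon-joined, in fixing order),
#'   `n_matches`, `proportion` (percentage of all foreground windows,
#'   half-up 2 decimals), and `score` (-log10 binomial p of the last fixed
#'   position).
#' @export
discover_motifs <- function(foreground, background, p_threshold = 1e-6,
                            min_occurrences = 20, pad = "_") {
  if (length(background) == 0L) stop("empty background")
  if (length(foreground) == 0L) stop("empty foreground")
  stopifnot(p_threshold > 0, p_threshold < 1, min_occurrences >= 1)
  width <- unique(nchar(c(foreground, background)))
  if (length(width) != 1L) stop("windows must share one width")
  center <- (width + 1L) / 2L
  n_fg_total <- length(foreground)

  fg_mat_all <- window_matrix(foreground, width)
  bg_mat_all <- window_matrix(background, width)

  results <- list()
  for (res_class in intersect(PHOSPHO_RESIDUES, unique(fg_mat_all[, center]))) {
    fg_mat <- fg_mat_all[fg_mat_all[, center] == res_class, , drop = FALSE]
    bg_mat <- bg_mat_all[bg_mat_all[, center] == res_class, , drop = FALSE]
    if (nrow(bg_mat) == 0L) next

    repeat {
      if (nrow(fg_mat) < min_occurrences) break
      fixed <- character(0)
      cur_fg <- fg_mat
      cur_bg <- bg_mat
      last_pval <- NA_real_
      repeat {
        open <- setdiff(seq_len(width), c(center, as.integer(names(fixed))))
        cand <- best_fixed_pair(cur_fg, cur_bg, open, pad, p_threshold,
                                min_occurrences)
        if (is.null(cand)) break
        fixed[as.character(cand$position)] <- cand$residue
        last_pval <- cand$pval
        cur_fg <- cur_fg[match_fixed(cur_fg, fixed), , drop = FALSE]
        cur_bg <- cur_bg[match_fixed(cur_bg, fixed), , drop = FALSE]
      }
      if (length(fixed) == 0L) break
      matched <- match_fixed(fg_mat, fixed)
      rendered <- render_motif(fixed, res_class, width)
      offsets <- as.integer(names(fixed)) - center
      results[[length(results) + 1L]] <- tibble::tibble(
        motif = rendered$core,
        pattern = rendered$full,
        center = res_class,
        fixed = paste0(ifelse(offsets > 0, "+", ""), offsets,
                       unname(fixed), collapse = ";"),
        n_matches = sum(matched),
        proportion = percent(sum(matched), n_fg_total),
        score = -log10(max(last_pval, .Machine$double.xmin))
      )
      fg_mat <- fg_mat[!matched, , drop = FALSE]
    }
  }
  if (length(results) == 0L) {
    return(tibble::tibble(motif = character(0), pattern = character(0),
                          center = character(0), fixed = character(0),
                          n_matches = integer(0), proportion = numeric(0),
                          score = numeric(0)))
  }
  dplyr::bind_rows(results)
}

#' Motif proportions of the foreground
#'
#' @param n_matches Integer vector of per-motif foreground match counts.
#' @param n_foreground Total number of foreground windows.
#' @return Percentages, half-up to 2 decimals.
#' @export
#' @examples
#' motif_proportions(58, 129)  # 44.96
motif_proportions <- function(n_matches, n_foreground) {
  percent(n_matches, n_foreground)
}
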