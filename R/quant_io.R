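#' Build a canonical site key
#'
#' The canonical text form of a phosphosite is
#' `"<protein_id>:<residue><position>"`, e.g. `"chx:102173139:S25"`. The
#' protein accession may itself contain colons; the site token is always the
#' last colon-delimited field.
#'
#' @param protein_id Accession string(s).
#' @param residue One-letter residue(s), one of `"S"`, `"T"`, `"Y"`.
#' @param position 1-based integer position(s) within the protein.
#' @return Character vector of site keys.
#' @export
#' @examples
#' site_key("chx:102173139", "S", 25)
site_key <- function(protein_id, residue, position) {
  stopifnot(all(residue %in% PHOSPHO_RESIDUES), all(position >= 1))
  paste0(protein_id, ":", residue, position)
}

#' Parse a residue-position token such as "Ser25" or "S25"
#'
#' Accepts three-letter (`Ser`, `Thr`, `Tyr`) and one-letter (`S`, `T`, `Y`)
#' residue codes and normalises to the one-letter form.
#'
#' @param token Character vector of tokens, e.g. `"Ser25"`, `"Thr688"`,
#'   `"Y1"`.
#' @return A tibble with columns `residue` (one letter) and `position`
#'   (integer), one row per token.
#' @export
#' @examples
#' parse_site_token(c("Ser25", "Tyr187"))
parse_site_token <- function(token) {
  m <- regmatches(token, regexec("^([A-Za-z]+)([0-9]+)$", token))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed site token(s): ", paste(token[bad], collapse = ", "))
  }
  res <- vapply(m, `[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  long <- res %in% names(RESIDUE_THREE_TO_ONE)
  res[long] <- RESIDUE_THREE_TO_ONE[res[long]]
  unsupported <- !res %in% PHOSPHO_RESIDUES
  if (any(unsupported)) {
    stop("unsupported residue in token(s): ",
         paste(token[unsupported], collapse = ", "),
         " (phosphosites are restricted to Ser/Thr/Tyr)")
  }
  if (any(pos < 1L)) stop("site position must be >= 1")
  tibble::tibble(residue = res, position = pos)
}

#' Parse canonical site keys back into their components
#'
#' @param key Character vector of site keys (`"<protein_id>:<residue><pos>"`).
#' @return Tibble with columns `site_key`, `protein_id`, `residue`,
#'   `position`.
#' @export
#' @examples
#' parse_site_key("chx:102173139:S25")
parse_site_key <- function(key) {
  m <- regmatches(key, regexec("^(.*):((?:Ser|Thr|Tyr|S|T|Y)[0-9]+)$", key))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed site key(s): ", paste(key[bad], collapse = ", "))
  pid <- vapply(m, `[`, character(1), 2L)
  tok <- parse_site_token(vapply(m, `[`, character(1), 3L))
  tibble::tibble(site_key = key, protein_id = pid,
                 residue = tok$residue, position = tok$position)
}

parse_mod_string <- function(x) {
  # "S25;T31" -> tibble(residue, position); validates order and alphabet
  tok <- strsplit(x, ";", fixed = TRUE)[[1]]
  tok <- tok[nzchar(tok)]
  if (length(tok) == 0L) stop("empty mod_positions")
  out <- parse_site_token(tok)
  if (is.unsorted(out$position, strictly = TRUE)) {
    stop("mod positions must be strictly increasing")
  }
  out
}

#' Read a phosphopeptide quantification table
#'
#' The expected format is tab-delimited text with a header and required
#' columns `peptide`, `protein_id`, `mod_positions` (semicolon-joined
#' residue-position tokens such as `"S25;T31"`) and `abundance`; optional
#' columns `condition` and `reliability`. Malformed rows (non-numeric
#' abundance, bad modification tokens) are dropped with a warning that lists
#' their file line numbers; well-formed rows are returned in file order.
#'
#' @param path Path to the TSV file.
#' @param condition Condition label to assign to every record; overrides a
#'   `condition` column if both are present. Required when the file has no
#'   `condition` column.
#' @return A tibble of peptide records with columns `condition`, `peptide`,
#'   `protein_id`, `mod_positions` (list of integer vectors), `residues`
#'   (list of character vectors), `abundance`, `reliability` (`NA` when
#'   absent). Skipped rows are recorded in the `"skipped"` attribute as a
#'   tibble of `line` and `reason`.
#' @export
read_peptide_table <- function(path, condition = NULL) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("peptide", "protein_id", "mod_positions", "abundance")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("peptide table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(condition)) {
    if (!"condition" %in% names(raw)) {
      stop("no `condition` column in ", path,
           " and no `condition` argument supplied")
    }
    cond <- raw$condition
  } else {
    cond <- rep_len(as.character(condition), nrow(raw))
  }

  n <- nrow(raw)
  abundance <- suppressWarnings(as.numeric(raw$abundance))
  reliability <- if ("reliability" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$reliability))
  } else {
    rep(NA_real_, n)
  }

  keep <- rep(TRUE, n)
  reason <- character(n)
  mods <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(abundance[i]) || abundance[i] < 0) {
      keep[i] <- FALSE
      reason[i] <- paste0("non-numeric or negative abundance '",
                          raw$abundance[i], "'")
      next
    }
    mods[[i]] <- tryCatch(parse_mod_string(raw$mod_positions[i]),
                          error = function(e) conditionMessage(e))
    if (is.character(mods[[i]])) {
      keep[i] <- FALSE
      reason[i] <- mods[[i]]
    }
  }

  skipped <- tibble::tibble(line = which(!keep) + 1L,  # +1 for the header line
                            reason = reason[!keep])
  if (nrow(skipped) > 0L) {
    warning("skipped ", nrow(skipped), " malformed row(s) in ", path, ": ",
            paste0("line ", skipped$line, " (", skipped$reason, ")",
                   collapse = "; "),
            call. = FALSE)
  }

  idx <- which(keep)
  records <- tibble::tibble(
    condition = cond[idx],
    peptide = toupper(raw$peptide[idx]),
    protein_id = raw$protein_id[idx],
    mod_positions = lapply(mods[idx], function(m) m$position),
    residues = lapply(mods[idx], function(m) m$residue),
    abundance = abundance[idx],
    reliability = reliability[idx]
  )
  attr(records, "skipped") <- skipped
  records
}

#' Write peptide records to a TSV file
#'
#' Inverse of [read_peptide_table()]: a written table read back reproduces
#' the records field-for-field.
#'
#' @param records Tibble of peptide records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  mod <- mapply(function(res, pos) paste0(res, pos, collapse = ";"),
                records$residues, records$mod_positions)
  out <- data.frame(
    condition = records$condition,
    peptide = records$peptide,
    protein_id = records$protein_id,
    mod_positions = mod,
    abundance = format(records$abundance, digits = 17, trim = TRUE,
                       scientific = FALSE),
    reliability = ifelse(is.na(records$reliability), "",
                         format(records$reliability, digits = 17,
                                trim = TRUE, scientific = FALSE)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Standard multi-line FASTA; the sequence identifier is the first
#' whitespace-delimited token of the header. Duplicate identifiers are an
#' error; an empty file yields an empty result with a warning.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of uppercase amino acid sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) NULL)
  if (is.null(set) || length(set) == 0L) {
    warning("no sequences found in ", path, call. = FALSE)
    return(setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  setNames(toupper(as.character(set)), ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a GMT-style annotation file
#'
#' Each line is `term <TAB> description <TAB> member1 <TAB> member2 ...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (term -> unique members), with a
#'   `"description"` attribute carrying the second column per term. An empty
#'   file yields an empty list with a warning.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("no terms found in ", path, call. = FALSE)
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  }
  terms <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(terms)) {
    stop("duplicate GMT term(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- terms
  attr(sets, "description") <- setNames(
    vapply(fields, `[`, character(1), 2L), terms)
  sets
}

#' Write annotation sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named character vector of term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  desc <- description %||% attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(term) {
    paste(c(term, desc[[term]] %||% "na", sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected protein-protein edge list
#'
#' Two tab-delimited identifier columns per line, with an optional third
#' numeric confidence-score column. Self-loops are dropped and duplicate
#' edges (in either orientation) are collapsed, keeping the maximum score.
#'
#' @param path Path to the edge-list file.
#' @param header Logical; does the file have a header line? Default `FALSE`.
#' @return Tibble with columns `a`, `b` (with `a <= b` lexicographically) and
#'   `score` (`NA` when absent). An empty file yields zero rows with a
#'   warning.
#' @export
read_edge_list <- function(path, header = FALSE) {
  empty <- tibble::tibble(a = character(0), b = character(0),
                          score = numeric(0))
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0L) {
    warning("no edges found in ", path, call. = FALSE)
    return(empty)
  }
  raw <- utils::read.delim(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    warning("no edges found in ", path, call. = FALSE)
    return(empty)
  }
  if (ncol(raw) < 2L) stop("edge list must have at least two columns")
  a <- as.character(raw[[1]])
  b <- as.character(raw[[2]])
  score <- if (ncol(raw) >= 3L) suppressWarnings(as.numeric(raw[[3]])) else
    rep(NA_real_, length(a))
  keep <- a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  edges <- tibble::tibble(a = lo, b = hi, score = score[keep])
  edges |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(score = if (all(is.na(.data$score))) NA_real_ else
      max(.data$score, na.rm = TRUE), .groups = "drop")
}
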