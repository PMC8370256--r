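#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the query protein list contains
#' more term members than expected by chance when drawing from the universe:
#' `p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)`, where `N` is the
#' universe size, `K` the term size within the universe, `n` the query size
#' and `k` the observed hits. P-values are Benjamini-Hochberg adjusted
#' across all tested terms.
#'
#' @param query Character vector of query protein identifiers; must be a
#'   subset of `universe`.
#' @param term_sets Named list of character vectors (term -> members), e.g.
#'   from [read_gmt()]. Members outside the universe are ignored.
#' @param universe Character vector of all proteins eligible for the test
#'   (typically every protein quantified in any condition).
#' @param min_size Minimum term size within the universe for a term to be
#'   tested, default 1.
#' @return Tibble with columns `term`, `description`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, sorted by `q` then `p`.
#' @export
#' @examples
#' hypergeom_ora(c("a", "b"), list(t1 = c("a", "b", "c")), letters[1:20])
hypergeom_ora <- function(query, term_sets, universe, min_size = 1) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    stop("query protein(s) not in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  desc <- attr(term_sets, "description") %||%
    setNames(rep(NA_character_, length(term_sets)), names(term_sets))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(term_sets), function(term) {
    members <- intersect(unique(term_sets[[term]]), universe)
    K <- length(members)
    if (K < min_size) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = term,
                   description = unname(desc[term]),
                   k = k, K = K, n = n, N = N, p = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(term = character(0), description = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), p = numeric(0), q = numeric(0)))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$q, out$p, out$term), ]
}
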