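# Hypergeometric over-representation analysis of a target list against a
# background, with Benjamini-Hochberg step-up correction.

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled step-up procedure (the operation itself, not a wrapper):
#' sort p ascending, multiply by m/rank, enforce monotonicity from the
#' largest rank down, cap at 1, and return values in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Read a term-to-gene annotation map
#'
#' @param path two-column TSV (`term_id`, `gene`), optional `label` third
#'   column.
#' @return named list of character vectors (term -> genes), with term
#'   labels in attribute `"labels"` when present.
#' @export
read_term_map <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("term_id", "gene") %in% names(df))) {
    stop("term map needs columns term_id and gene")
  }
  terms <- lapply(split(df$gene, df$term_id), unique)
  if ("label" %in% names(df)) {
    lab <- df$label[!duplicated(df$term_id)]
    names(lab) <- df$term_id[!duplicated(df$term_id)]
    attr(terms, "labels") <- lab
  }
  terms
}

#' Hypergeometric over-representation analysis
#'
#' For each term, with `N` the background size, `K` the background genes
#' annotated to the term, `n` the target size and `k` the target genes in
#' the term, computes the exact upper-tail p-value `P(X >= k)` of the
#' hypergeometric distribution, then adjusts across all tested terms with
#' [bh_adjust()].  Term annotations are intersected with the background
#' before testing; target genes not annotated to any term still count in
#' `n` and `N`.
#'
#' @param target character vector of hit genes (must be a subset of
#'   `background`).
#' @param background character vector defining the tested universe.
#' @param terms named list of term -> gene character vectors (see
#'   [read_term_map()]).
#' @param p_max flag threshold on the adjusted p.
#' @return data.frame: `term_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `bh_adjusted_p`, `enriched` flag; sorted by p then term id.
#' @export
hypergeometric_enrichment <- function(target, background, terms,
                                      p_max = 0.05) {
  target <- unique(target)
  background <- unique(background)
  if (!length(target) || !length(background)) {
    stop("target and background must be non-empty")
  }
  stray <- setdiff(target, background)
  if (length(stray)) {
    stop("target genes absent from the background: ",
         paste(head(stray, 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(target)
  rows <- lapply(names(terms), function(tid) {
    ann <- intersect(terms[[tid]], background)
    K <- length(ann)
    if (K == 0) return(NULL)
    k <- length(intersect(ann, target))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    stop("no term overlaps the background")
  }
  res$bh_adjusted_p <- bh_adjust(res$p_value)
  res$enriched <- res$bh_adjusted_p < p_max
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
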