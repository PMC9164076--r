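#' Rich factor of a pathway hit
#'
#' The rich factor is the fraction of a pathway's annotated genes that are
#' hit by the query set, `k / K`. Among significantly enriched pathways a
#' low rich factor marks a broad pathway touched selectively, which this
#' pipeline treats as the key-mechanism signature. Computed at full
#' precision; display rounding to 4 decimals is the caller's concern.
#'
#' @param k Hit count (query genes annotated to the pathway), `1 <= k <= K`.
#' @param K Pathway background size (total genes annotated to the pathway).
#' @return `k / K`.
#' @examples
#' round(rich_factor(2, 21), 4)  # 0.0952
#' @export
rich_factor <- function(k, K) {
  if (length(k) != 1L || length(K) != 1L || is.na(k) || is.na(K) ||
      K <= 0 || k < 1 || k > K) {
    stop("invalid annotation: need 1 <= k <= K with K > 0", call. = FALSE)
  }
  k / K
}

#' One-sided hypergeometric over-representation p-value
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: drawing `n` query genes
#' from a background of `N` genes of which `K` belong to the pathway. This
#' is the standard over-representation test used by pathway-annotation
#' servers. Evaluated through the stable log-space tail of [stats::phyper()].
#'
#' @param k Observed hit count.
#' @param K Pathway background size.
#' @param n Query size (targets mappable to the background).
#' @param N Background size (total assayable genes).
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("inconsistent hypergeometric counts: need k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, order-aligned
#' with the input; adjusted values never fall below the raw p-value and are
#' capped at 1. Delegates to [stats::p.adjust()] after domain validation.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway over-representation analysis with rich factors
#'
#' For every pathway with at least one hit, computes the hit gene set, the
#' rich factor `k/K`, the one-sided hypergeometric p-value against a
#' background of `N` genes, and the BH-FDR across tested pathways. Rows are
#' sorted ascending by rich factor. Pathways whose FDR fails `alpha` are
#' flagged `significant = FALSE`, or dropped when `strict = TRUE`.
#'
#' The background `N` defaults to 20,000, the human protein-coding scale;
#' rich factors do not depend on it, only p-values and FDR do.
#'
#' @param query A `target_set` of query genes.
#' @param db A `pathway_db` from [read_gmt()] or [gen_pathway_db()].
#' @param N Background size (total assayable genes).
#' @param alpha Significance level on the FDR (default 0.05).
#' @param strict Drop non-significant rows instead of flagging them.
#' @return An `enrichment_table`: data frame with columns `pathway_id`,
#'   `name`, `hit_genes` (list-column), `k`, `K`, `rich_factor`, `p_value`,
#'   `fdr`, `significant`; attributes `N` and `query_size`.
#' @export
enrich <- function(query, db, N = 20000, alpha = 0.05, strict = FALSE) {
  stopifnot(inherits(query, "target_set"), nrow(db) > 0L)
  hits <- lapply(db$genes, function(g) sort(intersect(query$members, g)))
  k <- lengths(hits)
  keep <- k > 0L
  if (!any(keep)) {
    warning("query set hits no pathway in the annotation", call. = FALSE)
    return(empty_enrichment_table(N, length(query$members)))
  }
  tab <- data.frame(pathway_id = db$pathway_id[keep],
                    name = db$name[keep],
                    k = k[keep], K = db$K[keep],
                    stringsAsFactors = FALSE)
  tab$hit_genes <- hits[keep]
  tab$rich_factor <- tab$k / tab$K
  n_query <- length(query$members)
  tab$p_value <- mapply(hypergeom_pvalue, tab$k, tab$K,
                        MoreArgs = list(n = n_query, N = N))
  tab$fdr <- bh_fdr(tab$p_value)
  tab$significant <- tab$fdr < alpha
  if (strict) tab <- tab[tab$significant, , drop = FALSE]
  tab <- tab[order(tab$rich_factor, tab$fdr, tab$pathway_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, N = N, query_size = n_query, alpha = alpha,
            class = c("enrichment_table", "data.frame"))
}

empty_enrichment_table <- function(N, n_query) {
  tab <- data.frame(pathway_id = character(0), name = character(0),
                    k = integer(0), K = integer(0),
                    rich_factor = numeric(0), p_value = numeric(0),
                    fdr = numeric(0), significant = logical(0),
                    stringsAsFactors = FALSE)
  tab$hit_genes <- list()
  structure(tab, N = N, query_size = n_query,
            class = c("enrichment_table", "data.frame"))
}

#' Assemble an enrichment table from precomputed rows
#'
#' Builds a valid `enrichment_table` from already-known per-pathway values
#' (for example a published enrichment result), bypassing the test. Rows
#' are sorted ascending by rich factor.
#'
#' @param rows Data frame with columns `pathway_id`, `rich_factor`, `fdr`
#'   and optionally `name`, `k`, `K`.
#' @return An `enrichment_table`.
#' @export
enrichment_table <- function(rows) {
  stopifnot(all(c("pathway_id", "rich_factor", "fdr") %in% names(rows)))
  tab <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (is.null(tab$name)) tab$name <- tab$pathway_id
  tab <- tab[order(tab$rich_factor, tab$fdr, tab$pathway_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("enrichment_table", "data.frame"))
}

#' Key-pathway selection by minimum rich factor
#'
#' Returns the pathway id of the row with the lowest rich factor, the
#' pipeline's key-mechanism candidate. Ties break by smaller FDR, then
#' lexicographic pathway id.
#'
#' @param table An `enrichment_table`.
#' @return Pathway id (character scalar).
#' @export
key_pathway <- function(table) {
  if (nrow(table) == 0L) {
    stop("no result: enrichment table is empty", call. = FALSE)
  }
  ord <- order(table$rich_factor, table$fdr, table$pathway_id)
  table$pathway_id[ord[1L]]
}

#' Bubble-chart data for an enrichment table
#'
#' One record per pathway with the rich factor, `-log10(FDR)` and hit
#' count; values pass through without recomputation, ready for a
#' significance-vs-rich-factor bubble plot.
#'
#' @param table An `enrichment_table`.
#' @return Data frame with columns `pathway_id`, `name`, `rich_factor`,
#'   `neg_log10_fdr`, `hits`.
#' @export
bubble_data <- function(table) {
  hits <- if (!is.null(table$k)) table$k
          else if (!is.null(table$hit_genes)) lengths(table$hit_genes)
          else rep(NA_integer_, nrow(table))
  data.frame(pathway_id = table$pathway_id,
             name = if (!is.null(table$name)) table$name else table$pathway_id,
             rich_factor = table$rich_factor,
             neg_log10_fdr = -log10(table$fdr),
             hits = hits,
             stringsAsFactors = FALSE)
}

#' Write an enrichment table as TSV
#'
#' @param table An `enrichment_table`.
#' @param path Output path.
#' @export
write_enrichment <- function(table, path) {
  out <- as.data.frame(table)
  if (!is.null(out$hit_genes)) {
    out$hit_genes <- vapply(out$hit_genes, paste, character(1), collapse = ",")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
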