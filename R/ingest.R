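#' Normalize gene symbols
#'
#' Gene identity throughout the pipeline is uppercase-symbol equality:
#' symbols are trimmed and uppercased, and no alias or HGNC resolution is
#' attempted. This makes set operations on targets deterministic and
#' dependency-free.
#'
#' @param raw Character vector of raw gene symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbol(" grin2b ")  # "GRIN2B"
#' @export
normalize_symbol <- function(raw) {
  if (!is.character(raw)) raw <- as.character(raw)
  out <- toupper(trimws(raw))
  if (any(!nzchar(out)) || anyNA(out)) {
    stop("malformed record: empty gene symbol after trimming", call. = FALSE)
  }
  out
}

# Normalize typographic minus/dash variants to ASCII minus before numeric
# conversion; published tables frequently print U+2212.
ascii_minus <- function(x) {
  gsub("[−–—]", "-", x)
}

# Auto-detect delimiter among tab/comma/semicolon from the header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return("\t")
  counts <- vapply(c("\t", ",", ";"), function(s) {
    lengths(regmatches(header, gregexpr(s, header, fixed = TRUE)))
  }, integer(1))
  c("\t", ",", ";")[which.max(counts)]
}

read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

# Case-insensitive required-column lookup that names the missing column.
require_column <- function(df, name, context) {
  hit <- which(tolower(names(df)) == tolower(name))
  if (length(hit) == 0L) {
    stop(sprintf("schema error in %s: required column '%s' not found",
                 context, name), call. = FALSE)
  }
  hit[1L]
}

#' Read a drug-target prediction table
#'
#' Reads a delimited export in the style of similarity-based target
#' prediction services (one row per predicted drug-target pair), normalizes
#' the gene symbols and deduplicates pairs. The delimiter is auto-detected
#' among tab, comma and semicolon unless given.
#'
#' @param path Path to a delimited text file.
#' @param source_name Label for the prediction source.
#' @param drug_col,target_col Column names holding the drug identifier and
#'   the target gene symbol.
#' @param prob_col Optional name of a predicted-probability column; rows
#'   below `min_prob` are dropped when both are supplied.
#' @param min_prob Probability threshold in `[0,1]`, applied only when
#'   `prob_col` is given.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return A `prediction_table`: list with `source_name` and `pairs`, a
#'   data frame of unique (drug, target) pairs. Attributes record the raw
#'   row count and the number of duplicates collapsed.
#' @export
read_prediction_table <- function(path, source_name,
                                  drug_col = "drug", target_col = "target",
                                  prob_col = NULL, min_prob = 0,
                                  sep = NULL) {
  df <- read_delim_auto(path, sep)
  if (nrow(df) == 0L) {
    warning(sprintf("prediction table '%s' (%s) is empty", path, source_name),
            call. = FALSE)
    pairs <- data.frame(drug = character(0), target = character(0),
                        stringsAsFactors = FALSE)
    return(new_prediction_table(source_name, pairs, n_rows = 0L, n_dup = 0L))
  }
  di <- require_column(df, drug_col, sprintf("prediction table '%s'", path))
  ti <- require_column(df, target_col, sprintf("prediction table '%s'", path))
  drug <- trimws(as.character(df[[di]]))
  target <- normalize_symbol(df[[ti]])
  keep <- rep(TRUE, length(drug))
  if (!is.null(prob_col)) {
    pi <- require_column(df, prob_col, sprintf("prediction table '%s'", path))
    keep <- suppressWarnings(as.numeric(ascii_minus(df[[pi]]))) >= min_prob
    keep[is.na(keep)] <- FALSE
  }
  pairs <- data.frame(drug = drug[keep], target = target[keep],
                      stringsAsFactors = FALSE)
  n_rows <- nrow(pairs)
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  new_prediction_table(source_name, pairs,
                       n_rows = n_rows, n_dup = n_rows - nrow(pairs))
}

new_prediction_table <- function(source_name, pairs, n_rows, n_dup) {
  structure(list(source_name = source_name, pairs = pairs),
            n_rows = n_rows, n_duplicates = n_dup,
            class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat(sprintf("prediction_table '%s': %d unique pairs, %d drugs, %d targets\n",
              x$source_name, nrow(x$pairs),
              length(unique(x$pairs$drug)), length(unique(x$pairs$target))))
  invisible(x)
}

#' Read pathway gene sets in GMT format
#'
#' Standard Broad-dialect GMT: one pathway per line, tab-separated fields
#' `name`, `description`, then member gene symbols. The pathway background
#' size `K` defaults to the member count; an explicit size table (columns
#' `pathway_id`, `K`) overrides it, which is how annotation-wide pathway
#' sizes are carried when the GMT stores only the assayable subset.
#'
#' @param path Path to a GMT file.
#' @param size_table Optional data frame with columns `pathway_id` and `K`.
#' @return A `pathway_db`: data frame with columns `pathway_id`, `name`,
#'   `K` and a list-column `genes` of normalized symbols.
#' @export
read_gmt <- function(path, size_table = NULL) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("GMT format error at line %d of '%s': fewer than 3 fields",
                 bad[1L], path), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop(sprintf("duplicate pathway id '%s' in '%s'", dup, path),
         call. = FALSE)
  }
  genes <- lapply(parts, function(p) unique(normalize_symbol(p[-(1:2)])))
  db <- data.frame(pathway_id = ids,
                   name = vapply(parts, `[[`, character(1), 2L),
                   K = lengths(genes),
                   stringsAsFactors = FALSE)
  db$genes <- genes
  if (!is.null(size_table)) {
    m <- match(db$pathway_id, size_table$pathway_id)
    db$K[!is.na(m)] <- size_table$K[m[!is.na(m)]]
    if (any(db$K < lengths(db$genes))) {
      stop("size table gives K smaller than the stored gene set",
           call. = FALSE)
    }
  }
  class(db) <- c("pathway_db", "data.frame")
  db
}

#' Read a protein-protein interaction edge list
#'
#' Reads a STRING-style delimited file with two node columns and an optional
#' confidence score column. Edges are undirected: `(A,B)` and `(B,A)`
#' collapse to one edge. Self-loops are dropped (count recorded as an
#' attribute), and edges below `min_confidence` are removed. When no score
#' column is present every edge gets confidence 1.
#'
#' @param path Path to the edge list.
#' @param min_confidence Confidence threshold in `[0,1]`.
#' @param node_cols Names of the two node columns.
#' @param score_col Name of the score column, used when present.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return Data frame with columns `from`, `to`, `confidence`; attribute
#'   `self_loops_dropped` holds the dropped self-loop count.
#' @export
read_edge_list <- function(path, min_confidence = 0,
                           node_cols = c("node1", "node2"),
                           score_col = "combined_score", sep = NULL) {
  df <- read_delim_auto(path, sep)
  i1 <- require_column(df, node_cols[1], sprintf("edge list '%s'", path))
  i2 <- require_column(df, node_cols[2], sprintf("edge list '%s'", path))
  a <- normalize_symbol(df[[i1]])
  b <- normalize_symbol(df[[i2]])
  si <- which(tolower(names(df)) == tolower(score_col))
  if (length(si) > 0L) {
    conf <- suppressWarnings(as.numeric(ascii_minus(df[[si[1L]]])))
    if (anyNA(conf)) {
      stop(sprintf("format error in '%s': non-numeric confidence score", path),
           call. = FALSE)
    }
  } else {
    conf <- rep(1, length(a))
  }
  as_edge_list(data.frame(from = a, to = b, confidence = conf,
                          stringsAsFactors = FALSE),
               min_confidence = min_confidence)
}

#' Canonicalize an in-memory edge list
#'
#' Applies the same rules as [read_edge_list()] to a data frame: drops
#' self-loops, orders each pair lexicographically, deduplicates (keeping the
#' highest confidence), and filters by confidence.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `confidence`.
#' @param min_confidence Confidence threshold.
#' @return Canonical edge list data frame.
#' @export
as_edge_list <- function(edges, min_confidence = 0) {
  if (is.null(edges$confidence)) edges$confidence <- rep(1, nrow(edges))
  loops <- edges$from == edges$to
  edges <- edges[!loops, , drop = FALSE]
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to, -edges$confidence), , drop = FALSE]
  edges <- edges[!duplicated(edges[c("from", "to")]), , drop = FALSE]
  edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, self_loops_dropped = sum(loops))
}

#' Write a pipeline graph to GraphML
#'
#' Round-trip safe: reading the file back with [read_graphml()] yields an
#' isomorphic graph with the same `role` vertex attributes.
#'
#' @param graph An `igraph` object whose vertices carry a `role` attribute
#'   (`pathway`/`target`/`drug`, or plain `target` for PPI graphs).
#' @param path Output file path.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(igraph::is_igraph(graph))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop(sprintf(
                    "cannot write GraphML to '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  close(con)
  igraph::write_graph(graph, path, format = "graphml")
  invisible(NULL)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
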