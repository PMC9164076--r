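#' Construct a named target set
#'
#' Members are normalized with [normalize_symbol()] and deduplicated, so set
#' operations are well-defined.
#'
#' @param label Set label.
#' @param members Character vector of gene symbols.
#' @return A `target_set`: list with `label` and sorted unique `members`.
#' @export
target_set <- function(label, members) {
  members <- if (length(members) > 0L) sort(unique(normalize_symbol(members)))
             else character(0)
  structure(list(label = label, members = members), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set '%s': %d symbols\n", x$label, length(x$members)))
  invisible(x)
}

#' Intersect two target sets
#'
#' Exact set intersection with Venn-ready counts. The invariants
#' `|A only| + |A and B| = |A|` and likewise for B hold by construction.
#'
#' @param a,b `target_set` objects (see [target_set()]).
#' @return A `venn_result`: list with `a_only`, `b_only`, `both` (counts),
#'   `members` (sorted intersection) and the input labels.
#' @export
intersect_sets <- function(a, b) {
  stopifnot(inherits(a, "target_set"), inherits(b, "target_set"))
  both <- sort(intersect(a$members, b$members))
  structure(list(label_a = a$label, label_b = b$label,
                 a_only = length(a$members) - length(both),
                 b_only = length(b$members) - length(both),
                 both = length(both),
                 members = both),
            class = "venn_result")
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("venn: %s only %d | both %d | %s only %d\n",
              x$label_a, x$a_only, x$both, x$label_b, x$b_only))
  invisible(x)
}

#' Two-stage target intersection
#'
#' The drug-repurposing target funnel: first intersect the two prediction
#' sources (stage 1), then intersect the surviving targets with the disease
#' target set (stage 2). The stage-2 member list is returned in sorted
#' order so reports diff deterministically. The raw union cardinality
#' across both sources is also reported.
#'
#' @param source_a,source_b Prediction-source `target_set`s.
#' @param disease Disease-associated `target_set`.
#' @return List with `stage1` and `stage2` (`venn_result`s), `final`
#'   (a `target_set` of the stage-2 members) and `union_size`.
#' @export
two_stage_overlap <- function(source_a, source_b, disease) {
  stage1 <- intersect_sets(source_a, source_b)
  shared <- target_set(paste0(source_a$label, "&", source_b$label),
                       stage1$members)
  stage2 <- intersect_sets(shared, disease)
  list(stage1 = stage1,
       stage2 = stage2,
       final = target_set("final", stage2$members),
       union_size = length(union(source_a$members, source_b$members)))
}

#' Write Venn counts and membership
#'
#' Emits the counts as JSON and the intersection membership one symbol per
#' line, the plot-ready inputs for a proportional Venn diagram.
#'
#' @param venn A `venn_result`.
#' @param json_path,members_path Output paths (either may be `NULL`).
#' @export
write_venn <- function(venn, json_path = NULL, members_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(a_only = venn$a_only, b_only = venn$b_only, both = venn$both,
           label_a = venn$label_a, label_b = venn$label_b),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(members_path)) {
    writeLines(venn$members, members_path)
  }
  invisible(NULL)
}
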