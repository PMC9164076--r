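#' Validate a pipeline configuration
#'
#' Checks the configuration file against the expected schema and returns
#' every problem found, not just the first: missing input keys, missing
#' files, and out-of-range parameters.
#'
#' @param config Path to a YAML configuration, or an already-parsed list.
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) {
    tryCatch(yaml::read_yaml(config),
             error = function(e) stop(sprintf(
               "cannot parse config '%s': %s", config,
               conditionMessage(e)), call. = FALSE))
  } else config
  problems <- character(0)
  need <- c("compounds", "predictions_a", "predictions_b",
            "disease_targets", "pathways", "ppi_edges", "docking_scores")
  inputs <- cfg$inputs
  if (is.null(inputs)) {
    problems <- c(problems, "missing 'inputs' block")
  } else {
    for (key in need) {
      if (is.null(inputs[[key]])) {
        problems <- c(problems, sprintf("missing input key '%s'", key))
      } else if (!file.exists(inputs[[key]])) {
        problems <- c(problems, sprintf("input file for '%s' not found: %s",
                                        key, inputs[[key]]))
      }
    }
  }
  p <- cfg$params
  check_range <- function(name, lo, hi) {
    v <- p[[name]]
    if (!is.null(v) && (!is.numeric(v) || v < lo || v > hi)) {
      problems <<- c(problems, sprintf(
        "parameter '%s' out of range [%g, %g]: %s", name, lo, hi, v))
    }
  }
  if (!is.null(p)) {
    check_range("tpsa_threshold", 0, Inf)
    check_range("alpha", 0, 1)
    check_range("fraction", 1e-9, 1)
    check_range("min_confidence", 0, 1)
    check_range("background", 1, Inf)
  }
  problems
}

default_params <- function() {
  list(tpsa_threshold = 140, alpha = 0.05, background = 20000,
       fraction = 0.30, docking_threshold = -6.0, min_confidence = 0)
}

#' Run the full network-pharmacology pipeline
#'
#' Orchestrates the analysis end-to-end: drug-likeness screening, two-stage
#' target intersection, pathway enrichment and key-pathway selection,
#' tripartite pathway-target-drug network construction with degree
#' analysis, two-stage centrality hub isolation on the PPI graph, and
#' docking triage. All intermediate artifacts are written under
#' `output_dir` and a machine-readable run report is returned (and written
#' as `report.json`). An empty final target set skips the downstream
#' stages with warnings and still succeeds. A failure inside a stage
#' aborts with an error naming the stage.
#'
#' @param config Path to a YAML configuration (see [validate_config()]) or
#'   an equivalent list.
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return The run report, invisibly (a nested list).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  problems <- validate_config(cfg)
  if (length(problems) > 0L) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  params <- utils::modifyList(default_params(),
                              if (is.null(cfg$params)) list() else cfg$params)
  out <- output_dir %||% cfg$output_dir %||% stop(
    "no output directory configured", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inp <- cfg$inputs
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  report <- list(package_version = as.character(utils::packageVersion("netpharm")),
                 params = params, config = cfg,
                 started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  # 1. drug-likeness screen
  scr <- stage("screen", {
    roster <- read_compounds(inp$compounds)
    s <- screen(roster, tpsa_threshold = params$tpsa_threshold)
    utils::write.table(s$per_compound, file.path(out, "screening.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s
  })
  report$screening <- scr$summary

  # 2. two-stage target overlap
  ov <- stage("overlap", {
    pa <- read_prediction_table(inp$predictions_a, "sourceA")
    pb <- read_prediction_table(inp$predictions_b, "sourceB")
    disease <- target_set("disease", readLines(inp$disease_targets,
                                               warn = FALSE))
    res <- two_stage_overlap(target_set("sourceA", pa$pairs$target),
                             target_set("sourceB", pb$pairs$target),
                             disease)
    write_venn(res$stage1, file.path(out, "venn_stage1.json"))
    write_venn(res$stage2, file.path(out, "venn_stage2.json"),
               file.path(out, "final_targets.txt"))
    list(res = res, predictions = rbind(pa$pairs, pb$pairs))
  })
  report$overlap <- list(
    source_a = ov$res$stage1$a_only + ov$res$stage1$both,
    source_b = ov$res$stage1$b_only + ov$res$stage1$both,
    union = ov$res$union_size,
    stage1 = ov$res$stage1$both,
    stage2 = ov$res$stage2$both)
  final <- ov$res$final

  if (length(final$members) == 0L) {
    warning("final target set is empty; downstream stages skipped",
            call. = FALSE)
    report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(report))
  }

  # 3. enrichment and key pathway
  enr <- stage("enrich", {
    db <- read_gmt(inp$pathways)
    tab <- enrich(final, db, N = params$background, alpha = params$alpha)
    write_enrichment(tab, file.path(out, "enrichment.tsv"))
    utils::write.table(bubble_data(tab), file.path(out, "bubble.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
    tab
  })
  report$enrichment <- list(
    n_pathways = nrow(enr),
    n_significant = sum(enr$significant),
    key_pathway = if (nrow(enr) > 0L) key_pathway(enr) else NA)

  # 4. tripartite network + degree analysis
  pta <- stage("pta", {
    sig <- enr[enr$significant, , drop = FALSE]
    pt <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i)
      data.frame(pathway = sig$pathway_id[i], target = sig$hit_genes[[i]],
                 stringsAsFactors = FALSE)))
    td <- ov$predictions[ov$predictions$target %in% final$members,
                         c("target", "drug")]
    if (is.null(pt) || nrow(td) == 0L) return(NULL)
    g <- build_pta(pt, td)
    write_graphml(g, file.path(out, "pta.graphml"))
    deg <- degree_table(g)
    write_centrality(deg, file.path(out, "pta_degrees.tsv"))
    list(graph = g, degrees = deg)
  })
  report$pta <- if (is.null(pta)) NULL else list(
    n_nodes = igraph::vcount(pta$graph),
    n_edges = igraph::ecount(pta$graph),
    top_target = pta$degrees$node[pta$degrees$role == "target"][1L],
    top_drug = pta$degrees$node[pta$degrees$role == "drug"][1L])

  # 5. PPI hub isolation
  hub <- stage("hub", {
    edges <- read_edge_list(inp$ppi_edges,
                            min_confidence = params$min_confidence)
    nodes <- if (!is.null(inp$ppi_nodes) && file.exists(inp$ppi_nodes))
      readLines(inp$ppi_nodes, warn = FALSE) else NULL
    h <- isolate_hub(edges, fraction = params$fraction, nodes = nodes)
    write_centrality(h$centrality_full, file.path(out, "ppi_centrality.tsv"))
    if (!is.null(h$subgraph)) {
      write_graphml(h$subgraph, file.path(out, "ppi_subnetwork.graphml"))
      write_centrality(h$centrality_sub,
                       file.path(out, "ppi_subnetwork_centrality.tsv"))
    }
    h
  })
  report$hub <- list(
    n_nodes = igraph::vcount(hub$graph),
    n_edges = igraph::ecount(hub$graph),
    subnetwork_nodes = length(hub$stage1$selected),
    hub = hub$hub)

  # 6. docking triage
  triage <- stage("triage", {
    rec <- parse_scores(inp$docking_scores)
    tri <- classify_binders(rec, threshold = params$docking_threshold)
    flat <- tri$records
    flat$hbond_residues <- vapply(flat$hbond_residues, paste,
                                  character(1), collapse = ",")
    flat$hydrophobic_residues <- vapply(flat$hydrophobic_residues, paste,
                                        character(1), collapse = ",")
    utils::write.table(flat, file.path(out, "triage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tri
  })
  report$triage <- list(
    n_active = triage$n_active, n_inactive = triage$n_inactive,
    threshold = triage$threshold,
    best_ligand = triage$best$ligand,
    best_energy = triage$best$binding_energy)

  report$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
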