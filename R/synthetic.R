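#' Configuration for the synthetic study generator
#'
#' The generators emulate the statistical structure of the web-database
#' stages of an antihistamine drug-repurposing study so that every pipeline
#' stage runs offline: two target-prediction sources with a controlled
#' intersection, a disease target set with a controlled second-stage
#' overlap, pathway annotations with planted hit counts, a PPI graph with a
#' planted high-betweenness bridge node, and a docking table with a
#' controlled active/inactive split. The defaults are the cardinalities of
#' the study this pipeline reproduces: 332 and 660 predicted-target sets
#' overlapping in 198, a 622-gene disease set overlapping the shared
#' targets in 15, and pathway size/hit pairs whose rich factors span the
#' published range.
#'
#' @param seed Integer seed; every generator is a pure function of it.
#' @param n_drugs Number of drugs in the roster.
#' @param n_targets_a,n_targets_b Target-set sizes of the two prediction
#'   sources.
#' @param overlap_ab Planted size of the source intersection.
#' @param n_disease Disease target-set size.
#' @param overlap_final Planted size of the second-stage overlap.
#' @param pathways Data frame with columns `K` (pathway background size)
#'   and `k` (planted hit count among the final targets).
#' @param clique_sizes Integer vector (length >= 2, each >= 3) of clique
#'   sizes in the planted-hub PPI graph.
#' @param n_isolated Isolated (degree-0) nodes appended to the PPI graph.
#' @param energy_range Docking energy interval (kcal/mol) spanning the
#'   -6.0 activity threshold.
#' @param n_active,n_inactive Planted docking split.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_drugs = 32L,
                         n_targets_a = 332L, n_targets_b = 660L,
                         overlap_ab = 198L,
                         n_disease = 622L, overlap_final = 15L,
                         pathways = data.frame(K = c(21L, 64L, 48L, 330L),
                                               k = c(2L, 3L, 2L, 4L)),
                         clique_sizes = c(5L, 5L),
                         n_isolated = 4L,
                         energy_range = c(-8, -4.5),
                         n_active = 6L, n_inactive = 2L) {
  cfg <- list(seed = as.integer(seed), n_drugs = n_drugs,
              n_targets_a = n_targets_a, n_targets_b = n_targets_b,
              overlap_ab = overlap_ab, n_disease = n_disease,
              overlap_final = overlap_final, pathways = pathways,
              clique_sizes = clique_sizes, n_isolated = n_isolated,
              energy_range = energy_range,
              n_active = n_active, n_inactive = n_inactive)
  if (overlap_ab > min(n_targets_a, n_targets_b)) {
    stop("config error: overlap_ab exceeds a source set size", call. = FALSE)
  }
  if (overlap_final > overlap_ab || overlap_final > n_disease) {
    stop("config error: overlap_final exceeds the sets it intersects",
         call. = FALSE)
  }
  if (any(unlist(cfg[c("n_drugs", "n_targets_a", "n_targets_b", "overlap_ab",
                       "n_disease", "overlap_final", "n_isolated",
                       "n_active", "n_inactive")]) < 0)) {
    stop("config error: counts must be non-negative", call. = FALSE)
  }
  if (any(pathways$k > pathways$K)) {
    stop("config error: planted hit count exceeds pathway size",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Run expr under a derived seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Zero-padded synthetic vocabularies; disjoint prefixes guarantee the
# planted intersections are exact.
syn_gene <- function(i) sprintf("G%06d", i)
syn_drug <- function(i) sprintf("DRUG%03d", i)

#' Generate two prediction sources with a planted intersection
#'
#' Source A and source B draw from disjoint unique-symbol pools plus a
#' shared pool of exactly `overlap_ab` symbols, so their target-set
#' intersection has exactly the planted cardinality. Each target is
#' attached to one or more random drugs, producing realistic
#' (drug, target) pair tables.
#'
#' @param cfg A [synth_config()].
#' @return List with `source_a` and `source_b` (`prediction_table`s) and
#'   `shared` (the planted intersection symbols).
#' @export
gen_prediction_sources <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 11L, {
    n_shared <- cfg$overlap_ab
    n_a_only <- cfg$n_targets_a - n_shared
    n_b_only <- cfg$n_targets_b - n_shared
    shared <- syn_gene(seq_len(n_shared))
    a_only <- syn_gene(n_shared + seq_len(n_a_only))
    b_only <- syn_gene(n_shared + n_a_only + seq_len(n_b_only))
    drugs <- syn_drug(seq_len(cfg$n_drugs))
    make_pairs <- function(targets, source_name) {
      n_links <- 1L + stats::rpois(length(targets), 0.5)
      pairs <- data.frame(
        drug = unlist(lapply(n_links, function(m)
          sample(drugs, min(m, length(drugs))))),
        target = rep(targets, pmin(n_links, length(drugs))),
        stringsAsFactors = FALSE)
      pairs <- unique(pairs[order(pairs$drug, pairs$target), ])
      rownames(pairs) <- NULL
      new_prediction_table(source_name, pairs,
                           n_rows = nrow(pairs), n_dup = 0L)
    }
    list(source_a = make_pairs(c(shared, a_only), "sourceA"),
         source_b = make_pairs(c(shared, b_only), "sourceB"),
         shared = shared)
  })
}

#' Generate a disease target set with a planted second-stage overlap
#'
#' Picks exactly `overlap_final` members of the stage-1 intersection and
#' pads the set to `n_disease` with symbols from a disjoint vocabulary
#' range, so the overlap with `stage1` is exactly as planted.
#'
#' @param cfg A [synth_config()].
#' @param stage1 `target_set` of stage-1 intersection members.
#' @return A disease `target_set`.
#' @export
gen_disease_set <- function(cfg, stage1) {
  stopifnot(inherits(cfg, "synth_config"), inherits(stage1, "target_set"))
  if (cfg$overlap_final > length(stage1$members)) {
    stop("config error: overlap_final exceeds the stage-1 intersection",
         call. = FALSE)
  }
  with_seed(cfg$seed + 23L, {
    inside <- sample(stage1$members, cfg$overlap_final)
    n_fill <- cfg$n_disease - cfg$overlap_final
    # filler range far beyond any symbol the sources can emit
    filler <- syn_gene(500000L + seq_len(n_fill))
    target_set("disease", c(inside, filler))
  })
}

#' Generate pathway annotations with planted hit counts
#'
#' Each configured pathway receives exactly `k` members drawn from the
#' final target set plus `K - k` filler genes, so the enrichment stage
#' recovers the planted rich factors `k/K` exactly. Pathways with `k = 0`
#' contain only filler and are absent from enrichment output.
#'
#' @param cfg A [synth_config()].
#' @param final_targets `target_set` of final (stage-2) targets.
#' @return A `pathway_db` as from [read_gmt()].
#' @export
gen_pathway_db <- function(cfg, final_targets) {
  stopifnot(inherits(cfg, "synth_config"), inherits(final_targets, "target_set"))
  pw <- cfg$pathways
  if (any(pw$k > length(final_targets$members))) {
    stop("config error: planted hit count exceeds the final target set",
         call. = FALSE)
  }
  with_seed(cfg$seed + 37L, {
    filler_next <- 800000L
    entries <- lapply(seq_len(nrow(pw)), function(i) {
      k <- pw$k[i]; K <- pw$K[i]
      hits <- if (k > 0L) sample(final_targets$members, k) else character(0)
      filler <- syn_gene(filler_next + (i - 1L) * 1000L + seq_len(K - k))
      list(id = sprintf("path%04d", i),
           name = sprintf("synthetic pathway %d", i),
           genes = sort(c(hits, filler)))
    })
    db <- data.frame(
      pathway_id = vapply(entries, `[[`, character(1), "id"),
      name = vapply(entries, `[[`, character(1), "name"),
      K = vapply(entries, function(e) length(e$genes), integer(1)),
      stringsAsFactors = FALSE)
    db$genes <- lapply(entries, `[[`, "genes")
    class(db) <- c("pathway_db", "data.frame")
    db
  })
}

#' Generate a planted-hub PPI graph
#'
#' Disjoint cliques are joined only through a single bridge node, connected
#' to every clique member: the bridge is the sole inter-clique connector,
#' so it lies on every shortest path between cliques (strictly maximal
#' betweenness) and, having degree equal to the sum of the clique sizes,
#' also dominates the degree ranking, surviving the first filter stage.
#' Optional isolated nodes (degree 0) are appended, mirroring real PPI
#' tables in which some targets have no interactions at the chosen
#' confidence.
#'
#' @param cfg A [synth_config()].
#' @return List with `edges` (canonical edge list), `hub` (the bridge
#'   node's name), and `nodes` (all node names including isolated ones).
#' @export
gen_hub_graph <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(cfg$clique_sizes) < 2L || any(cfg$clique_sizes < 3L)) {
    stop("config error: need >= 2 cliques of size >= 3", call. = FALSE)
  }
  with_seed(cfg$seed + 53L, {
    sizes <- cfg$clique_sizes
    offsets <- cumsum(c(0L, sizes[-length(sizes)]))
    total <- sum(sizes)
    node <- function(i) sprintf("P%03d", i)
    edges <- do.call(rbind, lapply(seq_along(sizes), function(ci) {
      ids <- node(offsets[ci] + seq_len(sizes[ci]))
      pairs <- utils::combn(ids, 2L)
      data.frame(from = pairs[1, ], to = pairs[2, ],
                 stringsAsFactors = FALSE)
    }))
    bridge <- node(total + 1L)
    edges <- rbind(edges, data.frame(from = bridge, to = node(seq_len(total)),
                                     stringsAsFactors = FALSE))
    isolated <- if (cfg$n_isolated > 0L)
      node(total + 1L + seq_len(cfg$n_isolated)) else character(0)
    list(edges = as_edge_list(edges), hub = bridge,
         nodes = c(node(seq_len(total)), bridge, isolated))
  })
}

#' Generate a docking score table with a planted active/inactive split
#'
#' Exactly `n_active` energies fall strictly below -6.0 kcal/mol and
#' `n_inactive` at or above it, drawn uniformly within the configured
#' energy range on either side of the threshold.
#'
#' @param cfg A [synth_config()].
#' @return Data frame of docking records.
#' @export
gen_docking_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  lo <- cfg$energy_range[1]; hi <- cfg$energy_range[2]
  if (!(lo < -6 && hi >= -6)) {
    stop("config error: energy range must span the -6.0 kcal/mol threshold",
         call. = FALSE)
  }
  with_seed(cfg$seed + 71L, {
    act <- stats::runif(cfg$n_active, lo, -6.001)
    inact <- stats::runif(cfg$n_inactive, -5.999, hi)
    n <- cfg$n_active + cfg$n_inactive
    rec <- data.frame(
      ligand = syn_drug(seq_len(n)),
      receptor = "HUB_TARGET",
      binding_energy = round(c(act, inact), 1),
      stringsAsFactors = FALSE)
    # rounding to 1 decimal must not cross the threshold
    rec$binding_energy[seq_len(cfg$n_active)] <-
      pmin(rec$binding_energy[seq_len(cfg$n_active)], -6.1)
    if (cfg$n_inactive > 0L) {
      idx <- cfg$n_active + seq_len(cfg$n_inactive)
      rec$binding_energy[idx] <- pmax(rec$binding_energy[idx], -5.9)
    }
    rec$hbond_residues <- rep(list(character(0)), n)
    rec$hydrophobic_residues <- rep(list(character(0)), n)
    rec
  })
}

#' Generate synthetic compound descriptors
#'
#' Descriptor values are drawn within ranges typical of marketed
#' small-molecule antihistamines (MW 250-510 g/mol, TPSA 3-90 square
#' Angstroms), so most compounds pass the drug-likeness screens while a
#' few carry single Lipinski violations.
#'
#' @param cfg A [synth_config()].
#' @return Compound roster data frame.
#' @export
gen_compounds <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed + 83L, {
    n <- cfg$n_drugs
    data.frame(
      name = syn_drug(seq_len(n)),
      mw = round(stats::runif(n, 250, 510), 2),
      hba = sample(1:6, n, replace = TRUE),
      hbd = sample(0:3, n, replace = TRUE),
      mlogp = round(stats::runif(n, 1.5, 5.5), 2),
      tpsa = round(stats::runif(n, 3, 90), 2),
      ba_score = 0.55,
      stringsAsFactors = FALSE)
  })
}

#' Write a complete synthetic study directory
#'
#' Emits every input the pipeline reads, in the exact dialects the readers
#' accept, so end-to-end runs exercise parsing as well as computation:
#' `compounds.csv`, `predictions_A.tsv`, `predictions_B.tsv`,
#' `disease_targets.txt`, `pathways.gmt`, `ppi_edges.tsv`,
#' `docking_scores.tsv` and the `config.yaml` used.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list of generated ground truths (`shared`,
#'   `final`, `hub`, `n_active`) for planted-recovery checks.
#' @export
write_synthetic_study <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  preds <- gen_prediction_sources(cfg)
  set_a <- target_set("sourceA", preds$source_a$pairs$target)
  set_b <- target_set("sourceB", preds$source_b$pairs$target)
  stage1 <- target_set("stage1", intersect(set_a$members, set_b$members))
  disease <- gen_disease_set(cfg, stage1)
  final <- target_set("final", intersect(stage1$members, disease$members))
  db <- gen_pathway_db(cfg, final)
  hubg <- gen_hub_graph(cfg)
  dock <- gen_docking_table(cfg)
  comp <- gen_compounds(cfg)

  utils::write.table(comp, file.path(dir, "compounds.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  wtab <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtab(preds$source_a$pairs, "predictions_A.tsv")
  wtab(preds$source_b$pairs, "predictions_B.tsv")
  writeLines(disease$members, file.path(dir, "disease_targets.txt"))
  gmt <- vapply(seq_len(nrow(db)), function(i)
    paste(c(db$pathway_id[i], db$name[i], db$genes[[i]]), collapse = "\t"),
    character(1))
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  ppi <- data.frame(node1 = hubg$edges$from, node2 = hubg$edges$to,
                    combined_score = hubg$edges$confidence)
  wtab(ppi, "ppi_edges.tsv")
  writeLines(hubg$nodes, file.path(dir, "ppi_nodes.txt"))
  dockout <- dock
  dockout$hbond_residues <- vapply(dock$hbond_residues, paste,
                                   character(1), collapse = ",")
  dockout$hydrophobic_residues <- vapply(dock$hydrophobic_residues, paste,
                                         character(1), collapse = ",")
  wtab(dockout, "docking_scores.tsv")
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "pathways")],
                   file.path(dir, "config.yaml"))
  invisible(list(shared = preds$shared, final = final, hub = hubg$hub,
                 n_active = cfg$n_active))
}
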