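#' Grid box for a docking run
#'
#' @param center Numeric length-3 vector, box center (x, y, z) in Angstroms.
#' @param size Numeric length-3 vector, box edge lengths in Angstroms;
#'   must be strictly positive.
#' @return A `grid_box` list.
#' @export
grid_box <- function(center, size) {
  stopifnot(length(center) == 3L, length(size) == 3L,
            is.numeric(center), is.numeric(size))
  if (any(size <= 0)) stop("grid box sizes must be strictly positive",
                           call. = FALSE)
  structure(list(center = center, size = size), class = "grid_box")
}

#' Emit a Vina-style docking configuration
#'
#' Deterministic, line-ordered `key = value` text consumable by a
#' Vina-family engine. Numbers are rendered with the precision they were
#' supplied at (no padding, no rounding), so the same box always produces
#' byte-identical output.
#'
#' @param box A [grid_box()].
#' @param receptor_file,ligand_file File names written into the config.
#' @param exhaustiveness Search exhaustiveness (default 8).
#' @param num_modes Number of poses requested (default 10).
#' @param energy_range Energy window above the best pose, kcal/mol
#'   (default 4).
#' @return Character scalar, the config text.
#' @export
make_grid_config <- function(box, receptor_file, ligand_file,
                             exhaustiveness = 8, num_modes = 10,
                             energy_range = 4) {
  stopifnot(inherits(box, "grid_box"))
  num <- function(x) format(x, trim = TRUE, scientific = FALSE)
  lines <- c(
    paste0("receptor = ", receptor_file),
    paste0("ligand = ", ligand_file),
    paste0("center_x = ", num(box$center[1])),
    paste0("center_y = ", num(box$center[2])),
    paste0("center_z = ", num(box$center[3])),
    paste0("size_x = ", num(box$size[1])),
    paste0("size_y = ", num(box$size[2])),
    paste0("size_z = ", num(box$size[3])),
    paste0("exhaustiveness = ", num(exhaustiveness)),
    paste0("num_modes = ", num(num_modes)),
    paste0("energy_range = ", num(energy_range)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

# Residue labels are 3-letter code + position, e.g. Trp391.
residue_pattern <- "^[A-Z][a-z]{2}[0-9]+$"

split_residues <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell)) ||
      toupper(trimws(cell)) == "N/A") return(character(0))
  res <- trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  res[nzchar(res)]
}

#' Parse a docking score table
#'
#' Reads a TSV with ligand, receptor and binding-energy columns, plus
#' optional hydrogen-bond and hydrophobic residue columns (comma-separated
#' residue labels; `N/A` or empty means none). Typographic minus signs in
#' energies are normalized before conversion. Residue labels that do not
#' match the `AaaNNN` pattern are kept but reported via a warning, not
#' fatal.
#'
#' @param path Path to the score table.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return Data frame of docking records with list-columns
#'   `hbond_residues` and `hydrophobic_residues`.
#' @export
parse_scores <- function(path, sep = NULL) {
  df <- read_delim_auto(path, sep)
  li <- require_column(df, "ligand", sprintf("score table '%s'", path))
  ri <- require_column(df, "receptor", sprintf("score table '%s'", path))
  ei <- require_column(df, "binding_energy", sprintf("score table '%s'", path))
  energy <- suppressWarnings(as.numeric(ascii_minus(as.character(df[[ei]]))))
  if (anyNA(energy)) {
    stop(sprintf("format error in '%s': non-numeric binding energy at row %d",
                 path, which(is.na(energy))[1L]), call. = FALSE)
  }
  rec <- data.frame(ligand = trimws(as.character(df[[li]])),
                    receptor = trimws(as.character(df[[ri]])),
                    binding_energy = energy,
                    stringsAsFactors = FALSE)
  for (opt in c("pubchem_id", "structure_id")) {
    idx <- which(tolower(names(df)) == opt)
    if (length(idx) > 0L) rec[[opt]] <- as.character(df[[idx[1L]]])
  }
  for (col in c(hbond_residues = "hbond_residues",
                hydrophobic_residues = "hydrophobic_residues")) {
    idx <- which(tolower(names(df)) == col)
    rec[[col]] <- if (length(idx) > 0L) {
      lapply(as.character(df[[idx[1L]]]), split_residues)
    } else rep(list(character(0)), nrow(rec))
  }
  bad <- unlist(lapply(c(rec$hbond_residues, rec$hydrophobic_residues),
                       function(r) r[!grepl(residue_pattern, r)]))
  if (length(bad) > 0L) {
    warning(sprintf("malformed residue label(s): %s",
                    paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  rec
}

#' Classify docking records against an activity threshold
#'
#' A record is active when its binding energy is strictly below the
#' threshold (default -6.0 kcal/mol, the conventional cutoff below which a
#' docked ligand is considered to bind stably). A record exactly at the
#' threshold is inactive.
#'
#' @param records Data frame of docking records (see [parse_scores()]).
#' @param threshold Activity threshold in kcal/mol.
#' @return A `triage_report`: list with `records` (input plus `active`
#'   flag, ranked by ascending energy), `threshold`, `n_active`,
#'   `n_inactive` and `best` (the top-ranked record row).
#' @export
classify_binders <- function(records, threshold = -6.0) {
  if (nrow(records) == 0L) stop("no docking records", call. = FALSE)
  if (any(!is.finite(records$binding_energy))) {
    stop("binding energies must be finite", call. = FALSE)
  }
  records$active <- records$binding_energy < threshold
  ord <- order(records$binding_energy, records$ligand)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records, threshold = threshold,
                 n_active = sum(records$active),
                 n_inactive = sum(!records$active),
                 best = records[1L, , drop = FALSE]),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf(
    "triage_report: %d active / %d inactive at < %g kcal/mol; best: %s (%g)\n",
    x$n_active, x$n_inactive, x$threshold,
    x$best$ligand, x$best$binding_energy))
  invisible(x)
}

#' Best binder by minimum binding energy
#'
#' Ties break lexicographically by ligand name.
#'
#' @param records Data frame of docking records.
#' @return Single-row data frame, the best-scoring record.
#' @export
best_binder <- function(records) {
  if (nrow(records) == 0L) stop("no result: empty docking record list",
                                call. = FALSE)
  ord <- order(records$binding_energy, records$ligand)
  out <- records[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}
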