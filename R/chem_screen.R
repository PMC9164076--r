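#' Lipinski rule-of-five violation count
#'
#' Applies the four drug-likeness bounds used for orally administered
#' compounds: molecular weight < 500 g/mol, hydrogen-bond acceptors < 10,
#' hydrogen-bond donors <= 5, and MLogP <= 4.15. The boundary semantics are
#' deliberately mixed (strict for MW and HBA, inclusive for HBD and MLogP):
#' these are the bounds as conventionally tabulated by SwissADME-style
#' profilers, and a compound sitting exactly on an inclusive bound passes.
#'
#' @param mw Molecular weight in g/mol.
#' @param hba Hydrogen-bond acceptor count.
#' @param hbd Hydrogen-bond donor count.
#' @param mlogp Moriguchi octanol-water partition coefficient.
#' @return List with `n_violations` (0-4) and `violated` (character vector
#'   of failed rule names among `"MW"`, `"HBA"`, `"HBD"`, `"MLOGP"`).
#' @examples
#' lipinski_violations(501.66, 5, 3, 3.86)  # 1 violation: MW
#' @export
lipinski_violations <- function(mw, hba, hbd, mlogp) {
  vals <- list(MW = mw, HBA = hba, HBD = hbd, MLOGP = mlogp)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || is.na(v) || !is.numeric(v)) {
      stop(sprintf("incomplete record: descriptor '%s' missing or non-numeric",
                   nm), call. = FALSE)
    }
  }
  if (mw <= 0) stop("molecular weight must be positive", call. = FALSE)
  if (hba < 0 || hbd < 0) stop("H-bond counts must be non-negative",
                               call. = FALSE)
  failed <- c(MW = !(mw < 500), HBA = !(hba < 10),
              HBD = !(hbd <= 5), MLOGP = !(mlogp <= 4.15))
  list(n_violations = sum(failed), violated = names(failed)[failed])
}

#' Filter a compound roster by topological polar surface area
#'
#' TPSA is a membrane-permeability proxy; orally administered drugs are
#' expected to fall strictly below 140 square Angstroms. A compound with
#' TPSA exactly at the threshold is excluded. Input order is preserved.
#'
#' @param roster Data frame with at least columns `name` and `tpsa`.
#' @param threshold TPSA cutoff in square Angstroms (default 140).
#' @return The subset of rows with `tpsa < threshold`.
#' @export
tpsa_filter <- function(roster, threshold = 140) {
  if (nrow(roster) == 0L) return(roster)
  if (is.null(roster$tpsa) || anyNA(roster$tpsa)) {
    stop("incomplete record: 'tpsa' missing for one or more compounds",
         call. = FALSE)
  }
  if (any(roster$tpsa < 0)) stop("tpsa must be non-negative", call. = FALSE)
  roster[roster$tpsa < threshold, , drop = FALSE]
}

#' Drug-likeness screen of a compound roster
#'
#' Runs [lipinski_violations()] and the TPSA membrane-permeability check on
#' every compound and summarizes the roster. Screening is annotative by
#' default (every compound is reported with its flags); set
#' `hard_filter = TRUE` to keep only compounds with zero Lipinski
#' violations and passing TPSA.
#'
#' @param roster Data frame with columns `name`, `mw`, `hba`, `hbd`,
#'   `mlogp`, `tpsa` (and optionally `ba_score`).
#' @param tpsa_threshold TPSA cutoff in square Angstroms.
#' @param hard_filter Drop failing compounds from `passing` output.
#' @return A `screen_report`: list with `per_compound` (data frame with
#'   `n_violations`, `violated`, `tpsa_pass`), `summary` (counts passing
#'   each rule), and `passing` (roster subset).
#' @export
screen <- function(roster, tpsa_threshold = 140, hard_filter = FALSE) {
  if (nrow(roster) == 0L) stop("empty compound roster", call. = FALSE)
  res <- lapply(seq_len(nrow(roster)), function(i) {
    r <- roster[i, ]
    v <- tryCatch(lipinski_violations(r$mw, r$hba, r$hbd, r$mlogp),
                  error = function(e) stop(sprintf(
                    "compound '%s': %s", r$name, conditionMessage(e)),
                    call. = FALSE))
    v
  })
  per <- data.frame(
    name = roster$name,
    n_violations = vapply(res, `[[`, integer(1), "n_violations"),
    violated = vapply(res, function(x) paste(x$violated, collapse = ","),
                      character(1)),
    tpsa = roster$tpsa,
    tpsa_pass = roster$tpsa < tpsa_threshold,
    stringsAsFactors = FALSE
  )
  ok_rule <- function(nm) sum(!grepl(nm, per$violated))
  summary <- list(
    n_compounds = nrow(per),
    pass_mw = ok_rule("MW"), pass_hba = ok_rule("HBA"),
    pass_hbd = ok_rule("HBD"), pass_mlogp = ok_rule("MLOGP"),
    pass_tpsa = sum(per$tpsa_pass),
    zero_violations = sum(per$n_violations == 0L),
    total_violations = sum(per$n_violations)
  )
  keep <- if (hard_filter) per$n_violations == 0L & per$tpsa_pass
          else per$tpsa_pass | TRUE
  structure(list(per_compound = per, summary = summary,
                 passing = roster[keep, , drop = FALSE],
                 tpsa_threshold = tpsa_threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "screen_report: %d compounds, %d with zero Lipinski violations, %d pass TPSA < %g\n",
    s$n_compounds, s$zero_violations, s$pass_tpsa, x$tpsa_threshold))
  invisible(x)
}

#' Read a compound roster
#'
#' Expects columns NAME, MW, HBA, HBD, MLOGP, TPSA (case-insensitive;
#' `MLogP` accepted) and optional BA_SCORE, SMILES, VIOLATIONS. Numeric
#' fields tolerate typographic minus signs.
#'
#' @param path Path to a CSV/TSV roster.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return Data frame with lower-case canonical column names.
#' @export
read_compounds <- function(path, sep = NULL) {
  df <- read_delim_auto(path, sep)
  want <- c(name = "name", mw = "mw", hba = "hba", hbd = "hbd",
            mlogp = "mlogp", tpsa = "tpsa")
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (canon in names(want)) {
    idx <- require_column(df, want[[canon]], sprintf("compound roster '%s'", path))
    col <- df[[idx]]
    out[[canon]] <- if (canon == "name") trimws(as.character(col))
                    else suppressWarnings(as.numeric(ascii_minus(col)))
  }
  for (opt in c("ba_score", "smiles", "violations")) {
    idx <- which(tolower(names(df)) == opt)
    if (length(idx) > 0L) {
      col <- df[[idx[1L]]]
      out[[opt]] <- if (opt == "smiles") as.character(col)
                    else suppressWarnings(as.numeric(ascii_minus(col)))
    }
  }
  rownames(out) <- NULL
  out
}
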