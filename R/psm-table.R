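#' PSM tables
#'
#' A PSM (peptide-spectrum match) table is an ordinary tibble with one row per
#' identified spectrum candidate and a small set of reserved columns:
#'
#' * `spectrum_id` (character) — identifier of the spectrum,
#' * `charge` (integer >= 1) — precursor ion charge,
#' * `rank` (integer >= 1) — candidate rank within its spectrum (best = 1),
#' * `ntt` (integer in 0..2) — number of tryptic termini,
#' * `nmc` (integer >= 0) — number of missed cleavages,
#' * `delta_mass` (numeric, Da) — precursor minus theoretical peptide mass,
#' * `is_decoy` (logical) — whether the match is against a decoy sequence,
#' * `discriminant_score` (numeric) — the summarized score, may be `NA`
#'   until [apply_discriminant()] is run,
#' * `peptide`, `protein` (character, optional),
#' * `true_label` (`"correct"`/`"incorrect"`, synthetic data only).
#'
#' Any other numeric column is treated as a search-engine feature (e.g.
#' `XCorr`, `deltaCn`, `SpRank`, `logDot`, `deltaDot`) and is preserved
#' untouched, so the package works with any engine that returns quantitative
#' scores.
#'
#' @name psm-table
NULL

.psm_reserved <- c("spectrum_id", "charge", "rank", "ntt", "nmc", "delta_mass",
                   "is_decoy", "discriminant_score", "peptide", "protein",
                   "true_label")

#' Validate a PSM table
#'
#' Checks the reserved-column invariants: `charge >= 1`, `rank >= 1`,
#' `ntt` in 0..2, `nmc >= 0`, unique `(spectrum_id, rank)` pairs, and that no
#' decoy row is labeled `"correct"`. Invoked by [read_psm_table()] and the
#' fitting functions; call it directly on tables assembled by hand.
#'
#' @param table A data frame with at least `spectrum_id` and `charge` columns.
#' @return The table, invisibly coerced to a tibble, or an error.
#' @export
validate_psm_table <- function(table) {
  table <- tibble::as_tibble(table)
  for (col in c("spectrum_id", "charge")) {
    if (!col %in% names(table))
      stop("PSM table is missing mandatory column `", col, "`", call. = FALSE)
  }
  if (nrow(table) == 0) return(invisible(table))
  if (any(table$charge < 1, na.rm = TRUE))
    stop("`charge` must be >= 1", call. = FALSE)
  if ("rank" %in% names(table) && any(table$rank < 1, na.rm = TRUE))
    stop("`rank` must be >= 1", call. = FALSE)
  if ("ntt" %in% names(table) && !all(table$ntt %in% c(0:2, NA)))
    stop("`ntt` must be 0, 1 or 2", call. = FALSE)
  if ("nmc" %in% names(table) && any(table$nmc < 0, na.rm = TRUE))
    stop("`nmc` must be >= 0", call. = FALSE)
  key <- paste(table$spectrum_id,
               if ("rank" %in% names(table)) table$rank else 1L)
  if (anyDuplicated(key))
    stop("`(spectrum_id, rank)` pairs must be unique", call. = FALSE)
  if (all(c("is_decoy", "true_label") %in% names(table)) &&
      any(table$is_decoy & table$true_label %in% "correct"))
    stop("a decoy record cannot have true_label = \"correct\"", call. = FALSE)
  invisible(table)
}

#' Names of search-engine feature columns
#'
#' @param table A PSM table.
#' @return Character vector of non-reserved numeric column names.
#' @export
feature_names <- function(table) {
  cand <- setdiff(names(table), .psm_reserved)
  cand[vapply(table[cand], is.numeric, logical(1))]
}

#' Read a PSM table from delimited text
#'
#' Reads a delimited file (tab by default) into a validated PSM tibble. The
#' decoy status is taken from an `is_decoy` column when present; otherwise,
#' when a `protein` column exists, rows whose protein accession starts with
#' `decoy_prefix` are flagged as decoys (the `"rev_"` reversed-sequence
#' convention by default).
#'
#' @param path Path to a delimited text file with a header row naming at
#'   least `spectrum_id`, `charge`, and one numeric score column.
#' @param delim Field delimiter, default tab.
#' @param decoy_prefix Protein-accession prefix marking decoys when no
#'   `is_decoy` column is present. `NULL` disables prefix matching.
#' @return A PSM tibble (see [psm-table]) with a `source` attribute recording
#'   the path.
#' @export
read_psm_table <- function(path, delim = "\t", decoy_prefix = "rev_") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  prob <- readr::problems(tb)
  if (nrow(prob) > 0) {
    p <- prob[1, ]
    stop(sprintf("unparseable cell at line %d, column %d of %s (expected %s, got %s)",
                 p$row + 1L, p$col, path, p$expected, p$actual), call. = FALSE)
  }
  if (!"spectrum_id" %in% names(tb))
    stop("missing mandatory column `spectrum_id` in ", path, call. = FALSE)
  if (!"charge" %in% names(tb))
    stop("missing mandatory column `charge` in ", path, call. = FALSE)
  # readr falls back to character when a numeric column contains a bad cell;
  # surface that as a row-level error (header is line 1)
  char_ok <- c("spectrum_id", "peptide", "protein", "true_label", "is_decoy")
  for (col in setdiff(names(tb), char_ok)) {
    if (!is.character(tb[[col]])) next
    vals <- tb[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(parsed))
    if (length(bad) > 0 && any(!is.na(parsed)))
      stop(sprintf("unparseable numeric cell in column `%s` at line %d of %s",
                   col, bad[1] + 1L, path), call. = FALSE)
    if (length(bad) == 0) tb[[col]] <- parsed
  }
  tb$spectrum_id <- as.character(tb$spectrum_id)
  tb$charge <- as.integer(tb$charge)
  for (col in c("rank", "ntt", "nmc")) {
    if (col %in% names(tb)) tb[[col]] <- as.integer(tb[[col]])
  }
  score_cols <- union(intersect("discriminant_score", names(tb)), feature_names(tb))
  if (length(score_cols) == 0 && nrow(tb) > 0)
    stop("no numeric score column found in ", path, call. = FALSE)
  if ("is_decoy" %in% names(tb)) {
    tb$is_decoy <- as.logical(tb$is_decoy)
  } else if (!is.null(decoy_prefix) && "protein" %in% names(tb)) {
    tb$is_decoy <- startsWith(tb$protein, decoy_prefix)
  } else {
    tb$is_decoy <- FALSE
  }
  if (!"rank" %in% names(tb)) tb$rank <- 1L
  validate_psm_table(tb)
  attr(tb, "source") <- path
  tb
}

#' Write a PSM table to delimited text
#'
#' Writes a PSM table so that [read_psm_table()] recovers it field-by-field
#' (floating point within 1e-9; full double precision is serialized). Absent
#' optional values are written as empty cells and reread as `NA`.
#'
#' @param table A PSM tibble.
#' @param path Output path.
#' @param delim Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(table, path, delim = "\t") {
  validate_psm_table(table)
  readr::write_delim(tibble::as_tibble(table), path, delim = delim, na = "")
  invisible(path)
}
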