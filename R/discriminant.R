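#' Discriminant coefficients
#'
#' A set of linear-discriminant coefficients maps search-engine features to a
#' single summarized score `S = intercept + sum_j weight_j * feature_j`,
#' trained so that `S > 0` for correct matches and `S < 0` for incorrect
#' ones. SEQUEST-style scoring combines `XCorr`, `deltaCn` and `SpRank`;
#' Tandem (k-score) combines `logDot` and `deltaDot`. Coefficients are
#' engine- and charge-specific: separate functions are trained for 1+, 2+
#' and 3+ precursor charges.
#'
#' An optional per-feature `transforms` list maps a feature name to a
#' function applied before weighting (default identity), e.g.
#' `list(SpRank = log)`.
#'
#' @param intercept Numeric intercept (beta0).
#' @param weights Named numeric vector of feature weights (beta1..betak);
#'   must be non-empty.
#' @param engine One of `"sequest"`, `"tandem"`, `"custom"`.
#' @param charge Integer charge the set applies to, or `NA` for any.
#' @param transforms Optional named list of per-feature transform functions.
#' @return A `psmix_coefficients` object.
#' @examples
#' discriminant_coefficients(-4, c(XCorr = 2, deltaCn = 8, SpRank = -0.2))
#' @export
discriminant_coefficients <- function(intercept, weights,
                                      engine = c("custom", "sequest", "tandem"),
                                      charge = NA_integer_, transforms = NULL) {
  engine <- match.arg(engine)
  if (length(weights) == 0 || is.null(names(weights)) || any(names(weights) == ""))
    stop("`weights` must be a non-empty named numeric vector", call. = FALSE)
  stopifnot(is.numeric(intercept), length(intercept) == 1)
  structure(
    list(engine = engine, charge = as.integer(charge),
         intercept = unname(intercept), weights = weights,
         transforms = transforms),
    class = "psmix_coefficients"
  )
}

#' @export
print.psmix_coefficients <- function(x, ...) {
  cat("<discriminant coefficients [", x$engine,
      if (!is.na(x$charge)) paste0(", charge ", x$charge), "]>\n", sep = "")
  cat("  intercept:", signif(x$intercept, 6), "\n")
  cat("  weights:  ",
      paste(names(x$weights), signif(x$weights, 6), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Read discriminant coefficients from a config file
#'
#' Parses a plain-text YAML file keyed by engine and charge, e.g.
#' ```
#' sequest:
#'   "2": {intercept: -4.0, weights: {XCorr: 2.0, deltaCn: 8.0, SpRank: -0.2}}
#' ```
#' The file shipped at `system.file("extdata", "default_coefficients.yaml",
#' package = "psmix")` contains illustrative placeholder values only: real
#' analyses should supply coefficients trained on a controlled mixture, or
#' use [fit_adaptive()] to estimate them from the data at hand.
#'
#' @param path Path to the YAML config.
#' @param engine Engine block to read.
#' @return Named list of `psmix_coefficients`, keyed by charge.
#' @export
read_coefficients <- function(path, engine = "sequest") {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg[[engine]]))
    stop("no coefficient block for engine `", engine, "` in ", path, call. = FALSE)
  purrr::imap(cfg[[engine]], function(block, ch) {
    discriminant_coefficients(block$intercept, unlist(block$weights),
                              engine = engine, charge = as.integer(ch))
  })
}

coeff_vector <- function(coeffs) {
  c(intercept = coeffs$intercept, coeffs$weights)
}

#' Apply a linear discriminant to a PSM table
#'
#' Fills (or overwrites) the `discriminant_score` column with
#' `intercept + sum_j weight_j * feature_j` for each record, using the
#' coefficient set matching the record's charge.
#'
#' @param table A PSM table with the required feature columns.
#' @param coeffs Either a single `psmix_coefficients` object (applied to all
#'   charges) or a list of them keyed by charge (names are charges). A list
#'   entry named `"default"` acts as the fallback for unmapped charges.
#' @return The table with `discriminant_score` populated; all other columns
#'   unchanged.
#' @export
apply_discriminant <- function(table, coeffs) {
  table <- validate_psm_table(table)
  if (inherits(coeffs, "psmix_coefficients")) {
    per_charge <- FALSE
  } else if (is.list(coeffs) && all(vapply(coeffs, inherits, logical(1),
                                           "psmix_coefficients"))) {
    per_charge <- TRUE
  } else {
    stop("`coeffs` must be psmix_coefficients or a charge-keyed list of them",
         call. = FALSE)
  }
  score_one_set <- function(rows, cf) {
    missing_feat <- setdiff(names(cf$weights), names(rows))
    if (length(missing_feat) > 0)
      stop("record ", rows$spectrum_id[1], " is missing feature `",
           missing_feat[1], "`", call. = FALSE)
    s <- rep(cf$intercept, nrow(rows))
    for (f in names(cf$weights)) {
      x <- rows[[f]]
      if (anyNA(x))
        stop("record ", rows$spectrum_id[which(is.na(x))[1]],
             " is missing feature `", f, "`", call. = FALSE)
      tr <- cf$transforms[[f]]
      if (!is.null(tr)) x <- tr(x)
      s <- s + cf$weights[[f]] * x
    }
    s
  }
  if (!per_charge) {
    table$discriminant_score <- score_one_set(table, coeffs)
    return(table)
  }
  out <- rep(NA_real_, nrow(table))
  for (ch in unique(table$charge)) {
    cf <- coeffs[[as.character(ch)]] %||% coeffs[["default"]]
    if (is.null(cf))
      stop("no discriminant coefficients for charge ", ch,
           " and no `default` fallback", call. = FALSE)
    idx <- which(table$charge == ch)
    out[idx] <- score_one_set(table[idx, , drop = FALSE], cf)
  }
  table$discriminant_score <- out
  table
}
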