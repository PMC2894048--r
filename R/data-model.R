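# Curated entry-table schema: one row per literature experiment, combining
# protein descriptors, GAG descriptors, experimental-condition descriptors and
# the observed kinetic outcome (the half-time pair and G).

#' Column schema of the curated GAG/aggregation entry table
#'
#' Returns the canonical column names of the entry table together with their
#' storage type and whether a value is required. All analysis functions in the
#' package address columns by these names.
#'
#' @return A data frame with columns `column`, `type`
#'   (`"numeric"`, `"integer"`, `"character"`, `"logical"`) and `required`.
#'
#' @details Descriptor columns:
#' \describe{
#'   \item{protein descriptors}{`protein`, `protein_length` (residues),
#'     `protein_net_charge` (at pH 7.5), `lys_arg_count`,
#'     `folding_status` (`"globular"` / `"natively_unfolded"`),
#'     `disease_related` (logical).}
#'   \item{GAG descriptors}{`gag`, `sulfates_per_disaccharide`,
#'     `charges_per_disaccharide`, `uronic_acid`
#'     (`"iduronic"` / `"glucuronic"` / `"none"`), `sulfation_position`
#'     (`"N"` / `"O"` / `"mixed"` / `"none"`), `gag_mw` (Da, optional).}
#'   \item{condition descriptors}{`solute_molarity` (total buffer solutes,
#'     mM), `protein_conc` (uM), `gag_conc` (uM),
#'     `protein_gag_molar_ratio`, `pH`, `temperature` (deg C), `buffer`.}
#'   \item{outcome}{`t_half_no_gag`, `t_half_with_gag` (same time unit,
#'     hours when `time_unit` is present), `time_unit`, `G`
#'     (log acceleration, dimensionless), `source` (citation).}
#' }
#' @export
gag_table_schema <- function() {
  s <- rbind(
    c("protein",                  "character", TRUE),
    c("protein_length",           "integer",   TRUE),
    c("protein_net_charge",       "numeric",   TRUE),
    c("lys_arg_count",            "integer",   TRUE),
    c("folding_status",           "character", TRUE),
    c("disease_related",          "logical",   TRUE),
    c("gag",                      "character", TRUE),
    c("sulfates_per_disaccharide","numeric",   TRUE),
    c("charges_per_disaccharide", "numeric",   TRUE),
    c("uronic_acid",              "character", TRUE),
    c("sulfation_position",       "character", TRUE),
    c("gag_mw",                   "numeric",   FALSE),
    c("solute_molarity",          "numeric",   TRUE),
    c("protein_conc",             "numeric",   FALSE),
    c("gag_conc",                 "numeric",   FALSE),
    c("protein_gag_molar_ratio",  "numeric",   TRUE),
    c("pH",                       "numeric",   FALSE),
    c("temperature",              "numeric",   FALSE),
    c("buffer",                   "character", FALSE),
    c("t_half_no_gag",            "numeric",   FALSE),
    c("t_half_with_gag",          "numeric",   FALSE),
    c("time_unit",                "character", FALSE),
    c("G",                        "numeric",   TRUE),
    c("source",                   "character", FALSE)
  )
  data.frame(column = s[, 1], type = s[, 2],
             required = as.logical(s[, 3]), stringsAsFactors = FALSE)
}

#' Validate entries of a curated GAG table
#'
#' Checks every row against the schema invariants:
#' `sulfates_per_disaccharide >= 0`;
#' `charges_per_disaccharide >= sulfates_per_disaccharide` (each sulfate
#' carries one negative charge; the uronic-acid carboxylate may add one more);
#' `sulfation_position == "none"` exactly when the sulfation state is 0;
#' `lys_arg_count <= protein_length` and `protein_length > 0`;
#' the stated `protein_gag_molar_ratio` agrees with
#' `protein_conc / gag_conc` within 5% relative tolerance when all three are
#' present; both half-times positive and, when both are present,
#' `G == log(t_half_no_gag / t_half_with_gag)` within `1e-6`.
#'
#' @param entries A data frame following [gag_table_schema()].
#' @return A data frame with columns `row`, `column`, `message`; zero rows
#'   when everything is valid.
#' @export
validate_gag_entries <- function(entries) {
  stopifnot(is.data.frame(entries))
  probs <- list()
  bad <- function(rows, column, message) {
    rows <- which(rows)
    if (length(rows))
      probs[[length(probs) + 1L]] <<-
        data.frame(row = rows, column = column, message = message,
                   stringsAsFactors = FALSE)
  }
  sch <- gag_table_schema()
  missing_cols <- setdiff(sch$column[sch$required], names(entries))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(entries)
  if (n == 0L) return(data.frame(row = integer(), column = character(),
                                 message = character(), stringsAsFactors = FALSE))
  e <- entries
  has <- function(x) !is.na(x)

  bad(has(e$sulfates_per_disaccharide) & e$sulfates_per_disaccharide < 0,
      "sulfates_per_disaccharide", "negative sulfation state")
  bad(has(e$charges_per_disaccharide) & has(e$sulfates_per_disaccharide) &
        e$charges_per_disaccharide < e$sulfates_per_disaccharide,
      "charges_per_disaccharide", "fewer charges than sulfates")
  bad(has(e$sulfation_position) & has(e$sulfates_per_disaccharide) &
        ((e$sulfation_position == "none") != (e$sulfates_per_disaccharide == 0)),
      "sulfation_position", "sulfation_position 'none' must coincide with 0 sulfates")
  bad(has(e$protein_length) & e$protein_length <= 0,
      "protein_length", "non-positive protein length")
  bad(has(e$lys_arg_count) & has(e$protein_length) &
        e$lys_arg_count > e$protein_length,
      "lys_arg_count", "more Lys+Arg residues than total length")
  ok3 <- has(e$protein_conc) & has(e$gag_conc) & has(e$protein_gag_molar_ratio)
  rel <- rep(0, n)
  rel[ok3] <- abs(e$protein_gag_molar_ratio[ok3] -
                    e$protein_conc[ok3] / e$gag_conc[ok3]) /
    abs(e$protein_gag_molar_ratio[ok3])
  bad(ok3 & rel > 0.05, "protein_gag_molar_ratio",
      "molar ratio inconsistent with protein_conc/gag_conc (>5% relative)")
  for (col in c("t_half_no_gag", "t_half_with_gag"))
    bad(has(e[[col]]) & e[[col]] <= 0, col, "non-positive half-time")
  both <- has(e$t_half_no_gag) & has(e$t_half_with_gag) & has(e$G) &
    e$t_half_no_gag > 0 & e$t_half_with_gag > 0
  dG <- rep(0, n)
  dG[both] <- abs(e$G[both] - log(e$t_half_no_gag[both] / e$t_half_with_gag[both]))
  bad(both & dG > 1e-6, "G",
      "stored G disagrees with log(t_half_no_gag/t_half_with_gag) beyond 1e-6")

  if (!length(probs))
    return(data.frame(row = integer(), column = character(),
                      message = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, probs)
  out[order(out$row, out$column), , drop = FALSE]
}

# Resolve a schema argument (NULL, named character vector, or YAML file path
# with a top-level `columns:` map of file header -> canonical name).
resolve_schema <- function(schema) {
  if (is.null(schema)) return(NULL)
  if (is.character(schema) && length(schema) == 1L && is.null(names(schema)) &&
      file.exists(schema)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML schema requires the 'yaml' package")
    y <- yaml::read_yaml(schema)
    cols <- y[["columns"]]
    if (is.null(cols)) stop("schema file has no 'columns' map")
    return(unlist(cols))
  }
  if (!is.character(schema) || is.null(names(schema)))
    stop("schema must be NULL, a named character vector, or a YAML file path")
  schema
}

#' Read a curated GAG entry table
#'
#' Reads a UTF-8, tab-separated entry table with one header row and a decimal
#' point, renames columns through an optional schema map, coerces every column
#' to its schema type with row/column-level parse diagnostics, and validates
#' the entries with [validate_gag_entries()].
#'
#' @param path Path to a TSV file.
#' @param schema `NULL`, a named character vector mapping file headers to
#'   canonical column names, or the path of a YAML file with a `columns:` map.
#' @param strict If `TRUE` (default), any invalid row is an error; if `FALSE`,
#'   invalid rows are dropped with a warning and the rejection table is
#'   attached as attribute `"rejected"`.
#' @return A validated data frame of entries.
#' @export
read_gag_table <- function(path, schema = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!length(grep("[^[:space:]]", readLines(path, warn = FALSE))))
    stop("empty input: '", path, "' contains no entries")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (nrow(raw) == 0L && ncol(raw) <= 1L)
    stop("empty input: '", path, "' contains no entries")
  map <- resolve_schema(schema)
  if (!is.null(map)) {
    hit <- names(raw) %in% names(map)
    names(raw)[hit] <- unname(map[names(raw)[hit]])
  }
  sch <- gag_table_schema()
  missing_cols <- setdiff(sch$column[sch$required], names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L)
    stop("empty input: '", path, "' contains a header but no entries")

  out <- raw
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]
    if (!col %in% names(out)) next
    x <- out[[col]]
    out[[col]] <- switch(sch$type[i],
      numeric = {
        v <- suppressWarnings(as.numeric(x))
        failed <- which(!is.na(x) & is.na(v))
        if (length(failed))
          stop("non-numeric value in numeric column '", col, "' at row(s) ",
               paste(failed, collapse = ", "))
        v
      },
      integer = {
        v <- suppressWarnings(as.integer(x))
        failed <- which(!is.na(x) & is.na(v))
        if (length(failed))
          stop("non-integer value in integer column '", col, "' at row(s) ",
               paste(failed, collapse = ", "))
        v
      },
      logical = {
        v <- rep(NA, length(x))
        v[!is.na(x) & toupper(x) %in% c("TRUE", "T", "1")] <- TRUE
        v[!is.na(x) & toupper(x) %in% c("FALSE", "F", "0")] <- FALSE
        failed <- which(!is.na(x) & is.na(v))
        if (length(failed))
          stop("non-logical value in column '", col, "' at row(s) ",
               paste(failed, collapse = ", "))
        v
      },
      x)
  }
  # half-times normalised to hours when a unit column is present
  if ("time_unit" %in% names(out)) {
    fac <- c(h = 1, hr = 1, hour = 1, hours = 1,
             min = 1 / 60, minute = 1 / 60, minutes = 1 / 60,
             s = 1 / 3600, sec = 1 / 3600, seconds = 1 / 3600,
             d = 24, day = 24, days = 24)
    u <- tolower(out$time_unit)
    known <- !is.na(u) & u %in% names(fac)
    bad_u <- which(!is.na(u) & !known)
    if (length(bad_u))
      stop("unknown time unit at row(s) ", paste(bad_u, collapse = ", "))
    out$t_half_no_gag[known] <- out$t_half_no_gag[known] * fac[u[known]]
    out$t_half_with_gag[known] <- out$t_half_with_gag[known] * fac[u[known]]
    out$time_unit[known] <- "h"
  }
  probs <- validate_gag_entries(out)
  if (nrow(probs)) {
    if (strict)
      stop("invalid entries:\n",
           paste(sprintf("  row %d [%s]: %s", probs$row, probs$column,
                         probs$message), collapse = "\n"))
    drop <- unique(probs$row)
    warning(length(drop), " invalid entr", if (length(drop) == 1) "y" else "ies",
            " dropped; see attr(, 'rejected')")
    out <- out[-drop, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rejected") <- probs
  }
  out
}

#' Write a curated GAG entry table
#'
#' Validates the entries and writes them as UTF-8 tab-separated text with one
#' header row, empty cells for missing optional values, and numbers printed at
#' 15 significant digits so that a [read_gag_table()] round trip reproduces
#' the values exactly at that precision.
#'
#' @param entries A valid entry data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gag_table <- function(entries, path) {
  probs <- validate_gag_entries(entries)
  if (nrow(probs))
    stop("refusing to write invalid entries:\n",
         paste(sprintf("  row %d [%s]: %s", probs$row, probs$column,
                       probs$message), collapse = "\n"))
  out <- entries
  for (col in names(out)) {
    x <- out[[col]]
    if (is.numeric(x)) {
      s <- vapply(x, function(v) if (is.na(v)) NA_character_ else
        format(v, digits = 15, scientific = FALSE, trim = TRUE), character(1))
      out[[col]] <- s
    } else if (is.logical(x)) {
      out[[col]] <- ifelse(is.na(x), NA_character_, ifelse(x, "TRUE", "FALSE"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarise a curated GAG entry table
#'
#' @param entries An entry data frame.
#' @return A list with the entry count, numbers of distinct proteins and
#'   GAGs, and per-variable ranges of the main continuous descriptors.
#' @export
gag_table_summary <- function(entries) {
  rng <- function(x) if (all(is.na(x))) c(NA_real_, NA_real_) else
    range(x, na.rm = TRUE)
  structure(list(
    n_entries = nrow(entries),
    n_proteins = length(unique(entries$protein)),
    n_gags = length(unique(entries$gag)),
    sulfates_range = rng(entries$sulfates_per_disaccharide),
    charges_range = rng(entries$charges_per_disaccharide),
    molarity_range = rng(entries$solute_molarity),
    molar_ratio_range = rng(entries$protein_gag_molar_ratio),
    G_range = rng(entries$G)
  ), class = "gag_table_summary")
}

#' @export
print.gag_table_summary <- function(x, ...) {
  cat(sprintf("Curated GAG aggregation dataset: %d entries (%d proteins, %d GAGs)\n",
              x$n_entries, x$n_proteins, x$n_gags))
  fmt <- function(r) sprintf("[%.3g, %.3g]", r[1], r[2])
  cat("  sulfates/disaccharide:", fmt(x$sulfates_range), "\n")
  cat("  charges/disaccharide: ", fmt(x$charges_range), "\n")
  cat("  solute molarity (mM): ", fmt(x$molarity_range), "\n")
  cat("  protein:GAG ratio:    ", fmt(x$molar_ratio_range), "\n")
  cat("  G:                    ", fmt(x$G_range), "\n")
  invisible(x)
}

# Default reference levels for the dichotomous descriptors; any other
# variable falls back to its alphabetically first observed level.
default_reference_levels <- c(
  uronic_acid = "glucuronic",
  sulfation_position = "O",
  folding_status = "globular",
  disease_related = "FALSE"
)

#' Recode categorical descriptors into 0/1 dummy variables
#'
#' One column per non-reference level, named `"variable=level"`, with levels
#' ordered alphabetically. The reference level is dropped: the uronic acid is
#' referenced to glucuronic, the sulfation position to O-sulfation, the
#' folding status to globular, and disease association to `FALSE`; any other
#' variable uses its alphabetically first level. Any consistent coding yields
#' the same regression fit; these defaults make column naming deterministic.
#'
#' @param entries An entry data frame.
#' @param variables Character vector of categorical column names.
#' @param reference Optional named character vector of reference levels,
#'   overriding the defaults.
#' @return A numeric matrix of 0/1 columns, one row per entry.
#' @export
encode_dummies <- function(entries, variables,
                           reference = default_reference_levels) {
  stopifnot(is.data.frame(entries), is.character(variables))
  cols <- list()
  for (v in variables) {
    if (!v %in% names(entries)) stop("no such column: ", v)
    x <- as.character(entries[[v]])
    lev <- sort(unique(x[!is.na(x)]))
    if (length(lev) < 2L)
      stop("degenerate encoding: '", v, "' has ", length(lev),
           " observed level(s); need at least 2")
    ref <- if (v %in% names(reference) && reference[[v]] %in% lev)
      reference[[v]] else lev[1L]
    for (l in setdiff(lev, ref))
      cols[[paste0(v, "=", l)]] <- as.numeric(x == l)
  }
  do.call(cbind, cols)
}
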