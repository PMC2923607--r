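#' Read a foci table
#'
#' Reads a tab-separated (default) or comma-separated table of stereotactic
#' foci, one row per reported peak coordinate. The header must declare the
#' columns \code{study_id}, \code{condition}, \code{space}, \code{x},
#' \code{y}, \code{z}, \code{direction}. A missing \code{space} column is
#' tolerated: all rows then default to \code{TAL_NATIVE} with a warning.
#'
#' @param path Path to the table.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param single_condition Set \code{TRUE} to accept a table carrying only
#'   one condition label (e.g. for a plain single-condition ALE). By default
#'   exactly one or two labels are required and three or more are an error.
#' @return A data frame of class \code{ale_foci} with character columns
#'   \code{study_id}, \code{condition}, \code{space}, \code{direction} and
#'   numeric \code{x}, \code{y}, \code{z}. Attribute \code{conditions} holds
#'   the sorted condition labels.
#' @export
parse_foci_table <- function(path, dialect = c("tsv", "csv"),
                             single_condition = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("foci table not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = TRUE,
                           fileEncoding = "UTF-8")
  required <- c("study_id", "condition", "x", "y", "z", "direction")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("foci table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!"space" %in% names(raw)) {
    warning("no 'space' column; assuming TAL_NATIVE for all foci")
    raw$space <- "TAL_NATIVE"
  }
  raw$space[is.na(raw$space) | raw$space == ""] <- "TAL_NATIVE"
  as_foci(raw, single_condition = single_condition)
}

#' Construct a validated foci data frame
#'
#' Validates column types, coordinate finiteness and the 120 mm sanity
#' bound, condition-label cardinality, and space/direction vocabularies.
#' Used by [parse_foci_table()] and by the synthetic generator.
#'
#' @param df Data frame with the foci columns (see [parse_foci_table()]).
#' @param single_condition Accept a single condition label.
#' @return The validated data frame of class \code{ale_foci}.
#' @export
as_foci <- function(df, single_condition = FALSE) {
  for (v in c("x", "y", "z")) {
    num <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(num) & !is.na(df[[v]]) | is.na(df[[v]]))
    if (length(bad) > 0)
      stop("non-numeric ", v, " coordinate at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    df[[v]] <- num
  }
  df$study_id <- as.character(df$study_id)
  df$condition <- as.character(df$condition)
  df$space <- as.character(df$space)
  df$direction <- toupper(as.character(df$direction))
  conds <- sort(unique(df$condition))
  if (!single_condition && length(conds) > 2)
    stop("more than two condition labels present: ",
         paste(conds, collapse = ", "))
  if (single_condition && length(conds) != 1)
    stop("single-condition mode requested but labels present: ",
         paste(conds, collapse = ", "))
  badsp <- setdiff(unique(df$space), .SPACES)
  if (length(badsp) > 0)
    stop("unknown coordinate space tag(s): ", paste(badsp, collapse = ", "))
  baddir <- setdiff(unique(df$direction), .DIRECTIONS)
  if (length(baddir) > 0)
    stop("unknown effect direction(s): ", paste(baddir, collapse = ", "),
         " (expected DEFICIT or EXCESS)")
  .check_coord_bounds(df)
  df <- df[, c("study_id", "condition", "space", "x", "y", "z", "direction")]
  class(df) <- c("ale_foci", "data.frame")
  attr(df, "conditions") <- conds
  df
}

#' Write a foci table
#'
#' Writes the standard foci TSV/CSV with coordinates formatted to three
#' decimal places, so that parse -> write -> parse reproduces the same
#' multiset of foci bit-exactly as decimal text.
#'
#' @param foci Foci data frame.
#' @param path Output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_foci_table <- function(foci, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  out <- as.data.frame(foci)
  for (v in c("x", "y", "z")) out[[v]] <- sprintf("%.3f", out[[v]])
  utils::write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split foci into per-study groups
#'
#' Groups a foci table by (study, condition, direction) — the unit over
#' which individual likelihood maps are built and then averaged within
#' condition.
#'
#' @param foci Foci data frame.
#' @return Named list of \code{ale_foci} data frames, one per group; names
#'   are \code{study_id/condition/direction}.
#' @export
split_studies <- function(foci) {
  key <- interaction(foci$study_id, foci$condition, foci$direction,
                     sep = "/", drop = TRUE)
  split(as.data.frame(foci), key)
}
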