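#' Read a protein intensity table
#'
#' Reads a delimited text table with one row per protein: an identifier
#' column plus one non-negative intensity column per labeling channel
#' (e.g. iTRAQ reporter channels 114/115/116/117). Intensities are assumed
#' to have been summarized from peptide to protein level upstream.
#'
#' Empty cells and the markers `"NA"`/`"NaN"` (case-insensitive) are read as
#' missing and stored as `NA` (absent channel), never as zero.
#'
#' @param path Path to a delimited text file with a header row.
#' @param id_column Name of the protein identifier column. Default: the
#'   first column.
#' @param channel_columns Character vector of intensity column names.
#'   Default: all columns other than `id_column`.
#' @param delimiter Field delimiter, `"tab"` (default) or `"comma"`.
#' @param run_id Label for the MS run this table came from; defaults to the
#'   file name.
#' @return A `ProteinProfile`: a data frame with column `protein_id`
#'   followed by one numeric column per channel, with attributes `run_id`
#'   and `channels`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("protein\tit114\tit115", "P1\t10\t20", "P2\t5\t"), tf)
#' prof <- load_profile_table(tf)
#' prof$it115  # NA for P2: absent, not zero
#' @export
load_profile_table <- function(path, id_column = NULL, channel_columns = NULL,
                               delimiter = c("tab", "comma"),
                               run_id = basename(path)) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) {
    stop("input table not found: ", path)
  }
  sep <- if (delimiter == "tab") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, comment.char = "",
                           encoding = "UTF-8")
  if (is.null(id_column)) id_column <- names(raw)[1L]
  if (!id_column %in% names(raw)) {
    stop("identifier column not found in table: '", id_column, "'")
  }
  if (is.null(channel_columns)) {
    channel_columns <- setdiff(names(raw), id_column)
  }
  missing_cols <- setdiff(channel_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("channel column(s) not found in table: ",
         paste(sQuote(missing_cols), collapse = ", "))
  }
  if (length(channel_columns) == 0) {
    stop("table must contain at least one channel column")
  }
  ids <- raw[[id_column]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate protein identifier(s): ",
         paste(sQuote(dup), collapse = ", "),
         "; intensities must be summarized to protein level upstream")
  }
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (ch in channel_columns) {
    cell <- raw[[ch]]
    is_missing <- cell == "" | tolower(cell) %in% c("na", "nan")
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(val))
    if (length(bad) > 0) {
      stop("non-numeric intensity in column '", ch, "', data row(s) ",
           paste(bad, collapse = ", "))
    }
    neg <- which(!is.na(val) & val < 0)
    if (length(neg) > 0) {
      stop("negative intensity in column '", ch, "', data row(s) ",
           paste(neg, collapse = ", "))
    }
    val[is_missing] <- NA_real_
    out[[ch]] <- val
  }
  structure(out,
            run_id = run_id,
            channels = channel_columns,
            class = c("ProteinProfile", "data.frame"))
}

#' Combine labeling channels into a two-condition profile pair
#'
#' Sums the listed channel intensities per protein to form the combined
#' intensity of each condition (as when reporter channels 114 and 115 are
#' technical labelings of the same sample). An absent channel contributes 0.
#' Proteins whose combined intensity is 0 in either condition are dropped —
#' a finite log2 ratio requires strictly positive intensity on both sides —
#' and the number dropped is recorded.
#'
#' @param profile A `ProteinProfile` from [load_profile_table()].
#' @param groups Named list of exactly two character vectors: condition
#'   label -> channel column names.
#' @return A `ConditionPair`: data frame with columns `protein_id`,
#'   `intensity_a`, `intensity_b`; attributes `conditions` (the two labels),
#'   `n_dropped`, and `run_id`.
#' @examples
#' prof <- structure(
#'   data.frame(protein_id = "P1", c114 = 10, c115 = 20, c116 = 5, c117 = 5),
#'   channels = c("c114", "c115", "c116", "c117"), run_id = "r1",
#'   class = c("ProteinProfile", "data.frame"))
#' combine_channels(prof, list(ctrl = c("c114", "c115"),
#'                             trt  = c("c116", "c117")))
#' @export
combine_channels <- function(profile, groups) {
  stopifnot(inherits(profile, "ProteinProfile"))
  if (!is.list(groups) || length(groups) != 2L || is.null(names(groups)) ||
      any(names(groups) == "")) {
    stop("'groups' must be a named list of exactly two conditions")
  }
  channels <- attr(profile, "channels")
  unknown <- setdiff(unlist(groups), channels)
  if (length(unknown) > 0) {
    stop("unknown channel label(s): ", paste(sQuote(unknown), collapse = ", "))
  }
  sum_group <- function(chs) {
    m <- as.matrix(profile[, chs, drop = FALSE])
    rowSums(m, na.rm = TRUE)
  }
  ia <- sum_group(groups[[1L]])
  ib <- sum_group(groups[[2L]])
  keep <- ia > 0 & ib > 0
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    stop("no protein has positive combined intensity in both conditions")
  }
  condition_pair(profile$protein_id[keep], ia[keep], ib[keep],
                 conditions = names(groups),
                 n_dropped = n_dropped,
                 run_id = attr(profile, "run_id"))
}

#' Construct a ConditionPair directly
#'
#' Low-level constructor used by [combine_channels()] and the synthetic-data
#' generator.
#'
#' @param protein_id Character vector of unique protein identifiers.
#' @param intensity_a,intensity_b Strictly positive combined intensities of
#'   the two conditions, in raw (non-log) MS units.
#' @param conditions Labels for the two conditions.
#' @param n_dropped Count of proteins excluded upstream for lacking positive
#'   intensity in both conditions.
#' @param run_id MS run label.
#' @return A `ConditionPair` data frame.
#' @export
condition_pair <- function(protein_id, intensity_a, intensity_b,
                           conditions = c("condition_1", "condition_2"),
                           n_dropped = 0L, run_id = NA_character_) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id)) {
    stop("duplicate protein identifier(s) in condition pair")
  }
  if (length(intensity_a) != length(protein_id) ||
      length(intensity_b) != length(protein_id)) {
    stop("intensity vectors must match the number of proteins")
  }
  if (any(!is.finite(intensity_a)) || any(!is.finite(intensity_b)) ||
      any(intensity_a <= 0) || any(intensity_b <= 0)) {
    stop("condition intensities must be finite and strictly positive")
  }
  structure(
    data.frame(protein_id = protein_id,
               intensity_a = as.numeric(intensity_a),
               intensity_b = as.numeric(intensity_b),
               stringsAsFactors = FALSE),
    conditions = conditions, n_dropped = as.integer(n_dropped),
    run_id = run_id,
    class = c("ConditionPair", "data.frame"))
}

#' @export
print.ConditionPair <- function(x, ...) {
  conds <- attr(x, "conditions")
  cat(sprintf("ConditionPair: %d proteins, %s vs %s (run %s)\n",
              nrow(x), conds[1], conds[2], attr(x, "run_id")))
  cat(sprintf("  dropped for zero intensity in either condition: %d\n",
              attr(x, "n_dropped")))
  invisible(x)
}

result_columns <- list(
  ComparisonResult  = c("protein_id", "A", "M", "sigma2", "Z", "P", "P_adj"),
  IntegrationResult = c("protein_id", "k", "best_P", "second_best_P",
                        "avg_Z", "avg_Z_P", "avg_Z_P_adj",
                        "fdr_second_best", "fdr_avg_z")
)

#' Write a result table
#'
#' Serializes a per-run `ComparisonResult` or a multi-run
#' `IntegrationResult` as a TSV with a fixed column order and full numeric
#' precision (17 significant digits), so that a write/read round trip
#' reproduces every value exactly.
#'
#' @param result A `ComparisonResult` or `IntegrationResult`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_results()]
#' @export
write_results <- function(result, path) {
  kind <- intersect(class(result), names(result_columns))
  if (length(kind) != 1L) {
    stop("'result' must be a ComparisonResult or an IntegrationResult")
  }
  cols <- intersect(result_columns[[kind]], names(result))
  out <- result[, cols, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open output path: ", path, " (", conditionMessage(e), ")")
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a result table written by write_results
#'
#' @param path Path to a TSV produced by [write_results()].
#' @return A `ComparisonResult` or `IntegrationResult` data frame, inferred
#'   from the header.
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = NA, check.names = FALSE,
                          stringsAsFactors = FALSE)
  df$protein_id <- as.character(df$protein_id)
  kind <- if (all(result_columns$ComparisonResult %in% names(df))) {
    "ComparisonResult"
  } else if (all(setdiff(result_columns$IntegrationResult,
                         c("fdr_second_best", "fdr_avg_z")) %in% names(df))) {
    "IntegrationResult"
  } else {
    stop("unrecognized result table header in ", path)
  }
  structure(df, class = c(kind, "data.frame"))
}
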