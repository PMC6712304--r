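# Feature tables: the common carrier for microbial (OTU / BGC-family counts)
# and molecular (LC-MS feature intensity) matrices.

#' Construct a feature table
#'
#' A feature table is the abundance matrix shared by both sides of the
#' pipeline: rows are features (OTUs, BGC families, or LC-MS molecular
#' features), columns are samples.  Microbial tables hold counts, molecular
#' tables hold intensities; molecular tables additionally carry a
#' mass-to-charge value (m/z, in Thomson) per feature.
#'
#' Missing values (`NA`) are treated as 0 (absent): upstream feature
#' extractors emit blanks and zeros interchangeably for undetected features.
#'
#' @param values Numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids).  All values must be >= 0.
#' @param kind `"microbial"` or `"molecular"`.
#' @param mz Numeric vector of m/z values, one per feature (molecular tables
#'   only; required for them).  Must be finite and > 0.
#' @param rt Optional numeric retention times, one per feature.
#' @param taxonomy Optional character vector of taxonomy strings
#'   (`k__...;p__...`), one per feature (microbial tables).
#' @param annotation Optional character vector of annotations per feature.
#' @return An object of class `feature_table`.
#' @export
#' @examples
#' m <- matrix(c(0, 5, 2, 0), 2, 2,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' feature_table(m, kind = "microbial")
feature_table <- function(values, kind = c("microbial", "molecular"),
                          mz = NULL, rt = NULL, taxonomy = NULL,
                          annotation = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("`values` must have rownames (feature ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    abort("duplicate feature ids: ",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    abort("duplicate sample ids: ",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  values[is.na(values)] <- 0
  if (any(values < 0))
    abort("abundances must be non-negative")
  nfeat <- nrow(values)
  check_len <- function(x, nm) {
    if (!is.null(x) && length(x) != nfeat)
      abort("`", nm, "` must have one entry per feature")
    x
  }
  mz <- check_len(mz, "mz")
  rt <- check_len(rt, "rt")
  taxonomy <- check_len(taxonomy, "taxonomy")
  annotation <- check_len(annotation, "annotation")
  if (kind == "molecular") {
    if (is.null(mz)) abort("molecular feature tables require `mz`")
    if (any(!is.finite(mz) | mz <= 0))
      abort("every molecular feature needs a finite m/z > 0")
    mz <- stats::setNames(as.numeric(mz), rownames(values))
  } else if (!is.null(mz)) {
    mz <- stats::setNames(as.numeric(mz), rownames(values))
  }
  structure(list(values = values, kind = kind, mz = mz, rt = rt,
                 taxonomy = taxonomy, annotation = annotation),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$mz))
    cat(sprintf("  m/z range: %.4f - %.4f\n", min(x$mz), max(x$mz)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample identifiers
#' @param x A `feature_table` or `binary_features` object.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) UseMethod("feature_ids")

#' @export
feature_ids.feature_table <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.feature_table <- function(x) colnames(x$values)

# dialect-specific metadata columns recognized on read
.meta_cols <- c("mz", "rt", "taxonomy", "annotation")

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature table from TSV/CSV
#'
#' Expects one header row of sample ids, a leading feature-id column, and
#' optionally the metadata columns `mz`, `rt` (molecular dialect) and
#' `taxonomy`, `annotation` (OTU-table dialect).  All remaining columns are
#' sample abundances.  Empty cells and `NA` are read as 0; any other
#' non-numeric cell is an error naming the offending row and column.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param kind `"microbial"` or `"molecular"`.  Molecular tables must carry
#'   an `mz` column.
#' @return A [feature_table].
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, kind = c("microbial", "molecular")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort("file not found: ", path)
  sep <- .sep_for(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort("table needs a feature-id column and >= 1 sample")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    abort("duplicate feature ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- raw[, -1, drop = FALSE]
  meta_here <- intersect(.meta_cols, colnames(body))
  sample_cols <- setdiff(colnames(body), meta_here)
  if (anyDuplicated(sample_cols))
    abort("duplicate sample ids: ",
          paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", "))
  num_meta <- intersect(meta_here, c("mz", "rt"))
  parse_num <- function(col, nm) {
    col[col == "" | toupper(col) == "NA"] <- NA_character_
    out <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(out))
    if (length(bad))
      abort(sprintf("non-numeric value '%s' at feature '%s', column '%s'",
                    col[bad[1]], ids[bad[1]], nm))
    out
  }
  values <- vapply(sample_cols, function(nm) {
    v <- parse_num(body[[nm]], nm)
    v[is.na(v)] <- 0
    v
  }, numeric(length(ids)))
  values <- matrix(values, nrow = length(ids),
                   dimnames = list(ids, sample_cols))
  get_meta <- function(nm, numeric = FALSE) {
    if (!nm %in% meta_here) return(NULL)
    if (numeric) parse_num(body[[nm]], nm) else body[[nm]]
  }
  if (kind == "molecular" && !"mz" %in% meta_here)
    abort("molecular table lacks an `mz` column: ", path)
  feature_table(values, kind = kind,
                mz = get_meta("mz", numeric = TRUE),
                rt = get_meta("rt", numeric = TRUE),
                taxonomy = get_meta("taxonomy"),
                annotation = get_meta("annotation"))
}

#' Write a feature table to TSV/CSV
#'
#' Writes back the dialect read by [read_feature_table()]: feature-id column,
#' any metadata columns present, then the sample columns.
#'
#' @param x A [feature_table].
#' @param path Output path; `.csv` selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  df <- data.frame(feature_id = rownames(x$values),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in .meta_cols) if (!is.null(x[[nm]])) df[[nm]] <- unname(x[[nm]])
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict paired tables to their shared samples
#'
#' The association test assumes paired data over one sample universe.  Real
#' exports often disagree; this keeps the intersection of the two tables'
#' sample ids (in the microbial table's order) and warns about anything
#' dropped.
#'
#' @param microbes,molecules `feature_table` objects.
#' @return List with elements `microbes` and `molecules`, both restricted to
#'   the shared samples.
#' @export
harmonize_samples <- function(microbes, molecules) {
  stopifnot(inherits(microbes, "feature_table"),
            inherits(molecules, "feature_table"))
  shared <- intersect(sample_ids(microbes), sample_ids(molecules))
  if (length(shared) == 0L) abort("the two tables share no samples")
  dropped <- c(setdiff(sample_ids(microbes), shared),
               setdiff(sample_ids(molecules), shared))
  if (length(dropped))
    warning(length(dropped), " unpaired sample(s) dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "", call. = FALSE)
  sub <- function(tb) {
    tb$values <- tb$values[, shared, drop = FALSE]
    tb
  }
  list(microbes = sub(microbes), molecules = sub(molecules))
}
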