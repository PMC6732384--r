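#' Read a fossil occurrence table
#'
#' Reads a delimited text file of genus-level fossil occurrences, one row per
#' occurrence, in the shape of a Paleobiology Database download: a genus name,
#' a collection identifier and an age range in Ma. Genus names are normalized
#' (whitespace trimmed and collapsed, subgenus qualifiers in parentheses
#' stripped, e.g. `"Olenus (Olenus)"` becomes `"Olenus"`); matching thereafter
#' is case-sensitive. Rows with unparseable or inverted age ranges, or empty
#' genus names, are rejected (not fatal) and returned in the `rejected`
#' attribute with a reason.
#'
#' @param path path to a CSV or TSV file with a header row.
#' @param column_map named character vector mapping the roles `genus`,
#'   `collection`, `older`, `younger` to column names in the file.
#' @return An `occurrence_table` data frame with columns `genus`,
#'   `collection`, `older`, `younger` (ages in Ma, `older >= younger`).
#'   Attribute `rejected` holds a data frame of dropped rows (`row`,
#'   `reason`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("genus,collection_no,max_ma,min_ma",
#'              "Olenus (Olenus),1,514,513",
#'              "Asaphus,2,513.5,512.8"), f)
#' occ <- read_occurrence_table(f)
#' occ$genus
#' @export
read_occurrence_table <- function(path,
                                  column_map = c(genus = "genus",
                                                 collection = "collection_no",
                                                 older = "max_ma",
                                                 younger = "min_ma")) {
  needed <- c("genus", "collection", "older", "younger")
  if (!all(needed %in% names(column_map)))
    stop("column_map must name columns for: ",
         paste(needed, collapse = ", "), call. = FALSE)
  df <- read_delimited(path)
  missing_cols <- setdiff(unname(column_map[needed]), names(df))
  if (length(missing_cols))
    stop("mapped column(s) not present in file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  occurrence_table(
    genus = df[[column_map[["genus"]]]],
    collection = df[[column_map[["collection"]]]],
    older = df[[column_map[["older"]]]],
    younger = df[[column_map[["younger"]]]]
  )
}

#' Build an occurrence table from vectors
#'
#' Applies the same genus-name normalization and row screening as
#' [read_occurrence_table()].
#'
#' @param genus character vector of genus names.
#' @param collection vector of collection identifiers.
#' @param older,younger numeric age-range endpoints in Ma.
#' @return An `occurrence_table`; see [read_occurrence_table()].
#' @export
occurrence_table <- function(genus, collection, older, younger) {
  n <- length(genus)
  stopifnot(length(collection) == n, length(older) == n, length(younger) == n)
  genus <- normalize_genus(as.character(genus))
  older <- suppressWarnings(as.numeric(older))
  younger <- suppressWarnings(as.numeric(younger))

  reason <- rep(NA_character_, n)
  bad_age <- !is.finite(older) | !is.finite(younger)
  reason[bad_age] <- "unparseable age"
  inv <- !bad_age & (younger > older)
  reason[inv] <- "age_younger > age_older"
  neg <- !bad_age & !inv & (younger < 0)
  reason[neg] <- "negative age"
  blank <- is.na(reason) & (is.na(genus) | genus == "")
  reason[blank] <- "empty genus name"

  keep <- is.na(reason)
  out <- data.frame(genus = genus[keep],
                    collection = as.character(collection)[keep],
                    older = older[keep], younger = younger[keep],
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- data.frame(row = which(!keep),
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Normalize genus names
#'
#' Trims and collapses whitespace and strips parenthesised subgenus
#' qualifiers: `"Olenus  (Olenus)"` -> `"Olenus"`.
#'
#' @param x character vector of raw genus names.
#' @return Normalized character vector.
#' @export
normalize_genus <- function(x) {
  x <- gsub("\\([^)]*\\)", " ", x)     # drop subgenus qualifiers
  x <- gsub("\\s+", " ", x)            # collapse internal whitespace
  trimws(x)
}

#' Bin occurrences into time intervals and build the incidence matrix
#'
#' Assigns each occurrence to a time bin and collapses occurrences to
#' genus-by-bin presence/absence: the capture histories used by the
#' capture-recapture models. Under the default `"strict"` policy an
#' occurrence is assigned to a bin only if its age range lies entirely inside
#' that bin; occurrences spanning bin boundaries are dropped (and counted in
#' the `dropped` attribute). Under `"majority"` an occurrence is assigned to
#' the bin holding the largest fraction of its age range, provided that
#' fraction exceeds 0.5. Genera with no assigned occurrence are excluded.
#'
#' @param table an `occurrence_table` (see [read_occurrence_table()]).
#' @param scheme a [time_bins] scheme.
#' @param policy `"strict"` (default) or `"majority"`.
#' @return An `incidence_matrix`: list with elements `matrix` (integer 0/1,
#'   genera in rows sorted by name, bins in columns oldest first) and `bins`
#'   (the scheme). Attribute `dropped` counts unassigned occurrences.
#' @export
bin_occurrences <- function(table, scheme, policy = c("strict", "majority")) {
  policy <- match.arg(policy)
  stopifnot(inherits(scheme, "time_bins"))
  if (!nrow(table)) stop("no binnable occurrences: empty table", call. = FALSE)
  K <- nrow(scheme)
  assigned <- rep(NA_integer_, nrow(table))
  if (policy == "strict") {
    for (j in seq_len(K)) {
      inside <- table$older <= scheme$older[j] + 1e-9 &
        table$younger >= scheme$younger[j] - 1e-9
      assigned[inside & is.na(assigned)] <- j
    }
  } else {
    span <- pmax(table$older - table$younger, 1e-12)
    best_frac <- rep(0, nrow(table))
    for (j in seq_len(K)) {
      ov <- pmin(table$older, scheme$older[j]) -
        pmax(table$younger, scheme$younger[j])
      # point ages (zero span) inside the bin count as full overlap
      frac <- ifelse(table$older == table$younger,
                     as.numeric(table$older <= scheme$older[j] &
                                  table$younger >= scheme$younger[j]),
                     pmax(ov, 0) / span)
      upd <- frac > best_frac
      assigned[upd] <- j
      best_frac[upd] <- frac[upd]
    }
    assigned[best_frac <= 0.5] <- NA_integer_
  }
  ok <- !is.na(assigned)
  if (!any(ok))
    stop("no binnable occurrences under policy '", policy, "'", call. = FALSE)
  genera <- sort(unique(table$genus[ok]))
  M <- matrix(0L, nrow = length(genera), ncol = K,
              dimnames = list(genera, scheme$name))
  M[cbind(match(table$genus[ok], genera), assigned[ok])] <- 1L
  out <- incidence_matrix(M, scheme)
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Construct an incidence matrix object
#'
#' @param mat integer 0/1 matrix, genera in rows (rownames required), bins in
#'   columns oldest first.
#' @param scheme the [time_bins] scheme the columns refer to.
#' @return An `incidence_matrix` object.
#' @export
incidence_matrix <- function(mat, scheme) {
  stopifnot(inherits(scheme, "time_bins"))
  mat <- as.matrix(mat)
  if (ncol(mat) != nrow(scheme))
    stop("matrix has ", ncol(mat), " columns but scheme has ", nrow(scheme),
         " bins", call. = FALSE)
  if (is.null(rownames(mat))) stop("matrix must carry genus rownames", call. = FALSE)
  storage.mode(mat) <- "integer"
  if (any(!(mat %in% c(0L, 1L)))) stop("cells must be 0/1", call. = FALSE)
  if (any(rowSums(mat) < 1L))
    stop("every genus row must have at least one presence", call. = FALSE)
  colnames(mat) <- scheme$name
  structure(list(matrix = mat, bins = scheme), class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Incidence matrix: %d genera x %d bins; observed richness %d-%d per bin\n",
              nrow(x$matrix), ncol(x$matrix),
              min(colSums(x$matrix)), max(colSums(x$matrix))))
  invisible(x)
}

#' Per-bin observed richness
#'
#' @param x an `incidence_matrix`.
#' @return Integer vector: number of genera sampled in each bin, oldest first.
#' @export
observed_richness <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  colSums(x$matrix)
}

#' Reverse an incidence matrix in time
#'
#' @param x an `incidence_matrix`.
#' @return The matrix with bin order reversed, on the mirrored bin scheme.
#' @keywords internal
#' @export
reverse_incidence <- function(x) {
  stopifnot(inherits(x, "incidence_matrix"))
  incidence_matrix(x$matrix[, rev(seq_len(ncol(x$matrix))), drop = FALSE],
                   reverse_bins(x$bins))
}

#' Write / read an incidence matrix as wide CSV
#'
#' The CSV holds one genus per row and one 0/1 column per bin, oldest first;
#' bin boundaries are embedded in the header as `name|older|younger` so the
#' scheme round-trips with the matrix.
#'
#' @param x an `incidence_matrix`.
#' @param path output (input) CSV path.
#' @return `write_incidence` returns `path` invisibly; `read_incidence`
#'   returns the reconstructed `incidence_matrix`.
#' @export
write_incidence <- function(x, path) {
  stopifnot(inherits(x, "incidence_matrix"))
  hdr <- sprintf("%s|%.10g|%.10g", x$bins$name, x$bins$older, x$bins$younger)
  df <- data.frame(genus = rownames(x$matrix), x$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("genus", hdr)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  parts <- strsplit(names(df)[-1L], "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) stop("malformed incidence header", call. = FALSE)
  scheme <- time_bins(vapply(parts, `[`, "", 1L),
                      older = as.numeric(vapply(parts, `[`, "", 2L)),
                      younger = as.numeric(vapply(parts, `[`, "", 3L)))
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df$genus
  colnames(M) <- scheme$name
  incidence_matrix(M, scheme)
}
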