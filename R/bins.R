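#' Construct a stratigraphic time-bin scheme
#'
#' A time-bin scheme is an ordered set of stratigraphic intervals with
#' boundaries in Ma (megaannum before present). Bins are stored oldest first;
#' "forward in time" means decreasing Ma. Bins may leave gaps but must not
#' overlap.
#'
#' @param name character vector of bin names.
#' @param older numeric vector, older (lower) boundary of each bin in Ma.
#' @param younger numeric vector, younger (upper) boundary of each bin in Ma.
#' @return A `time_bins` data frame with columns `bin` (1-based index, oldest
#'   = 1), `name`, `older`, `younger`, `duration` (Myr) and `midpoint` (Ma),
#'   sorted from oldest to youngest.
#' @examples
#' time_bins(c("A", "B", "C"), older = c(520, 515, 512), younger = c(515, 512, 510))
#' @export
time_bins <- function(name, older, younger) {
  if (length(name) != length(older) || length(older) != length(younger))
    stop("name, older and younger must have equal length", call. = FALSE)
  if (length(name) < 1L) stop("at least one bin is required", call. = FALSE)
  older <- as.numeric(older)
  younger <- as.numeric(younger)
  if (any(!is.finite(older)) || any(!is.finite(younger)))
    stop("bin boundaries must be finite numbers", call. = FALSE)
  if (any(older <= younger))
    stop("every bin must satisfy older > younger (ages in Ma)", call. = FALSE)
  ord <- order(older, decreasing = TRUE)
  name <- as.character(name)[ord]
  older <- older[ord]
  younger <- younger[ord]
  # overlap check on the age axis: the next (younger) bin must not reach into
  # the previous one
  if (length(older) > 1L) {
    over <- older[-1L] > younger[-length(younger)] + 1e-9
    if (any(over))
      stop("time bins overlap: ", paste(name[-1L][over], collapse = ", "),
           call. = FALSE)
  }
  out <- data.frame(
    bin = seq_along(name),
    name = name,
    older = older,
    younger = younger,
    duration = older - younger,
    midpoint = (older + younger) / 2,
    stringsAsFactors = FALSE
  )
  class(out) <- c("time_bins", "data.frame")
  out
}

#' Read a time-bin scheme from a delimited text file
#'
#' Expects a header with bin name and older/younger boundary columns. Column
#' names are matched case-insensitively against a small set of synonyms
#' (`name`/`bin_name`/`interval`; `older`/`max_ma`/`bottom`;
#' `younger`/`min_ma`/`top`). Delimiter is inferred from the file extension
#' (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @param path path to a CSV or TSV file.
#' @return A [time_bins] scheme.
#' @export
read_bin_scheme <- function(path) {
  df <- read_delimited(path)
  nm <- tolower(names(df))
  pick <- function(cands, what) {
    hit <- which(nm %in% cands)
    if (length(hit) == 0L)
      stop("bin-scheme file lacks a ", what, " column (looked for: ",
           paste(cands, collapse = ", "), ")", call. = FALSE)
    df[[hit[1L]]]
  }
  time_bins(
    name = pick(c("name", "bin_name", "interval", "bin"), "name"),
    older = pick(c("older", "max_ma", "bottom", "b_age"), "older boundary"),
    younger = pick(c("younger", "min_ma", "top", "t_age"), "younger boundary")
  )
}

#' @export
print.time_bins <- function(x, ...) {
  cat(sprintf("Time-bin scheme: %d bins, %.1f-%.1f Ma (mean duration %.2f Myr)\n",
              nrow(x), max(x$older), min(x$younger), mean(x$duration)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Reverse a time-bin scheme
#'
#' Utility used by time-reversal symmetry checks: maps the scheme onto a
#' mirrored age axis so that the youngest bin becomes the oldest.
#'
#' @param scheme a [time_bins] scheme.
#' @return The mirrored `time_bins` scheme.
#' @keywords internal
#' @export
reverse_bins <- function(scheme) {
  stopifnot(inherits(scheme, "time_bins"))
  ref <- max(scheme$older) + min(scheme$younger)
  time_bins(rev(scheme$name), older = ref - rev(scheme$younger),
            younger = ref - rev(scheme$older))
}

# shared delimited-text reader: delimiter by extension
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}
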