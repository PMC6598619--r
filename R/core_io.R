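#' Construct an ROI time-series object
#'
#' Container for one scan's T x R matrix of region-of-interest (ROI) BOLD
#' signals together with the metadata the downstream models need: subject,
#' scan index within condition, condition label and repetition time.
#'
#' @param values numeric matrix, rows = time points (TRs), columns = regions.
#' @param region_ids character vector of unique region labels, one per column.
#' @param subject_id subject identifier (coerced to character).
#' @param scan_index integer scan number within condition (1-based).
#' @param condition condition label, e.g. `"B"` (reference) or `"G"`.
#' @param tr_seconds positive repetition time in seconds. Carried as metadata
#'   only; all computation is in TR units.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, region_ids, subject_id, scan_index,
                           condition, tr_seconds = 2.25) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("time series must have at least 2 rows")
  if (ncol(values) < 2L)
    stop("at least 2 regions are required (R >= 2)")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d (region '%s')",
                 bad[1L], bad[2L], region_ids[bad[2L]]))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != ncol(values))
    stop("length(region_ids) must equal ncol(values)")
  if (anyDuplicated(region_ids))
    stop("region_ids must be unique")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("tr_seconds must be a positive number")
  colnames(values) <- region_ids
  structure(
    list(values = values, region_ids = region_ids,
         subject_id = as.character(subject_id),
         scan_index = as.integer(scan_index),
         condition = as.character(condition),
         tr_seconds = as.numeric(tr_seconds)),
    class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s, scan %d, condition %s: %d TRs x %d regions (TR = %g s)\n",
              x$subject_id, x$scan_index, x$condition,
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Read one ROI time-series file
#'
#' Reads a delimited text file (TSV or CSV, sniffed from the extension or the
#' first line) whose header row holds region ids and whose body is the T x R
#' numeric signal matrix.  The reader fails rather than imputes: any missing
#' or non-numeric cell is an error naming its location.
#'
#' @param path path to the delimited file.
#' @param subject_id,scan_index,condition,tr_seconds metadata for the scan,
#'   typically one record of a study manifest.
#' @param region_ids optional expected region ids; a header mismatch is a
#'   consistency error.
#' @return A [roi_timeseries()] object with `T` = number of data rows.
#' @export
read_timeseries <- function(path, subject_id, scan_index, condition,
                            tr_seconds = 2.25, region_ids = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "numeric",
                           comment.char = "")
  hdr <- colnames(dat)
  if (!is.null(region_ids) && !identical(hdr, as.character(region_ids)))
    stop(sprintf("region header of '%s' does not match the manifest (got: %s)",
                 path, paste(hdr, collapse = ", ")))
  m <- as.matrix(dat)
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric value in '%s' at data row %d, column '%s'",
                 path, bad[1L], hdr[bad[2L]]))
  }
  roi_timeseries(m, hdr, subject_id, scan_index, condition, tr_seconds)
}

#' Write an ROI time-series object to TSV
#'
#' @param ts a [roi_timeseries()] object.
#' @param path output path; the header row holds the region ids.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and validate a study manifest
#'
#' The manifest is a TSV with columns `subject_id`, `scan_index`,
#' `condition`, `path` listing every scan of the study.  Validation enforces
#' the study contract: unique (subject, condition, scan) triples, exactly two
#' condition labels, and — when `check_files` — existing files that all share
#' one region header and one number of time points.
#'
#' @param path path to the manifest TSV.
#' @param check_files verify the referenced files (existence, shared header
#'   and length). Default `TRUE`.
#' @return A data frame of manifest records with attribute `region_ids`
#'   (shared header) and `n_time` when `check_files` was used.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  need <- c("subject_id", "scan_index", "condition", "path")
  if (!all(need %in% colnames(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  man$subject_id <- as.character(man$subject_id)
  man$scan_index <- as.integer(man$scan_index)
  man$condition <- as.character(man$condition)
  key <- paste(man$subject_id, man$condition, man$scan_index)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, condition, scan_index) triple: ",
         key[duplicated(key)][1L])
  if (length(unique(man$condition)) != 2L)
    stop("exactly two condition labels are required, got: ",
         paste(unique(man$condition), collapse = ", "))
  if (check_files) {
    base <- dirname(path)
    man$path <- ifelse(file.exists(man$path), man$path,
                       file.path(base, man$path))
    missing <- !file.exists(man$path)
    if (any(missing))
      stop("manifest references missing file(s): ",
           paste(utils::head(man$path[missing], 3L), collapse = ", "))
    hdr <- NULL; nt <- NULL
    for (f in man$path) {
      sep <- if (grepl("\\.csv$", f, ignore.case = TRUE)) "," else "\t"
      h <- strsplit(readLines(f, n = 1L), sep, fixed = TRUE)[[1L]]
      n <- length(readLines(f)) - 1L
      if (is.null(hdr)) { hdr <- h; nt <- n }
      else if (!identical(h, hdr))
        stop(sprintf("region header of '%s' differs from the first file", f))
      else if (n != nt)
        stop(sprintf("'%s' has %d time points, expected %d", f, n, nt))
    }
    attr(man, "region_ids") <- hdr
    attr(man, "n_time") <- nt
  }
  man
}

#' Enumerate unordered region pairs
#'
#' All n(n+1)/2 - n = n(n-1)/2 unordered pairs of distinct regions, in the
#' deterministic lexicographic order of the column indices (the manifest
#' header order is canonical).
#'
#' @param region_ids character vector of n >= 2 unique region labels.
#' @return Data frame with columns `region_a`, `region_b`; `region_a` always
#'   precedes `region_b` in `region_ids` order.
#' @export
#' @examples
#' nrow(enumerate_pairs(paste0("r", 1:10)))  # 45
enumerate_pairs <- function(region_ids) {
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  if (n < 2L) stop("need at least 2 regions")
  if (anyDuplicated(region_ids))
    stop("duplicate region labels: ",
         region_ids[duplicated(region_ids)][1L])
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(region_a = region_ids[idx[, 1L]],
             region_b = region_ids[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Drop flagged regions, preserving order
#'
#' Region bookkeeping for parcellations where some parcels are excluded
#' (e.g. cerebellar parcels without full acquisition coverage): removes the
#' `discard` labels from `region_ids` and keeps the original order.
#'
#' @param region_ids full label list.
#' @param discard labels to drop; every one must be present in `region_ids`.
#' @return The retained labels, in original order.
#' @export
filter_regions <- function(region_ids, discard) {
  region_ids <- as.character(region_ids)
  discard <- as.character(discard)
  unknown <- setdiff(discard, region_ids)
  if (length(unknown))
    stop("discard label(s) not present: ", paste(unknown, collapse = ", "))
  region_ids[!region_ids %in% discard]
}

#' Read a region-to-network map
#'
#' TSV with columns `region_id` and `network`, assigning each region to one
#' resting-state network (or other grouping) used for block summaries.
#'
#' @param path path to the TSV.
#' @return Named character vector: names are region ids, values networks.
#' @export
read_network_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("region_id", "network") %in% colnames(d)))
    stop("network map must have columns region_id, network")
  if (anyDuplicated(d$region_id))
    stop("region mapped to more than one network: ",
         d$region_id[duplicated(d$region_id)][1L])
  stats::setNames(as.character(d$network), as.character(d$region_id))
}
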