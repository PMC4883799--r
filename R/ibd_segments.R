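#' Construct and validate a table of IBD segments
#'
#' An IBD segment table records shared haplotype segments between pairs of
#' individuals in genetic coordinates (cM, 0-based half-open intervals).
#'
#' @param id_a,id_b individual identifiers (unequal within a row).
#' @param chrom chromosome labels.
#' @param start,end genetic positions in cM, with \code{end > start}.
#' @param length optional segment lengths in cM; defaults to
#'   \code{end - start} and must agree with it to 1e-6 cM.
#' @return A \code{data.frame} with columns \code{id_a}, \code{id_b},
#'   \code{chrom}, \code{start}, \code{end}, \code{length}.
#' @export
ibd_segments <- function(id_a = character(), id_b = character(),
                         chrom = character(), start = numeric(),
                         end = numeric(), length = end - start) {
  df <- data.frame(id_a = as.character(id_a), id_b = as.character(id_b),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   length = as.numeric(length),
                   stringsAsFactors = FALSE)
  validate_ibd_segments(df)
}

validate_ibd_segments <- function(df) {
  need <- c("id_a", "id_b", "chrom", "start", "end", "length")
  if (!all(need %in% names(df)))
    stop("missing IBD segment columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) == 0L) return(df[, need])
  if (any(df$end <= df$start)) stop("IBD segments must have end > start")
  if (any(abs(df$length - (df$end - df$start)) > 1e-6))
    stop("segment length disagrees with end - start beyond 1e-6 cM")
  if (any(df$id_a == df$id_b)) stop("self-IBD rows (id_a == id_b) not allowed")
  df[, need]
}

#' Read IBD segments from disk
#'
#' Two dialects are supported. \code{"canonical"} is a header-bearing TSV with
#' columns \code{id_a, id_b, chrom, start_cM, end_cM, length_cM}.
#' \code{"germline-match"} is the whitespace-delimited GERMLINE \code{.match}
#' output; the pair identifiers (family+individual), chromosome, genetic
#' length and unit columns are used, rows whose unit is not \code{cM} are
#' rejected, and genetic start positions are approximated from the physical
#' coordinates at \code{cm_per_mb} (default 1 cM/Mb).
#'
#' @param path file path.
#' @param dialect \code{"canonical"} or \code{"germline-match"}.
#' @param min_length minimum segment length kept, cM (detection floor of the
#'   upstream IBD caller; 3 cM by default).
#' @param cm_per_mb physical-to-genetic scale used only for the
#'   germline-match dialect.
#' @return An IBD segment table (see [ibd_segments()]).
#' @export
read_ibd_segments <- function(path, dialect = c("canonical", "germline-match"),
                              min_length = 3, cm_per_mb = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "canonical") {
    if (length(lines) == 0L) stop("canonical IBD file must have a header row")
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    need <- c("id_a", "id_b", "chrom", "start_cM", "end_cM", "length_cM")
    if (!identical(header[seq_along(need)], need))
      stop("malformed header in ", path)
    body <- lines[-1L]
    body <- body[nzchar(body)]
    rows <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(rows, length, 1L) != length(need))
    if (length(bad))
      stop("malformed line ", bad[1L] + 1L, " in ", path)
    if (length(rows) == 0L) return(ibd_segments())
    m <- do.call(rbind, rows)
    num <- suppressWarnings(apply(m[, 4:6, drop = FALSE], 2L, as.numeric))
    num <- matrix(num, ncol = 3L)
    if (anyNA(num))
      stop("malformed line ", which(rowSums(is.na(num)) > 0)[1L] + 1L,
           " in ", path, ": non-numeric coordinate")
    df <- ibd_segments(m[, 1L], m[, 2L], m[, 3L],
                       num[, 1L], num[, 2L], num[, 3L])
  } else {
    body <- lines[nzchar(lines)]
    if (length(body) == 0L) return(ibd_segments())
    rows <- strsplit(trimws(body), "[ \t]+")
    bad <- which(vapply(rows, length, 1L) < 12L)
    if (length(bad))
      stop("malformed line ", bad[1L], " in ", path,
           ": expected >= 12 whitespace-delimited fields")
    m <- do.call(rbind, rows)
    unit <- m[, 12L]
    if (any(unit != "cM"))
      stop("malformed line ", which(unit != "cM")[1L], " in ", path,
           ": genetic length unit must be cM")
    len <- suppressWarnings(as.numeric(m[, 11L]))
    bp <- suppressWarnings(as.numeric(m[, 6L]))
    if (anyNA(len) || anyNA(bp))
      stop("malformed line ", which(is.na(len) | is.na(bp))[1L], " in ", path,
           ": non-numeric coordinate")
    start <- bp / 1e6 * cm_per_mb
    df <- ibd_segments(paste(m[, 1L], m[, 2L], sep = ":"),
                       paste(m[, 3L], m[, 4L], sep = ":"),
                       m[, 5L], start, start + len, len)
  }
  df[df$length >= min_length, , drop = FALSE]
}

#' Write IBD segments in the canonical TSV dialect
#'
#' @param segments an IBD segment table.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ibd_segments <- function(segments, path) {
  segments <- validate_ibd_segments(segments)
  out <- data.frame(id_a = segments$id_a, id_b = segments$id_b,
                    chrom = segments$chrom, start_cM = segments$start,
                    end_cM = segments$end, length_cM = segments$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
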