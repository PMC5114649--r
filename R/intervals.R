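#' Construct a table of genomic intervals
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval `[start, end)` covers bases `start .. end - 1`. One-based
#' single-base positions (e.g. methylation probe coordinates) are converted
#' on read by the corresponding readers.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, 0-based exclusive end (`end > start`).
#' @param strand Strand per interval, one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- length(chrom)
  strand <- rep_len(strand, n)
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

#' Validate an interval table's invariants
#'
#' Checks 0-based half-open coordinates (`start >= 0`, `end > start`) and
#' the strand alphabet; returns the table invisibly.
#'
#' @param iv Interval table.
#' @export
validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv),
            all(c("chrom", "start", "end") %in% names(iv)))
  if (any(iv$start < 0)) stop("interval start must be >= 0")
  if (any(iv$end <= iv$start)) stop("interval end must be > start")
  if (!is.null(iv$strand) && !all(iv$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(iv)
}

#' Merge overlapping intervals, optionally after symmetric padding
#'
#' @param iv Interval table as from [genomic_intervals()].
#' @param pad Bases added on both sides before merging (clipped at 0).
#' @return Merged interval table (strand dropped, set to `"."`).
#' @export
merge_intervals <- function(iv, pad = 0L) {
  validate_intervals(iv)
  out <- lapply(split(iv, iv$chrom), function(d) {
    r <- IRanges::IRanges(start = pmax(0L, d$start - pad) + 1L,
                          end = d$end + pad)  # to 1-based closed for IRanges
    r <- IRanges::reduce(r)
    data.frame(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Point-to-interval distance and window overlap
#'
#' Distance is 0 when the point lies inside `[start, end)`; otherwise the
#' distance to the nearest covered base. `points_near_intervals` reports, for
#' each point, whether any interval on the same chromosome lies within
#' `window` bases (boundary inclusive).
#'
#' @param point_chrom,point_pos Point coordinates (0-based base position).
#' @param iv Interval table.
#' @param window Maximum distance in bp, inclusive.
#' @return Logical vector, one element per point.
#' @export
points_near_intervals <- function(point_chrom, point_pos, iv, window = 0L) {
  validate_intervals(iv)
  out <- logical(length(point_pos))
  for (ch in unique(point_chrom)) {
    sel <- point_chrom == ch
    d <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0L) next
    p <- point_pos[sel]
    hit <- vapply(p, function(x) {
      any(x >= d$start - window & x <= d$end - 1L + window)
    }, logical(1))
    out[sel] <- hit
  }
  out
}

#' Strand-aware 5' position of TSS records
#'
#' For `+`/`.` strand the 5' end is `start`; for `-` strand it is `end - 1`.
#'
#' @param tss A TSS table with `start`, `end`, `strand` columns.
#' @return Integer vector of 0-based 5' positions.
#' @export
tss_positions <- function(tss) {
  ifelse(tss$strand == "-", tss$end - 1L, tss$start)
}
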