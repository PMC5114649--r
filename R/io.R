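#' Evaluate an expression with a locally fixed RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not perturb the
#' caller's random stream. Every stochastic operation in the package takes an
#' explicit `seed` and routes through this helper.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read a BED file of peaks or intervals
#'
#' Accepts 3+ tab-separated columns; `track`/`browser`/`#` lines are skipped.
#' Coordinates keep BED semantics (0-based, half-open). Column 4 is taken as
#' a name and column 6 as the strand when present.
#'
#' @param path Path to a BED file.
#' @return Interval `data.frame` with columns `chrom`, `start`, `end`,
#'   `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    return(genomic_intervals(character(), integer(), integer())[, c(1:3, 4)])
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    f <- parts[[i]]
    if (length(f) < 3L)
      stop(sprintf("BED parse error at line %d: fewer than 3 columns", idx[i]))
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("BED parse error at line %d: non-integer coordinates", idx[i]))
    if (e <= s)
      stop(sprintf("BED parse error at line %d: end <= start", idx[i]))
    out[[i]] <- data.frame(
      chrom = f[1], start = s, end = e,
      name = if (length(f) >= 4) f[4] else NA_character_,
      strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else ".",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  validate_intervals(res)
  res
}

#' Write intervals as BED
#' @param iv Interval table.
#' @param path Output path.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  nm <- if (!is.null(iv$name)) iv$name else "."
  strand <- if (!is.null(iv$strand)) iv$strand else "."
  df <- data.frame(iv$chrom, iv$start, iv$end, nm, 0L, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.tss_cols <- c("tss_id", "chrom", "start", "end", "strand",
               "nearest_gene", "par_flag", "repeat_overlap")

#' Read a TSS x sample expression table
#'
#' The expected layout is tab-delimited with a header: the TSS annotation
#' columns `tss_id`, `chrom`, `start`, `end`, `strand`, `nearest_gene`,
#' `par_flag`, `repeat_overlap`, followed by one numeric column per sample
#' (tags per million).
#'
#' @param path Path to the table.
#' @return A list with `values` (TSS x sample numeric matrix) and `tss`
#'   (annotation `data.frame`).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.tss_cols, names(df))
  if (length(missing))
    stop("expression schema error: missing annotation column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$tss_id))
    stop("expression schema error: duplicate tss_id")
  sample_ids <- setdiff(names(df), .tss_cols)
  if (length(sample_ids) == 0L)
    stop("expression schema error: no sample columns")
  vals <- as.matrix(df[, sample_ids, drop = FALSE])
  if (!is.numeric(vals)) stop("expression value error: non-numeric cells")
  if (anyNA(vals)) stop("expression value error: missing values")
  if (any(vals < 0)) stop("expression value error: negative expression")
  rownames(vals) <- df$tss_id
  tss <- df[, .tss_cols]
  tss$par_flag <- as.logical(tss$par_flag)
  tss$repeat_overlap <- as.logical(tss$repeat_overlap)
  list(values = vals, tss = tss)
}

#' Write a TSS x sample expression table
#' @param values TSS x sample matrix.
#' @param tss TSS annotation table (see [read_expression()]).
#' @param path Output path.
#' @export
write_expression <- function(values, tss, path) {
  stopifnot(nrow(values) == nrow(tss))
  df <- cbind(tss[, .tss_cols], as.data.frame(values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' Columns: `sample_id`, `sex` (male/female/unknown), `donor_id`,
#' `replicate_index`, `treated` (logical), `categories` (comma-separated
#' ontology term ids, may be empty).
#'
#' @param path Path to the table.
#' @return `data.frame` of sample records.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "donor_id", "replicate_index", "treated")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample schema error: duplicate sample_id")
  if (any(df$replicate_index < 1)) stop("sample value error: replicate_index < 1")
  df$treated <- as.logical(df$treated)
  if (is.null(df$categories)) df$categories <- ""
  df
}

#' @rdname read_samples
#' @param samples Sample table.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exclude treated samples and repeat donations
#'
#' Keeps only untreated samples and, for each donor, the first replicate,
#' so no donor contributes more than once.
#'
#' @param samples Sample table as from [read_samples()].
#' @return Filtered sample table.
#' @export
filter_samples <- function(samples) {
  s <- samples[!samples$treated, , drop = FALSE]
  s <- s[s$replicate_index == 1L, , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Read / write phased heterozygous sites
#'
#' Tab-delimited columns: `site_id`, `chrom`, `pos` (0-based), `allele_a`,
#' `allele_b`, `maternal_allele`. The paternal allele is the other member of
#' the pair.
#'
#' @param path Path to the table.
#' @return `data.frame` of het sites.
#' @export
read_het_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "pos", "allele_a", "allele_b", "maternal_allele")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("het-site schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$allele_a == df$allele_b))
    stop("het-site value error: identical alleles")
  bad <- !(df$maternal_allele == df$allele_a | df$maternal_allele == df$allele_b)
  if (any(bad))
    stop("het-site value error: maternal allele not in pair at ",
         paste(df$site_id[bad], collapse = ", "))
  df
}

#' @rdname read_het_sites
#' @param hets Het-site table.
#' @export
write_het_sites <- function(hets, path) {
  utils::write.table(hets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-site allelic count tables
#'
#' Columns: `site_id`, `dataset_id`, `factor`, `lab`, then either raw
#' per-allele counts (`allele_a_count`, `allele_b_count`) or assigned counts
#' (`Ra`, `Ri`).
#'
#' @param path Path to the table.
#' @return `data.frame` of counts.
#' @export
read_allelic_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "dataset_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("allelic-count schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  cnt <- intersect(c("allele_a_count", "allele_b_count", "Ra", "Ri"), names(df))
  if (length(cnt) == 0L) stop("allelic-count schema error: no count columns")
  if (any(as.matrix(df[, cnt]) < 0)) stop("allelic-count value error: negative counts")
  df
}

#' @rdname read_allelic_counts
#' @param counts Count table.
#' @export
write_allelic_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector, one element per contig (uppercase).
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a fixed-step wiggle depth track
#'
#' Supports `fixedStep chrom=<c> start=<s> step=1` blocks with one value per
#' line. Positions are converted to 0-based on read.
#'
#' @param path Wiggle path.
#' @return A depth track: named list per chromosome, each with `start`
#'   (0-based position of the first value) and `depth` (numeric vector).
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  track <- list()
  cur <- NULL; buf <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    prev <- track[[cur$chrom]]
    blk <- list(start = cur$start, depth = as.numeric(buf))
    if (is.null(prev)) track[[cur$chrom]] <<- blk
    else stop("read_wig: multiple blocks per chromosome not supported")
  }
  for (ln in lines) {
    if (grepl("^fixedStep", ln)) {
      flush()
      get1 <- function(key) sub(paste0(".*", key, "="), "", ln)
      chrom <- sub("\\s.*$", "", get1("chrom"))
      start <- as.integer(sub("\\s.*$", "", get1("start")))
      step <- if (grepl("step=", ln)) as.integer(sub("\\s.*$", "", get1("step"))) else 1L
      if (step != 1L) stop("read_wig: only step=1 supported")
      cur <- list(chrom = chrom, start = start - 1L)  # wiggle is 1-based
      buf <- character()
    } else if (grepl("^(track|browser|#)", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      if (is.null(cur)) stop("read_wig: data line before fixedStep header")
      buf <- c(buf, ln)
    }
  }
  flush()
  track
}

#' @rdname read_wig
#' @param track Depth track list.
#' @export
write_wig <- function(track, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (chrom in names(track)) {
    blk <- track[[chrom]]
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                       chrom, blk$start + 1L), con)
    writeLines(format(blk$depth, trim = TRUE, scientific = FALSE), con)
  }
  invisible(path)
}
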