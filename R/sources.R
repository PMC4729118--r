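# Data sources: the two backends behind one query contract. A bedfile
# source holds everything in memory; larger datasets use a sorted BED plus
# a sidecar linear index (fixed-size genomic bins -> earliest file offset
# of an overlapping record) for seek-and-scan region queries, optionally
# behind the HTTP service in server.R. All sources answer the same query,
# so the chart layer does not care which one it talks to.

#' Query a data source for records overlapping a region
#'
#' @param source A source object ([bedfile_source()], [http_source()]).
#' @param sample Sample identifier (one of [src_samples()]).
#' @param region A [genomic_region()] or region string.
#' @return Tibble of `chrom`, `start`, `end`, `value` records overlapping
#'   the region, in coordinate order.
#' @export
src_query <- function(source, sample, region) UseMethod("src_query")

#' List the sample identifiers a source can serve
#' @param source A source object.
#' @return Character vector of sample IDs.
#' @export
src_samples <- function(source) UseMethod("src_samples")

sample_id_from_path <- function(path) {
  sub("\\.bed(\\.gz)?$", "", basename(path))
}

#' In-memory BED source
#'
#' Loads one or more BED/BedGraph files fully into memory (one file per
#' sample; the sample ID is the file name without its `.bed`/`.bed.gz`
#' suffix) and answers region queries by overlap filtering. Simple and
#' exact; adequate until data outgrows memory, at which point the indexed
#' file/server path takes over.
#'
#' @param paths Character vector of BED file paths, or a directory
#'   containing `*.bed` / `*.bed.gz` files.
#' @param samples Optional sample IDs overriding the file-name default.
#' @return A `bedfile_source` object.
#' @export
bedfile_source <- function(paths, samples = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.bed(\\.gz)?$",
                             full.names = TRUE))
  }
  if (length(paths) == 0L) stop("no BED files found", call. = FALSE)
  if (is.null(samples)) samples <- vapply(paths, sample_id_from_path, "")
  stopifnot(length(samples) == length(paths), !anyDuplicated(samples))
  data <- lapply(paths, function(p) {
    dplyr::arrange(read_bed(p), .data$chrom, .data$start)
  })
  names(data) <- samples
  structure(list(data = data, paths = paths), class = "bedfile_source")
}

#' @export
src_samples.bedfile_source <- function(source) names(source$data)

#' @export
src_query.bedfile_source <- function(source, sample, region) {
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "genomic_region"))
  recs <- source$data[[sample]]
  if (is.null(recs)) stop("unknown sample: ", sample, call. = FALSE)
  dplyr::filter(recs, .data$chrom == region$chrom,
                .data$start < region$end, .data$end > region$start)
}

#' @export
print.bedfile_source <- function(x, ...) {
  cat(sprintf("<bedfile_source> %d sample(s): %s\n", length(x$data),
              paste(utils::head(names(x$data), 5), collapse = ", ")))
  invisible(x)
}

# ---- linear index ----------------------------------------------------------

INDEX_MAGIC <- "HBI1"
INDEX_VERSION <- 1L

index_path <- function(path) paste0(path, ".hbi")

write_string <- function(con, s) {
  writeBin(nchar(s, type = "bytes"), con, size = 4L, endian = "little")
  writeChar(s, con, eos = NULL)
}
read_string <- function(con) {
  n <- readBin(con, "integer", size = 4L, endian = "little")
  readChar(con, n, useBytes = TRUE)
}

# Byte offsets and parsed coordinates of every data line of an
# uncompressed BED file.
scan_bed_offsets <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) >= 2L && raw[1] == as.raw(0x1f) && raw[2] == as.raw(0x8b)) {
    stop("cannot index gzip-compressed BED files; decompress first",
         call. = FALSE)
  }
  nl <- which(raw == as.raw(0x0a))
  starts <- c(0, nl[-length(nl)])
  if (length(raw) > 0L && (length(nl) == 0L || nl[length(nl)] < length(raw))) {
    starts <- c(0, nl) # final line without trailing newline
  }
  text <- rawToChar(raw)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  stopifnot(length(lines) == length(starts) || length(lines) == 0L)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !grepl(bed_comment_re, trimmed)
  f <- strsplit(trimmed[keep], "[ \t]+")
  list(
    line_no = which(keep),
    offset = starts[keep],
    chrom = vapply(f, `[[`, "", 1L),
    start = as.numeric(vapply(f, `[[`, "", 2L)),
    end = as.numeric(vapply(f, `[[`, "", 3L))
  )
}

#' Build a linear region-query index for a sorted BED file
#'
#' Writes a sidecar `<path>.hbi` mapping fixed-size genomic bins (default
#' 16384 bp) to the smallest file offset of any record overlapping the
#' bin — a simplified tabix-style linear index. The input must be sorted by
#' (chrom, start) with each chromosome's records contiguous; unsorted input
#' is an error naming the first offending line. The sidecar records the
#' input's size and MD5 so a stale index is detected at query time.
#'
#' @param path Uncompressed BED/BedGraph file, sorted by (chrom, start).
#' @param bin_size_bp Bin width in bases (power of two; default 16384).
#' @return (Invisibly) the index as a `linear_index` object.
#' @export
build_index <- function(path, bin_size_bp = 16384L) {
  bin_size_bp <- as.integer(bin_size_bp)
  if (is.na(bin_size_bp) || bin_size_bp < 1L ||
      bitwAnd(bin_size_bp, bin_size_bp - 1L) != 0L) {
    stop("`bin_size_bp` must be a positive power of two", call. = FALSE)
  }
  sc <- scan_bed_offsets(path)

  if (length(sc$chrom) > 1L) {
    new_chrom <- sc$chrom[-1L] != sc$chrom[-length(sc$chrom)]
    seen_before <- vapply(which(new_chrom) + 1L, function(i) {
      sc$chrom[i] %in% sc$chrom[seq_len(i - 1L)]
    }, logical(1))
    if (any(seen_before)) {
      i <- (which(new_chrom) + 1L)[which(seen_before)[1L]]
      stop("input is not sorted by (chrom, start): chromosome block for '",
           sc$chrom[i], "' is not contiguous at line ", sc$line_no[i],
           "; sort the file first", call. = FALSE)
    }
    bad <- which(!new_chrom & sc$start[-1L] < sc$start[-length(sc$start)])
    if (length(bad) > 0L) {
      i <- bad[1L] + 1L
      stop("input is not sorted by (chrom, start) at line ", sc$line_no[i],
           "; sort the file first", call. = FALSE)
    }
  }

  chroms <- unique(sc$chrom)
  tables <- lapply(chroms, function(cn) {
    sel <- sc$chrom == cn
    s <- sc$start[sel]; e <- sc$end[sel]; off <- sc$offset[sel]
    if (length(s) == 0L) return(numeric(0))
    nb <- floor(max(e - 1) / bin_size_bp) + 1
    offsets <- rep(NA_real_, nb)
    for (i in seq_along(s)) {
      bins <- (floor(s[i] / bin_size_bp):floor((e[i] - 1) / bin_size_bp)) + 1
      upd <- is.na(offsets[bins]) | offsets[bins] > off[i]
      offsets[bins[upd]] <- off[i]
    }
    offsets
  })
  names(tables) <- chroms

  idx <- structure(
    list(bin_size_bp = bin_size_bp, file_size = as.numeric(file.size(path)),
         md5 = unname(tools::md5sum(path)), tables = tables),
    class = "linear_index")

  con <- file(index_path(path), "wb")
  on.exit(close(con))
  writeChar(INDEX_MAGIC, con, eos = NULL)
  writeBin(INDEX_VERSION, con, size = 4L, endian = "little")
  writeBin(bin_size_bp, con, size = 4L, endian = "little")
  writeBin(idx$file_size, con, size = 8L, endian = "little")
  write_string(con, idx$md5)
  writeBin(length(tables), con, size = 4L, endian = "little")
  for (cn in names(tables)) {
    write_string(con, cn)
    writeBin(length(tables[[cn]]), con, size = 4L, endian = "little")
    off <- tables[[cn]]
    off[is.na(off)] <- -1
    writeBin(off, con, size = 8L, endian = "little")
  }
  invisible(idx)
}

#' Read a sidecar linear index
#'
#' @param path The BED file path (the index is `<path>.hbi`) or the `.hbi`
#'   path itself.
#' @return A `linear_index` object.
#' @export
read_index <- function(path) {
  ip <- if (grepl("\\.hbi$", path)) path else index_path(path)
  if (!file.exists(ip)) stop("no index found at ", ip, call. = FALSE)
  con <- file(ip, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, INDEX_MAGIC)) {
    stop("not a linear index file (bad magic): ", ip, call. = FALSE)
  }
  version <- readBin(con, "integer", size = 4L, endian = "little")
  if (version != INDEX_VERSION) {
    stop("unsupported index version ", version, call. = FALSE)
  }
  bin_size_bp <- readBin(con, "integer", size = 4L, endian = "little")
  file_size <- readBin(con, "numeric", size = 8L, endian = "little")
  md5 <- read_string(con)
  n_chrom <- readBin(con, "integer", size = 4L, endian = "little")
  tables <- list()
  for (i in seq_len(n_chrom)) {
    cn <- read_string(con)
    nb <- readBin(con, "integer", size = 4L, endian = "little")
    off <- readBin(con, "numeric", n = nb, size = 8L, endian = "little")
    off[off < 0] <- NA_real_
    tables[[cn]] <- off
  }
  structure(list(bin_size_bp = bin_size_bp, file_size = file_size,
                 md5 = md5, tables = tables),
            class = "linear_index")
}

#' @export
print.linear_index <- function(x, ...) {
  cat(sprintf("<linear_index> %d bp bins, %d chromosome(s)\n",
              x$bin_size_bp, length(x$tables)))
  invisible(x)
}

parse_data_line <- function(line) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  list(chrom = f[1], start = as.numeric(f[2]), end = as.numeric(f[3]),
       value = as.numeric(f[if (length(f) >= 5L) 5L else 4L]))
}

#' Seek-and-scan region query on an indexed BED file
#'
#' Seeks to the indexed offset of the query region's first overlapping
#' bin, scans forward parsing records, emits those overlapping the region,
#' and stops at the first record starting at or beyond the region end (or
#' leaving the chromosome block) — valid because the file is start-sorted.
#' The result is identical to a full linear scan, but only a bounded slice
#' of the file is read. A stale index (the file changed since indexing) is
#' an error.
#'
#' @param path The indexed BED file.
#' @param region A [genomic_region()] or region string.
#' @param index The `linear_index`; defaults to reading `<path>.hbi`.
#' @return Tibble of overlapping records in coordinate order, with
#'   attribute `n_scanned` (records parsed during the scan).
#' @export
indexed_query <- function(path, region, index = read_index(path)) {
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "genomic_region"),
            inherits(index, "linear_index"))
  if (as.numeric(file.size(path)) != index$file_size ||
      !identical(unname(tools::md5sum(path)), index$md5)) {
    stop("stale index: ", path, " changed since the index was built; ",
         "rebuild with build_index()", call. = FALSE)
  }
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric())
  tab <- index$tables[[region$chrom]]
  if (is.null(tab)) {
    attr(empty, "n_scanned") <- 0L
    return(empty)
  }
  bin0 <- floor(region$start / index$bin_size_bp) + 1
  cand <- tab[seq(from = min(bin0, length(tab) + 1), length.out =
                    max(length(tab) - bin0 + 1, 0))]
  cand <- cand[!is.na(cand)]
  if (length(cand) == 0L) {
    attr(empty, "n_scanned") <- 0L
    return(empty)
  }
  offset <- cand[1L]

  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = offset, origin = "start")
  out <- list()
  n_scanned <- 0L
  repeat {
    lines <- readLines(con, n = 256L, warn = FALSE)
    if (length(lines) == 0L) break
    stop_now <- FALSE
    for (line in lines) {
      t <- trimws(line)
      if (!nzchar(t) || grepl(bed_comment_re, t)) next
      rec <- parse_data_line(t)
      n_scanned <- n_scanned + 1L
      if (rec$chrom != region$chrom || rec$start >= region$end) {
        stop_now <- TRUE
        break
      }
      if (rec$end > region$start) out[[length(out) + 1L]] <- rec
    }
    if (stop_now) break
  }
  res <- if (length(out) == 0L) empty else {
    tibble::tibble(
      chrom = vapply(out, `[[`, "", "chrom"),
      start = vapply(out, `[[`, 0, "start"),
      end = vapply(out, `[[`, 0, "end"),
      value = vapply(out, `[[`, 0, "value")
    )
  }
  attr(res, "n_scanned") <- n_scanned
  res
}
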