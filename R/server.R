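# A small RESTful region-query service over indexed BED files, and the
# matching client source. Single-threaded HTTP/1.1 on base R sockets,
# localhost-oriented: the point is the query contract (the same one the
# in-memory source satisfies), not a web framework.
#
# Routes (versioned under /v1):
#   GET /v1/samples                               -> JSON array of sample IDs
#   GET /v1/data/{sample}?chrom=&start=&end=      -> JSON array of
#                                                    [chrom, start, end, value]
#   GET /v1/ping                                  -> "ok" (readiness probe)
#   GET /v1/shutdown                              -> stops the server

url_decode_plus <- function(x) utils::URLdecode(gsub("+", " ", x, fixed = TRUE))

parse_query_string <- function(qs) {
  if (is.na(qs) || !nzchar(qs)) return(list())
  parts <- strsplit(qs, "&", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(
    lapply(kv, function(p) if (length(p) > 1L) url_decode_plus(p[2]) else ""),
    vapply(kv, `[[`, "", 1L)
  )
}

http_response <- function(con, status, body,
                          content_type = "application/json") {
  reason <- c(`200` = "OK", `400` = "Bad Request", `404` = "Not Found",
              `405` = "Method Not Allowed")[[as.character(status)]]
  head <- sprintf(
    "HTTP/1.1 %d %s\r\nContent-Type: %s\r\nContent-Length: %d\r\nConnection: close\r\n\r\n",
    status, reason, content_type, nchar(body, type = "bytes"))
  writeBin(charToRaw(paste0(head, body)), con)
}

json_error <- function(msg) {
  as.character(jsonlite::toJSON(list(error = msg), auto_unbox = TRUE))
}

# hand-assembled so values serialize with shortest-roundtrip precision:
# a client must recover bit-identical doubles
records_to_json <- function(recs) {
  if (nrow(recs) == 0L) return("[]")
  rows <- sprintf('["%s",%.0f,%.0f,%s]',
                  gsub('"', '\\\\"', recs$chrom), recs$start, recs$end,
                  vapply(recs$value, format_value, character(1)))
  paste0("[", paste(rows, collapse = ","), "]")
}

#' Serve indexed BED files over a RESTful region-query API
#'
#' Scans `data_dir` for `*.bed` files (one per sample; the file name is the
#' sample ID), builds any missing sidecar indexes, then blocks serving
#' requests until `/v1/shutdown` is requested or `max_requests` is
#' reached. Responses to region queries use [indexed_query()], so only the
#' necessary slice of each file is read per request.
#'
#' @param data_dir Directory of sorted per-sample BED files (+ optional
#'   `.hbi` sidecars; missing ones are built on startup).
#' @param port TCP port to bind.
#' @param host Interface to bind (default loopback).
#' @param max_requests Stop after this many requests (default unlimited).
#' @param port_file If non-`NULL`, the bound port is written here once the
#'   server is ready — a readiness signal for supervising processes.
#' @param quiet Suppress per-request logging.
#' @return (Invisibly) the number of requests served.
#' @export
serve_bed <- function(data_dir, port = 8731L, host = "127.0.0.1",
                      max_requests = Inf, port_file = NULL, quiet = TRUE) {
  paths <- sort(list.files(data_dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(paths) == 0L) {
    stop("no .bed files in ", data_dir, call. = FALSE)
  }
  samples <- vapply(paths, sample_id_from_path, "")
  names(paths) <- samples
  indexes <- lapply(paths, function(p) {
    if (file.exists(index_path(p))) read_index(p) else build_index(p)
  })

  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  if (!is.null(port_file)) writeLines(as.character(port), port_file)
  if (!quiet) message("serving ", length(paths), " sample(s) on ",
                      host, ":", port)

  handle <- function(method, target) {
    path <- sub("\\?.*$", "", target)
    qs <- if (grepl("?", target, fixed = TRUE)) {
      sub("^[^?]*\\?", "", target)
    } else NA_character_
    if (method != "GET") {
      return(list(405L, json_error("only GET is supported")))
    }
    if (path == "/v1/ping") {
      return(list(200L, "\"ok\""))
    }
    if (path == "/v1/samples") {
      return(list(200L, as.character(
        jsonlite::toJSON(unname(samples)))))
    }
    m <- regmatches(path, regexec("^/v1/data/([^/]+)$", path))[[1]]
    if (length(m) == 2L) {
      sample <- url_decode_plus(m[2])
      if (!sample %in% samples) {
        return(list(404L, json_error(paste0("unknown sample: ", sample))))
      }
      q <- parse_query_string(qs)
      chrom <- q[["chrom"]]
      start <- suppressWarnings(as.numeric(q[["start"]] %||% NA))
      end <- suppressWarnings(as.numeric(q[["end"]] %||% NA))
      if (is.null(chrom) || !nzchar(chrom) || is.na(start) || is.na(end) ||
          start != trunc(start) || end != trunc(end)) {
        return(list(400L, json_error(
          "need chrom=<name>&start=<int>&end=<int>")))
      }
      if (start < 0 || start >= end) {
        return(list(400L, json_error("need 0 <= start < end")))
      }
      region <- genomic_region(chrom, start, end)
      recs <- indexed_query(paths[[sample]], region,
                            index = indexes[[sample]])
      return(list(200L, records_to_json(recs)))
    }
    list(404L, json_error(paste0("no such route: ", path)))
  }

  served <- 0L
  shutting_down <- FALSE
  while (!shutting_down && served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    req <- tryCatch({
      line1 <- readLines(con, n = 1L, warn = FALSE)
      while (TRUE) { # drain headers
        h <- readLines(con, n = 1L, warn = FALSE)
        if (length(h) == 0L || !nzchar(h)) break
      }
      line1
    }, error = function(e) character(0))
    if (length(req) == 1L && nzchar(req)) {
      parts <- strsplit(trimws(req), " +")[[1]]
      method <- parts[1]
      target <- if (length(parts) >= 2L) parts[2] else "/"
      if (target == "/v1/shutdown") {
        http_response(con, 200L, "\"bye\"")
        shutting_down <- TRUE
      } else {
        resp <- tryCatch(handle(method, target), error = function(e) {
          list(400L, json_error(conditionMessage(e)))
        })
        http_response(con, resp[[1]], resp[[2]])
        if (!quiet) message(method, " ", target, " -> ", resp[[1]])
      }
      served <- served + 1L
    }
    close(con)
  }
  invisible(served)
}

#' Minimal HTTP GET over a raw socket
#'
#' @param host,port Server address.
#' @param path Request target (path + query string).
#' @param timeout Socket timeout in seconds.
#' @return List with `status` (integer) and `body` (string).
#' @keywords internal
http_get <- function(host, port, path, timeout = 10) {
  con <- socketConnection(host, port, blocking = TRUE, open = "r+b",
                          timeout = timeout)
  on.exit(close(con))
  writeBin(charToRaw(sprintf(
    "GET %s HTTP/1.1\r\nHost: %s\r\nConnection: close\r\n\r\n", path, host)),
    con)
  status_line <- readLines(con, n = 1L, warn = FALSE)
  status <- as.integer(strsplit(trimws(status_line), " +")[[1]][2])
  content_length <- NA_integer_
  repeat {
    h <- readLines(con, n = 1L, warn = FALSE)
    if (length(h) == 0L || !nzchar(h)) break
    if (grepl("^Content-Length:", h, ignore.case = TRUE)) {
      content_length <- as.integer(trimws(sub("^[^:]+:", "", h)))
    }
  }
  body <- if (!is.na(content_length) && content_length > 0L) {
    rawToChar(readBin(con, "raw", n = content_length))
  } else ""
  list(status = status, body = body)
}

#' HTTP-backed data source
#'
#' A client for the [serve_bed()] API satisfying the same query contract
#' as [bedfile_source()], so the two are interchangeable to the chart
#' layer.
#'
#' @param base_url Server base URL, e.g. `"http://127.0.0.1:8731"`.
#' @return An `http_source` object.
#' @export
http_source <- function(base_url) {
  m <- regmatches(base_url,
                  regexec("^http://([^:/]+)(?::([0-9]+))?/?$", base_url))[[1]]
  if (length(m) == 0L) {
    stop("base_url must look like http://host[:port]", call. = FALSE)
  }
  structure(list(host = m[2],
                 port = if (nzchar(m[3])) as.integer(m[3]) else 80L,
                 base_url = base_url),
            class = "http_source")
}

#' @export
print.http_source <- function(x, ...) {
  cat(sprintf("<http_source> %s\n", x$base_url))
  invisible(x)
}

http_source_get <- function(source, path) {
  resp <- http_get(source$host, source$port, path)
  if (resp$status != 200L) {
    msg <- tryCatch(jsonlite::fromJSON(resp$body)$error,
                    error = function(e) resp$body)
    stop("server returned ", resp$status, ": ", msg, call. = FALSE)
  }
  resp$body
}

#' @export
src_samples.http_source <- function(source) {
  as.character(jsonlite::fromJSON(http_source_get(source, "/v1/samples")))
}

#' @export
src_query.http_source <- function(source, sample, region) {
  if (is.character(region)) region <- parse_region(region)
  stopifnot(inherits(region, "genomic_region"))
  body <- http_source_get(source, sprintf(
    "/v1/data/%s?chrom=%s&start=%d&end=%d",
    utils::URLencode(sample, reserved = TRUE),
    utils::URLencode(region$chrom, reserved = TRUE),
    region$start, region$end))
  rows <- jsonlite::fromJSON(body, simplifyVector = FALSE)
  if (length(rows) == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric()))
  }
  tibble::tibble(
    chrom = vapply(rows, function(r) as.character(r[[1]]), ""),
    start = vapply(rows, function(r) as.numeric(r[[2]]), 0),
    end = vapply(rows, function(r) as.numeric(r[[3]]), 0),
    value = vapply(rows, function(r) as.numeric(r[[4]]), 0)
  )
}

#' Request a running server to stop
#'
#' @param source An [http_source()] (or base URL).
#' @return `TRUE` on acknowledgement.
#' @export
shutdown_server <- function(source) {
  if (is.character(source)) source <- http_source(source)
  resp <- http_get(source$host, source$port, "/v1/shutdown")
  identical(resp$status, 200L)
}
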