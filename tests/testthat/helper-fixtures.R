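# Shared test helpers: random record generators, brute-force oracles, and
# a background server harness.

random_records <- function(n, region, value_range = c(-50, 50),
                           max_len = NULL, chrom = region$chrom) {
  len <- region_length(region)
  if (is.null(max_len)) max_len <- max(2L, ceiling(len / 5))
  s <- region$start + floor(stats::runif(n, 0, len))
  l <- 1L + floor(stats::runif(n, 0, max_len))
  tibble::tibble(
    chrom = chrom,
    start = s,
    end = pmin(s + l, region$end + max_len), # may extend past the region
    value = round(stats::runif(n, value_range[1], value_range[2]), 3)
  )
}

# overlap filter by full linear scan: the reference for every source
linear_scan <- function(records, region) {
  keep <- records$chrom == region$chrom &
    records$start < region$end & records$end > region$start
  out <- records[keep, c("chrom", "start", "end", "value")]
  out[order(out$chrom, out$start), ]
}

# value-level comparison ignoring bookkeeping attributes and row names
expect_same_records <- function(a, b) {
  a <- as.data.frame(a)[c("chrom", "start", "end", "value")]
  b <- as.data.frame(b)[c("chrom", "start", "end", "value")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
}

# sorted per-sample BED files in a fresh temp dir
write_sim_dir <- function(n_samples = 3, seed = 42, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulate_coverage(n_samples = n_samples, seed = seed, ...)
  write_coverage(sim, dir)
  dir
}

free_port <- function() {
  for (i in 1:50) {
    port <- sample(20000:45000, 1)
    ok <- tryCatch({
      s <- serverSocket(port)
      close(s)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(port)
  }
  stop("no free port found")
}

# Launch serve_bed() in a background R process; returns proc + url.
# Caller should stop_test_server() (also registered as a deferred cleanup).
start_test_server <- function(data_dir, envir = parent.frame()) {
  port <- free_port()
  port_file <- tempfile()
  proc <- callr::r_bg(
    function(dir, port, pf) horizonbed::serve_bed(dir, port = port,
                                                  port_file = pf),
    args = list(dir = data_dir, port = port, pf = port_file)
  )
  for (i in 1:150) {
    if (file.exists(port_file)) break
    if (!proc$is_alive()) {
      stop("test server died: ", proc$read_all_error())
    }
    Sys.sleep(0.1)
  }
  if (!file.exists(port_file)) stop("test server did not become ready")
  srv <- list(proc = proc, url = sprintf("http://127.0.0.1:%d", port))
  withr::defer(stop_test_server(srv), envir = envir)
  srv
}

stop_test_server <- function(srv) {
  if (srv$proc$is_alive()) {
    tryCatch(shutdown_server(srv$url), error = function(e) NULL)
    srv$proc$wait(3000)
    if (srv$proc$is_alive()) srv$proc$kill()
  }
  invisible(NULL)
}
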