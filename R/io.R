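#' Read and write behavioral time series
#'
#' Trajectories are stored as tab-delimited text with `#`-prefixed metadata
#' lines (`dt`, `seed`) followed by a `time<TAB>value` header. Values are
#' written with 17 significant digits so a write/read round trip reproduces
#' every double bit-exactly, and regenerating a file from the same seed is
#' byte identical. On read, the time column must be uniform within a 1e-6
#' relative tolerance; `dt` is inferred from it.
#'
#' @param ts A [behav_ts()].
#' @param path File path.
#' @return `write_behav_ts()` returns `path` invisibly; `read_behav_ts()`
#'   returns a [behav_ts()].
#' @export
write_behav_ts <- function(ts, path) {
  stopifnot(inherits(ts, "behav_ts"))
  meta <- c(
    "# behavdim time series",
    sprintf("# dt = %.17g", attr(ts, "dt")),
    if (!is.null(attr(ts, "seed"))) sprintf("# seed = %d", attr(ts, "seed"))
  )
  body <- sprintf("%.17g\t%.17g", ts$time, ts$value)
  writeLines(c(meta, "time\tvalue", body), path)
  invisible(path)
}

#' @rdname write_behav_ts
#' @export
read_behav_ts <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  steps <- diff(df$time)
  dt0 <- stats::median(steps)
  if (dt0 <= 0 || any(abs(steps - dt0) > 1e-6 * dt0)) {
    stop_behavdim("time column is not uniformly sampled (1e-6 relative tolerance).",
                  class = "behavdim_parameter_error")
  }
  seed <- parse_meta_number(meta, "seed")
  behav_ts(df$value, dt = dt0,
           seed = if (is.na(seed)) NULL else as.integer(seed),
           t0 = df$time[1])
}

parse_meta_number <- function(meta, key) {
  hit <- grep(sprintf("^#\\s*%s\\s*=", key), meta, value = TRUE)
  if (length(hit) == 0L) return(NA_real_)
  as.numeric(sub(".*=\\s*", "", hit[1]))
}

#' Read and write correlation / chain model files
#'
#' Models are stored as key-value text (`key = value`, one per line, with a
#' `type` line). Supported types: `expmix`, `powerlaw`, `white`, `ising`.
#'
#' @param model A correlation model or [ising_chain()].
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   reconstructed object.
#' @export
write_model <- function(model, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = ", ")
  lines <- if (inherits(model, "corr_expmix")) {
    c("type = expmix",
      sprintf("amplitudes = %s", fmt(model$amplitudes)),
      sprintf("timescales = %s", fmt(model$timescales)))
  } else if (inherits(model, "corr_powerlaw")) {
    c("type = powerlaw",
      sprintf("variance = %s", fmt(model$variance)),
      sprintf("t0 = %s", fmt(model$t0)),
      sprintf("alpha = %s", fmt(model$alpha)))
  } else if (inherits(model, "corr_white")) {
    c("type = white", sprintf("variance = %s", fmt(model$variance)))
  } else if (inherits(model, "ising_chain")) {
    c("type = ising",
      sprintf("h = %s", fmt(model$h)),
      sprintf("couplings = %s", fmt(model$couplings)))
  } else {
    stop_behavdim("unsupported model type for writing.",
                  class = "behavdim_parameter_error")
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE)
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  kv <- setNames(as.list(vals), keys)
  num <- function(key) as.numeric(trimws(strsplit(kv[[key]], ",")[[1]]))
  switch(
    kv$type,
    expmix = exp_mixture_corr(num("amplitudes"), num("timescales")),
    powerlaw = powerlaw_corr(num("variance"), num("t0"), num("alpha")),
    white = white_noise_corr(num("variance")),
    ising = ising_chain(num("h"), num("couplings")),
    stop_behavdim(sprintf("unknown model type '%s'.", kv$type),
                  class = "behavdim_parameter_error")
  )
}

#' Write a past-future spectrum as delimited text
#'
#' Columns `index`, `coefficient`, `window_len`, tab-delimited with a
#' header.
#'
#' @param spec A `kpf_spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "kpf_spectrum"))
  body <- sprintf("%d\t%.17g\t%d", seq_along(spec$coeffs), spec$coeffs,
                  spec$window_len)
  writeLines(c("index\tcoefficient\twindow_len", body), path)
  invisible(path)
}

#' Write a rank report as JSON
#'
#' @param report A `rank_report` from [rank_vs_window()].
#' @param path File path.
#' @export
write_rank_report <- function(report, path) {
  stopifnot(inherits(report, "rank_report"))
  jsonlite::write_json(
    list(windows = report$window, ranks = report$rank,
         threshold = attr(report, "threshold"),
         verdict = attr(report, "verdict")),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a predictive-information curve as delimited text
#'
#' Tab-delimited `window` and `bits` columns; the header comment names the
#' units and classification.
#'
#' @param curve A `predinfo_curve`.
#' @param path File path.
#' @export
write_predinfo_curve <- function(curve, path) {
  stopifnot(inherits(curve, "predinfo_curve"))
  meta <- c(
    "# behavdim predictive information (units: bits)",
    sprintf("# classification = %s", attr(curve, "classification"))
  )
  body <- sprintf("%d\t%.17g", curve$window, curve$bits)
  writeLines(c(meta, "window\tbits", body), path)
  invisible(path)
}

#' Read and write spin sequences
#'
#' Single-column text of +1/-1 (or 0/1 with `encoding = "01"`).
#'
#' @param spins Integer vector in \{-1, +1\}.
#' @param path File path.
#' @param encoding `"pm1"` (default) writes/reads -1/+1; `"01"` maps 0 to -1
#'   and 1 to +1.
#' @export
write_spins <- function(spins, path, encoding = c("pm1", "01")) {
  encoding <- match.arg(encoding)
  out <- if (encoding == "01") (spins + 1L) %/% 2L else spins
  writeLines(as.character(out), path)
  invisible(path)
}

#' @rdname write_spins
#' @export
read_spins <- function(path, encoding = c("pm1", "01")) {
  encoding <- match.arg(encoding)
  x <- as.integer(readLines(path))
  if (encoding == "01") x <- 2L * x - 1L
  if (!all(x %in% c(-1L, 1L))) {
    stop_behavdim("spin file must contain only the two declared state labels.",
                  class = "behavdim_parameter_error")
  }
  x
}
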