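# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded simulations do not
#' disturb the caller's random stream. `seed = NULL` leaves the stream alone.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Count spikes in half-open windows (a, b]
#'
#' `spikes` must be sorted increasing; `starts`/`ends` are parallel vectors.
#' @noRd
count_in_windows <- function(spikes, starts, ends) {
  stopifnot(length(starts) == length(ends))
  if (length(spikes) == 0L) {
    return(integer(length(starts)))
  }
  findInterval(ends, spikes) - findInterval(starts, spikes)
}

#' Merge possibly overlapping intervals into maximal disjoint intervals
#'
#' `ivals` is a 2-column matrix (start, end); returns the same, sorted.
#' @noRd
merge_intervals <- function(ivals) {
  if (is.null(ivals) || nrow(ivals) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  ivals <- ivals[order(ivals[, 1L]), , drop = FALSE]
  out <- ivals[1L, , drop = FALSE]
  if (nrow(ivals) > 1L) {
    for (i in 2L:nrow(ivals)) {
      k <- nrow(out)
      if (ivals[i, 1L] <= out[k, 2L]) {
        out[k, 2L] <- max(out[k, 2L], ivals[i, 2L])
      } else {
        out <- rbind(out, ivals[i, , drop = FALSE])
      }
    }
  }
  out
}

#' Complement of a set of disjoint sorted intervals within [lo, hi]
#' @noRd
complement_intervals <- function(ivals, lo, hi) {
  if (nrow(ivals) == 0L) {
    return(matrix(c(lo, hi), ncol = 2L))
  }
  starts <- c(lo, ivals[, 2L])
  ends <- c(ivals[, 1L], hi)
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

#' Analytic signal of a real vector via the FFT
#'
#' Standard construction: double positive frequencies, zero negative ones.
#' Used for instantaneous phase of the band-passed whisker angle.
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n > 1L)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Stable hash of a configuration list (for output-table provenance)
#' @noRd
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a data frame as TSV with provenance header comments
#' @noRd
write_tsv_hashed <- function(df, path, hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (!is.null(hash)) {
    writeLines(sprintf("# config_hash: %s", hash), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by write_tsv_hashed (comment headers skipped)
#' @noRd
read_tsv_hashed <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Paired Wilcoxon signed-rank p-value robust to all-zero differences
#' @noRd
paired_signrank_p <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[is.finite(d)]
  if (length(d) == 0L || all(d == 0)) {
    return(1)
  }
  stats::wilcox.test(x, y,
    paired = TRUE, exact = FALSE, correct = TRUE,
    alternative = alternative
  )$p.value
}

#' One-sample Wilcoxon signed-rank p-value robust to all-zero samples
#' @noRd
signrank_p <- function(x, alternative = "two.sided") {
  x <- x[is.finite(x)]
  if (length(x) == 0L || all(x == 0)) {
    return(1)
  }
  stats::wilcox.test(x,
    mu = 0, exact = FALSE, correct = TRUE,
    alternative = alternative
  )$p.value
}
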