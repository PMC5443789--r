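# Episomal vector loss: geometric decay per cell generation, fitted by a
# log-linear least-squares regression.

#' Expected episome copies after a number of generations
#'
#' @param initial initial copy number (> 0).
#' @param loss_rate loss fraction per generation, in (0, 1).
#' @param generations number of cell generations (>= 0).
#' @return `initial * (1 - loss_rate)^generations`.
#' @export
expected_copies <- function(initial, loss_rate, generations) {
  assert_scalar_number(initial, "initial", lower = 1e-12)
  if (loss_rate <= 0 || loss_rate >= 1) {
    stop("loss rate must lie in (0, 1)", call. = FALSE)
  }
  if (any(generations < 0)) stop("generations must be >= 0", call. = FALSE)
  initial * (1 - loss_rate)^generations
}

#' Fit the per-generation loss rate of an episomal vector
#'
#' Ordinary least squares on `log(copies)` against generations
#' (`24 * days / generation_time_hours`); the slope `b` gives
#' `loss_rate = 1 - exp(b)`.  Fitting on the log scale matches the
#' multiplicative noise of qPCR quantification, and noiseless input is
#' recovered exactly.
#'
#' @param series a [decay_series()] with at least 3 timepoints.
#' @return list of class `decay_fit`: `loss_rate_per_generation`,
#'   `initial_copies`, `r_squared`, `generation_time_hours`.
#' @export
fit_loss_rate <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  if (length(series$timepoints) < 3L) {
    stop("need at least 3 timepoints to fit a loss rate", call. = FALSE)
  }
  if (any(series$copy_numbers <= 0)) {
    stop("copy numbers must be positive", call. = FALSE)
  }
  gens <- 24 * series$timepoints / series$generation_time_hours
  fit <- stats::lm(log(series$copy_numbers) ~ gens)
  slope <- unname(coef(fit)[2])
  rate <- 1 - exp(slope)
  if (!(rate > 1e-10 && rate < 1)) {
    stop(sprintf(
      "fitted loss rate %.4g is outside (0, 1): the series shows no measurable loss",
      rate), call. = FALSE)
  }
  structure(list(loss_rate_per_generation = rate,
                 initial_copies = exp(unname(coef(fit)[1])),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 generation_time_hours = series$generation_time_hours),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> loss %.2f%% per generation (initial %.3g, R^2 %.4f)\n",
    100 * x$loss_rate_per_generation, x$initial_copies, x$r_squared))
  invisible(x)
}

#' Read / write a decay series TSV (`day`, `relative_copies`)
#'
#' @param series a [decay_series()].
#' @param path TSV path.
#' @param generation_time_hours generation time attached on read.
#' @export
write_decay_series <- function(series, path) {
  write.table(data.frame(day = series$timepoints,
                         relative_copies = series$copy_numbers),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_series
#' @export
read_decay_series <- function(path, generation_time_hours = 24) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("day", "relative_copies") %in% names(tab)))
  decay_series(tab$day, tab$relative_copies, generation_time_hours)
}
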