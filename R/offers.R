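#' Load and validate the intertemporal offer grid
#'
#' The task presents a fixed menu of delayed offers: 18 delays (7--200 days),
#' each paired with 6 monetary amounts ($25--$54), against a constant
#' immediate reference of $25. A packaged copy of the grid ships with the
#' package and is used by default.
#'
#' @param source Path to a tab-separated table with header
#'   `delay amount1 ... amount6`. Defaults to the packaged grid.
#' @return A data frame of class `offer_grid` with columns `delay` and
#'   `amount1`..`amount6`, validated against the design invariants
#'   (18 delay rows, 6 nondecreasing amounts per row, strictly increasing
#'   delays, amounts in 25--54, delays in 7--200).
#' @export
load_offer_grid <- function(source = system.file("extdata", "offer_grid.tsv",
                                                 package = "tdconnect")) {
  raw <- utils::read.delim(source, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE)
  if (ncol(raw) != 7L)
    stop("offer grid must have 7 columns (delay + 6 amounts), got ", ncol(raw))
  if (nrow(raw) != 18L)
    stop("offer grid must have 18 delay rows, got ", nrow(raw))
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (anyNA(num)) stop("non-numeric cell in offer grid")
  if (any(num != round(num))) stop("non-integer cell in offer grid")
  grid <- as.data.frame(num)
  names(grid) <- c("delay", paste0("amount", 1:6))
  validate_offer_grid(grid)
  class(grid) <- c("offer_grid", "data.frame")
  grid
}

validate_offer_grid <- function(grid) {
  amounts <- as.matrix(grid[, paste0("amount", 1:6)])
  if (any(diff(grid$delay) <= 0))
    stop("delays must be strictly increasing across rows")
  if (any(t(apply(amounts, 1L, diff)) < 0))
    stop("amounts must be nondecreasing within each delay row")
  if (min(amounts) < 25 || max(amounts) > 54)
    stop("amounts must lie in [25, 54]")
  if (min(grid$delay) < 7 || max(grid$delay) > 200)
    stop("delays must lie in [7, 200]")
  invisible(grid)
}

#' Enumerate the unique (delay, amount) offers of a grid
#'
#' @param grid An `offer_grid`.
#' @return Data frame with one row per (delay, amount) cell, columns
#'   `delay` and `amount` (108 rows for the packaged grid).
#' @export
offer_pairs <- function(grid) {
  out <- data.frame(
    delay  = rep(grid$delay, each = 6L),
    amount = as.vector(t(as.matrix(grid[, paste0("amount", 1:6)])))
  )
  out
}

#' Build an unrealized two-run session of intertemporal choice trials
#'
#' Each of the 108 (delay, amount) offers appears exactly twice, in a random
#' order determined by `seed`, split into two runs of 108 trials. Trial
#' onsets assume the full 3 s decision window plus 250 ms feedback, with
#' inter-trial fixation intervals drawn uniformly on \[2, 6\] s. Choices and
#' reaction times are unset (`NA`); realize them with
#' [simulate_subject_behavior()] or fill them from observed event files.
#'
#' @param grid An `offer_grid`.
#' @param seed Integer seed controlling trial order and ITIs.
#' @return Data frame of 216 trials with columns `onset`, `duration`,
#'   `amount`, `delay`, `choice`, `rt`, `run`.
#' @export
build_session <- function(grid, seed) {
  validate_offer_grid(grid)
  pairs <- offer_pairs(grid)
  trials <- rbind(pairs, pairs)            # each option shown twice
  rng <- local_rng(seed)
  ord <- sample.int(nrow(trials))
  trials <- trials[ord, , drop = FALSE]
  n <- nrow(trials)
  run <- rep(c(1L, 2L), each = n %/% 2L)
  iti <- stats::runif(n, 2, 6)
  onset <- numeric(n)
  t_run <- c(0, 0)
  for (i in seq_len(n)) {
    r <- run[i]
    onset[i] <- t_run[r] + iti[i]
    t_run[r] <- onset[i] + 3.0 + 0.25     # max decision window + feedback
  }
  restore_rng(rng)
  data.frame(
    onset = onset, duration = NA_real_,
    amount = trials$amount, delay = trials$delay,
    choice = NA_character_, rt = NA_real_, run = run,
    stringsAsFactors = FALSE
  )
}

#' Read / write trial event tables
#'
#' Events use a BIDS-like tab-separated dialect with columns
#' `onset duration amount delay choice rt run`; times are seconds from the
#' start of each run.
#'
#' @param trials Trial data frame as returned by [build_session()].
#' @param path File path.
#' @return `read_events` returns the trial data frame; `write_events`
#'   returns `path` invisibly.
#' @export
write_events <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "amount", "delay", "choice", "rt", "run")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols))
    stop("event table missing columns: ", paste(missing_cols, collapse = ", "))
  ev$choice <- as.character(ev$choice)
  ev
}

# Seed scoping helpers: run a block under a given seed without disturbing the
# caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a child seed (< 2^31) from a parent seed and a stage label, so each
# stochastic stage of the pipeline gets an independent, loggable stream.
derive_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h * 1299721 + index * 7919) %% 2147483647)
}
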