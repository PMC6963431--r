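# Per-iteration logging and derived statistics: population counts, chain
# statistics, and the moving-average GTP consumption rate.

#' Per-iteration population counts
#'
#' Counts are computed from the bond graph and nucleotide states: a dimer is
#' active iff both members hold a bound nucleotide (dimers inside chains
#' included); a chain is a connected dimer component of two or more dimers,
#' its length measured in dimers; a closed ring is a chain whose bond graph
#' forms a cycle. `bound_nt` (bound nucleotides) completes the conservation
#' law `free_gtp + free_gdp + bound_nt = initial nucleotide population`.
#'
#' @param w an `mt_world`.
#' @return a one-row tibble with columns `iteration`, `inactive_dimers`,
#'   `active_dimers`, `free_gtp`, `free_gdp`, `max_chain_length`,
#'   `chain_count`, `closed_ring_count`, `bound_nt`.
#' @export
mt_snapshot <- function(w) {
  s <- snapshot_row(w)
  tibble::as_tibble(as.list(s))
}

# fast path used by the run loop: named numeric vector
snapshot_row <- function(w) {
  da <- dimer_alphas(w)
  n_dim <- length(da)
  n_act <- if (n_dim > 0) sum(dimer_active(w, da)) else 0L
  if (n_dim > 0) {
    csize <- tabulate(w$cluster)
    chains <- which(csize >= 4L)
    if (length(chains) > 0) {
      nb <- length(csize)
      cfree <- tabulate(w$cluster[w$bond_a == 0L], nbins = nb) +
        tabulate(w$cluster[w$bond_b == 0L], nbins = nb)
      closed <- sum(cfree[chains] == 0L)
      max_len <- max(csize[chains]) / 2
      n_chain <- length(chains)
    } else {
      closed <- 0L
      max_len <- 0
      n_chain <- 0L
    }
  } else {
    closed <- 0L
    max_len <- 0
    n_chain <- 0L
  }
  c(iteration = w$iteration,
    inactive_dimers = n_dim - n_act,
    active_dimers = n_act,
    free_gtp = sum(w$nuc_state == NT_GTP),
    free_gdp = sum(w$nuc_state == NT_GDP),
    max_chain_length = max_len,
    chain_count = n_chain,
    closed_ring_count = closed,
    bound_nt = sum(w$nuc_state == NT_BOUND))
}

#' Chain statistics of a world
#'
#' Chains are connected dimer components of size >= 2 dimers; lone dimers are
#' not chains. The histogram is keyed by chain length in dimers and flags how
#' many chains of each length are closed rings.
#'
#' @param w an `mt_world`.
#' @return a list with `max_length`, `chain_count` and `length_histogram`
#'   (a tibble with columns `length`, `n_chains`, `n_closed`).
#' @export
chain_statistics <- function(w) {
  if (n_tubulins(w) == 0 || length(dimer_alphas(w)) == 0) {
    return(list(max_length = 0L, chain_count = 0L,
                length_histogram = tibble::tibble(
                  length = integer(), n_chains = integer(),
                  n_closed = integer())))
  }
  csize <- tabulate(w$cluster)
  chains <- which(csize >= 4L)
  if (length(chains) == 0) {
    return(list(max_length = 0L, chain_count = 0L,
                length_histogram = tibble::tibble(
                  length = integer(), n_chains = integer(),
                  n_closed = integer())))
  }
  free <- (w$bond_a == 0L) + (w$bond_b == 0L)
  cfree <- rowsum(free, w$cluster, reorder = TRUE)
  lens <- csize[chains] / 2
  closed <- cfree[chains] == 0L
  hist <- tibble::tibble(length = as.integer(lens),
                         closed = as.logical(closed)) |>
    dplyr::count(.data$length, wt = NULL, name = "n_chains") |>
    dplyr::left_join(
      tibble::tibble(length = as.integer(lens[closed])) |>
        dplyr::count(.data$length, name = "n_closed"),
      by = "length") |>
    tidyr::replace_na(list(n_closed = 0L))
  list(max_length = as.integer(max(lens)),
       chain_count = length(chains),
       length_histogram = hist)
}

#' Moving-average GTP consumption rate
#'
#' Successive difference of a trailing moving average (default window 1000
#' points) of the free-GTP count series. The rate at a given iteration uses
#' only that iteration and earlier ones; output rows start once the window
#' is full, so the result has `length(series) - window` rows. A negative
#' rate of larger magnitude means faster GTP consumption.
#'
#' @param series numeric vector of free-GTP counts per iteration, or a
#'   counts tibble from [mt_run()]/[mt_snapshot()] (its `free_gtp` column is
#'   used and its `iteration` column labels the output).
#' @param window moving-average window length in points.
#' @param align `"trailing"` (default) or `"centered"` window alignment.
#' @return a tibble with columns `iteration`, `smoothed_gtp`, `rate`.
#' @export
gtp_consumption_rate <- function(series, window = 1000L,
                                 align = c("trailing", "centered")) {
  align <- match.arg(align)
  iters <- NULL
  if (is.data.frame(series)) {
    iters <- series$iteration
    series <- series$free_gtp
  }
  n <- length(series)
  window <- as.integer(window)
  if (window < 1) abort("`window` must be a positive integer")
  if (n <= window) {
    abort(sprintf(
      "series of length %d is too short: need more than %d points",
      n, window))
  }
  ma <- as.numeric(stats::filter(series, rep(1 / window, window),
                                 sides = if (align == "trailing") 1 else 2))
  keep <- which(!is.na(ma))
  ma <- ma[keep]
  rate <- diff(ma)
  idx <- keep[-1]
  if (is.null(iters)) iters <- seq_len(n) - 1L
  tibble::tibble(iteration = iters[idx],
                 smoothed_gtp = ma[-1],
                 rate = rate)
}

#' Write a counts table as comma-separated text
#'
#' One header row, one row per logged iteration; the format of the per-run
#' analytics log.
#'
#' @param counts a counts tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
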