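#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.  All randomness inside the package flows through this
#' helper, which is what makes equal `(config, seed)` give byte-identical
#' output.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## derive a stream-specific child seed; keeps independent emitters decoupled
child_seed <- function(seed, stream) {
  (as.double(seed) * 1000003 + stream) %% 2147483629
}

#' Build a sliding-window grid
#'
#' Windows of `window_size` bp advanced by `step` bp (defaults 20 kb / 10 kb),
#' 0-based half-open, per chromosome.  The last window is clipped to the
#' chromosome end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window width in bp.
#' @param step step between window starts in bp; must satisfy
#'   `0 < step <= window_size`.
#' @return `data.table` with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, window_size = 20000L, step = 10000L) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            step > 0, step <= window_size)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, ceiling(L / step) * step - step), by = step)
    starts <- starts[starts < L]
    data.table(chrom = ch, start = as.double(starts),
               end = pmin(as.double(starts) + window_size, as.double(L)))
  })
  out <- rbindlist(out)
  setattr(out, "window_size", as.double(window_size))
  setattr(out, "step", as.double(step))
  out
}

## map sites to the rows of a grid `windows` table (from make_windows) that
## contain them; a position falls into up to window_size/step windows
site_window_map <- function(windows, chrom, pos) {
  wsize <- attr(windows, "window_size")
  step <- attr(windows, "step")
  if (is.null(wsize) || is.null(step)) {
    step <- min(diff(sort(unique(windows$start))))
    wsize <- max(windows$end - windows$start)
  }
  w <- copy(windows)[, win := .I]
  setkey(w, chrom, start)
  kmax <- floor(pos / step)
  kmin <- pmax(0, floor((pos - wsize) / step) + 1)
  n_each <- as.integer(kmax - kmin + 1)
  dt <- data.table(
    chrom = rep(chrom, n_each),
    start = (sequence(n_each) - 1 + rep(kmin, n_each)) * step,
    site = rep(seq_along(pos), n_each)
  )
  hits <- w[dt, on = .(chrom, start), nomatch = NULL]
  hits[, .(site, win)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
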