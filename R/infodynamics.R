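#' Discretize a trajectory into per-cell symbol series
#'
#' The default (and the only self-consistent discrete reading for a
#' three-type system) takes each cell's expressed type over time as its
#' symbol series, alphabet `{1..n_types}`. A binned-continuous mode is
#' provided as an option: each state channel is uniformly binned over the
#' state bounds `[-3, 3]` into `bins` symbols `{0..bins-1}` (requires a
#' trajectory recorded with `record_states = TRUE`).
#'
#' @param trajectory an `nca_trajectory`.
#' @param mode `"types"` or `"binned"`.
#' @param bins number of bins for the binned mode.
#' @param l_c state bounds used for binning.
#' @return for `"types"`, an object of class `symbol_series`: a
#'   `(steps+1) x n_cells` integer matrix with attributes `alphabet` and
#'   cells in columns; for `"binned"`, a list of such matrices, one per state
#'   channel.
#' @export
symbolize <- function(trajectory, mode = c("types", "binned"), bins = 4L,
                      l_c = c(-3, 3)) {
  mode <- match.arg(mode)
  if (mode == "types") {
    s <- trajectory$types
    attr(s, "alphabet") <- trajectory$n_types
    class(s) <- c("symbol_series", "matrix")
    return(s)
  }
  if (is.null(trajectory$states)) {
    stop("binned mode requires a trajectory recorded with record_states = TRUE")
  }
  st <- trajectory$states  # n_state x n_cells x (steps+1)
  width <- (l_c[2] - l_c[1]) / bins
  lapply(seq_len(dim(st)[1]), function(ch) {
    x <- t(st[ch, , ])     # (steps+1) x n_cells
    s <- pmin(pmax(floor((x - l_c[1]) / width), 0), bins - 1)
    storage.mode(s) <- "integer"
    attr(s, "alphabet") <- bins
    class(s) <- c("symbol_series", "matrix")
    s
  })
}

encode_past <- function(x, k) {
  # returns list(next_sym, past_key) for valid times k+1 .. n (1-based)
  n <- length(x)
  if (n <= k) stop(sprintf("series of length %d too short for history length %d", n, k))
  x0 <- x - min(x)           # shift to 0-based symbols
  A <- max(x0) + 1
  idx <- (k + 1L):n
  key <- numeric(length(idx))
  for (j in seq_len(k)) key <- key * A + x0[idx - j]
  list(nxt = x0[idx], past = key, z_prev = x0[idx - 1L])
}

plugin_mean_local <- function(local) {
  # the distribution-weighted average of Eq.-style local values equals the
  # plain mean over occurrences
  mean(local)
}

#' Active information storage (plug-in estimator)
#'
#' Local active information storage of a single discrete series: the local
#' mutual information between the length-`k` past and the next symbol,
#' `a(n+1) = log2 p(past, next) / (p(past) p(next))`, with all probabilities
#' estimated by plug-in (maximum-likelihood) counts over the series itself.
#' The mean (the distribution-weighted time average) is non-negative; local
#' values may be negative.
#'
#' @param series integer vector (one cell's symbol series).
#' @param k history length.
#' @return an object of class `info_result` with `local` (per-time values in
#'   bits, aligned to times `k+1..n`), `mean` (bits), and `k`.
#' @export
local_ais <- function(series, k = 2L) {
  e <- encode_past(as.integer(series), k)
  m <- length(e$nxt)
  joint_key <- paste(e$past, e$nxt)
  p_joint <- table(joint_key) / m
  p_past <- table(e$past) / m
  p_next <- table(e$nxt) / m
  local <- log2(as.numeric(p_joint[joint_key]) /
                  (as.numeric(p_past[as.character(e$past)]) *
                     as.numeric(p_next[as.character(e$nxt)])))
  res <- list(local = local, mean = plugin_mean_local(local), k = k,
              n_obs = m, measure = "AIS")
  class(res) <- "info_result"
  res
}

#' Transfer entropy (plug-in estimator)
#'
#' Local transfer entropy from a source to a destination series: the
#' information the source's previous symbol adds about the destination's next
#' symbol beyond the destination's own length-`k` past,
#' `t(n+1) = log2 p(next | past, z) / p(next | past)`, with plug-in
#' probabilities. The mean is non-negative; local values may be negative.
#'
#' @param source,dest equal-length integer vectors.
#' @param k destination history length.
#' @return an `info_result` (see [local_ais()]).
#' @export
local_te <- function(source, dest, k = 2L) {
  source <- as.integer(source); dest <- as.integer(dest)
  if (length(source) != length(dest)) {
    stop("source and destination series must have equal length")
  }
  e <- encode_past(dest, k)
  es <- source - min(source)
  z <- es[((k + 1L):length(source)) - 1L]  # source symbol z_n preceding each next

  m <- length(e$nxt)
  key_pz <- paste(e$past, z)
  key_pn <- paste(e$past, e$nxt)
  key_pzn <- paste(e$past, z, e$nxt)
  c_p <- table(e$past)
  c_pz <- table(key_pz)
  c_pn <- table(key_pn)
  c_pzn <- table(key_pzn)
  # t = log2[ p(n|p,z) / p(n|p) ] = log2[ (c_pzn / c_pz) / (c_pn / c_p) ]
  local <- log2((as.numeric(c_pzn[key_pzn]) / as.numeric(c_pz[key_pz])) /
                  (as.numeric(c_pn[key_pn]) / as.numeric(c_p[as.character(e$past)])))
  res <- list(local = local, mean = plugin_mean_local(local), k = k,
              n_obs = m, measure = "TE")
  class(res) <- "info_result"
  res
}

#' @export
print.info_result <- function(x, ...) {
  cat(sprintf("%s (k = %d): mean %.4f bits over %d observations\n",
              x$measure, x$k, x$mean, x$n_obs))
  invisible(x)
}

#' Spatial entropy of a type grid
#'
#' Shannon entropy of the distribution of expressed cell types across the
#' grid at one time step: `H = -sum_s p(s) log2 p(s)` with `p(s)` the
#' fraction of cells in state `s`. Invariant under any permutation of cell
#' positions; bounded by `log2(alphabet)`.
#'
#' @param grid integer matrix or vector of cell types.
#' @return entropy in bits.
#' @export
spatial_entropy <- function(grid) {
  x <- as.vector(grid)
  if (!length(x)) stop("empty grid")
  p <- tabulate(match(x, unique(x)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Spatial entropy series of a trajectory
#'
#' @param trajectory an `nca_trajectory`.
#' @return numeric vector of length `steps + 1` (one value per recorded time).
#' @export
spatial_entropy_series <- function(trajectory) {
  apply(trajectory$types, 1L, spatial_entropy)
}

#' Per-cell information maps
#'
#' Computes, over a time window of a trajectory, a per-cell map of mean
#' active information storage (each cell's own type series) and a per-cell
#' map of mean incoming transfer entropy (averaged over the cell's open
#' incoming neighbor links; closed gap junctions are excluded). High values
#' at the former site of a lost organ indicate that spatial information about
#' the structure persists in the tissue after the structure itself is gone.
#'
#' @param trajectory an `nca_trajectory`.
#' @param k history length.
#' @param window integer vector of time steps to analyze (default: all
#'   recorded times); must contain at least `k + 2` steps.
#' @param gj optional [gap_junction_state()] defining open links (default:
#'   the trajectory's final gap-junction state).
#' @return a list with `ais` and `te`, both `height x width` matrices (bits).
#' @export
info_maps <- function(trajectory, k = 2L, window = NULL, gj = NULL) {
  times <- if (is.null(window)) seq_len(nrow(trajectory$types)) else
    as.integer(window) + 1L
  if (length(times) < k + 2L) stop("window too small for the history length")
  sym <- trajectory$types[times, , drop = FALSE]
  w <- trajectory$width; h <- trajectory$height
  n <- w * h
  open <- if (!is.null(gj)) gj$open else
    if (!is.null(trajectory$gj_open)) trajectory$gj_open else
      neighbor_index(w, h) > 0L
  nb <- neighbor_index(w, h)
  ais <- numeric(n); te <- numeric(n)
  for (i in seq_len(n)) {
    ais[i] <- local_ais(sym[, i], k)$mean
    srcs <- nb[i, open[i, ]]
    te[i] <- if (length(srcs)) {
      mean(vapply(srcs, function(j) local_te(sym[, j], sym[, i], k)$mean, 0))
    } else NA_real_
  }
  list(ais = matrix(ais, h, w), te = matrix(te, h, w))
}

#' Sliding-window information-dynamics series
#'
#' Mean AIS and mean incoming TE averaged over all cells, plus the spatial
#' entropy, evaluated on sliding windows across a trajectory; the standard
#' way to track information dynamics over a lifespan.
#'
#' @param trajectory an `nca_trajectory`.
#' @param k history length.
#' @param window window width in steps.
#' @param stride window stride in steps.
#' @return a data frame with columns `t_start`, `t_end`, `ais`, `te`, `se`
#'   (spatial entropy at the window end).
#' @export
info_series <- function(trajectory, k = 2L, window = 100L, stride = 10L) {
  n_t <- nrow(trajectory$types)
  starts <- seq(1L, max(1L, n_t - window + 1L), by = stride)
  out <- lapply(starts, function(s) {
    idx <- s:min(n_t, s + window - 1L)
    maps <- info_maps(trajectory, k = k, window = idx - 1L)
    data.frame(t_start = s - 1L, t_end = idx[length(idx)] - 1L,
               ais = mean(maps$ais), te = mean(maps$te, na.rm = TRUE),
               se = spatial_entropy(trajectory$types[idx[length(idx)], ]))
  })
  do.call(rbind, out)
}
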