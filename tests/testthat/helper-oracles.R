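# Independent reference implementations used to validate the package:
# deliberately naive (direct counting, exhaustive enumeration), sharing
# no code with the implementations they check.

# Circular-gap dispersion computed from first principles for one window,
# with the normalizer found by brute-force enumeration over ALL
# placements of k occurrences in a window of length W (rather than the
# closed form the package uses).
oracle_dispersion <- function(window, aa) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  W <- length(chars)
  pos <- which(chars == aa)
  k <- length(pos)
  if (k < 2) return(1)
  gap_sd <- function(p) stats::sd(c(diff(p), W - p[length(p)] + p[1]))
  sd_obs <- gap_sd(pos)
  placements <- utils::combn(W, k)
  sd_max <- max(apply(placements, 2, gap_sd))
  if (sd_max == 0) return(1)
  max(0, min(1, 1 - sd_obs / sd_max))
}

# Exhaustive per-window scan by direct counting; merging by unioning
# per-window residue sets.
oracle_passing_windows <- function(sequence, spec) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  W <- spec$window
  nw <- length(chars) - W + 1L
  if (nw < 1) return(integer(0))
  ok <- logical(nw)
  for (s in seq_len(nw)) {
    w <- chars[s:(s + W - 1)]
    np <- sum(w == spec$primary_aa)
    if (np < spec$primary_threshold * W - 1e-9) next
    if (!is.null(spec$secondary_aa)) {
      ns <- sum(w == spec$secondary_aa)
      if (ns < spec$secondary_threshold * W - 1e-9) next
    }
    dmin <- spec$dispersion_threshold - 1e-9
    pos_p <- which(w == spec$primary_aa)
    if (oracle_window_dispersion(pos_p, W) < dmin) next
    if (!is.null(spec$secondary_aa)) {
      pos_s <- which(w == spec$secondary_aa)
      if (oracle_window_dispersion(pos_s, W) < dmin) next
    }
    ok[s] <- TRUE
  }
  which(ok)
}

# Same statistic as oracle_dispersion but with the closed-form
# max-clustered normalizer (fast enough to run inside the window loop);
# equivalence of the two normalizers is asserted separately.
oracle_window_dispersion <- function(pos, W) {
  k <- length(pos)
  if (k < 2) return(1)
  gaps <- c(diff(pos), W - pos[k] + pos[1])
  gm <- c(rep(1, k - 1), W - k + 1)
  sd_max <- stats::sd(gm)
  if (sd_max == 0) return(1)
  max(0, min(1, 1 - stats::sd(gaps) / sd_max))
}

oracle_merge_intervals <- function(starts, W) {
  if (!length(starts)) return(data.frame(start = integer(0),
                                         end = integer(0)))
  covered <- sort(unique(unlist(lapply(starts, function(s)
    s:(s + W - 1L)))))
  brk <- which(diff(covered) > 1L)
  data.frame(start = covered[c(1L, brk + 1L)],
             end = covered[c(brk, length(covered))])
}

oracle_lcd_intervals <- function(sequence, spec) {
  oracle_merge_intervals(oracle_passing_windows(sequence, spec),
                         spec$window)
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, with probabilities from choose() products.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(NA_real_)
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  p_obs <- prob(a)
  sum(vapply(lo:hi, function(x) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) px else 0
  }, numeric(1)))
}

# Naive complete-linkage agglomeration returning the cophenetic
# distance matrix (comparison-robust to merge-order ambiguity).
oracle_complete_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(j, i) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Longest path to a root by exhaustive path enumeration.
oracle_longest_path <- function(parents, id) {
  pp <- parents[[id]]
  if (!length(pp)) return(0)
  1 + max(vapply(pp, function(p) oracle_longest_path(parents, p),
                 numeric(1)))
}

random_sequence <- function(L, freqs) {
  paste(sample(names(freqs), L, replace = TRUE, prob = freqs),
        collapse = "")
}
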