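# Sliding-window LCD scanner.
#
# A window passes for class "X" (primary) when the windowed fraction of X
# is >= the primary threshold and the linear dispersion of X is >= the
# dispersion threshold; for class "XY" (secondary) the fraction and
# dispersion criteria apply to X (primary threshold) and Y (secondary
# threshold, dispersion checked separately). Overlapping passing windows
# are merged into contiguous LCDs. Comparisons use a 1e-9 tolerance so
# exact-boundary compositions (e.g. 8/20 vs 0.40) pass deterministically.

.EPS <- 1e-9

#' Windowed composition of one amino acid
#'
#' Fraction of positions in \code{window} equal to \code{aa}. Non-canonical
#' letters (X, U, O, B, Z, ...) count toward the window length but never
#' toward any amino acid's composition.
#'
#' @param window Amino-acid string (length >= 1).
#' @param aa Single amino-acid letter.
#' @return Fraction in [0, 1].
#' @export
composition <- function(window, aa) {
  if (!nzchar(window)) stop("composition of an empty window is undefined")
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  aa <- toupper(aa)
  if (!aa %in% AA20) return(0)  # ambiguity codes never form a class
  sum(chars == aa) / length(chars)
}

#' Linear dispersion of one amino acid within a window
#'
#' Measures how evenly the occurrences of \code{aa} are spread across the
#' window, on [0, 1]: 1 for perfectly even spacing (and, by convention,
#' whenever fewer than two occurrences exist), decreasing toward 0 as the
#' occurrences cluster. Computed as 1 - sd(g)/sd(g_max), where g is the
#' circular gap vector between successive occurrences (the k - 1 gaps
#' between consecutive occurrence positions plus the wrap-around gap
#' W - last + first, so the k gaps always sum to W), and g_max is the
#' gap vector of the most clustered arrangement of the same occurrence
#' count (all k occurrences contiguous: k - 1 unit gaps and one gap of
#' W - k + 1). Perfectly periodic occurrences ("AGAGAG...") therefore
#' score exactly 1 regardless of phase.
#'
#' @param window Amino-acid string (length >= 2).
#' @param aa Single amino-acid letter.
#' @return Dispersion in [0, 1].
#' @export
linear_dispersion <- function(window, aa) {
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  W <- length(chars)
  if (W < 2) stop("linear dispersion needs a window of length >= 2")
  pos <- which(chars == toupper(aa))
  dispersion_from_positions(pos, W)
}

dispersion_from_positions <- function(pos, W) {
  k <- length(pos)
  if (k < 2) return(1)
  gaps <- c(diff(pos), W - pos[k] + pos[1])
  sd_obs <- stats::sd(gaps)
  var_max <- ((k - 1) + (W - k + 1)^2 - W^2 / k) / (k - 1)
  if (var_max <= .EPS) return(1)
  max(0, min(1, 1 - sd_obs / sqrt(var_max)))
}

# Per-window counts of `aa` for every window start, via running sums.
window_counts <- function(chars, aa, W) {
  L <- length(chars)
  nw <- L - W + 1L
  if (nw < 1L) return(integer(0))
  hit <- as.integer(chars == aa)
  cs <- c(0L, cumsum(hit))
  cs[(W + 1L):(L + 1L)] - cs[1:nw]
}

# Per-window linear dispersion of `aa` for every window start (vectorized).
window_dispersions <- function(chars, aa, W) {
  L <- length(chars)
  nw <- L - W + 1L
  if (nw < 1L) return(numeric(0))
  pos <- which(chars == aa)
  out <- rep(1, nw)
  if (length(pos) < 2) return(out)
  s <- seq_len(nw)
  i_first <- findInterval(s - 1L, pos) + 1L
  i_last <- findInterval(s + W - 1L, pos)
  k <- i_last - i_first + 1L
  sel <- which(k >= 2L)
  if (!length(sel)) return(out)
  cum <- c(0, cumsum(diff(pos)^2))
  internal <- cum[i_last[sel]] - cum[i_first[sel]]
  wrap <- W - (pos[i_last[sel]] - pos[i_first[sel]])
  ks <- k[sel]
  varr <- (internal + wrap^2 - W^2 / ks) / (ks - 1)
  var_max <- ((ks - 1) + (W - ks + 1)^2 - W^2 / ks) / (ks - 1)
  disp <- ifelse(var_max <= .EPS, 1,
                 1 - sqrt(pmax(varr, 0)) / sqrt(var_max))
  out[sel] <- pmax(0, pmin(1, disp))
  out
}

#' Window start positions passing an LCD class search
#'
#' Slides a window of the spec's size along the sequence with unit step
#' and returns the 1-based starts of all windows meeting the composition
#' and dispersion criteria. Sequences shorter than the window yield an
#' empty result.
#'
#' @param sequence Amino-acid string.
#' @param spec An \code{\link{lcd_class_spec}}.
#' @return Integer vector of passing window starts (ascending).
#' @export
find_passing_windows <- function(sequence, spec) {
  if (!inherits(spec, "lcd_class_spec"))
    stop("spec must be an lcd_class_spec")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  passing_starts(chars, spec)
}

passing_starts <- function(chars, spec,
                           comp_cache = NULL, disp_cache = NULL) {
  W <- spec$window
  nw <- length(chars) - W + 1L
  if (nw < 1L) return(integer(0))
  getc <- function(aa) {
    if (!is.null(comp_cache)) comp_cache(aa) else window_counts(chars, aa, W)
  }
  getd <- function(aa) {
    if (!is.null(disp_cache)) disp_cache(aa) else
      window_dispersions(chars, aa, W)
  }
  cnt_p <- getc(spec$primary_aa)
  need_p <- spec$primary_threshold * W - .EPS
  pass <- cnt_p >= need_p
  if (!any(pass)) return(integer(0))
  if (!is.null(spec$secondary_aa)) {
    cnt_s <- getc(spec$secondary_aa)
    pass <- pass & (cnt_s >= spec$secondary_threshold * W - .EPS)
    if (!any(pass)) return(integer(0))
  }
  dmin <- spec$dispersion_threshold - .EPS
  pass <- pass & (getd(spec$primary_aa) >= dmin)
  if (!is.null(spec$secondary_aa) && any(pass))
    pass <- pass & (getd(spec$secondary_aa) >= dmin)
  which(pass)
}

#' Merge overlapping passing windows into contiguous intervals
#'
#' Maximal runs of windows with contiguous residue coverage (overlapping
#' or directly abutting spans) are merged into a single interval
#' [min start, max start + W - 1]; the result is a set of disjoint,
#' sorted intervals separated by uncovered residues.
#'
#' @param starts Sorted, distinct 1-based window starts.
#' @param W Window size.
#' @return data.frame with columns \code{start}, \code{end} (1-based,
#'   inclusive).
#' @export
merge_windows <- function(starts, W) {
  if (!length(starts))
    return(data.frame(start = integer(0), end = integer(0)))
  starts <- as.integer(starts)
  W <- as.integer(W)
  if (is.unsorted(starts, strictly = TRUE))
    stop("starts must be sorted ascending and distinct")
  brk <- which(diff(starts) > W)
  first <- c(1L, brk + 1L)
  last <- c(brk, length(starts))
  data.frame(start = starts[first], end = starts[last] + W - 1L)
}

lcd_row_names <- c("accession", "class_label", "start", "end", "length",
                   "sequence", "primary_comp", "secondary_comp")

empty_lcd_table <- function(with_proteome_id = FALSE) {
  df <- data.frame(accession = character(0), class_label = character(0),
                   start = integer(0), end = integer(0),
                   length = integer(0), sequence = character(0),
                   primary_comp = numeric(0), secondary_comp = numeric(0),
                   stringsAsFactors = FALSE)
  if (with_proteome_id)
    df <- cbind(data.frame(proteome_id = character(0),
                           stringsAsFactors = FALSE), df)
  df
}

#' Scan one protein for LCDs of one class
#'
#' Finds all passing windows, merges them, and reports each merged
#' interval as an LCD with composition computed over the full merged span.
#' Merged spans are not re-filtered: every constituent window already
#' passed the thresholds.
#'
#' @param sequence Amino-acid string.
#' @param spec An \code{\link{lcd_class_spec}}.
#' @param accession Protein identifier attached to the output rows.
#' @return data.frame with one row per LCD: accession, class_label,
#'   start, end, length, sequence, primary_comp, secondary_comp
#'   (NA for primary classes).
#' @export
scan_protein <- function(sequence, spec, accession = "protein") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  starts <- passing_starts(chars, spec)
  lcds_from_starts(chars, starts, spec, accession)
}

lcds_from_starts <- function(chars, starts, spec, accession) {
  if (!length(starts)) return(empty_lcd_table())
  iv <- merge_windows(starts, spec$window)
  n <- nrow(iv)
  seqs <- character(n)
  pc <- numeric(n)
  sc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    span <- chars[iv$start[i]:iv$end[i]]
    seqs[i] <- paste(span, collapse = "")
    len <- length(span)
    pc[i] <- sum(span == spec$primary_aa) / len
    if (!is.null(spec$secondary_aa))
      sc[i] <- sum(span == spec$secondary_aa) / len
  }
  data.frame(accession = accession, class_label = spec$label,
             start = iv$start, end = iv$end,
             length = iv$end - iv$start + 1L,
             sequence = seqs, primary_comp = pc, secondary_comp = sc,
             stringsAsFactors = FALSE)
}

#' Amino-acid composition of a sequence span
#'
#' Named fractions over the 20 canonical amino acids; non-canonical
#' letters contribute to the denominator only, so the fractions sum to
#' at most 1.
#'
#' @param sequence Amino-acid string.
#' @return Named numeric vector of length 20.
#' @export
lcd_composition <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  counts <- vapply(AA20, function(a) sum(chars == a), numeric(1))
  counts / length(chars)
}

#' Scan a whole proteome for LCDs of many classes
#'
#' Runs \code{\link{scan_protein}} for every (protein, class) pair. For
#' efficiency the per-window composition counts and dispersion values of
#' each amino acid are computed once per protein and shared across the
#' class specs; the output is identical to independent per-class scans.
#'
#' @param p A \code{\link{proteome}}.
#' @param specs List of \code{\link{lcd_class_spec}} (e.g.
#'   \code{\link{all_class_specs}()}).
#' @return data.frame of LCDs with a leading \code{proteome_id} column.
#' @export
scan_proteome <- function(p, specs = all_class_specs()) {
  stopifnot(inherits(p, "proteome"))
  if (inherits(specs, "lcd_class_spec")) specs <- list(specs)
  out <- vector("list", length(p$sequences))
  for (pi in seq_along(p$sequences)) {
    chars <- strsplit(toupper(p$sequences[[pi]]), "", fixed = TRUE)[[1]]
    acc <- names(p$sequences)[pi]
    comp_env <- new.env(parent = emptyenv())
    disp_env <- new.env(parent = emptyenv())
    rows <- list()
    for (spec in specs) {
      key <- function(aa) paste0(aa, "_", spec$window)
      comp_cache <- function(aa) {
        k <- key(aa)
        v <- comp_env[[k]]
        if (is.null(v)) {
          v <- window_counts(chars, aa, spec$window)
          comp_env[[k]] <- v
        }
        v
      }
      disp_cache <- function(aa) {
        k <- key(aa)
        v <- disp_env[[k]]
        if (is.null(v)) {
          v <- window_dispersions(chars, aa, spec$window)
          disp_env[[k]] <- v
        }
        v
      }
      starts <- passing_starts(chars, spec, comp_cache, disp_cache)
      if (length(starts))
        rows[[length(rows) + 1L]] <-
          lcds_from_starts(chars, starts, spec, acc)
    }
    if (length(rows)) out[[pi]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else empty_lcd_table()
  cbind(data.frame(proteome_id = rep(p$proteome_id, nrow(res)),
                   stringsAsFactors = FALSE), res)
}
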