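## Seed-and-extend tandem-repeat detection plus control-region domain
## partitioning. This is deliberately not a reimplementation of Tandem
## Repeats Finder's alignment/statistical model: an exact k-mer recurrence
## seed at distance p, identity-bounded merging and consensus-anchored
## X-drop boundary refinement reproduce the quantities of interest (period,
## fractional copy number, consensus, identity) and are fully
## oracle-testable.

## minimum exact seed-run length so that i.i.d. random sequence of the
## scanned length is expected to produce < alpha chance seeds across all
## scanned periods: solves L * P * (1/4)^r <= alpha.
min_seed_run <- function(L, n_periods, alpha) {
  max(2L, as.integer(ceiling(log(L * n_periods / alpha) / log(4))))
}

#' Detect tandem repeats in a DNA sequence
#'
#' For each candidate period `p`, positions where the base equals the base
#' `p` positions downstream are computed; maximal runs of such matches at
#' least as long as a chance-significance threshold (and at least `p`, so a
#' full period is exactly repeated somewhere) seed candidate arrays. Seed
#' runs are merged while the identity of the merged span stays at or above
#' `min_identity` and the bridge between them itself looks periodic; array
#' boundaries are then refined by X-drop extension against the phased core
#' consensus (match +1, mismatch -2, an advance must beat the running
#' maximum by 2), which tolerates isolated mutations near the edges without
#' drifting into random background. The consensus is the position-wise
#' majority over period-phased columns; overlapping candidates across
#' periods are resolved by keeping the highest `length * identity` score,
#' with harmonic candidates (period a multiple of an equally good shorter
#' period) suppressed in favour of the fundamental period.
#'
#' @param sequence DNA string, length at least `2 * min_period`.
#' @param min_period,max_period Period range in bp (the scan is capped at
#'   `floor(length/2)`).
#' @param min_identity Minimum fraction of array positions matching the
#'   consensus.
#' @param min_copies Minimum fractional copy number (array length / period).
#' @param seed_alpha Expected number of chance seed runs tolerated in a
#'   random sequence of this length; the seed-length threshold is derived
#'   from it (smaller = more conservative).
#' @return `data.frame` with columns `start`, `end` (1-based inclusive),
#'   `period`, `copy_number`, `consensus`, `identity`, sorted by `start`;
#'   zero rows when nothing is found.
#' @export
#' @examples
#' find_tandem_repeats("ACGACGACG", min_period = 3)
find_tandem_repeats <- function(sequence, min_period = 2L, max_period = 12L,
                                min_identity = 0.85, min_copies = 2,
                                seed_alpha = 0.05) {
  sequence <- toupper(sequence)
  validate_dna(sequence)
  L <- nchar(sequence)
  if (min_period < 1L || max_period < min_period) {
    stop("invalid period range", call. = FALSE)
  }
  if (min_identity <= 0 || min_identity > 1 || min_copies < 1 || seed_alpha <= 0) {
    stop("invalid detector parameters", call. = FALSE)
  }
  if (L < 2L * min_period) stop("sequence shorter than twice min_period", call. = FALSE)
  ch <- seq_chars(sequence)
  periods <- seq.int(min_period, min(max_period, L %/% 2L))
  r_min <- min_seed_run(L, length(periods), seed_alpha)

  candidates <- list()
  for (p in periods) {
    m <- ch[seq_len(L - p)] == ch[seq_len(L - p) + p]
    runs <- true_runs(m)
    runs <- runs[runs$len >= max(p, r_min), , drop = FALSE]
    if (nrow(runs) == 0L) next
    ## merge neighbouring runs while merged-span periodicity identity holds
    merged <- merge_runs(runs, m, p, min_identity = min_identity)
    for (k in seq_len(nrow(merged))) {
      a <- merged$start[k]
      b <- merged$end[k] + p            # array spans the trailing period copy
      ## X-drop boundary extension against the core consensus (comparing to
      ## the consensus, not to the base one period back, means an edge
      ## mutation costs one mismatch instead of two)
      core_cons <- phased_consensus(ch[a:b], p)$consensus
      ## boundaries are re-derived from a 2-base-retracted core so that a
      ## chance match sitting at a seed-run edge must be re-earned by the
      ## advance rule instead of being inherited from the run
      b <- xdrop_extend(ch, max(a, b - 2L), p, L, dir = +1L,
                        anchor = a, cons = core_cons)
      a <- xdrop_extend(ch, min(b, a + 2L), p, L, dir = -1L,
                        anchor = a, cons = core_cons)
      arr <- ch[a:b]
      cons <- phased_consensus(arr, p)
      identity <- mean(arr == cons$expanded)
      copy <- (b - a + 1L) / p
      if (copy + 1e-9 >= min_copies && identity >= min_identity) {
        candidates[[length(candidates) + 1L]] <-
          data.frame(start = a, end = b, period = p, copy_number = copy,
                     consensus = cons$consensus, identity = identity,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(candidates)) {
    return(data.frame(start = integer(0), end = integer(0), period = integer(0),
                      copy_number = numeric(0), consensus = character(0),
                      identity = numeric(0)))
  }
  cand <- do.call(rbind, candidates)
  ## fundamental-period preference: a candidate whose period is a multiple
  ## of an overlapping candidate's period is dominated by it unless it
  ## scores substantially better (a mutated array always spawns harmonic
  ## candidates at 2p, 3p, ... with near-identical score; report p)
  score <- (cand$end - cand$start + 1L) * cand$identity
  dominated <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    for (k in seq_len(nrow(cand))) {
      if (i == k || cand$period[k] >= cand$period[i]) next
      if (cand$period[i] %% cand$period[k] != 0L) next
      ov <- min(cand$end[i], cand$end[k]) - max(cand$start[i], cand$start[k]) + 1L
      if (ov >= 0.5 * (cand$end[i] - cand$start[i] + 1L) &&
          score[k] >= 0.9 * score[i]) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  cand <- cand[!dominated, , drop = FALSE]
  score <- score[!dominated]
  ## resolve remaining overlaps: best score first, shorter period breaks ties
  cand <- cand[order(-score, cand$period, cand$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    clash <- which(keep & cand$start <= cand$end[i] & cand$end >= cand$start[i])
    if (!length(clash)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## extend an array boundary at `pos` outwards (dir +1 right / -1 left),
## scoring each base against the phased consensus (match +1, mismatch -2),
## X-drop termination, boundary at the running-maximum position
xdrop_extend <- function(ch, pos, p, L, dir, anchor, cons, xdrop = 8L) {
  cch <- seq_chars(cons)
  score <- 0L; best <- 0L; best_pos <- pos
  i <- pos; streak <- 0L
  repeat {
    i <- i + dir
    if (i < 1L || i > L) break
    match <- ch[i] == cch[((i - anchor) %% p) + 1L]
    score <- score + if (match) 1L else -2L
    streak <- if (match) streak + 1L else 0L
    ## lone chance matches (1/4 per background base) must not move the
    ## boundary, neither at the seed edge nor after a recovered tail:
    ## each advance must beat the previous maximum by at least 2
    if (score >= best + 2L) { best <- score; best_pos <- i }
    if (score <= best - xdrop) break
  }
  best_pos
}

## maximal runs of TRUE in a logical vector -> data.frame(start, end, len)
true_runs <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  data.frame(start = starts[sel], end = ends[sel], len = r$lengths[sel])
}

## merge successive seed runs while the periodicity identity of the merged
## match-span stays >= min_identity (no distance cap: random interleaving
## sequence has ~0.25 identity and blocks the merge by itself)
merge_runs <- function(runs, m, p, min_identity) {
  out <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      last <- nrow(out)
      span_id <- mean(m[out$start[last]:runs$end[i]])
      ## the bridge between the runs must itself look periodic (~0.25
      ## identity for random interleaving sequence): a long array must not
      ## absorb a distant chance run by diluting the span average
      bridge <- seq.int(out$end[last] + 1L, runs$start[i] - 1L)
      ## short bridges are what a single interior mutation leaves behind
      ## ([F, T x (p-1), F], identity (p-1)/(p+1)) and always merge; long
      ## ones must themselves look periodic
      bridge_ok <- length(bridge) <= 2L * p || mean(m[bridge]) >= 0.5
      if (span_id >= min_identity && bridge_ok) {
        out$end[last] <- runs$end[i]
        out$len[last] <- out$end[last] - out$start[last] + 1L
      } else {
        out <- rbind(out, runs[i, ])
      }
    }
  }
  out
}

## position-wise majority consensus over period-phased columns
phased_consensus <- function(arr, p) {
  phase <- ((seq_along(arr) - 1L) %% p) + 1L
  cons <- vapply(seq_len(p), function(k) {
    tab <- table(factor(arr[phase == k], levels = c(DNA_BASES, "N")))
    names(tab)[which.max(tab)]
  }, character(1))
  list(consensus = seq_collapse(cons), expanded = cons[phase])
}

#' Partition a control region into labelled domains
#'
#' Splits a CR sequence at user-supplied anchor coordinates (the canonical
#' mammalian domains are ETAS1/ETAS2, the central domain CD, and CSB1-3;
#' their motifs vary across taxa, so anchors are supplied, not detected).
#' Unlabelled gaps between anchors are reported as `"."` segments; each
#' segment carries its [composition_profile()].
#'
#' @param cr_sequence CR DNA string.
#' @param anchors `data.frame` with columns `label`, `start`, `end` (1-based
#'   inclusive within the CR), sorted and non-overlapping; `NULL` for a
#'   single unlabelled segment.
#' @return `data.frame`: `label`, `start`, `end`, `length_bp` plus the
#'   composition columns of [composition_profile()].
#' @export
#' @examples
#' cr_domains(strrep("ACGT", 50), data.frame(label = c("ETAS1", "ETAS2"),
#'                                           start = c(1, 61), end = c(60, 127)))
cr_domains <- function(cr_sequence, anchors = NULL) {
  cr_sequence <- toupper(cr_sequence)
  L <- nchar(cr_sequence)
  if (is.null(anchors) || nrow(anchors) == 0L) {
    anchors <- data.frame(label = ".", start = 1L, end = L,
                          stringsAsFactors = FALSE)
  }
  anchors$start <- as.integer(anchors$start)
  anchors$end <- as.integer(anchors$end)
  if (any(anchors$start > anchors$end) || any(anchors$start < 1L) ||
      any(anchors$end > L)) {
    stop("anchors out of CR bounds", call. = FALSE)
  }
  if (is.unsorted(anchors$start, strictly = TRUE)) {
    stop("anchors must be sorted by start", call. = FALSE)
  }
  if (nrow(anchors) > 1L &&
      any(anchors$start[-1L] <= anchors$end[-nrow(anchors)])) {
    stop("anchors overlap", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    s <- substr(cr_sequence, anchors$start[i], anchors$end[i])
    prof <- composition_profile(s, anchors$label[i])
    cbind(data.frame(label = anchors$label[i], start = anchors$start[i],
                     end = anchors$end[i],
                     length_bp = anchors$end[i] - anchors$start[i] + 1L,
                     stringsAsFactors = FALSE),
          prof[, setdiff(names(prof), c("region_class", "length_bp"))])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
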