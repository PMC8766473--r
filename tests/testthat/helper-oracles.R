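## Independent oracles. These deliberately re-derive quantities from first
## principles (direct enumeration over explicitly materialised objects)
## rather than sharing code paths with the package.

ORACLE_CODE <- Biostrings::getGeneticCode("2")
ORACLE_STOPS <- names(ORACLE_CODE)[ORACLE_CODE == "*"]

## every ordering of a vector, as a matrix of rows (iterative heap-style
## construction, distinct from the package's recursive generator)
oracle_orderings <- function(v) {
  out <- matrix(v[1], nrow = 1)
  for (k in seq_along(v)[-1]) {
    grown <- list()
    for (r in seq_len(nrow(out))) {
      row <- out[r, ]
      for (pos in 0:length(row)) {
        grown[[length(grown) + 1]] <- append(row, v[k], after = pos)
      }
    }
    out <- do.call(rbind, grown)
  }
  out
}

## NG86 pathway enumeration: average syn/nonsyn steps over all mutation
## orderings whose intermediates avoid stop codons
oracle_count_differences <- function(a, b) {
  pa <- strsplit(a, "")[[1]]; pb <- strsplit(b, "")[[1]]
  dpos <- which(pa != pb)
  if (length(dpos) == 0) return(c(sd = 0, nd = 0))
  ords <- oracle_orderings(dpos)
  tot_s <- c(); tot_n <- c()
  for (r in seq_len(nrow(ords))) {
    cur <- pa; s <- 0; n <- 0; blocked <- FALSE
    for (pos in ords[r, ]) {
      before <- paste(cur, collapse = "")
      cur[pos] <- pb[pos]
      after <- paste(cur, collapse = "")
      if (after %in% ORACLE_STOPS) { blocked <- TRUE; break }
      if (ORACLE_CODE[[before]] == ORACLE_CODE[[after]]) s <- s + 1 else n <- n + 1
    }
    if (!blocked) { tot_s <- c(tot_s, s); tot_n <- c(tot_n, n) }
  }
  if (!length(tot_s)) return(NULL)  # all pathways blocked
  c(sd = mean(tot_s), nd = mean(tot_n))
}

## fractional synonymous sites of one codon by direct enumeration
oracle_count_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; ok <- 0
    for (bb in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      mut <- ch; mut[pos] <- bb
      mc <- paste(mut, collapse = "")
      if (mc %in% ORACLE_STOPS) next
      ok <- ok + 1
      if (ORACLE_CODE[[mc]] == ORACLE_CODE[[codon]]) syn <- syn + 1
    }
    if (ok > 0) s <- s + syn / ok
  }
  c(s = s, n = 3 - s)
}

## brute-force overlap of two features as a position-set intersection
oracle_overlap_bp <- function(s1, e1, s2, e2) {
  length(intersect(seq(s1, e1), seq(s2, e2)))
}
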