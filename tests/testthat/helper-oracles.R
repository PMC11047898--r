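# Independent brute-force oracles: direct pair enumeration and set
# arithmetic, deliberately naive, never sharing code with the package.

oracle_hd <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  n <- length(labels)
  if (n < 2) return(0)
  diff <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (labels[i] != labels[j]) diff <- diff + 1
  }
  diff / choose(n, 2)
}

# seqs: character vector of residue strings (already on used columns)
oracle_pair_diffs <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  sum(a != b)
}

oracle_K <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + oracle_pair_diffs(seqs[i], seqs[j])
  }
  tot / choose(n, 2)
}

oracle_dxy <- function(seqs_a, seqs_b, L) {
  tot <- 0
  for (i in seq_along(seqs_a)) for (j in seq_along(seqs_b)) {
    tot <- tot + oracle_pair_diffs(seqs_a[i], seqs_b[j])
  }
  tot / (length(seqs_a) * length(seqs_b) * L)
}

oracle_fst <- function(seqs_a, seqs_b) {
  hw <- (oracle_K(seqs_a) + oracle_K(seqs_b)) / 2
  hb <- 0
  for (i in seq_along(seqs_a)) for (j in seq_along(seqs_b)) {
    hb <- hb + oracle_pair_diffs(seqs_a[i], seqs_b[j])
  }
  hb <- hb / (length(seqs_a) * length(seqs_b))
  1 - hw / hb
}

# naive per-haplotype unit-splitting of richness
oracle_contrib_RT <- function(counts) {
  K <- ncol(counts)
  rt <- rep(0, K)
  names(rt) <- colnames(counts)
  for (h in seq_len(nrow(counts))) {
    carriers <- which(counts[h, ] > 0)
    for (k in carriers) rt[k] <- rt[k] + 1 / length(carriers)
  }
  rt
}

# random gap-free alignment with population structure, for oracle sweeps
random_test_alignment <- function(seed, n_max = 30, L_max = 50,
                                  n_pops = 2) {
  set.seed(seed)
  n <- sample(max(4, n_pops * 2):n_max, 1)
  L <- sample(10:L_max, 1)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    nmut <- sample(0:max(1, L %/% 3), 1)
    if (nmut > 0) {
      pos <- sample(L, nmut)
      s[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  ids <- sprintf("s%03d", seq_len(n))
  pops <- stats::setNames(
    paste0("P", rep_len(seq_len(n_pops), n)), ids)
  attr(pops, "pop_order") <- paste0("P", seq_len(n_pops))
  list(aln = hap_alignment(ids, seqs), pops = pops, L = L)
}
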