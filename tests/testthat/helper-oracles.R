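# Deliberately naive reference implementations used as independent oracles.
# They share no code with the package: the genetic code is spelled out from
# the standard table, pathways are enumerated by explicit permutation, and
# family building is a literal transitive closure.

oracle_codon_table <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- character(0)
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons <- c(codons, paste0(b1, b2, b3))
  }
  stats::setNames(aa, codons)
}

# Synonymous sites of one codon: at each position, the fraction of the
# non-stop single-nucleotide alternatives that leave the amino acid unchanged.
oracle_syn_sites <- function(codon) {
  tab <- oracle_codon_table()
  this_aa <- tab[[codon]]
  s <- 0
  for (i in 1:3) {
    syn <- 0L
    ok <- 0L
    for (b in c("A", "C", "G", "T")) {
      alt <- codon
      substr(alt, i, i) <- b
      if (alt == codon) next
      if (tab[[alt]] == "*") next
      ok <- ok + 1L
      if (tab[[alt]] == this_aa) syn <- syn + 1L
    }
    if (ok > 0L) s <- s + syn / ok
  }
  s
}

oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (tail in oracle_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], tail)
    }
  }
  out
}

# Synonymous / nonsynonymous differences between two codons, averaged over
# all minimal mutational pathways; pathways visiting a stop codon are
# excluded unless every pathway does.
oracle_pair_diffs <- function(c1, c2) {
  tab <- oracle_codon_table()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, non = 0))
  rows <- lapply(oracle_permutations(pos), function(ord) {
    cur <- c1
    syn <- 0
    non <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tab[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (tab[[cur]] == tab[[nxt]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn = syn, non = non, blocked = as.numeric(blocked))
  })
  m <- do.call(rbind, rows)
  use <- m[m[, "blocked"] == 0, , drop = FALSE]
  if (nrow(use) == 0) use <- m
  c(syn = mean(use[, "syn"]), non = mean(use[, "non"]))
}

oracle_jc <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

# Full NG86 Ka/Ks on two equal-length, gap-free coding sequences.
oracle_ng86 <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) == nchar(seq_b), nchar(seq_a) %% 3 == 0)
  n_codons <- nchar(seq_a) / 3
  S1 <- S2 <- sd <- nd <- 0
  for (k in seq_len(n_codons)) {
    ca <- substr(seq_a, 3 * k - 2, 3 * k)
    cb <- substr(seq_b, 3 * k - 2, 3 * k)
    S1 <- S1 + oracle_syn_sites(ca)
    S2 <- S2 + oracle_syn_sites(cb)
    d <- oracle_pair_diffs(ca, cb)
    sd <- sd + d[["syn"]]
    nd <- nd + d[["non"]]
  }
  S <- (S1 + S2) / 2
  N <- 3 * n_codons - S
  ps <- if (S > 0) sd / S else NA_real_
  pn <- if (N > 0) nd / N else NA_real_
  list(S = S, N = N, sd = sd, nd = nd, ps = ps, pn = pn,
       ks = oracle_jc(ps), ka = oracle_jc(pn))
}

# Literal transitive closure of a thresholded edge list: repeatedly merge any
# two groups linked by a kept edge until nothing changes.
oracle_components <- function(edges, genes, level) {
  groups <- lapply(genes, function(g) g)
  keep <- edges[edges$identity_pct > level & edges$coverage_pct > level, , drop = FALSE]
  repeat {
    merged <- FALSE
    if (nrow(keep) > 0) {
      for (r in seq_len(nrow(keep))) {
        ia <- which(vapply(groups, function(g) keep$query_id[r] %in% g, logical(1)))
        ib <- which(vapply(groups, function(g) keep$subject_id[r] %in% g, logical(1)))
        if (ia != ib) {
          groups[[ia]] <- c(groups[[ia]], groups[[ib]])
          groups[[ib]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  lapply(groups, function(g) sort(unique(g)))
}

# Welch two-sample t statistic from the textbook formula.
oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}
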