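# Precomputed Nei-Gojobori (1986) lookup tables: per-codon synonymous site
# counts and, for every ordered codon pair, synonymous/nonsynonymous
# difference counts averaged over minimal mutational pathways.
#
# Conventions (stated in the methods vignette): single-nucleotide changes to
# stop codons are removed from the per-position site denominator; pathways
# passing through a stop codon are excluded from the pathway average unless
# every pathway does.

.ng86_env <- new.env(parent = emptyenv())

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.syn_sites_one <- function(codon, code) {
  aa <- code[[codon]]
  if (aa == "*") return(NA_real_)
  s <- 0
  for (i in 1:3) {
    alts <- vapply(c("A", "C", "G", "T"), function(b) {
      x <- codon
      substr(x, i, i) <- b
      x
    }, character(1))
    alts <- alts[alts != codon]
    alt_aa <- code[alts]
    alt_aa <- alt_aa[alt_aa != "*"]
    if (length(alt_aa) > 0) s <- s + sum(alt_aa == aa) / length(alt_aa)
  }
  s
}

# All orderings of the differing positions, built iteratively.
.pos_orders <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Pathway enumeration on integer codon indices (digits base 4) for speed.
.pair_diffs_digits <- function(d1, d2, aa_idx, is_stop) {
  w <- c(16L, 4L, 1L)
  i2 <- sum(d2 * w) + 1L
  diffpos <- which(d1 != d2)
  ndp <- length(diffpos)
  if (ndp == 0) return(c(0, 0))
  orders <- .pos_orders[[as.character(ndp)]]
  syn <- non <- blocked <- numeric(length(orders))
  for (o in seq_along(orders)) {
    cur <- d1
    cur_i <- sum(cur * w) + 1L
    for (p in diffpos[orders[[o]]]) {
      nxt_i <- cur_i + (d2[p] - cur[p]) * w[p]
      if (is_stop[nxt_i] && nxt_i != i2) blocked[o] <- 1
      if (aa_idx[cur_i] == aa_idx[nxt_i]) syn[o] <- syn[o] + 1
      else non[o] <- non[o] + 1
      cur[p] <- d2[p]
      cur_i <- nxt_i
    }
  }
  ok <- which(blocked == 0)
  if (length(ok) == 0) ok <- seq_along(orders)
  c(mean(syn[ok]), mean(non[ok]))
}

ng86_tables <- function() {
  if (!is.null(.ng86_env$sites)) {
    return(list(sites = .ng86_env$sites, sd = .ng86_env$sd, nd = .ng86_env$nd))
  }
  code <- genetic_code()
  codons <- .all_codons()
  sites <- vapply(codons, .syn_sites_one, numeric(1), code = code)
  aa <- unname(code[codons])
  aa_idx <- match(aa, unique(aa))
  is_stop <- aa == "*"
  digits <- cbind((seq_len(64) - 1L) %/% 16L,
                  ((seq_len(64) - 1L) %/% 4L) %% 4L,
                  (seq_len(64) - 1L) %% 4L)
  sd <- nd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  for (i in which(!is_stop)) {
    for (j in which(!is_stop)) {
      d <- .pair_diffs_digits(digits[i, ], digits[j, ], aa_idx, is_stop)
      sd[i, j] <- d[1]
      nd[i, j] <- d[2]
    }
  }
  .ng86_env$sites <- sites
  .ng86_env$sd <- sd
  .ng86_env$nd <- nd
  list(sites = sites, sd = sd, nd = nd)
}
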