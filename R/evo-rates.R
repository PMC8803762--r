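#' Protein-guided codon alignment of two coding sequences
#'
#' Aligns the translations with a global Needleman-Wunsch alignment
#' (BLOSUM62, affine gaps) and threads the alignment back onto the
#' nucleotide sequences, so that every alignment column is one codon
#' (or a `---` gap triple).
#'
#' @param cds_a,cds_b Nucleotide coding sequences (character scalars),
#'   frame 0, length a multiple of 3, no internal stop codons. A single
#'   trailing stop codon is trimmed.
#' @param id_a,id_b Identifiers used in error messages.
#' @return An object of class `codon_alignment`: a list with character
#'   vectors `a` and `b` of aligned codons (gap codons are `"---"`).
#' @examples
#' aln <- codon_align("ATGGCTGCT", "ATGGCT")
#' aln$a
#' @export
codon_align <- function(cds_a, cds_b, id_a = "cds_a", id_b = "cds_b") {
  ca <- check_cds(cds_a, id_a)
  cb <- check_cds(cds_b, id_b)
  pa <- paste(genetic_code()[ca], collapse = "")
  pb <- paste(genetic_code()[cb], collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  out_a <- out_b <- character(length(sa))
  for (k in seq_along(sa)) {
    if (sa[k] == "-") {
      out_a[k] <- "---"
    } else {
      ia <- ia + 1L
      out_a[k] <- ca[ia]
    }
    if (sb[k] == "-") {
      out_b[k] <- "---"
    } else {
      ib <- ib + 1L
      out_b[k] <- cb[ib]
    }
  }
  structure(list(a = out_a, b = out_b), class = "codon_alignment")
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over minimal mutational pathways,
#' excluding pathways through stop codons) over the ungapped codon columns,
#' then applies the Jukes-Cantor correction
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4}{3} p)} to each raw proportion.
#' Gapped columns are dropped (pairwise deletion). A raw proportion at or
#' above 3/4 saturates the correction; the pair is then flagged and the
#' corresponding rate is `NA`.
#'
#' @param x Either a `codon_alignment` (see [codon_align()]) or a CDS
#'   character scalar (then `y` must be an equal-length CDS and the
#'   sequences are compared codon by codon without alignment).
#' @param y Second CDS when `x` is a character sequence.
#' @return A list: `ka`, `ks`, `omega` (`NA` when `ks` is 0 or saturated),
#'   `sites` (named `S`, `N`), `diffs` (named `sd`, `nd`), raw proportions
#'   `ps`, `pn`, and logical `saturated`.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @export
ng86 <- function(x, y = NULL) {
  if (inherits(x, "codon_alignment")) {
    ca <- x$a
    cb <- x$b
  } else {
    ca <- check_cds(x)
    cb <- check_cds(y)
    if (length(ca) != length(cb)) {
      stop("unaligned sequences of different codon length; use codon_align()")
    }
  }
  keep <- ca != "---" & cb != "---"
  ca <- ca[keep]
  cb <- cb[keep]
  if (length(ca) == 0) stop("no ungapped codon columns to compare")
  tabs <- ng86_tables()
  S <- (sum(tabs$sites[ca]) + sum(tabs$sites[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, rownames(tabs$sd)), match(cb, colnames(tabs$sd)))
  sd <- sum(tabs$sd[idx])
  nd <- sum(tabs$nd[idx])
  ps <- if (S > 0) sd / S else NA_real_
  pn <- if (N > 0) nd / N else NA_real_
  saturated <- (!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75)
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  omega <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, omega = omega,
       sites = c(S = S, N = N), diffs = c(sd = sd, nd = nd),
       ps = ps, pn = pn, saturated = saturated)
}

#' Paralog/ortholog call for a gene pair
#'
#' @param gene_a,gene_b Gene identifiers.
#' @param species_map Named character vector mapping gene id to species.
#' @return `"paralog"` (same species) or `"ortholog"` (different species).
#' @export
classify_pair <- function(gene_a, gene_b, species_map) {
  sa <- unname(species_map[gene_a])
  sb <- unname(species_map[gene_b])
  if (is.na(sa) || is.na(sb)) {
    stop("missing species for gene ", if (is.na(sa)) gene_a else gene_b)
  }
  if (sa == sb) "paralog" else "ortholog"
}

#' Fraction of gene pairs under positive selection
#'
#' Counts pairs with Ka/Ks greater than 1 and reports the percentage (two
#' decimals, half-up). Pairs with Ka/Ks within 0.01 of 1 are additionally
#' reported as neutral candidates. `NA` ratios (Ks = 0 or saturation) are
#' excluded from the total.
#'
#' @param omega Numeric vector of Ka/Ks ratios (`NA` allowed).
#' @return List with `count_gt1`, `total`, `percent`, `neutral_candidates`.
#' @export
positive_selection_fraction <- function(omega) {
  omega <- omega[!is.na(omega)]
  total <- length(omega)
  count <- sum(omega > 1)
  list(count_gt1 = count, total = total,
       percent = pct(count, total),
       neutral_candidates = sum(abs(omega - 1) <= 0.01))
}

#' Nucleotide diversity (Pi) of a gene family
#'
#' Mean over all unordered member pairs of the proportion of differing
#' nucleotide positions among compared (mutually ungapped) columns.
#' Equal-length members are compared column by column; unequal lengths go
#' through the protein-guided codon alignment, with gap columns excluded
#' per pair (pairwise deletion).
#'
#' @param seqs Named character vector of member coding sequences (>= 2).
#' @return List with `pi` and `n_pairs`; `pi` is `NA` for fewer than two
#'   members.
#' @export
nucleotide_diversity <- function(seqs) {
  if (length(seqs) < 2) return(list(pi = NA_real_, n_pairs = 0L))
  pairs <- utils::combn(length(seqs), 2)
  props <- apply(pairs, 2, function(ij) {
    a <- toupper(seqs[[ij[1]]])
    b <- toupper(seqs[[ij[2]]])
    if (nchar(a) == nchar(b)) {
      va <- strsplit(a, "")[[1]]
      vb <- strsplit(b, "")[[1]]
    } else {
      aln <- codon_align(a, b)
      keep <- aln$a != "---" & aln$b != "---"
      va <- strsplit(paste(aln$a[keep], collapse = ""), "")[[1]]
      vb <- strsplit(paste(aln$b[keep], collapse = ""), "")[[1]]
    }
    mean(va != vb)
  })
  list(pi = mean(props), n_pairs = ncol(pairs))
}

#' Dating parameters: per-generation mutation rate and generation time
#'
#' Defaults follow the peach estimates used throughout: 9.48e-9 point
#' mutations per site per generation and 3 years per generation.
#'
#' @param mu Mutation rate per site per generation.
#' @param gen_years Years per generation.
#' @export
dating_params <- function(mu = 9.48e-9, gen_years = 3) {
  stopifnot(mu > 0, gen_years > 0)
  list(mu = mu, gen_years = gen_years)
}

#' Date a duplication event from its synonymous divergence
#'
#' Converts Ks into an age in million years as
#' `T = Ks * gen_years / mu / 1e6`. With the default parameters Ks = 0.1
#' gives 31.65 MY and Ks = 0.5 gives 158.23 MY (printed to two decimals).
#' Note no division by 2 for the two diverging lineages: the convention is
#' fixed so the dated Ks peaks reproduce the published divergence times.
#'
#' @param ks Synonymous substitutions per synonymous site (vectorised).
#' @param params A [dating_params()] list.
#' @return Age(s) in million years (unrounded; round for reporting).
#' @export
date_duplication <- function(ks, params = dating_params()) {
  if (any(is.na(ks)) || any(ks < 0)) stop("ks must be non-negative")
  ks * params$gen_years / params$mu / 1e6
}

#' Welch comparison of two groups with box-plot summaries
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return List with `t_statistic`, `p_value`, and a `summary` data frame
#'   (min, Q1, median, Q3, max, mean per group; type-7 quantiles).
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  five <- function(v) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5], mean = mean(v))
  }
  degenerate <- stats::var(values_a) == 0 && stats::var(values_b) == 0
  if (degenerate && isTRUE(all.equal(mean(values_a), mean(values_b)))) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  }
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       summary = data.frame(group = c("a", "b"),
                            rbind(five(values_a), five(values_b)),
                            row.names = NULL))
}

#' Histogram of Ks values with modal bins
#'
#' Bins are half-open intervals `[k*w, (k+1)*w)` over `[0, max_ks)`. A bin
#' is modal when its count is positive and not exceeded by either
#' neighbour; runs of equal counts are collapsed to their first bin.
#'
#' @param ks Numeric vector of Ks values, already filtered to `[0, max_ks)`.
#' @param bin_width Bin width (default 0.1).
#' @param max_ks Upper bound of the binned range (default 1).
#' @return List with a `bins` data frame (`lower`, `upper`, `count`) and
#'   `modal_bins`, the integer indices of the local maxima.
#' @export
ks_histogram <- function(ks, bin_width = 0.1, max_ks = 1) {
  if (any(ks < 0 | ks >= max_ks)) stop("ks values must lie in [0, max_ks)")
  nb <- ceiling(max_ks / bin_width)
  counts <- tabulate(floor(ks / bin_width) + 1L, nbins = nb)
  left <- c(0L, counts[-nb])
  right <- c(counts[-1], 0L)
  is_peak <- counts > 0 & counts >= left & counts >= right
  # collapse plateaus: keep a peak only if the previous bin is strictly lower
  modal <- which(is_peak & counts > left)
  list(bins = data.frame(lower = (seq_len(nb) - 1) * bin_width,
                         upper = seq_len(nb) * bin_width,
                         count = counts),
       modal_bins = modal)
}

#' Pairwise Ka/Ks statistics within gene families
#'
#' Runs [codon_align()] + [ng86()] for every unordered pair of members in
#' every multi-gene family, labels each pair paralog/ortholog, and dates it
#' from Ks. Pairs whose correction saturates are kept with `NA` rates.
#'
#' @param seqs Named character vector of coding sequences (names are gene
#'   ids, `species|gene` format or any ids covered by `species_map`).
#' @param membership Data frame with columns `gene_id`, `family_id`.
#' @param species_map Named character vector gene id -> species; defaults
#'   to the prefix before `|` in the gene ids.
#' @param params Dating parameters for the `t_my` column.
#' @return Data frame: `gene_a`, `gene_b`, `family_id`, `pair_type`, `ka`,
#'   `ks`, `omega`, `t_my`, `saturated`.
#' @export
family_pair_stats <- function(seqs, membership, species_map = NULL,
                              params = dating_params()) {
  species_map <- species_map %||%
    stats::setNames(species_of(names(seqs)), names(seqs))
  rows <- list()
  for (fam in unique(membership$family_id)) {
    members <- membership$gene_id[membership$family_id == fam]
    if (length(members) < 2) next
    prs <- utils::combn(members, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]
      b <- prs[2, k]
      est <- ng86(codon_align(seqs[[a]], seqs[[b]], a, b))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, family_id = fam,
        pair_type = classify_pair(a, b, species_map),
        ka = est$ka, ks = est$ks, omega = est$omega,
        t_my = if (is.na(est$ks)) NA_real_ else date_duplication(est$ks, params),
        saturated = est$saturated
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      family_id = character(), pair_type = character(),
                      ka = numeric(), ks = numeric(), omega = numeric(),
                      t_my = numeric(), saturated = logical()))
  }
  do.call(rbind, rows)
}
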