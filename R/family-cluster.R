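# Gene-family clustering from pairwise identity/coverage at the three
# stringency levels (> 70 / > 80 / > 90 percent, strict inequality on both
# criteria), with single-linkage connected components.

#' Pairwise identity and coverage of two coding sequences
#'
#' Best local alignment (match +1, mismatch -2, gap open -5, gap extend -2,
#' BLASTN-like defaults). Identity is matches over aligned columns; coverage
#' is the aligned span on the shorter sequence over that sequence's length.
#'
#' @param cds_a,cds_b Non-empty nucleotide strings.
#' @param id_a,id_b Identifiers for the returned edge.
#' @return One-row data frame: `query_id`, `subject_id`, `identity_pct`,
#'   `coverage_pct`.
#' @export
pairwise_similarity <- function(cds_a, cds_b, id_a = "a", id_b = "b") {
  if (nchar(cds_a) == 0 || nchar(cds_b) == 0) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds_a), Biostrings::DNAString(cds_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pat)
  matches <- Biostrings::nmatch(aln)
  identity <- if (cols > 0) 100 * matches / cols else 0
  len_a <- nchar(cds_a)
  len_b <- nchar(cds_b)
  span_short <- if (len_a <= len_b) nchar(gsub("-", "", pat)) else nchar(gsub("-", "", sub))
  coverage <- 100 * span_short / min(len_a, len_b)
  data.frame(query_id = id_a, subject_id = id_b,
             identity_pct = identity, coverage_pct = coverage)
}

#' All-versus-all similarity edges for a gene set
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @return Data frame of undirected [pairwise_similarity()] edges (i < j).
#' @export
similarity_edges <- function(seqs) {
  ids <- names(seqs)
  if (length(ids) < 2) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity_pct = numeric(), coverage_pct = numeric()))
  }
  prs <- utils::combn(ids, 2)
  do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
    pairwise_similarity(seqs[[prs[1, k]]], seqs[[prs[2, k]]],
                        prs[1, k], prs[2, k])
  }))
}

#' Read BLASTN tabular (outfmt 6) output as similarity edges
#'
#' Keeps the best HSP (highest bit score) per directed pair, removes
#' self-hits, and merges reciprocal hits into one undirected edge with the
#' maximum identity and maximum coverage. Coverage is the HSP alignment
#' length over the shorter sequence's length, so sequence lengths must be
#' supplied.
#'
#' @param path 12-column tabular file (qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore).
#' @param seq_lengths Named numeric vector of sequence lengths.
#' @return Data frame of undirected edges as in [pairwise_similarity()].
#' @export
read_blast_tab <- function(path, seq_lengths) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity_pct = numeric(), coverage_pct = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    stop("malformed BLAST tabular row on line ", which(nf < 12)[1],
         " (expected 12 columns, got ", nf[which(nf < 12)[1]], ")")
  }
  df <- data.frame(query_id = vapply(fields, `[[`, "", 1),
                   subject_id = vapply(fields, `[[`, "", 2),
                   pident = as.numeric(vapply(fields, `[[`, "", 3)),
                   length = as.numeric(vapply(fields, `[[`, "", 4)),
                   bitscore = as.numeric(vapply(fields, `[[`, "", 12)))
  bad <- which(is.na(df$pident) | is.na(df$length) | is.na(df$bitscore))
  if (length(bad) > 0) stop("non-numeric BLAST field on line ", bad[1])
  df <- df[df$query_id != df$subject_id, , drop = FALSE]
  if (nrow(df) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity_pct = numeric(), coverage_pct = numeric()))
  }
  miss <- setdiff(unique(c(df$query_id, df$subject_id)), names(seq_lengths))
  if (length(miss) > 0) stop("no sequence length for ", miss[1])
  # best HSP per directed pair
  dkey <- paste(df$query_id, df$subject_id, sep = "\r")
  df <- df[order(dkey, -df$bitscore), , drop = FALSE]
  df <- df[!duplicated(paste(df$query_id, df$subject_id, sep = "\r")), , drop = FALSE]
  shorter <- pmin(seq_lengths[df$query_id], seq_lengths[df$subject_id])
  df$coverage_pct <- 100 * pmin(df$length, shorter) / shorter
  # merge reciprocal directions: max identity, max coverage
  a <- pmin(df$query_id, df$subject_id)
  b <- pmax(df$query_id, df$subject_id)
  key <- paste(a, b, sep = "\r")
  ident <- tapply(df$pident, key, max)
  cov <- tapply(df$coverage_pct, key, max)
  parts <- strsplit(names(ident), "\r", fixed = TRUE)
  data.frame(query_id = vapply(parts, `[[`, "", 1),
             subject_id = vapply(parts, `[[`, "", 2),
             identity_pct = as.numeric(ident),
             coverage_pct = as.numeric(cov),
             row.names = NULL)
}

#' Build gene families at one stringency level
#'
#' Keeps edges whose identity and coverage both strictly exceed the level,
#' then takes single-linkage connected components; genes without a kept
#' edge become singleton families. The average identity of a family is the
#' mean identity of its kept edges (`NA` for singletons).
#'
#' @param edges Data frame of undirected similarity edges.
#' @param genes Character vector of all gene ids in scope (the TNL or
#'   non-TNL genes; the two scopes are clustered separately).
#' @param level Threshold in percent, one of the study's 70/80/90 or any
#'   other value.
#' @param scope Label recorded on the result (`"TNL"`, `"NON_TNL"`, ...).
#' @return Object of class `gene_families`: list with `membership`
#'   (`gene_id`, `family_id`), `families` (`family_id`, `n_members`,
#'   `avg_identity_pct`), `level`, `scope`.
#' @export
build_families <- function(edges, genes, level, scope = "ALL") {
  stray <- setdiff(unique(c(edges$query_id, edges$subject_id)), genes)
  if (length(stray) > 0) {
    stop("edge references gene outside scope: ", stray[1])
  }
  kept <- edges[edges$identity_pct > level & edges$coverage_pct > level, ,
                drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("query_id", "subject_id")], directed = FALSE,
    vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  # stable family ids: number components by their lexicographically first member
  comp_ids <- sort(unique(comp$membership))
  first_member <- vapply(comp_ids,
                         function(ci) min(genes[comp$membership == ci]),
                         character(1))
  fam_rank <- rank(first_member, ties.method = "first")
  fam_ids <- sprintf("%s_L%g_f%03d", scope, level,
                     fam_rank[match(comp$membership, comp_ids)])
  membership <- data.frame(gene_id = genes, family_id = fam_ids)
  avg_ident <- vapply(split(seq_len(nrow(membership)), membership$family_id),
                      function(ix) {
                        mem <- membership$gene_id[ix]
                        e <- kept[kept$query_id %in% mem & kept$subject_id %in% mem, ,
                                  drop = FALSE]
                        if (nrow(e) == 0) NA_real_ else mean(e$identity_pct)
                      }, numeric(1))
  families <- data.frame(family_id = names(avg_ident),
                         n_members = as.integer(table(membership$family_id)[names(avg_ident)]),
                         avg_identity_pct = unname(avg_ident))
  structure(list(membership = membership, families = families,
                 level = level, scope = scope),
            class = "gene_families")
}

#' @export
print.gene_families <- function(x, ...) {
  cat(sprintf("gene_families: %d genes in %d families (scope %s, level > %g%%)\n",
              nrow(x$membership), nrow(x$families), x$scope, x$level))
  cat(sprintf("  multi-gene families: %d (%d genes)\n",
              sum(x$families$n_members >= 2),
              sum(x$families$n_members[x$families$n_members >= 2])))
  invisible(x)
}

#' Summarise families across species, scopes and levels
#'
#' For every clustering result and species (plus a `Total` row): counts of
#' single-copy and multi-gene-family genes, the multi-gene proportion
#' (percent, two decimals), and on the `Total` row the number of multi-gene
#' families and their mean average identity.
#'
#' @param fam_list List of `gene_families` objects (e.g. one per scope and
#'   level).
#' @param species_map Named vector gene id -> species; defaults to the
#'   prefix before `|` in gene ids.
#' @return Long data frame: `scope`, `level`, `species`, `n_single`,
#'   `n_multi`, `multi_pct`, `n_families_multi`, `mean_avg_identity`.
#' @export
family_summary <- function(fam_list, species_map = NULL) {
  if (inherits(fam_list, "gene_families")) fam_list <- list(fam_list)
  rows <- list()
  for (fams in fam_list) {
    mem <- fams$membership
    species_map_i <- species_map %||%
      stats::setNames(species_of(mem$gene_id), mem$gene_id)
    sizes <- table(mem$family_id)
    mem$multi <- sizes[mem$family_id] >= 2
    mem$species <- unname(species_map_i[mem$gene_id])
    for (s in c(sort(unique(mem$species)), "Total")) {
      sub <- if (s == "Total") mem else mem[mem$species == s, , drop = FALSE]
      n_multi <- sum(sub$multi)
      n_single <- sum(!sub$multi)
      multi_fams <- fams$families[fams$families$n_members >= 2, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        scope = fams$scope, level = fams$level, species = s,
        n_single = n_single, n_multi = n_multi,
        multi_pct = pct(n_multi, n_single + n_multi),
        n_families_multi = if (s == "Total") nrow(multi_fams) else NA_integer_,
        mean_avg_identity = if (s == "Total" && nrow(multi_fams) > 0) {
          half_up(mean(multi_fams$avg_identity_pct, na.rm = TRUE), 2)
        } else NA_real_)
    }
  }
  do.call(rbind, rows)
}
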