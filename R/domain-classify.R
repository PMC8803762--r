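# Architecture subclass classification of NBS-LRR genes from domain hits.
#
# Taxonomy: a gene is an NBS-LRR when it carries at least one NB-ARC and one
# LRR hit. The N-terminal domain then decides the subclass:
# TIR -> TNL; CC+RPW8 -> RPW8-CNL; CC -> CNL'; RPW8 -> RPW8-XNL; none -> XNL'.
# Derived groupings: CNL = {CNL', RPW8-CNL}, XNL = {XNL', RPW8-XNL},
# RNL = {RPW8-CNL, RPW8-XNL}, non-TNL = CNL + XNL.

#' NBS-LRR subclass labels and groupings
#'
#' @return Named list: `subclasses` (the five architecture labels) and the
#'   derived groupings `CNL`, `XNL`, `RNL`, `NON_TNL`.
#' @export
nlr_subclasses <- function() {
  list(subclasses = c("TNL", "CNL_PRIME", "RPW8_CNL", "XNL_PRIME", "RPW8_XNL"),
       CNL = c("CNL_PRIME", "RPW8_CNL"),
       XNL = c("XNL_PRIME", "RPW8_XNL"),
       RNL = c("RPW8_CNL", "RPW8_XNL"),
       NON_TNL = c("CNL_PRIME", "RPW8_CNL", "XNL_PRIME", "RPW8_XNL"))
}

# Map free-text domain labels onto the controlled vocabulary.
normalize_domain <- function(x) {
  u <- toupper(trimws(x))
  out <- rep("OTHER", length(u))
  out[grepl("NB[-_ ]?ARC|NBARC|NBS", u)] <- "NB-ARC"
  out[grepl("LRR|LEUCINE", u)] <- "LRR"
  out[grepl("^TIR|TOLL", u)] <- "TIR"
  out[grepl("^CC$|COILED|COILS?$", u)] <- "CC"
  out[grepl("RPW8", u)] <- "RPW8"
  out
}

#' Is a gene an NBS-LRR candidate?
#'
#' True iff the gene's hits include at least one NB-ARC domain and at least
#' one LRR domain (any annotation source suffices for the LRR).
#'
#' @param hits Data frame of the gene's hits with a `domain` column.
#' @return Logical scalar.
#' @export
is_nbs_lrr <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(FALSE)
  any(hits$domain == "NB-ARC") && any(hits$domain == "LRR")
}

#' Classify the architecture subclass of one NBS-LRR gene
#'
#' The qualifying N-terminal domain must start before the first NB-ARC hit
#' (smallest `aa_start`). TIR takes precedence: a gene carrying both an
#' N-terminal TIR and CC is classified TNL and flagged ambiguous (attribute
#' `ambiguous`, surfaced by [classify_genes()] for QC).
#'
#' @param hits Data frame of the gene's hits: `domain`, `aa_start`, `aa_end`.
#' @return One of `"TNL"`, `"CNL_PRIME"`, `"RPW8_CNL"`, `"XNL_PRIME"`,
#'   `"RPW8_XNL"`, with attribute `ambiguous`.
#' @export
classify_architecture <- function(hits) {
  if (!is_nbs_lrr(hits)) {
    stop("gene is not an NBS-LRR (needs both NB-ARC and LRR hits)")
  }
  nbarc_start <- min(hits$aa_start[hits$domain == "NB-ARC"])
  nterm <- function(dom) {
    any(hits$domain == dom & hits$aa_start < nbarc_start)
  }
  has_tir <- nterm("TIR")
  has_cc <- nterm("CC")
  has_rpw8 <- nterm("RPW8")
  cls <- if (has_tir) "TNL"
  else if (has_cc && has_rpw8) "RPW8_CNL"
  else if (has_cc) "CNL_PRIME"
  else if (has_rpw8) "RPW8_XNL"
  else "XNL_PRIME"
  attr(cls, "ambiguous") <- has_tir && has_cc
  cls
}

#' Classify every gene in a domain-hit table
#'
#' @param hits Data frame of hits (`gene_id`, `domain`, `aa_start`,
#'   `aa_end`), e.g. from [parse_domain_tsv()].
#' @param species_map Optional named vector gene id -> species; defaults to
#'   the prefix before `|` in the gene ids.
#' @return Data frame (`gene_id`, `species`, `class`, `ambiguous`) with one
#'   row per gene passing [is_nbs_lrr()].
#' @export
classify_genes <- function(hits, species_map = NULL) {
  ids <- unique(hits$gene_id)
  species_map <- species_map %||% stats::setNames(species_of(ids), ids)
  rows <- lapply(ids, function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    if (!is_nbs_lrr(h)) return(NULL)
    cls <- classify_architecture(h)
    data.frame(gene_id = g, species = unname(species_map[g]),
               class = as.character(cls),
               ambiguous = isTRUE(attr(cls, "ambiguous")))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), species = character(),
                      class = character(), ambiguous = logical())
  }
  out
}

#' Species-by-subclass count table with margins
#'
#' @param classified Data frame from [classify_genes()] (`gene_id`, `class`,
#'   optionally `species`).
#' @param species_map Named vector gene id -> species; required when
#'   `classified` lacks a species column. A gene without a species entry is
#'   an error naming the gene.
#' @return Matrix with one row per species plus `"Total"`, columns the five
#'   subclasses plus the derived `NON_TNL` grouping and the `NBS_LRR` total.
#' @export
tabulate_classes <- function(classified, species_map = NULL) {
  groups <- nlr_subclasses()
  if (!"species" %in% names(classified) && is.null(species_map)) {
    stop("need either a species column or a species_map")
  }
  if (!"species" %in% names(classified) || !is.null(species_map)) {
    sp <- species_map[classified$gene_id]
    bad <- classified$gene_id[is.na(sp)]
    if (length(bad) > 0) stop("no species for gene ", bad[1])
    classified$species <- unname(sp)
  }
  if (nrow(classified) > 0 && anyNA(classified$species)) {
    stop("no species for gene ",
         classified$gene_id[is.na(classified$species)][1])
  }
  species <- sort(unique(classified$species))
  cols <- c(groups$subclasses, "NON_TNL", "NBS_LRR")
  m <- matrix(0L, nrow = length(species) + 1L, ncol = length(cols),
              dimnames = list(c(species, "Total"), cols))
  for (s in species) {
    cl <- classified$class[classified$species == s]
    for (k in groups$subclasses) m[s, k] <- sum(cl == k)
    m[s, "NON_TNL"] <- sum(cl %in% groups$NON_TNL)
    m[s, "NBS_LRR"] <- length(cl)
  }
  m["Total", ] <- colSums(m[seq_along(species), , drop = FALSE])
  m
}

#' Read a domain-annotation TSV
#'
#' Two dialects are accepted. The native dialect has a header with columns
#' `gene_id`, `domain`, `aa_start`, `aa_end` (1-based inclusive amino-acid
#' coordinates); extra columns are ignored. A headerless file with 11 or
#' more columns is treated as InterProScan tab output (protein accession,
#' md5, length, analysis, signature accession, signature description,
#' start, stop, ...), mapping columns 1, 5, 7 and 8. Unknown domain labels
#' map to `OTHER` with a warning; rows with `aa_end < aa_start` abort with
#' their line numbers.
#'
#' @param path Path to the TSV.
#' @return Data frame of hits: `gene_id`, `domain`, `aa_start`, `aa_end`,
#'   `source`.
#' @export
parse_domain_tsv <- function(path) {
  if (!file.exists(path)) stop("domain file not found: ", path)
  first <- readLines(path, n = 1)
  header_fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if ("gene_id" %in% header_fields) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    for (col in c("gene_id", "domain", "aa_start", "aa_end")) {
      if (!col %in% names(df)) stop("domain table is missing column '", col, "'")
    }
    src <- if ("source" %in% names(df)) df$source else "tsv"
    hits <- data.frame(gene_id = df$gene_id, domain_raw = df$domain,
                       aa_start = as.integer(df$aa_start),
                       aa_end = as.integer(df$aa_end),
                       source = src, line = seq_len(nrow(df)) + 1L)
  } else if (length(header_fields) >= 11) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    hits <- data.frame(gene_id = df[[1]], domain_raw = df[[5]],
                       aa_start = as.integer(df[[7]]),
                       aa_end = as.integer(df[[8]]),
                       source = df[[4]], line = seq_len(nrow(df)))
  } else {
    stop("unrecognised domain table format: need a 'gene_id' header or ",
         ">= 11 InterProScan-style columns")
  }
  bad <- which(is.na(hits$aa_start) | is.na(hits$aa_end) |
                 hits$aa_start < 1 | hits$aa_end < hits$aa_start)
  if (length(bad) > 0) {
    stop("invalid coordinates (aa_end < aa_start or non-positive) on line(s) ",
         paste(hits$line[bad], collapse = ", "))
  }
  dom <- normalize_domain(hits$domain_raw)
  unk <- unique(hits$domain_raw[dom == "OTHER"])
  if (length(unk) > 0) {
    warning("unknown domain label(s) mapped to OTHER: ",
            paste(unk, collapse = ", "))
  }
  data.frame(gene_id = hits$gene_id, domain = dom,
             aa_start = hits$aa_start, aa_end = hits$aa_end,
             source = hits$source)
}
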