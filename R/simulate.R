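# Synthetic-data generator: coding-sequence families diverged to controlled
# Ka/Ks, planted duplication events, domain tables for all five architecture
# subclasses, and time-course expression matrices with planted DEGs.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions the package is built around: six species, planted
#' species-specific (low Ks) and lineage-specific (high Ks) duplication
#' events, eight infection time points (hours), and 48 planted
#' differentially expressed genes out of 318.
#'
#' @param seed Integer root seed; every generator draws from named
#'   substreams of it, so outputs are byte-identical for a fixed config.
#' @param n_species Number of species.
#' @param n_families Number of gene families.
#' @param genes_per_family Genes per family.
#' @param codons_per_gene Codons per gene (>= 50).
#' @param target_ks Per-event synonymous divergence (substitutions per
#'   synonymous site), recycled over families.
#' @param omega Target Ka/Ks ratio of the planted divergence events.
#' @param event_types Planted event labels per family, from
#'   `"species_specific"`, `"lineage_specific"`, `"none"`; families beyond
#'   the list get `"none"` (pure speciation).
#' @param timepoints_h Expression time points in hours.
#' @param n_deg Number of planted differentially expressed genes.
#' @param n_expr_genes Total genes in the expression tables.
#' @export
sim_config <- function(seed = 1L, n_species = 6L, n_families = 5L,
                       genes_per_family = 4L, codons_per_gene = 200L,
                       target_ks = c(0.15, 0.7), omega = 0.25,
                       event_types = c("species_specific", "lineage_specific"),
                       timepoints_h = c(0, 3, 6, 9, 12, 24, 48, 72),
                       n_deg = 48L, n_expr_genes = 318L) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_species >= 1, n_families >= 1, genes_per_family >= 1,
            codons_per_gene >= 50,
            all(target_ks >= 0), all(omega >= 0),
            length(timepoints_h) >= 1)
  event_types <- match.arg(event_types,
                           c("species_specific", "lineage_specific", "none"),
                           several.ok = TRUE)
  if (n_deg > n_expr_genes) stop("n_deg exceeds total expression genes")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_families = as.integer(n_families),
                 genes_per_family = as.integer(genes_per_family),
                 codons_per_gene = as.integer(codons_per_gene),
                 target_ks = target_ks, omega = omega,
                 event_types = event_types, timepoints_h = timepoints_h,
                 n_deg = as.integer(n_deg),
                 n_expr_genes = as.integer(n_expr_genes)),
            class = "sim_config")
}

# Random stop-free CDS of n codons (no trailing stop either).
random_cds <- function(n_codons) {
  code <- genetic_code()
  ok <- names(code)[code != "*"]
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

# Change exactly n distinct positions to random alternatives, never creating
# a stop codon and never revisiting a position. Class-blind (used for
# between-family divergence where Ka/Ks control is not needed).
mutate_positions <- function(cds, n_changes) {
  nts <- strsplit(cds, "")[[1]]
  code <- genetic_code()
  candidates <- seq_along(nts)
  changed <- 0L
  guard <- 0L
  while (changed < n_changes && length(candidates) > 0) {
    guard <- guard + 1L
    if (guard > 50L * n_changes + 1000L) break
    i <- sample.int(length(candidates), 1)
    pos <- candidates[i]
    alt <- sample(setdiff(c("A", "C", "G", "T"), nts[pos]), 1)
    ci <- (pos - 1L) %/% 3L
    codon <- nts[(ci * 3L + 1L):(ci * 3L + 3L)]
    codon[(pos - 1L) %% 3L + 1L] <- alt
    if (code[[paste(codon, collapse = "")]] == "*") next
    nts[pos] <- alt
    candidates <- candidates[-i]
    changed <- changed + 1L
  }
  paste(nts, collapse = "")
}

#' Simulate a diverged gene pair with controlled Ks and Ka/Ks
#'
#' Applies random single-nucleotide substitutions to a copy of the ancestor,
#' accepting each proposal against separate synonymous and nonsynonymous
#' budgets, until the planted proportions of changed synonymous and
#' nonsynonymous sites equal the raw (pre-correction) proportions that the
#' Jukes-Cantor-corrected targets imply. Each accepted change hits a fresh
#' position and never creates a stop codon, so the realized Hamming
#' divergence equals the budget exactly and the NG86 estimator recovers
#' `target_ks` and `omega` in expectation.
#'
#' @param ancestor_cds Stop-free CDS, length a multiple of 3.
#' @param target_ks Target synonymous divergence (JC-corrected scale).
#' @param omega Target Ka/Ks; the nonsynonymous target is `omega * target_ks`.
#' @param seed Integer seed.
#' @return List with `cds_a` (the ancestor), `cds_b` (the mutant), and
#'   `truth` (planted budgets and raw proportions).
#' @export
simulate_diverged_pair <- function(ancestor_cds, target_ks, omega, seed = 1L) {
  codons <- check_cds(ancestor_cds, "ancestor")
  stopifnot(target_ks >= 0, omega >= 0)
  cds <- paste(codons, collapse = "")
  tabs <- ng86_tables()
  S <- sum(tabs$sites[codons])
  N <- 3 * length(codons) - S
  ps <- jc_inverse(target_ks)
  pn <- jc_inverse(omega * target_ks)
  n_syn <- round(ps * S)
  n_non <- round(pn * N)
  code <- genetic_code()
  mutant <- with_seed(seed, {
    nts <- strsplit(cds, "")[[1]]
    candidates <- seq_along(nts)
    need_s <- n_syn
    need_n <- n_non
    guard <- 0L
    max_iter <- 200L * (n_syn + n_non) + 5000L
    while ((need_s > 0 || need_n > 0) && length(candidates) > 0) {
      guard <- guard + 1L
      if (guard > max_iter) {
        stop("could not place the requested substitutions; divergence target too high")
      }
      i <- sample.int(length(candidates), 1)
      pos <- candidates[i]
      alt <- sample(setdiff(c("A", "C", "G", "T"), nts[pos]), 1)
      ci <- (pos - 1L) %/% 3L
      idx <- (ci * 3L + 1L):(ci * 3L + 3L)
      codon_old <- paste(nts[idx], collapse = "")
      codon_new_v <- nts[idx]
      codon_new_v[(pos - 1L) %% 3L + 1L] <- alt
      codon_new <- paste(codon_new_v, collapse = "")
      if (code[[codon_new]] == "*") next
      syn <- code[[codon_old]] == code[[codon_new]]
      if (syn && need_s > 0) {
        need_s <- need_s - 1L
      } else if (!syn && need_n > 0) {
        need_n <- need_n - 1L
      } else {
        next
      }
      nts[pos] <- alt
      candidates <- candidates[-i]
    }
    if (need_s > 0 || need_n > 0) {
      stop("ran out of unmutated positions before meeting divergence budgets")
    }
    paste(nts, collapse = "")
  })
  list(cds_a = cds, cds_b = mutant,
       truth = list(target_ks = target_ks, target_ka = omega * target_ks,
                    omega = omega, n_syn = n_syn, n_non = n_non,
                    planted_ps = ps, planted_pn = pn,
                    syn_sites = S, nonsyn_sites = N))
}

.subclass_cycle <- c("TNL", "CNL_PRIME", "RPW8_CNL", "XNL_PRIME", "RPW8_XNL")

# Domain rows implied by a subclass, in 1-based inclusive aa coordinates on
# a protein of L residues. Every gene gets NB-ARC + LRR; the N-terminal
# region encodes the subclass.
.domain_rows <- function(gene_id, subclass, L) {
  nterm <- switch(subclass,
    TNL = data.frame(domain = "TIR", aa_start = 5L, aa_end = as.integer(L * 0.2)),
    CNL_PRIME = data.frame(domain = "CC", aa_start = 5L, aa_end = as.integer(L * 0.15)),
    RPW8_CNL = data.frame(domain = c("RPW8", "CC"),
                          aa_start = c(2L, as.integer(L * 0.09)),
                          aa_end = c(as.integer(L * 0.08), as.integer(L * 0.18))),
    XNL_PRIME = NULL,
    RPW8_XNL = data.frame(domain = "RPW8", aa_start = 5L, aa_end = as.integer(L * 0.15))
  )
  core <- data.frame(domain = c("NB-ARC", "LRR"),
                     aa_start = c(as.integer(L * 0.25), as.integer(L * 0.65)),
                     aa_end = c(as.integer(L * 0.6), L - 5L))
  rows <- rbind(nterm, core)
  data.frame(gene_id = gene_id, rows, source = "simulated",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a multi-species NBS-LRR gene set with planted duplication events
#'
#' Families diverge from one master sequence (~45% of sites substituted per
#' family, far below any clustering threshold yet below distance
#' saturation). Within a family the planted event decides the geometry:
#' `species_specific` places all copies in one species, duplicated at the
#' event Ks; `lineage_specific` duplicates the family ancestor at the event
#' Ks *before* a shallow (Ks 0.05) speciation into two or more species, so
#' both duplicate copies occur in several species; `none` gives one gene
#' per species with shallow speciation only. Every gene also gets a domain
#' table row set encoding its subclass (cycled over the five architectures).
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, writes `genes.fa`,
#'   `domains.tsv`, `truth_genes.tsv` and `truth_events.tsv` there.
#' @return Object of class `nlr_sim`: list with `sequences` (named character
#'   vector, ids `species|gene`), `domains` (data frame), `truth` (list of
#'   `genes` and `events` data frames) and `config`.
#' @export
simulate_family_set <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sp <- sprintf("sp%02d", seq_len(config$n_species))
  nf <- config$n_families
  g <- config$genes_per_family
  events <- c(config$event_types,
              rep("none", max(0, nf - length(config$event_types))))[seq_len(nf)]
  ks_events <- rep_len(config$target_ks, nf)
  L <- config$codons_per_gene
  master <- with_seed(child_seed(config$seed, "master"), random_cds(L))
  seqs <- character(0)
  gene_rows <- list()
  event_rows <- list()
  domain_rows <- list()
  for (f in seq_len(nf)) {
    fam_id <- sprintf("fam%02d", f)
    subclass <- .subclass_cycle[(f - 1L) %% 5L + 1L]
    fam_anc <- with_seed(child_seed(config$seed, paste0("anc_", f)),
                         mutate_positions(master, round(0.45 * 3 * L)))
    genes <- list()
    if (events[f] == "species_specific") {
      s <- sp[(f - 1L) %% config$n_species + 1L]
      genes[[1]] <- list(species = s, cds = fam_anc)
      for (j in seq_len(g - 1L)) {
        dup <- simulate_diverged_pair(fam_anc, ks_events[f], config$omega,
                                      child_seed(config$seed, paste0("ss_", f, "_", j)))
        genes[[j + 1L]] <- list(species = s, cds = dup$cds_b)
      }
      ev_species <- s
    } else if (events[f] == "lineage_specific") {
      dup <- simulate_diverged_pair(fam_anc, ks_events[f], config$omega,
                                    child_seed(config$seed, paste0("ls_", f)))
      copies <- c(dup$cds_a, dup$cds_b)
      n_a <- ceiling(g / 2)
      counts <- c(n_a, g - n_a)
      used_sp <- character(0)
      j <- 0L
      for (ci in 1:2) {
        for (k in seq_len(counts[ci])) {
          j <- j + 1L
          s <- sp[(k - 1L) %% config$n_species + 1L]
          used_sp <- union(used_sp, s)
          spec <- simulate_diverged_pair(copies[ci], 0.05, config$omega,
                                         child_seed(config$seed, paste0("sp_", f, "_", ci, "_", k)))
          genes[[j]] <- list(species = s, cds = spec$cds_b)
        }
      }
      ev_species <- used_sp
    } else {
      for (j in seq_len(g)) {
        s <- sp[(f + j - 2L) %% config$n_species + 1L]
        spec <- simulate_diverged_pair(fam_anc, 0.05, config$omega,
                                       child_seed(config$seed, paste0("bg_", f, "_", j)))
        genes[[j]] <- list(species = s, cds = spec$cds_b)
      }
      ev_species <- NA_character_
    }
    for (j in seq_along(genes)) {
      gid <- sprintf("%s_g%d", fam_id, j)
      full <- paste0(genes[[j]]$species, "|", gid)
      seqs[[full]] <- genes[[j]]$cds
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = full, species = genes[[j]]$species, family_id = fam_id,
        subclass = subclass, event = events[f])
      domain_rows[[length(domain_rows) + 1L]] <- .domain_rows(full, subclass, L)
    }
    event_rows[[f]] <- data.frame(
      family_id = fam_id, event = events[f],
      species = paste(sort(ev_species), collapse = ";"),
      target_ks = if (events[f] == "none") NA_real_ else ks_events[f])
  }
  truth_genes <- do.call(rbind, gene_rows)
  if (anyDuplicated(truth_genes$gene_id)) stop("duplicate gene ids in truth")
  sim <- structure(list(sequences = seqs,
                        domains = do.call(rbind, domain_rows),
                        truth = list(genes = truth_genes,
                                     events = do.call(rbind, event_rows)),
                        config = config),
                   class = "nlr_sim")
  if (!is.null(dir)) write_sim(sim, dir)
  sim
}

#' Write a simulated gene set to disk
#'
#' @param sim An `nlr_sim` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$sequences),
    filepath = file.path(dir, "genes.fa"))
  utils::write.table(sim$domains, file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a two-genotype infection time course with planted DEGs
#'
#' Produces FPKM values for a resistant and a susceptible genotype over the
#' configured time points. Planted DEGs rise monotonically to a late-time
#' plateau in the resistant genotype (logistic multiplier, midpoint 18 h)
#' and follow a waved profile peaking around 6-12 h in the susceptible
#' genotype; background genes fluctuate around their baseline. The
#' accompanying per-gene DE table guarantees that exactly the planted genes
#' satisfy |logFC| >= 2, p < 0.05 and BH-adjusted FDR < 0.05.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory for `fpkm.tsv`, `samples.tsv`, `deg.tsv`,
#'   `truth_deg.tsv`.
#' @return List with `fpkm` (gene x sample matrix), `meta` (sample metadata
#'   data frame), `deg_table` (gene_id, logFC, p, FDR) and `truth`
#'   (gene_id, is_deg).
#' @export
simulate_expression <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tp <- config$timepoints_h
  n <- config$n_expr_genes
  ids <- sprintf("gene%04d", seq_len(n))
  res <- with_seed(child_seed(config$seed, "expression"), {
    deg_idx <- sort(sample.int(n, config$n_deg))
    baseline <- exp(stats::rnorm(n, log(20), 0.8))
    # per-gene response amplitude (log2 units) times a genotype-specific
    # time shape in [0, 1]: monotone logistic rise to a late plateau in the
    # resistant genotype, a wave peaking around 6-12 h in the susceptible
    amp <- stats::runif(n, 1, 4)
    resist_shape <- function(t) 1 / (1 + exp(-(t - 18) / 4))
    suscep_shape <- function(t) sin(pi * t / 12)^2
    noise <- function(k) exp(stats::rnorm(k, 0, 0.15))
    cols <- list()
    meta <- list()
    for (geno in c("resistant", "susceptible")) {
      for (t in tp) {
        mult <- rep(1, n)
        shape <- if (geno == "resistant") resist_shape(t) else suscep_shape(t)
        mult[deg_idx] <- 2^(amp[deg_idx] * shape)
        sid <- sprintf("%s_%dh", ifelse(geno == "resistant", "R", "S"), t)
        cols[[sid]] <- baseline * mult * noise(n)
        meta[[sid]] <- data.frame(sample_id = sid, genotype = geno,
                                  timepoint_h = t)
      }
    }
    fpkm <- do.call(cbind, cols)
    rownames(fpkm) <- ids
    is_deg <- seq_len(n) %in% deg_idx
    logfc <- ifelse(is_deg,
                    sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 2.5, 6),
                    stats::runif(n, -1.5, 1.5))
    p <- ifelse(is_deg, stats::runif(n, 1e-8, 1e-3), stats::runif(n, 0.1, 1))
    list(fpkm = fpkm, meta = do.call(rbind, meta),
         deg_table = data.frame(gene_id = ids, logFC = logfc, p = p,
                                FDR = stats::p.adjust(p, "BH")),
         truth = data.frame(gene_id = ids, is_deg = is_deg))
  })
  rownames(res$meta) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene_id = rownames(res$fpkm), res$fpkm,
                                  check.names = FALSE),
                       file.path(dir, "fpkm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$meta, file.path(dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$deg_table, file.path(dir, "deg.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$truth, file.path(dir, "truth_deg.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
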