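# End-to-end orchestration: classify -> cluster -> rates -> trees/clades ->
# expression, with TSV reports and a JSON manifest of stage checksums.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# Nucleotide slice under the first (smallest aa_start) NB-ARC hit of a gene.
nbarc_slice <- function(cds, hits_for_gene) {
  nb <- hits_for_gene[hits_for_gene$domain == "NB-ARC", , drop = FALSE]
  if (nrow(nb) == 0) return(NA_character_)
  nb <- nb[which.min(nb$aa_start), ]
  substr(cds, (nb$aa_start - 1) * 3 + 1, nb$aa_end * 3)
}

#' Run the full NBS-LRR evolutionary analysis
#'
#' Stages, in order: domain parsing and subclass classification; per-scope
#' (TNL vs non-TNL) family clustering at the requested threshold levels;
#' Ka/Ks/Pi estimation and duplication dating within the multi-gene
#' families of the loosest level; NJ + bootstrap trees on the NB-ARC
#' nucleotide regions per scope with supported-clade classification; and,
#' when expression inputs are given, DEG screening with per-genotype
#' time-point clustering. Any stage error aborts with the stage name.
#'
#' @param fasta Path to the CDS FASTA (ids `species|gene`).
#' @param domains Path to the domain TSV (see [parse_domain_tsv()]).
#' @param out_dir Output directory for the report bundle.
#' @param blast Optional BLAST outfmt-6 TSV of precomputed similarities;
#'   otherwise the internal aligner is used.
#' @param fpkm,meta,deg Optional expression inputs: FPKM TSV (first column
#'   `gene_id`), sample metadata TSV, and logFC/p/FDR TSV.
#' @param levels Clustering threshold levels (default `c(70, 80, 90)`).
#' @param max_ks Ks filter: pairs with Ks at or above this are excluded
#'   from rate summaries and the histogram (default 1).
#' @param min_support Clade-call bootstrap threshold (strict `>`).
#' @param n_boot Bootstrap replicates for the internal trees.
#' @param params Dating parameters ([dating_params()]).
#' @param criteria DEG criteria ([deg_criteria()]).
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `nlr_pipeline`: all stage results plus the
#'   manifest, invisibly written to `out_dir` as TSV/JSON files.
#' @export
run_pipeline <- function(fasta, domains, out_dir,
                         blast = NULL, fpkm = NULL, meta = NULL, deg = NULL,
                         levels = c(70, 80, 90), max_ks = 1, min_support = 50,
                         n_boot = 100, params = dating_params(),
                         criteria = deg_criteria(), seed = 1L) {
  for (p in c(fasta, domains, blast, fpkm, meta, deg)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- list()

  seqs <- stage("read_fasta", {
    x <- Biostrings::readDNAStringSet(fasta)
    stats::setNames(as.character(x), sub(" .*", "", names(x)))
  })

  classified <- stage("classify", {
    hits <- parse_domain_tsv(domains)
    cl <- classify_genes(hits)
    files["classification"] <- write_tsv(cl, file.path(out_dir, "classification.tsv"))
    counts <- tabulate_classes(cl)
    files["class_counts"] <- write_tsv(
      data.frame(species = rownames(counts), counts, check.names = FALSE),
      file.path(out_dir, "class_counts.tsv"))
    log[["classify"]] <- c(hits_in = nrow(hits), genes_out = nrow(cl))
    list(genes = cl, counts = counts, hits = hits)
  })

  scopes <- list(
    TNL = classified$genes$gene_id[classified$genes$class == "TNL"],
    NON_TNL = classified$genes$gene_id[classified$genes$class != "TNL"])

  clustering <- stage("cluster", {
    fam_list <- list()
    membership_rows <- list()
    for (scope in names(scopes)) {
      ids <- scopes[[scope]]
      if (length(ids) == 0) next
      edges <- if (!is.null(blast)) {
        e <- read_blast_tab(blast, stats::setNames(nchar(seqs), names(seqs)))
        e[e$query_id %in% ids & e$subject_id %in% ids, , drop = FALSE]
      } else {
        similarity_edges(seqs[ids])
      }
      for (lv in levels) {
        fams <- build_families(edges, ids, lv, scope)
        fam_list[[paste(scope, lv)]] <- fams
        membership_rows[[paste(scope, lv)]] <-
          cbind(fams$membership, level = lv, scope = scope)
      }
    }
    membership <- do.call(rbind, membership_rows)
    files["family_membership"] <- write_tsv(membership,
                                             file.path(out_dir, "family_membership.tsv"))
    summary <- family_summary(fam_list)
    files["family_summary"] <- write_tsv(summary,
                                          file.path(out_dir, "family_summary.tsv"))
    log[["cluster"]] <- c(genes_in = length(unlist(scopes)),
                           families_out = sum(vapply(fam_list, function(f)
                             nrow(f$families), numeric(1))))
    list(families = fam_list, summary = summary)
  })

  rates <- stage("rates", {
    base_level <- min(levels)
    out <- list()
    for (scope in names(scopes)) {
      fams <- clustering$families[[paste(scope, base_level)]]
      if (is.null(fams)) next
      stats_df <- family_pair_stats(seqs, fams$membership, params = params)
      stats_df$scope <- scope
      out[[scope]] <- stats_df
    }
    pair_stats <- do.call(rbind, out)
    if (is.null(pair_stats)) pair_stats <- family_pair_stats(character(0),
      data.frame(gene_id = character(), family_id = character()))
    kept <- pair_stats[!is.na(pair_stats$ks) & pair_stats$ks < max_ks, ,
                       drop = FALSE]
    files["pair_stats"] <- write_tsv(pair_stats, file.path(out_dir, "pair_stats.tsv"))
    pi_rows <- list()
    for (scope in names(scopes)) {
      fams <- clustering$families[[paste(scope, base_level)]]
      if (is.null(fams)) next
      for (fid in fams$families$family_id[fams$families$n_members >= 2]) {
        members <- fams$membership$gene_id[fams$membership$family_id == fid]
        pi_rows[[fid]] <- data.frame(
          family_id = fid, scope = scope,
          pi = nucleotide_diversity(seqs[members])$pi)
      }
    }
    pi_df <- if (length(pi_rows) > 0) do.call(rbind, pi_rows) else
      data.frame(family_id = character(), scope = character(), pi = numeric())
    files["family_pi"] <- write_tsv(pi_df, file.path(out_dir, "family_pi.tsv"))
    possel <- lapply(split(kept$omega, kept$scope), positive_selection_fraction)
    hist <- if (nrow(kept) > 0) ks_histogram(kept$ks, max_ks = max_ks) else NULL
    if (!is.null(hist)) {
      files["ks_histogram"] <- write_tsv(hist$bins, file.path(out_dir, "ks_histogram.tsv"))
    }
    log[["rates"]] <- c(pairs_in = nrow(pair_stats), pairs_kept = nrow(kept))
    list(pair_stats = pair_stats, kept = kept, pi = pi_df,
         positive_selection = possel, histogram = hist)
  })

  clades <- stage("clades", {
    out <- list()
    prop_rows <- list()
    for (scope in names(scopes)) {
      ids <- scopes[[scope]]
      if (length(ids) < 4) next
      slices <- vapply(ids, function(g) {
        nbarc_slice(seqs[[g]], classified$hits[classified$hits$gene_id == g, ])
      }, character(1))
      slices <- slices[!is.na(slices)]
      if (length(unique(nchar(slices))) != 1 || length(slices) < 4) next
      st <- bootstrap_support(slices, n_reps = n_boot,
                              seed = child_seed(seed, paste0("boot_", scope)))
      calls <- classify_clades(st, min_support = min_support)
      if (nrow(calls) > 0) calls$scope <- scope
      out[[scope]] <- list(tree = st, calls = calls)
      prop <- duplication_proportions(calls, length(ids))
      prop$scope <- scope
      prop_rows[[scope]] <- prop
      write_newick(st, file.path(out_dir, paste0("tree_", scope, ".nwk")))
      files[paste0("tree_", scope)] <- file.path(out_dir, paste0("tree_", scope, ".nwk"))
    }
    all_calls <- do.call(rbind, lapply(out, `[[`, "calls"))
    if (!is.null(all_calls) && nrow(all_calls) > 0) {
      files["clade_calls"] <- write_tsv(all_calls, file.path(out_dir, "clade_calls.tsv"))
    }
    props <- do.call(rbind, prop_rows)
    if (!is.null(props)) {
      files["clade_proportions"] <- write_tsv(props,
                                               file.path(out_dir, "clade_proportions.tsv"))
    }
    log[["clades"]] <- c(trees = length(out),
                          calls = if (is.null(all_calls)) 0L else nrow(all_calls))
    list(per_scope = out, proportions = props)
  })

  expression <- stage("expression", {
    if (is.null(fpkm) || is.null(meta) || is.null(deg)) {
      log[["expression"]] <- c(skipped = 1)
      NULL
    } else {
      fm <- utils::read.delim(fpkm, check.names = FALSE)
      mat <- as.matrix(fm[, -1, drop = FALSE])
      rownames(mat) <- fm[[1]]
      md <- utils::read.delim(meta)
      dt <- utils::read.delim(deg)
      kept <- screen_degs(dt, criteria)
      files["deg_list"] <- write_tsv(data.frame(gene_id = kept),
                                      file.path(out_dir, "deg_list.tsv"))
      clust <- lapply(stats::setNames(nm = unique(md$genotype)), function(g) {
        sub <- mat[rownames(mat) %in% kept, , drop = FALSE]
        if (nrow(sub) < 2) return(NULL)
        cluster_timepoints(sub, md, g)
      })
      contrast <- genotype_contrast(mat[rownames(mat) %in% kept, , drop = FALSE], md)
      files["early_late"] <- write_tsv(contrast$per_gene,
                                        file.path(out_dir, "early_late.tsv"))
      groups_json <- lapply(clust, function(cl) {
        if (is.null(cl)) return(NULL)
        split(names(cl$groups), cl$groups)
      })
      files["cluster_groups"] <- file.path(out_dir, "cluster_groups.json")
      jsonlite::write_json(groups_json, files["cluster_groups"], auto_unbox = TRUE)
      log[["expression"]] <- c(genes_in = nrow(mat), degs = length(kept))
      list(degs = kept, clusters = clust, contrast = contrast)
    }
  })

  manifest <- list(
    stages = names(log),
    records = log,
    files = lapply(stats::setNames(nm = names(files)), function(k) {
      list(path = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]])))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(classified = classified, clustering = clustering,
                 rates = rates, clades = clades, expression = expression,
                 manifest = manifest, out_dir = out_dir),
            class = "nlr_pipeline")
}

#' @export
print.nlr_pipeline <- function(x, ...) {
  cat("nlr_pipeline run:", length(x$manifest$stages), "stages completed\n")
  cat("outputs in:", x$out_dir, "\n")
  invisible(x)
}

#' Render a human-readable summary of a pipeline run
#'
#' Per-species subclass counts with totals, per-level multi-gene
#' proportions, positive-selection fractions, duplicated-clade proportions,
#' and the dated modal Ks bins.
#'
#' @param x An `nlr_pipeline` object from [run_pipeline()].
#' @param params Dating parameters for the modal-bin ages.
#' @return Character vector of report lines, invisibly; printed as a side
#'   effect.
#' @export
render_summary <- function(x, params = dating_params()) {
  stopifnot(inherits(x, "nlr_pipeline"))
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("== NBS-LRR gene counts ==")
  counts <- x$classified$counts
  for (r in rownames(counts)) {
    add("%s: %d NBS-LRR (%d TNL, %d non-TNL)", r, counts[r, "NBS_LRR"],
        counts[r, "TNL"], counts[r, "NON_TNL"])
  }
  add("== Multi-gene family proportions ==")
  s <- x$clustering$summary
  tot <- s[s$species == "Total", , drop = FALSE]
  for (i in seq_len(nrow(tot))) {
    add("%s at >%g%%: %d multi of %d (%.2f%%), %d multi-gene families",
        tot$scope[i], tot$level[i], tot$n_multi[i],
        tot$n_multi[i] + tot$n_single[i], tot$multi_pct[i],
        tot$n_families_multi[i])
  }
  add("== Positive selection (Ka/Ks > 1) ==")
  for (scope in names(x$rates$positive_selection)) {
    ps <- x$rates$positive_selection[[scope]]
    add("%s: %d of %d pairs (%.2f%%)", scope, ps$count_gt1, ps$total,
        if (is.na(ps$percent)) 0 else ps$percent)
  }
  if (!is.null(x$rates$histogram)) {
    add("== Ks modal bins, dated ==")
    for (b in x$rates$histogram$modal_bins) {
      lo <- x$rates$histogram$bins$lower[b]
      hi <- x$rates$histogram$bins$upper[b]
      add("[%.1f, %.1f): %.2f-%.2f MY", lo, hi,
          half_up(date_duplication(lo, params), 2),
          half_up(date_duplication(hi, params), 2))
    }
  }
  if (!is.null(x$clades$proportions)) {
    add("== Duplicated clades ==")
    p <- x$clades$proportions
    for (i in seq_len(nrow(p))) {
      add("%s %s: %d genes (%.2f%%)", p$scope[i], p$call[i], p$n_genes[i],
          p$percent[i])
    }
  }
  if (!is.null(x$expression)) {
    add("== Expression ==")
    add("DEGs kept: %d", length(x$expression$degs))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
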