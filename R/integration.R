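# Cross-stage joins and the end-to-end synthetic study driver: differential
# expression filtering, per-group direction summaries, the upregulated-gene
# cis-element check, subcellular-localisation reconciliation, the
# chromosome table, and the deterministic pipeline with a hash manifest.

#' Filter a differential-expression table
#'
#' Significant iff |fold change| > `fc_min` (i.e. |log2FC| > log2(fc_min))
#' and p < `p_max`, both strict. Direction is up iff log2FC > 0.
#'
#' @param table data.frame with columns gene_id, log2fc, p (and optionally
#'   condition).
#' @param fc_min Linear fold-change threshold.
#' @param p_max P-value threshold.
#' @return Input rows with `significant` and `direction` columns added.
#' @export
filter_de <- function(table, fc_min = 2.0, p_max = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "p") %in% names(table)))
  if (any(table$p <= 0 | table$p > 1)) stop("p-values must lie in (0, 1]")
  out <- table
  out$significant <- abs(out$log2fc) > log2(fc_min) & out$p < p_max
  out$direction <- ifelse(!out$significant, "ns",
                          ifelse(out$log2fc > 0, "up", "down"))
  out
}

#' Per-group counts of up/down/ns with a monotone-direction flag
#'
#' The flag is TRUE for a group iff all of its significant members share
#' one direction; NA for a group with no significant member.
#'
#' @param de_records Output of [filter_de()].
#' @param group_assignment data.frame (leaf-or-gene id, group) as returned
#'   by [assign_groups()], matched on gene_id.
#' @return data.frame (group, n_up, n_down, n_ns, monotone, direction).
#' @export
group_de_summary <- function(de_records, group_assignment) {
  names(group_assignment)[1] <- "gene_id"
  merged <- merge(de_records, group_assignment, by = "gene_id")
  rows <- lapply(split(merged, merged$group), function(d) {
    n_up <- sum(d$direction == "up")
    n_down <- sum(d$direction == "down")
    monotone <- if (n_up + n_down == 0L) NA else (n_up == 0L || n_down == 0L)
    dirn <- if (isTRUE(monotone)) {
      if (n_up > 0L) "up" else "down"
    } else NA_character_
    data.frame(group = d$group[1], n_up = n_up, n_down = n_down,
               n_ns = sum(d$direction == "ns"), monotone = monotone,
               direction = dirn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of upregulated genes carrying at least one cis element
#'
#' @param de_records Output of [filter_de()].
#' @param element_matrix Count matrix from [scan_all()] (genes x motifs).
#' @return Fraction in [0, 1].
#' @export
upregulated_cis_check <- function(de_records, element_matrix) {
  up <- unique(de_records$gene_id[de_records$direction == "up"])
  if (length(up) == 0L) stop("no upregulated genes")
  missing <- setdiff(up, rownames(element_matrix))
  if (length(missing) > 0L) {
    stop("upregulated gene(s) missing from element matrix: ", paste(missing, collapse = ", "))
  }
  mean(rowSums(element_matrix[up, , drop = FALSE]) > 0)
}

#' Reconcile primary and auxiliary subcellular-localisation calls
#'
#' The primary predictor's compartment always stands as the final call;
#' disagreement with the auxiliary predictor is flagged as a conflict.
#'
#' @param protein_id Protein id.
#' @param primary_call Compartment from the primary predictor (required).
#' @param auxiliary_call Compartment or targeting-peptide label from the
#'   auxiliary predictor (NA allowed).
#' @return One-row data.frame (protein_id, primary_call, auxiliary_call,
#'   final, conflict).
#' @export
reconcile_localisation <- function(protein_id, primary_call, auxiliary_call = NA_character_) {
  if (is.na(primary_call) || !nzchar(primary_call)) {
    stop("missing primary localisation call for ", protein_id)
  }
  conflict <- !is.na(auxiliary_call) && nzchar(auxiliary_call) &&
    auxiliary_call != primary_call
  data.frame(protein_id = protein_id, primary_call = primary_call,
             auxiliary_call = auxiliary_call, final = primary_call,
             conflict = conflict, stringsAsFactors = FALSE)
}

#' Per-chromosome ordered family listing with duplication classes
#'
#' @param family_genes Character vector of family gene ids.
#' @param models A [gene_models()] object.
#' @param duplication_calls Output of [classify_duplicates()].
#' @return data.frame (chrom, gene_id, start, end, strand, class) sorted by
#'   chromosome then coordinate; each family gene appears exactly once.
#' @export
chromosome_table <- function(family_genes, models, duplication_calls) {
  g <- models$genes
  missing <- setdiff(family_genes, g$gene_id)
  if (length(missing) > 0L) stop("family gene(s) absent from models: ", paste(missing, collapse = ", "))
  tab <- g[g$gene_id %in% family_genes, , drop = FALSE]
  tab$class <- duplication_calls$class[match(tab$gene_id, duplication_calls$gene_id)]
  if (anyNA(tab$class)) stop("family gene(s) without duplication call")
  tab <- tab[order(tab$chrom, tab$start), c("chrom", "gene_id", "start", "end", "strand", "class")]
  rownames(tab) <- NULL
  tab
}

#' Run the full synthetic study end to end
#'
#' Simulates a genome with planted families, motifs, ages and expression;
#' runs family identification, promoter scanning, duplication
#' classification, tandem enrichment, Ka/Ks, gene ages, protein properties,
#' clade grouping and the integration summaries; writes every stage's table
#' plus a manifest of input parameters, seed and md5 hashes. Identical
#' config + seed give byte-identical outputs.
#'
#' @param out_dir Report directory (created).
#' @param seed Master seed.
#' @param config Genome configuration overrides (see
#'   [default_genome_config()]).
#' @param n_families Number of planted families.
#' @param kaks_bootstrap Bootstrap replicates for the Ka/Ks stage.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest path.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = list(),
                         n_families = 3L, kaks_bootstrap = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # --- simulate ---------------------------------------------------------
  sim <- simulate_genome(config, seed = seed)
  layouts <- list(
    c("tandem", "tandem", "proximal", "dispersed"),
    c("tandem", "proximal", "dispersed", "dispersed"),
    c("tandem", "tandem", "dispersed")
  )
  for (i in seq_len(n_families)) {
    lay <- layouts[[(i - 1L) %% length(layouts) + 1L]]
    sim <- plant_family(sim, family_size = length(lay) + 1L, layout = lay,
                        mutation_rate = 0.01, seed = seed + i,
                        family_id = sprintf("fam%02d", i))
  }
  family_genes <- sort(unique(unlist(sim$ledger$planted_families)))
  elements <- nematode_elements()
  elements$motif_id <- make.unique(elements$element)
  # two elements share one motif word; plant each distinct word once so the
  # per-window target counts stay satisfiable
  plant_el <- elements[!duplicated(elements$iupac), , drop = FALSE]
  set.seed(stream_seed(seed, "motif_targets"))
  instances <- do.call(rbind, lapply(family_genes, function(g) {
    data.frame(gene_id = g, motif_id = plant_el$motif_id, iupac = plant_el$iupac,
               count = sample(0:3, nrow(plant_el), replace = TRUE,
                              prob = c(0.45, 0.3, 0.15, 0.1)),
               stringsAsFactors = FALSE)
  }))
  instances <- harmonize_motif_targets(instances)
  sim <- plant_promoter_motifs(sim, instances, seed = seed)
  write_sim(sim, file.path(out_dir, "inputs"))

  # --- family identification -------------------------------------------
  proteins <- protein_sequences(sim)
  evidence <- data.frame(
    gene_id = family_genes,
    channel = rep(c("blastp", "hmm_full", "hmm_pfam"), length.out = length(family_genes)),
    e_value = 1e-10, stringsAsFactors = FALSE
  )
  names(evidence)[1] <- "protein_id"
  candidates <- merge_candidates(evidence)
  validation <- data.frame(protein_id = family_genes, source = "Pfam",
                           has_c4_domain = TRUE, stringsAsFactors = FALSE)
  fam <- validate_family(candidates, validation)
  write_tsv(fam$family, file.path(out_dir, "family.tsv"))

  # --- promoter scan ----------------------------------------------------
  promoters <- extract_upstream(sim$models, sim$seqs, window = 2000L)
  fam_prom <- promoters[promoters$gene_id %in% family_genes, , drop = FALSE]
  patterns <- lapply(seq_len(nrow(elements)), function(i) {
    iupac_to_pattern(elements$iupac[i], motif_id = elements$motif_id[i])
  })
  counts <- scan_all(fam_prom, patterns)
  counts_df <- data.frame(gene_id = rownames(counts), counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts_df, file.path(out_dir, "element_counts.tsv"))

  # --- duplication + enrichment ----------------------------------------
  index <- gene_rank_index(sim$models)
  calls <- classify_duplicates(sim$hits, index)
  write_tsv(calls, file.path(out_dir, "duplication_calls.tsv"))
  ann <- data.frame(gene_id = calls$gene_id,
                    term_id = paste0("class:", calls$class),
                    stringsAsFactors = FALSE)
  enr <- enrich_sets(family_genes, ann, q_max = 0.05, fe_min = 2)
  write_tsv(enr$table, file.path(out_dir, "tandem_enrichment.tsv"))

  # --- Ka/Ks over planted family pairs ---------------------------------
  pair_list <- list()
  pair_labels <- character(0)
  for (fam_id in names(sim$ledger$planted_families)) {
    members <- sim$ledger$planted_families[[fam_id]]
    founder <- members[1]
    for (m in members[-1]) {
      aln <- codon_alignment(cds_sequence(sim, founder), cds_sequence(sim, m),
                             pair_id = paste(founder, m, sep = "|"))
      pair_list[[aln$pair_id]] <- aln
      pair_labels <- c(pair_labels, "paralogous")
    }
  }
  kaks <- batch_kaks(pair_list, labels = pair_labels,
                     bootstrap = kaks_bootstrap, seed = seed)
  write_tsv(kaks$table, file.path(out_dir, "kaks.tsv"))
  write_tsv(kaks$summary, file.path(out_dir, "kaks_summary.tsv"))

  # --- gene age ---------------------------------------------------------
  ladder <- lineage_ladder(
    DEFAULT_LADDER,
    c(ecoli = "Cellular organisms", yeast = "Eukaryota", athaliana = "Eukaryota",
      celegans = "Metazoa", dmelanogaster = "Metazoa", rvarieornatus = "Tardigrada-specific")
  )
  set.seed(stream_seed(seed, "strata_targets"))
  strata <- stats::setNames(
    sample(DEFAULT_LADDER, length(family_genes), replace = TRUE,
           prob = c(0.05, 0.8, 0.1, 0.05)),
    family_genes
  )
  sim$ledger$planted_strata <- strata
  evidence_age <- simulate_homolog_evidence(strata, ladder, seed = seed)
  ages <- assign_strata(evidence_age, ladder, gene_ids = family_genes)
  write_tsv(ages, file.path(out_dir, "gene_ages.tsv"))
  write_tsv(age_distribution(ages, ladder), file.path(out_dir, "age_distribution.tsv"))

  # --- protein properties ----------------------------------------------
  fam_prot <- proteins[family_genes]
  cds_len <- stats::setNames(rep(nchar(cds_sequence(sim, family_genes[1])), length(family_genes)),
                             family_genes)
  props <- protein_properties(fam_prot, cds_len)
  write_tsv(props, file.path(out_dir, "protein_properties.tsv"))

  # --- clade groups: one group per planted family ----------------------
  # a star-free caricature tree: families as clades, paralog depth by family
  newick <- paste0(
    "(outgroup,(",
    paste(vapply(names(sim$ledger$planted_families), function(fid) {
      mem <- sim$ledger$planted_families[[fid]]
      paste0("(", paste(mem, collapse = ","), ")")
    }, character(1)), collapse = ","),
    "));"
  )
  tree <- reroot_at_outgroup(newick, "outgroup")
  anchors <- lapply(sim$ledger$planted_families, function(mem) mem[1:2])
  names(anchors) <- paste0("Group", seq_along(anchors))
  groups <- assign_groups(tree, anchors)
  write_tsv(groups, file.path(out_dir, "groups.tsv"))

  # --- differential expression + integration ---------------------------
  de_sim <- simulate_de_table(family_genes, frac_signif = 0.4, seed = seed)
  sim$ledger$planted_de <- de_sim$planted
  de <- filter_de(de_sim$table)
  write_tsv(de, file.path(out_dir, "de_filtered.tsv"))
  grp_for_de <- groups
  names(grp_for_de)[1] <- "gene_id"
  de_groups <- group_de_summary(de, grp_for_de)
  write_tsv(de_groups, file.path(out_dir, "de_group_summary.tsv"))
  cis_fraction <- tryCatch(upregulated_cis_check(de, counts), error = function(e) NA_real_)
  chrom_tab <- chromosome_table(family_genes, sim$models, calls)
  write_tsv(chrom_tab, file.path(out_dir, "chromosome_table.tsv"))
  write_ledger(sim$ledger, file.path(out_dir, "inputs", "truth_ledger.json"))

  # --- manifest ---------------------------------------------------------
  files <- sort(c(
    list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE),
    list.files(file.path(out_dir, "inputs"), full.names = TRUE)
  ))
  manifest <- data.frame(
    file = substring(files, nchar(out_dir) + 2L),
    md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE
  )
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_tsv(manifest, manifest_path)
  summary_obj <- list(
    seed = seed, n_genes = nrow(sim$models$genes),
    n_family_genes = length(family_genes),
    cis_fraction_upregulated = cis_fraction
  )
  jsonlite::write_json(summary_obj, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    sim = sim, family = fam$family, promoters = fam_prom, element_counts = counts,
    duplication = calls, enrichment = enr, kaks = kaks, ages = ages,
    props = props, groups = groups, de = de, de_groups = de_groups,
    cis_fraction = cis_fraction, chromosome_table = chrom_tab,
    manifest = manifest, manifest_path = manifest_path
  ))
}
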