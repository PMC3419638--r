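# End-to-end orchestration: simulate (dataset generation), analyze (QC ->
# repeat annotation -> mapping -> synteny classification -> expansion and
# repeat reports) and tables (worked-example recomputation of the derived
# statistics from published summary-table fixtures). Every stage logs
# record counts in and out; the run manifest collects them so the filter
# accounting can be audited.

besmap_version <- function() {
  as.character(utils::packageVersion("besmap"))
}

#' Simulate a dataset and write a run manifest
#'
#' @param cfg a [bes_config()] with a seed.
#' @param out_dir output directory.
#' @return invisible result of [make_dataset()] plus the manifest path.
#' @export
run_simulate <- function(cfg = bes_config(), out_dir) {
  seed <- require_seed(cfg)
  ds <- make_dataset(cfg, out_dir)
  manifest <- list(
    tool = "besmap", version = besmap_version(), stage = "simulate",
    seed = seed,
    counts = list(
      clones = nrow(ds$truth$clones),
      reads = nrow(ds$reads),
      reference_chromosomes = length(ds$reference),
      contaminated_clones = length(ds$truth$contaminated_clones),
      planted_repeat_copies = nrow(ds$truth$repeats)),
    outputs = lapply(ds$paths, normalizePath))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  ds$manifest <- manifest_path
  invisible(ds)
}

# pairs table (clone_id, read_f, read_r) from the clone list; read ids
# follow the <clone>_f / <clone>_r convention.
pairs_from_clones <- function(clone_ids, read_ids) {
  pairs <- data.frame(clone_id = clone_ids,
                      read_f = paste0(clone_ids, "_f"),
                      read_r = paste0(clone_ids, "_r"),
                      stringsAsFactors = FALSE)
  stray <- setdiff(read_ids, c(pairs$read_f, pairs$read_r))
  if (length(stray)) {
    stopf("reads not attributable to a clone (expected <clone>_f/_r ids): %s",
          paste(head(stray, 3), collapse = ", "))
  }
  per_clone <- table(sub("_[fr]$", "", read_ids))
  if (any(per_clone > 2)) {
    stopf("clone %s has more than two reads", names(per_clone)[per_clone > 2][1])
  }
  pairs
}

#' Analyse a BES dataset against a reference
#'
#' Runs the full analysis: vector/quality trimming, organelle screening,
#' repeat annotation and repeat-fraction exclusion, read mapping (or
#' imported external alignments), paired-end synteny classification,
#' expansion/contraction statistics and the repeat ledger. All reports
#' are written as TSV to `out_dir` with a YAML manifest.
#'
#' @param reads_path FASTQ (or FASTA) of BES reads, ids `<clone>_f/_r`.
#' @param reference_path reference genome FASTA.
#' @param inserts_path TSV with columns clone_id, insert_size.
#' @param cfg a [bes_config()].
#' @param out_dir report directory.
#' @param vector_path optional cloning-vector FASTA (enables vector trim).
#' @param organelle_path optional organelle FASTA (enables the screen).
#' @param repeat_library_path optional repeat consensus FASTA (enables
#'   repeat annotation and exclusion).
#' @param alignments_path optional pre-computed alignment table; when
#'   given the built-in mapper is bypassed.
#' @param alignments_dialect dialect of `alignments_path`.
#' @return invisible list of all stage results and report paths.
#' @export
run_analyze <- function(reads_path, reference_path, inserts_path,
                        cfg = bes_config(), out_dir,
                        vector_path = NULL, organelle_path = NULL,
                        repeat_library_path = NULL,
                        alignments_path = NULL,
                        alignments_dialect = "native") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  reads <- if (grepl("\\.(fq|fastq)$", reads_path, ignore.case = TRUE)) {
    read_fastq(reads_path)
  } else read_fasta(reads_path)
  reference <- as_genome(read_fasta(reference_path))
  inserts <- read_tsv(inserts_path)
  if (!all(c("clone_id", "insert_size") %in% names(inserts))) {
    stopf("insert table needs clone_id and insert_size columns")
  }
  vector_seq <- if (!is.null(vector_path)) as_genome(read_fasta(vector_path))[1]
  organelle <- if (!is.null(organelle_path)) as_genome(read_fasta(organelle_path))

  pairs <- pairs_from_clones(inserts$clone_id, reads$id)
  clone_of <- setNames(rep(inserts$clone_id, each = 2),
                       c(rbind(pairs$read_f, pairs$read_r)))

  # --- QC ---------------------------------------------------------------
  qc <- qc_reads(reads, cfg, vector_seq, organelle, clone_of)
  passed <- qc$reads

  # --- repeat annotation and exclusion ----------------------------------
  annotations <- data.frame(read_id = character(0), start = integer(0),
                            end = integer(0), family = character(0),
                            score = numeric(0), stringsAsFactors = FALSE)
  excluded <- character(0)
  if (!is.null(repeat_library_path)) {
    lib <- read_fasta(repeat_library_path)
    rindex <- build_repeat_index(lib, cfg$repeat_k)
    annotations <- annotate_reads(passed, rindex, cfg$repeat_min_score)
    frac <- vapply(seq_len(nrow(passed)), function(i) {
      repeat_fraction(nchar(passed$sequence[i]),
                      annotations[annotations$read_id == passed$id[i], ,
                                  drop = FALSE])
    }, numeric(1))
    excluded <- passed$id[frac > cfg$repeat_exclusion_fraction]
  }

  # --- mapping ----------------------------------------------------------
  mappable <- passed[!(passed$id %in% c(qc$contaminated_reads, excluded)), ,
                     drop = FALSE]
  if (!is.null(alignments_path)) {
    hits <- read_alignment_table(alignments_path, alignments_dialect)
    hits <- hits[hits$evalue <= cfg$max_evalue &
                   hits$query_id %in% mappable$id, , drop = FALSE]
  } else {
    index <- build_seed_index(reference, cfg$map_k)
    masks <- split(annotations[, c("start", "end")], annotations$read_id)
    hits <- map_reads(mappable, index, cfg, masks)
  }

  # --- synteny classification -------------------------------------------
  calls <- classify_library(pairs, hits, cfg,
                            excluded_reads = c(qc$contaminated_reads, excluded))
  counts <- class_count_table(calls)

  # --- expansion statistics ---------------------------------------------
  insert_sizes <- setNames(inserts$insert_size, inserts$clone_id)
  regions <- build_regions(calls, insert_sizes)
  agg <- aggregate_by_chromosome(regions)
  expansion_pct <- if (agg$grand_totals[["sum_query_bp"]] > 0) {
    total_expansion_percent(
      if (cfg$expansion_method == "per_region_mean") regions
      else agg$grand_totals,
      cfg$expansion_method)
  } else NA_real_

  genome_size <- if (!is.null(cfg$genome_size_bp)) cfg$genome_size_bp else
    sum(nchar(reference))
  coverage <- coverage_estimate(nrow(inserts), mean(inserts$insert_size),
                                genome_size)
  contamination_pct <- contamination_rate(length(qc$contaminated_clones),
                                          nrow(inserts))

  # --- repeat ledger ----------------------------------------------------
  total_read_bases <- sum(nchar(passed$sequence))
  ledger <- summarize_repeats(annotations, total_read_bases)

  # --- reports ----------------------------------------------------------
  paths <- list(
    qc = file.path(out_dir, "qc_report.tsv"),
    alignments = file.path(out_dir, "alignments.tsv"),
    annotations = file.path(out_dir, "repeat_annotations.tsv"),
    calls = file.path(out_dir, "synteny_calls.tsv"),
    class_counts = file.path(out_dir, "class_counts.tsv"),
    expansion = file.path(out_dir, "expansion_by_chromosome.tsv"),
    ledger = file.path(out_dir, "repeat_ledger.tsv"),
    summary = file.path(out_dir, "summary.tsv"))
  write_tsv(qc$report, paths$qc)
  write_alignment_table(hits, paths$alignments, "native")
  write_repeat_annotations(annotations, paths$annotations)
  write_tsv(calls, paths$calls)
  write_tsv(counts$counts, paths$class_counts)
  write_tsv(agg$by_chromosome, paths$expansion)
  write_tsv(as.data.frame(ledger), paths$ledger)
  summary_row <- data.frame(
    n_clones = nrow(inserts),
    n_input_reads = qc$report$n_input_reads,
    n_passing_reads = qc$report$n_passing_reads,
    aligned_bes = counts$aligned_bes,
    nohit_bes = counts$nohit_bes,
    n_concordant = sum(calls$class_label == "C1"),
    expansion_percent = expansion_pct,
    expansion_percent_rounded = round(expansion_pct),
    coverage_fold = round(coverage, 2),
    genome_size_bp = genome_size,
    contamination_percent = contamination_pct,
    total_read_bases = total_read_bases,
    repeat_percent_of_bases = round(
      100 * attr(ledger, "total_repeat_bases") / max(total_read_bases, 1), 2))
  write_tsv(summary_row, paths$summary)

  manifest <- list(
    tool = "besmap", version = besmap_version(), stage = "analyze",
    inputs = list(reads = reads_path, reference = reference_path,
                  inserts = inserts_path),
    counts = list(
      reads_in = nrow(reads),
      reads_passing_qc = nrow(passed),
      reads_rejected_qc = nrow(reads) - nrow(passed),
      reads_contaminated = length(qc$contaminated_reads),
      reads_repeat_excluded = length(excluded),
      reads_mapped = length(unique(hits$query_id)),
      alignments = nrow(hits),
      clones = nrow(inserts),
      clones_classified = nrow(calls),
      concordant_clones = sum(calls$class_label == "C1")),
    outputs = paths)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(qc = qc, annotations = annotations, excluded = excluded,
                 hits = hits, calls = calls, counts = counts,
                 regions = regions, aggregate = agg,
                 expansion_percent = expansion_pct, coverage = coverage,
                 contamination_percent = contamination_pct, ledger = ledger,
                 summary = summary_row, paths = paths,
                 manifest = manifest_path))
}

#' Recompute derived statistics from published summary tables
#'
#' Worked-example mode: consumes TSV transcriptions of the surveyed
#' library's summary tables (shipped under
#' `system.file("extdata", "ss_sba", package = "besmap")`) and recomputes
#' every derived quantity: syntenic-region grand totals and expansion
#' percent, class-count accounting (aligned and no-hit BES totals,
#' discordant same-chromosome clones), repeat-ledger fractions, coverage
#' and contamination.
#'
#' @param fixtures_dir directory with library_summary.tsv,
#'   bes_class_counts.tsv, syntenic_regions.tsv, repeat_ledger_nodes.tsv.
#' @param out_dir optional directory for the derived-statistics TSV.
#' @return named list of derived statistics.
#' @export
run_tables <- function(fixtures_dir, out_dir = NULL) {
  need <- c("library_summary.tsv", "bes_class_counts.tsv",
            "syntenic_regions.tsv", "repeat_ledger_nodes.tsv")
  for (f in need) {
    if (!file.exists(file.path(fixtures_dir, f))) {
      stopf("missing fixture %s in %s", f, fixtures_dir)
    }
  }
  lib <- read_tsv(file.path(fixtures_dir, "library_summary.tsv"))
  libv <- setNames(lib$value, lib$key)
  classes <- read_tsv(file.path(fixtures_dir, "bes_class_counts.tsv"))
  regions <- read_tsv(file.path(fixtures_dir, "syntenic_regions.tsv"))
  nodes <- read_tsv(file.path(fixtures_dir, "repeat_ledger_nodes.tsv"))

  # syntenic-region totals from the per-chromosome rows
  agg <- aggregate_by_chromosome(data.frame(
    clone_id = seq_len(nrow(regions)), chrom = regions$chrom,
    query_bp = regions$sum_query_bp, ref_bp = regions$sum_ref_bp,
    delta_bp = regions$sum_ref_bp - regions$sum_query_bp,
    direction = regions$direction, stringsAsFactors = FALSE))
  gt <- agg$grand_totals
  n_expanded <- sum(regions$n_regions[regions$direction == "expanded"])
  n_contracted <- sum(regions$n_regions[regions$direction == "contracted"])

  # class-count accounting
  aligned_bes <- sum(classes$n_bacs * classes$aligned_bes)
  n_hq <- as.numeric(libv[["n_hq_bes"]])
  nohit_bes <- n_hq - aligned_bes
  discordant_same_chrom <- sum(classes$n_bacs[classes$class_label %in%
                                                c("C2", "C3", "C4", "C5")])
  n_clone_total <- sum(classes$n_bacs)

  # repeat-ledger fractions
  ledger <- ledger_from_table(nodes)
  stats <- list(
    sum_query_bp = gt[["sum_query_bp"]],
    sum_ref_bp = gt[["sum_ref_bp"]],
    sum_delta_bp = gt[["sum_ref_bp"]] - gt[["sum_query_bp"]],
    expansion_percent = total_expansion_percent(gt),
    n_expanded_regions = n_expanded,
    n_contracted_regions = n_contracted,
    n_syntenic_regions = n_expanded + n_contracted,
    aligned_bes = aligned_bes,
    nohit_bes = nohit_bes,
    discordant_same_chrom_bacs = discordant_same_chrom,
    n_clones_classified = n_clone_total,
    copia_pct_of_ltr = fraction_of(ledger, "Copia", "LTR Retrotransposon"),
    gypsy_pct_of_ltr = fraction_of(ledger, "Gypsy", "LTR Retrotransposon"),
    ltr_pct_of_te = fraction_of(ledger, "LTR Retrotransposon",
                                "Transposable Element"),
    dna_pct_of_repeats = fraction_of(ledger, "DNA transposon", "Total"),
    nonltr_pct_of_repeats = fraction_of(ledger, "Non-LTR Retrotransposon",
                                        "Total"),
    ltr_pct_of_repeats = fraction_of(ledger, "LTR Retrotransposon", "Total"),
    coverage_fold_low = round(coverage_estimate(
      as.numeric(libv[["n_clones"]]), as.numeric(libv[["mean_insert_bp"]]),
      as.numeric(libv[["genome_size_high_bp"]])), 2),
    coverage_fold_high = round(coverage_estimate(
      as.numeric(libv[["n_clones"]]), as.numeric(libv[["mean_insert_bp"]]),
      as.numeric(libv[["genome_size_low_bp"]])), 2),
    coverage_fold_revised = round(coverage_estimate(
      as.numeric(libv[["n_clones"]]), as.numeric(libv[["mean_insert_bp"]]),
      as.numeric(libv[["genome_size_revised_bp"]])), 2),
    contamination_percent = contamination_rate(
      as.numeric(libv[["chloroplast_contaminated_clones"]]),
      as.numeric(libv[["n_sampled_clones"]])))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(data.frame(statistic = names(stats),
                         value = unlist(stats, use.names = FALSE)),
              file.path(out_dir, "derived_statistics.tsv"))
  }
  stats
}
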