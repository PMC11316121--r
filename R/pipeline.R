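#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage_log <- function(level, stage, msg) {
  lv <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  opt <- getOption("pirnascreen.log_level", "info")
  if (lv[[level]] >= lv[[opt]])
    message(sprintf("[%s] %s: %s", toupper(level), stage, msg))
}

#' Run the full demonstration pipeline
#'
#' Executes simulate -> screen -> phase -> enrich -> spectrum -> report on
#' seedable synthetic inputs plus the packaged cohort table, writing every
#' stage's outputs and a machine-readable run manifest to `out_dir`. With a
#' fixed seed the tabular outputs are byte-identical across reruns.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param sim A [sim_config()].
#' @param config A [screen_config()].
#' @param spec_config A [spectrum_config()].
#' @param n_control,n_case Small-RNA samples per group (defaults 3 and 3).
#' @param cohort_table Path to a cohort table TSV for the report stage;
#'   defaults to the packaged table.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, sim = sim_config(),
                         config = screen_config(),
                         spec_config = spectrum_config(),
                         n_control = 3L, n_case = 3L,
                         cohort_table = cohort_table_path()) {
  if (!file.exists(cohort_table))
    stop("input path does not exist: ", cohort_table)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("pirnascreen")),
                   stages = list())
  run_stage <- function(name, fun) {
    .stage_log("info", name, "starting")
    res <- tryCatch(fun(), error = function(e) {
      .stage_log("error", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), res)
    .stage_log("info", name, "done")
    res
  }

  # --- simulate -------------------------------------------------------------
  cohort <- assets <- samples <- NULL
  run_stage("simulate", function() {
    cohort <<- simulate_cohort(sim, seed)
    assets <<- make_toy_genome(sim, seed + 1L)
    samples <<- c(
      lapply(seq_len(n_control), function(i)
        c(simulate_smallrna_sample("control", sim, assets, seed + 10L + i),
          sample_id = sprintf("ctrl%d", i), group = "control")),
      lapply(seq_len(n_case), function(i)
        c(simulate_smallrna_sample("case", sim, assets, seed + 100L + i),
          sample_id = sprintf("case%d", i), group = "case")))
    joined <- merge(cohort$calls,
                    as.data.frame(cohort$variants), by = "variant_id")
    joined <- joined[order(joined$patient, joined$variant_id), ]
    write_tsv(joined[, c("patient", "chrom", "pos", "ref", "alt", "gene",
                         "consequence", "pop_af", "cadd", "zygosity")],
              file.path(out_dir, "simulated_cohort.tsv"))
    Biostrings::writeXStringSet(assets$genome,
                                file.path(out_dir, "toy_genome.fa"))
    write_bed(assets$loci, file.path(out_dir, "pirna_loci.bed"))
    write_bed(assets$blacklist, file.path(out_dir, "sncrna_blacklist.bed"))
    for (s in samples)
      write_smallrna_reads(s$reads,
                           file.path(out_dir, paste0(s$sample_id, ".fastq")))
    list(n_patients = nrow(cohort$truth),
         n_variants = nrow(cohort$variants),
         n_smallrna_samples = length(samples))
  })

  # --- screen ---------------------------------------------------------------
  screen <- excl <- NULL
  run_stage("screen", function() {
    screen <<- screen_cohort(cohort$variants, cohort$calls, cohort$panel,
                             config, cohort$phase_calls)
    excl <<- exclusion_screen(cohort$variants, cohort$calls,
                              list(cohort$exclusion_panel), config)
    write_tsv(screen$candidates, file.path(out_dir, "candidates.tsv"))
    jsonlite::write_json(screen$candidates,
                         file.path(out_dir, "candidates.json"),
                         dataframe = "rows", pretty = TRUE)
    write_tsv(excl, file.path(out_dir, "exclusion_report.tsv"))
    truth <- cohort$truth
    found <- paste(screen$candidates$patient, screen$candidates$gene)
    expected <- paste(truth$patient[truth$expected_candidate],
                      truth$gene[truth$expected_candidate])
    list(n_candidates = nrow(screen$candidates),
         n_needs_confirmation = nrow(screen$needs_confirmation),
         n_excluded = sum(excl$decision == "exclude"),
         screen_precision = if (length(found))
           mean(found %in% expected) else NA,
         screen_recall = if (length(expected))
           mean(expected %in% found) else NA)
  })

  # --- phase ----------------------------------------------------------------
  run_stage("phase", function() {
    trio <- simulate_trio("trans", seed + 200L)
    tp <- trio_phase(trio)
    frags <- simulate_fragments("trans", n = 20L, seed = seed + 201L)
    rp <- read_phase(frags)
    jsonlite::write_json(
      list(trio = list(configuration = tp$configuration,
                       evidence = tp$evidence),
           long_read = list(configuration = rp$configuration,
                            n_trans = rp$n_trans, n_cis = rp$n_cis)),
      file.path(out_dir, "phase_calls.json"), auto_unbox = TRUE, pretty = TRUE)
    list(trio_call = tp$configuration, long_read_call = rp$configuration)
  })

  # --- enrich ---------------------------------------------------------------
  run_stage("enrich", function() {
    testis <- c(sim$panel_genes, sim$background_genes)
    disc <- discovery_lof_genes(cohort$variants, cohort$calls, testis, config)
    ann <- c(list(pirna_processing = sim$panel_genes),
             lapply(stats::setNames(
               split(sim$background_genes,
                     rep(1:4, length.out = length(sim$background_genes))),
               paste0("decoy_term_", 1:4)), identity))
    res <- enrich(intersect(disc, testis), ann, universe = testis)
    write_tsv(as.data.frame(res), file.path(out_dir, "enrichment.tsv"))
    list(n_discovery_genes = length(disc), n_terms = nrow(res),
         top_term = if (nrow(res)) res$term[1L] else NA)
  })

  # --- spectrum ---------------------------------------------------------------
  run_stage("spectrum", function() {
    runs <- lapply(samples, function(s)
      run_spectrum_pipeline(s$reads, assets$genome, assets$loci,
                            assets$blacklist, spec_config,
                            sample_id = s$sample_id, group = s$group,
                            spikes = assets$spikes))
    spectra <- lapply(runs, `[[`, "spectrum")
    tab <- do.call(rbind, lapply(spectra, function(sp)
      data.frame(sample = sp$sample, group = sp$group,
                 length = as.integer(names(sp$counts)),
                 count = as.integer(sp$counts),
                 normalized = as.numeric(sp$normalized),
                 stringsAsFactors = FALSE)))
    write_tsv(tab, file.path(out_dir, "length_spectra.tsv"))
    cmp <- compare_case_control(spectra, spec_config)
    jsonlite::write_json(
      list(U = cmp$U, p_two_sided = cmp$p_two_sided, method = cmp$method,
           n_control = cmp$n_a, n_case = cmp$n_b,
           shapiro_control = cmp$normality$control[c("W", "p")],
           shapiro_case = cmp$normality$case[c("W", "p")]),
      file.path(out_dir, "spectrum_comparison.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(p_two_sided = cmp$p_two_sided,
         qc_pass = all(vapply(runs, function(r) r$qc$pass, logical(1))))
  })

  # --- report -----------------------------------------------------------------
  run_stage("report", function() {
    records <- parse_cohort_table(cohort_table)
    summ <- summarize_cohort(records)
    jsonlite::write_json(
      list(n_patients = summ$n_patients, n_genes = summ$n_genes,
           n_distinct_variants = summ$n_distinct_variants,
           n_homozygous = summ$n_homozygous,
           n_compound_het = summ$n_compound_het,
           semen_counts = as.list(summ$semen_counts),
           histology_counts = as.list(summ$histology_counts)),
      file.path(out_dir, "cohort_summary.json"), auto_unbox = TRUE,
      pretty = TRUE)
    list(n_patients = summ$n_patients, n_genes = summ$n_genes,
         n_distinct_variants = summ$n_distinct_variants,
         n_compound_het = summ$n_compound_het)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
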