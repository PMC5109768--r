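# End-to-end orchestration: simulate -> digest -> filter -> split ->
# classify -> characterize -> probes -> trees.

#' Pipeline run configuration
#'
#' Bundles all module configurations, a master seed, and the output
#' directory. Stage seeds are derived from the master seed by fixed
#' offsets.
#'
#' @param seed Master integer seed (required).
#' @param families Named list of [family_spec()] objects.
#' @param arrays List of [array_spec()] objects.
#' @param error_model An [error_model()].
#' @param reference Filtering/orientation reference; defaults to the
#'   phase-rotated consensus of the first family.
#' @param n_reads Named vector: reads per band.
#' @param cut_skip_prob Partial-digestion probability (source of
#'   site-bearing X dimers).
#' @param k_monomer,k_dimer Cluster counts for the two fits (`"auto"` for
#'   the silhouette choice).
#' @param n_components,train_size Classification parameters.
#' @param consensus_subset,identity_subset,tree_subset Per-family subset
#'   sizes for consensus building, identity estimation and trees.
#' @param probe_config A [probe_design_config()].
#' @param n_bootstrap Bootstrap replicates for the family tree.
#' @param out_dir Artifact directory, or `NULL` for no files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed,
                       families = solatus_families(),
                       arrays = default_arrays(),
                       error_model = alphasat::error_model(),
                       reference = NULL,
                       n_reads = c(monomer = 4000, dimer = 1500),
                       cut_skip_prob = 0.10,
                       k_monomer = "auto", k_dimer = "auto",
                       n_components = 100, train_size = 2500,
                       consensus_subset = 500, identity_subset = 200,
                       tree_subset = 12,
                       probe_config = probe_design_config(),
                       n_bootstrap = 100,
                       out_dir = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is required", call. = FALSE)
  }
  if (is.null(reference)) reference <- phase_rotate(families[[1]]$consensus)
  structure(list(seed = as.integer(seed), families = families,
                 arrays = arrays, error_model = error_model,
                 reference = reference, n_reads = n_reads,
                 cut_skip_prob = cut_skip_prob,
                 k_monomer = k_monomer, k_dimer = k_dimer,
                 n_components = n_components, train_size = train_size,
                 consensus_subset = consensus_subset,
                 identity_subset = identity_subset,
                 tree_subset = tree_subset, probe_config = probe_config,
                 n_bootstrap = n_bootstrap, out_dir = out_dir),
            class = "run_config")
}

.save <- function(cfg, name, writer) {
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    writer(file.path(cfg$out_dir, name))
  }
}

#' Run the full pipeline
#'
#' Executes every stage in order on a synthetic genome: simulation,
#' digestion-targeted read generation for both gel bands, the four-stage
#' filter cascade, dimer splitting into paired monomers, family
#' classification of the monomer dataset and of the dimer-derived
#' monomers, per-family characterization (consensus, identity, motif
#' frequencies, duplicate census with artifact test, left-right
#' association), probe design, and a bootstrapped family tree. When
#' `out_dir` is set, plain-text artifacts (FASTA/FASTQ/TSV/newick) are
#' written for every stage.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  fc <- filter_config(reference = config$reference)

  genome <- simulate_genome(config$families, config$arrays, seed = seed + 1L)
  .save(config, "genome.fasta",
        function(p) write_fasta(c(genome = genome$genome), p))
  .save(config, "genome_truth.tsv", function(p) write_tsv(genome$copies, p))

  reads <- list(
    monomer = simulate_reads(genome, config$error_model, "monomer",
                             config$n_reads[["monomer"]], seed = seed + 2L,
                             cut_skip_prob = config$cut_skip_prob),
    dimer = simulate_reads(genome, config$error_model, "dimer",
                           config$n_reads[["dimer"]], seed = seed + 3L,
                           cut_skip_prob = config$cut_skip_prob))
  for (band in names(reads)) {
    .save(config, paste0("reads_", band, ".fastq"),
          function(p) write_reads_fastq(reads[[band]], p))
    .save(config, paste0("truth_", band, ".tsv"),
          function(p) write_tsv(reads[[band]], p))
  }

  filtered <- lapply(names(reads), function(band) {
    run_filter_cascade(reads[[band]], fc, band)
  })
  names(filtered) <- names(reads)
  for (band in names(filtered)) {
    .save(config, paste0("filter_report_", band, ".tsv"),
          function(p) write_tsv(filtered[[band]]$report, p))
  }
  monomer_records <- filtered$monomer$records
  .save(config, "monomer_dataset.fasta", function(p) {
    write_fasta(stats::setNames(monomer_records$bases, monomer_records$id), p)
  })

  split <- build_pairs(filtered$dimer$records, config$reference)
  .save(config, "dimer_splits.tsv", function(p) write_tsv(split$pairs, p))
  if (!is.null(split$monomers) && nrow(split$monomers) > 0) {
    for (side in c("dimer_left", "dimer_right")) {
      rec <- split$monomers[split$monomers$source == side, ]
      .save(config, paste0(side, ".fasta"), function(p) {
        write_fasta(stats::setNames(
          rec$bases, paste0(rec$id, " partner=", rec$partner_id)), p)
      })
    }
  }

  # family classification of the monomer dataset
  profiles <- kmer_profile(stats::setNames(monomer_records$bases,
                                           monomer_records$id))
  model <- fit_family_model(profiles, n_components = config$n_components,
                            train_size = config$train_size,
                            k = config$k_monomer, seed = seed + 4L)
  assign <- assign_families(model, profiles)
  .save(config, "assignments_monomer.tsv", function(p) write_tsv(assign, p))
  scores <- project_profiles(model, profiles)
  .save(config, "pca_scatter.tsv", function(p) {
    write_tsv(data.frame(id = assign$id, PC1 = scores[, 1],
                         PC2 = scores[, 2], family = assign$family), p)
  })

  # dimer-derived monomers: separate fit + assignment
  dimer_report <- NULL
  association <- NULL
  if (!is.null(split$monomers) && nrow(split$monomers) >= 10) {
    dprof <- kmer_profile(stats::setNames(split$monomers$bases,
                                          split$monomers$id))
    dmodel <- fit_family_model(dprof, n_components = config$n_components,
                               train_size = config$train_size,
                               k = config$k_dimer, seed = seed + 5L)
    dassign <- assign_families(dmodel, dprof)
    .save(config, "assignments_dimer.tsv", function(p) write_tsv(dassign, p))
    lab <- stats::setNames(dassign$family, dassign$id)
    lefts <- split$monomers[split$monomers$source == "dimer_left", ]
    association <- association_test(lab[lefts$id], lab[lefts$partner_id],
                                    seed = seed + 6L)
    .save(config, "association.tsv", function(p) {
      write_tsv(as.data.frame.matrix(association$table), p)
    })
    dimer_report <- list(
      n_pairs = nrow(lefts),
      dataset_sizes = table(split$pairs$dataset[split$pairs$kept]),
      k = dmodel$k,
      family_sizes = table(dassign$family))
  }

  # per-family characterization of the monomer dataset
  fam_members <- split(monomer_records$bases, assign$family)
  characterization <- lapply(names(fam_members), function(f) {
    mem <- fam_members[[f]]
    cons <- if (length(mem) >= 2) {
      build_consensus(mem, subset_size = config$consensus_subset,
                      seed = seed + 7L)
    } else NULL
    list(family = f, n = length(mem),
         consensus = cons,
         identity = if (length(mem) >= 2) {
           mean_pairwise_identity(mem, subset_size = config$identity_subset,
                                  seed = seed + 8L)
         } else NA_real_,
         pjalpha = motif_frequency(mem, PJALPHA_BOX),
         cenpb = motif_frequency(mem, CENPB_BOX))
  })
  names(characterization) <- names(fam_members)
  .save(config, "consensus.fasta", function(p) {
    cs <- vapply(characterization, function(x) {
      if (is.null(x$consensus)) "" else x$consensus$consensus
    }, "")
    write_fasta(cs[nzchar(cs)], p)
  })

  census <- duplicate_census(monomer_records)
  census <- orientation_bias_test(census)
  .save(config, "census.tsv",
        function(p) write_tsv(census[census$copy_number >= 2, ], p))

  # probe design per monomer family
  probes <- lapply(names(fam_members), function(f) {
    cons <- characterization[[f]]$consensus
    if (is.null(cons)) return(NULL)
    enumerate_candidates(cons$consensus, fam_members, f,
                         config$probe_config)
  })
  names(probes) <- names(fam_members)
  for (f in names(probes)) {
    if (!is.null(probes[[f]]) && nrow(probes[[f]]) > 0) {
      .save(config, paste0("probes_", f, ".tsv"),
            function(p) write_tsv(probes[[f]], p))
    }
  }

  # family tree on a per-family subset of the monomer dataset
  tree <- NULL
  if (length(fam_members) >= 2) {
    sel <- with_seed(seed + 9L, {
      unlist(lapply(names(fam_members), function(f) {
        mem <- fam_members[[f]]
        take <- sample.int(length(mem), min(config$tree_subset, length(mem)))
        stats::setNames(mem[take], paste0(f, "_", seq_along(take)))
      }))
    })
    aln <- project_align(sel, config$reference)
    tree <- bootstrap_support(aln, n_reps = config$n_bootstrap,
                              seed = seed + 10L)
    .save(config, "family_tree.nwk", function(p) ape::write.tree(tree, p))
  }

  structure(list(
    seed = seed,
    filter_reports = lapply(filtered, `[[`, "report"),
    n_monomer_dataset = nrow(monomer_records),
    monomer_k = model$k,
    family_sizes = table(assign$family),
    characterization = characterization,
    census = census,
    n_artifact_flagged = sum(census$artifact_flag, na.rm = TRUE),
    split = split$pairs,
    dimer = dimer_report,
    association = association,
    probes = probes,
    tree = tree), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("alpha satellite pipeline run (seed ", x$seed, ")\n", sep = "")
  for (band in names(x$filter_reports)) {
    r <- x$filter_reports[[band]]
    cat("  ", band, " band cascade: ",
        paste(r$stage, r$count, sep = "=", collapse = " > "), "\n", sep = "")
  }
  cat("  monomer dataset: ", x$n_monomer_dataset, " sequences in ",
      x$monomer_k, " families (",
      paste(names(x$family_sizes), as.integer(x$family_sizes),
            sep = ":", collapse = ", "), ")\n", sep = "")
  for (f in names(x$characterization)) {
    ch <- x$characterization[[f]]
    cat(sprintf("    %s: n=%d identity=%.1f%% pJalpha=%.2f CENP-B=%.4f\n",
                f, ch$n, ch$identity, ch$pjalpha, ch$cenpb))
  }
  cat("  duplicate groups (>=2 copies): ",
      sum(x$census$copy_number >= 2), "; artifact-flagged: ",
      x$n_artifact_flagged, "\n", sep = "")
  if (!is.null(x$dimer)) {
    cat("  dimer pairs: ", x$dimer$n_pairs, " (",
        paste(names(x$dimer$dataset_sizes),
              as.integer(x$dimer$dataset_sizes), sep = ":",
              collapse = ", "), "), k=", x$dimer$k, "\n", sep = "")
  }
  if (!is.null(x$association) && !is.na(x$association$p.value)) {
    cat(sprintf("  left-right association: X2=%.1f p=%.3g (%s)\n",
                x$association$statistic, x$association$p.value,
                x$association$method))
  }
  invisible(x)
}
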