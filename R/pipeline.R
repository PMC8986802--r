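#' Build a validated pipeline configuration
#'
#' The configuration is a plain list (YAML-serialisable, versioned schema).
#' Either point the run at existing inputs (`genome_fasta`,
#' `annotations_bed`, `plate_tsv`, `r1_fastq`, `r2_fastq`, optionally
#' `counts_tsv`) or supply a `simulate` block to generate them first.
#'
#' @param out_dir output directory for the run.
#' @param genome_fasta,annotations_bed,plate_tsv,r1_fastq,r2_fastq,counts_tsv
#'   input paths (validated to exist when given and no `simulate` block is
#'   present).
#' @param simulate optional list: `n_cells`, `methylation` (recycled per
#'   cell, proportions), `n_read_pairs`, `consensus_length`, `cpg_density`,
#'   `n_copies`, `divergence`, `flank_len`, `n_wells`.
#' @param te_site_threshold QC threshold on distinct TE elements (1000
#'   default, 500 for the HL60 preset).
#' @param max_mismatch index demultiplexing mismatch tolerance.
#' @param trim5,trim3 post-demultiplex end trims.
#' @param bootstrap_depths optional depths for the stability analysis.
#' @param n_boot_reps replicates per bootstrap depth.
#' @param fdr_threshold significance cutoff for the correlation stage.
#' @param seed master seed for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            genome_fasta = NULL, annotations_bed = NULL,
                            plate_tsv = NULL, r1_fastq = NULL,
                            r2_fastq = NULL, counts_tsv = NULL,
                            simulate = NULL,
                            te_site_threshold = 1000L, max_mismatch = 1L,
                            trim5 = 10L, trim3 = 10L,
                            bootstrap_depths = NULL, n_boot_reps = 20L,
                            fdr_threshold = 0.05, seed = 1L,
                            schema_version = 1L) {
  thr <- c(te_site_threshold, max_mismatch, trim5, trim3, n_boot_reps)
  if (any(thr < 0)) stop("thresholds must be nonnegative", call. = FALSE)
  if (is.null(simulate)) {
    for (p in c(genome_fasta, annotations_bed, plate_tsv, r1_fastq,
                r2_fastq, counts_tsv)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("configured path does not exist: ", p, call. = FALSE)
      }
    }
    need <- list(genome_fasta = genome_fasta,
                 annotations_bed = annotations_bed, plate_tsv = plate_tsv,
                 r1_fastq = r1_fastq, r2_fastq = r2_fastq)
    miss <- names(need)[vapply(need, is.null, logical(1L))]
    if (length(miss)) {
      stop("without a simulate block the config must provide: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  } else if (!is.null(counts_tsv) && !file.exists(counts_tsv)) {
    stop("configured path does not exist: ", counts_tsv, call. = FALSE)
  }
  structure(list(schema_version = schema_version, out_dir = out_dir,
                 genome_fasta = genome_fasta,
                 annotations_bed = annotations_bed, plate_tsv = plate_tsv,
                 r1_fastq = r1_fastq, r2_fastq = r2_fastq,
                 counts_tsv = counts_tsv, simulate = simulate,
                 te_site_threshold = as.integer(te_site_threshold),
                 max_mismatch = as.integer(max_mismatch),
                 trim5 = as.integer(trim5), trim3 = as.integer(trim3),
                 bootstrap_depths = bootstrap_depths,
                 n_boot_reps = as.integer(n_boot_reps),
                 fdr_threshold = fdr_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full scTEM-seq pipeline
#'
#' Executes (optional) simulation, demultiplexing, bisulfite alignment,
#' methylation calling, (optional) bootstrap stability and (optional)
#' methylation-expression correlation, writing every output plus a
#' checksum manifest under `config$out_dir`. Reruns with identical
#' configuration and seed reproduce identical checksums. On stage failure
#' partial outputs are moved to a `quarantine/` subdirectory and the run
#' aborts naming the stage.
#'
#' @param config a [pipeline_config()] (or path to its YAML).
#' @return Invisible list with `status` (0), `manifest` (file/md5
#'   data.frame) and `summary` (per-cell methylation table).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      qdir <- file.path(out, "quarantine")
      dir.create(qdir, showWarnings = FALSE)
      for (f in outputs) {
        if (file.exists(f)) file.rename(f, file.path(qdir, basename(f)))
      }
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(path) { outputs <<- c(outputs, path); path }

  sim <- config$simulate
  if (!is.null(sim)) {
    stage("simulate", {
      cons <- build_consensus(sim$consensus_length %||% 300L,
                              sim$cpg_density %||% 0.08,
                              seed = derive_seed(config$seed, "consensus"))
      tg <- synth_genome(cons, sim$n_copies %||% 2000L,
                         divergence = sim$divergence %||% 0.05,
                         flank_len = sim$flank_len %||% 100L,
                         seed = derive_seed(config$seed, "genome"))
      plate <- design_plate(cons, n_wells = sim$n_wells %||% 96L,
                            seed = derive_seed(config$seed, "plate"))
      n_cells <- sim$n_cells %||% 8L
      meth <- rep(sim$methylation %||% c(0.865, 0.42),
                  length.out = n_cells)
      params <- lapply(seq_len(n_cells), function(i) {
        cell_sim_params(
          cell_id = sprintf("cell%02d", i),
          well_id = plate$well_id[i],
          true_methylation = meth[i],
          n_read_pairs = sim$n_read_pairs %||% 5000L,
          seed = derive_seed(config$seed, "cell", i)
        )
      })
      pool <- simulate_plate(tg$genome, tg$annotations, plate, params,
                             seed = derive_seed(config$seed, "pool"))
      config$genome_fasta <-
        emit(write_fasta(stats::setNames(tg$genome$seq, tg$genome$name),
                         file.path(out, "genome.fa")))
      config$annotations_bed <-
        emit(write_bed(tg$annotations, file.path(out, "annotations.bed")))
      config$plate_tsv <- emit(write_plate(plate,
                                            file.path(out, "plate.tsv")))
      config$r1_fastq <- emit(write_fastq(pool$r1,
                                           file.path(out, "reads_R1.fastq")))
      config$r2_fastq <- emit(write_fastq(pool$r2,
                                           file.path(out, "reads_R2.fastq")))
      tt <- pool$truth_table
      data.table::fwrite(tt, emit(file.path(out, "truth_table.tsv")),
                         sep = "\t")
    })
  }

  env <- new.env()
  stage("load-inputs", {
    fa <- read_fasta(config$genome_fasta)
    env$genome <- list(name = names(fa)[1L], seq = unname(fa[1L]))
    env$annotations <- read_bed(config$annotations_bed)
    env$plate <- read_plate(config$plate_tsv)
  })

  stage("demux", {
    env$dm <- demultiplex(config$r1_fastq, config$r2_fastq, env$plate,
                          max_mismatch = config$max_mismatch)
    rep <- env$dm$report$per_well
    rep$unassigned <- env$dm$report$unassigned
    rep$ambiguous <- env$dm$report$ambiguous
    data.table::fwrite(rep, emit(file.path(out, "demux_report.tsv")),
                       sep = "\t")
  })

  stage("methylation", {
    active <- names(env$dm$wells)[vapply(env$dm$wells, function(w) {
      length(w$r1) > 0L
    }, logical(1L))]
    summaries <- list()
    env$calls <- list()
    for (w in active) {
      pw <- process_well(env$dm$wells[[w]]$r1, env$dm$wells[[w]]$r2,
                         env$genome, env$annotations, cell_id = w,
                         te_site_threshold = config$te_site_threshold,
                         trim5 = config$trim5, trim3 = config$trim3)
      write_cov(pw$cov, emit(file.path(out, paste0(w, ".cov"))))
      summaries[[w]] <- pw$summary
      env$calls[[w]] <- pw$calls
    }
    env$summary <- do.call(rbind, summaries)
    data.table::fwrite(env$summary, emit(file.path(out, "summary.tsv")),
                       sep = "\t")
  })

  if (!is.null(config$bootstrap_depths)) {
    stage("bootstrap", {
      tabs <- lapply(names(env$calls), function(w) {
        bs <- suppressWarnings(
          bootstrap_stability(env$calls[[w]], config$bootstrap_depths,
                              n_reps = config$n_boot_reps,
                              seed = derive_seed(config$seed, "boot", w)))
        if (nrow(bs$table)) cbind(cell_id = w, bs$table) else NULL
      })
      tabs <- tabs[!vapply(tabs, is.null, logical(1L))]
      if (length(tabs)) {
        data.table::fwrite(do.call(rbind, tabs),
                           emit(file.path(out, "bootstrap.tsv")), sep = "\t")
      }
    })
  }

  if (!is.null(config$counts_tsv)) {
    stage("correlate", {
      counts <- read_counts(config$counts_tsv)
      keep <- env$summary$qc_pass
      meth <- stats::setNames(env$summary$mean_site_methylation,
                              env$summary$cell_id)[keep]
      expr <- normalize_expression(filter_features(counts,
                                                   preset = "standard"))
      res <- correlate_methylation_expression(meth, expr)
      data.table::fwrite(res, emit(file.path(out, "correlations.tsv")),
                         sep = "\t")
      paths <- export_ranked_genes(res, counts, out,
                                   fdr_threshold = config$fdr_threshold)
      emit(paths[["significant"]]); emit(paths[["background"]])
    })
  }

  manifest <- stage("manifest", {
    files <- sort(unique(basename(outputs)))
    md5 <- tools::md5sum(file.path(out, files))
    mf <- data.frame(file = files, md5 = unname(md5),
                     stringsAsFactors = FALSE)
    data.table::fwrite(mf, file.path(out, "manifest.tsv"), sep = "\t")
    mf
  })
  invisible(list(status = 0L, manifest = manifest, summary = env$summary))
}
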