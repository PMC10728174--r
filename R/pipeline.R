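#' @title End-to-end pipeline orchestration
#'
#' @description
#' Runs the stages over a sample sheet: primer-identity classification and
#' translocation filtering of raw FASTQs, (optionally) external alignment
#' and pileup generation, mutation calling from pileups, and the
#' delta/metagene/summary analysis. Samples come in damaged/undamaged
#' (`plus_dsb`/`minus_dsb`) pairs per treatment; the damaged-undamaged
#' delta is computed per treatment and, when a control treatment is named,
#' the chained treatment-control delta as well.
#'
#' @name pipeline_cli
NULL

CONFIG_KEYS <- c("pool", "out_dir", "control_treatment", "stages", "params",
                 "samples")
STAGE_KEYS <- c("transloc", "align", "call", "analyze")
PARAM_KEYS <- c("min_depth", "adjacency_bp", "window", "max_mismatch", "seed")
SAMPLE_KEYS <- c("id", "condition", "treatment", "pileup", "fastq")

#' Load and validate a pipeline configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (no silent
#' ignoring), fills defaults (`window` 100, `adjacency_bp` 10, `min_depth`
#' 100, `max_mismatch` 1, all stages on except `align`), and checks the
#' sample sheet: ids unique, conditions in `plus_dsb`/`minus_dsb`, every
#' `plus_dsb` sample matched by a `minus_dsb` sample of the same
#' treatment, and input paths present for the enabled stages.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop("config validation error: unknown key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(cfg, CONFIG_KEYS, "top level")
  if (is.null(cfg$pool)) stop("config validation error: 'pool' is required")
  if (is.null(cfg$samples) || !length(cfg$samples))
    stop("config validation error: 'samples' is required")
  check_keys(cfg$stages, STAGE_KEYS, "stages")
  check_keys(cfg$params, PARAM_KEYS, "params")
  stages <- utils::modifyList(list(transloc = TRUE, align = FALSE,
                                   call = TRUE, analyze = TRUE),
                              cfg$stages %||% list())
  params <- utils::modifyList(list(min_depth = 100L, adjacency_bp = 10L,
                                   window = 100L, max_mismatch = 1L,
                                   seed = 1L),
                              cfg$params %||% list())
  samples <- lapply(cfg$samples, function(s) {
    check_keys(s, SAMPLE_KEYS, paste0("sample '", s$id %||% "?", "'"))
    if (is.null(s$id) || is.null(s$condition) || is.null(s$treatment))
      stop("config validation error: every sample needs id, condition ",
           "and treatment")
    if (!s$condition %in% c("plus_dsb", "minus_dsb"))
      stop("config validation error: sample '", s$id, "' condition must ",
           "be plus_dsb or minus_dsb")
    s
  })
  ids <- vapply(samples, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("config validation error: duplicate sample id '",
         ids[duplicated(ids)][1], "'")
  cond <- vapply(samples, `[[`, "", "condition")
  treat <- vapply(samples, `[[`, "", "treatment")
  for (tr in unique(treat[cond == "plus_dsb"]))
    if (!any(cond == "minus_dsb" & treat == tr))
      stop("config validation error: treatment '", tr, "' has a plus_dsb ",
           "sample but no matched minus_dsb sample")
  if (!file.exists(cfg$pool))
    stop("config validation error: pool file not found: ", cfg$pool)
  for (s in samples) {
    if (stages$transloc && !is.null(s$fastq))
      for (p in unlist(s$fastq))
        if (!file.exists(p))
          stop("config validation error: sample '", s$id,
               "' FASTQ not found: ", p)
    if (stages$call && !stages$align && is.null(s$pileup) &&
        is.null(s$fastq))
      stop("config validation error: sample '", s$id, "' has neither ",
           "pileup nor fastq input")
    if (stages$call && !stages$align && !is.null(s$pileup) &&
        !file.exists(s$pileup))
      stop("config validation error: sample '", s$id,
           "' pileup not found: ", s$pileup)
  }
  out <- list(pool = cfg$pool, out_dir = cfg$out_dir %||% "imutseq_out",
              control_treatment = cfg$control_treatment,
              stages = stages, params = params, samples = samples)
  class(out) <- "run_config"
  out
}

#' Write a (normalised) run configuration back to YAML
#'
#' `load_config(write_config(cfg))` is the identity on validated configs.
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the pipeline over a configuration
#'
#' Per sample: the transloc stage scans raw FASTQs, writes the
#' translocation matrix and the cis/trans split (translocated reads must
#' not reach the mutation caller); the optional align stage hands the cis
#' reads to an external aligner and pileup generator; the call stage turns
#' pileup text into an mprofile plus deletion annotations. Per treatment,
#' the analyze stage computes the damaged-undamaged delta, the chained
#' delta against the control treatment (when named), HR/NHEJ metagene
#' profiles, per-locus summaries and translocation summaries. Outputs are
#' TSV/CSV under `out_dir`; `run_info.yaml` records the effective
#' configuration, its hash, the seed, and per-stage counts. Any stage
#' failure aborts with the stage name, leaving an `INCOMPLETE` marker.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @return Invisibly, a list with the per-sample profiles, per-treatment
#'   deltas, summaries, and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)
  stage <- "setup"
  log <- list()
  res <- tryCatch({
    pool <- load_primer_pool(config$pool,
                             max_mismatch = config$params$max_mismatch)
    cfg_path <- file.path(out_dir, "effective_config.yaml")
    write_config(config, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))

    samples <- config$samples
    names(samples) <- vapply(samples, `[[`, "", "id")
    profiles <- list(); matrices <- list()

    for (s in samples) {
      if (config$stages$transloc && !is.null(s$fastq)) {
        stage <- paste0("transloc[", s$id, "]")
        scan <- scan_fastq(s$fastq$r1, s$fastq$r2, pool,
                           out_prefix = file.path(out_dir, s$id),
                           max_mismatch = config$params$max_mismatch)
        write_transloc_matrix(scan$matrix, file.path(out_dir, s$id))
        write.table(scan$report,
                    file.path(out_dir, paste0(s$id, "_transloc_report.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        matrices[[s$id]] <- scan$matrix
        log[[stage]] <- setNames(scan$report$count, scan$report$status)
        message("[", stage, "] ", scan$report$count[4], " pairs: ",
                scan$report$count[1], " cis, ", scan$report$count[2],
                " trans, ", scan$report$count[3], " unmatched")
        s$fastq <- list(r1 = scan$files$cis_r1, r2 = scan$files$cis_r2)
      }
      if (config$stages$align && is.null(s$pileup)) {
        stage <- paste0("align[", s$id, "]")
        s$pileup <- align_and_pileup(s$fastq$r1, s$fastq$r2, pool,
                                     file.path(out_dir, s$id))
      }
      if (config$stages$call && !is.null(s$pileup)) {
        stage <- paste0("call[", s$id, "]")
        prof <- pileup_to_profile(s$pileup, pool,
                                  min_depth = config$params$min_depth,
                                  adjacency_bp = config$params$adjacency_bp)
        write_mprofile(prof,
                       file.path(out_dir, paste0(s$id, "_mprofile.tsv")),
                       file.path(out_dir, paste0(s$id, "_deletions.tsv")))
        profiles[[s$id]] <- prof
        med <- stats::median(prof$depth)
        if (med < 10 * config$params$min_depth)
          warning("sample '", s$id, "': median depth ", med,
                  " is below 10x min_depth", call. = FALSE)
        log[[stage]] <- c(positions = nrow(prof))
        message("[", stage, "] ", nrow(prof), " positions profiled")
      }
    }

    deltas <- list(); chained <- list(); summaries <- list()
    transloc_sum <- lapply(matrices, translocation_summary, pool = pool)
    if (config$stages$analyze) {
      stage <- "analyze"
      cond <- vapply(samples, `[[`, "", "condition")
      treat <- vapply(samples, `[[`, "", "treatment")
      called <- names(samples)[names(samples) %in% names(profiles)]
      for (tr in unique(treat)) {
        plus <- called[treat[called] == tr & cond[called] == "plus_dsb"]
        minus <- called[treat[called] == tr & cond[called] == "minus_dsb"]
        if (!length(plus) || !length(minus)) next
        d <- delta_profiles(profiles[[plus[1]]], profiles[[minus[1]]])
        deltas[[tr]] <- d
        write_delta_profile(d, file.path(out_dir,
                                         paste0(tr, "_delta.tsv")))
        summaries[[tr]] <- locus_summary(profiles[[plus[1]]], pool,
                                         window = config$params$window)
        write.table(summaries[[tr]],
                    file.path(out_dir, paste0(tr, "_locus_summary.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        for (grp in c("HR", "NHEJ")) {
          if (!any(pool$repair_class == grp)) next
          mg <- metagene_profile(d, pool, grp,
                                 window = config$params$window)
          write_metagene(mg, file.path(out_dir,
                           paste0(tr, "_metagene_", grp, "_sub.tsv")))
        }
      }
      ctrl <- config$control_treatment
      if (!is.null(ctrl) && ctrl %in% names(deltas))
        for (tr in setdiff(names(deltas), ctrl)) {
          ch <- delta_profiles(deltas[[tr]], deltas[[ctrl]])
          chained[[tr]] <- ch
          write_delta_profile(ch, file.path(out_dir,
                               paste0(tr, "_vs_", ctrl, "_delta.tsv")))
        }
      message("[analyze] ", length(deltas), " treatment delta(s), ",
              length(chained), " chained delta(s)")
    }

    stage <- "provenance"
    yaml::write_yaml(list(config_hash = cfg_hash,
                          seed = config$params$seed,
                          stage_counts = lapply(log, as.list)),
                     file.path(out_dir, "run_info.yaml"))
    file.remove(marker)
    invisible(list(pool = pool, profiles = profiles, matrices = matrices,
                   deltas = deltas, chained = chained,
                   summaries = summaries, transloc_summary = transloc_sum,
                   out_dir = out_dir))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs in ", out_dir, " are marked INCOMPLETE)",
         call. = FALSE)
  })
  res
}

# External alignment + pileup wrapper (bowtie2 + samtools); used only when
# the align stage is enabled and the executables are on PATH.
align_and_pileup <- function(r1, r2, pool, out_prefix,
                             genome = default_aligner_genome(),
                             space = default_aligner_space()) {
  for (exe in c("bowtie2", "bowtie2-build", "samtools"))
    if (Sys.which(exe) == "")
      stop("align stage requires '", exe, "' on PATH; provide pileup ",
           "inputs to bypass alignment")
  ref <- paste0(out_prefix, "_ref.fasta")
  write_reference_fasta(pool, ref)
  idx <- paste0(out_prefix, "_idx")
  run <- function(cmd, args) {
    st <- system2(cmd, args, stdout = paste0(out_prefix, "_align.log"),
                  stderr = paste0(out_prefix, "_align.log"))
    if (st != 0L) stop(cmd, " failed with exit status ", st)
  }
  run("bowtie2-build", c(shQuote(ref), shQuote(idx)))
  sam <- paste0(out_prefix, ".sam"); bam <- paste0(out_prefix, ".bam")
  run("bowtie2", c(emit_aligner_args(genome, space), "-x", shQuote(idx),
                   "-1", shQuote(r1), "-2", shQuote(r2), "-S", shQuote(sam)))
  run("samtools", c("sort", "-o", shQuote(bam), shQuote(sam)))
  run("samtools", c("index", shQuote(bam)))
  pile <- paste0(out_prefix, ".pileup")
  st <- system2("samtools", c("mpileup", "-f", shQuote(ref), "-A", "-B",
                              "-d", "0", shQuote(bam)), stdout = pile)
  if (st != 0L) stop("samtools mpileup failed with exit status ", st)
  pile
}
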