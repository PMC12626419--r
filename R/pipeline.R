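#' Pipeline run configuration
#'
#' @param wav_dir Directory of input WAV files.
#' @param out_dir Output directory for per-stage artifacts.
#' @param seg_table Optional path to an externally produced segment CSV
#'   (e.g. a neural segmenter's output); when `NULL` the amplitude
#'   segmenter is used.
#' @param onset_thr,offset_thr Amplitude-segmentation thresholds.
#' @param seed Seed for the embedding stage.
#' @param min_cluster_size Optional clustering override.
#' @param resume Skip stages whose outputs already exist.
#' @return List of class `run_config`.
#' @export
run_config <- function(wav_dir, out_dir, seg_table = NULL,
                       onset_thr = 0.04, offset_thr = 0.05, seed = 42L,
                       min_cluster_size = NULL, resume = FALSE) {
  structure(list(wav_dir = wav_dir, out_dir = out_dir, seg_table = seg_table,
                 onset_thr = onset_thr, offset_thr = offset_thr,
                 seed = as.integer(seed), min_cluster_size = min_cluster_size,
                 resume = resume),
            class = "run_config")
}

#' Run the full song-phenotyping pipeline
#'
#' Executes segment -> label -> features on a directory of WAV files,
#' writing per-stage artifacts (`segments.csv`, `labels.csv`,
#' `features.csv`) plus a YAML snapshot of the effective configuration to
#' `out_dir`, and logging record counts and timings per stage. With
#' `resume = TRUE`, stages whose outputs already exist are skipped and
#' their outputs re-read, so a failed run restarts from the last completed
#' stage.
#'
#' @param config A [run_config] (or a path to a YAML file of its fields).
#' @return Invisibly, a one-row data frame: bird id columns plus the 55
#'   feature columns.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- do.call(run_config, yaml::read_yaml(config))
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$wav_dir)) {
    stop("WAV directory does not exist: ", config$wav_dir, call. = FALSE)
  }
  paths <- sort(list.files(config$wav_dir, pattern = "\\.[Ww][Aa][Vv]$",
                           full.names = TRUE))
  if (length(paths) == 0L) {
    stop("no WAV files found in ", config$wav_dir, call. = FALSE)
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  snap <- unclass(config)
  snap$min_cluster_size <- if (is.null(snap$min_cluster_size)) "auto" else snap$min_cluster_size
  snap$seg_table <- if (is.null(snap$seg_table)) "" else snap$seg_table
  yaml::write_yaml(snap, file.path(config$out_dir, "config_snapshot.yaml"))

  stage <- function(name, out_file, fn) {
    out_path <- file.path(config$out_dir, out_file)
    t0 <- Sys.time()
    if (config$resume && file.exists(out_path)) {
      message(sprintf("[%s] reusing existing %s", name, out_file))
      return(out_path)
    }
    fn(out_path)
    message(sprintf("[%s] wrote %s (%.1f s)", name, out_file,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out_path
  }

  recs <- lapply(paths, load_wav)
  names(recs) <- vapply(recs, `[[`, character(1), "source_id")
  message(sprintf("[load] %d files from %s", length(recs), config$wav_dir))

  seg_path <- stage("segment", "segments.csv", function(out) {
    if (!is.null(config$seg_table)) {
      segs <- read_segment_table(config$seg_table)
    } else {
      segs <- do.call(rbind, lapply(recs, function(r) {
        segment_amplitude(compute_rmse_trace(bandpass(r, 200, min(9000, 0.45 * r$rate))),
                          config$onset_thr, config$offset_thr)
      }))
    }
    write_segment_table(segs, out)
  })
  segs <- read_segment_table(seg_path)
  message(sprintf("[segment] %d segments", nrow(segs)))

  lab_path <- stage("label", "labels.csv", function(out) {
    specs <- prepare_syllable_spectrograms(recs, segs)
    embv <- embed_umap(specs, seed = config$seed)
    labs <- cluster_hdbscan(embv, min_cluster_size = config$min_cluster_size)
    labelled <- segment_table(segs$file, segs$onset, segs$offset, labs)
    write_segment_table(labelled, out)
  })
  labels <- read_segment_table(lab_path)
  message(sprintf("[label] %d clusters",
                  length(setdiff(unique(labels$label), "noise"))))

  feat_path <- stage("features", "features.csv", function(out) {
    syn <- syntax_features(labels)
    tim <- timing_features(labels, recs)
    aco <- summarize_by_type(recs, labels)
    fv <- assemble_feature_vector(aco, syn, tim)
    df <- as.data.frame(t(fv))
    df <- cbind(data.frame(bird = basename(config$wav_dir)), df)
    utils::write.csv(df, out, row.names = FALSE)
  })
  out <- utils::read.csv(feat_path, check.names = FALSE)
  message(sprintf("[features] %d feature columns", ncol(out) - 1L))
  invisible(out)
}
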