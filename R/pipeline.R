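#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input source
#' (simulated scenario presets or files on disk), band-extraction
#' parameters, segmentation, clustering, entropy estimation and the seed.
#'
#' @param scenario \code{"presets"} to simulate the control and radio
#'   cohorts, or \code{"files"} to analyse \code{inputs}.
#' @param inputs data frame with columns \code{path}, \code{subject},
#'   \code{group} (required when \code{scenario = "files"}).
#' @param output_dir directory for the result tables (created if absent).
#' @param fs sampling rate for table inputs lacking a sidecar.
#' @param levels,wavelet,denoise band-extraction parameters, see
#'   [extract_alpha()].
#' @param segment_seconds stage duration in seconds.
#' @param Z number of merge-order classes (default 4).
#' @param linkage clustering linkage, see [agglomerate()].
#' @param de_estimator,de_base differential-entropy parameters, see
#'   [differential_entropy()].
#' @param center mean-center signals before correlation (default FALSE).
#' @param alpha_level significance threshold for the rank-sum tables.
#' @param seed integer seed driving simulation and the Louvain sweep order.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = c("presets", "files"), inputs = NULL,
                            output_dir = "alphanet_out", fs = 500,
                            levels = 9L, wavelet = "db8",
                            denoise = c("none", "universal_soft"),
                            segment_seconds = 60, Z = 4L,
                            linkage = c("single", "complete", "average"),
                            de_estimator = c("gaussian", "histogram"),
                            de_base = exp(1), center = FALSE,
                            alpha_level = 0.05, seed = 1L) {
  scenario <- match.arg(scenario)
  if (scenario == "files") {
    stopifnot(is.data.frame(inputs),
              all(c("path", "subject", "group") %in% names(inputs)))
    missing <- inputs$path[!file.exists(inputs$path)]
    if (length(missing) > 0L)
      stop("input file(s) not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  stopifnot(Z >= 1L)
  structure(list(scenario = scenario, inputs = inputs,
                 output_dir = output_dir, fs = fs, levels = as.integer(levels),
                 wavelet = wavelet, denoise = match.arg(denoise),
                 segment_seconds = segment_seconds, Z = as.integer(Z),
                 linkage = match.arg(linkage),
                 de_estimator = match.arg(de_estimator), de_base = de_base,
                 center = center, alpha_level = alpha_level,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment; values
#' are unquoted or double-quoted scalars.  Keys mirror the arguments of
#' [pipeline_config()].
#'
#' @param path path to the config file.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    val <- gsub('^"|"$', "", trimws(m[3]))
    num <- suppressWarnings(as.numeric(val))
    kv[[m[2]]] <- if (!is.na(num)) num else val
  }
  do.call(pipeline_config, kv)
}

#' Analyse one subject's recording through every stage
#'
#' Band extraction, segmentation, connectivity, clustering with merge-order
#' classes, Louvain communities, alpha ratios and node-level differential
#' entropy.
#'
#' @param rec an [eeg_recording()] of raw EEG.
#' @param subject,group identifiers carried into the result tables.
#' @param config a [pipeline_config()].
#' @return A list of per-subject tables and per-segment objects:
#'   \code{connectivity} (list of [connectivity_matrix()]),
#'   \code{assignments} (list of [assign_classes()] results),
#'   \code{trajectory}, \code{energy}, \code{alpha_ratios},
#'   \code{de}, \code{communities}.
#' @export
analyze_recording <- function(rec, subject, group, config = pipeline_config()) {
  montage <- default_montage()
  alpha <- extract_alpha(rec, levels = config$levels,
                         wavelet = config$wavelet, denoise = config$denoise)
  segs_raw <- segment_recording(rec, config$segment_seconds)
  segs_alpha <- segment_recording(alpha, config$segment_seconds)
  K <- length(segs_alpha$segments)
  connectivity <- vector("list", K)
  assignments <- vector("list", K)
  energy <- alpha_rows <- de_rows <- comm_rows <- vector("list", K)
  for (k in seq_len(K)) {
    seg <- segs_alpha$segments[[k]]
    F <- build_connectivity(seg, segment_index = k, center = config$center)
    connectivity[[k]] <- F
    dend <- agglomerate(node_vectors(F), linkage = config$linkage)
    assignments[[k]] <- assign_classes(dend, config$Z)
    louv <- louvain_communities(F, seed = config$seed)
    energy[[k]] <- data.frame(subject = subject, group = group, segment = k,
                              energy = global_connectivity_energy(F))
    alpha_rows[[k]] <- do.call(rbind, lapply(
      list(montage$frontal, montage$parieto_occipital), function(region) {
        r <- alpha_ratio(segs_raw$segments[[k]], region,
                         levels = config$levels, wavelet = config$wavelet,
                         segment_index = k)
        data.frame(subject = subject, group = group, segment = k,
                   region = region$name, ratio = r$value)
      }))
    de_rows[[k]] <- data.frame(
      subject = subject, group = group, segment = k, node = seg$labels,
      de = apply(seg$data, 1, differential_entropy,
                 estimator = config$de_estimator, base = config$de_base))
    comm_rows[[k]] <- data.frame(subject = subject, group = group,
                                 segment = k, node = names(louv$membership),
                                 community = unname(louv$membership),
                                 Q = louv$Q)
  }
  traj <- class_trajectory(assignments)
  traj_rows <- data.frame(subject = subject, group = group,
                          node = rep(rownames(traj), ncol(traj)),
                          segment = rep(seq_len(ncol(traj)),
                                        each = nrow(traj)),
                          class = as.vector(traj))
  list(connectivity = connectivity, assignments = assignments,
       trajectory = traj,
       energy = do.call(rbind, energy),
       alpha_ratios = do.call(rbind, alpha_rows),
       de = do.call(rbind, de_rows),
       communities = do.call(rbind, comm_rows),
       trajectory_rows = traj_rows)
}

#' Run the full decoding pipeline and write its result tables
#'
#' Executes simulate (for scenario presets) or load, band extraction,
#' connectivity, connection-cluster classification, Louvain comparator,
#' differential entropy and group statistics, writing TSV tables plus a
#' JSON run manifest under \code{config$output_dir}:
#' \itemize{
#'   \item \code{connectivity/<subject>_<group>_seg<k>.tsv} - per-segment
#'     matrices, and \code{<group>_mean_seg<k>.tsv} group averages
#'   \item \code{global_energy.tsv}, \code{alpha_ratio.tsv},
#'     \code{de_table.tsv}, \code{communities.tsv}
#'   \item \code{class_trajectory.tsv} - per-subject and group-mean
#'     merge-order classes (group-mean rows have subject
#'     \code{<group>_mean})
#'   \item \code{stats_ranksum.tsv} - two-group rank-sum tests per feature,
#'     segment and (where applicable) region
#'   \item \code{manifest.json}
#' }
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages (default FALSE;
#'   messages go to stderr).
#' @return Invisibly, a list of the assembled tables and the group-mean
#'   class trajectories.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$output_dir
  dir.create(file.path(out, "connectivity"), recursive = TRUE,
             showWarnings = FALSE)
  subjects <- pipeline_subjects(config)
  energy <- ratios <- de <- comms <- traj <- list()
  mean_conn <- list()   # group -> list over segments of running sums
  counts <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject[i]
    grp <- subjects$group[i]
    say("[%s] subject %s (%s)", format(Sys.time() - t0), sid, grp)
    rec <- load_subject(subjects[i, ], config)
    res <- analyze_recording(rec, sid, grp, config)
    for (k in seq_along(res$connectivity)) {
      write_matrix_tsv(res$connectivity[[k]],
                       file.path(out, "connectivity",
                                 sprintf("%s_%s_seg%d.tsv", sid, grp, k)))
      if (is.null(mean_conn[[grp]])) {
        mean_conn[[grp]] <- list()
        counts[[grp]] <- 0L
      }
      if (length(mean_conn[[grp]]) < k)
        mean_conn[[grp]][[k]] <- res$connectivity[[k]]$values * 0
      mean_conn[[grp]][[k]] <- mean_conn[[grp]][[k]] +
        res$connectivity[[k]]$values
    }
    counts[[grp]] <- counts[[grp]] + 1L
    energy[[i]] <- res$energy
    ratios[[i]] <- res$alpha_ratios
    de[[i]] <- res$de
    comms[[i]] <- res$communities
    traj[[i]] <- res$trajectory_rows
  }
  # group-mean connectivity and its classification (the group-level view)
  mean_traj <- list()
  for (grp in names(mean_conn)) {
    asg <- list()
    for (k in seq_along(mean_conn[[grp]])) {
      m <- mean_conn[[grp]][[k]] / counts[[grp]]
      F <- connectivity_matrix(m, rownames(m), k)
      write_matrix_tsv(F, file.path(out, "connectivity",
                                    sprintf("%s_mean_seg%d.tsv", grp, k)))
      dend <- agglomerate(node_vectors(F), linkage = config$linkage)
      asg[[k]] <- assign_classes(dend, config$Z)
    }
    tm <- class_trajectory(asg)
    mean_traj[[grp]] <- tm
    traj[[length(traj) + 1L]] <- data.frame(
      subject = paste0(grp, "_mean"), group = grp,
      node = rep(rownames(tm), ncol(tm)),
      segment = rep(seq_len(ncol(tm)), each = nrow(tm)),
      class = as.vector(tm))
  }
  tables <- list(global_energy = do.call(rbind, energy),
                 alpha_ratio = do.call(rbind, ratios),
                 de_table = do.call(rbind, de),
                 communities = do.call(rbind, comms),
                 class_trajectory = do.call(rbind, traj))
  tables$stats_ranksum <- pipeline_stats(tables, config)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    utils::write.table(tables[[nm]], file.path(out, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- unclass(config)
  manifest$inputs <- if (is.null(config$inputs)) NULL else
    as.list(config$inputs)
  manifest$n_subjects <- nrow(subjects)
  manifest$package_version <- as.character(utils::packageVersion("alphanet"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("[%s] done; tables in %s", format(Sys.time() - t0), out)
  invisible(c(tables, list(mean_trajectory = mean_traj)))
}

pipeline_subjects <- function(config) {
  if (config$scenario == "files") {
    data.frame(subject = config$inputs$subject, group = config$inputs$group,
               path = config$inputs$path, index = NA_integer_,
               stringsAsFactors = FALSE)
  } else {
    presets <- scenario_presets(config$seed,
                                segment_seconds = config$segment_seconds)
    do.call(rbind, lapply(presets, function(cfg) {
      data.frame(subject = sprintf("%s_S%02d", cfg$name,
                                   seq_len(cfg$n_subjects)),
                 group = cfg$name, path = NA_character_,
                 index = seq_len(cfg$n_subjects),
                 stringsAsFactors = FALSE)
    }))
  }
}

load_subject <- function(row, config) {
  if (config$scenario == "files") {
    # a sidecar (or EDF header) declares the rate; config$fs is the fallback
    has_meta <- grepl("\\.edf$", row$path, ignore.case = TRUE) ||
      file.exists(paste0(row$path, ".json"))
    if (has_meta) read_recording(row$path)
    else read_recording(row$path, fs = config$fs)
  } else {
    presets <- scenario_presets(config$seed,
                                segment_seconds = config$segment_seconds)
    simulate_recording(presets[[row$group]], row$index)
  }
}

# Two-group rank-sum tables over global energy, regional alpha ratio and
# regional differential entropy, per segment.
pipeline_stats <- function(tables, config) {
  groups <- unique(tables$global_energy$group)
  if (length(groups) != 2L) return(NULL)
  montage <- default_montage()
  rows <- list()
  add <- function(feature, segment, region, a, b) {
    tst <- rank_sum_test(a, b, alpha_level = config$alpha_level)
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, segment = segment, region = region,
      n1 = tst$n1, n2 = tst$n2, Z = tst$z_stat, p = tst$p_value,
      significant = tst$significant)
  }
  rde_all <- rbind(regional_de(tables$de_table, montage$frontal),
                   regional_de(tables$de_table, montage$parieto_occipital))
  for (k in sort(unique(tables$global_energy$segment))) {
    e <- tables$global_energy
    add("global_energy", k, NA,
        e$energy[e$group == groups[1] & e$segment == k],
        e$energy[e$group == groups[2] & e$segment == k])
    for (region in list(montage$frontal, montage$parieto_occipital)) {
      r <- tables$alpha_ratio
      sel <- r$segment == k & r$region == region$name
      add("alpha_ratio", k, region$name,
          r$ratio[sel & r$group == groups[1]],
          r$ratio[sel & r$group == groups[2]])
      sel <- rde_all$segment == k & rde_all$region == region$name
      add("regional_de", k, region$name,
          rde_all$de[sel & rde_all$group == groups[1]],
          rde_all$de[sel & rde_all$group == groups[2]])
    }
  }
  do.call(rbind, rows)
}
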