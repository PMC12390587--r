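#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks.  [run_pipeline()] rejects
#' configurations containing keys that do not appear here.
#'
#' @param seed global seed.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 0) {
  structure(list(
    seed = seed,
    synth = list(n_subjects = 20, hands = c("LH", "RH"), n_samples = 5,
                 difficulty = "default", size = c(340, 300)),
    segmentation = list(width_stop_factor = 1.8, min_rows = 10, pad = 5,
                        opening_radius = 5, palm_down = TRUE),
    enhancement = list(method = "baseline", bg_sigma = 15, lcn_sigma = 8),
    features = list(sigma = 3,
                    directions = c("transverse", "longitudinal",
                                   "diagonal", "antidiagonal"),
                    erode_margin = 3),
    matching = list(max_shift = NULL, normalization = "min"),
    evaluation = list(target_fmr_pct = 0.1, n_zei = 3,
                      camera = "left", wavelength = "850")
  ), class = "pipeline_config")
}

check_config_keys <- function(config, defaults, path = "") {
  extra <- setdiff(names(config), names(defaults))
  if (length(extra))
    stopf("unknown config key(s): %s", paste0(path, extra, collapse = ", "))
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(config[[k]]))
      check_config_keys(config[[k]], defaults[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with (a subset of) the [default_config()] keys.
#' @param seed seed used for keys the file omits.
#' @return a merged `pipeline_config`.
#' @export
read_config <- function(path, seed = 0) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(seed), user)
}

#' Merge a partial configuration into the defaults
#' @param base a `pipeline_config` (defaults).
#' @param user named list overriding a subset of keys.
#' @return merged `pipeline_config`.
#' @export
merge_config <- function(base, user) {
  check_config_keys(user, base)
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else base[[k]] <- user[[k]]
  }
  base
}

# Segment one rendered sample into labeled, normalized fingers.
# Returns NULL when the sample must be excluded (not exactly 4 fingers, or a
# finger failed normalization / template extraction upstream).
segment_sample <- function(image, hand, seg_cfg) {
  mask <- tryCatch(foreground_mask(image, opening_radius = seg_cfg$opening_radius),
                   error = function(e) NULL)
  if (is.null(mask)) return(NULL)
  res <- extract_fingers(image, mask,
                         width_stop_factor = seg_cfg$width_stop_factor,
                         min_rows = seg_cfg$min_rows, pad = seg_cfg$pad)
  if (!res$complete) return(NULL)
  res <- reorder_fingers(res, hand, palm_down = seg_cfg$palm_down)
  normed <- lapply(res$fingers, function(f)
    tryCatch(normalize_finger(f), error = function(e) NULL))
  if (any(vapply(normed, is.null, logical(1)))) return(NULL)
  res$fingers <- normed
  res
}

# Template for one finger: enhance then extract; NULL on failure.
finger_template <- function(finger, enh_cfg, feat_cfg) {
  tryCatch({
    f <- enhance_veins(finger, method = enh_cfg$method,
                       params = list(bg_sigma = enh_cfg$bg_sigma,
                                     lcn_sigma = enh_cfg$lcn_sigma))
    extract_mc(f, sigma = feat_cfg$sigma, directions = feat_cfg$directions,
               erode_margin = feat_cfg$erode_margin)
  }, error = function(e) NULL)
}

#' Run the full synthetic recognition pipeline
#'
#' Simulates the benchmark dataset, segments and normalizes fingers, extracts
#' maximum-curvature templates for the index, middle and ring fingers, builds
#' per-hand protocols with a dev/eval subject split (sorted subject id, first
#' half dev), scores all genuine and zero-effort-impostor comparisons,
#' evaluates single-finger recognition with dev-to-eval threshold transfer,
#' and fuses the three finger scores per hand with an RBF-SVM.
#'
#' @param config a `pipeline_config` from [default_config()] /
#'   [read_config()].
#' @return list with `manifest`, `scores` (a [score_table()]),
#'   `results` (per protocol: single-finger and fused dev/eval
#'   [evaluate_scores()] results), and `provenance` (the config).
#' @export
run_pipeline <- function(config = default_config()) {
  check_config_keys(config, default_config())
  params <- render_difficulty(config$synth$difficulty)
  samples <- simulate_benchmark(config$synth$n_subjects, config$synth$hands,
                                config$synth$n_samples, params,
                                seed = config$seed, size = config$synth$size)
  # --- segmentation + template extraction -------------------------------
  manifest <- data.frame(subject_id = character(0), hand = character(0),
                         sample_index = integer(0), complete = logical(0))
  templates <- new.env(parent = emptyenv())
  use_fingers <- c("index", "middle", "ring")
  for (smp in samples) {
    seg <- segment_sample(smp$image, smp$hand, config$segmentation)
    ok <- !is.null(seg)
    if (ok) {
      tpl <- list()
      for (f in seg$fingers) {
        if (!f$finger_label %in% use_fingers) next
        t <- finger_template(f, config$enhancement, config$features)
        if (is.null(t)) { ok <- FALSE; break }
        tpl[[f$finger_label]] <- t
      }
      if (ok)
        assign(paste(smp$subject_id, smp$hand, smp$sample_index, sep = "|"),
               tpl, envir = templates)
    }
    manifest <- rbind(manifest, data.frame(
      subject_id = smp$subject_id, hand = smp$hand,
      sample_index = smp$sample_index, complete = ok))
  }
  # --- dev/eval split by sorted subject id ------------------------------
  subjects <- sort(unique(manifest$subject_id))
  dev_subjects <- subjects[seq_len(length(subjects) %/% 2)]
  splits <- list(dev = dev_subjects, eval = setdiff(subjects, dev_subjects))
  # --- protocols, scoring, evaluation, fusion ---------------------------
  all_rows <- list()
  results <- list()
  for (pi in seq_along(config$synth$hands)) {
    hd <- config$synth$hands[pi]
    proto <- protocol_def(hd, config$evaluation$camera,
                          config$evaluation$wavelength)
    split_scores <- list()
    for (sp in names(splits)) {
      mf <- manifest[manifest$subject_id %in% splits[[sp]], , drop = FALSE]
      bp <- build_protocol(mf, proto, n_zei = config$evaluation$n_zei,
                           seed = child_seed(config$seed, 500 + 10 * pi +
                                               match(sp, names(splits))))
      enrol_sample <- setNames(bp$enrolled$sample_index, bp$enrolled$subject_id)
      rows <- list()
      for (i in seq_len(nrow(bp$comparisons))) {
        cmpr <- bp$comparisons[i, ]
        probe_tpl <- get(paste(cmpr$probe_subject, hd, cmpr$probe_sample, sep = "|"),
                         envir = templates)
        enr_tpl <- get(paste(cmpr$enrolled_subject, hd,
                             enrol_sample[[cmpr$enrolled_subject]], sep = "|"),
                       envir = templates)
        for (fl in use_fingers) {
          ms <- match_templates(enr_tpl[[fl]], probe_tpl[[fl]],
                                max_shift = config$matching$max_shift,
                                normalization = config$matching$normalization)
          rows[[length(rows) + 1]] <- data.frame(
            probe_id = paste(cmpr$probe_subject, cmpr$probe_sample, sep = ":"),
            enrolled_id = cmpr$enrolled_subject, finger_label = fl,
            protocol_id = paste(proto$id, sp, sep = ":"),
            score = ms$score, is_genuine = cmpr$is_genuine)
        }
      }
      split_scores[[sp]] <- do.call(rbind, rows)
      all_rows[[length(all_rows) + 1]] <- split_scores[[sp]]
    }
    thr <- threshold_at_fmr(split_scores$dev, config$evaluation$target_fmr_pct)
    single <- list(dev = evaluate_scores(split_scores$dev, thr),
                   eval = evaluate_scores(split_scores$eval, thr))
    fused <- fuse_fingers(fusion_vectors(split_scores$dev),
                          fusion_vectors(split_scores$eval),
                          target_fmr_pct = config$evaluation$target_fmr_pct,
                          seed = child_seed(config$seed, 900 + pi))
    results[[proto$id]] <- list(single = single,
                                fused = fused[c("dev", "eval")],
                                threshold_single = thr,
                                threshold_fused = fused$threshold)
  }
  sc <- do.call(rbind, all_rows)
  scores <- score_table(sc$probe_id, sc$enrolled_id, sc$finger_label,
                        sc$protocol_id, sc$score, sc$is_genuine)
  list(manifest = manifest, scores = scores, results = results,
       provenance = config)
}
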