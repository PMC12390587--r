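#' Canonical verification protocols
#'
#' The eight canonical protocols are the full cross-product of hand (LH/RH),
#' NIR camera (left/right) and NIR wavelength (850/950), named
#' `<Modality>_<Camera>_<NIR>`.
#'
#' @param modality `"LH"` or `"RH"`.
#' @param camera `"left"` or `"right"`.
#' @param wavelength `"850"` or `"950"`.
#' @return Object of class `protocol_def` with an `id` field.
#' @export
protocol_def <- function(modality, camera = "left", wavelength = "850") {
  stopifnot(modality %in% c("LH", "RH"), camera %in% c("left", "right"),
            as.character(wavelength) %in% c("850", "950"))
  structure(list(modality = modality, camera = camera,
                 wavelength = as.character(wavelength),
                 id = paste(modality, camera, wavelength, sep = "_")),
            class = "protocol_def")
}

#' All eight canonical protocols
#' @return list of [protocol_def()] objects P1..P8.
#' @export
all_protocols <- function() {
  grid <- expand.grid(wavelength = c("850", "950"), camera = c("left", "right"),
                      modality = c("LH", "RH"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    protocol_def(grid$modality[i], grid$camera[i], grid$wavelength[i]))
}

#' Build enrolment/probe sets and the comparison list for a protocol
#'
#' Samples whose segmentation did not find exactly four fingers are excluded.
#' For each identity the enrolment-designated sample is the first remaining
#' sample index; all other samples become probes.  Every probe is paired with
#' its genuine identity and with 3 distinct zero-effort-impostor (ZEI)
#' identities drawn without replacement from the other enrolled identities,
#' using the given seed (so the comparison list is reproducible).
#'
#' @param manifest data frame with columns `subject_id`, `hand`,
#'   `sample_index`, `complete` (logical: four-finger segmentation
#'   succeeded).
#' @param protocol a [protocol_def()]; only `modality` filters the manifest
#'   (camera/wavelength select the image channel upstream).
#' @param n_zei ZEI comparisons per probe (default 3).
#' @param seed RNG seed for the ZEI draw.
#' @return list with `enrolled` and `probes` data frames and `comparisons`
#'   (probe_subject, probe_sample, enrolled_subject, is_genuine).
#' @export
build_protocol <- function(manifest, protocol, n_zei = 3, seed = 0) {
  stopifnot(inherits(protocol, "protocol_def"))
  m <- manifest[manifest$hand == protocol$modality & manifest$complete, , drop = FALSE]
  if (nrow(m) == 0) stopf("protocol error: no usable samples for %s", protocol$id)
  m <- m[order(m$subject_id, m$sample_index), ]
  first_idx <- !duplicated(m$subject_id)
  enrolled <- m[first_idx, c("subject_id", "sample_index")]
  probes <- m[!first_idx, c("subject_id", "sample_index")]
  if (nrow(enrolled) < n_zei + 1)
    stopf("protocol error: %d enrolled identities cannot support %d ZEI comparisons",
          nrow(enrolled), n_zei)
  no_probe <- setdiff(enrolled$subject_id, probes$subject_id)
  if (length(no_probe))
    warnf("%d enrolled identit(ies) have zero probes", length(no_probe))
  comp <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(probes)), function(i) {
      sid <- probes$subject_id[i]
      others <- setdiff(enrolled$subject_id, sid)
      zei <- sample(others, n_zei, replace = FALSE)
      data.frame(probe_subject = sid, probe_sample = probes$sample_index[i],
                 enrolled_subject = c(sid, zei),
                 is_genuine = c(TRUE, rep(FALSE, n_zei)))
    })
    do.call(rbind, rows)
  })
  list(protocol = protocol, enrolled = enrolled, probes = probes,
       comparisons = comp)
}

#' Decision threshold at a target false-match rate
#'
#' Scans the sorted grid of dev-set impostor scores and returns the smallest
#' threshold whose FMR (fraction of impostors scoring at or above it, decision
#' rule: accept iff `score >= threshold`) does not exceed the target.  If the
#' target is below the resolution of the impostor set (`100 / n_impostor`),
#' every threshold above the maximum impostor score yields the same dev-set
#' rates (FMR = 0); the max-margin representative is returned: the midpoint
#' between the largest impostor score and the smallest genuine score above
#' it (or a value just above the impostor maximum when no genuine score lies
#' there).  This stabilizes the dev-to-eval threshold transfer.
#'
#' @param scores a [score_table()] (or data frame with `score`,
#'   `is_genuine`) from the dev set.
#' @param target_fmr_pct target FMR in percent (default 0.1).
#' @return the threshold (numeric scalar).
#' @export
threshold_at_fmr <- function(scores, target_fmr_pct = 0.1) {
  imp <- sort(scores$score[!scores$is_genuine])
  if (length(imp) == 0) stopf("dev set contains no impostor scores")
  n <- length(imp)
  cand <- unique(imp)
  # FMR at threshold t = 100 * (# imp >= t) / n; for t = cand[i] that is
  # 100 * (n - (first index of cand[i] in imp) + 1) / n
  first_ge <- findInterval(cand, imp, left.open = TRUE) + 1
  fmr <- 100 * (n - first_ge + 1) / n
  ok <- which(fmr <= target_fmr_pct)
  if (length(ok)) return(cand[ok[1]])
  gen_above <- scores$score[scores$is_genuine & scores$score > imp[n]]
  if (length(gen_above)) (imp[n] + min(gen_above)) / 2 else next_up(imp[n])
}

#' Evaluate a labeled score set at a threshold
#'
#' FMR is the percentage of impostor scores at or above the threshold, FNMR
#' the percentage of genuine scores below it, and HTER their mean.
#'
#' @param scores a [score_table()] (or data frame with `score`, `is_genuine`).
#' @param threshold decision threshold (accept iff `score >= threshold`).
#' @return Object of class `eval_result` with `fmr_pct`, `fnmr_pct`,
#'   `hter_pct`, `threshold`, `n_genuine`, `n_impostor`.
#' @export
evaluate_scores <- function(scores, threshold) {
  gen <- scores$score[scores$is_genuine]
  imp <- scores$score[!scores$is_genuine]
  if (length(gen) == 0 || length(imp) == 0)
    stopf("undefined-rate error: need both genuine and impostor scores")
  fmr <- 100 * mean(imp >= threshold)
  fnmr <- 100 * mean(gen < threshold)
  structure(list(fmr_pct = fmr, fnmr_pct = fnmr,
                 hter_pct = 0.5 * (fmr + fnmr), threshold = threshold,
                 n_genuine = length(gen), n_impostor = length(imp)),
            class = "eval_result")
}

#' Half total error rate from printed FMR/FNMR percentages
#'
#' `HTER = 0.5 * (FMR + FNMR)`.
#'
#' @param fmr_pct,fnmr_pct rates in percent.
#' @return HTER in percent.
#' @export
hter <- function(fmr_pct, fnmr_pct) 0.5 * (fmr_pct + fnmr_pct)

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: FMR %.2f%%  FNMR %.2f%%  HTER %.2f%%  (thr %.6g; %d genuine / %d impostor)\n",
              x$fmr_pct, x$fnmr_pct, x$hter_pct, x$threshold,
              x$n_genuine, x$n_impostor))
  invisible(x)
}

#' Build per-hand fusion vectors from a finger-level score table
#'
#' Collapses the finger-level scores of each (probe, enrolled) hand pair into
#' a 3-vector (index, middle, ring).  Pairs missing any of the three finger
#' scores are excluded.
#'
#' @param scores a [score_table()] restricted to one protocol.
#' @return data frame with columns `probe_id`, `enrolled_id`, `s_index`,
#'   `s_middle`, `s_ring`, `is_genuine`.
#' @export
fusion_vectors <- function(scores) {
  keep <- scores$finger_label %in% c("index", "middle", "ring")
  s <- scores[keep, , drop = FALSE]
  key <- paste(s$probe_id, s$enrolled_id, sep = "|")
  out <- lapply(split(seq_len(nrow(s)), key), function(i) {
    sub <- s[i, ]
    if (!all(c("index", "middle", "ring") %in% sub$finger_label)) return(NULL)
    data.frame(probe_id = sub$probe_id[1], enrolled_id = sub$enrolled_id[1],
               s_index = sub$score[sub$finger_label == "index"][1],
               s_middle = sub$score[sub$finger_label == "middle"][1],
               s_ring = sub$score[sub$finger_label == "ring"][1],
               is_genuine = sub$is_genuine[1])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out[order(out$probe_id, out$enrolled_id), ]
}

#' Fuse per-finger scores into hand decisions with an RBF-kernel SVM
#'
#' Fits a two-class SVM with radial basis kernel on the dev-set 3-D fusion
#' vectors (genuine vs. zero-effort impostor), produces continuous
#' classification scores (signed decision values, oriented so genuine scores
#' are high) for both sets, selects the classification-score threshold on the
#' dev set at the target FMR, and evaluates both sets at that threshold.
#'
#' @param dev_vectors,eval_vectors data frames from [fusion_vectors()].
#' @param target_fmr_pct dev-set FMR ceiling in percent (default 0.1).
#' @param cost,gamma SVM hyperparameters (library defaults when `NULL`).
#' @param normalize_scores scale the three finger-score columns to dev-set
#'   z-scores before fitting (default FALSE: raw scores).
#' @param seed RNG seed (the fit itself is deterministic; the seed guards any
#'   library-internal randomization).
#' @return list with `dev` and `eval` [evaluate_scores()] results, the
#'   fitted `model` and the `threshold`.
#' @export
fuse_fingers <- function(dev_vectors, eval_vectors, target_fmr_pct = 0.1,
                         cost = NULL, gamma = NULL, normalize_scores = FALSE,
                         seed = 0) {
  cols <- c("s_index", "s_middle", "s_ring")
  if (!all(cols %in% names(dev_vectors)))
    stopf("fusion vectors need columns %s", paste(cols, collapse = ", "))
  if (length(unique(dev_vectors$is_genuine)) < 2)
    stopf("fit error: dev set contains a single class")
  Xd <- as.matrix(dev_vectors[, cols])
  Xe <- as.matrix(eval_vectors[, cols])
  if (normalize_scores) {
    mu <- colMeans(Xd); sdv <- apply(Xd, 2, sd)
    sdv[sdv == 0] <- 1
    Xd <- sweep(sweep(Xd, 2, mu), 2, sdv, "/")
    Xe <- sweep(sweep(Xe, 2, mu), 2, sdv, "/")
  }
  y <- factor(ifelse(dev_vectors$is_genuine, "genuine", "impostor"),
              levels = c("genuine", "impostor"))
  wts <- 100 / table(y)
  args <- list(x = Xd, y = y, kernel = "radial", scale = FALSE,
               class.weights = wts, probability = FALSE)
  if (!is.null(cost)) args$cost <- cost
  if (!is.null(gamma)) args$gamma <- gamma
  model <- with_seed(seed, do.call(e1071::svm, args))
  dec <- function(X) {
    d <- attr(predict(model, X, decision.values = TRUE), "decision.values")[, 1]
    as.numeric(d)
  }
  dd <- dec(Xd); de <- dec(Xe)
  # orient decision values so genuine scores are high
  if (mean(dd[dev_vectors$is_genuine]) < mean(dd[!dev_vectors$is_genuine])) {
    dd <- -dd; de <- -de
  }
  dev_scores <- data.frame(score = dd, is_genuine = dev_vectors$is_genuine)
  eval_scores <- data.frame(score = de, is_genuine = eval_vectors$is_genuine)
  thr <- threshold_at_fmr(dev_scores, target_fmr_pct)
  list(dev = evaluate_scores(dev_scores, thr),
       eval = evaluate_scores(eval_scores, thr),
       model = model, threshold = thr)
}
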